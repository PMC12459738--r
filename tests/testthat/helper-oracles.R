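# Independent oracles and small fixture builders used across the suite.

# Dense multivariate normal log-density computed the long way (solve +
# determinant), independent of the package's Cholesky/pseudo-inverse path.
# Applies the same diagonal jitter so the two are comparable exactly.
dense_mvn_loglik <- function(y_row, mu, Sigma, jitter = 1e-4) {
  S <- Sigma
  diag(S) <- diag(S) + jitter
  r <- y_row - mu
  k <- length(mu)
  -0.5 * (k * log(2 * pi) + log(det(S)) + drop(t(r) %*% solve(S) %*% r))
}

# A small complete-data trial-like list for likelihood tests.
tiny_dataset <- function(n = 8, seed = 99, basis = time_basis(c(0, 1, 2, 3)),
                         params = lgcm_params(b00 = 5, b0exp = 1,
                                              b0female = -0.5, b10 = -1,
                                              b1exp = -0.3, b1female = 0.2,
                                              var_e0 = 4, var_e1 = 0.5,
                                              cov_e01 = 0.4, var_e2 = 2)) {
  set.seed(seed)
  g_exp <- rep(c(0, 1), length.out = n)
  g_female <- rep(c(1, 1, 0), length.out = n)
  y <- t(vapply(seq_len(n), function(i) {
    mom <- implied_moments(params, g_exp[i], g_female[i], basis)
    drop(mom$mean + t(chol(mom$cov + diag(1e-8, length(mom$mean)))) %*%
           rnorm(length(mom$mean)))
  }, numeric(length(basis$loadings))))
  list(y = y, g_exp = g_exp, g_female = g_female, params = params,
       basis = basis)
}

# Random positive-semidefinite 2x2 random-effect matrices for property
# tests.
random_psi_params <- function(seed) {
  set.seed(seed)
  sd0 <- runif(1, 0.1, 5)
  sd1 <- runif(1, 0.1, 3)
  rho <- runif(1, -0.99, 0.99)
  lgcm_params(b00 = rnorm(1, 0, 5), b0exp = rnorm(1), b0female = rnorm(1),
              b10 = rnorm(1), b1exp = rnorm(1), b1female = rnorm(1),
              var_e0 = sd0^2, var_e1 = sd1^2, cov_e01 = rho * sd0 * sd1,
              var_e2 = runif(1, 0, 4))
}

# Small generated trial shared by io/pipeline tests.
small_trial <- function(seed = 5, n = 60) {
  generate_trial(generator_config(n_exp = n, n_wait = n, seed = seed))
}
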