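#' Latent growth curve model parameters
#'
#' The model gives participant `i` at wave `t` the outcome
#' `Y[it] = B0[i] + B1[i] * F[t] + e[it]`, where the latent intercept and
#' slope are `B0[i] = b00 + b0exp * g_exp + b0female * g_female + u0[i]` and
#' `B1[i] = b10 + b1exp * g_exp + b1female * g_female + u1[i]`, with
#' `(u0, u1)` bivariate normal with variances `var_e0`, `var_e1` and
#' covariance `cov_e01`, and residuals `e[it] ~ N(0, var_e2)` shared across
#' waves. `b1exp` is the intervention effect on the rate of change and is the
#' coefficient of primary interest.
#'
#' @param b00,b0exp,b0female Fixed effects on the latent intercept: grand
#'   mean, experimental-arm offset, female offset (outcome units).
#' @param b10,b1exp,b1female Fixed effects on the latent slope (outcome units
#'   per unit of the time loading `F[t]`).
#' @param var_e0,var_e1 Variances of the random intercept and slope (>= 0).
#' @param cov_e01 Intercept--slope covariance; the 2x2 random-effect matrix
#'   must be positive semidefinite.
#' @param var_e2 Residual variance (>= 0), shared across waves.
#' @return An object of class `lgcm_params`.
#' @examples
#' lgcm_params(b00 = 8, b10 = -0.4, var_e0 = 25, var_e1 = 1, var_e2 = 10)
#' @export
lgcm_params <- function(b00 = 0, b0exp = 0, b0female = 0,
                        b10 = 0, b1exp = 0, b1female = 0,
                        var_e0 = 0, var_e1 = 0, cov_e01 = 0, var_e2 = 0) {
  p <- list(b00 = b00, b0exp = b0exp, b0female = b0female,
            b10 = b10, b1exp = b1exp, b1female = b1female,
            var_e0 = var_e0, var_e1 = var_e1, cov_e01 = cov_e01,
            var_e2 = var_e2)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (var_e0 < 0 || var_e1 < 0 || var_e2 < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  # PSD check with a small tolerance for square-root round-off
  if (cov_e01^2 > var_e0 * var_e1 * (1 + 1e-10) + 1e-12) {
    stop("random-effect matrix [[var_e0, cov_e01], [cov_e01, var_e1]] ",
         "is not positive semidefinite", call. = FALSE)
  }
  structure(p, class = "lgcm_params")
}

#' @export
print.lgcm_params <- function(x, ...) {
  cat("LGCM parameters\n")
  cat("  intercept: b00 =", format(x$b00), " b0exp =", format(x$b0exp),
      " b0female =", format(x$b0female), "\n")
  cat("  slope:     b10 =", format(x$b10), " b1exp =", format(x$b1exp),
      " b1female =", format(x$b1female), "\n")
  cat("  variances: var_e0 =", format(x$var_e0), " var_e1 =",
      format(x$var_e1), " cov_e01 =", format(x$cov_e01), " var_e2 =",
      format(x$var_e2), "\n")
  invisible(x)
}

# Random-effect covariance matrix Psi.
psi_matrix <- function(params) {
  matrix(c(params$var_e0, params$cov_e01, params$cov_e01, params$var_e1),
         2, 2)
}

#' Model-implied mean vector and covariance matrix
#'
#' For given covariates the implied moments of the wave-level outcome vector
#' are `mu[t] = (b00 + b0exp g_exp + b0female g_female) +
#' (b10 + b1exp g_exp + b1female g_female) F[t]` and
#' `Sigma = Lambda Psi Lambda' + var_e2 I`, where row `t` of `Lambda` is
#' `(1, F[t])` and `Psi` is the random-effect covariance matrix.
#'
#' @param params An [lgcm_params()] object.
#' @param g_exp,g_female 0/1 covariate indicators (experimental arm, female).
#' @param basis A [time_basis()] object.
#' @return List with `mean` (length `T`) and `cov` (`T x T`, symmetric PSD).
#' @examples
#' b <- time_basis(c(0, 1, 2, 3))
#' implied_moments(lgcm_params(b00 = 5, b10 = -1), 0, 0, b)$mean
#' @export
implied_moments <- function(params, g_exp, g_female, basis) {
  stopifnot(inherits(params, "lgcm_params"), inherits(basis, "time_basis"))
  if (!g_exp %in% c(0, 1) || !g_female %in% c(0, 1)) {
    stop("`g_exp` and `g_female` must be 0/1 indicators", call. = FALSE)
  }
  f <- basis$loadings
  mu <- (params$b00 + params$b0exp * g_exp + params$b0female * g_female) +
    (params$b10 + params$b1exp * g_exp + params$b1female * g_female) * f
  Lambda <- cbind(1, f)
  Sigma <- Lambda %*% psi_matrix(params) %*% t(Lambda) +
    params$var_e2 * diag(length(f))
  Sigma <- (Sigma + t(Sigma)) / 2  # enforce exact symmetry
  list(mean = mu, cov = Sigma)
}

# ---------------------------------------------------------------------------
# FIML machinery. The observed-data log-likelihood sums, over participants,
# the multivariate normal log-density of each participant's observed
# sub-vector under the corresponding sub-mean and sub-covariance. For speed
# the participants are grouped by missingness pattern so the sub-matrix is
# factorized once per pattern; means are vectorized over participants.

# Precompute the grouping used by the fast likelihood path.
fiml_groups <- function(y) {
  obs <- !is.na(y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  split(seq_len(nrow(y)), key)
}

# Core evaluator. y: n x T outcome matrix with NA for missing; g_exp,
# g_female: length-n indicator vectors; groups from fiml_groups(y).
fiml_core <- function(y, g_exp, g_female, params, basis,
                      jitter = 1e-4, groups = NULL, pointwise = FALSE) {
  f <- basis$loadings
  Tn <- length(f)
  n <- nrow(y)
  Lambda <- cbind(1, f)
  Sigma <- Lambda %*% psi_matrix(params) %*% t(Lambda) +
    params$var_e2 * diag(Tn)
  mu_int <- params$b00 + params$b0exp * g_exp + params$b0female * g_female
  mu_slp <- params$b10 + params$b1exp * g_exp + params$b1female * g_female
  R <- y - (matrix(mu_int, n, Tn) + outer(mu_slp, f))
  if (is.null(groups)) groups <- fiml_groups(y)
  ll <- numeric(n)
  for (key in names(groups)) {
    rows <- groups[[key]]
    obs <- which(strsplit(key, "")[[1]] == "1")
    k <- length(obs)
    if (k == 0L) next  # all-missing participants contribute exactly 0
    S <- Sigma[obs, obs, drop = FALSE]
    diag(S) <- diag(S) + jitter
    dec <- safe_inverse_logdet(S)
    Rsub <- R[rows, obs, drop = FALSE]
    q <- rowSums((Rsub %*% dec$inv) * Rsub)
    ll[rows] <- -0.5 * (dec$rank * log(2 * pi) + dec$logdet + q)
  }
  if (pointwise) ll else sum(ll)
}

#' Observed-data (FIML) log-likelihood of a latent growth curve model
#'
#' Sums each participant's multivariate normal log-density over the waves
#' they actually completed, so incomplete participants contribute their
#' observed sub-vector instead of being dropped (full-information maximum
#' likelihood). Before inversion a jitter of `1e-4` is added to the diagonal
#' of every observed sub-covariance to keep it positive; if the jittered
#' matrix is still singular, an eigenvalue pseudo-inverse and
#' pseudo-determinant (tolerance `1e-12`, null directions dropped) are used
#' so the likelihood remains finite. Participants with no observed waves
#' contribute exactly 0.
#'
#' @param y Numeric matrix, participants x waves, `NA` marking missing waves.
#' @param g_exp,g_female 0/1 covariate vectors, one entry per participant.
#' @param params An [lgcm_params()] object.
#' @param basis A [time_basis()] whose length matches `ncol(y)`.
#' @param jitter Diagonal jitter added before inversion (default `1e-4`).
#' @param pointwise If `TRUE`, return the per-participant log-likelihood
#'   vector instead of its sum.
#' @return Scalar log-likelihood, or a length-`nrow(y)` vector.
#' @export
fiml_loglik <- function(y, g_exp, g_female, params, basis,
                        jitter = 1e-4, pointwise = FALSE) {
  stopifnot(inherits(params, "lgcm_params"), inherits(basis, "time_basis"))
  y <- as.matrix(y)
  if (ncol(y) != length(basis$loadings)) {
    stop("`y` has ", ncol(y), " wave columns but the basis has ",
         length(basis$loadings), " loadings", call. = FALSE)
  }
  n <- nrow(y)
  if (length(g_exp) == 1L) g_exp <- rep(g_exp, n)
  if (length(g_female) == 1L) g_female <- rep(g_female, n)
  if (length(g_exp) != n || length(g_female) != n) {
    stop("covariate vectors must match the number of rows of `y`",
         call. = FALSE)
  }
  if (!all(g_exp %in% c(0, 1)) || !all(g_female %in% c(0, 1))) {
    stop("`g_exp` and `g_female` must be 0/1 indicators", call. = FALSE)
  }
  if (!any(!is.na(y))) {
    stop("at least one observed outcome value is required", call. = FALSE)
  }
  fiml_core(y, g_exp, g_female, params, basis, jitter = jitter,
            pointwise = pointwise)
}

#' Extract an outcome matrix and covariates from a trial data frame
#'
#' Pulls the four wave columns of one outcome out of a wide trial data frame
#' (as produced by [generate_trial()] or [read_trial_csv()]) together with
#' the arm and gender indicators the growth model uses. Behaviour-count
#' outcomes (`"bell_log2"`, `"custom_log2"`) are log2(count + 1) transformed
#' on extraction.
#'
#' @param data Wide trial data frame.
#' @param outcome One of `"qids"`, `"lsas_v"`, `"lsas_p"`, `"bell_log2"`,
#'   `"custom_log2"`.
#' @return List with `y` (n x 4 matrix), `g_exp`, `g_female`.
#' @export
outcome_matrix <- function(data, outcome = c("qids", "lsas_v", "lsas_p",
                                             "bell_log2", "custom_log2")) {
  outcome <- match.arg(outcome)
  stem <- switch(outcome, qids = "qids", lsas_v = "lsas_v",
                 lsas_p = "lsas_p", bell_log2 = "bell",
                 custom_log2 = "custom")
  cols <- paste0(stem, "_w", 1:4)
  if (!all(cols %in% names(data))) {
    stop("data frame lacks columns: ",
         paste(setdiff(cols, names(data)), collapse = ", "), call. = FALSE)
  }
  y <- as.matrix(data[cols])
  if (outcome %in% c("bell_log2", "custom_log2")) {
    y[!is.na(y)] <- log2p1(y[!is.na(y)])
  }
  list(y = unname(y),
       g_exp = as.integer(data$arm == "experimental"),
       g_female = as.integer(data$female))
}
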