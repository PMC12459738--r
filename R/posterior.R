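# Posterior sampling of the growth model over the same FIML likelihood used
# for point estimation, with convergence and predictive-fit diagnostics
# (split R-hat, WAIC, importance-sampling LOO).

# Log-prior on the internal parameter scale, including Jacobians of the
# log-SD and atanh-correlation transforms. Defaults: normal(0, 10*sd(y)) on
# fixed effects, half-normal(0, 5*sd(y)) on SD-scale variance parameters,
# uniform(-1, 1) on the random-effect correlation.
log_prior_internal <- function(theta, map, sy,
                               fe_scale = 10, sd_scale = 5) {
  lp <- 0
  for (j in seq_along(theta)) {
    nm <- map$free_internal[j]
    v <- theta[j]
    if (nm %in% fixed_effect_names) {
      lp <- lp + stats::dnorm(v, 0, fe_scale * sy, log = TRUE)
    } else if (nm %in% c("lsd0", "lsd1", "lsdr")) {
      s <- exp(v)  # half-normal density on sd, plus Jacobian ds/dlsd = s
      lp <- lp + log(2) + stats::dnorm(s, 0, sd_scale * sy, log = TRUE) + v
    } else if (nm == "z01") {
      # uniform(-1,1) on the correlation; Jacobian dr/dz = 1 - tanh(z)^2
      lp <- lp + log1p(-tanh(v)^2) - log(2)
    }
  }
  lp
}

#' Sample the growth-model posterior by adaptive random-walk Metropolis
#'
#' Targets `prior x exp(FIML log-likelihood)` with a Haario-style adaptive
#' random-walk Metropolis sampler: during burn-in the proposal covariance is
#' adapted to the chain history (scaled by `2.38^2 / d`) and the global step
#' size tuned toward a 0.234 acceptance rate; both are frozen afterwards.
#' Retained draws are thinned, and the per-participant log-likelihood is
#' recorded at every retained draw for WAIC/LOO. Each chain's RNG stream is
#' seeded deterministically from `seed`, so runs are reproducible.
#'
#' Priors default to normal(0, 10 sd(y)) on fixed effects, half-normal(0,
#' 5 sd(y)) on SD-scale variance parameters, and uniform(-1, 1) on the
#' intercept--slope correlation; `priors` can override the two scale
#' multipliers.
#'
#' @inheritParams fit_ml
#' @param priors Optional list with elements `fe_scale` and/or `sd_scale`
#'   overriding the prior scale multipliers.
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Post-burn-in iterations per chain.
#' @param burn Burn-in (adaptation) iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` uses `seed + c - 1` unless
#'   `chain_seeds` is given.
#' @param chain_seeds Optional explicit per-chain seeds.
#' @param init Optional named internal-scale start vector (defaults to the
#'   FIML starting values).
#' @return An object of class `lgcm_posterior`: `draws` (list of retained
#'   draw matrices per chain, natural-scale columns), `rhat` (per-parameter
#'   split R-hat), `pointwise_loglik` (retained draws x participants),
#'   `accept_rate`, `waic`, `loo`, and bookkeeping fields.
#' @export
sample_posterior <- function(data, outcome = NULL, basis = time_basis(),
                             spec = lgcm_spec(), fixed = NULL,
                             priors = NULL, n_chains = 2, n_iter = 2000,
                             burn = 2000, thin = 5, seed = 1,
                             chain_seeds = NULL, jitter = 1e-4,
                             init = NULL) {
  if (n_chains < 2) stop("`n_chains` must be >= 2", call. = FALSE)
  if (is.data.frame(data)) {
    if (is.null(outcome)) {
      stop("supply `outcome` when `data` is a data frame", call. = FALSE)
    }
    data <- outcome_matrix(data, outcome)
  }
  y <- as.matrix(data$y)
  g_exp <- data$g_exp
  g_female <- data$g_female
  map <- build_parmap(spec, fixed)
  groups <- fiml_groups(y)
  sy <- stats::sd(as.numeric(y), na.rm = TRUE)
  if (!is.finite(sy) || sy <= 0) sy <- 1
  fe_scale <- (priors$fe_scale %||% 10)
  sd_scale <- (priors$sd_scale %||% 5)
  d <- length(map$free_internal)

  log_post <- function(theta) {
    p <- tryCatch(theta_to_params(theta, map), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    ll <- fiml_core(y, g_exp, g_female, p, basis, jitter = jitter,
                    groups = groups)
    if (!is.finite(ll)) return(-Inf)
    ll + log_prior_internal(theta, map, sy, fe_scale, sd_scale)
  }

  theta0 <- init %||% init_theta(map, y)
  names(theta0) <- map$free_internal
  lp0 <- log_post(theta0)
  if (!is.finite(lp0)) {
    stop("posterior is not finite at the initial values (",
         paste(map$free_internal, collapse = ", "),
         "); check the data and any `fixed` values", call. = FALSE)
  }
  if (is.null(chain_seeds)) chain_seeds <- seed + seq_len(n_chains) - 1L

  n_keep <- floor(n_iter / thin)
  draws <- vector("list", n_chains)
  pw <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)

  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    theta <- theta0
    lp <- log_post(theta)
    log_scale <- log(0.1)
    prop_chol <- diag(d) # updated from history during burn-in
    run_mean <- theta
    run_cov <- diag(1e-4, d)
    kept <- matrix(NA_real_, n_keep, d)
    kept_pw <- matrix(NA_real_, n_keep, nrow(y))
    n_acc <- 0L
    k <- 0L
    total <- burn + n_iter
    for (it in seq_len(total)) {
      step <- exp(log_scale) * drop(crossprod(prop_chol, stats::rnorm(d)))
      cand <- theta + step
      lp_cand <- log_post(cand)
      if (is.finite(lp_cand) &&
          log(stats::runif(1)) < lp_cand - lp) {
        theta <- cand
        lp <- lp_cand
        if (it > burn) n_acc <- n_acc + 1L
        acc <- 1
      } else acc <- 0
      if (it <= burn) {
        # Robbins-Monro scale adaptation toward 0.234 acceptance
        log_scale <- log_scale + (acc - 0.234) / sqrt(it)
        # running covariance of the chain history (Haario adaptation)
        dlt <- theta - run_mean
        run_mean <- run_mean + dlt / (it + 1)
        run_cov <- run_cov * (it / (it + 1)) +
          tcrossprod(dlt) * (it / (it + 1)^2)
        if (it >= 50 && it %% 25 == 0) {
          C <- (2.38^2 / d) * (run_cov + diag(1e-8, d))
          ch_try <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(ch_try)) {
            prop_chol <- ch_try
            log_scale <- 0
          }
        }
      } else if ((it - burn) %% thin == 0) {
        k <- k + 1L
        kept[k, ] <- theta
        p <- theta_to_params(theta, map)
        kept_pw[k, ] <- fiml_core(y, g_exp, g_female, p, basis,
                                  jitter = jitter, groups = groups,
                                  pointwise = TRUE)
      }
    }
    # report draws on the natural scale
    p_nat <- length(map$free_natural)
    nat <- vapply(seq_len(nrow(kept)), function(s) {
      th <- kept[s, ]
      names(th) <- map$free_internal
      unlist(theta_to_params(th, map))[map$free_natural]
    }, numeric(p_nat))
    nat <- matrix(nat, ncol = p_nat, byrow = TRUE,
                  dimnames = list(NULL, map$free_natural))
    draws[[ch]] <- nat
    pw[[ch]] <- kept_pw
    acc_rates[ch] <- n_acc / n_iter
  }

  pointwise <- do.call(rbind, pw)
  structure(list(draws = draws, rhat = gelman_rubin(draws),
                 pointwise_loglik = pointwise,
                 accept_rate = acc_rates, waic = waic(pointwise),
                 loo = loo(pointwise), n_chains = n_chains,
                 n_iter = n_iter, burn = burn, thin = thin,
                 seed = seed, map = map),
            class = "lgcm_posterior")
}

#' @export
print.lgcm_posterior <- function(x, digits = 3, ...) {
  cat("Growth-model posterior:", x$n_chains, "chains x",
      nrow(x$draws[[1]]), "retained draws (thin", x$thin, ")\n")
  cat("  acceptance:", paste(round(x$accept_rate, 2), collapse = ", "), "\n")
  all_draws <- do.call(rbind, x$draws)
  tab <- data.frame(mean = colMeans(all_draws),
                    sd = apply(all_draws, 2, stats::sd),
                    rhat = round(x$rhat, 4))
  print(round(tab, digits))
  cat("WAIC (deviance scale):", round(x$waic["waic"], 1),
      "  LOO:", round(x$loo["looic"], 1), "\n")
  invisible(x)
}

#' Split-chain Gelman--Rubin convergence diagnostic
#'
#' Each chain is split in half and, per parameter, the potential scale
#' reduction factor `R-hat = sqrt(((n-1)/n W + B/n) / W)` is computed from
#' the between- (`B`) and within- (`W`) split-chain variances. Chains with
#' zero within variance but nonzero between variance yield `Inf`; chains
#' that are all constant at the same value yield 1.
#'
#' @param draws List of draw matrices (iterations x parameters), one per
#'   chain, or a single matrix treated as columns = parameters only if a
#'   list is not supplied.
#' @return Named vector of per-parameter R-hat values.
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- list(draws)
  if (length(draws) < 2 && nrow(draws[[1]]) < 4) {
    stop("need >= 2 chains or enough draws to split", call. = FALSE)
  }
  # split each chain in half
  halves <- list()
  for (ch in draws) {
    n <- nrow(ch)
    if (n < 4) stop("each chain needs >= 4 draws", call. = FALSE)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  p <- ncol(halves[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    xs <- lapply(halves, function(h) h[, j])
    W <- mean(vapply(xs, stats::var, numeric(1)))
    B <- n * stats::var(vapply(xs, mean, numeric(1)))
    if (W == 0) {
      out[j] <- if (B > 0) Inf else 1
    } else {
      out[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(out) <- colnames(draws[[1]])
  out
}

#' Widely applicable information criterion (WAIC)
#'
#' From a pointwise log-likelihood matrix (draws x participants):
#' `elpd_waic = sum_i [ log mean_s exp(ll_si) - var_s(ll_si) ]`, with
#' `p_waic` the summed variance penalty and the conventional deviance-scale
#' value `-2 * elpd_waic`.
#'
#' @param pointwise_loglik Matrix of log-likelihood values, rows = posterior
#'   draws, columns = participants.
#' @return Named vector: `elpd_waic`, `p_waic`, `waic` (deviance scale).
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) {
    stop("pointwise log-likelihood contains non-finite values",
         call. = FALSE)
  }
  lpd <- apply(ll, 2, log_mean_exp)
  p_i <- if (nrow(ll) > 1) apply(ll, 2, stats::var) else numeric(ncol(ll))
  elpd <- sum(lpd - p_i)
  c(elpd_waic = elpd, p_waic = sum(p_i), waic = -2 * elpd)
}

#' Importance-sampling leave-one-out cross-validation (LOO)
#'
#' Per participant the LOO predictive density is estimated by importance
#' sampling with weights `1 / p(y_i | theta_s)`, truncated at
#' `S^(3/4)` times the mean weight to control variance. Participants whose
#' largest normalized weight exceeds 0.7 are flagged as unstable.
#'
#' @inheritParams waic
#' @return Named vector `elpd_loo`, `p_loo`, `looic` (deviance scale), with
#'   attribute `unstable` listing flagged participant indices.
#' @export
loo <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) {
    stop("pointwise log-likelihood contains non-finite values",
         call. = FALSE)
  }
  S <- nrow(ll)
  elpd_i <- numeric(ncol(ll))
  unstable <- integer(0)
  for (i in seq_len(ncol(ll))) {
    l <- ll[, i]
    lw <- -l                                # log raw weights
    lw_bar <- log_mean_exp(lw)
    lw_trunc <- pmin(lw, lw_bar + 0.75 * log(S))
    elpd_i[i] <- log_sum_exp(lw_trunc + l) - log_sum_exp(lw_trunc)
    wmax <- exp(max(lw_trunc) - log_sum_exp(lw_trunc))
    if (S > 1 && wmax > 0.7) unstable <- c(unstable, i)
  }
  lpd <- apply(ll, 2, log_mean_exp)
  elpd <- sum(elpd_i)
  structure(c(elpd_loo = elpd, p_loo = sum(lpd - elpd_i),
              looic = -2 * elpd),
            unstable = unstable)
}
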