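# Point estimation of the growth model by bounded quasi-Newton (L-BFGS-B)
# maximization of the FIML log-likelihood.
#
# Internal parameterization: fixed effects are optimized on their natural
# scale; variance components are optimized as log standard deviations and
# the intercept-slope covariance as atanh(correlation), which keeps the
# random-effect matrix positive semidefinite throughout and stabilizes the
# numerical Hessian. Bounds on the log-SD scale enforce the variance floor.

fixed_effect_names <- c("b00", "b0exp", "b0female", "b10", "b1exp",
                        "b1female")
natural_names <- c(fixed_effect_names, "var_e0", "var_e1", "cov_e01",
                   "var_e2")
internal_of_natural <- c(b00 = "b00", b0exp = "b0exp", b0female = "b0female",
                         b10 = "b10", b1exp = "b1exp", b1female = "b1female",
                         var_e0 = "lsd0", var_e1 = "lsd1", cov_e01 = "z01",
                         var_e2 = "lsdr")

#' Model specification switches for fitting and sampling
#'
#' Controls which terms of the growth model are estimated. Terms switched
#' off are fixed at zero; arbitrary parameters can additionally be held at
#' given values through the `fixed` argument of [fit_ml()] and
#' [sample_posterior()].
#'
#' @param arm Estimate the arm effects `b0exp`, `b1exp`? (default `TRUE`)
#' @param gender Estimate the gender effects `b0female`, `b1female`?
#' @param slope Estimate slope terms at all? `FALSE` fixes `b10`, `b1exp`,
#'   `b1female`, `var_e1` and `cov_e01` at 0 (intercept-only model).
#' @param cov01 Estimate the intercept--slope covariance freely? `FALSE`
#'   fixes it at 0.
#' @return A list of class `lgcm_spec`.
#' @export
lgcm_spec <- function(arm = TRUE, gender = TRUE, slope = TRUE,
                      cov01 = TRUE) {
  structure(list(arm = isTRUE(arm), gender = isTRUE(gender),
                 slope = isTRUE(slope), cov01 = isTRUE(cov01)),
            class = "lgcm_spec")
}

# Resolve which natural parameters are fixed (and at what value) and which
# internal coordinates are free, given a spec and user-supplied fixings.
build_parmap <- function(spec = lgcm_spec(), fixed = NULL) {
  fix <- list()
  if (!spec$arm) fix[c("b0exp", "b1exp")] <- 0
  if (!spec$gender) fix[c("b0female", "b1female")] <- 0
  if (!spec$slope) fix[c("b10", "b1exp", "b1female", "var_e1",
                         "cov_e01")] <- 0
  if (!spec$cov01) fix["cov_e01"] <- 0
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% natural_names)) {
      stop("`fixed` must be a named vector over: ",
           paste(natural_names, collapse = ", "), call. = FALSE)
    }
    fix[names(fixed)] <- as.list(as.numeric(fixed))
  }
  # the covariance is parameterized through the correlation, so it can only
  # be free when both variances are free
  if (!("cov_e01" %in% names(fix)) &&
      any(c("var_e0", "var_e1") %in% names(fix))) {
    fix["cov_e01"] <- 0
  }
  free_nat <- setdiff(natural_names, names(fix))
  list(fixed = fix, free_natural = free_nat,
       free_internal = unname(internal_of_natural[free_nat]))
}

# Natural lgcm_params from a free internal vector + the map's fixings.
theta_to_params <- function(theta, map) {
  g <- function(nm) unname(theta[internal_of_natural[[nm]]])
  val <- function(nm) {
    if (nm %in% names(map$fixed)) map$fixed[[nm]] else g(nm)
  }
  sd0 <- if ("var_e0" %in% map$free_natural) exp(g("var_e0")) else
    sqrt(map$fixed[["var_e0"]])
  sd1 <- if ("var_e1" %in% map$free_natural) exp(g("var_e1")) else
    sqrt(map$fixed[["var_e1"]])
  cov01 <- if ("cov_e01" %in% map$free_natural)
    tanh(g("cov_e01")) * sd0 * sd1 else map$fixed[["cov_e01"]]
  lgcm_params(
    b00 = val("b00"), b0exp = val("b0exp"), b0female = val("b0female"),
    b10 = val("b10"), b1exp = val("b1exp"), b1female = val("b1female"),
    var_e0 = sd0^2, var_e1 = sd1^2, cov_e01 = cov01,
    var_e2 = if ("var_e2" %in% map$free_natural) exp(2 * g("var_e2")) else
      map$fixed[["var_e2"]])
}

# Starting values: intercept terms at the grand mean of observed baseline
# values, slope terms at 0, the observed outcome variance split equally
# across the free variance components, correlation at 0.
init_theta <- function(map, y) {
  v_obs <- stats::var(as.numeric(y), na.rm = TRUE)
  if (!is.finite(v_obs) || v_obs <= 0) v_obs <- 1
  base_mean <- mean(y[, 1], na.rm = TRUE)
  if (!is.finite(base_mean)) base_mean <- mean(y, na.rm = TRUE)
  n_var_free <- sum(c("var_e0", "var_e1", "var_e2") %in% map$free_natural)
  v0 <- v_obs / max(n_var_free, 1)
  init <- c(b00 = base_mean, b0exp = 0, b0female = 0, b10 = 0, b1exp = 0,
            b1female = 0, lsd0 = 0.5 * log(v0), lsd1 = 0.5 * log(v0),
            z01 = 0, lsdr = 0.5 * log(v0))
  init[map$free_internal]
}

# Box bounds for L-BFGS-B: fixed effects unbounded; log-SDs bounded below so
# variances stay >= 1e-8; atanh-correlation kept in (-1, 1) comfortably.
theta_bounds <- function(map) {
  lower <- c(b00 = -Inf, b0exp = -Inf, b0female = -Inf, b10 = -Inf,
             b1exp = -Inf, b1female = -Inf, lsd0 = 0.5 * log(1e-8),
             lsd1 = 0.5 * log(1e-8), z01 = -6, lsdr = 0.5 * log(1e-8))
  upper <- c(b00 = Inf, b0exp = Inf, b0female = Inf, b10 = Inf,
             b1exp = Inf, b1female = Inf, lsd0 = 20, lsd1 = 20, z01 = 6,
             lsdr = 20)
  list(lower = lower[map$free_internal], upper = upper[map$free_internal])
}

# Central-difference Hessian with step h_j = step * (1 + |x_j|).
num_hessian <- function(f, x, step = 1e-4) {
  p <- length(x)
  h <- step * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- h[j]
    H[j, j] <- (f(x + ej) - 2 * f0 + f(x - ej)) / h[j]^2
    if (j < p) {
      for (k in (j + 1):p) {
        ek <- numeric(p); ek[k] <- h[k]
        H[j, k] <- H[k, j] <-
          (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) +
             f(x - ej - ek)) / (4 * h[j] * h[k])
      }
    }
  }
  (H + t(H)) / 2
}

z975 <- 1.959964

#' Wald test and 95% confidence interval from an estimate and its SE
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @return List with `z` (`estimate/se`), `pvalue` (two-sided normal), and
#'   `ci95` (`estimate +/- 1.959964 * se`).
#' @examples
#' wald_test(0.195, 0.084)
#' @export
wald_test <- function(estimate, se) {
  if (!is.numeric(se) || any(se <= 0)) {
    stop("`se` must be positive", call. = FALSE)
  }
  z <- estimate / se
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)),
       ci95 = cbind(lower = estimate - z975 * se,
                    upper = estimate + z975 * se))
}

#' Fit a latent growth curve model by FIML
#'
#' Maximizes the observed-data (FIML) log-likelihood of the growth model
#' with bounded L-BFGS-B: fixed effects are unbounded, variance components
#' bounded below at `1e-8` (enforced through a log-SD parameterization,
#' which also keeps the random-effect matrix positive semidefinite).
#' Starting values put the intercept at the grand mean of observed baseline
#' values, slope terms at 0, and split the observed outcome variance equally
#' across the free variance components. Standard errors come from the
#' inverse of the negative numerical Hessian at the optimum (central
#' differences, step `1e-4 * (1 + |theta|)`, variance components on the log
#' scale; pseudo-inverse fallback with the `1e-4` diagonal jitter rule when
#' the Hessian is singular).
#'
#' @param data Either a wide trial data frame (then `outcome` selects the
#'   measure) or a list with elements `y` (participants x waves matrix,
#'   `NA` = missing), `g_exp` and `g_female`.
#' @param outcome Outcome name when `data` is a data frame; see
#'   [outcome_matrix()].
#' @param basis A [time_basis()].
#' @param spec An [lgcm_spec()] choosing which terms to estimate.
#' @param fixed Optional named vector of natural-scale parameters to hold
#'   fixed (e.g. `c(b1exp = 0)` for a null model).
#' @param jitter Diagonal jitter used inside the likelihood (default 1e-4).
#' @param control Passed to [stats::optim()] (`maxit` defaults to 500).
#' @param se Compute Hessian-based standard errors? (default `TRUE`; skip
#'   for speed in simulation loops that only need point estimates)
#' @return An object of class `lgcm_fit`: list with `params` (estimates as
#'   [lgcm_params()]), `coef` (data frame with `beta`, `se`, `ll95`, `ul95`,
#'   `wald`, `pvalue` per free fixed effect), `loglik`, `converged`,
#'   `n_iter`, `n`, `n_obs`, `vcov` (free-parameter covariance), and the
#'   `basis`/`map` used.
#' @examples
#' cfg <- generator_config(n_exp = 80, n_wait = 80, seed = 1)
#' dat <- generate_trial(cfg)
#' fit <- fit_ml(dat, outcome = "qids")
#' fit$coef
#' @export
fit_ml <- function(data, outcome = NULL, basis = time_basis(),
                   spec = lgcm_spec(), fixed = NULL, jitter = 1e-4,
                   control = list(), se = TRUE) {
  if (is.data.frame(data)) {
    if (is.null(outcome)) {
      stop("supply `outcome` when `data` is a data frame", call. = FALSE)
    }
    data <- outcome_matrix(data, outcome)
  }
  y <- as.matrix(data$y)
  g_exp <- data$g_exp
  g_female <- data$g_female
  if (ncol(y) != length(basis$loadings)) {
    stop("outcome matrix and time basis disagree on the number of waves",
         call. = FALSE)
  }
  if (!any(!is.na(y))) {
    stop("no observed outcome values to fit", call. = FALSE)
  }
  all_missing <- colSums(!is.na(y)) == 0L
  if (any(all_missing)) {
    stop("wave column(s) with no observed values: ",
         paste(which(all_missing), collapse = ", "),
         "; drop the wave from the basis instead", call. = FALSE)
  }
  if (spec$slope && sum(!duplicated(round(basis$loadings, 12))) < 2L) {
    stop("slope estimation needs at least 2 distinct time loadings",
         call. = FALSE)
  }
  map <- build_parmap(spec, fixed)
  groups <- fiml_groups(y)
  negll <- function(theta) {
    names(theta) <- map$free_internal
    p <- tryCatch(theta_to_params(theta, map), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- fiml_core(y, g_exp, g_female, p, basis, jitter = jitter,
                   groups = groups)
    if (!is.finite(v)) 1e10 else -v
  }
  bounds <- theta_bounds(map)
  control <- utils::modifyList(list(maxit = 500, factr = 1e4), control)
  opt <- stats::optim(init_theta(map, y), negll, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = control)
  theta_hat <- opt$par
  names(theta_hat) <- map$free_internal
  params <- theta_to_params(theta_hat, map)

  free_fe <- intersect(fixed_effect_names, map$free_natural)
  coef_tab <- NULL
  vcov_free <- NULL
  if (se && length(theta_hat)) {
    H <- num_hessian(negll, theta_hat)
    dec <- tryCatch(list(inv = solve(H)), error = function(e) NULL)
    if (is.null(dec)) {
      Hj <- H
      diag(Hj) <- diag(Hj) + 1e-4
      dec <- pseudo_inverse_logdet(Hj)
    }
    vcov_free <- (dec$inv + t(dec$inv)) / 2
    dimnames(vcov_free) <- list(map$free_internal, map$free_internal)
    if (length(free_fe)) {
      est <- vapply(free_fe, function(nm) params[[nm]], numeric(1))
      se_fe <- sqrt(pmax(diag(vcov_free)[free_fe], 0))
      ok <- se_fe > 0
      w <- ifelse(ok, est / se_fe, NA_real_)
      coef_tab <- data.frame(
        term = free_fe, beta = est, se = se_fe,
        ll95 = est - z975 * se_fe, ul95 = est + z975 * se_fe,
        wald = w, pvalue = ifelse(ok, 2 * stats::pnorm(-abs(w)), NA_real_),
        row.names = NULL)
    }
  }
  structure(list(params = params, coef = coef_tab, loglik = -opt$value,
                 converged = opt$convergence == 0,
                 n_iter = unname(opt$counts["function"]),
                 n = nrow(y), n_obs = sum(!is.na(y)), vcov = vcov_free,
                 basis = basis, map = map, message = opt$message),
            class = "lgcm_fit")
}

#' @export
print.lgcm_fit <- function(x, digits = 3, ...) {
  cat("Latent growth curve model (FIML)\n")
  cat("  participants:", x$n, "  observed values:", x$n_obs,
      "  log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("  converged:", x$converged, " (", x$n_iter, "likelihood evaluations )\n\n")
  if (!is.null(x$coef)) {
    tab <- x$coef
    tab[-1] <- lapply(tab[-1], round, digits = digits)
    print(tab, row.names = FALSE)
  }
  cat("\nVariance components: var_e0 =",
      format(x$params$var_e0, digits = digits),
      " var_e1 =", format(x$params$var_e1, digits = digits),
      " cov_e01 =", format(x$params$cov_e01, digits = digits),
      " var_e2 =", format(x$params$var_e2, digits = digits), "\n")
  invisible(x)
}
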