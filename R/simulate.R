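# Seeded generator of complete synthetic two-arm trials with the
# statistical structure the growth-model analysis assumes: latent
# intercept/slope outcome trajectories with arm and gender effects,
# heavy-tailed behaviour counts whose log2(count + 1) values have
# configurable per-arm per-wave means, wave-wise dropout, and the trial's
# reward bookkeeping.

#' Questionnaire reward schedule
#'
#' Per-wave questionnaire payments plus the monthly completion bonus
#' (experimental arm: awarded for completing >= 60% of prompted tasks in a
#' month; waitlist arm: awarded by lottery). Defaults reproduce the study
#' design: JPY 500 / 200 / 200 / 500 for the four waves and a JPY 500 bonus
#' for each of 3 intervention months, with a 0.73 waitlist lottery
#' probability.
#'
#' @param wave_payments Length-4 non-negative payments (JPY).
#' @param completion_bonus Bonus per intervention month (JPY).
#' @param n_bonus_months Number of bonus-eligible months.
#' @param waitlist_lottery_p Monthly lottery win probability for the
#'   waitlist arm, in `[0, 1]`.
#' @return List of class `reward_schedule`.
#' @export
reward_schedule <- function(wave_payments = c(500, 200, 200, 500),
                            completion_bonus = 500, n_bonus_months = 3,
                            waitlist_lottery_p = 0.73) {
  if (length(wave_payments) != 4 || any(wave_payments < 0)) {
    stop("`wave_payments` must be 4 non-negative amounts", call. = FALSE)
  }
  if (completion_bonus < 0) {
    stop("`completion_bonus` must be non-negative", call. = FALSE)
  }
  assert_count(n_bonus_months, "n_bonus_months")
  if (waitlist_lottery_p < 0 || waitlist_lottery_p > 1) {
    stop("`waitlist_lottery_p` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(wave_payments = wave_payments,
                 completion_bonus = completion_bonus,
                 n_bonus_months = n_bonus_months,
                 waitlist_lottery_p = waitlist_lottery_p),
            class = "reward_schedule")
}

#' Maximum total compensation under a reward schedule
#'
#' Sum of all per-wave payments plus the completion bonus for every
#' bonus-eligible month; the default schedule yields JPY 2900.
#'
#' @param schedule A [reward_schedule()].
#' @return Amount in JPY.
#' @examples
#' max_total_compensation(reward_schedule())  # 2900
#' @export
max_total_compensation <- function(schedule = reward_schedule()) {
  stopifnot(inherits(schedule, "reward_schedule"))
  sum(schedule$wave_payments) +
    schedule$completion_bonus * schedule$n_bonus_months
}

#' Randomly assign participants to arms
#'
#' Mirrors 1:1 randomization with R's default Mersenne-Twister generator:
#' each participant is independently assigned to the experimental arm with
#' probability `p`, so the realized arm counts vary around `n_total / 2`.
#'
#' @param n_total Number of participants (>= 2).
#' @param seed Integer seed.
#' @param p Allocation probability for the experimental arm.
#' @return Character vector of `"experimental"` / `"waitlist"` labels.
#' @export
assign_arms <- function(n_total, seed, p = 0.5) {
  if (n_total < 2) stop("`n_total` must be >= 2", call. = FALSE)
  set.seed(seed)
  ifelse(stats::rbinom(n_total, 1, p) == 1, "experimental", "waitlist")
}

default_count_model <- function() {
  list(
    family = "lognormal",
    bell = list(
      log2_mean = rbind(experimental = c(8.07, 7.93, 7.29, 6.65),
                        waitlist = c(8.15, 7.80, 6.99, 6.35)),
      log2_sd = 2.5, icc = 0.6),
    custom = list(
      log2_mean = rbind(experimental = c(7.71, 7.56, 6.50, 6.13),
                        waitlist = c(7.65, 7.48, 6.39, 5.90)),
      log2_sd = 1.8, icc = 0.55),
    powerlaw_exponent = 2.5)
}

default_truth <- function() {
  list(
    qids = lgcm_params(b00 = 8.0, b0exp = 0, b0female = 0.6,
                       b10 = -0.35, b1exp = -0.319, b1female = -0.05,
                       var_e0 = 25, var_e1 = 1.2, cov_e01 = -1.5,
                       var_e2 = 11.6),
    lsas_v = lgcm_params(b00 = 26.5, b0exp = 0.3, b0female = 2.5,
                         b10 = 1.3, b1exp = 0.666, b1female = 0.1,
                         var_e0 = 300, var_e1 = 6, cov_e01 = -8,
                         var_e2 = 62),
    lsas_p = lgcm_params(b00 = 44, b0exp = 0.8, b0female = 2.5,
                         b10 = -0.1, b1exp = 0.319, b1female = 0,
                         var_e0 = 480, var_e1 = 6, cov_e01 = -10,
                         var_e2 = 65))
}

#' Configuration of the synthetic trial generator
#'
#' Defaults emulate the study conditions: arms of 548 and 557 participants,
#' a 0.7475 female proportion, age 23.68 (SD 10.44) years truncated to
#' 9--82, four waves at 0/1/2/3 months, growth-model truths whose baseline
#' means/SDs and intervention effects mirror the reported tables (the
#' depression truth implies a change-score SMD of about -0.12), behaviour
#' counts whose log2(count + 1) means match the reported per-arm wave means,
#' and a 0.73 monthly completion/lottery probability. Dropout is
#' missing-completely-at-random per wave by default, with a
#' missing-at-random mode in which the current symptom level shifts the
#' missingness odds.
#'
#' @param n_exp,n_wait Arm sizes (>= 1).
#' @param p_female Probability of being female.
#' @param age_mean,age_sd Age distribution (years), truncated to `[9, 82]`.
#' @param basis [time_basis()] of the four waves.
#' @param truth Named list of [lgcm_params()] truths for `qids`, `lsas_v`,
#'   `lsas_p`.
#' @param count_model Behaviour-count model: per-arm per-wave `log2_mean`
#'   matrices, marginal `log2_sd`, within-person intraclass correlation
#'   `icc` for `bell` and `custom`; `family` is `"lognormal"` (counts are
#'   `round(2^L) - 1` of a normal log2-scale value, the analysis transform
#'   inverted) or `"powerlaw"` (discrete Pareto tail with exponent
#'   `powerlaw_exponent`, scaled so the median matches the configured
#'   log2 mean).
#' @param dropout Length-4 per-wave questionnaire missingness
#'   probabilities.
#' @param dropout_mechanism `"mcar"` (default) or `"mar"` (missingness odds
#'   increase with the participant's current depression score).
#' @param mar_slope Log-odds shift per SD of current symptom score under
#'   `"mar"`.
#' @param behavior_outcome_corr Target correlation between the bell-count
#'   log2 change and the chosen outcome's change (|rho| <= 0.7).
#' @param behavior_outcome Outcome coupled to the bell change
#'   (`"qids"`, `"lsas_v"`, `"lsas_p"`).
#' @param completion_p Monthly probability an experimental participant
#'   completes >= 60% of tasks (earning the bonus).
#' @param rewards A [reward_schedule()].
#' @param seed Integer seed used by [generate_trial()].
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_exp = 548, n_wait = 557, p_female = 0.7475,
                             age_mean = 23.68, age_sd = 10.44,
                             basis = time_basis(c(0, 1, 2, 3)),
                             truth = default_truth(),
                             count_model = default_count_model(),
                             dropout = c(0, 0.10, 0.15, 0.20),
                             dropout_mechanism = c("mcar", "mar"),
                             mar_slope = 0.5,
                             behavior_outcome_corr = 0,
                             behavior_outcome = c("qids", "lsas_v",
                                                  "lsas_p"),
                             completion_p = 0.73,
                             rewards = reward_schedule(), seed = 1) {
  dropout_mechanism <- match.arg(dropout_mechanism)
  behavior_outcome <- match.arg(behavior_outcome)
  if (n_exp < 1 || n_wait < 1) stop("arm sizes must be >= 1", call. = FALSE)
  if (p_female < 0 || p_female > 1) {
    stop("`p_female` must lie in [0, 1]", call. = FALSE)
  }
  if (length(dropout) != length(basis$loadings) ||
      any(dropout < 0 | dropout > 1)) {
    stop("`dropout` must give one probability in [0, 1] per wave",
         call. = FALSE)
  }
  if (abs(behavior_outcome_corr) > 1 / sqrt(2)) {
    stop("|behavior_outcome_corr| must be <= 0.707 (the coupling keeps ",
         "wave-wise count marginals intact)", call. = FALSE)
  }
  if (completion_p < 0 || completion_p > 1) {
    stop("`completion_p` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("qids", "lsas_v", "lsas_p") %in% names(truth)))
  for (tr in truth[c("qids", "lsas_v", "lsas_p")]) {
    stopifnot(inherits(tr, "lgcm_params"))
  }
  structure(list(n_exp = n_exp, n_wait = n_wait, p_female = p_female,
                 age_mean = age_mean, age_sd = age_sd, basis = basis,
                 truth = truth, count_model = count_model,
                 dropout = dropout, dropout_mechanism = dropout_mechanism,
                 mar_slope = mar_slope,
                 behavior_outcome_corr = behavior_outcome_corr,
                 behavior_outcome = behavior_outcome,
                 completion_p = completion_p, rewards = rewards,
                 seed = seed),
            class = "generator_config")
}

#' Change-score SMD implied by a growth-model truth
#'
#' Under the model, a participant's wave-4 minus wave-1 change is
#' `(F[4] - F[1]) * B1[i] + e[i4] - e[i1]`, so the between-arm mean change
#' difference is `(F[4] - F[1]) * b1exp` and the change SD (equal in both
#' arms) is `sqrt((F[4] - F[1])^2 var_e1 + 2 var_e2)`. Useful for choosing
#' truths that imply a target effect size.
#'
#' @param params An [lgcm_params()] truth.
#' @param basis A [time_basis()].
#' @return The implied change-score SMD.
#' @export
implied_smd <- function(params, basis = time_basis()) {
  df <- basis$loadings[length(basis$loadings)] - basis$loadings[1]
  df * params$b1exp / sqrt(df^2 * params$var_e1 + 2 * params$var_e2)
}

# Draw n latent (intercept, slope) pairs from N(0, Psi).
draw_effects <- function(n, params) {
  Psi <- psi_matrix(params)
  e <- eigen(Psi, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
  matrix(stats::rnorm(2 * n), n, 2) %*% A
}

# Outcome trajectories (complete data): n x T matrix.
draw_outcome <- function(params, g_exp, g_female, basis) {
  n <- length(g_exp)
  f <- basis$loadings
  U <- draw_effects(n, params)
  b0 <- params$b00 + params$b0exp * g_exp + params$b0female * g_female +
    U[, 1]
  b1 <- params$b10 + params$b1exp * g_exp + params$b1female * g_female +
    U[, 2]
  matrix(b0, n, length(f)) + outer(b1, f) +
    matrix(stats::rnorm(n * length(f), sd = sqrt(params$var_e2)), n)
}

# Heavy-tailed counts from a log2-scale latent matrix L (n x T).
counts_from_log2 <- function(L, family, exponent) {
  out <- if (family == "lognormal") {
    pmax(0, round(2^L - 1))
  } else {
    # discrete power-law tail: Pareto(alpha - 1) scaled so the median sits
    # at the configured log2 mean, floored to integers
    u <- stats::runif(length(L))
    x <- (1 - u)^(-1 / (exponent - 1))          # Pareto(1, alpha - 1)
    med <- 2^(1 / (exponent - 1))
    pmax(0, floor(2^L * x / med))
  }
  matrix(as.integer(out), nrow(L), ncol(L))
}

#' Generate a synthetic two-arm trial
#'
#' Draws a complete trial under the configured study conditions: covariates,
#' latent growth outcome trajectories for the three questionnaire outcomes,
#' heavy-tailed bell-ring and avatar-customization counts (optionally
#' correlated, on the change-score scale, with one outcome's change),
#' wave-wise questionnaire dropout, monthly completion bonuses, and the
#' resulting compensation. Behaviour counts come from game logs and are
#' never missing. Fully reproducible given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return Wide data frame of class `trial_data`, one row per participant:
#'   `id`, `arm`, `female`, `age`, `qids_w1..4`, `lsas_v_w1..4`,
#'   `lsas_p_w1..4`, `bell_w1..4`, `custom_w1..4`, `bonus_months`,
#'   `reward_jpy`.
#' @examples
#' dat <- generate_trial(generator_config(n_exp = 50, n_wait = 50, seed = 7))
#' dim(dat)
#' @export
generate_trial <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed %||% config$seed)
  n <- config$n_exp + config$n_wait
  arm <- rep(c("experimental", "waitlist"), c(config$n_exp, config$n_wait))
  g_exp <- as.integer(arm == "experimental")
  female <- stats::rbinom(n, 1, config$p_female)
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                   9), 82)
  basis <- config$basis
  Tn <- length(basis$loadings)

  Y <- lapply(config$truth[c("qids", "lsas_v", "lsas_p")], draw_outcome,
              g_exp = g_exp, g_female = female, basis = basis)

  # standardized complete-data change of the coupled outcome
  ym <- Y[[config$behavior_outcome]]
  dz <- ym[, Tn] - ym[, 1]
  dz <- (dz - mean(dz)) / stats::sd(dz)
  rho <- config$behavior_outcome_corr

  cm <- config$count_model
  make_counts <- function(spec, couple) {
    sd_w <- spec$log2_sd * sqrt(1 - spec$icc)
    sd_a <- spec$log2_sd * sqrt(spec$icc)
    a <- stats::rnorm(n, 0, sd_a)
    Ew <- matrix(stats::rnorm(n * Tn, 0, sd_w), n, Tn)
    if (couple && rho != 0) {
      # wave-4 innovation built so corr(change, dz) = rho while keeping the
      # wave-4 marginal SD at sd_w (requires |rho| <= 1/sqrt(2))
      eps <- stats::rnorm(n)
      Ew[, Tn] <- sqrt(2) * sd_w * rho * dz +
        sqrt(max(sd_w^2 - 2 * sd_w^2 * rho^2, 0)) * eps
    }
    M <- spec$log2_mean[arm, , drop = FALSE]
    counts_from_log2(M + a + Ew, cm$family, cm$powerlaw_exponent)
  }
  bell <- make_counts(cm$bell, couple = TRUE)
  custom <- make_counts(cm$custom, couple = FALSE)

  # wave-wise questionnaire dropout (all three instruments jointly)
  miss <- matrix(FALSE, n, Tn)
  for (t in seq_len(Tn)) {
    p <- rep(config$dropout[t], n)
    if (config$dropout_mechanism == "mar" && config$dropout[t] > 0) {
      z <- (Y$qids[, t] - mean(Y$qids[, t])) / stats::sd(Y$qids[, t])
      p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) +
                           config$mar_slope * z)
    }
    miss[, t] <- stats::runif(n) < p
  }
  for (k in seq_along(Y)) Y[[k]][miss] <- NA_real_

  bonus <- ifelse(g_exp == 1,
                  stats::rbinom(n, config$rewards$n_bonus_months,
                                config$completion_p),
                  stats::rbinom(n, config$rewards$n_bonus_months,
                                config$rewards$waitlist_lottery_p))
  reward <- (!miss) %*% config$rewards$wave_payments +
    bonus * config$rewards$completion_bonus

  out <- data.frame(id = seq_len(n), arm = arm, female = female, age = age)
  wave_cols <- function(m, stem) {
    m <- as.data.frame(m)
    names(m) <- paste0(stem, "_w", seq_len(ncol(m)))
    m
  }
  out <- cbind(out, wave_cols(Y$qids, "qids"), wave_cols(Y$lsas_v, "lsas_v"),
               wave_cols(Y$lsas_p, "lsas_p"), wave_cols(bell, "bell"),
               wave_cols(custom, "custom"))
  out$bonus_months <- as.integer(bonus)
  out$reward_jpy <- as.numeric(reward)
  class(out) <- c("trial_data", "data.frame")
  out
}
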