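# Effect sizes and descriptive inference: change-score SMD, cross-sectional
# Cohen's d, two-sample t tests, 2x2 chi-square with phi, and change-score
# correlation matrices.

#' Group summary (n, mean, SD)
#'
#' Container for printed-table style summaries used by [cohen_d_cross()].
#'
#' @param n Participant count (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0, n-1 denominator).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

pooled_sd <- function(n1, s1, n2, s2) {
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Standardized mean difference of change scores between arms
#'
#' The trial's intervention effect size: the between-arm difference in mean
#' within-participant change (wave 4 minus wave 1), divided by the pooled
#' standard deviation of the change scores,
#' `s_p = sqrt(((n_e - 1) s_e^2 + (n_w - 1) s_w^2) / (n_e + n_w - 2))`.
#' This is Cohen's d applied to change scores; sample SDs use `n - 1`.
#' Missing change scores (either endpoint unobserved) must be removed by the
#' caller or are dropped here with a complete-case rule.
#'
#' @param exp_changes,wait_changes Numeric change-score vectors for the
#'   experimental and waitlist arms (>= 2 complete values each).
#' @return Signed SMD. If the pooled SD is zero with unequal means, a signed
#'   infinity carrying attribute `degenerate = TRUE` is returned.
#' @examples
#' smd_change(c(1, 3), c(0, 0))  # 2
#' @export
smd_change <- function(exp_changes, wait_changes) {
  exp_changes <- exp_changes[!is.na(exp_changes)]
  wait_changes <- wait_changes[!is.na(wait_changes)]
  if (length(exp_changes) < 2 || length(wait_changes) < 2) {
    stop("need at least 2 complete change scores per arm", call. = FALSE)
  }
  num <- mean(exp_changes) - mean(wait_changes)
  sp <- pooled_sd(length(exp_changes), stats::sd(exp_changes),
                  length(wait_changes), stats::sd(wait_changes))
  if (sp == 0) {
    if (num == 0) return(0)
    return(structure(sign(num) * Inf, degenerate = TRUE))
  }
  num / sp
}

#' Cross-sectional Cohen's d from group summaries
#'
#' `d = |mean_a - mean_b| / s_pooled` with the usual pooled SD; reported
#' unsigned by default to match printed baseline tables, with a signed
#' variant available.
#'
#' @param a,b [group_summary()] objects.
#' @param signed Return the signed value `(mean_a - mean_b) / s_p`?
#' @return Cohen's d. Zero pooled SD with unequal means returns a signed
#'   infinity with attribute `degenerate = TRUE`.
#' @examples
#' cohen_d_cross(group_summary(548, 24.151, 10.528),
#'               group_summary(557, 23.226, 10.347))  # 0.089
#' @export
cohen_d_cross <- function(a, b, signed = FALSE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  num <- a$mean - b$mean
  sp <- pooled_sd(a$n, a$sd, b$n, b$sd)
  if (sp == 0) {
    if (num == 0) return(0)
    return(structure(sign(num) * Inf, degenerate = TRUE))
  }
  d <- num / sp
  if (signed) d else abs(d)
}

#' Independent-samples t test
#'
#' Pooled-variance t with `df = n_a + n_b - 2`, or Welch's t with
#' Welch--Satterthwaite df when `welch = TRUE` (printed baseline tables may
#' mix the two: fractional df indicate Welch).
#'
#' @param a_values,b_values Numeric vectors (>= 2 values each).
#' @param welch Use the Welch (unequal-variance) form?
#' @return List with `t`, `df`, `pvalue`, and `degenerate` (`TRUE` when both
#'   group variances are zero).
#' @export
two_sample_t <- function(a_values, b_values, welch = FALSE) {
  a_values <- a_values[!is.na(a_values)]
  b_values <- b_values[!is.na(b_values)]
  if (length(a_values) < 2 || length(b_values) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::var(a_values) == 0 && stats::var(b_values) == 0) {
    eq <- mean(a_values) == mean(b_values)
    return(list(t = if (eq) 0 else sign(mean(a_values) - mean(b_values)) * Inf,
                df = length(a_values) + length(b_values) - 2,
                pvalue = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a_values, b_values, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       pvalue = ht$p.value, degenerate = FALSE)
}

#' Phi coefficient from a chi-square statistic
#'
#' `phi = sqrt(chi2 / N)` for a 2x2 table with `N` total observations.
#'
#' @param chi2 Chi-square statistic (>= 0).
#' @param n Total count (> 0).
#' @return Phi coefficient.
#' @examples
#' phi_from_chisq(4.394, 1105)  # 0.063
#' @export
phi_from_chisq <- function(chi2, n) {
  if (chi2 < 0 || n <= 0) stop("invalid chi-square or N", call. = FALSE)
  sqrt(chi2 / n)
}

#' Pearson chi-square test for a 2x2 table with phi
#'
#' Uncorrected Pearson chi-square by default (so that `phi^2 * N = chi2`
#' exactly), with an optional Yates continuity correction.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the Yates continuity correction?
#' @return List with `chi2`, `df` (= 1), `pvalue`, `phi`.
#' @export
chisq_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || anyNA(table)) {
    stop("`table` must be a 2x2 matrix of non-negative counts",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("every row and column margin must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  chi2 <- unname(ht$statistic)
  list(chi2 = chi2, df = 1L, pvalue = ht$p.value,
       phi = phi_from_chisq(chi2, sum(table)))
}

#' Wave 4 minus wave 1 change scores
#'
#' Computes per-participant change scores for an outcome or a log2-scale
#' behaviour count; the change is missing whenever either endpoint is
#' missing (complete-case rule).
#'
#' @param data Wide trial data frame.
#' @param variable One of `"qids"`, `"lsas_v"`, `"lsas_p"`, `"bell_log2"`,
#'   `"custom_log2"`.
#' @return Numeric vector of changes, `NA` where undefined.
#' @export
change_scores <- function(data, variable = c("qids", "lsas_v", "lsas_p",
                                             "bell_log2", "custom_log2")) {
  variable <- match.arg(variable)
  m <- outcome_matrix(data, variable)$y
  m[, 4] - m[, 1]
}

cor_var_labels <- c(qids = "diff_dep", lsas_v = "diff_sa_v",
                    lsas_p = "diff_sa_p", bell_log2 = "diff_bell_log2",
                    custom_log2 = "diff_custom_log2")

#' Change-score correlation matrix for one arm
#'
#' Pairwise-complete Pearson correlations among the five change scores
#' (depression, virtual and physical social anxiety, log2 bell-ring and
#' avatar-customization counts) and the number of bonus rewards received
#' (0--3), with two-sided p-values and significance stars at .05 / .01.
#' Cells with fewer than 3 complete pairs are marked unavailable (`NA`).
#'
#' @param data Wide trial data frame.
#' @param arm `"experimental"` or `"waitlist"`.
#' @return Object of class `change_cor`: list of matrices `r`, `pvalue`,
#'   `n`, and character `stars`.
#' @export
change_correlations <- function(data, arm = c("experimental", "waitlist")) {
  arm <- match.arg(arm)
  sub <- data[data$arm == arm, , drop = FALSE]
  vars <- c(lapply(names(cor_var_labels), function(v) change_scores(sub, v)),
            list(sub$bonus_months))
  names(vars) <- c(unname(cor_var_labels), "total_reward")
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k,
                           dimnames = list(names(vars), names(vars)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(vars[[i]], vars[[j]])
      nmat[i, j] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (sum(ok) < 3) next
      if (stats::sd(vars[[i]][ok]) == 0 || stats::sd(vars[[j]][ok]) == 0) next
      ct <- stats::cor.test(vars[[i]][ok], vars[[j]][ok],
                            method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(arm = arm, r = r, pvalue = p, n = nmat, stars = stars),
            class = "change_cor")
}

#' @export
print.change_cor <- function(x, digits = 2, ...) {
  cat("Change-score correlations (", x$arm, " arm, pairwise complete)\n",
      sep = "")
  disp <- matrix(paste0(formatC(round(x$r, digits), format = "f",
                                digits = digits), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(disp, quote = FALSE)
  cat("* p < .05, ** p < .01\n")
  invisible(x)
}

#' Baseline comparison table between arms
#'
#' Emits a baseline table in the style of trial reports: Welch t test for
#' age, chi-square with phi for the female proportion, and pooled t tests
#' with Cohen's d for the three baseline symptom scores.
#'
#' @param data Wide trial data frame.
#' @return Data frame with one row per comparison (`variable`, per-arm
#'   summaries, `statistic`, `df`, `pvalue`, `effect_size`).
#' @export
baseline_table <- function(data) {
  e <- data[data$arm == "experimental", ]
  w <- data[data$arm == "waitlist", ]
  rows <- list()
  tt <- two_sample_t(e$age, w$age, welch = TRUE)
  rows[["age"]] <- data.frame(
    variable = "age", test = "welch_t",
    exp_summary = sprintf("%.3f (%.3f)", mean(e$age), stats::sd(e$age)),
    wait_summary = sprintf("%.3f (%.3f)", mean(w$age), stats::sd(w$age)),
    statistic = tt$t, df = tt$df, pvalue = tt$pvalue,
    effect_size = cohen_d_cross(
      group_summary(nrow(e), mean(e$age), stats::sd(e$age)),
      group_summary(nrow(w), mean(w$age), stats::sd(w$age))))
  tab <- rbind(c(sum(e$female), sum(1 - e$female)),
               c(sum(w$female), sum(1 - w$female)))
  cs <- chisq_2x2(tab)
  rows[["female"]] <- data.frame(
    variable = "female", test = "chisq",
    exp_summary = sprintf("%d (%.3f)", sum(e$female), mean(e$female)),
    wait_summary = sprintf("%d (%.3f)", sum(w$female), mean(w$female)),
    statistic = cs$chi2, df = cs$df, pvalue = cs$pvalue,
    effect_size = cs$phi)
  for (v in c("qids", "lsas_v", "lsas_p")) {
    col <- paste0(v, "_w1")
    ev <- e[[col]][!is.na(e[[col]])]
    wv <- w[[col]][!is.na(w[[col]])]
    tt <- two_sample_t(ev, wv, welch = FALSE)
    rows[[v]] <- data.frame(
      variable = paste0(v, "_baseline"), test = "pooled_t",
      exp_summary = sprintf("%.2f (%.2f)", mean(ev), stats::sd(ev)),
      wait_summary = sprintf("%.2f (%.2f)", mean(wv), stats::sd(wv)),
      statistic = tt$t, df = tt$df, pvalue = tt$pvalue,
      effect_size = cohen_d_cross(
        group_summary(length(ev), mean(ev), stats::sd(ev)),
        group_summary(length(wv), mean(wv), stats::sd(wv))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
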