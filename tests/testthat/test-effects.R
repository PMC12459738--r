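test_that("change-score SMD follows the pooled-SD formula", {
  expect_equal(smd_change(c(1, 3), c(0, 0)), 2)
  # identical distributions: zero
  expect_equal(smd_change(c(1, 2, 3), c(1, 2, 3)), 0)
  # scale equivariance: scaling by c flips only the sign of c
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  expect_equal(smd_change(-2 * a, -2 * b), -smd_change(a, b))
  expect_equal(smd_change(3 * a, 3 * b), smd_change(a, b))
  # shift invariance
  expect_equal(smd_change(a + 7, b + 7), smd_change(a, b))
  # degenerate: zero pooled SD with unequal means
  deg <- smd_change(c(1, 1), c(0, 0))
  expect_identical(as.numeric(deg), Inf)
  expect_true(attr(deg, "degenerate"))
  expect_error(smd_change(1, c(0, 0)), "at least 2")
  # missing endpoints are dropped, complete-case
  expect_equal(smd_change(c(a, NA), b), smd_change(a, b))
})

test_that("SMD from raw changes equals the formula applied to group
           summaries", {
  set.seed(9)
  a <- rnorm(40, -0.5, 2); b <- rnorm(45, 0.1, 2.2)
  direct <- smd_change(a, b)
  viaform <- (mean(a) - mean(b)) /
    sqrt(((40 - 1) * sd(a)^2 + (45 - 1) * sd(b)^2) / (40 + 45 - 2))
  expect_equal(direct, viaform, tolerance = 1e-12)
})

test_that("cross-sectional Cohen's d matches hand computation and is
           shift invariant", {
  expect_equal(cohen_d_cross(group_summary(10, 3, 1),
                             group_summary(10, 3, 2)), 0)
  g1 <- group_summary(20, 5.5, 1.5)
  g2 <- group_summary(25, 4.9, 1.7)
  sp <- sqrt((19 * 1.5^2 + 24 * 1.7^2) / 43)
  expect_equal(cohen_d_cross(g1, g2), 0.6 / sp)
  expect_equal(cohen_d_cross(g1, g2, signed = TRUE), 0.6 / sp)
  expect_equal(cohen_d_cross(g2, g1, signed = TRUE), -0.6 / sp)
  # unsigned by default
  expect_equal(cohen_d_cross(g2, g1), cohen_d_cross(g1, g2))
  # shift invariance
  g1s <- group_summary(20, 15.5, 1.5); g2s <- group_summary(25, 14.9, 1.7)
  expect_equal(cohen_d_cross(g1s, g2s), cohen_d_cross(g1, g2))
})

test_that("two-sample t matches the textbook formula; Welch df never
           exceeds pooled df", {
  set.seed(10)
  a <- rnorm(12, 1); b <- rnorm(15)
  tt <- two_sample_t(a, b)
  sp2 <- ((11 * var(a) + 14 * var(b)) / 25)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 25)
  expect_equal(tt$pvalue, 2 * pt(-abs(t_hand), 25), tolerance = 1e-12)
  tw <- two_sample_t(a, b, welch = TRUE)
  expect_lte(tw$df, tt$df)
  # identical groups
  ti <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ti$t, 0)
  expect_equal(ti$pvalue, 1)
  # degenerate variance flagged
  td <- two_sample_t(c(1, 1), c(1, 1))
  expect_true(td$degenerate)
})

test_that("2x2 chi-square matches a brute-force expected-count oracle and
           phi^2 N = chi2", {
  tab <- matrix(c(394, 432, 154, 125), 2, 2)
  oracle <- function(tab, yates) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    d <- abs(tab - E)
    if (yates) d <- pmax(d - 0.5, 0)
    sum(d^2 / E)
  }
  for (yates in c(FALSE, TRUE)) {
    res <- chisq_2x2(tab, yates = yates)
    expect_equal(res$chi2, oracle(tab, yates), tolerance = 1e-12)
    expect_equal(res$df, 1L)
  }
  res <- chisq_2x2(tab)
  expect_equal(res$phi^2 * sum(tab), res$chi2, tolerance = 1e-12)
  # the Yates-corrected statistic reproduces the published baseline
  # comparison for this table (548/557 arms, 394 vs 432 female)
  expect_equal(round(chisq_2x2(tab, yates = TRUE)$chi2, 3), 4.394)
  # proportional table: no association
  prop <- chisq_2x2(matrix(c(10, 30, 20, 60), 2, 2))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$phi, 0)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("change scores require both endpoints and correlations use
           pairwise deletion", {
  dat <- small_trial(seed = 12, n = 120)
  cs <- change_scores(dat, "qids")
  expect_identical(is.na(cs), is.na(dat$qids_w1) | is.na(dat$qids_w4))
  ok <- !is.na(cs)
  expect_equal(cs[ok], dat$qids_w4[ok] - dat$qids_w1[ok])
  cc <- change_correlations(dat, "experimental")
  expect_identical(cc$r, t(cc$r))
  expect_equal(unname(diag(cc$r)), rep(1, 6))
  expect_true(all(cc$r >= -1 & cc$r <= 1, na.rm = TRUE))
  # each cell matches cor() with pairwise complete observations
  d_dep <- change_scores(dat[dat$arm == "experimental", ], "qids")
  d_bell <- change_scores(dat[dat$arm == "experimental", ], "bell_log2")
  expect_equal(cc$r["diff_dep", "diff_bell_log2"],
               cor(d_dep, d_bell, use = "pairwise.complete.obs"))
})

test_that("an antithetic pair correlates at -1 and self-correlation is 1", {
  dat <- small_trial(seed = 14, n = 40)
  # force an exact antithetic relationship between two change scores
  dat$lsas_v_w1 <- 0
  dat$lsas_v_w4 <- -(dat$qids_w4 - dat$qids_w1)
  dat$lsas_v_w4[is.na(dat$qids_w1)] <- 0
  cc <- change_correlations(dat, "waitlist")
  expect_equal(cc$r["diff_dep", "diff_sa_v"], -1, tolerance = 1e-12)
})

test_that("a built-in behaviour/outcome change correlation is recovered", {
  cfg <- generator_config(n_exp = 2000, n_wait = 2000,
                          dropout = rep(0, 4),
                          behavior_outcome_corr = 0.5,
                          behavior_outcome = "lsas_v", seed = 19)
  dat <- generate_trial(cfg)
  r <- cor(change_scores(dat, "bell_log2"), change_scores(dat, "lsas_v"))
  expect_lt(abs(r - 0.5), 3 / sqrt(4000))
})

test_that("baseline table assembles the arm comparison statistics", {
  dat <- small_trial(seed = 16, n = 100)
  bt <- baseline_table(dat)
  expect_setequal(bt$variable, c("age", "female", "qids_baseline",
                                 "lsas_v_baseline", "lsas_p_baseline"))
  e <- dat[dat$arm == "experimental", ]; w <- dat[dat$arm == "waitlist", ]
  row <- bt[bt$variable == "qids_baseline", ]
  tt <- two_sample_t(e$qids_w1, w$qids_w1)
  expect_equal(row$statistic, tt$t)
  expect_equal(row$pvalue, tt$pvalue)
  frow <- bt[bt$variable == "female", ]
  expect_equal(frow$effect_size,
               phi_from_chisq(frow$statistic, nrow(dat)))
})
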