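#' Score a QIDS response (16 items, 4-point scale)
#'
#' The Quick Inventory of Depressive Symptomatology (QIDS) has 16 items rated
#' 0--3 but is scored over 9 symptom domains: the four sleep items (1--4)
#' contribute their maximum, the four appetite/weight items (6--9) their
#' maximum, and the psychomotor pair (15, 16) its maximum; the remaining six
#' items (5, 10, 11, 12, 13, 14) enter singly. The total therefore lives on a
#' 0--27 metric, on which the clinical depression cut-off of 6 is defined.
#'
#' @param items Integer vector of length 16, each element in 0..3.
#' @param method `"domain"` (default) for the standard 9-domain maximum rule,
#'   or `"sum"` for a plain 16-item summation (sensitivity checks only; the
#'   0--27 cut-off does not apply to that metric).
#' @return Integer total severity score (0--27 under `"domain"`).
#' @examples
#' score_qids(rep(0, 16))            # 0
#' score_qids(rep(3, 16))            # 27
#' score_qids(c(3, rep(0, 3), rep(1, 12)))  # 11
#' @export
score_qids <- function(items, method = c("domain", "sum")) {
  method <- match.arg(method)
  if (length(items) != 16L) {
    stop("a QIDS response has exactly 16 items, got ", length(items),
         call. = FALSE)
  }
  if (anyNA(items) || !all(items %in% 0:3)) {
    stop("QIDS items must all be integers in 0..3", call. = FALSE)
  }
  items <- as.integer(items)
  if (method == "sum") return(sum(items))
  sum(max(items[1:4]),            # sleep domain
      items[5],                   # sad mood
      max(items[6:9]),            # appetite/weight domain
      items[10:14],               # concentration, self-view, suicidality,
                                  # interest, energy
      max(items[15:16]))          # psychomotor slowing/agitation pair
}

#' Score a Brief LSAS response (14 situations, fear + avoidance)
#'
#' The Brief Liebowitz Social Anxiety Scale rates 14 social situations twice,
#' once for fear/anxiety and once for avoidance, each on a 0--3 scale; the
#' raw total is the sum of all 28 ratings (0--84). The instrument is
#' administered separately for a virtual (in-game) and a physical
#' (face-to-face) community context.
#'
#' @param fear,avoidance Integer vectors of length 14, entries in 0..3.
#' @return Integer raw total in 0..84. Rescale to the full 24-item LSAS
#'   metric with [adjust_lsas()].
#' @examples
#' score_brief_lsas(rep(1, 14), rep(0, 14))  # 14
#' @export
score_brief_lsas <- function(fear, avoidance) {
  for (nm in c("fear", "avoidance")) {
    x <- get(nm)
    if (length(x) != 14L) {
      stop("`", nm, "` must have exactly 14 items, got ", length(x),
           call. = FALSE)
    }
    if (anyNA(x) || !all(x %in% 0:3)) {
      stop("`", nm, "` items must all be integers in 0..3", call. = FALSE)
    }
  }
  sum(as.integer(fear)) + sum(as.integer(avoidance))
}

#' Rescale a Brief LSAS raw total to the 24-item LSAS metric
#'
#' The Brief LSAS covers 14 of the original 24 LSAS situations; raw totals
#' are multiplied by 24/14 so that the established full-scale clinical
#' cut-off of 30 applies. The value is returned unrounded and classification
#' compares the exact rational value against the cut-off.
#'
#' @param raw Non-negative raw total (or vector of totals).
#' @return `raw * 24/14`, unrounded.
#' @examples
#' adjust_lsas(14)    # 24
#' adjust_lsas(17.5)  # 30, exactly the cut-off
#' @export
adjust_lsas <- function(raw) {
  if (anyNA(raw) || any(raw < 0)) {
    stop("raw LSAS totals must be non-negative", call. = FALSE)
  }
  raw * 24 / 14
}

#' Clinical classification from scored totals
#'
#' `classify_depression()` flags QIDS totals at or above the clinical cut-off
#' of 6; `classify_social_anxiety()` flags adjusted (24-item metric) LSAS
#' scores at or above the cut-off of 30. Both thresholds are inclusive.
#'
#' @param qids_total QIDS total(s) in 0..27.
#' @param adjusted Adjusted LSAS score(s), non-negative.
#' @return Logical vector.
#' @examples
#' classify_depression(6)       # TRUE
#' classify_social_anxiety(29.999)  # FALSE
#' @export
classify_depression <- function(qids_total) {
  if (anyNA(qids_total) || any(qids_total < 0 | qids_total > 27)) {
    stop("QIDS totals must lie in 0..27", call. = FALSE)
  }
  qids_total >= 6
}

#' @rdname classify_depression
#' @export
classify_social_anxiety <- function(adjusted) {
  if (anyNA(adjusted) || any(adjusted < 0)) {
    stop("adjusted LSAS scores must be non-negative", call. = FALSE)
  }
  adjusted >= 30
}

#' Log2(x + 1) transform for heavy-tailed behaviour counts
#'
#' In-game behaviour counts (bell rings, avatar customizations) are
#' approximately power-law distributed; analyses use `log2(count + 1)` so
#' that zero maps to zero and doublings are unit steps.
#'
#' @param count Non-negative count(s).
#' @return `log2(count + 1)`.
#' @examples
#' log2p1(c(0, 1, 255))  # 0, 1, 8
#' @export
log2p1 <- function(count) {
  if (anyNA(count) || any(count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  log2(count + 1)
}

#' Build the log-time basis of the growth model
#'
#' The latent slope acts on transformed time `F[t] = log2(months + 1)`,
#' capturing the fast-then-slow shape typical of symptom change: with waves
#' at 0, 1, 2 and 3 months the loadings are 0.000, 1.000, 1.585 and 2.000.
#'
#' @param months Numeric vector of wave times in months since baseline,
#'   sorted ascending with first element 0.
#' @return An object of class `time_basis`: list with `waves` (1-based
#'   indices), `months`, and `loadings`.
#' @examples
#' time_basis(c(0, 1, 2, 3))$loadings  # 0 1 1.585 2
#' @export
time_basis <- function(months = c(0, 1, 2, 3)) {
  if (length(months) < 1L || anyNA(months) || any(months < 0)) {
    stop("`months` must be non-negative and non-missing", call. = FALSE)
  }
  if (is.unsorted(months, strictly = TRUE)) {
    stop("`months` must be strictly increasing", call. = FALSE)
  }
  if (months[1] != 0) {
    stop("the first wave must be at 0 months (baseline)", call. = FALSE)
  }
  structure(
    list(waves = seq_along(months), months = months,
         loadings = log2(months + 1)),
    class = "time_basis"
  )
}

#' @export
print.time_basis <- function(x, ...) {
  cat("Log-time basis (F[t] = log2(months + 1)):\n")
  print(data.frame(wave = x$waves, months = x$months,
                   loading = round(x$loadings, 3)), row.names = FALSE)
  invisible(x)
}

#' Score item-level questionnaire responses in a data frame
#'
#' Takes a data frame with item columns `qids_01..qids_16`,
#' `lsasV_fear_01..14` / `lsasV_avoid_01..14` (virtual community) and
#' `lsasP_fear_01..14` / `lsasP_avoid_01..14` (physical community) and
#' appends scored totals `qids_total`, `lsasV_adj`, `lsasP_adj` (the LSAS
#' columns already rescaled to the 24-item metric). Instruments whose
#' columns are absent are skipped.
#'
#' @param df Data frame of item-level responses, one row per participant.
#' @return `df` with scored-total columns appended.
#' @export
score_item_responses <- function(df) {
  stopifnot(is.data.frame(df))
  qids_cols <- sprintf("qids_%02d", 1:16)
  if (all(qids_cols %in% names(df))) {
    df$qids_total <- apply(as.matrix(df[qids_cols]), 1, score_qids)
  }
  for (ctx in c("V", "P")) {
    fear_cols <- sprintf("lsas%s_fear_%02d", ctx, 1:14)
    avoid_cols <- sprintf("lsas%s_avoid_%02d", ctx, 1:14)
    if (all(c(fear_cols, avoid_cols) %in% names(df))) {
      raw <- vapply(seq_len(nrow(df)), function(i) {
        score_brief_lsas(as.numeric(df[i, fear_cols]),
                         as.numeric(df[i, avoid_cols]))
      }, numeric(1))
      df[[paste0("lsas", ctx, "_adj")]] <- adjust_lsas(raw)
    }
  }
  df
}
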