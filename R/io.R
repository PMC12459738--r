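# Readers/writers for the wide and long trial CSV formats. Dialect:
# comma-separated, UTF-8, missing = empty cell.

trial_schema <- function() {
  c("id", "arm", "female", "age",
    paste0("qids_w", 1:4), paste0("lsas_v_w", 1:4),
    paste0("lsas_p_w", 1:4), paste0("bell_w", 1:4),
    paste0("custom_w", 1:4), "bonus_months", "reward_jpy")
}

#' Write a trial dataset to wide CSV
#'
#' One row per participant; missing values are written as empty cells.
#' Reals are written with full precision so a read round-trips to 1e-12.
#'
#' @param data A `trial_data` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  missing_cols <- setdiff(trial_schema(), names(data))
  if (length(missing_cols)) {
    stop("dataset lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[trial_schema()]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "", trimws(formatC(x, digits = 17, format = "g"))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a trial dataset from wide CSV
#'
#' Validates the header against the expected schema (unknown or missing
#' columns are an error naming them), maps empty cells to missing, and
#' checks that numeric columns parse (a non-numeric cell is an error giving
#' the row index). An empty data section is an error, not an empty dataset.
#'
#' @param path CSV file path.
#' @return A `trial_data` data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  schema <- trial_schema()
  unknown <- setdiff(names(raw), schema)
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(schema, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    stop("file has a header but no data rows: ", path, call. = FALSE)
  }
  out <- raw[schema]
  numeric_cols <- setdiff(schema, "arm")
  for (col in numeric_cols) {
    x <- out[[col]]
    x[x == ""] <- NA
    suppressWarnings(v <- as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("non-numeric value in column `", col, "`, row ", bad[1],
           ": \"", x[bad[1]], "\"", call. = FALSE)
    }
    out[[col]] <- v
  }
  int_cols <- c("id", "female", paste0("bell_w", 1:4),
                paste0("custom_w", 1:4), "bonus_months")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  bad_arm <- which(!out$arm %in% c("experimental", "waitlist"))
  if (length(bad_arm)) {
    stop("invalid arm label in row ", bad_arm[1], ": \"",
         out$arm[bad_arm[1]], "\"", call. = FALSE)
  }
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Reshape a trial dataset to long (participant-wave) format
#'
#' @param data A `trial_data` data frame.
#' @param basis The [time_basis()] supplying months and loadings per wave.
#' @return Data frame with one row per participant-wave: `id`, `arm`,
#'   `female`, `age`, `wave`, `months`, `loading`, `qids`, `lsas_v`,
#'   `lsas_p`, `bell`, `custom`.
#' @export
trial_long <- function(data, basis = time_basis()) {
  Tn <- length(basis$loadings)
  rows <- lapply(seq_len(Tn), function(t) {
    data.frame(id = data$id, arm = data$arm, female = data$female,
               age = data$age, wave = t, months = basis$months[t],
               loading = basis$loadings[t],
               qids = data[[paste0("qids_w", t)]],
               lsas_v = data[[paste0("lsas_v_w", t)]],
               lsas_p = data[[paste0("lsas_p_w", t)]],
               bell = data[[paste0("bell_w", t)]],
               custom = data[[paste0("custom_w", t)]])
  })
  out <- do.call(rbind, rows)
  out[order(out$id, out$wave), ]
}
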