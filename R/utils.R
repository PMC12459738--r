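# Internal numerical helpers shared by the likelihood and inference code.

# Inverse + log-determinant of a symmetric positive-definite matrix via
# Cholesky; returns NULL when the factorization fails so callers can fall
# back to the pseudo-inverse branch.
chol_inverse_logdet <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))), rank = ncol(S))
}

# Eigen pseudo-inverse with log-pseudo-determinant: eigenvalues at or below
# `tol` are treated as null directions and dropped from both the inverse and
# the determinant, keeping the likelihood finite for singular matrices.
pseudo_inverse_logdet <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol
  if (!any(keep)) {
    stop("covariance matrix has no eigenvalue above tolerance ", tol,
         call. = FALSE)
  }
  V <- e$vectors[, keep, drop = FALSE]
  list(inv = V %*% (t(V) / e$values[keep]),
       logdet = sum(log(e$values[keep])),
       rank = sum(keep))
}

# Either of the above, preferring the exact Cholesky route.
safe_inverse_logdet <- function(S, tol = 1e-12) {
  out <- chol_inverse_logdet(S)
  if (is.null(out)) out <- pseudo_inverse_logdet(S, tol = tol)
  out
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation helper: scalar integer-ish check.
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop("`", name, "` must be a single non-negative integer", call. = FALSE)
  }
  invisible(x)
}

# Small stable string hash (FNV-1a, 32-bit) for embedding a config
# fingerprint in reports without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
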