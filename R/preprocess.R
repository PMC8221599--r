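#' Discrete cosine transform band-pass filter
#'
#' Projects each time series onto an orthonormal DCT-II basis, removes the
#' `n_drop_low` lowest-frequency non-constant components (slow scanner drift)
#' and every component with frequency above `f_high` (high-frequency noise),
#' and reconstructs. The constant (DC) component is retained; the mean is
#' handled by the subsequent z-scoring step. Component `k` (`k = 0` the
#' constant) of a length-`T` series sampled at `tr` has frequency
#' `k / (2 T tr)` Hz.
#'
#' The operation is an orthogonal projection, hence idempotent.
#'
#' @param series numeric vector, or matrix with one column per vertex
#'   (rows = TRs).
#' @param tr sampling interval in seconds.
#' @param n_drop_low number of low-frequency non-constant components to
#'   remove (default 2).
#' @param f_high high-frequency cutoff in Hz (default 0.26); components with
#'   frequency strictly above it are removed.
#' @return filtered series, same shape as the input.
#' @export
dct_filter <- function(series, tr, n_drop_low = 2L, f_high = 0.26) {
  x <- as.matrix(series)
  T_ <- nrow(x)
  if (T_ < 8L) stop("series too short for DCT filtering (length < 8)")
  nyq <- 1 / (2 * tr)
  if (!(f_high > 0 && f_high < nyq)) stop("f_high must lie in (0, Nyquist)")
  keep <- dct_keep_mask(T_, tr, n_drop_low, f_high)
  B <- dct_basis(T_)                       # orthonormal, T x T
  coef <- crossprod(B, x)                  # DCT coefficients
  coef[!keep, ] <- 0
  out <- B %*% coef
  if (is.matrix(series)) out else drop(out)
}

# orthonormal DCT-II basis, columns indexed k = 0 .. T-1
dct_basis <- function(T_) {
  t_ <- seq_len(T_) - 0.5
  k <- seq_len(T_) - 1L
  B <- cos(outer(t_, k) * pi / T_)
  B <- sweep(B, 2L, sqrt(colSums(B^2)), "/")
  B
}

dct_keep_mask <- function(T_, tr, n_drop_low, f_high) {
  k <- seq_len(T_) - 1L
  freq <- k / (2 * T_ * tr)
  keep <- freq <= f_high
  if (n_drop_low > 0L) keep[1L + seq_len(n_drop_low)] <- FALSE
  keep
}

#' Condition raw BOLD runs into an averaged vertex time-series set
#'
#' Per run: drop the design's dummy volumes, DCT band-pass filter
#' ([dct_filter()]), and z-score each vertex's series; then average
#' element-wise across runs. A run whose series is constant for some vertex
#' (z-score undefined) is excluded from that vertex's average with a warning.
#' The averaged series is not re-standardized, so averaging independent noise
#' across R runs shrinks its SD by about `1/sqrt(R)`.
#'
#' @param runs list of numeric matrices (rows = volumes incl. dummies,
#'   columns = vertices), or a list of vectors for a single vertex.
#' @param design the `run_design` the runs follow.
#' @param n_drop_low,f_high passed to [dct_filter()].
#' @return object of class `vertex_series`: list with `values`
#'   (T_active x n_vertices matrix), `tr`, `n_runs_averaged` (per vertex),
#'   `condition`.
#' @export
preprocess_runs <- function(runs, design, n_drop_low = 2L, f_high = 0.26) {
  stopifnot(inherits(design, "run_design"))
  if (length(runs) == 0L) stop("zero runs supplied")
  runs <- lapply(runs, as.matrix)
  tv <- total_volumes(design)
  nr <- vapply(runs, nrow, integer(1))
  if (any(nr != tv))
    stop("runs of unequal or wrong length: expected ", tv, " volumes")
  nv <- ncol(runs[[1L]])
  if (any(vapply(runs, ncol, integer(1)) != nv))
    stop("runs differ in vertex count")

  ta <- active_volumes(design)
  acc <- matrix(0, ta, nv)
  nval <- integer(nv)
  n_const <- 0L
  for (r in runs) {
    raw <- r[design$n_dummy + seq_len(ta), , drop = FALSE]
    a <- dct_filter(raw, design$tr, n_drop_low, f_high)
    s <- apply(a, 2L, stats::sd)
    # constancy judged on the raw trimmed run (filtering leaves harmless
    # numerical ripples on an exactly constant series)
    ok <- apply(raw, 2L, stats::sd) > 0 & s > 0
    n_const <- n_const + sum(!ok)
    if (any(ok)) {
      z <- sweep(sweep(a[, ok, drop = FALSE], 2L, colMeans(a[, ok, drop = FALSE])),
                 2L, s[ok], "/")
      acc[, ok] <- acc[, ok] + z
      nval[ok] <- nval[ok] + 1L
    }
  }
  if (n_const > 0L)
    warning(n_const, " constant run/vertex series excluded from averaging")
  if (any(nval == 0L))
    warning(sum(nval == 0L), " vertex series constant in every run; returned as zeros")
  out <- sweep(acc, 2L, pmax(nval, 1L), "/")
  structure(list(values = out, tr = design$tr, n_runs_averaged = nval,
                 condition = design$kind),
            class = "vertex_series")
}

#' @export
print.vertex_series <- function(x, ...) {
  cat(sprintf("<vertex_series: %s, %d TRs x %d vertices, tr %g s, runs averaged %s>\n",
              x$condition, nrow(x$values), ncol(x$values), x$tr,
              paste(range(x$n_runs_averaged), collapse = "-")))
  invisible(x)
}

#' Write / read a vertex time-series matrix as TSV with a JSON sidecar
#'
#' @param series a `vertex_series`.
#' @param path TSV path (rows = TRs, columns = vertices); sidecar at
#'   `paste0(path, ".json")`.
#' @return `write_series`: `path` invisibly; `read_series`: a
#'   `vertex_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "vertex_series"))
  utils::write.table(series$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tr = series$tr, condition = series$condition,
                            n_runs_averaged = series$n_runs_averaged),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(v) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = v, tr = side$tr,
                 n_runs_averaged = side$n_runs_averaged,
                 condition = side$condition),
            class = "vertex_series")
}
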