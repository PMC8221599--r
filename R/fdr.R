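#' Empirical-null upper bound on the false discovery rate
#'
#' Estimates the FDR implied by an R-squared threshold as the proportion of
#' threshold crossings in a null distribution (time courses carrying no
#' stimulus-driven signal, e.g. white-matter series or pure-noise
#' simulations run through the identical fitting pipeline) divided by the
#' proportion of threshold crossings in the region of interest. This is a
#' conservative upper bound: it assumes every null-level crossing in the ROI
#' is a false discovery.
#'
#' @param null_r2 R-squared values of the null distribution.
#' @param roi_r2 R-squared values of the ROI vertices.
#' @param threshold R-squared threshold (strict `>`, default 0.3).
#' @return list with `p_fdr`, `p_null_cross`, `p_roi_cross`, `threshold`.
#' @examples
#' fdr_upper_bound(c(rep(0.1, 99), 0.5), c(rep(0.6, 5), rep(0.1, 5)))
#' @export
fdr_upper_bound <- function(null_r2, roi_r2, threshold = 0.3) {
  if (length(null_r2) == 0L || length(roi_r2) == 0L)
    stop("null and ROI distributions must be nonempty")
  p_null <- mean(null_r2 > threshold)
  p_roi <- mean(roi_r2 > threshold)
  if (p_roi == 0)
    stop("FDR undefined: no discoveries (no ROI series crosses the threshold)")
  list(p_fdr = p_null / p_roi, p_null_cross = p_null, p_roi_cross = p_roi,
       threshold = threshold)
}

#' Threshold fit results on R-squared
#'
#' Strict inequality, matching the convention that a fit at exactly the
#' threshold is excluded.
#'
#' @param fits a `fit_result` data.frame (or anything with an `r2` column),
#'   or a numeric vector of R-squared values.
#' @param r2_threshold threshold (default 0.3).
#' @return logical inclusion mask.
#' @export
threshold_fits <- function(fits, r2_threshold = 0.3) {
  r2 <- if (is.numeric(fits)) fits else fits$r2
  if (is.null(r2)) stop("fits carry no r2 values")
  r2 > r2_threshold
}

#' Write / read a null R-squared distribution as single-column TSV
#' @param r2 numeric vector of null R-squared values.
#' @param path file path.
#' @return `write_null_r2`: path invisibly; `read_null_r2`: numeric vector.
#' @export
write_null_r2 <- function(r2, path) {
  utils::write.table(data.frame(r2 = r2), path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_null_r2
#' @export
read_null_r2 <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)$r2
}
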