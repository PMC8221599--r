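#' Double-gamma hemodynamic response function parameters
#'
#' Parameter container for the double-gamma HRF: the difference of two gamma
#' density shapes, a positive response peaking at `peak_delay` seconds and an
#' undershoot peaking near `undershoot_delay` seconds scaled by
#' `1 / peak_undershoot_ratio`. Defaults are the widely used SPM-style
#' canonical values (peak delay 6 s, undershoot delay 16 s, dispersions 1,
#' ratio 6, kernel length 32 s).
#'
#' @param peak_delay,undershoot_delay delays in seconds (> 0).
#' @param peak_dispersion,undershoot_dispersion dimensionless dispersions (> 0).
#' @param peak_undershoot_ratio positive-to-undershoot amplitude ratio (> 0).
#' @param kernel_length kernel support in seconds (>= peak_delay).
#' @return object of class `hrf_params`.
#' @examples
#' hrf_params()  # canonical
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_undershoot_ratio = peak_undershoot_ratio,
            kernel_length = kernel_length)
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive")
  if (kernel_length < peak_delay) stop("kernel_length must be >= peak_delay")
  structure(p, class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(paste0("<hrf_params: peak %g s (disp %g), undershoot %g s (disp %g), ",
                     "ratio %g, length %g s>\n"),
              x$peak_delay, x$peak_dispersion, x$undershoot_delay,
              x$undershoot_dispersion, x$peak_undershoot_ratio, x$kernel_length))
  invisible(x)
}

#' Sample a double-gamma HRF kernel
#'
#' Evaluates the double-gamma response at `dt` spacing over
#' `[0, kernel_length]` and scales it to unit peak. Each lobe is a gamma
#' density with shape `delay / dispersion` and scale `dispersion`, so its
#' mode sits at `delay - dispersion`.
#'
#' @param params an `hrf_params`.
#' @param dt sampling interval in seconds (> 0).
#' @return numeric kernel vector with attribute `times`.
#' @export
double_gamma_kernel <- function(params, dt) {
  stopifnot(inherits(params, "hrf_params"))
  if (dt <= 0) stop("dt must be positive")
  t_ <- seq(0, params$kernel_length, by = dt)
  k <- stats::dgamma(t_, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(t_, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) / params$peak_undershoot_ratio
  k <- k / max(k)
  attr(k, "times") <- t_
  k
}

#' Convolve a neural prediction with an HRF kernel
#'
#' Causal linear convolution of the TR-resolution neural time course with the
#' kernel, truncated to the length of the input. The kernel may be supplied
#' as a vector already sampled at `tr`, or as an `hrf_params` object (sampled
#' internally).
#'
#' @param neural numeric vector, or matrix with one prediction per column.
#' @param kernel numeric kernel at `tr` spacing, or an `hrf_params`.
#' @param tr sampling interval in seconds.
#' @return predicted series, same shape as `neural`.
#' @export
convolve_prediction <- function(neural, kernel, tr) {
  if (length(neural) == 0L) stop("empty neural input")
  if (inherits(kernel, "hrf_params")) kernel <- double_gamma_kernel(kernel, tr)
  if (length(kernel) == 0L) stop("empty kernel")
  x <- as.matrix(neural)
  M <- conv_matrix(as.numeric(kernel), nrow(x))
  out <- M %*% x
  if (is.matrix(neural)) out else drop(out)
}

# T x T lower-triangular banded convolution operator for a causal kernel
conv_matrix <- function(kernel, T_) {
  nk <- min(length(kernel), T_)
  M <- matrix(0, T_, T_)
  for (j in seq_len(nk)) {
    idx <- seq_len(T_ - j + 1L)
    M[cbind(idx + j - 1L, idx)] <- kernel[j]
  }
  M
}

#' Fit pooled HRF parameters to observed series given fixed neural predictions
#'
#' Second stage of the two-pass procedure: with each vertex's best-fitting
#' neural prediction frozen from pass 1, searches for the HRF that maximizes
#' the mean R-squared (squared Pearson correlation between convolved
#' prediction and observed series) across vertices whose pass-1 fit crossed
#' `inclusion_r2`. A coarse grid over (peak delay, undershoot delay, peak
#' dispersion, ratio) is followed by a Nelder-Mead refinement on
#' log-parameters, clamped to the grid's bounding box; the undershoot
#' dispersion is tied to the peak dispersion. The result never scores below
#' the canonical HRF on the inclusion set.
#'
#' @param neural T x V matrix of pass-1 best neural predictions
#'   (pre-convolution), pooled across hemispheres/conditions.
#' @param observed T x V matrix of preprocessed series, same vertex order.
#' @param pass1_r2 length-V vector of pass-1 R-squared values.
#' @param tr sampling interval (seconds).
#' @param inclusion_r2 inclusion threshold on pass-1 R-squared (default 0.2,
#'   strict `>`).
#' @param canonical the fallback/reference `hrf_params`.
#' @param grid named list of candidate values for `peak_delay`,
#'   `undershoot_delay`, `peak_dispersion`, `peak_undershoot_ratio`.
#' @return list with `params` (`hrf_params`), `mean_r2`, `mean_r2_canonical`,
#'   `n_included`.
#' @export
fit_hrf <- function(neural, observed, pass1_r2, tr = 1,
                    inclusion_r2 = 0.2, canonical = hrf_params(),
                    grid = list(peak_delay = seq(4, 9, by = 1),
                                undershoot_delay = seq(12, 20, by = 2),
                                peak_dispersion = c(0.7, 1, 1.4),
                                peak_undershoot_ratio = c(3, 6, 12))) {
  neural <- as.matrix(neural); observed <- as.matrix(observed)
  stopifnot(nrow(neural) == nrow(observed), ncol(neural) == ncol(observed))
  inc <- which(pass1_r2 > inclusion_r2)
  if (length(inc) == 0L) {
    warning("no vertex crossed the HRF inclusion threshold; returning canonical HRF")
    return(list(params = canonical, mean_r2 = NA_real_,
                mean_r2_canonical = NA_real_, n_included = 0L))
  }
  N <- neural[, inc, drop = FALSE]
  Y <- scale(observed[, inc, drop = FALSE])   # unit-variance columns
  T_ <- nrow(N)

  score <- function(p) {
    # p = (peak_delay, undershoot_delay, peak_dispersion, ratio)
    par <- try(hrf_params(peak_delay = p[1], undershoot_delay = p[2],
                          peak_dispersion = p[3], undershoot_dispersion = p[3],
                          peak_undershoot_ratio = p[4],
                          kernel_length = canonical$kernel_length),
               silent = TRUE)
    if (inherits(par, "try-error")) return(-Inf)
    k <- double_gamma_kernel(par, tr)
    P <- conv_matrix(as.numeric(k), T_) %*% N
    P <- scale(P)
    r <- colSums(P * Y, na.rm = TRUE) / (T_ - 1)
    mean(r^2, na.rm = TRUE)
  }

  cand <- as.matrix(expand.grid(grid$peak_delay, grid$undershoot_delay,
                                grid$peak_dispersion, grid$peak_undershoot_ratio))
  scores <- apply(cand, 1L, score)
  best <- cand[which.max(scores), ]
  lo <- vapply(grid, min, numeric(1)); hi <- vapply(grid, max, numeric(1))
  obj <- function(lp) {
    p <- pmin(pmax(exp(lp), lo), hi)
    if (p[2] <= p[1]) return(Inf)        # undershoot after peak
    -score(p)
  }
  opt <- stats::optim(log(best), obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  p_fine <- pmin(pmax(exp(opt$par), lo), hi)

  canon_score <- score(c(canonical$peak_delay, canonical$undershoot_delay,
                         canonical$peak_dispersion, canonical$peak_undershoot_ratio))
  cands <- list(canonical = c(canonical$peak_delay, canonical$undershoot_delay,
                              canonical$peak_dispersion,
                              canonical$peak_undershoot_ratio),
                grid = best, fine = p_fine)
  sc <- c(canonical = canon_score, grid = max(scores), fine = -opt$value)
  win <- cands[[which.max(sc)]]
  list(params = hrf_params(peak_delay = win[1], undershoot_delay = win[2],
                           peak_dispersion = win[3], undershoot_dispersion = win[3],
                           peak_undershoot_ratio = win[4],
                           kernel_length = canonical$kernel_length),
       mean_r2 = max(sc), mean_r2_canonical = canon_score,
       n_included = length(inc))
}

#' Serialize HRF parameters to / from JSON
#' @param params an `hrf_params`.
#' @param path JSON file path.
#' @return `write_hrf`: `path` invisibly; `read_hrf`: an `hrf_params`.
#' @export
write_hrf <- function(params, path) {
  stopifnot(inherits(params, "hrf_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hrf
#' @export
read_hrf <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(hrf_params, p)
}
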