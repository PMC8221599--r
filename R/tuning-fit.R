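#' Default search grids for the Gaussian tuning model
#'
#' The peak grid spans normalized positions -0.2 to 1.2 in steps of 0.005
#' (281 values; peaks may lie somewhat outside the stimulus edges). The width
#' grid is log-spaced: `2^x` with `x` from -5.6 to 1 in steps of 0.05
#' (133 values, from about 0.0206 to 2 normalized units).
#'
#' @return numeric grid vector.
#' @export
default_mu_grid <- function() seq(-0.2, 1.2, by = 0.005)

#' @rdname default_mu_grid
#' @export
default_sigma_grid <- function() 2^seq(-5.6, 1, by = 0.05)

#' Gaussian population tuning curve parameters
#'
#' @param mu peak preference in normalized stimulus units (may lie in
#'   \[-0.2, 1.2\]).
#' @param sigma tuning width (SD) in normalized units (> 0).
#' @param beta response amplitude in z-units.
#' @return object of class `gaussian_ptc`.
#' @export
gaussian_ptc <- function(mu, sigma, beta = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(mu = mu, sigma = sigma, beta = beta), class = "gaussian_ptc")
}

#' Model-based neural response to one aperture position
#'
#' Integrates an unnormalized unit-peak Gaussian tuning curve against the
#' aperture occupancy of a single TR:
#' `sum_b w_b exp(-(x_b - mu)^2 / (2 sigma^2)) dx`.
#'
#' @param ptc a `gaussian_ptc` (or list with `mu`, `sigma`).
#' @param aperture_row occupancy weights for one TR (length = bin count).
#' @param bin_centers normalized bin center positions.
#' @return scalar neural response.
#' @export
neural_response <- function(ptc, aperture_row, bin_centers) {
  if (is.null(ptc$sigma) || ptc$sigma <= 0) stop("sigma must be positive")
  if (length(aperture_row) != length(bin_centers))
    stop("aperture_row length must equal bin count")
  dx <- if (length(bin_centers) > 1L) diff(bin_centers[1:2]) else 1
  sum(aperture_row * exp(-(bin_centers - ptc$mu)^2 / (2 * ptc$sigma^2))) * dx
}

# T x n neural time courses for parameter vectors mu, sigma over an aperture
neural_timecourses <- function(aperture, mu, sigma) {
  x <- aperture$bin_centers
  D2 <- outer(x, mu, "-")^2
  G <- exp(-sweep(D2, 2L, 2 * sigma^2, "/"))
  (aperture$weights %*% G) * aperture$bin_width
}

#' Build the convolved, variance-normalized prediction grid
#'
#' For every (mu, sigma) pair, computes the neural time course over the
#' aperture, convolves it with the HRF, and standardizes the result to zero
#' mean and unit variance (so that grid search reduces to a correlation
#' maximum). Pairs whose prediction is degenerate (near-zero variance, e.g.
#' a tiny Gaussian far outside the aperture's path) are flagged and excluded
#' from the search.
#'
#' Pairs are ordered by mu (ascending), then sigma (ascending), which fixes
#' the deterministic tie-break of [coarse_fit()]: the first maximizer wins.
#'
#' @param aperture an `aperture_matrix`.
#' @param mu_grid,sigma_grid parameter grids (defaults [default_mu_grid()],
#'   [default_sigma_grid()]).
#' @param hrf an `hrf_params` or kernel vector sampled at `tr`.
#' @param tr sampling interval in seconds.
#' @return object of class `prediction_grid`: list with `pred`
#'   (T x n_retained standardized matrix), `grid` (data.frame `mu`, `sigma`
#'   for retained pairs), `dropped` (data.frame of excluded pairs), `tr`.
#' @export
prediction_grid <- function(aperture, mu_grid = default_mu_grid(),
                            sigma_grid = default_sigma_grid(),
                            hrf = hrf_params(), tr = 1) {
  stopifnot(inherits(aperture, "aperture_matrix"))
  if (length(mu_grid) == 0L || length(sigma_grid) == 0L) stop("empty grid")
  g <- expand.grid(sigma = sigma_grid, mu = mu_grid,
                   KEEP.OUT.ATTRS = FALSE)   # sigma fastest => mu-major order
  g <- g[, c("mu", "sigma")]
  N <- neural_timecourses(aperture, g$mu, g$sigma)
  P <- convolve_prediction(N, hrf, tr)
  mu_c <- colMeans(P)
  sdv <- sqrt(colSums(sweep(P, 2L, mu_c)^2) / (nrow(P) - 1L))
  ok <- is.finite(sdv) & sdv > 1e-10 * max(sdv, 1e-300)
  Pn <- sweep(sweep(P[, ok, drop = FALSE], 2L, mu_c[ok]), 2L, sdv[ok], "/")
  structure(list(pred = Pn, grid = g[ok, , drop = FALSE],
                 dropped = g[!ok, , drop = FALSE], tr = tr),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("<prediction_grid: %d TRs x %d (mu, sigma) pairs (%d dropped)>\n",
              nrow(x$pred), nrow(x$grid), nrow(x$dropped)))
  invisible(x)
}

#' Coarse grid fit of the Gaussian tuning model
#'
#' Selects, independently for every vertex, the (mu, sigma) pair whose
#' convolved prediction maximizes the squared Pearson correlation with the
#' observed series; R-squared is that maximum. The amplitude `beta` is the
#' least-squares scaling of the chosen (standardized) prediction onto the
#' series, and the residual sum of squares feeds the per-vertex BIC
#' (`n log(RSS/n) + k log n`, `k = 3`). Ties break to the first maximizer
#' (lowest mu, then lowest sigma). A constant series gets `r2 = 0` and is
#' flagged invalid.
#'
#' @param series numeric vector, matrix (T x vertices), or `vertex_series`.
#' @param pgrid a `prediction_grid`.
#' @return data.frame of class `fit_result` with one row per vertex:
#'   `vertex_id`, `mu`, `sigma`, `beta`, `r2`, `rss`, `bic`, `valid`;
#'   attributes `model = "gaussian"`, `k = 3`.
#' @export
coarse_fit <- function(series, pgrid) {
  stopifnot(inherits(pgrid, "prediction_grid"))
  Y <- if (inherits(series, "vertex_series")) series$values else as.matrix(series)
  T_ <- nrow(Y)
  if (T_ != nrow(pgrid$pred)) stop("series and predictions differ in length")
  nv <- ncol(Y)
  ym <- colMeans(Y)
  ysd <- sqrt(colSums(sweep(Y, 2L, ym)^2) / (T_ - 1L))
  valid <- is.finite(ysd) & ysd > 0

  idx <- integer(nv); r2 <- numeric(nv)
  P <- pgrid$pred
  chunk <- max(1L, floor(2e7 / max(nrow(pgrid$grid), 1L)))
  for (s in seq(1L, nv, by = chunk)) {
    cols <- s:min(s + chunk - 1L, nv)
    vc <- cols[valid[cols]]
    if (!length(vc)) { idx[cols] <- 1L; next }
    Yn <- sweep(sweep(Y[, vc, drop = FALSE], 2L, ym[vc]), 2L, ysd[vc], "/")
    R2 <- (crossprod(P, Yn) / (T_ - 1L))^2
    idx[vc] <- apply(R2, 2L, which.max)
    r2[vc] <- R2[cbind(idx[vc], seq_along(vc))]
    bad <- cols[!valid[cols]]
    if (length(bad)) idx[bad] <- 1L
  }
  mu <- pgrid$grid$mu[idx]
  sigma <- pgrid$grid$sigma[idx]
  Psel <- P[, idx, drop = FALSE]
  beta <- colSums(Psel * Y) / colSums(Psel^2)
  beta[!valid] <- 0
  rss <- colSums((Y - sweep(Psel, 2L, beta, "*"))^2)
  r2[!valid] <- 0
  bic <- ifelse(rss > 0, T_ * log(rss / T_) + 3 * log(T_), -Inf)
  out <- data.frame(vertex_id = seq_len(nv), mu = mu, sigma = sigma,
                    beta = beta, r2 = r2, rss = rss, bic = bic, valid = valid)
  structure(out, class = c("fit_result", "data.frame"),
            model = "gaussian", k = 3L, n_timepoints = T_)
}

#' Local refinement of a coarse Gaussian fit
#'
#' Nelder-Mead optimization of (mu, log2 sigma) maximizing the squared
#' Pearson correlation of the convolved prediction with the observed series,
#' started from the coarse-fit solution. mu is clamped to \[-0.2, 1.2\] and
#' sigma to the default grid's range; the returned fit never scores below
#' the initial one.
#'
#' @param series numeric vector (one vertex).
#' @param init list/row with `mu`, `sigma` (typically a [coarse_fit()] row).
#' @param aperture an `aperture_matrix`.
#' @param hrf an `hrf_params` or kernel vector at `tr`.
#' @param tr sampling interval in seconds.
#' @param mu_bounds,log2_sigma_bounds clamping boxes.
#' @return one-row `fit_result` data.frame (see [coarse_fit()]).
#' @export
fine_fit <- function(series, init, aperture, hrf = hrf_params(), tr = 1,
                     mu_bounds = c(-0.2, 1.2), log2_sigma_bounds = c(-5.6, 1)) {
  y <- as.numeric(series)
  T_ <- length(y)
  if (stats::sd(y) == 0) stop("constant series")
  if (inherits(hrf, "hrf_params")) hrf <- double_gamma_kernel(hrf, tr)
  M <- conv_matrix(as.numeric(hrf), T_)
  yc <- y - mean(y)

  r2_of <- function(mu, sigma) {
    n <- neural_timecourses(aperture, mu, sigma)
    p <- drop(M %*% n)
    pc <- p - mean(p)
    vp <- sum(pc^2)
    if (vp < 1e-300) return(list(r2 = 0, pred = NULL))
    r2 <- sum(pc * yc)^2 / (vp * sum(yc^2))
    list(r2 = r2, pred = p)
  }
  obj <- function(par) {
    mu <- min(max(par[1], mu_bounds[1]), mu_bounds[2])
    ls <- min(max(par[2], log2_sigma_bounds[1]), log2_sigma_bounds[2])
    -r2_of(mu, 2^ls)$r2
  }
  p0 <- c(init$mu, log2(init$sigma))
  opt <- try(stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(opt, "try-error")) {
    warning("fine fit optimizer failed; returning initial fit")
    par <- p0
  } else par <- opt$par
  mu <- min(max(par[1], mu_bounds[1]), mu_bounds[2])
  sigma <- 2^min(max(par[2], log2_sigma_bounds[1]), log2_sigma_bounds[2])
  if (-obj(c(mu, log2(sigma))) < r2_of(init$mu, init$sigma)$r2) {
    mu <- init$mu; sigma <- init$sigma
  }
  fr <- r2_of(mu, sigma)
  p <- if (is.null(fr$pred)) NULL else fr$pred - mean(fr$pred)
  beta <- if (is.null(p)) 0 else sum(p * y) / sum(p^2)
  rss <- if (is.null(p)) sum(y^2) else sum((y - beta * p)^2)
  out <- data.frame(vertex_id = 1L, mu = mu, sigma = sigma, beta = beta,
                    r2 = fr$r2, rss = rss,
                    bic = ifelse(rss > 0, T_ * log(rss / T_) + 3 * log(T_), -Inf),
                    valid = TRUE)
  structure(out, class = c("fit_result", "data.frame"),
            model = "gaussian", k = 3L, n_timepoints = T_)
}

#' Two-pass tuning fit with pooled HRF estimation
#'
#' Pass 1 fits the Gaussian grid under the canonical HRF for every condition.
#' Vertices whose pass-1 R-squared exceeds `inclusion_r2` (default 0.2) are
#' pooled across conditions, their best neural predictions frozen, and the
#' double-gamma HRF parameters fitted to maximize mean R-squared
#' ([fit_hrf()]). Pass 2 refits the tuning grid under the fitted HRF
#' (optionally followed by a per-vertex [fine_fit()]). If no vertex crosses
#' the inclusion threshold, pass 2 uses the canonical HRF with a warning.
#'
#' @param series_list named list of `vertex_series` (or T x V matrices), one
#'   per condition; all conditions must share the vertex count for pooling.
#' @param apertures named list of `aperture_matrix` objects matching
#'   `series_list`.
#' @param mu_grid,sigma_grid search grids.
#' @param canonical canonical `hrf_params` for pass 1.
#' @param inclusion_r2 HRF-fit inclusion threshold on pass-1 R-squared.
#' @param fine logical; run [fine_fit()] on every vertex in pass 2.
#' @param tr sampling interval in seconds.
#' @param hrf_grid optional HRF coarse grid passed to [fit_hrf()].
#' @return list with `fits` (per condition: list `pass1`, `pass2` of
#'   `fit_result` data.frames), `hrf` (fitted `hrf_params`), `hrf_fit`
#'   (diagnostics from [fit_hrf()]).
#' @export
two_pass_fit <- function(series_list, apertures,
                         mu_grid = default_mu_grid(),
                         sigma_grid = default_sigma_grid(),
                         canonical = hrf_params(), inclusion_r2 = 0.2,
                         fine = FALSE, tr = 1, hrf_grid = NULL) {
  stopifnot(length(series_list) >= 1L,
            identical(sort(names(series_list)), sort(names(apertures))))
  conds <- names(series_list)
  getY <- function(s) if (inherits(s, "vertex_series")) s$values else as.matrix(s)

  pass1 <- list(); pooled_neural <- list(); pooled_obs <- list(); pooled_r2 <- list()
  for (cn in conds) {
    pg <- prediction_grid(apertures[[cn]], mu_grid, sigma_grid, canonical, tr)
    f1 <- coarse_fit(series_list[[cn]], pg)
    pass1[[cn]] <- f1
    Y <- getY(series_list[[cn]])
    pooled_neural[[cn]] <- neural_timecourses(apertures[[cn]], f1$mu, f1$sigma)
    pooled_obs[[cn]] <- Y
    pooled_r2[[cn]] <- f1$r2
  }
  hrf_args <- list(neural = do.call(cbind, pooled_neural),
                   observed = do.call(cbind, pooled_obs),
                   pass1_r2 = unlist(pooled_r2), tr = tr,
                   inclusion_r2 = inclusion_r2, canonical = canonical)
  if (!is.null(hrf_grid)) hrf_args$grid <- hrf_grid
  hf <- do.call(fit_hrf, hrf_args)
  fitted_hrf <- hf$params

  pass2 <- list()
  for (cn in conds) {
    pg2 <- prediction_grid(apertures[[cn]], mu_grid, sigma_grid, fitted_hrf, tr)
    f2 <- coarse_fit(series_list[[cn]], pg2)
    if (fine) {
      Y <- getY(series_list[[cn]])
      for (v in which(f2$valid)) {
        ff <- fine_fit(Y[, v], f2[v, ], apertures[[cn]], fitted_hrf, tr)
        f2[v, c("mu", "sigma", "beta", "r2", "rss", "bic")] <-
          ff[1L, c("mu", "sigma", "beta", "r2", "rss", "bic")]
      }
    }
    pass2[[cn]] <- f2
  }
  list(fits = lapply(stats::setNames(conds, conds), function(cn)
         list(pass1 = pass1[[cn]], pass2 = pass2[[cn]])),
       hrf = fitted_hrf, hrf_fit = hf)
}
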