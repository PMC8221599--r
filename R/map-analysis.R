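#' Posterior-anterior axis positions of surface vertices
#'
#' Projects each vertex's 3D position onto the direction defined by the two
#' axis endpoints and min-max normalizes the projections to \[0, 1\], with 0
#' at the most posterior vertex and 1 at the most anterior. The result is
#' invariant to rigid-body transforms applied jointly to vertices and axis
#' endpoints.
#'
#' @param roi a `surface_roi` from [surface_roi()], or a list with
#'   `coordinates` (n x 3), `axis_start`, `axis_end`.
#' @return numeric vector of axis positions in \[0, 1\].
#' @export
axis_positions <- function(roi) {
  xyz <- as.matrix(roi$coordinates)
  dir <- as.numeric(roi$axis_end) - as.numeric(roi$axis_start)
  if (sqrt(sum(dir^2)) < 1e-12) stop("degenerate axis: coincident endpoints")
  proj <- drop(xyz %*% (dir / sqrt(sum(dir^2))))
  rng <- range(proj)
  if (diff(rng) < 1e-12) stop("all vertices project to one point on the axis")
  (proj - rng[1]) / diff(rng)
}

#' Construct a surface region of interest
#'
#' @param coordinates n x 3 matrix of vertex positions (mm).
#' @param hemisphere hemisphere label.
#' @param axis_start,axis_end 3D points defining the posterior-anterior axis
#'   (start = posterior).
#' @param vertex_ids optional ids (default `1:n`).
#' @return object of class `surface_roi`.
#' @export
surface_roi <- function(coordinates, hemisphere, axis_start, axis_end,
                        vertex_ids = seq_len(nrow(coordinates))) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 3L) stop("an ROI needs at least 3 vertices")
  if (ncol(coordinates) != 3L) stop("coordinates must be n x 3")
  if (isTRUE(all.equal(as.numeric(axis_start), as.numeric(axis_end))))
    stop("degenerate axis: coincident endpoints")
  structure(list(vertex_ids = vertex_ids, coordinates = coordinates,
                 hemisphere = hemisphere, axis_start = axis_start,
                 axis_end = axis_end),
            class = "surface_roi")
}

#' Assemble the per-vertex tuning-pair table
#'
#' One row per vertex: the spatial and face fit parameters, the axis
#' position and the hemisphere label — the unit of every map-level
#' statistic.
#'
#' @param spatial_fit,face_fit `fit_result` data.frames, same vertex order.
#' @param axis_position per-vertex positions in \[0, 1\].
#' @param hemisphere per-vertex hemisphere labels.
#' @return data.frame of class `tuning_pairs` with columns `vertex_id`,
#'   `hemisphere`, `axis_position`, `sp_mu`, `sp_sigma`, `sp_r2`, `face_mu`,
#'   `face_sigma`, `face_r2`.
#' @export
tuning_pairs <- function(spatial_fit, face_fit, axis_position, hemisphere) {
  stopifnot(nrow(spatial_fit) == nrow(face_fit),
            nrow(spatial_fit) == length(axis_position),
            nrow(spatial_fit) == length(hemisphere))
  out <- data.frame(vertex_id = spatial_fit$vertex_id, hemisphere = hemisphere,
                    axis_position = axis_position,
                    sp_mu = spatial_fit$mu, sp_sigma = spatial_fit$sigma,
                    sp_r2 = spatial_fit$r2,
                    face_mu = face_fit$mu, face_sigma = face_fit$sigma,
                    face_r2 = face_fit$r2)
  structure(out, class = c("tuning_pairs", "data.frame"))
}

#' Per-hemisphere map correlations
#'
#' Computes one correlation per hemisphere over threshold-passing vertices,
#' for one of the map-level relationships:
#' \describe{
#'   \item{`sigma_vs_axis`}{tuning width (log2 sigma) vs posterior-anterior
#'     axis position, within `domain`.}
#'   \item{`mu_cross`}{spatial vs face peak position.}
#'   \item{`sigma_cross`}{spatial vs face tuning width (log2).}
#'   \item{`sigma_vs_ecc`}{tuning width vs absolute distance of the peak from
#'     the space center `|mu - 0.5|`, within `domain`.}
#' }
#' The robustness restriction (`restricted = TRUE`) keeps only vertices with
#' `sigma < 1` and `0 < mu < 1` in both domains.
#'
#' @param pairs a `tuning_pairs` data.frame.
#' @param what one of `"sigma_vs_axis"`, `"mu_cross"`, `"sigma_cross"`,
#'   `"sigma_vs_ecc"`.
#' @param domain `"spatial"` or `"face"` (used by the within-domain specs).
#' @param method `"pearson"` or `"spearman"`.
#' @param r2_threshold R-squared inclusion threshold (strict, both fits).
#' @param restricted logical; apply the sigma < 1, 0 < mu < 1 restriction.
#' @param log2_sigma correlate widths on a log2 scale (default TRUE).
#' @return named numeric vector of per-hemisphere correlations; hemispheres
#'   with fewer than 3 qualifying vertices are omitted with a warning.
#' @export
map_correlations <- function(pairs,
                             what = c("sigma_vs_axis", "mu_cross",
                                      "sigma_cross", "sigma_vs_ecc"),
                             domain = c("spatial", "face"),
                             method = c("pearson", "spearman"),
                             r2_threshold = 0.3, restricted = FALSE,
                             log2_sigma = TRUE) {
  what <- match.arg(what); domain <- match.arg(domain)
  method <- match.arg(method)
  keep <- pairs$sp_r2 > r2_threshold & pairs$face_r2 > r2_threshold
  if (restricted)
    keep <- keep & pairs$sp_sigma < 1 & pairs$face_sigma < 1 &
      pairs$sp_mu > 0 & pairs$sp_mu < 1 & pairs$face_mu > 0 & pairs$face_mu < 1
  p <- pairs[keep, , drop = FALSE]
  wtrans <- if (log2_sigma) log2 else identity
  xy <- switch(what,
    sigma_vs_axis = if (domain == "spatial")
      list(x = p$axis_position, y = wtrans(p$sp_sigma))
    else list(x = p$axis_position, y = wtrans(p$face_sigma)),
    mu_cross    = list(x = p$sp_mu, y = p$face_mu),
    sigma_cross = list(x = wtrans(p$sp_sigma), y = wtrans(p$face_sigma)),
    sigma_vs_ecc = if (domain == "spatial")
      list(x = abs(p$sp_mu - 0.5), y = wtrans(p$sp_sigma))
    else list(x = abs(p$face_mu - 0.5), y = wtrans(p$face_sigma)))
  hemis <- unique(pairs$hemisphere)
  r <- vapply(hemis, function(h) {
    i <- p$hemisphere == h
    if (sum(i) < 3L) return(NA_real_)
    stats::cor(xy$x[i], xy$y[i], method = method)
  }, numeric(1))
  names(r) <- hemis
  if (anyNA(r)) {
    warning(sum(is.na(r)), " hemisphere(s) omitted (< 3 qualifying vertices)")
    r <- r[!is.na(r)]
  }
  r
}

#' Fisher-z one-sample group test of per-hemisphere correlations
#'
#' Converts the per-hemisphere correlations to Fisher z (`atanh`), then
#' tests the group mean against 0 with a one-sample t test (two-sided p).
#' Correlations with `|r| = 1` (infinite z) are excluded with a warning.
#'
#' @param per_hemisphere_r named numeric vector of correlations.
#' @param method tag recorded in the result (`"pearson"` or `"spearman"`).
#' @return object of class `group_stat`: list with `per_hemisphere_r`,
#'   `fisher_z`, `t_value`, `df`, `p_two_sided`, `method`, `median_r`.
#' @export
group_ttest <- function(per_hemisphere_r, method = "pearson") {
  r <- per_hemisphere_r
  bad <- abs(r) >= 1
  if (any(bad)) {
    warning(sum(bad), " correlation(s) with |r| = 1 excluded (infinite Fisher z)")
    r <- r[!bad]
  }
  if (length(r) < 2L) stop("need at least 2 hemispheres for the group test")
  z <- atanh(r)
  if (stats::sd(z) == 0) stop("zero variance in Fisher-z values")
  n <- length(z)
  t_val <- mean(z) / (stats::sd(z) / sqrt(n))
  p <- 2 * stats::pt(-abs(t_val), df = n - 1L)
  structure(list(per_hemisphere_r = per_hemisphere_r, fisher_z = z,
                 t_value = t_val, df = n - 1L, p_two_sided = p,
                 method = method, median_r = stats::median(r)),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("<group_stat: median r = %.3f, t(%d) = %.2f, p = %.4g (%s)>\n",
              x$median_r, x$df, x$t_value, x$p_two_sided, x$method))
  invisible(x)
}

#' Compare fits between paired sub-conditions
#'
#' For split-condition controls (eye- vs mouth-stimulus spatial maps; upper-
#' vs lower-location face maps). Reports (a) the per-hemisphere difference in
#' median peak height (height = `0.5 - mu`, positive = higher in the
#' face / visual field) tested across hemispheres with a one-sample t test,
#' and (b) the difference in median R-squared between sub-conditions tested
#' by permutation: the pooled R-squared values are randomly re-partitioned
#' `n_permutations` times and the reported p is the add-one-smoothed
#' proportion of permuted |median differences| at least as large as the
#' observed one (identical sets therefore give p = 1).
#'
#' @param fits_a,fits_b `fit_result` data.frames for the two sub-conditions,
#'   same vertex order.
#' @param hemisphere per-vertex hemisphere labels.
#' @param n_permutations permutation count (default 10000).
#' @param seed RNG seed for the permutation test.
#' @return list with `peak_height`: (`per_hemisphere_diff`, `t_value`, `df`,
#'   `p_two_sided`) and `goodness`: (`median_r2_a`, `median_r2_b`,
#'   `observed_diff`, `p_perm`, `n_permutations`).
#' @export
split_compare <- function(fits_a, fits_b, hemisphere,
                          n_permutations = 10000L, seed = 1L) {
  if (nrow(fits_a) != nrow(fits_b)) stop("mismatched vertex sets")
  stopifnot(length(hemisphere) == nrow(fits_a))
  height_a <- 0.5 - fits_a$mu
  height_b <- 0.5 - fits_b$mu
  hemis <- unique(hemisphere)
  dmed <- vapply(hemis, function(h) {
    i <- hemisphere == h
    stats::median(height_a[i]) - stats::median(height_b[i])
  }, numeric(1))
  names(dmed) <- hemis
  if (length(dmed) >= 2L && stats::sd(dmed) > 0) {
    t_val <- mean(dmed) / (stats::sd(dmed) / sqrt(length(dmed)))
    p_t <- 2 * stats::pt(-abs(t_val), df = length(dmed) - 1L)
  } else {
    t_val <- NA_real_; p_t <- NA_real_
  }

  ra <- fits_a$r2; rb <- fits_b$r2
  obs <- stats::median(ra) - stats::median(rb)
  pooled <- c(ra, rb)
  na <- length(ra)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(length(pooled), na)
    d <- stats::median(pooled[idx]) - stats::median(pooled[-idx])
    if (abs(d) >= abs(obs)) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1L) / (n_permutations + 1L)
  list(peak_height = list(per_hemisphere_diff = dmed, t_value = t_val,
                          df = length(dmed) - 1L, p_two_sided = p_t),
       goodness = list(median_r2_a = stats::median(ra),
                       median_r2_b = stats::median(rb),
                       observed_diff = obs, p_perm = p_perm,
                       n_permutations = n_permutations))
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
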