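# Shared fixtures: reduced search grids and a fast miniature design.

# reduced grids (29 mu x 14 sigma) used wherever the full canonical grids
# would only add runtime
red_mu <- seq(-0.2, 1.2, by = 0.05)
red_sigma <- 2^seq(-5.6, 1, by = 0.5)

# miniature run design: 6 x 8 s trials (48 active TRs), coarser aperture;
# same invariant structure as the canonical designs
tiny_design <- function(kind = "spatial") {
  make_run_design(kind, overrides = list(
    trial_duration = 8, n_dummy = 4L, aperture_height = 0.25,
    step_size = 0.2, update_period = 2L))
}

tiny_aperture <- function(kind = "spatial", n_bins = 50L) {
  build_aperture(tiny_design(kind), n_bins)
}

# noiseless observed series at given (mu, sigma): the convolved neural
# time course itself (no preprocessing), standardized
noiseless_series <- function(aperture, mu, sigma, hrf = hrf_params(), tr = 1) {
  n <- neural_timecourses(aperture, mu, sigma)
  p <- convolve_prediction(n, hrf, tr)
  scale(p)
}

# independent brute-force grid fit: loop over all pairs, stats::cor each.
# Applies the same degenerate-prediction rule as the contract (pairs whose
# prediction variance is negligible relative to the grid maximum are not
# searched), then picks the first maximizer in (mu, sigma) order.
brute_force_fit <- function(y, aperture, mu_grid, sigma_grid,
                            hrf = hrf_params(), tr = 1) {
  preds <- list()
  i <- 0L
  for (mu in mu_grid) for (sg in sigma_grid) {
    n <- vapply(seq_len(nrow(aperture$weights)), function(t_)
      neural_response(list(mu = mu, sigma = sg), aperture$weights[t_, ],
                      aperture$bin_centers), numeric(1))
    p <- convolve_prediction(n, hrf, tr)
    i <- i + 1L
    preds[[i]] <- list(mu = mu, sigma = sg, p = p, sd = stats::sd(p))
  }
  sd_max <- max(vapply(preds, `[[`, numeric(1), "sd"))
  best <- list(r2 = -1, mu = NA, sigma = NA)
  for (pr in preds) {
    if (pr$sd <= 1e-10 * sd_max) next
    r2 <- stats::cor(pr$p, y)^2
    if (is.finite(r2) && r2 > best$r2)
      best <- list(r2 = r2, mu = pr$mu, sigma = pr$sigma)
  }
  best
}
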