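straight_roi <- function(n = 20L, seed = 51) {
  set.seed(seed)
  ax <- seq(0, 1, length.out = n)
  surface_roi(cbind(40 * ax, rnorm(n, 0, 2), rnorm(n, 0, 2)), "H01",
              axis_start = c(0, 0, 0), axis_end = c(40, 0, 0))
}

test_that("axis positions span [0, 1] from posterior to anterior", {
  roi <- straight_roi()
  pos <- axis_positions(roi)
  expect_equal(min(pos), 0)
  expect_equal(max(pos), 1)
  expect_equal(which.min(pos), 1L)   # most posterior vertex
  expect_equal(which.max(pos), 20L)  # most anterior

  # geometric midpoint of two extremes on a straight axis -> 0.5
  roi3 <- surface_roi(rbind(c(0, 0, 0), c(5, 1, -1), c(10, 0, 0)), "H01",
                      c(0, 0, 0), c(10, 0, 0))
  expect_equal(axis_positions(roi3)[2], 0.5)

  expect_error(surface_roi(matrix(0, 3, 3), "H01", c(1, 1, 1), c(1, 1, 1)),
               "degenerate axis")
  expect_error(axis_positions(list(coordinates = matrix(rnorm(9), 3),
                                   axis_start = c(0, 0, 0),
                                   axis_end = c(0, 0, 0))),
               "degenerate axis")
})

test_that("axis positions are rigid-body invariant", {
  roi <- straight_roi()
  pos <- axis_positions(roi)
  set.seed(52)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))       # random rotation (maybe improper)
  shift <- c(12, -7, 3)
  roi2 <- surface_roi(sweep(roi$coordinates %*% Q, 2, -shift), "H01",
                      drop(roi$axis_start %*% Q) + shift,
                      drop(roi$axis_end %*% Q) + shift)
  expect_lt(max(abs(axis_positions(roi2) - pos)), 1e-8)
})

fake_pairs <- function(n = 400L, n_hemi = 4L, seed = 53) {
  set.seed(seed)
  hemi <- rep(sprintf("H%02d", seq_len(n_hemi)), each = n / n_hemi)
  ax <- runif(n)
  sp_sigma <- 2^(-4 + 3 * ax + rnorm(n, 0, 0.8))
  data.frame(vertex_id = seq_len(n), hemisphere = hemi, axis_position = ax,
             sp_mu = runif(n), sp_sigma = sp_sigma, sp_r2 = runif(n, 0.35, 0.9),
             face_mu = runif(n), face_sigma = 2^(log2(sp_sigma) * 0.5 - 1),
             face_r2 = runif(n, 0.35, 0.9))
}

test_that("map_correlations recover exact and directional structure", {
  p <- fake_pairs()
  # face sigma an exact log-linear function of spatial sigma -> r = 1
  r <- map_correlations(p, "sigma_cross")
  expect_equal(unname(r), rep(1, 4), tolerance = 1e-12)

  # widths grow with axis position by construction
  r_ax <- map_correlations(p, "sigma_vs_axis", "spatial")
  expect_true(all(r_ax > 0))

  # width vs peak eccentricity: positive when built in
  p2 <- fake_pairs()
  p2$sp_sigma <- 2^(-4 + 4 * abs(p2$sp_mu - 0.5) + rnorm(nrow(p2), 0, 0.4))
  r_ecc <- map_correlations(p2, "sigma_vs_ecc", "spatial")
  expect_true(all(r_ecc > 0))
})

test_that("pearson and spearman agree on well-behaved bivariate maps", {
  set.seed(54)
  n <- 2000L
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, sqrt(0.75))
  p <- data.frame(vertex_id = seq_len(n), hemisphere = "H01",
                  axis_position = runif(n), sp_mu = x, sp_sigma = 0.2,
                  sp_r2 = 0.5, face_mu = y, face_sigma = 0.2, face_r2 = 0.5)
  r_p <- map_correlations(p, "mu_cross", method = "pearson")
  r_s <- map_correlations(p, "mu_cross", method = "spearman")
  expect_lt(abs(r_p - r_s), 0.05)
})

test_that("underpopulated hemispheres are omitted with a warning", {
  p <- fake_pairs(40L, 2L)
  p$sp_r2[p$hemisphere == "H02"] <- 0.1   # nothing crosses threshold
  expect_warning(r <- map_correlations(p, "sigma_cross"), "omitted")
  expect_named(r, "H01")
})

test_that("the restricted-range control drops wide and out-of-space fits", {
  p <- fake_pairs()
  # make one hemisphere entirely wide-tuned: the restriction empties it
  set.seed(57)
  p$sp_sigma[p$hemisphere == "H04"] <- runif(sum(p$hemisphere == "H04"), 1.2, 1.9)
  r_full <- map_correlations(p, "sigma_cross")
  expect_length(r_full, 4L)
  expect_warning(r_res <- map_correlations(p, "sigma_cross", restricted = TRUE),
                 "omitted")
  expect_false("H04" %in% names(r_res))
})

test_that("group_ttest matches the reference t test and its symmetries", {
  # symmetric correlations: t = 0, p = 1
  g <- group_ttest(c(0.5, -0.5, 0.3, -0.3))
  expect_equal(g$t_value, 0, tolerance = 1e-12)
  expect_equal(g$p_two_sided, 1, tolerance = 1e-12)
  expect_identical(g$df, 3L)

  # reference-stats oracle on a fixed vector
  r <- c(0.2, 0.3, 0.4, 0.5)
  g2 <- group_ttest(r)
  ref <- t.test(atanh(r), mu = 0)
  expect_equal(g2$t_value, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(g2$p_two_sided, ref$p.value, tolerance = 1e-10)

  expect_warning(group_ttest(c(1.0, 0.3, 0.2)), "excluded")
  expect_error(group_ttest(c(0.3, 0.3, 0.3)), "zero variance")
  expect_error(suppressWarnings(group_ttest(c(1.0, 0.5))), "at least 2")
})

test_that("group_ttest holds its type-I error rate", {
  set.seed(55)
  rej <- vapply(seq_len(2000L), function(i) {
    r <- tanh(rnorm(7, 0, 0.3))
    group_ttest(r)$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("split_compare detects shifts and respects its null", {
  set.seed(56)
  n <- 2000L
  hemi <- rep(sprintf("H%02d", 1:4), each = n / 4)
  fa <- data.frame(vertex_id = 1:n, mu = runif(n), r2 = runif(n, 0.2, 0.8))

  # identical sub-conditions: zero median differences, permutation p = 1
  same <- split_compare(fa, fa, hemi, n_permutations = 500L, seed = 1)
  expect_true(all(same$peak_height$per_hemisphere_diff == 0))
  expect_equal(same$goodness$p_perm, 1)

  # R2 reduced by 0.1 everywhere: permutation p < 0.001
  fb <- fa; fb$r2 <- fa$r2 - 0.1
  shift <- split_compare(fa, fb, hemi, n_permutations = 10000L, seed = 1)
  expect_lt(shift$goodness$p_perm, 0.001)
  expect_equal(shift$goodness$observed_diff, 0.1, tolerance = 1e-6)

  # default permutation count is the canonical 10,000
  expect_equal(eval(formals(split_compare)$n_permutations), 10000L)
  expect_error(split_compare(fa, fa[-1, ], hemi), "mismatched")
})
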