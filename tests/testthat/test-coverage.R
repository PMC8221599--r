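cov_pairs <- function(n, face_mu, face_sigma = 0.3, sp_mu_dva = 2,
                      seed = 61) {
  set.seed(seed)
  data.frame(vertex_id = seq_len(n), hemisphere = "H01",
             axis_position = runif(n),
             sp_mu = norm_dva_convert(rep(sp_mu_dva, n), "dva_to_u"),
             sp_sigma = 0.2, sp_r2 = 0.7,
             face_mu = face_mu, face_sigma = face_sigma, face_r2 = 0.7)
}

test_that("coverage selection applies the printed criteria strictly", {
  base <- data.frame(vertex_id = 1:5, hemisphere = "H01", axis_position = 0.5,
                     sp_mu = norm_dva_convert(c(2, 0.5, 2, -2, 2), "dva_to_u"),
                     sp_sigma = c(0.2, 0.2, 0.4, 0.2, 0.2),
                     sp_r2 = c(0.6, 0.6, 0.6, 0.6, 0.45),
                     face_mu = 0.5, face_sigma = 0.3,
                     face_r2 = c(0.6, 0.6, 0.6, 0.6, 0.6))
  sel <- suppressMessages(select_coverage_vertices(base))
  # vertex 1: R2 = 0.6 both, sigma 2 d.v.a., mu +2 d.v.a. -> UVF
  expect_identical(sel$uvf$vertex_id, 1L)
  # vertex 4 peaks 2 d.v.a. below fixation -> LVF
  expect_identical(sel$lvf$vertex_id, 4L)
  # vertex 2 (+0.5 d.v.a., under the 1 d.v.a. eccentricity floor),
  # vertex 3 (sigma = 4 d.v.a.) and vertex 5 (R2 = 0.45) are excluded
  expect_false(any(c(2L, 3L, 5L) %in% c(sel$uvf$vertex_id, sel$lvf$vertex_id)))
})

test_that("every averaged coverage curve is unit amplitude", {
  set.seed(62)
  C <- ptcmap:::coverage_curves(runif(50, -0.1, 1.1), 2^runif(50, -4, 1),
                                seq(0, 1, length.out = 101))
  expect_equal(unname(apply(C, 2, max)), rep(1, 50))
})

test_that("identical groups produce no flagged grid points", {
  g <- cov_pairs(60, face_mu = rnorm(60, 0.5, 0.1))
  out <- coverage_permutation(g, g, n_shuffles = 500L, seed = 2)
  expect_false(any(out$sig_mask))
  expect_true(all(out$p_point >= out$p_floor))
  expect_equal(out$p_floor, 1 / 500)
})

test_that("coverage permutation is exactly reproducible from its seed", {
  set.seed(63)
  u <- cov_pairs(40, rnorm(40, 0.4, 0.1), seed = 63)
  l <- cov_pairs(40, rnorm(40, 0.6, 0.1), seed = 64)
  a <- coverage_permutation(u, l, n_shuffles = 300L, seed = 9)
  b <- coverage_permutation(u, l, n_shuffles = 300L, seed = 9)
  expect_identical(a$p_point, b$p_point)
  expect_identical(a$sig_mask, b$sig_mask)
  c_ <- coverage_permutation(u, l, n_shuffles = 300L, seed = 10)
  expect_false(identical(a$p_point, c_$p_point))
})

test_that("well-separated groups are detected at the p floor", {
  u <- cov_pairs(200, rnorm(200, 0.4, 0.05), face_sigma = 0.3, seed = 65)
  l <- cov_pairs(200, rnorm(200, 0.6, 0.05), face_sigma = 0.3, seed = 66)
  out <- coverage_permutation(u, l, n_shuffles = 2000L, seed = 3)
  expect_true(any(out$sig_mask))
  expect_equal(min(out$p_point), 1 / 2000)
})

test_that("degenerate coverage inputs error cleanly", {
  g <- cov_pairs(10, rnorm(10, 0.5, 0.1))
  expect_error(coverage_permutation(g[0, ], g), "nonempty")
  expect_error(coverage_permutation(g, g, n_shuffles = 0L), "n_shuffles")
})

test_that("type-I error of the all-shuffles criterion is controlled", {
  # both groups from one generative distribution; any flagged point is a
  # false positive. 60 replicates at 400 shuffles each.
  set.seed(67)
  false_pos <- vapply(seq_len(60L), function(i) {
    mu <- rnorm(60, 0.5, 0.15)
    g <- cov_pairs(60, mu, seed = 670 + i)
    idx <- sample.int(60, 30)
    any(coverage_permutation(g[idx, ], g[-idx, ], n_shuffles = 400L,
                             seed = i)$sig_mask)
  }, logical(1))
  expect_lte(mean(false_pos), 0.05)
})

test_that("coverage TSV + JSON roundtrip carries curves and flags", {
  u <- cov_pairs(30, rnorm(30, 0.4, 0.1), seed = 68)
  l <- cov_pairs(30, rnorm(30, 0.6, 0.1), seed = 69)
  out <- coverage_permutation(u, l, n_shuffles = 200L, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage(out, path)
  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(tab$uvf, out$mean_curve_uvf, tolerance = 1e-12)
  expect_identical(tab$sig, out$sig_mask)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_shuffles, 200L)
})
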