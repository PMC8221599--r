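# independent oracle: DCT-II projection built from the explicit basis
# formula, reconstructing only the retained components via lm-style fit
dct_oracle <- function(x, tr, n_drop_low = 2L, f_high = 0.26) {
  T_ <- length(x)
  k <- 0:(T_ - 1L)
  keep <- (k / (2 * T_ * tr)) <= f_high
  keep[1L + seq_len(n_drop_low)] <- FALSE
  B <- sapply(k[keep], function(kk) cos(pi * (seq_len(T_) - 0.5) * kk / T_))
  drop(B %*% solve(crossprod(B), crossprod(B, x)))
}

test_that("dct_filter removes drift and high frequencies, keeps the passband", {
  T_ <- 192L; tr <- 1
  expect_equal(dct_filter(rep(0, T_), tr), rep(0, T_))

  rms <- function(x) sqrt(mean(x^2))
  # pure linear drift: the bulk of the energy sits in the two dropped
  # components. The projection oracle puts the exact residual at ~9% (the
  # ramp leaks into higher odd components); assert equality with the oracle
  # plus the qualitative bound.
  drift <- seq(-1, 1, length.out = T_)
  expect_equal(dct_filter(drift, tr), dct_oracle(drift, tr), tolerance = 1e-8)
  expect_lt(rms(dct_filter(drift, tr)), 0.15 * rms(drift))

  # exact DCT components at 0.2995 Hz (above the 0.26 Hz cutoff) and
  # 0.0495 Hz (inside the passband): removed completely / kept completely
  t_ <- seq_len(T_) - 0.5
  hi <- cos(pi * t_ * 115 / T_)            # k = 115 -> 0.2995 Hz
  lo <- cos(pi * t_ * 19 / T_)             # k = 19  -> 0.0495 Hz
  expect_lt(rms(dct_filter(hi, tr)), 1e-8)
  expect_gt(rms(dct_filter(lo, tr)), 0.9999 * rms(lo))
  # generic (phase-misaligned) sinusoids: strong but not perfect separation
  hi2 <- sin(2 * pi * 0.30 * t_ * tr)
  lo2 <- sin(2 * pi * 0.05 * t_ * tr)
  expect_lt(rms(dct_filter(hi2, tr)), 0.15 * rms(hi2))
  expect_gt(rms(dct_filter(lo2, tr)), 0.95 * rms(lo2))

  # agreement with the independent projection oracle
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(T_) + 3 * seq(0, 1, length.out = T_)
    expect_equal(dct_filter(x, tr), dct_oracle(x, tr), tolerance = 1e-8)
  }
})

test_that("dct_filter is an idempotent projection", {
  set.seed(7)
  x <- matrix(rnorm(192 * 5), 192)
  once <- dct_filter(x, 1)
  expect_equal(dct_filter(once, 1), once, tolerance = 1e-10)
})

test_that("dct_filter validates its inputs", {
  expect_error(dct_filter(rnorm(5), 1), "too short")
  expect_error(dct_filter(rnorm(100), 1, f_high = 0.6), "Nyquist")
})

test_that("preprocess_runs trims dummies, standardizes and averages", {
  d <- make_run_design("spatial")
  set.seed(1)
  run <- matrix(rnorm(202 * 3), 202, 3)
  one <- preprocess_runs(list(run), d)
  expect_equal(nrow(one$values), 192L)
  expect_true(all(abs(colMeans(one$values)) < 1e-8))
  expect_true(all(abs(apply(one$values, 2, sd) - 1) < 1e-8))

  # two identical runs equal the single-run result
  two <- preprocess_runs(list(run, run), d)
  expect_equal(two$values, one$values, tolerance = 1e-12)

  expect_error(preprocess_runs(list(), d), "zero runs")
  expect_error(preprocess_runs(list(run[-1, ]), d), "unequal or wrong length")
})

test_that("constant runs are excluded from the average with a warning", {
  d <- tiny_design()
  set.seed(2)
  good <- matrix(rnorm(total_volumes(d) * 2), ncol = 2)
  const <- matrix(1, total_volumes(d), 2)
  expect_warning(out <- preprocess_runs(list(good, const), d), "constant")
  ref <- preprocess_runs(list(good), d)
  expect_equal(out$values, ref$values, tolerance = 1e-12)
  expect_identical(out$n_runs_averaged, c(1L, 1L))
})

test_that("run averaging shrinks noise SD like 1/sqrt(R)", {
  d <- tiny_design()
  nv <- 1000L
  for (R in c(4L, 16L)) {
    set.seed(100 + R)
    runs <- lapply(seq_len(R), function(i)
      matrix(rnorm(total_volumes(d) * nv), ncol = nv))
    avg <- preprocess_runs(runs, d)
    ratio <- median(apply(avg$values, 2, sd))
    expect_lt(abs(ratio - 1 / sqrt(R)), 0.1 / sqrt(R))
  }
})

test_that("vertex series TSV + sidecar roundtrip is lossless", {
  d <- tiny_design()
  set.seed(3)
  vs <- preprocess_runs(list(matrix(rnorm(total_volumes(d) * 2), ncol = 2)), d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(vs, path)
  back <- read_series(path)
  expect_equal(back$values, vs$values, tolerance = 1e-12)
  expect_identical(back$condition, vs$condition)
  expect_equal(back$tr, vs$tr)
})
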