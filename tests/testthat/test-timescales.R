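# ACF estimator, INT statistic, region means and hierarchies.

test_that("hand-checked ACF cases match the estimator to 1e-12", {
  # values verified against stats::acf and a direct numpy computation
  expect_equal(sample_acf(c(1, 2, 1, 2))$values, c(1, -0.75, 0.5, -0.25),
               tolerance = 1e-12)
  a <- sample_acf(c(1, 1, 2, 2, 1, 1, 2, 2), max_lag = 2)
  expect_equal(a$values, c(1, 0.125, -0.75), tolerance = 1e-12)
})

test_that("ACF agrees with the stats::acf oracle on random series", {
  set.seed(101)
  for (n in c(20, 113, 400)) {
    x <- cumsum(rnorm(n))  # strongly autocorrelated
    L <- min(n - 1, 50)
    expect_equal(sample_acf(x, L)$values, acf_oracle(x, L),
                 tolerance = 1e-12)
  }
})

test_that("ACF normalisation identities hold", {
  set.seed(7)
  x <- rnorm(50)
  a <- sample_acf(x, 20)
  expect_identical(a$values[1], 1)
  expect_true(all(abs(a$values) <= 1 + 1e-12))
  expect_error(sample_acf(rep(3, 10)), "zero variance")
  expect_error(sample_acf(x, 50), "max_lag")
})

test_that("INT sums the initial positive period and flags censoring", {
  expect_equal(int_from_acf(c(1, -0.75, 0.5, -0.25)),
               list(int = 0, zero_crossing_lag = 1L, censored = FALSE))
  r <- int_from_acf(c(1, 0.125, -0.75))
  expect_equal(r$int, 0.125, tolerance = 1e-12)
  expect_equal(r$zero_crossing_lag, 2L)
  expect_equal(int_from_acf(c(1, 0.6, 0.3, 0.1, -0.05)),
               list(int = 1.0, zero_crossing_lag = 4L, censored = FALSE))
  # exact zero counts as crossed
  expect_equal(int_from_acf(c(1, 0.5, 0, 0.4))$zero_crossing_lag, 2L)
  # no crossing: all lags summed, censored
  cen <- int_from_acf(c(1, 0.5, 0.4, 0.3))
  expect_true(cen$censored)
  expect_equal(cen$int, 1.2)
  expect_true(is.na(cen$zero_crossing_lag))
  # optional lag-0 inclusion adds exactly 1
  expect_equal(int_from_acf(c(1, 0.125, -0.75), include_lag0 = TRUE)$int,
               1.125, tolerance = 1e-12)
})

test_that("time constant is the crossing lag times the TR", {
  expect_equal(time_constant(2, 1.1), 2.2)
  expect_equal(time_constant(1, 1.1), 1.1)
  expect_equal(time_constant(10, 2.0), 20.0)
  expect_true(is.na(time_constant(NA, 1.1)))  # censored
  expect_error(time_constant(0, 1.1), ">= 1")
})

test_that("INT is invariant to affine rescaling of the series", {
  set.seed(31)
  x <- ar1_series(0.6, 200)
  base <- int_from_acf(sample_acf(x))
  shifted <- int_from_acf(sample_acf(5 + 3 * x))
  expect_equal(base$int, shifted$int, tolerance = 1e-10)
  expect_identical(base$zero_crossing_lag, shifted$zero_crossing_lag)
})

test_that("expected INT increases monotonically with AR(1) phi", {
  set.seed(41)
  phis <- seq(0.1, 0.9, by = 0.2)
  mean_int <- vapply(phis, function(p)
    mean(replicate(60, int_from_acf(sample_acf(ar1_series(p, 400)))$int)),
    numeric(1))
  expect_true(all(diff(mean_int) > 0))
})

test_that("int_map averages runs voxelwise and checks alignment", {
  set.seed(51)
  mk <- function(run_id) voxel_ts(matrix(rnorm(5 * 80), 5), 1.1,
                                  run_id = run_id)
  r1 <- mk(1); r2 <- mk(2)
  m12 <- int_map(list(r1, r2))
  m1 <- int_map(r1); m2 <- int_map(r2)
  expect_equal(m12$int, (m1$int + m2$int) / 2, tolerance = 1e-12)
  expect_equal(m12$n_runs, 2)
  expect_equal(m12$time_constant_s, m12$zero_crossing_lag * 1.1)
  # single run equals the per-run map
  expect_equal(int_map(list(r1))$int, m1$int)
  bad <- voxel_ts(matrix(rnorm(4 * 80), 4), 1.1)
  expect_error(int_map(list(r1, bad)), "alignment")
})

test_that("int_map flags degenerate voxels instead of silently zeroing", {
  vals <- rbind(ar1_series(0.5, 100, seed = 1), rep(2, 100))
  m <- int_map(voxel_ts(vals, 1.1))
  expect_false(m$degenerate[1])
  expect_true(m$degenerate[2])
  expect_true(is.na(m$int[2]))
})

test_that("INT map values are nonnegative and zero iff ACF(1) <= 0", {
  set.seed(61)
  vts <- voxel_ts(matrix(rnorm(30 * 120), 30), 1.1)
  m <- int_map(vts)
  expect_true(all(m$int >= 0, na.rm = TRUE))
  a1 <- apply(vts$values, 1, function(x) sample_acf(x, 1)$values[2])
  expect_identical(unname(m$int == 0), a1 <= 0)
})

test_that("region means aggregate uncensored voxels with counts", {
  atlas <- region_atlas(c(1, 1, 2, 2, 2))
  rm <- region_mean(c(0.2, 0.4, 1, 2, 3), atlas)
  expect_equal(rm$mean, c(0.3, 2))
  expect_equal(rm$n_voxels, c(2, 3))
  # all-equal map
  expect_equal(region_mean(rep(7, 5), atlas)$mean, c(7, 7))
  # censored voxel excluded only on request, with a count
  m <- structure(list(int = c(0.2, 0.4, 1, 2, 3),
                      censored = c(FALSE, FALSE, TRUE, FALSE, FALSE)),
                 class = "int_map")
  strict <- region_mean(m, atlas, include_censored = FALSE)
  expect_equal(strict$mean[2], 2.5)
  expect_equal(strict$n_excluded[2], 1)
  expect_error(region_mean(c(1, 2, 3, 4, 5), atlas, region_ids = 9),
               "region 9")
})

test_that("hierarchies sort ascending with id tie-breaks", {
  rm <- data.frame(region_id = c(1, 2, 3), mean = c(0.1, 0.3, 0.2))
  h <- build_hierarchy(rm)
  expect_equal(h$region_id, c(1, 3, 2))
  expect_equal(h$rank, 1:3)
  ties <- data.frame(region_id = c(3, 1, 2), mean = c(0.5, 0.5, 0.5))
  expect_equal(build_hierarchy(ties)$region_id, 1:3)
  expect_error(build_hierarchy(rm[1, ]), "at least 2")
})

test_that("synthetic regions recover the planted hierarchy order", {
  ok <- vapply(1:6, function(seed) {
    ds <- generate_dataset(small_config(seed = seed, n_runs = 3,
                                        n_timepoints = 400, n_voxels = 15))
    h <- build_hierarchy(region_mean(int_map(ds$runs[[1]]), ds$atlas))
    cor(h$region_id, 1:3, method = "spearman") == 1
  }, logical(1))
  expect_gte(sum(ok), 4)
})
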