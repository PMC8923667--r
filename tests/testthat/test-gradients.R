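# FC matrices, sparsification, cosine affinity, diffusion embedding.

test_that("fc_matrix gives Pearson r with unit self-correlation", {
  set.seed(71)
  v <- voxel_ts(matrix(rnorm(4 * 100), 4), 1.1)
  fc <- fc_matrix(v)
  expect_true(isTRUE(attr(fc, "symmetric")))
  expect_equal(unname(diag(fc)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(abs(fc) <= 1 + 1e-12))
  # voxel against its negation
  neg <- voxel_ts(-v$values, 1.1)
  cross <- fc_matrix(v, neg)
  expect_equal(unname(diag(cross)), rep(-1, 4), tolerance = 1e-12)
  # independent white noise stays near zero
  set.seed(72)
  w <- voxel_ts(matrix(rnorm(2 * 700), 2), 1.1)
  expect_lt(abs(fc_matrix(w)[1, 2]), 3 / sqrt(700))
})

test_that("fc_matrix flags zero-variance voxels with NA", {
  v <- voxel_ts(rbind(rnorm(50), rep(1, 50)), 1.1)
  expect_warning(fc <- fc_matrix(v), "zero-variance")
  expect_true(all(is.na(fc[2, ])))
  expect_true(all(is.na(fc[, 2])))
  expect_false(is.na(fc[1, 1]))
})

test_that("group_fc averages on the Fisher z scale", {
  m1 <- as_fc_matrix(matrix(c(1, 0, 0, 1), 2))
  m2 <- as_fc_matrix(matrix(c(1, 0.5, 0.5, 1), 2))
  g <- group_fc(list(m1, m2))
  expect_equal(g[1, 2], tanh(atanh(0.5) / 2), tolerance = 1e-12)  # ~0.2680
  # identical matrices come back unchanged off-diagonal
  gg <- group_fc(list(m2, m2))
  expect_equal(gg[1, 2], 0.5, tolerance = 1e-12)
  # unit diagonal is clipped before atanh, returns >= 1 - 2e-7
  expect_gte(g[1, 1], 1 - 2e-7)
  m3 <- as_fc_matrix(matrix(0.1, 3, 3))
  expect_error(group_fc(list(m1, m3)), "alignment")
})

test_that("sparsify keeps the top entries per row by signed value", {
  row <- matrix(seq(0.1, 1, by = 0.1), 1)
  s <- sparsify(as_fc_matrix(row, symmetric = FALSE), 0.1)
  expect_equal(sum(s != 0), 1)
  expect_equal(s[1, 10], 1)
  # ties at the cutoff: lower column index retained
  tied <- matrix(c(0.5, 0.5, 0.5, 0.1, 0.1), 1)
  st <- sparsify(as_fc_matrix(tied, symmetric = FALSE), 0.4)  # keep 2 of 5
  expect_equal(which(st != 0), c(1, 2))
  # density 1 is the identity
  m <- matrix(rnorm(30), 5, 6)
  expect_equal(unclass(sparsify(as_fc_matrix(m, FALSE), 1))[, ], m[, ],
               ignore_attr = TRUE)
  # negative values lose to positive ones (signed, not absolute)
  sgn <- matrix(c(-0.9, 0.2, 0.1, 0.05), 1)
  ss <- sparsify(as_fc_matrix(sgn, FALSE), 0.25)
  expect_equal(which(ss != 0), 2L)
  expect_error(sparsify(as_fc_matrix(m, FALSE), 0), "density")
  expect_error(sparsify(as_fc_matrix(m, FALSE), 1.2), "density")
})

test_that("cosine affinity matches a direct dot-product oracle", {
  set.seed(81)
  m <- matrix(rnorm(8 * 20), 8)
  m[m < 0.3] <- 0  # sparse-ish profiles
  m[1, ] <- abs(m[2, ]) + 0.1  # guarantee no zero rows
  a <- cosine_affinity(m)
  # independent brute-force computation
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- max(0, sum(m[i, ] * m[j, ]) /
                          sqrt(sum(m[i, ]^2) * sum(m[j, ]^2)))
  diag(oracle) <- 1
  expect_equal(unclass(a), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(a - t(a))), 1e-12)
  expect_true(all(a >= 0 & a <= 1 + 1e-12))
  expect_true(all(diag(a) >= apply(a, 1, max) - 1e-12))
})

test_that("cosine affinity handles identical, orthogonal and zero rows", {
  m <- rbind(c(1, 1, 0, 0), c(2, 2, 0, 0), c(0, 0, 3, 1))
  a <- cosine_affinity(m)
  expect_equal(a[1, 2], 1, tolerance = 1e-12)      # identical direction
  expect_equal(a[1, 3], 0, tolerance = 1e-12)      # disjoint support
  expect_error(cosine_affinity(rbind(m, 0)), "all-zero|degenerate")
})

test_that("diffusion embedding matches the dense spectral oracle", {
  set.seed(91)
  for (n in c(20, 50)) {
    w <- random_affinity(n)
    g <- diffusion_embedding(w, n_components = 5)
    o <- diffusion_oracle(w, 5)
    expect_lt(component_dev(g$components, o$components), 1e-8)
    expect_equal(g$eigenvalues, o$eigenvalues, tolerance = 1e-10)
  }
})

test_that("embedding separates two weakly bridged blocks", {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  w[3, 4] <- w[4, 3] <- 1e-4  # minimal bridge
  g <- diffusion_embedding(w, n_components = 2)
  g1 <- g$components[, 1]
  g1 <- g1 / max(abs(g1))  # component scale is arbitrary near lambda = 1
  expect_lt(max(abs(g1[1:3] - mean(g1[1:3]))), 1e-3)   # ~constant per block
  expect_lt(max(abs(g1[4:6] - mean(g1[4:6]))), 1e-3)
  expect_lt(sign(mean(g1[1:3])) * sign(mean(g1[4:6])), 0)  # opposite signs
})

test_that("uniform affinity has all nontrivial eigenvalues near zero", {
  w <- matrix(1, 10, 10)
  g <- diffusion_embedding(w, n_components = 3)
  expect_lt(max(abs(g$eigenvalues)), 1e-10)
})

test_that("disconnected affinities are rejected with component info", {
  w <- matrix(0, 5, 5)
  w[1:2, 1:2] <- 1
  w[3:5, 3:5] <- 1
  expect_error(diffusion_embedding(w, 2), "disconnected")
})

test_that("eigenvalues are descending and in [0, 1] for cosine affinities", {
  set.seed(92)
  v <- voxel_ts(matrix(rnorm(30 * 150), 30), 1.1)
  a <- cosine_affinity(sparsify(fc_matrix(v), 0.2))
  g <- diffusion_embedding(a, n_components = 10)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  expect_true(all(g$eigenvalues >= -1e-12 & g$eigenvalues <= 1 + 1e-12))
  expect_true(g$sign_arbitrary)
  expect_lte(ncol(g$components), nrow(a) - 1)
})

test_that("embedding is permutation-equivariant up to sign", {
  set.seed(93)
  w <- random_affinity(25)
  g <- diffusion_embedding(w, 3)
  perm <- sample(25)
  gp <- diffusion_embedding(w[perm, perm], 3)
  expect_lt(component_dev(g$components[perm, ], gp$components), 1e-8)
})

test_that("first gradient recovers a planted 1-D topography", {
  rs <- vapply(1:5, function(seed) {
    ds <- generate_dataset(small_config(seed = seed, n_runs = 2,
                                        n_timepoints = 300, n_voxels = 20))
    fc <- group_fc(lapply(ds$runs[[1]], fc_matrix))
    g <- diffusion_embedding(cosine_affinity(sparsify(fc, 0.1)), 3)
    abs(cor(ds$ground_truth$gradient_axis, g$components[, 1]))
  }, numeric(1))
  expect_gte(median(rs), 0.9)
})
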