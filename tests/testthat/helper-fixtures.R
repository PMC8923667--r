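# Shared fixtures: small synthetic configurations and independent oracles.

small_config <- function(seed = 1, n_subjects = 1, n_runs = 2,
                         n_timepoints = 150, n_voxels = 12,
                         phis = c(0.2, 0.5, 0.8), ...) {
  synthetic_config(
    n_subjects = n_subjects, n_runs = n_runs, n_timepoints = n_timepoints,
    regions = data.frame(region_id = seq_along(phis), n_voxels = n_voxels,
                         phi = phis),
    seed = seed, ...)
}

# Acceptance-scale configuration: 6 regions, ascending timescales, 5 runs of
# 700 timepoints at TR 1.1 s (one subject per seed).
recovery_config <- function(seed) {
  synthetic_config(n_subjects = 1, n_runs = 5, n_timepoints = 700,
                   regions = default_regions(), seed = seed)
}

# Independent ACF oracle: stats::acf (C implementation, biased
# normalisation) -- a separate code path from intgrad's matrix computation.
acf_oracle <- function(x, max_lag) {
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}

# Independent diffusion-map oracle: eigendecomposition of the explicit
# non-symmetric row-stochastic operator (vs the package's symmetric
# conjugate route). Same normalisation conventions.
diffusion_oracle <- function(w, n_components, alpha = 0.5,
                             diffusion_time = 0) {
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  p <- w1 / d1
  e <- eigen(p)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  u <- Re(e$vectors)[, ord, drop = FALSE]
  # normalise as unit vectors under the sqrt(d1) weighting, matching the
  # symmetric route's unit-norm eigenvectors
  u <- sweep(u, 2L, sqrt(colSums(d1 * u^2)), "/")
  psi <- u / u[, 1L]
  idx <- 2:(n_components + 1L)
  lam_nt <- lam[idx]
  scale <- if (diffusion_time == 0) lam_nt / (1 - lam_nt) else
    lam_nt^diffusion_time
  list(components = psi[, idx, drop = FALSE] *
         matrix(scale, nrow(w), n_components, byrow = TRUE),
       eigenvalues = lam_nt)
}

# Max abs deviation between two component matrices, up to per-component sign.
component_dev <- function(a, b) {
  max(vapply(seq_len(ncol(a)), function(j)
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j]))), numeric(1)))
}

# Random symmetric nonnegative affinity with unit diagonal.
random_affinity <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  a
}
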