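# Synthetic multi-subject, multi-run BOLD-like data with planted timescales
# and a planted 1-D connectivity topography.

#' Simulate a stationary AR(1) series
#'
#' Draws a Gaussian first-order autoregressive series
#' \eqn{x_t = \phi x_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0, sd^2)},
#' started from its stationary distribution so the population autocorrelation
#' is exactly \eqn{\phi^k} at lag \eqn{k}.
#'
#' @param phi AR(1) coefficient, in `[0, 1)`. Larger values give slower
#'   decorrelation and hence larger intrinsic timescales.
#' @param n Series length (at least 2).
#' @param sd Innovation standard deviation (> 0).
#' @param seed Optional integer seed; when given, the draw is deterministic.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- ar1_series(0.8, 500, seed = 1)
#' stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]  # near 0.8
#' @export
ar1_series <- function(phi, n, sd = 1, seed = NULL) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi >= 1)
    stop("`phi` must be a single value in [0, 1): nonstationary generators are rejected")
  if (n < 2) stop("`n` must be at least 2")
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive")
  if (!is.null(seed)) set.seed(seed)
  x0 <- stats::rnorm(1L, 0, sd / sqrt(1 - phi^2))
  e <- stats::rnorm(n, 0, sd)
  if (phi == 0) return(e)
  as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
}

## Matrix of independent stationary AR(1) rows sharing one RNG stream.
## phis is recycled over rows; all rows have unit stationary variance.
.ar1_matrix <- function(phis, n_rows, n_cols) {
  phis <- rep_len(phis, n_rows)
  e <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  x0 <- stats::rnorm(n_rows)
  out <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    p <- phis[i]
    innov_sd <- sqrt(1 - p^2)  # unit stationary variance
    if (p == 0) {
      out[i, ] <- e[i, ]
    } else {
      out[i, ] <- as.numeric(stats::filter(innov_sd * e[i, ], p,
                                           method = "recursive",
                                           init = x0[i]))
    }
  }
  out
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Sampled at the repetition time; peak at ~5 s with a ~15 s undershoot,
#' normalised to unit sum. Used (optionally) to convolve simulated neural
#' series into BOLD-like series.
#'
#' @param tr_seconds Sampling interval in seconds.
#' @param duration_seconds Kernel support in seconds.
#' @return Numeric vector of kernel weights.
#' @export
hrf_kernel <- function(tr_seconds, duration_seconds = 30) {
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Configuration for the synthetic dataset generator
#'
#' Describes a multi-subject, multi-run voxel time-series simulation with
#' region-specific AR(1) timescales arranged along a planted 1-D spatial
#' axis, plus shared latent signals whose mixing weights vary smoothly along
#' the same axis (so voxel connectivity profiles change gradually with axis
#' position). Defaults emulate the acquisition the package targets: 9
#' subjects, 5 runs, 700 timepoints at TR = 1.1 s.
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Runs per subject.
#' @param n_timepoints Timepoints per run (>= 10).
#' @param tr_seconds Sampling interval in seconds.
#' @param regions Data frame with columns `region_id` (integer), `n_voxels`
#'   (positive integer) and `phi` (AR(1) coefficient in `[0, 1)`). Region
#'   order defines position along the planted axis.
#' @param gradient_axis Optional per-voxel position in `[0, 1]` along the
#'   planted topography; default: voxels equally spaced in region order.
#' @param latent_dim Number of shared latent AR(1) signals.
#' @param mixing_bandwidth Width (in axis units) of the Gaussian mixing
#'   profiles tying voxels to latent signals; smaller values localise
#'   connectivity more sharply along the axis.
#' @param latent_strength Fraction of (noise-free) signal variance carried by
#'   the shared latents, in `[0, 1)`; controls functional-connectivity
#'   strength between voxels with nearby axis positions.
#' @param noise_sd Observation (thermal) noise standard deviation, relative
#'   to unit signal variance.
#' @param hrf_enabled Convolve series with a double-gamma haemodynamic
#'   kernel. Off by default so the AR(1) autocorrelation is undistorted.
#' @param seed Integer master seed; expanded deterministically to
#'   per-subject/run substreams.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 9,
                             n_runs = 5,
                             n_timepoints = 700,
                             tr_seconds = 1.1,
                             regions = default_regions(),
                             gradient_axis = NULL,
                             latent_dim = 10,
                             mixing_bandwidth = 0.12,
                             latent_strength = 0.5,
                             noise_sd = 0.3,
                             hrf_enabled = FALSE,
                             seed = 1L) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("region_id", "n_voxels", "phi") %in% names(regions)))
  if (any(regions$phi < 0 | regions$phi >= 1))
    stop("all region `phi` must lie in [0, 1)")
  if (any(regions$n_voxels < 1)) stop("region voxel counts must be positive")
  n_vox <- sum(regions$n_voxels)
  if (n_vox == 0) stop("region voxel counts sum to zero")
  if (n_subjects < 1 || n_runs < 1) stop("subject and run counts must be positive")
  if (n_timepoints < 10) stop("`n_timepoints` must be at least 10")
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive")
  if (is.null(gradient_axis)) {
    gradient_axis <- if (n_vox == 1) 0.5 else seq(0, 1, length.out = n_vox)
  }
  if (length(gradient_axis) != n_vox)
    stop("`gradient_axis` must have one entry per voxel")
  if (any(gradient_axis < 0 | gradient_axis > 1))
    stop("`gradient_axis` values must lie in [0, 1]")
  if (latent_dim < 1) stop("`latent_dim` must be positive")
  if (mixing_bandwidth <= 0) stop("`mixing_bandwidth` must be positive")
  if (latent_strength < 0 || latent_strength >= 1)
    stop("`latent_strength` must lie in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_runs = as.integer(n_runs),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    regions = regions,
    gradient_axis = as.numeric(gradient_axis),
    latent_dim = as.integer(latent_dim),
    mixing_bandwidth = mixing_bandwidth,
    latent_strength = latent_strength,
    noise_sd = noise_sd,
    hrf_enabled = isTRUE(hrf_enabled),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default six-region layout with ascending timescales
#'
#' Six regions of 30 voxels whose AR(1) coefficients increase from 0.1 to
#' 0.85 along the planted axis, mimicking a sensory-to-association hierarchy
#' of intrinsic timescales.
#'
#' @return Data frame with columns `region_id`, `name`, `n_voxels`, `phi`.
#' @export
default_regions <- function() {
  data.frame(
    region_id = 1:6,
    name = c("R1", "R2", "R3", "R4", "R5", "R6"),
    n_voxels = 30L,
    phi = seq(0.1, 0.85, length.out = 6)
  )
}

## Deterministic substream seed for (subject, run); independent of the order
## in which runs are generated. Kept below 2^31.
.substream_seed <- function(seed, subject, run) {
  as.integer((as.double(seed %% 32768L) * 48271 +
                subject * 69621 + run * 16807) %% 2147483629 + 1)
}

#' Generate a synthetic multi-subject, multi-run dataset
#'
#' Each voxel's series is a mixture of a private stationary AR(1) process
#' (coefficient set by the voxel's region), shared latent AR(1) signals
#' whose Gaussian mixing weights vary smoothly with the voxel's position on
#' the planted axis, and white observation noise; an optional haemodynamic
#' convolution is applied last. Latent signals take their own AR(1)
#' coefficients by interpolating the planted region coefficients at the
#' latent's axis centre, so both timescales and connectivity vary along the
#' same axis. Regeneration from the same config is bit-identical.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with `runs` (per
#'   subject, a list of [voxel_ts()] objects), `ground_truth` (per-voxel
#'   `phi`, `gradient_axis`, region label, population INT proxy
#'   `phi/(1-phi)`, and the voxel-by-latent mixing weight matrix), `atlas`
#'   (a [region_atlas()]), and the `config`.
#' @examples
#' cfg <- synthetic_config(n_subjects = 1, n_runs = 2, n_timepoints = 120,
#'                         regions = data.frame(region_id = 1:2, n_voxels = 5,
#'                                              phi = c(0.2, 0.7)), seed = 7)
#' ds <- generate_dataset(cfg)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  reg <- config$regions
  voxel_region <- rep(reg$region_id, reg$n_voxels)
  voxel_phi <- rep(reg$phi, reg$n_voxels)
  n_vox <- length(voxel_phi)
  axis <- config$gradient_axis

  # Gaussian-bump mixing weights, centres equally spaced on the axis;
  # rows normalised to unit L2 norm so shared variance is axis-uniform.
  centers <- if (config$latent_dim == 1) 0.5 else
    seq(0, 1, length.out = config$latent_dim)
  W <- exp(-outer(axis, centers, "-")^2 / (2 * config$mixing_bandwidth^2))
  W <- W / sqrt(rowSums(W^2))

  # Latent timescales follow the planted axis: interpolate region phi at
  # each latent centre.
  latent_phi <- stats::approx(axis, voxel_phi, xout = centers, rule = 2,
                              ties = "ordered")$y

  s <- config$latent_strength
  hrf <- if (config$hrf_enabled) hrf_kernel(config$tr_seconds) else NULL

  runs <- vector("list", config$n_subjects)
  for (subj in seq_len(config$n_subjects)) {
    subj_runs <- vector("list", config$n_runs)
    for (run in seq_len(config$n_runs)) {
      set.seed(.substream_seed(config$seed, subj, run))
      latents <- .ar1_matrix(latent_phi, config$latent_dim, config$n_timepoints)
      private <- .ar1_matrix(voxel_phi, n_vox, config$n_timepoints)
      y <- sqrt(1 - s) * private + sqrt(s) * (W %*% latents)
      if (config$noise_sd > 0)
        y <- y + matrix(stats::rnorm(n_vox * config$n_timepoints,
                                     0, config$noise_sd),
                        n_vox, config$n_timepoints)
      if (!is.null(hrf))
        y <- t(apply(y, 1L, function(v)
          stats::filter(v, hrf, method = "convolution", sides = 1L)))
      if (!is.null(hrf)) {
        # convolution leaves leading NAs within the kernel support; pad with
        # the first finite value to keep a full-length series
        y <- t(apply(y, 1L, function(v) {
          v[is.na(v)] <- v[which(!is.na(v))[1L]]
          v
        }))
      }
      subj_runs[[run]] <- voxel_ts(y, tr_seconds = config$tr_seconds,
                                   subject_id = subj, run_id = run)
    }
    runs[[subj]] <- subj_runs
  }

  ground_truth <- list(
    phi = voxel_phi,
    gradient_axis = axis,
    region = voxel_region,
    int_proxy = voxel_phi / (1 - voxel_phi),
    mixing_weights = W,
    latent_phi = latent_phi
  )
  atlas <- region_atlas(voxel_region,
                        region_names = if ("name" %in% names(reg))
                          stats::setNames(reg$name, reg$region_id) else NULL)
  structure(list(runs = runs, ground_truth = ground_truth,
                 atlas = atlas, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic voxel time-series dataset\n")
  cat(sprintf("  %d subject(s) x %d run(s), %d voxels x %d timepoints, TR = %g s\n",
              cfg$n_subjects, cfg$n_runs, length(x$ground_truth$phi),
              cfg$n_timepoints, cfg$tr_seconds))
  cat(sprintf("  %d regions, phi in [%g, %g]; latent dim %d, bandwidth %g\n",
              nrow(cfg$regions), min(cfg$regions$phi), max(cfg$regions$phi),
              cfg$latent_dim, cfg$mixing_bandwidth))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  str <- utils::capture.output(utils::str(unclass(x), max.level = 1))
  cat(paste0("  ", str, collapse = "\n"), "\n")
  invisible(x)
}
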