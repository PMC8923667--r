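# Voxelwise autocorrelation functions, intrinsic-timescale (INT) maps,
# region means and timescale hierarchies.

#' Voxel time-series container
#'
#' One run's voxels-by-timepoints matrix of BOLD-like values (arbitrary
#' units) with its sampling interval and identifiers.
#'
#' @param values Numeric matrix, voxels in rows, timepoints in columns.
#' @param tr_seconds Sampling interval in seconds (> 0).
#' @param subject_id,run_id Identifiers.
#' @param voxel_ids Optional per-voxel identifiers (default `1:nrow`); used
#'   to check alignment across runs and against atlases.
#' @return Object of class `voxel_ts`.
#' @export
voxel_ts <- function(values, tr_seconds, subject_id = NA, run_id = NA,
                     voxel_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("time series must have at least 2 timepoints")
  if (anyNA(values)) stop("voxel time series contain missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be positive")
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nrow(values))
  if (length(voxel_ids) != nrow(values))
    stop("`voxel_ids` must have one entry per voxel")
  structure(list(values = values, tr_seconds = tr_seconds,
                 subject_id = subject_id, run_id = run_id,
                 voxel_ids = voxel_ids),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("Voxel time series: %d voxels x %d timepoints, TR = %g s (subject %s, run %s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              as.character(x$subject_id), as.character(x$run_id)))
  invisible(x)
}

## Row-wise biased-normalisation sample ACF for a voxels x timepoints matrix.
## ACF(k) = sum_t d_t d_{t+k} / sum_t d_t^2 with d the mean-centred series;
## the length-N denominator guarantees |ACF| <= 1 and a positive-semidefinite
## sequence. Returns an n_vox x (max_lag + 1) matrix including lag 0; rows
## with zero variance are NA.
.acf_matrix <- function(x, max_lag) {
  n <- ncol(x)
  d <- x - rowMeans(x)
  denom <- rowSums(d * d)
  out <- matrix(NA_real_, nrow(x), max_lag + 1L)
  out[, 1L] <- 1
  ok <- denom > 0
  for (k in seq_len(max_lag)) {
    num <- rowSums(d[, seq_len(n - k), drop = FALSE] *
                     d[, (k + 1L):n, drop = FALSE])
    out[ok, k + 1L] <- num[ok] / denom[ok]
  }
  out[!ok, 1L] <- NA_real_
  out
}

#' Sample autocorrelation function of one series
#'
#' Mean-subtracted, biased-normalisation estimator:
#' \eqn{ACF(k) = \sum_{t=1}^{N-k} d_t d_{t+k} / \sum_{t=1}^{N} d_t^2} with
#' \eqn{d = y - \bar y}. The biased (length-N) denominator keeps every value
#' in \eqn{[-1, 1]} and the curve positive semidefinite.
#'
#' @param series Numeric vector, length >= 2, nonzero variance.
#' @param max_lag Largest lag to compute; defaults to
#'   `min(length(series) - 1, 100)`.
#' @return Object of class `acf_curve`: list with `values` (lags 0..max_lag,
#'   `values[1] == 1`), `lags`, and `estimator` tag.
#' @examples
#' sample_acf(c(1, 2, 1, 2))$values[2]  # -0.75
#' @export
sample_acf <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2) stop("series must have length >= 2")
  if (is.null(max_lag)) max_lag <- min(n - 1L, 100L)
  if (max_lag < 1 || max_lag >= n)
    stop("`max_lag` must satisfy 1 <= max_lag < length(series)")
  if (stats::var(series) == 0)
    stop("degenerate input: series has zero variance")
  vals <- drop(.acf_matrix(matrix(series, 1L), max_lag))
  structure(list(values = vals, lags = 0:max_lag,
                 estimator = "biased-normalisation, mean-subtracted"),
            class = "acf_curve")
}

#' INT statistic from an ACF curve
#'
#' The intrinsic neural timescale is the sum of ACF values over the initial
#' positive period: lags `1 .. L-1` where `L` is the zero-crossing lag, the
#' smallest lag `k >= 1` with `ACF(k) <= 0`. An empty sum gives INT = 0. If
#' the ACF never crosses within the computed lags, all lags are summed and
#' the value is flagged censored.
#'
#' @param acf An [sample_acf()] result, or a numeric vector of ACF values
#'   starting at lag 0.
#' @param include_lag0 Also add the lag-0 value (always 1) to the sum;
#'   default off (lag 0 carries no information).
#' @return List with `int`, `zero_crossing_lag` (in TR steps; `NA` when
#'   censored) and `censored`.
#' @examples
#' int_from_acf(c(1, 0.375, -0.75))  # INT 0.375, crossing lag 2
#' @export
int_from_acf <- function(acf, include_lag0 = FALSE) {
  vals <- if (inherits(acf, "acf_curve")) acf$values else as.numeric(acf)
  if (length(vals) < 2) stop("ACF must include at least lag 1")
  lagged <- vals[-1L]
  cross <- which(lagged <= 0)
  if (length(cross) == 0L) {
    int <- sum(lagged)
    lag <- NA_integer_
    censored <- TRUE
  } else {
    lag <- cross[1L]
    int <- if (lag == 1L) 0 else sum(lagged[seq_len(lag - 1L)])
    censored <- FALSE
  }
  if (include_lag0) int <- int + vals[1L]
  list(int = int, zero_crossing_lag = if (censored) NA_integer_ else lag,
       censored = censored)
}

#' Time constant from the zero-crossing lag
#'
#' The zero-crossing lag, measured in TR steps, multiplied by the TR gives a
#' timescale estimate in seconds.
#'
#' @param zero_crossing_lag Lag in TR steps (>= 1); `NA` for censored voxels.
#' @param tr_seconds Sampling interval in seconds.
#' @return Time constant in seconds; `NA` where the lag is `NA` (censored).
#' @examples
#' time_constant(2, 1.1)  # 2.2
#' @export
time_constant <- function(zero_crossing_lag, tr_seconds) {
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive")
  if (any(!is.na(zero_crossing_lag) & zero_crossing_lag < 1))
    stop("zero-crossing lags must be >= 1")
  as.numeric(zero_crossing_lag) * tr_seconds
}

#' Voxelwise INT map from one or more runs
#'
#' For each run, each voxel's ACF is estimated and reduced to its INT and
#' zero-crossing lag; per-voxel values are then averaged across runs. Maps
#' are never smoothed. Voxels whose ACF does not cross zero within `max_lag`
#' in some run are flagged; by default their truncated sums still enter the
#' average (`strict = TRUE` excludes those run values). Zero-variance voxels
#' are flagged and excluded, never silently set to 0.
#'
#' @param runs A [voxel_ts()] or list of them (same voxel count and order).
#' @param max_lag Largest ACF lag; default `min(N - 1, 100)`.
#' @param include_lag0 Include the lag-0 ACF value in the INT sum.
#' @param strict Exclude censored run values from per-voxel means.
#' @return Object of class `int_map`: per-voxel `int`, `zero_crossing_lag`
#'   (run-averaged), `time_constant_s`, `censored` (flag: censored in any
#'   run), `censored_runs` (count), `degenerate` (zero-variance flag),
#'   `n_runs`, `tr_seconds`, `voxel_ids`.
#' @export
int_map <- function(runs, max_lag = NULL, include_lag0 = FALSE,
                    strict = FALSE) {
  if (inherits(runs, "voxel_ts")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "voxel_ts")))
  n_vox <- nrow(runs[[1L]]$values)
  ids <- runs[[1L]]$voxel_ids
  tr <- runs[[1L]]$tr_seconds
  for (r in runs) {
    if (nrow(r$values) != n_vox || !identical(r$voxel_ids, ids))
      stop("alignment error: runs differ in voxel count or ordering")
  }
  n_runs <- length(runs)
  ints <- lags <- matrix(NA_real_, n_vox, n_runs)
  cens <- matrix(FALSE, n_vox, n_runs)
  degen <- rep(FALSE, n_vox)
  for (j in seq_len(n_runs)) {
    x <- runs[[j]]$values
    L <- if (is.null(max_lag)) min(ncol(x) - 1L, 100L) else max_lag
    a <- .acf_matrix(x, L)
    bad <- is.na(a[, 1L])
    degen <- degen | bad
    lagged <- a[, -1L, drop = FALSE]
    pos <- lagged > 0
    pos[is.na(pos)] <- FALSE
    # first lag k with ACF(k) <= 0; run-length of the initial positive period
    first_nonpos <- max.col(!pos, ties.method = "first")
    none <- rowSums(!pos) == 0L          # never crosses: censored
    run_len <- ifelse(none, L, first_nonpos - 1L)
    csum <- if (L == 1L) cbind(0, lagged) else
      cbind(0, t(apply(lagged, 1L, cumsum)))
    ints[, j] <- csum[cbind(seq_len(n_vox), run_len + 1L)]
    if (include_lag0) ints[, j] <- ints[, j] + 1
    lags[, j] <- ifelse(none, NA_real_, first_nonpos)
    cens[, j] <- none
    ints[bad, j] <- NA_real_
    lags[bad, j] <- NA_real_
  }
  use <- !is.na(ints) & (!strict | !cens)
  int_mean <- rowSums(ints * use, na.rm = TRUE) / rowSums(use)
  int_mean[rowSums(use) == 0] <- NA_real_
  lag_mean <- rowMeans(lags, na.rm = TRUE)
  lag_mean[!is.finite(lag_mean)] <- NA_real_
  structure(list(
    int = int_mean,
    zero_crossing_lag = lag_mean,
    time_constant_s = lag_mean * tr,
    censored = rowSums(cens) > 0L,
    censored_runs = rowSums(cens),
    degenerate = degen,
    n_runs = n_runs,
    tr_seconds = tr,
    voxel_ids = ids,
    strict = strict
  ), class = "int_map")
}

#' @export
print.int_map <- function(x, ...) {
  cat(sprintf("INT map: %d voxels, %d run(s), TR = %g s\n",
              length(x$int), x$n_runs, x$tr_seconds))
  cat(sprintf("  INT range [%.3g, %.3g]; %d voxel(s) censored in >= 1 run; %d degenerate\n",
              min(x$int, na.rm = TRUE), max(x$int, na.rm = TRUE),
              sum(x$censored), sum(x$degenerate)))
  invisible(x)
}

#' @export
summary.int_map <- function(object, ...) {
  out <- list(
    n_voxels = length(object$int),
    n_runs = object$n_runs,
    int = summary(object$int),
    zero_crossing_lag = summary(object$zero_crossing_lag),
    time_constant_s = summary(object$time_constant_s),
    censored_voxels = sum(object$censored),
    degenerate_voxels = sum(object$degenerate)
  )
  class(out) <- "summary.int_map"
  out
}

#' @export
print.summary.int_map <- function(x, ...) {
  cat(sprintf("INT map over %d voxels (%d runs)\n", x$n_voxels, x$n_runs))
  cat("INT:\n"); print(x$int)
  cat("Zero-crossing lag (TR steps):\n"); print(x$zero_crossing_lag)
  cat(sprintf("Censored voxels: %d; degenerate voxels: %d\n",
              x$censored_voxels, x$degenerate_voxels))
  invisible(x)
}

#' @export
plot.int_map <- function(x, ...) {
  graphics::hist(x$int, breaks = "FD", main = "Voxelwise INT",
                 xlab = "INT (sum of ACF values, unitless)", ...)
  invisible(x)
}

#' Region atlas
#'
#' Integer region label per voxel plus an id-to-name table.
#'
#' @param labels Integer vector of region ids, one per voxel (`NA` or 0 =
#'   unlabelled).
#' @param region_names Optional named character vector mapping ids to names.
#' @param bilateral Labels pool both hemispheres.
#' @return Object of class `region_atlas`.
#' @export
region_atlas <- function(labels, region_names = NULL, bilateral = TRUE) {
  labels <- as.integer(labels)
  ids <- sort(unique(labels[!is.na(labels) & labels != 0L]))
  if (is.null(region_names)) {
    region_names <- stats::setNames(paste0("region_", ids), ids)
  } else {
    missing_ids <- setdiff(as.character(ids), names(region_names))
    if (length(missing_ids))
      stop("labelled voxels map to unknown region id(s): ",
           paste(missing_ids, collapse = ", "))
  }
  structure(list(labels = labels, region_ids = ids,
                 region_names = region_names, bilateral = bilateral),
            class = "region_atlas")
}

#' Region-mean statistics from a voxel map
#'
#' Arithmetic mean of per-voxel values within each atlas region. Degenerate
#' (`NA`) voxels are always excluded; censored voxels are excluded only when
#' `include_censored = FALSE`, and exclusion counts are reported.
#'
#' @param map An [int_map()] or a plain numeric per-voxel vector.
#' @param atlas A [region_atlas()].
#' @param region_ids Regions to summarise (default: all atlas regions).
#' @param include_censored Include values from voxels flagged censored.
#' @return Data frame with `region_id`, `name`, `mean`, `n_voxels`,
#'   `n_excluded`.
#' @export
region_mean <- function(map, atlas, region_ids = NULL,
                        include_censored = TRUE) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (inherits(map, "int_map")) {
    values <- map$int
    censored <- map$censored
  } else {
    values <- as.numeric(map)
    censored <- rep(FALSE, length(values))
  }
  if (length(values) != length(atlas$labels))
    stop("alignment error: map and atlas have different voxel counts")
  if (is.null(region_ids)) region_ids <- atlas$region_ids
  out <- lapply(region_ids, function(id) {
    in_region <- !is.na(atlas$labels) & atlas$labels == id
    if (!any(in_region))
      stop("region ", id, " has no voxels in the atlas")
    keep <- in_region & !is.na(values) & (include_censored | !censored)
    data.frame(region_id = id,
               name = unname(atlas$region_names[as.character(id)]),
               mean = mean(values[keep]),
               n_voxels = sum(keep),
               n_excluded = sum(in_region) - sum(keep))
  })
  do.call(rbind, out)
}

#' Order regions into a timescale hierarchy
#'
#' Regions sorted ascending by mean INT (fast, sensory-like regions first);
#' ties broken by region id.
#'
#' @param region_means Data frame from [region_mean()] (columns `region_id`,
#'   `mean`; optional `name`).
#' @return Object of class `hierarchy`: the sorted data frame with a `rank`
#'   column.
#' @export
build_hierarchy <- function(region_means) {
  region_means <- as.data.frame(region_means)
  stopifnot(all(c("region_id", "mean") %in% names(region_means)))
  if (nrow(region_means) < 2) stop("a hierarchy needs at least 2 regions")
  ord <- order(region_means$mean, region_means$region_id)
  out <- region_means[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hierarchy", "data.frame")
  out
}

#' @export
print.hierarchy <- function(x, ...) {
  cat("Timescale hierarchy (ascending mean INT)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.hierarchy <- function(x, ...) {
  lab <- if ("name" %in% names(x)) x$name else as.character(x$region_id)
  graphics::dotchart(x$mean, labels = lab, xlab = "mean INT",
                     main = "Region timescale hierarchy", ...)
  invisible(x)
}
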