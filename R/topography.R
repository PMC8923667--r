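# Relating INT maps to gradient maps; cross-structure projections.

## Coerce a "scalar map" (int_map, numeric vector, or 1-column matrix) to a
## named numeric vector of per-voxel values.
.map_values <- function(x) {
  if (inherits(x, "int_map")) return(x$int)
  if (is.matrix(x) && ncol(x) == 1L) return(drop(x))
  as.numeric(x)
}

#' Spatial correlation between two voxel maps
#'
#' Pearson correlation across voxels. The absolute value is reported
#' alongside because gradient signs are arbitrary: only the magnitude of an
#' INT-gradient correlation is meaningful.
#'
#' @param a,b Per-voxel maps over the same voxel set ([int_map()], numeric
#'   vector, or gradient component).
#' @param use Voxel filter passed to [stats::cor()]'s `use`; default drops
#'   pairs with missing values.
#' @return List with `r`, `abs_r`, `n_voxels`.
#' @export
map_correlation <- function(a, b, use = "pairwise.complete.obs") {
  va <- .map_values(a)
  vb <- .map_values(b)
  if (length(va) != length(vb))
    stop("alignment error: maps cover different voxel sets (",
         length(va), " vs ", length(vb), " voxels)")
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) stop("need at least 3 voxels with finite values")
  r <- stats::cor(va[ok], vb[ok])
  list(r = r, abs_r = abs(r), n_voxels = sum(ok))
}

#' Gradient most correlated with a map
#'
#' Correlates a voxel map with every gradient component and returns the
#' component maximising `|r|` (ensuing gradients are assumed to reflect
#' other organisational principles). Ties go to the lower component index.
#'
#' @param map Per-voxel map ([int_map()] or numeric vector).
#' @param grads A [diffusion_embedding()] result.
#' @return List with `component` (index), `r`, `abs_r`.
#' @export
best_gradient <- function(map, grads) {
  stopifnot(inherits(grads, "gradient_set"))
  v <- .map_values(map)
  if (length(v) != nrow(grads$components))
    stop("alignment error: map and gradients cover different voxel sets")
  rs <- vapply(seq_len(ncol(grads$components)), function(j)
    map_correlation(v, grads$components[, j])$r, numeric(1))
  j <- which.max(abs(rs))  # ties -> lower index
  list(component = j, r = rs[j], abs_r = abs(rs[j]))
}

#' Project a gradient map across structures by strongest connectivity
#'
#' For each target voxel, the output takes the gradient value of the source
#' voxel with which it is most strongly functionally connected (largest
#' signed correlation; ties go to the lower source index). This carries,
#' e.g., a striatal gradient onto the cortex. No smoothing is applied.
#'
#' @param gradient Per-voxel values over structure A (source of values).
#' @param fc FC matrix, rows = structure-A voxels, columns = structure-B
#'   voxels.
#' @return Numeric vector over structure B; `NA` where a target voxel has no
#'   finite FC.
#' @export
project_gradient <- function(gradient, fc) {
  g <- .map_values(gradient)
  m <- unclass(as.matrix(fc))
  if (length(g) != nrow(m))
    stop("alignment error: gradient length must equal FC row count")
  out <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(is.na(col))) next
    out[j] <- g[which.max(col)]  # which.max: NA-safe, ties -> lower index
  }
  out
}

#' Reconstruct a map from the top-k most connected voxels
#'
#' For each target voxel (FC row), identifies the `k` source voxels with the
#' highest signed functional correlation and averages their map values —
#' e.g. reconstructing striatal INTs from each striatal voxel's 10 most
#' correlated cortical voxels.
#'
#' @param map Per-voxel values over the source structure (FC columns).
#' @param fc FC matrix, rows = target voxels, columns = source voxels.
#' @param k Number of top correlations averaged (default 10).
#' @return Numeric vector over the target structure (FC rows).
#' @export
project_int <- function(map, fc, k = 10) {
  v <- .map_values(map)
  m <- unclass(as.matrix(fc))
  if (length(v) != ncol(m))
    stop("alignment error: map length must equal FC column count")
  if (k < 1 || k > ncol(m))
    stop("`k` must lie between 1 and the number of source voxels (",
         ncol(m), ")")
  out <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (all(is.na(row))) next
    top <- order(row, decreasing = TRUE, na.last = TRUE)[seq_len(k)]
    out[i] <- mean(v[top])
  }
  out
}
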