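# Functional-connectivity matrices, cosine-similarity affinities and
# diffusion-map gradients.

#' Voxel-pair functional connectivity matrix
#'
#' Pearson correlation between the time series of every source voxel and
#' every target voxel. With one argument the matrix is symmetric with unit
#' diagonal. Zero-variance voxels yield `NA` rows/columns and a warning
#' naming them.
#'
#' @param source A [voxel_ts()].
#' @param target Optional second [voxel_ts()] with the same timepoint count;
#'   default: `source` itself.
#' @return Object of class `fc_matrix`: a correlation matrix with attributes
#'   `source_ids`, `target_ids`, `symmetric`.
#' @export
fc_matrix <- function(source, target = NULL) {
  stopifnot(inherits(source, "voxel_ts"))
  symmetric <- is.null(target)
  if (symmetric) target <- source else stopifnot(inherits(target, "voxel_ts"))
  if (ncol(source$values) != ncol(target$values))
    stop("source and target must have equal timepoint counts")
  sv <- apply(source$values, 1L, stats::var)
  tv <- apply(target$values, 1L, stats::var)
  bad_s <- which(sv == 0)
  bad_t <- which(tv == 0)
  m <- suppressWarnings(stats::cor(t(source$values), t(target$values)))
  if (length(bad_s) || length(bad_t)) {
    m[bad_s, ] <- NA_real_
    m[, bad_t] <- NA_real_
    warning("zero-variance voxel(s) flagged with NA: source ",
            paste(bad_s, collapse = ","), " target ",
            paste(bad_t, collapse = ","))
  }
  structure(m, source_ids = source$voxel_ids, target_ids = target$voxel_ids,
            symmetric = symmetric, class = c("fc_matrix", "matrix", "array"))
}

## Wrap a plain matrix as fc_matrix (internal + for tests on constructed FC).
as_fc_matrix <- function(m, symmetric = isTRUE(all.equal(m, t(m)))) {
  structure(as.matrix(m), source_ids = seq_len(nrow(m)),
            target_ids = seq_len(ncol(m)), symmetric = symmetric,
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix: %d x %d voxel pairs%s, r in [%.3f, %.3f]\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "symmetric"))) " (symmetric)" else "",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Group-average FC matrices via Fisher z
#'
#' Entries are clipped to `|r| <= 1 - 1e-7`, Fisher z-transformed (atanh),
#' averaged across matrices, and transformed back. Clipping keeps unit
#' diagonals finite; they return as values `>= 1 - 2e-7`.
#'
#' @param matrices List of [fc_matrix()] objects with identical shapes and
#'   voxel index maps.
#' @return An `fc_matrix` of the same shape.
#' @export
group_fc <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1L]]
  for (m in matrices) {
    if (!all(dim(m) == dim(ref)) ||
        !identical(attr(m, "source_ids"), attr(ref, "source_ids")) ||
        !identical(attr(m, "target_ids"), attr(ref, "target_ids")))
      stop("alignment error: FC matrices differ in shape or index maps")
  }
  zs <- lapply(matrices, function(m) atanh(pmin(pmax(m, -1 + 1e-7), 1 - 1e-7)))
  avg <- tanh(Reduce(`+`, zs) / length(zs))
  structure(avg, source_ids = attr(ref, "source_ids"),
            target_ids = attr(ref, "target_ids"),
            symmetric = attr(ref, "symmetric"),
            class = class(ref))
}

#' Row-wise sparsification of an FC matrix
#'
#' Keeps, per row, the `ceiling(density * ncol)` largest entries by signed
#' value and zeroes the rest, so retained entries are the strongest positive
#' correlations. Ties at the cutoff retain the lower column index.
#'
#' @param fc An `fc_matrix` (or plain matrix).
#' @param density Fraction of entries retained per row, in `(0, 1]`.
#' @return Sparsified matrix of the same shape (`symmetric` attribute
#'   dropped: row-wise thresholding breaks symmetry in general).
#' @export
sparsify <- function(fc, density = 0.10) {
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]")
  m <- unclass(fc)
  attrs <- attributes(fc)
  if (density == 1) return(fc)
  k <- ceiling(density * ncol(m))
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    keep <- order(m[i, ], decreasing = TRUE)[seq_len(k)]  # stable: ties -> lower index
    out[i, keep] <- m[i, keep]
  }
  structure(out, source_ids = attrs$source_ids, target_ids = attrs$target_ids,
            symmetric = FALSE, class = c("fc_matrix", "matrix", "array"))
}

#' Cosine-similarity affinity of connectivity profiles
#'
#' Affinity(i, j) is the cosine similarity between rows i and j of the
#' (sparsified) FC matrix; negative similarities are clipped to 0 so the
#' matrix is a valid nonnegative diffusion weight matrix. Symmetric by
#' construction with unit diagonal.
#'
#' @param fc_sparse Matrix of connectivity profiles (rows = voxels).
#' @return Object of class `affinity_matrix` (square, symmetric,
#'   nonnegative).
#' @export
cosine_affinity <- function(fc_sparse) {
  m <- unclass(as.matrix(fc_sparse))
  nrm <- sqrt(rowSums(m^2))
  zero_rows <- which(nrm == 0)
  if (length(zero_rows))
    stop("degenerate voxel(s) with all-zero connectivity profile: ",
         paste(zero_rows, collapse = ", "))
  a <- tcrossprod(m) / outer(nrm, nrm)
  a <- pmax(a, 0)
  a <- (a + t(a)) / 2  # exact symmetry against fp round-off
  diag(a) <- 1
  structure(a, class = c("affinity_matrix", "matrix", "array"))
}

## Connected components of the graph with edges where w > 0 (BFS).
.graph_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Computes connectivity gradients: anisotropic normalisation of the
#' affinity with exponent `alpha`, row normalisation to a diffusion
#' operator, spectral decomposition (via the symmetric conjugate operator),
#' removal of the trivial stationary component, and per-component scaling by
#' the diffusion-time convention (`lambda / (1 - lambda)` at
#' `diffusion_time = 0`, else `lambda ^ diffusion_time`). Components are
#' returned in descending-eigenvalue order; their signs are arbitrary.
#'
#' @param affinity Square symmetric nonnegative matrix
#'   (see [cosine_affinity()]).
#' @param n_components Number of gradients to return (default 10, capped at
#'   `nrow - 1`).
#' @param alpha Anisotropic-diffusion exponent in `[0, 1]`; 0.5 balances
#'   geometry against sampling density.
#' @param diffusion_time Diffusion time; 0 selects the multi-scale
#'   `lambda / (1 - lambda)` weighting.
#' @return Object of class `gradient_set`: `components` (voxels x
#'   components), `eigenvalues` (nontrivial, descending), `sign_arbitrary =
#'   TRUE`, plus the parameters used.
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0) {
  w <- unclass(as.matrix(affinity))
  n <- nrow(w)
  if (ncol(w) != n) stop("affinity must be square")
  if (max(abs(w - t(w))) > 1e-12) stop("affinity must be symmetric")
  if (min(w) < 0) stop("affinity must be nonnegative")
  comp <- .graph_components(w)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("affinity graph is disconnected (", max(comp),
         " components of sizes ", paste(sizes, collapse = ", "),
         "); embed components separately or bridge them")
  }
  n_components <- min(n_components, n - 1L)
  if (n_components < 1) stop("need at least 2 voxels for one component")

  d <- rowSums(w)
  if (any(d <= 0)) stop("isolated voxel(s) with zero total affinity")
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  # symmetric conjugate of the row-stochastic operator P = D1^-1 W1
  m <- w1 / sqrt(outer(d1, d1))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  idx <- seq_len(n_components + 1L)
  lam <- e$values[idx]
  v <- e$vectors[, idx, drop = FALSE]
  # eigenvectors of P are D1^-1/2 v; dividing by the stationary vector
  # (first column) removes the scale and makes the trivial component constant
  psi <- v / v[, 1L]
  lam_nt <- lam[-1L]
  scale <- if (diffusion_time == 0) lam_nt / (1 - lam_nt) else
    lam_nt^diffusion_time
  components <- psi[, -1L, drop = FALSE] *
    matrix(scale, n, n_components, byrow = TRUE)
  structure(list(components = components, eigenvalues = lam_nt,
                 sign_arbitrary = TRUE, alpha = alpha,
                 diffusion_time = diffusion_time, n_voxels = n),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("Diffusion-map gradients: %d components over %d voxels (alpha = %g, t = %g)\n",
              ncol(x$components), x$n_voxels, x$alpha, x$diffusion_time))
  cat("  eigenvalues:", paste(sprintf("%.4f", utils::head(x$eigenvalues, 6)),
                              collapse = " "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  cat("  component signs are arbitrary\n")
  invisible(x)
}

#' @export
plot.gradient_set <- function(x, ...) {
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                 xlab = "component", ylab = "eigenvalue",
                 main = "Diffusion embedding spectrum", ...)
  invisible(x)
}
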