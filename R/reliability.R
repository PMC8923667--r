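# Intra-subject stability, inter-subject similarity, and combinatorial
# hierarchy stability.

#' Fisher z transform of a correlation
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so comparisons of identical
#' maps stay finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @examples
#' fisher_z(0.5)  # atanh(0.5) ~ 0.54931
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Inverse Fisher z
#'
#' @param z Fisher z value(s).
#' @return Correlation value(s), `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

## Pairwise Pearson correlations between list elements (as voxel maps).
.pairwise_r <- function(maps) {
  vals <- lapply(maps, .map_values)
  n <- length(vals)
  stats::cor(do.call(cbind, vals), use = "pairwise.complete.obs")
}

#' Intra-subject map stability across runs
#'
#' Pearson correlation between each pair of a subject's run maps, averaged
#' on the Fisher z scale.
#'
#' @param run_maps List of >= 2 per-voxel maps over a common voxel set.
#' @return Mean Fisher z across all run pairs.
#' @export
intra_subject_stability <- function(run_maps) {
  if (length(run_maps) < 2)
    stop("insufficient data: stability needs at least 2 runs")
  r <- .pairwise_r(run_maps)
  mean(fisher_z(r[upper.tri(r)]))
}

#' Inter-subject map similarity
#'
#' For each subject (whose map is already averaged across runs), the mean
#' Fisher z of its correlations with every other subject's map.
#'
#' @param subject_maps List of >= 2 per-voxel maps over a common voxel set.
#' @return Numeric vector of per-subject mean z scores.
#' @export
inter_subject_similarity <- function(subject_maps) {
  n <- length(subject_maps)
  if (n < 2)
    stop("insufficient data: similarity needs at least 2 subjects")
  z <- fisher_z(.pairwise_r(subject_maps))
  diag(z) <- NA
  scores <- rowMeans(z, na.rm = TRUE)
  names(scores) <- names(subject_maps)
  scores
}

#' Hierarchy stability by subject-subset resampling
#'
#' Re-computes the region hierarchy from every subset of `subset_size`
#' subjects (region means averaged over the subset, then ranked) and
#' correlates each subset ranking with the full-group ordering by Spearman's
#' rank correlation (average-rank tie handling). The stability score is the
#' mean correlation over all `choose(n_subjects, subset_size)` subsets,
#' enumerated in lexicographic order.
#'
#' @param per_subject_region_means Matrix or data frame, subjects in rows,
#'   regions in columns, entries = per-subject region-mean INTs.
#' @param group_order A [build_hierarchy()] result, or a numeric vector of
#'   group-level region means in the column order of the table.
#' @param subset_size Number of subjects per subset (default 4; must be <
#'   number of subjects).
#' @return Object of class `reliability_report` fragment: list with `score`
#'   (mean Spearman rho), `subset_count`, `subset_size`, `per_subset_rho`.
#' @export
hierarchy_stability <- function(per_subject_region_means, group_order = NULL,
                                subset_size = 4) {
  tab <- as.matrix(per_subject_region_means)
  n_subj <- nrow(tab)
  n_reg <- ncol(tab)
  if (n_reg < 2) stop("hierarchy stability needs at least 2 regions")
  if (subset_size < 1 || subset_size >= n_subj)
    stop("`subset_size` must be positive and smaller than the number of subjects")
  if (is.null(group_order)) {
    group_means <- colMeans(tab)
  } else if (inherits(group_order, "hierarchy")) {
    idx <- match(group_order$region_id, colnames(tab))
    if (anyNA(idx)) idx <- match(group_order$region_id, seq_len(n_reg))
    if (anyNA(idx))
      stop("group hierarchy regions do not match table columns")
    group_means <- numeric(n_reg)
    group_means[idx] <- group_order$mean
  } else {
    group_means <- as.numeric(group_order)
    if (length(group_means) != n_reg)
      stop("`group_order` must supply one value per region")
  }
  subsets <- utils::combn(n_subj, subset_size)  # lexicographic order
  rho <- apply(subsets, 2L, function(s)
    stats::cor(colMeans(tab[s, , drop = FALSE]), group_means,
               method = "spearman"))
  structure(list(score = mean(rho), subset_count = ncol(subsets),
                 subset_size = subset_size, per_subset_rho = rho),
            class = "hierarchy_stability")
}

#' @export
print.hierarchy_stability <- function(x, ...) {
  cat(sprintf("Hierarchy stability: mean Spearman rho = %.4f over %d subsets of size %d\n",
              x$score, x$subset_count, x$subset_size))
  invisible(x)
}

#' Full reliability report
#'
#' Bundles per-subject intra-subject stability (across that subject's run
#' maps), inter-subject similarity (across run-averaged subject maps), and
#' hierarchy stability.
#'
#' @param run_maps_by_subject List (one element per subject) of lists of
#'   per-voxel run maps.
#' @param per_subject_region_means Subjects x regions table of region means.
#' @param group_order See [hierarchy_stability()].
#' @param subset_size Subjects per subset for hierarchy stability.
#' @return Object of class `reliability_report`.
#' @export
reliability_report <- function(run_maps_by_subject,
                               per_subject_region_means = NULL,
                               group_order = NULL, subset_size = 4) {
  intra <- vapply(run_maps_by_subject, function(maps)
    if (length(maps) >= 2) intra_subject_stability(maps) else NA_real_,
    numeric(1))
  subject_maps <- lapply(run_maps_by_subject, function(maps)
    rowMeans(do.call(cbind, lapply(maps, .map_values))))
  inter <- if (length(subject_maps) >= 2)
    inter_subject_similarity(subject_maps) else NULL
  hier <- if (!is.null(per_subject_region_means) &&
              nrow(as.matrix(per_subject_region_means)) > subset_size)
    hierarchy_stability(per_subject_region_means, group_order, subset_size)
  else NULL
  structure(list(intra_subject = intra, inter_subject = inter,
                 hierarchy = hier), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability report\n")
  cat("  intra-subject stability (mean Fisher z):",
      paste(sprintf("%.3f", x$intra_subject), collapse = " "), "\n")
  if (!is.null(x$inter_subject))
    cat("  inter-subject similarity (mean Fisher z):",
        paste(sprintf("%.3f", x$inter_subject), collapse = " "), "\n")
  if (!is.null(x$hierarchy))
    cat(sprintf("  hierarchy stability: %.4f (%d subsets of %d)\n",
                x$hierarchy$score, x$hierarchy$subset_count,
                x$hierarchy$subset_size))
  invisible(x)
}
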