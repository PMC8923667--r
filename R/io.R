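# NIfTI and table I/O. Voxel flattening order is fixed: fastest axis (x)
# first, i.e. R's column-major order over (x, y, z), restricted to mask
# voxels. The order is recorded in provenance sidecars.

#' Read a 4D NIfTI run as a voxel time-series
#'
#' Masked voxels are flattened in column-major (fastest-axis-first) order.
#' The TR is taken from the header's 4th pixdim unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param mask_path 3D NIfTI mask (nonzero = in-brain), same spatial grid.
#' @param tr_seconds Optional TR override; required when the header carries
#'   no usable TR.
#' @param subject_id,run_id Identifiers attached to the result.
#' @return A [voxel_ts()].
#' @export
read_timeseries <- function(path, mask_path, tr_seconds = NULL,
                            subject_id = NA, run_id = NA) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4D volume, got ", length(dm), "D")
  mask <- RNifti::readNifti(mask_path)
  if (!identical(dim(mask)[1:3], dm[1:3]))
    stop("alignment error: mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ", paste(dm[1:3], collapse = "x"))
  sel <- which(as.vector(mask) != 0)
  if (length(sel) == 0L) stop("mask selects no voxels")
  arr <- array(img, dim = c(prod(dm[1:3]), dm[4L]))
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4L]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("no usable TR in header; pass `tr_seconds` explicitly")
  }
  voxel_ts(arr[sel, , drop = FALSE], tr_seconds = tr_seconds,
           subject_id = subject_id, run_id = run_id, voxel_ids = sel)
}

## Smallest 3D box holding n voxels (near-cubic), for synthetic volumes.
.box_dims <- function(n) {
  nx <- max(1L, as.integer(ceiling(n^(1 / 3))))
  ny <- max(1L, as.integer(ceiling(sqrt(n / nx))))
  nz <- as.integer(ceiling(n / (nx * ny)))
  c(nx, ny, nz)
}

#' Write a voxel time-series as a 4D NIfTI volume
#'
#' Voxels are packed into positions given by `voxel_positions` (linear
#' indices into the 3D grid, column-major) or, by default, the first `n`
#' positions of a near-cubic box.
#'
#' @param vts A [voxel_ts()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param dims Optional 3D grid; default: smallest near-cubic box.
#' @param voxel_positions Optional linear indices, one per voxel.
#' @return The grid dimensions used, invisibly.
#' @export
write_timeseries <- function(vts, path, dims = NULL, voxel_positions = NULL) {
  stopifnot(inherits(vts, "voxel_ts"))
  n <- nrow(vts$values)
  if (is.null(dims)) dims <- .box_dims(n)
  if (is.null(voxel_positions)) voxel_positions <- seq_len(n)
  arr <- array(0, dim = c(dims, ncol(vts$values)))
  flat <- array(arr, dim = c(prod(dims), ncol(vts$values)))
  flat[voxel_positions, ] <- vts$values
  arr <- array(flat, dim = c(dims, ncol(vts$values)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, vts$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(dims)
}

#' Write a per-voxel scalar map as a 3D NIfTI volume
#'
#' @param values Per-voxel values (or an [int_map()], whose INT values are
#'   written).
#' @param path Output path.
#' @param dims 3D grid (default near-cubic box).
#' @param voxel_positions Linear indices, one per voxel.
#' @export
write_map <- function(values, path, dims = NULL, voxel_positions = NULL) {
  v <- .map_values(values)
  if (is.null(dims)) dims <- .box_dims(length(v))
  if (is.null(voxel_positions)) voxel_positions <- seq_along(v)
  flat <- numeric(prod(dims))
  flat[voxel_positions] <- ifelse(is.na(v), 0, v)
  RNifti::writeNifti(RNifti::asNifti(array(flat, dim = dims)), path)
  invisible(dims)
}

#' Write an integer-label atlas volume
#'
#' @param atlas A [region_atlas()].
#' @param path Output path.
#' @param dims,voxel_positions As in [write_map()].
#' @export
write_atlas <- function(atlas, path, dims = NULL, voxel_positions = NULL) {
  stopifnot(inherits(atlas, "region_atlas"))
  lab <- atlas$labels
  lab[is.na(lab)] <- 0L
  write_map(as.numeric(lab), path, dims, voxel_positions)
}

#' Read a 3D NIfTI label volume as a region atlas
#'
#' @param path Label volume (integers; 0 = unlabelled).
#' @param mask_path Optional mask restricting and ordering the voxels
#'   (column-major order, matching [read_timeseries()]).
#' @param region_names Optional id-to-name mapping.
#' @return A [region_atlas()].
#' @export
read_atlas <- function(path, mask_path = NULL, region_names = NULL) {
  img <- RNifti::readNifti(path)
  lab <- as.vector(img)
  if (!is.null(mask_path)) {
    mask <- RNifti::readNifti(mask_path)
    if (!identical(dim(mask), dim(img)))
      stop("alignment error: mask and atlas grids differ")
    lab <- lab[as.vector(mask) != 0]
  }
  region_atlas(as.integer(round(lab)), region_names = region_names)
}

#' Write a synthetic dataset to disk
#'
#' One 4D NIfTI per run (`sub-XX_run-YY_bold.nii.gz`), a mask, an atlas
#' label volume, the ground truth as JSON and CSV, and the configuration as
#' YAML — so the file-based pipeline can be exercised end to end on
#' generated data.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_vox <- length(dataset$ground_truth$phi)
  dims <- .box_dims(n_vox)
  run_paths <- list()
  for (s in seq_along(dataset$runs)) {
    for (r in seq_along(dataset$runs[[s]])) {
      p <- file.path(dir, sprintf("sub-%02d_run-%02d_bold.nii.gz", s, r))
      write_timeseries(dataset$runs[[s]][[r]], p, dims = dims)
      run_paths[[sprintf("sub%02d", s)]] <- c(
        run_paths[[sprintf("sub%02d", s)]], p)
    }
  }
  mask_path <- file.path(dir, "mask.nii.gz")
  mask <- numeric(prod(dims))
  mask[seq_len(n_vox)] <- 1
  RNifti::writeNifti(RNifti::asNifti(array(mask, dim = dims)), mask_path)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_atlas(dataset$atlas, atlas_path, dims = dims)
  gt <- dataset$ground_truth
  gt_json <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(phi = gt$phi, gradient_axis = gt$gradient_axis,
                            region = gt$region, int_proxy = gt$int_proxy,
                            latent_phi = gt$latent_phi),
                       gt_json, digits = NA, auto_unbox = TRUE)
  gt_csv <- file.path(dir, "ground_truth.csv")
  utils::write.csv(data.frame(voxel = seq_len(n_vox), phi = gt$phi,
                              gradient_axis = gt$gradient_axis,
                              region = gt$region, int_proxy = gt$int_proxy),
                   gt_csv, row.names = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- unclass(dataset$config)
  cfg$regions <- as.list(as.data.frame(cfg$regions))
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(runs = run_paths, mask = mask_path, atlas = atlas_path,
                 ground_truth_json = gt_json, ground_truth_csv = gt_csv,
                 config = cfg_path, dims = dims))
}
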