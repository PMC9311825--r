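# Cohort containers: intracranial mask geometry and the subjects x voxels
# Jacobian matrix. Voxel order is ascending linear index in R's native
# column-major layout (first axis fastest); every segment index in the
# package refers to positions in that masked order.

#' Voxel mask geometry
#'
#' Builds the mask container from a binary 3D array (or a NIfTI path).
#' Masked voxels are stored as strictly increasing linear indices
#' (column-major, first axis fastest); matrix columns throughout the package
#' follow this order.
#'
#' @param mask Binary 3D array, or a path to a NIfTI mask volume.
#' @param affine 4x4 grid-to-world transform (ignored when `mask` is a path).
#' @param voxel_size Voxel edge lengths in mm (ignored when `mask` is a path).
#' @return An object of class `voxel_mask` with fields `grid_shape`,
#'   `voxel_size`, `affine`, `indices` (1-based linear indices), `n_voxels`.
#' @export
voxel_mask <- function(mask, affine = NULL, voxel_size = NULL) {
  if (is.character(mask)) {
    vol <- nifti_read(mask)
    affine <- vol$affine
    voxel_size <- vol$pixdim
    mask <- vol$data
  }
  if (length(dim(mask)) != 3L) stop("mask must be a 3D volume")
  if (is.null(affine)) affine <- diag(4)
  if (is.null(voxel_size)) voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  idx <- which(mask != 0)
  if (length(idx) < 2L) stop("mask must contain at least 2 voxels")
  structure(
    list(grid_shape = as.integer(dim(mask)), voxel_size = as.double(voxel_size),
         affine = affine, indices = as.integer(idx),
         n_voxels = length(idx)),
    class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> grid %s, %d masked voxels, voxel size %s mm\n",
              paste(x$grid_shape, collapse = "x"), x$n_voxels,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

.mask_checksum <- function(mask) {
  # order-sensitive plain-arithmetic checksum; stable across sessions
  idx <- as.double(mask$indices)
  sprintf("%s-%d-%.0f", paste(mask$grid_shape, collapse = "x"), length(idx),
          sum(idx * (seq_along(idx) %% 97 + 1)) %% 1e12)
}

#' Jacobian cohort container
#'
#' @param data n_subjects x n_voxels numeric matrix of Jacobian determinants,
#'   columns in mask index order.
#' @param mask A [voxel_mask()].
#' @param subject_ids Character vector, one per row.
#' @return An object of class `jacobian_cohort`.
#' @export
jacobian_cohort <- function(data, mask, subject_ids = NULL) {
  if (!inherits(mask, "voxel_mask")) stop("`mask` must be a voxel_mask")
  data <- as.matrix(data)
  if (ncol(data) != mask$n_voxels)
    stop("data has ", ncol(data), " columns but mask has ",
         mask$n_voxels, " voxels")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(nrow(data)))
  if (length(subject_ids) != nrow(data))
    stop("need one subject id per data row")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (!all(is.finite(data))) stop("non-finite Jacobian values inside the mask")
  n_nonpos <- sum(data <= 0)
  if (n_nonpos > 0)
    warning(n_nonpos, " non-positive Jacobian values inside the mask ",
            "(possible at smoothed edges; values kept)")
  rownames(data) <- subject_ids
  structure(list(data = data, mask = mask, subject_ids = as.character(subject_ids)),
            class = "jacobian_cohort")
}

#' @export
print.jacobian_cohort <- function(x, ...) {
  cat(sprintf("<jacobian_cohort> %d subjects x %d masked voxels (grid %s)\n",
              nrow(x$data), ncol(x$data),
              paste(x$mask$grid_shape, collapse = "x")))
  invisible(x)
}

#' Load a Jacobian cohort from NIfTI volumes
#'
#' All volumes must share grid shape and affine with the mask (affine entries
#' within `tol`). Row `s` of the result samples volume `s` at the masked
#' voxels in mask index order.
#'
#' @param volume_paths Character vector of per-subject NIfTI paths.
#' @param mask_path Path to the binary intracranial mask volume.
#' @param subject_ids Optional ids; defaults to file basenames.
#' @param tol Absolute tolerance on affine entries.
#' @return A [jacobian_cohort()].
#' @export
load_jacobian_cohort <- function(volume_paths, mask_path, subject_ids = NULL,
                                 tol = 1e-4) {
  mask <- voxel_mask(mask_path)
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  data <- matrix(NA_real_, nrow = length(volume_paths), ncol = mask$n_voxels)
  for (s in seq_along(volume_paths)) {
    vol <- nifti_read(volume_paths[s])
    if (!identical(as.integer(vol$dim), mask$grid_shape))
      stop("grid shape of ", volume_paths[s], " (",
           paste(vol$dim, collapse = "x"), ") does not match the mask (",
           paste(mask$grid_shape, collapse = "x"), ")")
    if (max(abs(vol$affine - mask$affine)) > tol)
      stop("affine of ", volume_paths[s], " differs from the mask affine ",
           "beyond tolerance ", tol)
    row <- as.vector(vol$data)[mask$indices]
    if (!all(is.finite(row)))
      stop("non-finite voxel values inside the mask in ", volume_paths[s])
    data[s, ] <- row
  }
  jacobian_cohort(data, mask, subject_ids)
}

#' Re-insert masked values into the 3D grid
#'
#' @param values Numeric vector, one value per masked voxel.
#' @param mask A [voxel_mask()].
#' @param fill Value for voxels outside the mask.
#' @return 3D array of the mask's grid shape.
#' @export
values_to_grid <- function(values, mask, fill = 0) {
  if (length(values) != mask$n_voxels)
    stop("need one value per masked voxel")
  grid <- array(fill, dim = mask$grid_shape)
  grid[mask$indices] <- values
  grid
}

#' Write each cohort row as a NIfTI volume
#'
#' Inverse of [load_jacobian_cohort()]: values outside the mask are zero;
#' storage is float64 so the reload is bitwise-identical.
#'
#' @param cohort A [jacobian_cohort()].
#' @param dir Output directory (created if needed).
#' @param gz Compress volumes (`.nii.gz`).
#' @return Named character vector of written volume paths (mask written as
#'   `mask.nii[.gz]` alongside).
#' @export
write_cohort_volumes <- function(cohort, dir, gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  mask <- cohort$mask
  mask_grid <- values_to_grid(rep(1, mask$n_voxels), mask)
  nifti_write(mask_grid, file.path(dir, paste0("mask", ext)),
              affine = mask$affine, datatype = "uint8")
  paths <- character(nrow(cohort$data))
  for (s in seq_len(nrow(cohort$data))) {
    paths[s] <- file.path(dir, paste0(cohort$subject_ids[s], ext))
    nifti_write(values_to_grid(cohort$data[s, ], mask), paths[s],
                affine = mask$affine, datatype = "float64")
  }
  names(paths) <- cohort$subject_ids
  paths
}

#' Per-subject sample homogeneity
#'
#' Quality-control score: each subject's masked Jacobian map correlated
#' (Pearson) with every other subject's map, averaged. Scores lie in
#' \[-1, 1\]; low values flag outlying maps.
#'
#' @param cohort A [jacobian_cohort()] with at least 3 subjects.
#' @return Named numeric vector of mean pairwise correlations.
#' @export
sample_homogeneity <- function(cohort) {
  X <- cohort$data
  n <- nrow(X)
  if (n < 3L) stop("sample homogeneity needs at least 3 subjects")
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance Jacobian map for subject(s): ",
         paste(cohort$subject_ids[sds == 0], collapse = ", "))
  C <- stats::cor(t(X))
  scores <- (rowSums(C) - 1) / (n - 1)
  names(scores) <- cohort$subject_ids
  scores
}

#' Export a hierarchy level as a NIfTI label map
#'
#' Each masked voxel carries the integer id of the segment covering it at
#' `level`; voxels outside the mask (and voxels whose branch stopped early
#' above this level) are 0.
#'
#' @param tree A `segment_tree` (see [build_hierarchy()]).
#' @param level Level to export (1 = root).
#' @param mask A [voxel_mask()].
#' @param path Optional output NIfTI path; when `NULL` the label array is
#'   returned instead.
#' @return The label array (invisibly when written to `path`).
#' @export
export_label_map <- function(tree, level, mask, path = NULL) {
  labels <- tree_level_labels(tree, level)
  grid <- values_to_grid(labels, mask)
  if (!is.null(path)) {
    nifti_write(grid, path, affine = mask$affine, datatype = "int32")
    return(invisible(grid))
  }
  grid
}

# ---- cohort table ----------------------------------------------------------

.cohort_table_required <- c("subject_id", "mutation", "status", "phenotype",
                            "age", "sex", "site", "family")

#' Read and validate a cohort table
#'
#' CSV with columns subject_id, mutation (C9orf72/GRN/MAPT), status
#' (non-carrier/asymptomatic/symptomatic), phenotype (may be empty), age,
#' sex, site, family. age/sex/site/family must be complete (they enter every
#' model as covariates of no interest).
#'
#' @param path CSV path, or a data.frame to validate in place.
#' @param subject_ids Optional cohort subject ids the table must cover.
#' @return Validated data.frame.
#' @export
read_cohort_table <- function(path, subject_ids = NULL) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_table_required, names(tab))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id in cohort table")
  bad <- !tab$mutation %in% c("C9orf72", "GRN", "MAPT")
  if (any(bad)) stop("unknown mutation value(s): ",
                     paste(unique(tab$mutation[bad]), collapse = ", "))
  bad <- !tab$status %in% c("non-carrier", "asymptomatic", "symptomatic")
  if (any(bad)) stop("unknown status value(s): ",
                     paste(unique(tab$status[bad]), collapse = ", "))
  for (col in c("age", "sex", "site", "family")) {
    if (anyNA(tab[[col]])) stop("missing values in covariate column '", col, "'")
  }
  if (!is.null(subject_ids)) {
    missing_ids <- setdiff(subject_ids, tab$subject_id)
    if (length(missing_ids))
      stop("cohort table lacks subject(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    tab <- tab[match(subject_ids, tab$subject_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
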