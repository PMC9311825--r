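# Per-segment form features.
#
# Size: the mean Jacobian over a segment's voxels, one value per subject.
# Shape: each subject's within-segment Jacobian pattern after dividing by
# its size (every row then averages to exactly 1), mean-centered per voxel
# and summarized by principal components; Horn's parallel analysis against
# column-permutation nulls decides how many components carry signal.

#' Segmental size
#'
#' @param cohort A [jacobian_cohort()].
#' @param voxels Segment voxel column indices (nonempty).
#' @return Named numeric vector: mean Jacobian per subject.
#' @export
segmental_size <- function(cohort, voxels) {
  if (length(voxels) == 0L) stop("empty segment")
  out <- rowMeans(cohort$data[, voxels, drop = FALSE])
  names(out) <- cohort$subject_ids
  out
}

#' Size-normalized segment residuals
#'
#' Divides each subject's Jacobians over the segment by that subject's
#' segmental size; every row of the result has mean exactly 1.
#'
#' @inheritParams segmental_size
#' @return n_subjects x n_segment_voxels matrix.
#' @export
size_normalized_residuals <- function(cohort, voxels) {
  sizes <- segmental_size(cohort, voxels)
  if (any(sizes == 0)) {
    bad <- cohort$subject_ids[sizes == 0]
    stop("zero segmental size for subject(s) ", paste(bad, collapse = ", "),
         " on a ", length(voxels), "-voxel segment: cannot size-normalize")
  }
  cohort$data[, voxels, drop = FALSE] / sizes
}

#' Shape space of a segment
#'
#' PCA (by singular value decomposition) of the size-normalized residuals
#' after mean-centering each voxel across subjects. When the segment has
#' more voxels than subjects, the decomposition runs on the subjects-side
#' Gram matrix, which is exact and much cheaper.
#'
#' @param residuals Matrix from [size_normalized_residuals()]
#'   (n_subjects >= 3).
#' @param tol Relative tolerance under which singular values count as zero.
#' @return List of class `shape_space`: `scores` (subjects x components,
#'   zero column means), `loadings` (components x voxels, orthonormal rows),
#'   `explained_variance` (eigenvalues of the covariance), `k` (rank).
#' @export
shape_space <- function(residuals, tol = 1e-10) {
  n <- nrow(residuals)
  if (n < 3L) stop("shape space needs at least 3 subjects")
  Xc <- sweep(residuals, 2L, colMeans(residuals))
  if (ncol(Xc) > n) {
    G <- tcrossprod(Xc)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    # threshold on the eigenvalue scale: sqrt would inflate noise eigenvalues
    keep <- e$values > tol * max(e$values, .Machine$double.eps)
    dvals <- sqrt(pmax(e$values, 0))
    u <- e$vectors[, keep, drop = FALSE]
    dvals <- dvals[keep]
    scores <- sweep(u, 2L, dvals, "*")
    loadings <- t(crossprod(Xc, u) %*% diag(1 / dvals, length(dvals)))
  } else {
    s <- svd(Xc)
    keep <- s$d > tol * max(s$d, .Machine$double.eps)
    dvals <- s$d[keep]
    scores <- sweep(s$u[, keep, drop = FALSE], 2L, dvals, "*")
    loadings <- t(s$v[, keep, drop = FALSE])
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = dvals^2 / (n - 1),
                 k = length(dvals)),
            class = "shape_space")
}

.pca_eigenvalues <- function(X) {
  # covariance eigenvalues of a column-centered matrix via the cheaper side
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  if (ncol(Xc) > n) {
    ev <- eigen(tcrossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  }
  pmax(ev, 0) / (n - 1)
}

#' Parallel analysis component retention
#'
#' Horn's procedure with permutation nulls: each null dataset permutes every
#' column independently across subjects (preserving marginals, destroying
#' covariance); component j is retained while its eigenvalue exceeds the
#' `percentile` percentile of the j-th null eigenvalue, stopping at the
#' first failure.
#'
#' @param residuals Matrix from [size_normalized_residuals()].
#' @param n_null Number of permutation null datasets.
#' @param percentile Null percentile a component must beat (95 by default).
#' @param seed Integer seed for the permutations.
#' @return Integer: number of retained components (possibly 0).
#' @export
parallel_analysis <- function(residuals, n_null = 100L, percentile = 95,
                              seed = 1L) {
  n <- nrow(residuals)
  if (n < 3L) stop("parallel analysis needs at least 3 subjects")
  obs <- .pca_eigenvalues(residuals)
  n_comp <- length(obs)
  null_ev <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      perm <- apply(residuals, 2L, function(col) col[sample.int(n)])
      .pca_eigenvalues(perm)[seq_len(n_comp)]
    }, numeric(n_comp))
  })
  null_ev <- matrix(null_ev, nrow = n_comp)
  crit <- apply(null_ev, 1L, stats::quantile, probs = percentile / 100,
                names = FALSE, type = 7)
  k <- 0L
  for (j in seq_len(n_comp)) {
    if (obs[j] > crit[j]) k <- k + 1L else break
  }
  k
}

#' Compute size and shape features for every tree segment
#'
#' @param cohort A [jacobian_cohort()].
#' @param tree A `segment_tree`.
#' @param n_null,percentile,seed Passed to [parallel_analysis()]; each
#'   segment uses a seed derived deterministically from `seed` and its id.
#' @return List of class `segment_features`: per node id, `size` (vector),
#'   `shape` (a `shape_space` truncated to the retained components) and
#'   `k_retained`.
#' @export
segment_features <- function(cohort, tree, n_null = 100L, percentile = 95,
                             seed = 1L) {
  out <- list()
  for (nd in tree$nodes) {
    res <- size_normalized_residuals(cohort, nd$voxels)
    k_ret <- parallel_analysis(res, n_null, percentile,
                               seed = (seed + nd$id * 131L) %% 2147483647L)
    sp <- shape_space(res)
    k_use <- min(k_ret, sp$k)
    shape <- list(scores = sp$scores[, seq_len(k_use), drop = FALSE],
                  loadings = sp$loadings[seq_len(k_use), , drop = FALSE],
                  explained_variance = sp$explained_variance[seq_len(k_use)],
                  k = k_use)
    out[[as.character(nd$id)]] <- list(
      id = nd$id, level = nd$level, n_voxels = length(nd$voxels),
      size = segmental_size(cohort, nd$voxels),
      shape = shape, k_retained = k_use)
  }
  structure(out, class = "segment_features",
            subject_ids = cohort$subject_ids)
}

#' Write segment features to disk
#'
#' Sizes as one TSV (segments x subjects) plus one score TSV per segment
#' with a JSON manifest.
#'
#' @param features A [segment_features()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_segment_features <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- t(vapply(features, function(f) f$size,
                    numeric(length(attr(features, "subject_ids")))))
  rownames(sizes) <- names(features)
  utils::write.table(sizes, file.path(dir, "sizes.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  manifest <- list(subject_ids = attr(features, "subject_ids"),
                   segments = lapply(unname(features), function(f)
                     list(id = f$id, level = f$level, n_voxels = f$n_voxels,
                          k_retained = f$k_retained)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in features) {
    if (f$k_retained > 0L) {
      sc <- f$shape$scores
      rownames(sc) <- attr(features, "subject_ids")
      utils::write.table(sc, file.path(dir, sprintf("scores-%04d.tsv", f$id)),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  invisible(dir)
}
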