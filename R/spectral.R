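# Population-level hierarchical spectral clustering.
#
# Affinity between voxels i and j is A(i,j) = 0.5*(corr(J_i, J_j) + 1), the
# Pearson correlation of the two voxels' Jacobian values across all subjects
# mapped to [0,1]. The normalized Laplacian L = D^{-1/2} A D^{-1/2} (D =
# diagonal of column sums) is eigendecomposed; the k = 2 leading eigenvectors
# embed the voxels and drive k-means into two clusters. At scale neither A
# nor L is formed: a Nystrom estimate from random landmark columns is
# averaged over repeated draws, and k-means is repeated and merged by a
# normalized vote-weighting consensus. Recursive binary splitting yields the
# global-to-local hierarchy (complete depth-8 tree = 255 segments).

#' Segmentation configuration
#'
#' @param landmark_frac Fraction of segment voxels used as Nystrom landmarks.
#' @param min_landmarks Lower bound on the landmark count (capped at the
#'   segment size).
#' @param n_estimations Number of averaged Nystrom estimations per split.
#' @param kmeans_repeats Number of k-means repeats merged by consensus.
#' @param row_normalize Scale embedding rows to unit length before k-means
#'   (Ng-Jordan-Weiss convention).
#' @param min_segment_voxels Nodes smaller than this are not split further.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(landmark_frac = 0.1, min_landmarks = 100L,
                           n_estimations = 50L, kmeans_repeats = 50L,
                           row_normalize = TRUE, min_segment_voxels = 32L) {
  stopifnot(landmark_frac > 0, landmark_frac <= 1, min_landmarks >= 2,
            n_estimations >= 1, kmeans_repeats >= 1, min_segment_voxels >= 2)
  structure(list(landmark_frac = landmark_frac,
                 min_landmarks = as.integer(min_landmarks),
                 n_estimations = as.integer(n_estimations),
                 kmeans_repeats = as.integer(kmeans_repeats),
                 row_normalize = isTRUE(row_normalize),
                 min_segment_voxels = as.integer(min_segment_voxels)),
            class = "segment_config")
}

.n_landmarks_for <- function(n_voxels, config) {
  min(n_voxels, max(ceiling(config$landmark_frac * n_voxels),
                    config$min_landmarks))
}

#' Pairwise voxel affinity
#'
#' `0.5 * (Pearson(col_i, col_j) + 1)`: anticorrelated voxel pairs get
#' affinity 0, perfectly correlated pairs 1.
#'
#' @param cohort A [jacobian_cohort()].
#' @param i,j Voxel column indices.
#' @return Affinity in \[0, 1\].
#' @export
pairwise_affinity <- function(cohort, i, j) {
  if (i == j) return(1)
  x <- cohort$data[, i]
  y <- cohort$data[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance voxel column (", if (stats::sd(x) == 0) i else j,
         "): affinity undefined")
  0.5 * (stats::cor(x, y) + 1)
}

#' Dense affinity matrix over a voxel subset
#'
#' Exact `0.5*(cor+1)` affinity; intended for oracles and small segments.
#'
#' @inheritParams pairwise_affinity
#' @param voxel_subset Column indices (default all).
#' @return Symmetric matrix with unit diagonal.
#' @export
affinity_matrix <- function(cohort, voxel_subset = NULL) {
  X <- if (is.null(voxel_subset)) cohort$data else
    cohort$data[, voxel_subset, drop = FALSE]
  sds <- .col_sds(X)
  if (any(sds == 0))
    stop("zero-variance voxel column(s) in subset: affinity undefined")
  A <- 0.5 * (stats::cor(X) + 1)
  diag(A) <- 1
  A
}

.col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}

#' Normalized Laplacian
#'
#' `L = D^{-1/2} A D^{-1/2}` with `d_ii` the sum of column i of A. All
#' eigenvalues of L lie in \[-1, 1\].
#'
#' @param A Symmetric nonnegative affinity matrix.
#' @return List with `L` (matrix) and `d` (degree vector).
#' @export
normalized_laplacian <- function(A) {
  d <- colSums(A)
  if (any(d <= 0)) stop("zero column sum in affinity matrix")
  inv_sqrt_d <- 1 / sqrt(d)
  L <- A * tcrossprod(inv_sqrt_d)
  list(L = (L + t(L)) / 2, d = d)
}

#' Dense spectral embedding (reference path)
#'
#' Full affinity, full normalized Laplacian, exact eigendecomposition.
#' The independent oracle against which the Nystrom path is validated;
#' feasible up to a few thousand voxels.
#'
#' @inheritParams affinity_matrix
#' @param k Number of leading eigenvectors (2 for a binary split).
#' @return List of class `spectral_embedding`: `coordinates`
#'   (voxels x k), `eigenvalues` (descending).
#' @export
dense_embedding <- function(cohort, voxel_subset = NULL, k = 2L) {
  A <- affinity_matrix(cohort, voxel_subset)
  L <- normalized_laplacian(A)$L
  e <- eigen(L, symmetric = TRUE)
  structure(list(coordinates = e$vectors[, seq_len(k), drop = FALSE],
                 eigenvalues = e$values[seq_len(k)]),
            class = "spectral_embedding")
}

.pinv_sqrt <- function(W, tol = 1e-10, warn_below = 0L) {
  # symmetric pseudo-inverse square root. Rank deficiency is structural
  # whenever landmarks outnumber subjects (the correlation affinity has rank
  # <= n_subjects + 1), so the pseudo-inverse is silent unless the rank
  # falls below `warn_below` (e.g. the requested eigenvector count).
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (sum(keep) < warn_below)
    warning("landmark block rank ", sum(keep), " below requested ",
            warn_below, ": pseudo-inverse fallback")
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / sqrt(e$values[keep]))
}

#' Nystrom spectral embedding
#'
#' Estimates the leading eigenvectors of the normalized Laplacian over
#' `voxel_subset` from the affinity columns of a random landmark subset,
#' without forming the full matrix. Degrees are approximated through the
#' low-rank expansion `A ~ C W^{-1} C'`; the one-shot orthogonalization of
#' the normalized column block yields orthonormal eigenvector estimates.
#' With all voxels as landmarks the estimate is exact.
#'
#' @inheritParams dense_embedding
#' @param n_landmarks Number of landmark voxels (>= 2).
#' @param seed Integer seed controlling the landmark draw.
#' @return A `spectral_embedding` with attribute `landmarks`.
#' @export
nystrom_embedding <- function(cohort, voxel_subset = NULL, n_landmarks,
                              k = 2L, seed = 1L) {
  if (is.null(voxel_subset)) voxel_subset <- seq_len(ncol(cohort$data))
  n <- length(voxel_subset)
  stopifnot(n_landmarks >= 2, n_landmarks <= n, k <= n_landmarks)
  X <- cohort$data[, voxel_subset, drop = FALSE]
  ns <- nrow(X)
  sds <- .col_sds(X)
  if (any(sds == 0))
    stop("zero-variance voxel column(s) in subset: affinity undefined")
  Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, sds * sqrt(ns - 1), "/")
  landmarks <- if (n_landmarks == n) seq_len(n) else
    withr::with_seed(seed, sort(sample.int(n, n_landmarks)))
  # affinity columns: C = 0.5*(cor + 1)
  C <- crossprod(Xs, Xs[, landmarks, drop = FALSE]) * 0.5 + 0.5
  W <- C[landmarks, , drop = FALSE]
  W <- (W + t(W)) / 2
  # approximate degrees: d = C W^{-1} C' 1
  Winv_sqrt <- .pinv_sqrt(W)
  ct1 <- colSums(C)
  d <- as.vector(C %*% (Winv_sqrt %*% (Winv_sqrt %*% ct1)))
  d <- pmax(d, 1e-8)
  Cb <- C / sqrt(d)
  Cb <- sweep(Cb, 2L, sqrt(d[landmarks]), "/")
  Wb <- Cb[landmarks, , drop = FALSE]
  Q <- Cb %*% .pinv_sqrt((Wb + t(Wb)) / 2, warn_below = k)
  M <- crossprod(Q)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], .Machine$double.eps)
  U <- Q %*% e$vectors[, seq_len(k), drop = FALSE]
  U <- sweep(U, 2L, sqrt(ev), "/")
  structure(list(coordinates = U, eigenvalues = e$values[seq_len(k)],
                 landmarks = landmarks),
            class = "spectral_embedding")
}

.align_embedding <- function(E, ref) {
  # per-column sign flip toward ref, then orthogonal Procrustes rotation
  for (j in seq_len(ncol(E))) {
    if (sum(E[, j] * ref[, j]) < 0) E[, j] <- -E[, j]
  }
  s <- svd(crossprod(E, ref))
  E %*% (s$u %*% t(s$v))
}

#' Averaged Nystrom embedding
#'
#' Runs `n_estimations` Nystrom estimations on independently drawn landmark
#' subsets, aligns each to the first (per-component sign flip, then
#' orthogonal Procrustes — raw eigenvectors carry arbitrary sign/rotation,
#' so naive averaging would cancel), and returns the element-wise mean.
#'
#' @inheritParams nystrom_embedding
#' @param n_estimations Number of estimations to average (50 by default).
#' @return A `spectral_embedding`.
#' @export
average_nystrom <- function(cohort, voxel_subset = NULL, n_estimations = 50L,
                            n_landmarks, k = 2L, seed = 1L) {
  if (is.null(voxel_subset)) voxel_subset <- seq_len(ncol(cohort$data))
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_estimations))
  first <- nystrom_embedding(cohort, voxel_subset, n_landmarks, k, seeds[1])
  acc <- first$coordinates
  ev <- first$eigenvalues
  if (n_estimations > 1L) {
    for (r in 2:n_estimations) {
      est <- nystrom_embedding(cohort, voxel_subset, n_landmarks, k, seeds[r])
      acc <- acc + .align_embedding(est$coordinates, first$coordinates)
      ev <- ev + est$eigenvalues
    }
  }
  structure(list(coordinates = acc / n_estimations,
                 eigenvalues = ev / n_estimations),
            class = "spectral_embedding")
}

#' Consensus k-means
#'
#' Repeats k-means `n_repeats` times from random starts, matches each
#' repeat's labels to the first valid repeat by maximal overlap, accumulates
#' votes weighted by the inverse size of the voting cluster, and assigns
#' each point to the label with the larger normalized vote (ties toward the
#' smaller label id). Repeats producing an empty cluster are discarded.
#'
#' @param coordinates Numeric matrix (points x embedding dims), or a
#'   `spectral_embedding`.
#' @param k Number of clusters (2).
#' @param n_repeats Number of k-means repeats.
#' @param seed Integer seed.
#' @return Integer label vector in `1:k`; both clusters nonempty.
#' @export
consensus_kmeans <- function(coordinates, k = 2L, n_repeats = 50L, seed = 1L) {
  if (inherits(coordinates, "spectral_embedding"))
    coordinates <- coordinates$coordinates
  stopifnot(k == 2L)
  n <- nrow(coordinates)
  if (n < k) stop("fewer points than clusters")
  votes <- matrix(0, nrow = n, ncol = k)
  ref <- NULL
  n_valid <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      labels <- tryCatch({
        km <- suppressWarnings(
          stats::kmeans(coordinates, centers = k, nstart = 1L, iter.max = 100L))
        if (any(tabulate(km$cluster, k) == 0L)) NULL else km$cluster
      }, error = function(e) NULL)
      if (is.null(labels)) next
      if (is.null(ref)) {
        ref <- labels
      } else {
        # for k = 2: keep or swap, whichever agrees more with the reference
        if (sum(labels == ref) < n / 2) labels <- 3L - labels
      }
      sizes <- tabulate(labels, k)
      w <- 1 / sizes
      votes[cbind(seq_len(n), labels)] <-
        votes[cbind(seq_len(n), labels)] + w[labels]
      n_valid <- n_valid + 1L
    }
  })
  if (n_valid == 0L)
    stop(structure(class = c("hierseg_split_failure", "error", "condition"),
                   list(message = "all k-means repeats produced an empty cluster",
                        call = sys.call())))
  out <- max.col(votes, ties.method = "first")
  if (any(tabulate(out, k) == 0L))
    stop(structure(class = c("hierseg_split_failure", "error", "condition"),
                   list(message = "consensus produced an empty cluster",
                        call = sys.call())))
  out
}

#' Split a segment into two
#'
#' Recomputes the affinity from scratch on the segment's columns (Pearson
#' across all subjects restricted to these voxels), embeds with averaged
#' Nystrom, and bipartitions with consensus k-means. Zero-variance voxels
#' (possible in synthetic data) are held out of the clustering and assigned
#' to the cluster of their nearest non-degenerate voxel in mask order. If
#' consensus fails, the deterministic fallback thresholds the second
#' eigenvector at its median.
#'
#' @inheritParams dense_embedding
#' @param config A [segment_config()].
#' @param seed Integer seed.
#' @return List with `left` and `right`: disjoint, nonempty index sets
#'   (partitioning `voxel_subset`); `left` contains the smallest index.
#' @export
split_segment <- function(cohort, voxel_subset, config = segment_config(),
                          seed = 1L) {
  n <- length(voxel_subset)
  if (n < 2L) stop("cannot split a segment of fewer than 2 voxels")
  sds <- .col_sds(cohort$data[, voxel_subset, drop = FALSE])
  active <- which(sds > 0)
  degenerate <- which(sds == 0)
  if (length(active) < 2L)
    stop("segment has fewer than 2 non-degenerate voxels; cannot split")
  sub <- voxel_subset[active]
  if (length(sub) == 2L) {
    labels <- c(1L, 2L)
  } else {
    m <- .n_landmarks_for(length(sub), config)
    emb <- average_nystrom(cohort, sub, config$n_estimations, m,
                           k = 2L, seed = seed)
    coords <- emb$coordinates
    if (config$row_normalize) {
      nrm <- sqrt(rowSums(coords^2))
      nrm[nrm == 0] <- 1
      coords <- coords / nrm
    }
    labels <- tryCatch(
      consensus_kmeans(coords, k = 2L, n_repeats = config$kmeans_repeats,
                       seed = seed),
      hierseg_split_failure = function(e) {
        v2 <- emb$coordinates[, 2L]
        as.integer(v2 > stats::median(v2)) + 1L
      })
    if (length(unique(labels)) < 2L) {
      v2 <- emb$coordinates[, 2L]
      ord <- order(v2)
      labels <- integer(length(sub))
      labels[ord[seq_len(floor(length(sub) / 2))]] <- 1L
      labels[labels == 0L] <- 2L
    }
  }
  full <- integer(n)
  full[active] <- labels
  for (dg in degenerate) {
    nearest <- active[which.min(abs(active - dg))]
    full[dg] <- full[nearest]
  }
  side1 <- voxel_subset[full == 1L]
  side2 <- voxel_subset[full == 2L]
  if (min(side1) <= min(side2)) list(left = side1, right = side2)
  else list(left = side2, right = side1)
}

#' Build the global-to-local segment hierarchy
#'
#' Recursively bipartitions the full mask (`levels = 8` gives up to
#' `2^8 - 1 = 255` segments, 128 at the deepest level). Level 1 is the
#' entire mask; every split recomputes the affinity on the segment's own
#' columns; segmentation never sees group labels. Nodes smaller than
#' `min_segment_voxels` become leaves early (recorded in the
#' `incomplete_nodes` attribute) and are excluded from deeper levels.
#'
#' @inheritParams split_segment
#' @param levels Number of hierarchy levels (>= 1).
#' @return Object of class `segment_tree`: list of nodes (id, level, parent,
#'   children, voxels) with heap-style ids (root 1, children of `i` are `2i`
#'   and `2i+1`), plus `depth` and `n_voxels`.
#' @export
build_hierarchy <- function(cohort, levels = 8L, config = segment_config(),
                            seed = 1L) {
  stopifnot(levels >= 1L)
  root_voxels <- seq_len(ncol(cohort$data))
  nodes <- list(`1` = list(id = 1L, level = 1L, parent = NA_integer_,
                           children = integer(0), voxels = root_voxels))
  incomplete <- integer(0)
  for (level in seq_len(levels - 1L)) {
    level_ids <- vapply(nodes, function(nd) nd$id, integer(1))
    level_ids <- level_ids[vapply(nodes, function(nd)
      nd$level == level && length(nd$children) == 0L, logical(1))]
    for (id in sort(level_ids)) {
      nd <- nodes[[as.character(id)]]
      if (length(nd$voxels) < config$min_segment_voxels) {
        incomplete <- c(incomplete, id)
        next
      }
      node_seed <- (as.double(seed) * 2654435761 + as.double(id) * 40503) %%
        2147483647
      halves <- split_segment(cohort, nd$voxels, config,
                              seed = as.integer(node_seed))
      lid <- 2L * id
      rid <- 2L * id + 1L
      nodes[[as.character(id)]]$children <- c(lid, rid)
      nodes[[as.character(lid)]] <- list(id = lid, level = level + 1L,
                                         parent = id, children = integer(0),
                                         voxels = halves$left)
      nodes[[as.character(rid)]] <- list(id = rid, level = level + 1L,
                                         parent = id, children = integer(0),
                                         voxels = halves$right)
    }
  }
  nodes <- nodes[order(as.integer(names(nodes)))]
  structure(list(nodes = nodes, depth = as.integer(levels),
                 n_voxels = length(root_voxels)),
            class = "segment_tree",
            incomplete_nodes = incomplete)
}

#' @export
print.segment_tree <- function(x, ...) {
  lv <- vapply(x$nodes, function(nd) nd$level, integer(1))
  cat(sprintf("<segment_tree> depth %d, %d segments (%s per level), %d voxels\n",
              x$depth, length(x$nodes),
              paste(tabulate(lv, x$depth), collapse = "/"), x$n_voxels))
  inc <- attr(x, "incomplete_nodes")
  if (length(inc)) cat("  early-stopped nodes:", paste(inc, collapse = ", "), "\n")
  invisible(x)
}

#' Segment ids per tree level
#'
#' @param tree A `segment_tree`.
#' @param level Level (1 = root).
#' @return Integer vector over masked voxels: the id of the level-`level`
#'   segment covering each voxel, or 0 for voxels whose branch stopped
#'   before this level.
#' @export
tree_level_labels <- function(tree, level) {
  if (level < 1L || level > tree$depth)
    stop("level must be in 1..", tree$depth)
  labels <- integer(tree$n_voxels)
  for (nd in tree$nodes) {
    if (nd$level == level) labels[nd$voxels] <- nd$id
  }
  labels
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (1 = identical).
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# ---- tree serialization ----------------------------------------------------

#' Write a segment tree as JSON
#'
#' @param tree A `segment_tree`.
#' @param path Output path.
#' @param mask Optional [voxel_mask()]; adds a `mask_checksum` field tying
#'   the tree to the mask it was built on.
#' @return `path`, invisibly.
#' @export
write_segment_tree <- function(tree, path, mask = NULL) {
  nodes <- lapply(unname(tree$nodes), function(nd) {
    list(id = nd$id, level = nd$level,
         parent = if (is.na(nd$parent)) NULL else nd$parent,
         children = nd$children, voxel_indices = nd$voxels)
  })
  obj <- list(depth = tree$depth, n_voxels = tree$n_voxels,
              incomplete_nodes = as.integer(attr(tree, "incomplete_nodes")),
              mask_checksum = if (is.null(mask)) NULL else .mask_checksum(mask),
              nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segment tree from JSON
#'
#' @param path Path written by [write_segment_tree()].
#' @param mask Optional [voxel_mask()]; when given, the stored checksum is
#'   verified.
#' @return A `segment_tree`.
#' @export
read_segment_tree <- function(path, mask = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!is.null(mask) && !is.null(obj$mask_checksum) &&
      !identical(obj$mask_checksum, .mask_checksum(mask)))
    stop("segment tree was built on a different mask (checksum mismatch)")
  nodes <- lapply(obj$nodes, function(nd) {
    list(id = as.integer(nd$id), level = as.integer(nd$level),
         parent = if (length(nd$parent) == 0) NA_integer_ else
           as.integer(nd$parent),
         children = as.integer(nd$children),
         voxels = as.integer(nd$voxel_indices))
  })
  names(nodes) <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  nodes <- nodes[order(as.integer(names(nodes)))]
  structure(list(nodes = nodes, depth = as.integer(obj$depth),
                 n_voxels = as.integer(obj$n_voxels)),
            class = "segment_tree",
            incomplete_nodes = as.integer(obj$incomplete_nodes))
}
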