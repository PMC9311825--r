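# Exploratory map algebra on top of the contrast results.
#
# For one contrast and one feature, every hierarchy level yields a binary
# voxel map marking the FDR-significant segments; the level maps are summed
# into a 0..depth weight map used to weight Jacobians per subject, and
# concatenated (not summed) when two results are compared with the Dice
# coefficient.

#' Thresholded significance map
#'
#' @param results A `contrast_results` data.frame (see
#'   [run_all_contrasts()]).
#' @param tree The `segment_tree` the results were computed on.
#' @param contrast Contrast name as it appears in `results$contrast`.
#' @param feature `"size"` or `"shape"`.
#' @return Object of class `thresholded_map`: `per_level` (depth x
#'   n_voxels binary matrix), `summed` (per-voxel level count, 0..depth),
#'   `contrast`, `feature`, `depth`.
#' @export
thresholded_map <- function(results, tree, contrast, feature) {
  stopifnot(feature %in% c("size", "shape"))
  sub <- results[results$contrast == contrast & results$feature == feature &
                   results$significant, , drop = FALSE]
  per_level <- matrix(0L, nrow = tree$depth, ncol = tree$n_voxels)
  for (i in seq_len(nrow(sub))) {
    nd <- tree$nodes[[as.character(sub$segment_id[i])]]
    per_level[nd$level, nd$voxels] <- 1L
  }
  structure(list(per_level = per_level, summed = colSums(per_level),
                 contrast = contrast, feature = feature, depth = tree$depth),
            class = "thresholded_map")
}

#' Weighted Jacobian per subject
#'
#' Weights each subject's Jacobians by the summed thresholded map:
#' `sum_v w(v) J(s, v) / sum_v w(v)`.
#'
#' @param cohort A [jacobian_cohort()].
#' @param map A [thresholded_map()] (or a bare nonnegative weight vector).
#' @return Named numeric vector, one weighted average per subject.
#' @export
weighted_jacobian <- function(cohort, map) {
  w <- if (inherits(map, "thresholded_map")) map$summed else as.numeric(map)
  stopifnot(length(w) == ncol(cohort$data))
  total <- sum(w)
  if (total == 0) stop("all-zero weight map: weighted Jacobian undefined")
  out <- as.vector(cohort$data %*% w) / total
  names(out) <- cohort$subject_ids
  out
}

#' One-way ANOVA across clinical phenotypes
#'
#' Fixed-effects one-way ANOVA of per-subject values (typically weighted
#' Jacobians) across phenotype labels within a symptomatic group.
#'
#' @param values Numeric vector.
#' @param phenotype Character/factor labels aligned with `values`.
#' @return List with `F`, `p`, `df1`, `df2`; or a list with
#'   `computable = FALSE` and a `reason` when fewer than 2 phenotypes have
#'   at least 2 subjects each.
#' @export
phenotype_anova <- function(values, phenotype) {
  stopifnot(length(values) == length(phenotype))
  keep <- !is.na(phenotype) & phenotype != ""
  values <- values[keep]
  phenotype <- as.character(phenotype[keep])
  counts <- table(phenotype)
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < 2L)
    return(list(computable = FALSE,
                reason = "fewer than 2 phenotypes with >= 2 subjects"))
  sel <- phenotype %in% usable
  ft <- stats::oneway.test(values[sel] ~ factor(phenotype[sel]),
                           var.equal = TRUE)
  list(computable = TRUE, F = unname(ft$statistic), p = ft$p.value,
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Dice coefficient between thresholded maps
#'
#' The per-level binary maps are concatenated (not summed) into one long
#' binary vector per side; Dice = `2|X & Y| / (|X| + |Y|)`.
#'
#' @param map_x,map_y [thresholded_map()]s on the same mask and depth.
#' @return Dice coefficient in \[0, 1\]; `NA` (not computable) when both
#'   maps are empty.
#' @export
dice_between <- function(map_x, map_y) {
  stopifnot(ncol(map_x$per_level) == ncol(map_y$per_level),
            map_x$depth == map_y$depth)
  x <- as.vector(t(map_x$per_level)) > 0
  y <- as.vector(t(map_y$per_level)) > 0
  denom <- sum(x) + sum(y)
  if (denom == 0) {
    warning("both maps empty: Dice not computable")
    return(NA_real_)
  }
  2 * sum(x & y) / denom
}

#' Pairwise Dice matrix
#'
#' @param maps Named list of [thresholded_map()]s.
#' @return Numeric matrix of pairwise Dice coefficients. For maps of the
#'   same feature the matrix is symmetric with unit diagonal; mixing size
#'   and shape maps it need not be.
#' @export
dice_matrix <- function(maps) {
  n <- length(maps)
  out <- matrix(NA_real_, n, n, dimnames = list(names(maps), names(maps)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- suppressWarnings(dice_between(maps[[i]], maps[[j]]))
  out
}

#' Export a circular-dendrogram summary
#'
#' Node list (level, parent, -log10 p, significance flag) for one contrast
#' and feature, ready for dendrogram rendering; only significant nodes are
#' marked for display.
#'
#' @param tree A `segment_tree`.
#' @param results A `contrast_results` data.frame covering the tree.
#' @param contrast,feature Which slice of the results to export.
#' @param path Optional JSON output path.
#' @return The export list (invisibly when written to `path`): `contrast`,
#'   `feature`, `depth`, `nodes` (each with `id`, `level`, `parent`,
#'   `n_voxels`, `neg_log10_p`, `significant`, `display`).
#' @export
dendrogram_export <- function(tree, results, contrast, feature, path = NULL) {
  sub <- results[results$contrast == contrast & results$feature == feature, ,
                 drop = FALSE]
  nodes <- lapply(unname(tree$nodes), function(nd) {
    i <- match(nd$id, sub$segment_id)
    sig <- !is.na(i) && sub$significant[i]
    list(id = nd$id, level = nd$level,
         parent = if (is.na(nd$parent)) NULL else nd$parent,
         n_voxels = length(nd$voxels),
         neg_log10_p = if (is.na(i)) NULL else sub$neg_log10_p[i],
         significant = sig,
         display = sig)  # sub-threshold results are not illustrated
  })
  out <- list(contrast = contrast, feature = feature, depth = tree$depth,
              nodes = nodes)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
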