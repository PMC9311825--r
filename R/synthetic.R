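# Synthetic Jacobian cohorts with planted covariance structure.
#
# The generator emulates what the segmentation assumes about real TBM data:
# voxels organized into spatially contiguous blocks with high within-block
# and low between-block correlation. A balanced binary hierarchy is planted
# by recursive spatial bisection of the mask; each internal node carries a
# latent factor loading +1 on its left and -1 on its right child
# (hierarchically nested covariance), and leaves may carry independent
# block factors. Group effects are planted either as mean Jacobian shifts
# (size) or as zero-mean spatial patterns (shape) that leave segmental size
# untouched, so size and shape effects are orthogonal by construction.

#' Synthetic cohort specification
#'
#' Defaults state a small but realistic desk-scale world: a 12^3 grid
#' (1728 voxels, full-grid mask), a planted depth-3 hierarchy (4 leaf
#' blocks), hierarchical factor sd twice the voxel noise sd (within-leaf
#' correlation about 0.9), 20 subjects per mutation x status cell (180
#' total), mild age/sex/site confounds.
#'
#' @param grid_shape Integer triple, image grid.
#' @param levels_planted Depth of the planted binary hierarchy (>= 1).
#' @param n_per_group Subjects per mutation x status cell.
#' @param hier_factor_sd Sd of the per-internal-node latent factors (the
#'   nested covariance signal driving recoverability).
#' @param leaf_factor_sd Sd of independent per-leaf-block factors (0 to
#'   disable; makes between-block correlation approximately zero).
#' @param noise_sd Sd of the iid voxel noise (> 0).
#' @param size_effects List of `list(node=, mutation=, status=, delta=)`:
#'   mean Jacobian shift `delta` on the node's voxels for that group.
#' @param shape_effects List of `list(node=, mutation=, status=, delta=)`:
#'   zero-mean spatial pattern of amplitude `delta` on the node's voxels
#'   (changes shape, leaves size unchanged).
#' @param age_slope Jacobian change per year of age (global confound).
#' @param sex_effect Additive offset for sex = 1.
#' @param site_sd Sd of per-site additive offsets.
#' @param n_sites Number of acquisition sites.
#' @param family_size Subjects per family.
#' @param seed Integer seed; identical seeds give bitwise-identical cohorts.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(12L, 12L, 12L), levels_planted = 3L,
                           n_per_group = 20L, hier_factor_sd = 0.1,
                           leaf_factor_sd = 0, noise_sd = 0.05,
                           size_effects = list(), shape_effects = list(),
                           age_slope = -0.002, sex_effect = 0.01,
                           site_sd = 0.01, n_sites = 3L, family_size = 2L,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            levels_planted >= 1L, n_per_group >= 2L, noise_sd > 0,
            hier_factor_sd >= 0, leaf_factor_sd >= 0, n_sites >= 1L,
            family_size >= 1L)
  if (prod(grid_shape) < 2^(levels_planted - 1))
    stop("grid too small for ", levels_planted, " planted levels")
  structure(list(grid_shape = as.integer(grid_shape),
                 levels_planted = as.integer(levels_planted),
                 n_per_group = as.integer(n_per_group),
                 hier_factor_sd = hier_factor_sd,
                 leaf_factor_sd = leaf_factor_sd, noise_sd = noise_sd,
                 size_effects = size_effects, shape_effects = shape_effects,
                 age_slope = age_slope, sex_effect = sex_effect,
                 site_sd = site_sd, n_sites = as.integer(n_sites),
                 family_size = as.integer(family_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Planted hierarchy by recursive spatial bisection
#'
#' Splits the masked voxels along the axis of greatest coordinate spread at
#' the median, recursively, producing a balanced binary `segment_tree` of
#' spatially contiguous blocks. Deterministic.
#'
#' @param mask A [voxel_mask()].
#' @param levels Planted depth.
#' @return A `segment_tree`.
#' @export
planted_tree <- function(mask, levels) {
  coords <- arrayInd(mask$indices, mask$grid_shape)
  bisect <- function(vox) {
    spread <- apply(coords[vox, , drop = FALSE], 2L, function(x) diff(range(x)))
    axis <- which.max(spread)
    ord <- vox[order(coords[vox, axis], vox)]
    half <- floor(length(ord) / 2)
    list(left = sort(ord[seq_len(half)]),
         right = sort(ord[(half + 1):length(ord)]))
  }
  nodes <- list(`1` = list(id = 1L, level = 1L, parent = NA_integer_,
                           children = integer(0),
                           voxels = seq_len(mask$n_voxels)))
  for (level in seq_len(levels - 1L)) {
    ids <- vapply(nodes, function(nd) nd$id, integer(1))
    ids <- ids[vapply(nodes, function(nd) nd$level == level, logical(1))]
    for (id in sort(ids)) {
      nd <- nodes[[as.character(id)]]
      if (length(nd$voxels) < 2L)
        stop("planted block hierarchy not binary-nested: node ", id,
             " has fewer than 2 voxels")
      halves <- bisect(nd$voxels)
      lid <- 2L * id; rid <- 2L * id + 1L
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
                 n_voxels = mask$n_voxels),
            class = "segment_tree", incomplete_nodes = integer(0))
}

.shape_pattern <- function(n) {
  # deterministic zero-mean, unit-sd pattern over n voxels
  p <- rep(c(1, -1), length.out = n)
  if (n %% 2L == 1L) p[n] <- 0
  p <- p - mean(p)
  p / stats::sd(p)
}

.make_cohort_table <- function(spec) {
  mutations <- c("C9orf72", "GRN", "MAPT")
  statuses <- c("non-carrier", "asymptomatic", "symptomatic")
  phenos <- list(
    C9orf72 = c("bvFTD", "bvFTD", "bvFTD", "FTD-ALS", "ALS", "PPA"),
    GRN = c("bvFTD", "bvFTD", "PPA", "PPA", "CBS"),
    MAPT = c("bvFTD"))
  rows <- list()
  for (m in mutations) {
    n_m <- spec$n_per_group * length(statuses)
    fam <- paste0("fam-", m, "-",
                  ceiling(sample.int(n_m) / spec$family_size))
    st_code <- c(`non-carrier` = "NC", asymptomatic = "AS", symptomatic = "SY")
    i <- 0L
    for (st in statuses) {
      for (r in seq_len(spec$n_per_group)) {
        i <- i + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s-%s-%03d", m, st_code[[st]], r),
          mutation = m, status = st,
          phenotype = if (st == "symptomatic")
            sample(phenos[[m]], 1L) else "",
          age = round(stats::runif(1, 20, 80), 1),
          sex = stats::rbinom(1, 1, 0.5),
          site = paste0("site-", sample.int(spec$n_sites, 1L)),
          family = fam[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

.group_rows <- function(tab, mutation = NULL, status = NULL) {
  sel <- rep(TRUE, nrow(tab))
  if (!is.null(mutation)) sel <- sel & tab$mutation == mutation
  if (!is.null(status)) sel <- sel & tab$status == status
  which(sel)
}

#' Generate a synthetic Jacobian cohort
#'
#' Voxel value = 1 + hierarchical/leaf latent factors + group size shifts +
#' group shape patterns + covariate terms + iid Gaussian noise. The same
#' seed always reproduces the same cohort bitwise.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` ([jacobian_cohort()]), `table` (cohort
#'   data.frame) and `tree` (planted ground-truth `segment_tree`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mask_grid <- array(1L, dim = spec$grid_shape)
  mask <- voxel_mask(mask_grid, affine = diag(c(1.5, 1.5, 1.5, 1)))
  tree <- planted_tree(mask, spec$levels_planted)
  withr::with_seed(spec$seed, {
    tab <- .make_cohort_table(spec)
    n_sub <- nrow(tab)
    n_vox <- mask$n_voxels
    X <- matrix(stats::rnorm(n_sub * n_vox, sd = spec$noise_sd),
                nrow = n_sub) + 1
    # nested hierarchical factors: +1 on left child, -1 on right child
    if (spec$hier_factor_sd > 0) {
      for (nd in tree$nodes) {
        if (length(nd$children) == 0L) next
        f <- stats::rnorm(n_sub, sd = spec$hier_factor_sd)
        left <- tree$nodes[[as.character(nd$children[1])]]$voxels
        right <- tree$nodes[[as.character(nd$children[2])]]$voxels
        X[, left] <- X[, left] + f
        X[, right] <- X[, right] - f
      }
    }
    # independent per-leaf-block factors
    if (spec$leaf_factor_sd > 0) {
      for (nd in tree$nodes) {
        if (length(nd$children) != 0L) next
        f <- stats::rnorm(n_sub, sd = spec$leaf_factor_sd)
        X[, nd$voxels] <- X[, nd$voxels] + f
      }
    }
    # covariate confounds (global, affect every voxel)
    site_levels <- sort(unique(tab$site))
    site_offsets <- stats::rnorm(length(site_levels), sd = spec$site_sd)
    subj_off <- spec$age_slope * (tab$age - 50) +
      spec$sex_effect * tab$sex +
      site_offsets[match(tab$site, site_levels)]
    X <- X + subj_off
    # planted group effects
    for (eff in spec$size_effects) {
      vox <- tree$nodes[[as.character(eff$node)]]$voxels
      rows <- .group_rows(tab, eff$mutation, eff$status)
      if (length(rows) == 0L) stop("size effect targets an empty group")
      X[rows, vox] <- X[rows, vox] + eff$delta
    }
    for (eff in spec$shape_effects) {
      vox <- tree$nodes[[as.character(eff$node)]]$voxels
      rows <- .group_rows(tab, eff$mutation, eff$status)
      if (length(rows) == 0L) stop("shape effect targets an empty group")
      p <- .shape_pattern(length(vox))
      X[rows, vox] <- X[rows, vox] +
        matrix(eff$delta * p, nrow = length(rows), ncol = length(vox),
               byrow = TRUE)
    }
    cohort <- jacobian_cohort(X, mask, tab$subject_id)
  })
  list(cohort = cohort, table = tab, tree = tree)
}

#' Add a group mean shift on a voxel block
#'
#' Adds `delta` to the named group's rows over `block`'s columns, leaving
#' everything else untouched; segmental size over the block moves by exactly
#' `delta` for that group.
#'
#' @param cohort A [jacobian_cohort()].
#' @param table The cohort table.
#' @param block Voxel column indices.
#' @param group Either a character vector of subject ids or a list with
#'   `mutation` and/or `status`.
#' @param delta Mean Jacobian shift.
#' @return A new [jacobian_cohort()].
#' @export
plant_group_size_effect <- function(cohort, table, block, group, delta) {
  stopifnot(all(block >= 1L), all(block <= ncol(cohort$data)))
  rows <- if (is.character(group)) {
    m <- match(group, cohort$subject_ids)
    if (anyNA(m)) stop("unknown subject id(s) in group: ",
                       paste(group[is.na(m)], collapse = ", "))
    m
  } else {
    r <- .group_rows(table, group$mutation, group$status)
    if (length(r) == 0L) stop("unknown or empty group")
    match(table$subject_id[r], cohort$subject_ids)
  }
  X <- cohort$data
  X[rows, block] <- X[rows, block] + delta
  suppressWarnings(jacobian_cohort(X, cohort$mask, cohort$subject_ids))
}

#' Read a synthetic spec from a JSON config
#'
#' @param path JSON file whose fields mirror the [synthetic_spec()]
#'   arguments (missing fields take the defaults).
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown synthetic spec field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$size_effects))
    cfg$size_effects <- lapply(seq_len(nrow(cfg$size_effects)), function(i)
      as.list(cfg$size_effects[i, ]))
  if (!is.null(cfg$shape_effects))
    cfg$shape_effects <- lapply(seq_len(nrow(cfg$shape_effects)), function(i)
      as.list(cfg$shape_effects[i, ]))
  do.call(synthetic_spec, cfg)
}
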