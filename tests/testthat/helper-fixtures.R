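# Shared fixture builders; everything is generated in code at test time.

# cohort wrapping an explicit matrix; mask is a flat grid matching ncol
matrix_cohort <- function(data, ids = NULL) {
  data <- as.matrix(data)
  mask <- voxel_mask(array(1L, dim = c(ncol(data), 1L, 1L)))
  suppressWarnings(jacobian_cohort(data, mask, ids))
}

# two independent strongly-correlated voxel blocks + weak noise
two_block_cohort <- function(n_subjects = 60, block = 50, seed = 1,
                             factor_sd = 1, noise_sd = 0.1) {
  withr::with_seed(seed, {
    f1 <- rnorm(n_subjects, sd = factor_sd)
    f2 <- rnorm(n_subjects, sd = factor_sd)
    X <- cbind(matrix(f1, n_subjects, block),
               matrix(f2, n_subjects, block)) +
      matrix(rnorm(n_subjects * 2 * block, sd = noise_sd), n_subjects) + 1
  })
  list(cohort = matrix_cohort(X),
       truth = rep(1:2, each = block))
}

# minimal valid cohort table for n subjects (single site/sex variation)
simple_table <- function(ids, mutation = "C9orf72",
                         status = "non-carrier") {
  n <- length(ids)
  data.frame(subject_id = ids,
             mutation = rep_len(mutation, n),
             status = rep_len(status, n),
             phenotype = "",
             age = seq(30, 70, length.out = n),
             sex = rep_len(c(0, 1, 1, 0, 0, 1, 0, 1, 1), n),
             site = rep_len(c("site-1", "site-2", "site-1", "site-1",
                             "site-2", "site-2", "site-2"), n),
             family = paste0("fam-", ceiling(seq_len(n) / 2)),
             stringsAsFactors = FALSE)
}

# minimal hand-built tree over 8 voxels for map algebra
toy_tree <- function() {
  nodes <- list(
    `1` = list(id = 1L, level = 1L, parent = NA_integer_, children = c(2L, 3L),
               voxels = 1:8),
    `2` = list(id = 2L, level = 2L, parent = 1L, children = integer(0),
               voxels = 1:4),
    `3` = list(id = 3L, level = 2L, parent = 1L, children = integer(0),
               voxels = 5:8))
  structure(list(nodes = nodes, depth = 2L, n_voxels = 8L),
            class = "segment_tree", incomplete_nodes = integer(0))
}

toy_results <- function(sig_ids, feature = "size",
                        contrast = "C9orf72:symptomatic-vs-non-carrier") {
  data.frame(segment_id = c(1L, 2L, 3L), level = c(1L, 2L, 2L),
             contrast = contrast, feature = feature,
             statistic = 1, p = ifelse(c(1, 2, 3) %in% sig_ids, 1e-4, 0.9),
             neg_log10_p = ifelse(c(1, 2, 3) %in% sig_ids, 4, 0.046),
             significant = c(1, 2, 3) %in% sig_ids)
}

expect_partition <- function(parts, whole) {
  all_vox <- sort(unname(unlist(parts)))
  expect_equal(all_vox, sort(whole))
  expect_equal(length(unlist(parts)), length(unique(unlist(parts))))
}
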