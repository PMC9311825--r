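test_that("pairwise affinity maps correlation to [0,1] with hand-checked values", {
  cohort <- matrix_cohort(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1),
                                c(1, 2, 4)))
  expect_equal(pairwise_affinity(cohort, 1, 2), 1)
  expect_equal(pairwise_affinity(cohort, 1, 3), 0)
  expect_equal(pairwise_affinity(cohort, 2, 2), 1)
  # hand Pearson: cov = 3/2, sds 1 and sqrt(7/3)
  expect_equal(pairwise_affinity(cohort, 1, 4),
               0.5 * ((3 / 2) / sqrt(7 / 3) + 1))
  expect_equal(pairwise_affinity(cohort, 1, 4), pairwise_affinity(cohort, 4, 1))
  flat <- matrix_cohort(cbind(c(1, 2, 3), c(2, 2, 2)))
  expect_error(pairwise_affinity(flat, 1, 2), "zero-variance")
})

test_that("affinity matrices have unit diagonal and entries in [0,1]", {
  for (seed in 1:5) {
    withr::with_seed(seed, X <- matrix(rnorm(20 * 30), 20))
    A <- affinity_matrix(matrix_cohort(X))
    expect_true(all(diag(A) == 1))
    expect_true(all(A >= 0 & A <= 1 + 1e-12))
    expect_equal(A, t(A))
  }
})

test_that("normalized Laplacian matches closed forms and spectral bounds", {
  lap <- normalized_laplacian(diag(2))
  expect_equal(lap$L, diag(2))
  expect_equal(lap$d, c(1, 1))
  ones <- matrix(1, 2, 2)
  lap <- normalized_laplacian(ones)
  expect_equal(lap$L, matrix(0.5, 2, 2))
  e <- eigen(lap$L, symmetric = TRUE)
  expect_equal(e$values[1], 1)
  expect_equal(abs(e$vectors[, 1]), rep(1 / sqrt(2), 2))
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- matrix(runif(15 * 15), 15); A <- (A + t(A)) / 2; diag(A) <- 1
    })
    vals <- eigen(normalized_laplacian(A)$L, symmetric = TRUE,
                  only.values = TRUE)$values
    expect_true(all(vals >= -1 - 1e-10 & vals <= 1 + 1e-10))
  }
  expect_error(normalized_laplacian(matrix(0, 2, 2)), "zero column sum")
})

test_that("Nystrom with all landmarks reproduces the dense eigendecomposition", {
  fx <- two_block_cohort(n_subjects = 40, block = 30, seed = 2)
  dense <- dense_embedding(fx$cohort, k = 2)
  nys <- nystrom_embedding(fx$cohort, n_landmarks = 60, k = 2, seed = 1)
  aligned <- hierseg:::.align_embedding(nys$coordinates, dense$coordinates)
  expect_lt(max(abs(aligned - dense$coordinates)), 1e-6)
  expect_equal(nys$eigenvalues, dense$eigenvalues, tolerance = 1e-8)
})

test_that("subsampled Nystrom second eigenvector separates planted blocks", {
  fx <- two_block_cohort(n_subjects = 60, block = 100, seed = 3)
  nys <- nystrom_embedding(fx$cohort, n_landmarks = 40, k = 2, seed = 5)
  side <- as.integer(nys$coordinates[, 2] > 0) + 1L
  expect_equal(adjusted_rand_index(side, fx$truth), 1)
  rerun <- nystrom_embedding(fx$cohort, n_landmarks = 40, k = 2, seed = 5)
  expect_identical(rerun$coordinates, nys$coordinates)
  other <- nystrom_embedding(fx$cohort, n_landmarks = 40, k = 2, seed = 6)
  expect_false(identical(other$landmarks, nys$landmarks))
})

test_that("averaging aligned Nystrom runs preserves the dense partition", {
  fx <- two_block_cohort(n_subjects = 50, block = 60, seed = 4)
  # identical landmark sets (all voxels): average equals any single run
  avg_full <- average_nystrom(fx$cohort, n_estimations = 5, n_landmarks = 120,
                              k = 2, seed = 1)
  single_full <- nystrom_embedding(fx$cohort, n_landmarks = 120, k = 2)
  aligned <- hierseg:::.align_embedding(avg_full$coordinates,
                                        single_full$coordinates)
  expect_lt(max(abs(aligned - single_full$coordinates)), 1e-10)
  # random subsets: averaged embedding clusters like the dense oracle
  avg <- average_nystrom(fx$cohort, n_estimations = 20, n_landmarks = 24,
                         k = 2, seed = 7)
  km_avg <- consensus_kmeans(avg$coordinates, seed = 1)
  dense <- dense_embedding(fx$cohort, k = 2)
  km_dense <- withr::with_seed(1,
    stats::kmeans(dense$coordinates, 2, nstart = 25)$cluster)
  expect_equal(adjusted_rand_index(km_avg, km_dense), 1)
})

test_that("consensus k-means is unanimous on separated data and deterministic", {
  withr::with_seed(8, coords <- rbind(matrix(rnorm(40, 0, 0.05), ncol = 2),
                                      matrix(rnorm(40, 3, 0.05), ncol = 2)))
  labels <- consensus_kmeans(coords, n_repeats = 50, seed = 3)
  expect_equal(adjusted_rand_index(labels, rep(1:2, each = 20)), 1)
  expect_identical(consensus_kmeans(coords, n_repeats = 50, seed = 3), labels)
  expect_setequal(unique(labels), 1:2)
  expect_error(consensus_kmeans(coords[1, , drop = FALSE]), "fewer points")
})

test_that("split_segment returns a nonempty bipartition for any seed", {
  fx <- two_block_cohort(n_subjects = 40, block = 25, seed = 9)
  cfg <- segment_config(n_estimations = 5, kmeans_repeats = 10,
                        min_landmarks = 10)
  for (seed in 1:6) {
    halves <- split_segment(fx$cohort, 1:50, cfg, seed = seed)
    expect_partition(halves, 1:50)
    expect_gt(length(halves$left), 0)
    expect_gt(length(halves$right), 0)
    expect_true(min(halves$left) < min(halves$right))
  }
  # anti-correlated groups split exactly
  withr::with_seed(10, {
    f <- rnorm(50)
    X <- cbind(matrix(f, 50, 8), matrix(-f, 50, 8)) +
      matrix(rnorm(50 * 16, sd = 0.05), 50) + 1
  })
  anti <- matrix_cohort(X)
  halves <- split_segment(anti, 1:16, cfg, seed = 1)
  expect_equal(halves$left, 1:8)
  expect_equal(halves$right, 9:16)
  pair <- split_segment(anti, c(3L, 12L), cfg, seed = 1)
  expect_equal(pair, list(left = 3L, right = 12L))
})

test_that("zero-variance voxels are adopted by their nearest active neighbour", {
  withr::with_seed(11, {
    f <- rnorm(40)
    X <- cbind(matrix(f, 40, 6), matrix(-f, 40, 6)) +
      matrix(rnorm(40 * 12, sd = 0.05), 40) + 1
  })
  X <- cbind(X[, 1:6], 1, X[, 7:12])  # constant voxel at column 7
  cohort <- matrix_cohort(X)
  halves <- split_segment(cohort, 1:13,
                          segment_config(n_estimations = 3,
                                         kmeans_repeats = 5,
                                         min_landmarks = 6), seed = 2)
  expect_partition(halves, 1:13)
  expect_true(7 %in% halves$left)  # nearest active voxel is 6, in the left
  expect_equal(halves$left, 1:7)
})

test_that("hierarchy recovers planted structure and obeys partition laws", {
  spec <- synthetic_spec(grid_shape = c(8, 8, 4), levels_planted = 3,
                         n_per_group = 15, seed = 13)
  sim <- generate_cohort(spec)
  cfg <- segment_config(n_estimations = 10, kmeans_repeats = 20,
                        min_landmarks = 32)
  tree <- build_hierarchy(sim$cohort, levels = 3, config = cfg, seed = 17)
  expect_equal(length(tree$nodes), 7L)
  for (lv in 1:3) {
    labels <- tree_level_labels(tree, lv)
    expect_true(all(labels > 0))
    ids <- unique(labels)
    expect_equal(length(ids), 2^(lv - 1))
    segs <- lapply(ids, function(i) which(labels == i))
    expect_partition(segs, seq_len(sim$cohort$mask$n_voxels))
  }
  expect_equal(adjusted_rand_index(tree_level_labels(tree, 3),
                                   tree_level_labels(sim$tree, 3)), 1)
  # determinism: pure function of (cohort, config, seed)
  tree2 <- build_hierarchy(sim$cohort, levels = 3, config = cfg, seed = 17)
  expect_identical(tree2$nodes, tree$nodes)
  # global rescaling of the cohort changes no correlation, hence no tree
  scaled <- suppressWarnings(jacobian_cohort(sim$cohort$data * 3.2,
                                             sim$cohort$mask,
                                             sim$cohort$subject_ids))
  tree3 <- build_hierarchy(scaled, levels = 3, config = cfg, seed = 17)
  expect_identical(tree3$nodes, tree$nodes)
  # degenerate depth
  tree1 <- build_hierarchy(sim$cohort, levels = 1, config = cfg, seed = 17)
  expect_equal(length(tree1$nodes), 1L)
  expect_equal(tree1$nodes[["1"]]$voxels, seq_len(sim$cohort$mask$n_voxels))
})

test_that("nodes below min_segment_voxels stop early and are recorded", {
  fx <- two_block_cohort(n_subjects = 30, block = 4, seed = 14)
  cfg <- segment_config(n_estimations = 3, kmeans_repeats = 5,
                        min_landmarks = 4, min_segment_voxels = 5)
  tree <- build_hierarchy(fx$cohort, levels = 3, config = cfg, seed = 1)
  expect_lt(length(tree$nodes), 7L)
  expect_gt(length(attr(tree, "incomplete_nodes")), 0)
  lab3 <- tree_level_labels(tree, 3)
  expect_true(any(lab3 == 0))  # early-stopped branches excluded from level 3
})

test_that("segment trees survive a JSON round trip tied to their mask", {
  spec <- synthetic_spec(grid_shape = c(6, 6, 4), n_per_group = 4, seed = 15)
  sim <- generate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_segment_tree(sim$tree, path, mask = sim$cohort$mask)
  back <- read_segment_tree(path, mask = sim$cohort$mask)
  expect_identical(back$nodes, sim$tree$nodes)
  expect_identical(back$depth, sim$tree$depth)
  other_mask <- voxel_mask(array(1L, dim = c(4, 6, 6)))
  expect_error(read_segment_tree(path, mask = other_mask), "checksum")
})

test_that("adjusted Rand index behaves on known partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  withr::with_seed(16, {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:4, 200, replace = TRUE)
  })
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
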