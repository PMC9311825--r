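test_that("residualize matches hand OLS and is orthogonal to the design", {
  design <- cbind(1, c(1, 1, 2, 2))
  res <- residualize(c(1, 2, 3, 4), design)
  expect_equal(as.vector(res), c(-0.5, 0.5, -0.5, 0.5))
  expect_lt(max(abs(crossprod(design, res))), 1e-10)
  # values equal to a covariate column -> residuals vanish
  expect_lt(max(abs(residualize(c(1, 1, 2, 2), design))), 1e-12)
  # covariate orthogonal to values -> centering only
  y <- c(-1, 1, -1, 1)
  expect_equal(as.vector(residualize(y, design)), y - mean(y))
  withr::with_seed(1, {
    D <- cbind(1, matrix(rnorm(40), 20))
    Y <- matrix(rnorm(60), 20)
  })
  R <- residualize(Y, D)
  expect_lt(max(abs(crossprod(D, R))) / max(abs(Y)), 1e-8)
  expect_error(residualize(Y, cbind(D, D[, 2])), "rank-deficient")
})

test_that("design builder dummy-codes and flags aliasing", {
  tab <- simple_table(letters[1:8])
  design <- build_design(tab)
  expect_equal(design[, "(Intercept)"], rep(1, 8))
  expect_true(all(c("age", "sex") %in% colnames(design)))
  expect_equal(qr(design)$rank, ncol(design))
  # single-subject categorical levels are dropped with a warning
  tab2 <- tab; tab2$site[1] <- "site-solo"
  expect_warning(d2 <- build_design(tab2), "single subject.*site-solo")
  expect_false(any(grepl("solo", colnames(d2))))
  # aliased numeric covariates error with names
  tab3 <- tab; tab3$sex <- tab3$age
  expect_error(build_design(tab3), "aliased.*sex|collinear")
})

test_that("size test reproduces the closed-form pooled t and the lm oracle", {
  st <- size_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(st$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$p, 0.021312, tolerance = 1e-4)
  tt <- t.test(1:3, 4:6, var.equal = TRUE)
  expect_equal(st$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$p, tt$p.value, tolerance = 1e-12)
  # identical groups
  same <- size_test(rep(c(2, 3, 4), 2), rep(1:0, each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # covariate-adjusted path against stats::lm
  withr::with_seed(2, {
    n <- 40
    grp <- rep(1:0, each = n / 2)
    age <- runif(n, 20, 80)
    sex <- rbinom(n, 1, 0.5)
    y <- 1 - 0.3 * grp + 0.01 * age + rnorm(n, sd = 0.5)
  })
  design <- cbind(`(Intercept)` = 1, age = age, sex = sex)
  st <- size_test(y, grp, design)
  fit <- summary(lm(y ~ age + sex + grp))$coefficients["grp", ]
  expect_equal(st$t, unname(fit["t value"]), tolerance = 1e-10)
  expect_equal(st$p, unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(st$df, 36)
  # group aliased with a covariate
  expect_error(size_test(y, grp, cbind(design, dup = grp)), "aliased")
})

test_that("shape test equals the t test for one component and the regression F in general", {
  withr::with_seed(3, {
    n <- 30
    grp <- rep(1:0, each = 15)
    score <- rnorm(n) + 0.8 * grp
  })
  sh <- shape_test(matrix(score, ncol = 1), grp)
  st <- size_test(score, grp)
  expect_equal(sh$p, st$p, tolerance = 1e-10)
  expect_equal(sh$F, st$t^2, tolerance = 1e-10)
  # perfect association
  perfect <- shape_test(matrix(as.numeric(grp), ncol = 1), grp)
  expect_equal(perfect$canonical_r, 1)
  expect_equal(perfect$p, 0)
  # multivariate case against the regression-F oracle
  withr::with_seed(4, scores <- matrix(rnorm(30 * 3), 30))
  sh <- shape_test(scores, grp)
  fs <- summary(lm(grp ~ scores))$fstatistic
  expect_equal(sh$F, unname(fs[1]), tolerance = 1e-10)
  expect_equal(sh$p, unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
               tolerance = 1e-10)
  # covariate partialling against the added-variable oracle
  design <- cbind(1, withr::with_seed(5, rnorm(30)))
  sh_c <- shape_test(scores, grp, design)
  fit_full <- lm(grp ~ design[, 2] + scores)
  fit_null <- lm(grp ~ design[, 2])
  av <- anova(fit_null, fit_full)
  expect_equal(sh_c$p, av$`Pr(>F)`[2], tolerance = 1e-10)
  expect_error(shape_test(scores[, 0, drop = FALSE], grp), "at least one")
  expect_error(shape_test(scores[1:5, ], rep(0:1, length.out = 5)),
               "too few subjects")
  expect_error(shape_test(scores[1:8, ], rep(1, 8)), "aliased")
})

test_that("Benjamini-Yekutieli matches hand cutoffs and the p.adjust oracle", {
  one <- fdr_dep(0.01)
  expect_true(one$significant)
  expect_equal(one$threshold, 0.01)
  # hand worked example: c(4) = 25/12, cutoffs i * 0.006
  fx <- fdr_dep(c(0.001, 0.01, 0.02, 0.5), alpha = 0.05)
  expect_equal(fx$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fx$threshold, 0.01)
  none <- fdr_dep(rep(1, 10))
  expect_false(any(none$significant))
  expect_equal(none$threshold, 0)
  expect_error(fdr_dep(numeric(0)), "empty")
  expect_error(fdr_dep(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute-force agreement with base R's independent BY implementation
  withr::with_seed(6, {
    for (rep in 1:25) {
      m <- sample(c(1, 5, 50, 400), 1)
      p <- round(runif(m)^sample(1:3, 1), 4)
      mine <- fdr_dep(p, alpha = 0.05)$significant
      oracle <- p.adjust(p, method = "BY") <= 0.05
      expect_identical(mine, oracle)
    }
  })
})

test_that("run_all_contrasts pools the full family and matches the public tests", {
  spec <- synthetic_spec(grid_shape = c(6, 6, 4), n_per_group = 12, seed = 71,
                         size_effects = list(list(node = 4, mutation = "C9orf72",
                                                  status = "symptomatic",
                                                  delta = 0.15)))
  sim <- generate_cohort(spec)
  feats <- segment_features(sim$cohort, sim$tree, n_null = 30, seed = 3)
  res <- suppressMessages(suppressWarnings(
    run_all_contrasts(sim$tree, feats, sim$table, alpha = 0.05)))
  expect_s3_class(res, "contrast_results")
  n_nodes <- length(sim$tree$nodes)
  expect_equal(sum(res$feature == "size"), n_nodes * 6)
  expect_equal(nrow(res) + attr(res, "n_not_computable"), n_nodes * 6 * 2)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$significant, res$p <= attr(res, "fdr_threshold") &
                 attr(res, "fdr_threshold") > 0)
  # the inline fast path must agree with the public size_test/shape_test
  ct <- default_contrasts()[[2]]  # C9orf72 symptomatic
  sel <- hierseg:::.contrast_subjects(sim$table, ct)
  design <- suppressWarnings(build_design(sim$table[sel$rows, ]))
  f4 <- feats[["4"]]
  st <- size_test(f4$size[sel$rows], sel$group, design)
  row <- res[res$segment_id == 4 & res$contrast == ct$name &
               res$feature == "size", ]
  expect_equal(row$statistic, st$t, tolerance = 1e-12)
  expect_equal(row$p, st$p, tolerance = 1e-12)
  if (f4$k_retained >= 1) {
    sh <- shape_test(f4$shape$scores[sel$rows, , drop = FALSE],
                     sel$group, design)
    row <- res[res$segment_id == 4 & res$contrast == ct$name &
                 res$feature == "shape", ]
    expect_equal(row$statistic, sh$canonical_r, tolerance = 1e-12)
    expect_equal(row$p, sh$p, tolerance = 1e-12)
  }
  # the planted effect dominates the smallest size p-values in its contrast
  sub <- res[res$feature == "size" & res$contrast == ct$name, ]
  best <- sub$segment_id[which.min(sub$p)]
  expect_true(best %in% c(4, 2, 1, 8, 9))  # the planted node or its lineage
  # per-contrast families behind the flag
  res_split <- suppressMessages(suppressWarnings(
    run_all_contrasts(sim$tree, feats, sim$table, pool_family = FALSE)))
  expect_equal(length(attr(res_split, "fdr_threshold")), 6)
  # serialization
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_results(res, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(res))
  summ <- jsonlite::read_json(paste0(path, ".summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$family_size, nrow(res))
})
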