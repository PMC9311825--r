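# Segmental hypothesis testing.
#
# Six contrasts (3 mutations x {asymptomatic, symptomatic} vs non-carriers),
# each adjusted for age, sex, acquisition site and family membership as
# covariates of no interest. Size differences use an equal-variance
# Student's t (as the group coefficient of a single linear model, so the
# degrees of freedom are exact); shape differences use canonical correlation
# analysis between the retained principal component scores and the group
# indicator with the covariates partialled out of both sets. All resulting
# p-values form one family corrected by the Benjamini-Yekutieli ('dep')
# procedure, valid under arbitrary dependence. No intracranial-volume
# covariate is used: the Jacobians encode only the non-linear deformation.

#' Default contrast set
#'
#' The six carrier-versus-non-carrier contrasts; `group_b` is always the
#' pooled non-carriers.
#'
#' @return List of contrast descriptors (`mutation`, `status`, `name`).
#' @export
default_contrasts <- function() {
  out <- list()
  for (m in c("C9orf72", "GRN", "MAPT")) {
    for (st in c("asymptomatic", "symptomatic")) {
      out[[length(out) + 1L]] <- list(
        mutation = m, status = st,
        name = paste0(m, ":", st, "-vs-non-carrier"))
    }
  }
  out
}

.contrast_subjects <- function(table, contrast) {
  a <- which(table$mutation == contrast$mutation &
               table$status == contrast$status)
  b <- which(table$status == "non-carrier")
  if (length(a) == 0L || length(b) == 0L)
    stop("contrast ", contrast$name, " has an empty group")
  list(rows = c(a, b),
       group = c(rep(1L, length(a)), rep(0L, length(b))))
}

#' Covariate design matrix
#'
#' Intercept + age + sex + dummy-coded site and family. Categorical levels
#' represented by fewer than 2 subjects in the subset alias the intercept
#' given the family structure and are dropped with a warning (their
#' subjects fall into the reference class). Errors on residual rank
#' deficiency, naming the aliased columns.
#'
#' @param table Cohort table subset (the contrast's subjects).
#' @param covariates Columns to adjust for.
#' @return Numeric design matrix (n x p), full column rank.
#' @export
build_design <- function(table,
                         covariates = c("age", "sex", "site", "family")) {
  n <- nrow(table)
  design <- matrix(1, nrow = n, ncol = 1,
                   dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    x <- table[[cv]]
    if (is.null(x)) stop("covariate column '", cv, "' not in table")
    if (is.numeric(x)) {
      design <- cbind(design, x)
      colnames(design)[ncol(design)] <- cv
    } else {
      counts <- table(x)
      small <- names(counts)[counts < 2L]
      if (length(small))
        warning("dropping ", cv, " level(s) with a single subject: ",
                paste(small, collapse = ", "))
      levels_use <- names(counts)[counts >= 2L]
      # first usable level is the reference
      for (lv in levels_use[-1L]) {
        design <- cbind(design, as.numeric(x == lv))
        colnames(design)[ncol(design)] <- paste0(cv, lv)
      }
    }
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("collinear covariate design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  design
}

#' Residualize columns on a design
#'
#' Ordinary-least-squares residuals of every column of `values` on the
#' design matrix.
#'
#' @param values Numeric vector or n x m matrix.
#' @param design Numeric design matrix (full column rank; include the
#'   intercept if centering is wanted).
#' @return Residual matrix of the same shape as `values`.
#' @export
residualize <- function(values, design) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(design))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("rank-deficient design in residualize")
  qr.resid(qr_d, values)
}

#' Covariate-adjusted two-sample t test on segmental size
#'
#' Fits `size ~ intercept + group + covariates` by least squares and
#' returns the group coefficient's t statistic with
#' `df = n - rank(design)`. With no covariates this is exactly the
#' classical pooled-variance two-sample t test.
#'
#' @param size Numeric vector (the contrast subjects' segmental sizes).
#' @param group Binary indicator (1 = carriers, 0 = non-carriers).
#' @param design Covariate design from [build_design()] (or `NULL` for the
#'   intercept-only model).
#' @return List with `t`, `p` (two-sided), `df`, `estimate`.
#' @export
size_test <- function(size, group, design = NULL) {
  n <- length(size)
  if (is.null(design))
    design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(length(group) == n, nrow(design) == n)
  if (length(unique(group)) != 2L) stop("group indicator must take 2 values")
  Z <- cbind(design, group = as.numeric(group))
  qr_z <- qr(Z)
  if (qr_z$rank < ncol(Z)) {
    stop("collinear design: group indicator aliased with covariate(s) [",
         paste(colnames(Z)[qr_z$pivot[(qr_z$rank + 1):ncol(Z)]],
               collapse = ", "), "]")
  }
  coefs <- qr.coef(qr_z, size)
  res <- qr.resid(qr_z, size)
  df <- n - qr_z$rank
  if (df < 1L) stop("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_z))
  se <- sqrt(sigma2 * XtX_inv[ncol(Z), ncol(Z)])
  est <- unname(coefs["group"])
  if (se == 0) {
    warning("zero residual variance in size test")
    return(list(t = if (est == 0) 0 else sign(est) * Inf,
                p = if (est == 0) 1 else 0, df = df, estimate = est))
  }
  t_stat <- est / se
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df), df = df,
       estimate = est)
}

#' CCA test on segmental shape scores
#'
#' Partial canonical correlation between the retained principal component
#' scores and the binary group indicator: both sets are residualized on the
#' covariate design (intercept included), the first canonical correlation
#' is computed, and the p-value comes from Rao's F transformation of
#' Wilks' Lambda — exact here since one set is univariate. With a single
#' retained component and no covariates this reproduces the equal-variance
#' t test p-value on that component.
#'
#' @param scores n x k matrix of retained component scores (k >= 1).
#' @param group Binary indicator.
#' @param design Covariate design (or `NULL` for intercept only).
#' @param ridge Ridge added to the score covariance only if it is singular.
#' @return List with `canonical_r`, `p`, `F`, `df1`, `df2`, `k`.
#' @export
shape_test <- function(scores, group, design = NULL, ridge = 1e-8) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (k < 1L) stop("shape test needs at least one retained component")
  if (is.null(design))
    design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(length(group) == n, nrow(design) == n)
  c_rank <- qr(design)$rank
  if (n < c_rank + k + 2L)
    stop("too few subjects (", n, ") for ", k,
         " components plus ", c_rank, " covariate columns")
  Xr <- residualize(scores, design)
  yr <- residualize(as.numeric(group), design)
  if (sum(yr^2) < 1e-10 * n) stop("group indicator aliased with the covariates")
  Sxx <- crossprod(Xr)
  ok <- tryCatch({chol(Sxx); TRUE}, error = function(e) FALSE)
  if (!ok) {
    warning("singular within-set covariance in CCA; adding ridge")
    Sxx <- Sxx + diag(ridge * mean(diag(Sxx)), k)
  }
  Sxy <- crossprod(Xr, yr)
  r2 <- as.numeric(crossprod(Sxy, solve(Sxx, Sxy))) / sum(yr^2)
  r2 <- min(max(r2, 0), 1)
  df1 <- k
  df2 <- n - c_rank - k
  if (r2 >= 1) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (r2 / df1) / ((1 - r2) / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  list(canonical_r = sqrt(r2), p = p, F = f_stat, df1 = df1, df2 = df2, k = k)
}

#' Benjamini-Yekutieli FDR threshold ('dep')
#'
#' The FDR procedure valid under arbitrary dependence: sort the m p-values
#' ascending and reject up to the largest i with
#' `p(i) <= i * alpha / (m * c(m))`, `c(m) = sum(1/j)`. Returns the
#' data-dependent rejection threshold (0 when nothing is rejected) and the
#' per-test flags.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Target FDR level.
#' @return List with `threshold`, `significant` (logical, same order as the
#'   input), `alpha`, `m`.
#' @export
fdr_dep <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0L) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  cm <- sum(1 / seq_len(m))
  sorted <- sort(p_values)
  cutoffs <- seq_len(m) * alpha / (m * cm)
  passing <- which(sorted <= cutoffs)
  threshold <- if (length(passing)) sorted[max(passing)] else 0
  significant <- if (length(passing)) p_values <= threshold
    else rep(FALSE, m)
  list(threshold = threshold, significant = significant,
       alpha = alpha, m = m)
}

#' Run all contrasts over all tree segments
#'
#' Executes the size t test and the shape CCA test for every segment and
#' every contrast, pools every computable p-value into a single
#' Benjamini-Yekutieli family (a complete depth-8 tree with 6 contrasts
#' gives 12 x 255 = 3060 tests), and returns the tidy results table.
#'
#' @param tree A `segment_tree`.
#' @param features A [segment_features()] result covering the tree.
#' @param table Cohort table aligned with the feature subject order.
#' @param alpha FDR level.
#' @param contrasts Contrast list (default [default_contrasts()]); contrasts
#'   whose carrier group is empty in `table` are skipped with a message.
#' @param covariates Covariate columns for [build_design()]; use
#'   `character(0)` for unadjusted tests.
#' @param pool_family `TRUE` (default) corrects one pooled family; `FALSE`
#'   corrects each contrast separately.
#' @return A data.frame of class `contrast_results` with columns
#'   `segment_id`, `level`, `contrast`, `feature`, `statistic`, `p`,
#'   `neg_log10_p`, `significant`; attributes `fdr_threshold`, `alpha`,
#'   `family_size`, `n_not_computable`.
#' @export
run_all_contrasts <- function(tree, features, table, alpha = 0.05,
                              contrasts = default_contrasts(),
                              covariates = c("age", "sex", "site", "family"),
                              pool_family = TRUE) {
  stopifnot(inherits(features, "segment_features"))
  table <- read_cohort_table(table, attr(features, "subject_ids"))
  rows <- list()
  n_skipped <- 0L
  for (ct in contrasts) {
    has_carriers <- any(table$mutation == ct$mutation &
                          table$status == ct$status)
    if (!has_carriers) {
      message("skipping contrast with no carriers: ", ct$name)
      next
    }
    sel <- .contrast_subjects(table, ct)
    sub_tab <- table[sel$rows, , drop = FALSE]
    n_ct <- nrow(sub_tab)
    design <- if (length(covariates)) build_design(sub_tab, covariates)
      else matrix(1, n_ct, 1, dimnames = list(NULL, "(Intercept)"))
    # factor the shared designs once per contrast; only y changes by segment
    Z <- cbind(design, group = as.numeric(sel$group))
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z))
      stop("collinear design in contrast ", ct$name)
    xtx_inv_last <- chol2inv(qr.R(qr_z))[ncol(Z), ncol(Z)]
    df_t <- n_ct - qr_z$rank
    qr_d <- qr(design)
    c_rank <- qr_d$rank
    yr <- qr.resid(qr_d, as.numeric(sel$group))
    yr_ss <- sum(yr^2)
    if (yr_ss < 1e-10 * n_ct) yr_ss <- 0
    for (f in features) {
      y <- f$size[sel$rows]
      est <- qr.coef(qr_z, y)[["group"]]
      sigma2 <- sum(qr.resid(qr_z, y)^2) / df_t
      se <- sqrt(sigma2 * xtx_inv_last)
      t_stat <- if (se == 0) {if (est == 0) 0 else sign(est) * Inf} else est / se
      p_t <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df_t)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = f$id, level = f$level, contrast = ct$name,
        feature = "size", statistic = t_stat, p = p_t,
        stringsAsFactors = FALSE)
      k <- f$k_retained
      if (k >= 1L && n_ct >= c_rank + k + 2L && yr_ss > 0) {
        Xr <- qr.resid(qr_d, f$shape$scores[sel$rows, , drop = FALSE])
        Sxx <- crossprod(Xr)
        Sxy <- crossprod(Xr, yr)
        r2 <- tryCatch(
          as.numeric(crossprod(Sxy, solve(Sxx, Sxy))) / yr_ss,
          error = function(e) {
            Sxx_r <- Sxx + diag(1e-8 * mean(diag(Sxx)), k)
            as.numeric(crossprod(Sxy, solve(Sxx_r, Sxy))) / yr_ss
          })
        r2 <- min(max(r2, 0), 1)
        df2 <- n_ct - c_rank - k
        p_f <- if (r2 >= 1) 0 else
          stats::pf((r2 / k) / ((1 - r2) / df2), k, df2, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          segment_id = f$id, level = f$level, contrast = ct$name,
          feature = "shape", statistic = sqrt(r2), p = p_f,
          stringsAsFactors = FALSE)
      } else {
        n_skipped <- n_skipped + 1L
      }
    }
  }
  res <- do.call(rbind, rows)
  if (pool_family) {
    fdr <- fdr_dep(res$p, alpha)
    res$significant <- fdr$significant
    threshold <- fdr$threshold
  } else {
    res$significant <- FALSE
    threshold <- numeric(0)
    for (ct_name in unique(res$contrast)) {
      idx <- res$contrast == ct_name
      fdr <- fdr_dep(res$p[idx], alpha)
      res$significant[idx] <- fdr$significant
      threshold[ct_name] <- fdr$threshold
    }
  }
  res$neg_log10_p <- -log10(pmax(res$p, .Machine$double.xmin))
  res <- res[, c("segment_id", "level", "contrast", "feature", "statistic",
                 "p", "neg_log10_p", "significant")]
  if (n_skipped > 0L)
    message(n_skipped, " shape test(s) not computable ",
            "(no retained components or too few subjects)")
  structure(res, class = c("contrast_results", "data.frame"),
            fdr_threshold = threshold, alpha = alpha,
            family_size = nrow(res), n_not_computable = n_skipped)
}

#' Write contrast results
#'
#' TSV of the per-test rows plus a JSON summary (alpha, threshold, family
#' size, not-computable count).
#'
#' @param results A `contrast_results` data.frame.
#' @param path Output TSV path; the summary goes to `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_contrast_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(alpha = attr(results, "alpha"),
                  fdr_threshold = attr(results, "fdr_threshold"),
                  family_size = attr(results, "family_size"),
                  n_not_computable = attr(results, "n_not_computable"))
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
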