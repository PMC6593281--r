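# Group-level statistical battery: two-sample tests (also recomputable from
# printed summary statistics), chi-square on counts, covariate-adjusted
# comparison via a linear model, Bonferroni correction, and partial
# correlation.

group_result <- function(metric, statistic, df, p, method, covariates = NULL) {
  data.frame(metric = metric, statistic = statistic, df = df,
             p_value = p, method = method,
             covariates = paste(covariates %||% character(0), collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Welch t-test from printed summary statistics
#'
#' Recomputes an unequal-variance two-sample t-test from per-group mean,
#' standard error of the mean and sample size (the `mean +/- SEM` format of
#' clinical tables): `t = (m_a - m_b) / sqrt(sem_a^2 + sem_b^2)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean_a,sem_a,n_a group A mean, SEM (> 0) and size (>= 2).
#' @param mean_b,sem_b,n_b group B likewise.
#' @param metric label carried into the result.
#' @return one-row `data.frame` with `statistic`, `df`, `p_value`.
#' @export
welch_t_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                                 metric = NA_character_) {
  stopifnot(sem_a > 0, sem_b > 0, n_a >= 2, n_b >= 2)
  va <- sem_a^2
  vb <- sem_b^2
  t_stat <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  group_result(metric, t_stat, df, p, "welch_t_summary")
}

#' Welch t-test on raw data
#'
#' Identical (to machine precision) to [welch_t_from_summary] applied to
#' the samples' own means and SEMs. Groups with zero within-group variance
#' are rejected.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param metric label carried into the result.
#' @return one-row `data.frame`.
#' @export
welch_t <- function(a, b, metric = NA_character_) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance; t statistic undefined")
  }
  welch_t_from_summary(mean(a), stats::sd(a) / sqrt(length(a)), length(a),
                       mean(b), stats::sd(b) / sqrt(length(b)), length(b),
                       metric = metric)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the tie-corrected normal approximation; the exact
#' null distribution is used when both groups have at most `exact_max`
#' observations and no ties are present.
#'
#' @param a,b numeric vectors (non-empty).
#' @param metric label carried into the result.
#' @param exact_max largest group size for which the exact method is used.
#' @return one-row `data.frame`; `statistic` is U for group `a`.
#' @export
mann_whitney <- function(a, b, metric = NA_character_, exact_max = 8L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = !use_exact))
  group_result(metric, unname(wt$statistic), NA_real_, wt$p.value,
               if (use_exact) "mann_whitney_exact" else "mann_whitney_normal")
}

#' Pearson chi-square test on a 2 x 2 count table
#'
#' Without continuity correction by default (switchable), df = 1.
#'
#' @param counts 2 x 2 matrix of non-negative counts with positive margins.
#' @param correct apply Yates continuity correction.
#' @param metric label carried into the result.
#' @return one-row `data.frame`.
#' @export
chi_square_counts <- function(counts, correct = FALSE,
                              metric = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: a table margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  group_result(metric, unname(ct$statistic), unname(ct$parameter),
               ct$p.value, "chi_square")
}

#' Covariate-adjusted group comparison
#'
#' Fits `y ~ group + covariates` by least squares and reports the t-test on
#' the group coefficient — the linear-model realization of "two-sample
#' t-test with covariates". With no covariates this reduces to the pooled
#' two-sample t-test.
#'
#' @param y numeric outcome.
#' @param group two-level factor or character vector.
#' @param covariates data.frame (or matrix) of covariates, or `NULL`.
#' @param metric label carried into the result.
#' @return one-row `data.frame`; `statistic` is the t for the group term
#'   (direction: second factor level minus first).
#' @export
adjusted_group_compare <- function(y, group, covariates = NULL,
                                   metric = NA_character_) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("each group needs at least 2 members")
  dat <- data.frame(y = y, group = group)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    cov_names <- names(covariates)
  } else {
    cov_names <- character(0)
  }
  fit <- stats::lm(stats::as.formula(
    paste("y ~ group", if (length(cov_names))
      paste("+", paste(cov_names, collapse = " + ")) else "")), data = dat)
  if (any(is.na(coef(fit)))) stop("rank-deficient adjustment design")
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  group_result(metric, sm[row, "t value"], fit$df.residual,
               sm[row, "Pr(>|t|)"], "lm_group_coefficient", cov_names)
}

#' Bonferroni correction
#'
#' Rejects H0 when `p <= alpha / m`; adjusted p is `min(1, m * p)`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return `data.frame` with `p_value`, `p_adjusted`, `reject`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  data.frame(p_value = pvals,
             p_adjusted = stats::p.adjust(pvals, method = "bonferroni"),
             reject = pvals <= alpha / m)
}

#' Partial correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares removal of the covariates (plus intercept); the p-value
#' uses the t transform with `n - k - 2` degrees of freedom, `k` the number
#' of covariate columns. With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates or `NULL`.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  if (k > 0) {
    z <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    qz <- qr(z)
    if (qz$rank < ncol(z)) stop("rank-deficient covariate matrix")
    x <- x - z %*% qr.coef(qz, x)
    y <- y - z %*% qr.coef(qz, y)
  }
  r <- stats::cor(as.numeric(x), as.numeric(y))
  df <- n - k - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(t_stat), df)
  list(r = r, p = p, df = df)
}
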