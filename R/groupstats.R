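# Group-level inference and clinical statistics: ANCOVA with an age
# covariate, FDR correction, partial correlation, two-sample power, and
# demographic-table tests.

#' Group effect on a network metric, adjusting for age
#'
#' One-way analysis of covariance implemented as the ordinary least
#' squares model `value ~ group + covariate` with the group coded 0/1;
#' the reported statistic is the group coefficient's t (equivalent to the
#' classical single-covariate ANCOVA F via F = t^2), with df = n - 3 and a
#' two-sided p.
#'
#' @param values Numeric metric value per subject (e.g. an AUC).
#' @param group Two-level group labels.
#' @param covariate Numeric nuisance covariate per subject (age).
#' @return List: `estimate` (adjusted group1-minus-group2 difference),
#'   `t`, `df`, `p`, `groups`.
#' @export
ancova_group_effect <- function(values, group, covariate) {
  g <- as.character(group)
  lev <- sort(unique(g))
  if (setequal(lev, c("control", "patient")))
    lev <- c("patient", "control")  # patient-minus-control contrast
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(g)) < 3) stop("need at least 3 subjects per group",
                              call. = FALSE)
  if (sd(values) == 0) stop("metric values are constant", call. = FALSE)
  x <- as.numeric(g == lev[1])
  fit <- lm(values ~ x + covariate)
  s <- summary(fit)$coefficients
  list(estimate = unname(coef(fit)["x"]), t = unname(s["x", "t value"]),
       df = fit$df.residual, p = unname(s["x", "Pr(>|t|)"]),
       groups = lev)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement, plus the
#' rejection set at level `q`.
#'
#' @param pvals Raw p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List: `p_adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0)
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  adj <- p.adjust(pvals, method = "BH")
  # step-up rule rejects at adjusted p <= q (boundary cases inclusive)
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Pearson partial correlation controlling for one covariate
#'
#' Residualizes both variables on (intercept, covariate) and correlates
#' the residuals; p from `t = r * sqrt((n - 3) / (1 - r^2))` with
#' df = n - 3, two-sided.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric covariate of the same length.
#' @return List: `r`, `t`, `df`, `p`, `n`.
#' @export
partial_corr <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations", call. = FALSE)
  rx <- stats::resid(lm(x ~ covariate))
  ry <- stats::resid(lm(y ~ covariate))
  # residuals numerically zero (x or y collinear with the covariate)
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-12) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-12))
    stop("zero residual variance after removing the covariate",
         call. = FALSE)
  r <- cor(rx, ry)
  df <- n - 3
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * pt(-abs(t), df), n = n)
}

#' Power of the two-sample pooled t-test
#'
#' Exact noncentral-t power for detecting a mean difference `delta` with
#' common standard deviation `sd` between groups of sizes `n1` and `n2`:
#' noncentrality `ncp = (delta/sd) * sqrt(n1 n2 / (n1 + n2))`,
#' df = n1 + n2 - 2.
#'
#' @param delta Absolute mean difference to detect.
#' @param sd Common standard deviation (> 0).
#' @param n1,n2 Group sizes.
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default `TRUE`).
#' @return Power in \[0, 1\].
#' @examples
#' power_two_sample_t(0.32, 0.37, 21, 25)   # ~0.8
#' @export
power_two_sample_t <- function(delta, sd, n1, n2, alpha = 0.05,
                               two_sided = TRUE) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2",
                             call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- (delta / sd) * sqrt(n1 * n2 / (n1 + n2))
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    1 - pt(tc, df, ncp)
  }
}

#' Demographic table tests
#'
#' `summary_ttest` is the unpaired pooled-variance t-test computed from
#' group summaries (mean, SD, n), as used for continuous demographic
#' rows; `chisq_2x2` is the Pearson chi-square test without continuity
#' correction (df = 1), as used for the gender row.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @return List with the statistic, `df` and two-sided `p`.
#' @examples
#' summary_ttest(14.71, 3.40, 21, 16.16, 3.91, 25)  # p ~ 0.19
#' chisq_2x2(matrix(c(8, 13, 8, 17), 2, byrow = TRUE))  # p ~ 0.665
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2",
                             call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' @param counts 2 x 2 contingency table (groups x categories).
#' @rdname summary_ttest
#' @export
chisq_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in 2x2 table", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L, p = 1 - pchisq(chi2, 1))
}

#' Group comparison of metric AUCs across a cohort
#'
#' Runs the age-adjusted ANCOVA per metric column and applies BH-FDR over
#' the family of metrics supplied (the intended families are the global
#' metric AUCs, and separately the per-node efficiency AUCs).
#'
#' @param auc_matrix Subjects x metrics numeric matrix (or data.frame).
#' @param group,age Per-subject labels and ages (e.g. from a cohort
#'   manifest).
#' @return data.frame: metric, estimate, t, df, p, p_fdr.
#' @export
compare_metric_auc <- function(auc_matrix, group, age) {
  auc_matrix <- as.matrix(auc_matrix)
  res <- lapply(colnames(auc_matrix), function(mc) {
    a <- ancova_group_effect(auc_matrix[, mc], group, age)
    data.frame(metric = mc, estimate = a$estimate, t = a$t, df = a$df,
               p = a$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdr_bh(out$p)$p_adjusted
  rownames(out) <- NULL
  out
}
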