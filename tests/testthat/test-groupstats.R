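# ANCOVA, FDR, partial correlation, power, demographics tests.

test_that("ANCOVA group t matches a hand-solved normal-equations oracle", {
  vals <- c(3.1, 2.8, 3.5, 2.2, 2.0, 2.6)
  grp <- rep(c("patient", "control"), each = 3)
  age <- c(30, 40, 50, 32, 41, 52)
  a <- ancova_group_effect(vals, grp, age)
  # oracle: beta = (X'X)^{-1} X'y, t = beta / sqrt(s2 * (X'X)^{-1}_gg)
  X <- cbind(1, grp == "patient", age)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% vals
  res <- vals - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  t_ref <- beta[2] / sqrt(s2 * XtXi[2, 2])
  expect_equal(a$t, as.numeric(t_ref), tolerance = 1e-9)
  expect_equal(a$df, 3)
  expect_equal(a$p, 2 * pt(-abs(a$t), 3), tolerance = 1e-12)
})

test_that("ANCOVA with a constant covariate reduces to the unpaired t-test", {
  set.seed(4)
  vals <- rnorm(20)
  grp <- rep(c("patient", "control"), each = 10)
  a <- ancova_group_effect(vals, grp, rep(35, 20))
  tt <- t.test(vals[grp == "patient"], vals[grp == "control"],
               var.equal = TRUE)
  expect_equal(a$t, unname(tt$statistic), tolerance = 1e-9)
})

test_that("a purely age-driven signal shows no group effect on average", {
  ps <- vapply(1:20, function(r) {
    set.seed(400 + r)
    age <- c(rnorm(12, 38, 10), rnorm(12, 32, 10))
    grp <- rep(c("patient", "control"), each = 12)
    vals <- 2 * age + rnorm(24, 0, 0.5)
    ancova_group_effect(vals, grp, age)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)          # ~ uniform p under the null
})

test_that("constant metric values are flagged", {
  expect_error(ancova_group_effect(rep(1, 12),
                                   rep(c("patient", "control"), each = 6),
                                   rnorm(12)), "constant")
})

test_that("BH adjustment reproduces the step-up procedure by hand", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(out$p_adjusted, rep(0.05, 5))
  expect_true(all(out$rejected))                    # boundary rejects
  expect_equal(fdr_bh(rep(1, 4))$p_adjusted, rep(1, 4))
  expect_equal(fdr_bh(0.037)$p_adjusted, 0.037)     # m = 1
  expect_equal(fdr_bh(numeric(0))$p_adjusted, numeric(0))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))        # monotone
})

test_that("partial correlation matches the closed-form three-variable formula", {
  set.seed(12)
  z <- rnorm(10)
  x <- 0.5 * z + rnorm(10)
  y <- -0.3 * z + rnorm(10)
  pc <- partial_corr(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r_ref <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, r_ref, tolerance = 1e-9)
  expect_equal(pc$df, 7)
  t_ref <- r_ref * sqrt(7 / (1 - r_ref^2))
  expect_equal(pc$p, 2 * pt(-abs(t_ref), 7), tolerance = 1e-12)
})

test_that("partial correlation removes a shared confound and keeps identity", {
  set.seed(21)
  z <- rnorm(40)
  x <- z + rnorm(40, 0, 1e-3)
  expect_equal(partial_corr(x, x, rnorm(40))$r, 1, tolerance = 1e-12)
  rs <- vapply(1:20, function(r) {
    set.seed(600 + r)
    z <- rnorm(40)
    partial_corr(2 * z + rnorm(40, 0, 0.05),
                 -3 * z + rnorm(40, 0, 0.05), z)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  # constant covariate: plain Pearson correlation
  set.seed(22)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(partial_corr(x, y, rep(5, 15))$r, cor(x, y),
               tolerance = 1e-12)
  expect_error(partial_corr(z, 2 * z, z), "residual variance")
})

test_that("noncentral-t power behaves at the limits and against Monte-Carlo", {
  expect_equal(power_two_sample_t(0, 0.37, 21, 25), 0.05, tolerance = 1e-9)
  expect_gt(power_two_sample_t(100, 0.37, 21, 25), 0.999)
  # monotone in effect, n, alpha
  expect_gt(power_two_sample_t(0.4, 0.37, 21, 25),
            power_two_sample_t(0.3, 0.37, 21, 25))
  expect_gt(power_two_sample_t(0.32, 0.37, 40, 40),
            power_two_sample_t(0.32, 0.37, 21, 25))
  expect_gt(power_two_sample_t(0.32, 0.37, 21, 25, alpha = 0.10),
            power_two_sample_t(0.32, 0.37, 21, 25, alpha = 0.05))
  # Monte-Carlo oracle at the study design point
  set.seed(77)
  rej <- vapply(1:4000, function(r) {
    x <- rnorm(21, 0.32, 0.37); y <- rnorm(25, 0, 0.37)
    t.test(x, y, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_equal(power_two_sample_t(0.32, 0.37, 21, 25), mean(rej),
               tolerance = 0.02)
  expect_error(power_two_sample_t(0.3, 0, 21, 25), "sd")
  expect_error(power_two_sample_t(0.3, 0.37, 1, 25), "at least 2")
})

test_that("demographic tests reproduce the printed clinical-table values", {
  g <- chisq_2x2(matrix(c(8, 13, 8, 17), 2, byrow = TRUE))
  expect_equal(round(g$p, 3), 0.665)
  expect_equal(g$chi2, 0.1869, tolerance = 1e-3)
  bal <- chisq_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$chi2, 0)
  expect_equal(bal$p, 1)
  # agreement with the uncorrected Pearson chi-square in base R
  ref <- suppressWarnings(chisq.test(matrix(c(8, 13, 8, 17), 2,
                                            byrow = TRUE), correct = FALSE))
  expect_equal(g$chi2, unname(ref$statistic), tolerance = 1e-12)
  tt <- summary_ttest(14.71, 3.40, 21, 16.16, 3.91, 25)
  expect_equal(abs(tt$t), 1.33, tolerance = 0.01)
  expect_equal(tt$p, 0.19, tolerance = 0.005)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("metric AUC comparison applies the ANCOVA per metric with FDR over the family", {
  set.seed(9)
  n <- 24
  grp <- rep(c("patient", "control"), each = 12)
  age <- rnorm(n, 35, 10)
  auc <- cbind(sigma = rnorm(n) - 0.8 * (grp == "patient"),
               Cp = rnorm(n), Lp = rnorm(n))
  res <- compare_metric_auc(auc, grp, age)
  expect_equal(res$metric, c("sigma", "Cp", "Lp"))
  expect_equal(res$p_fdr, fdr_bh(res$p)$p_adjusted)
  one <- ancova_group_effect(auc[, "sigma"], grp, age)
  expect_equal(res$t[1], one$t)
})
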