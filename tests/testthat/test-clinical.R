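# Reference cohort 2x2 tables, reconstructed from the published per-class
# percentages (n = 53 MIA, 89 IAC): rows = covariate absent/present,
# columns = MIA/IAC.
ref_tab <- function(mia_yes, iac_yes, n = c(53, 89)) {
  rbind(c(n[1] - mia_yes, n[2] - iac_yes), c(mia_yes, iac_yes))
}

test_that("Pearson chi-squared reproduces the reference cohort statistics", {
  vcs <- ref_tab(9, 40)
  expect_equal(round(pearson_chi2(vcs)$statistic, 3), 11.493)
  expect_equal(round(pearson_chi2(ref_tab(7, 26))$statistic, 3), 4.771)  # vacuole
  expect_equal(round(pearson_chi2(ref_tab(11, 20))$statistic, 3), 0.057) # male
  expect_equal(round(pearson_chi2(ref_tab(27, 44))$statistic, 3), 0.030) # spiculation
  # continuity-corrected rows
  expect_equal(round(pearson_chi2(ref_tab(4, 9), "yates")$statistic, 3),
               0.045)  # drinking
  expect_equal(round(pearson_chi2(ref_tab(4, 4), "yates")$statistic, 3),
               0.150)  # family history
  expect_equal(round(pearson_chi2(ref_tab(0, 5), "yates")$statistic, 3),
               1.654)  # air bronchogram
})

test_that("chi-squared invariances and errors", {
  tb <- ref_tab(9, 40)
  expect_equal(pearson_chi2(tb)$statistic,
               pearson_chi2(tb[2:1, 2:1])$statistic)
  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)
  # closed form n(ad-bc)^2/(r1 r2 c1 c2)
  a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  n <- sum(tb)
  expect_equal(pearson_chi2(tb)$statistic,
               n * (a * d - b * c)^2 /
                 (sum(tb[1, ]) * sum(tb[2, ]) * sum(tb[, 1]) * sum(tb[, 2])))
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  set.seed(51)
  for (rep in 1:15) {
    tb <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    got <- fisher_exact(tb)$p
    # enumerate all tables with the observed margins
    r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    probs <- dhyper(lo:hi, c1, n - c1, r1)
    p_obs <- dhyper(tb[1, 1], c1, n - c1, r1)
    oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(got, oracle, tolerance = 1e-7)
  }
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p, 1)
  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4)))$p, 1) # zero margin
})

test_that("Wald odds ratios reproduce the reference cohort", {
  vcs <- odds_ratio_wald(ref_tab(9, 40))
  expect_equal(round(vcs$or, 3), 3.991)
  expect_equal(round(vcs$ci, 3), c(1.741, 9.151))
  vac <- odds_ratio_wald(ref_tab(7, 26))
  expect_equal(round(vac$or, 3), 2.712)
  expect_equal(round(vac$ci, 3), c(1.084, 6.785))
  expect_equal(odds_ratio_wald(matrix(5, 2, 2))$or, 1)
  # swapping one margin inverts the OR
  tb <- ref_tab(9, 40)
  expect_equal(odds_ratio_wald(tb[2:1, ])$or, 1 / vcs$or)
  expect_true(odds_ratio_wald(ref_tab(0, 5))$corrected)
})

test_that("Mann-Whitney U agrees with wilcox.test and exact enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  set.seed(52)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # exact small-sample p equals the full permutation distribution
  xs <- c(1.2, 3.4, 0.5, 2.2); ys <- c(2.9, 4.1, 3.3)
  gotx <- mann_whitney_u(xs, ys)
  refx <- wilcox.test(xs, ys, exact = TRUE)
  expect_equal(gotx$p, refx$p.value, tolerance = 1e-10)
  # U / (n1 n2) equals the AUC of the pooled scores (cross-module identity)
  u <- mann_whitney_u(y, x)$statistic
  auc <- roc_auc(c(x, y), rep(c(0, 1), c(20, 25)))$auc
  expect_equal(u / (20 * 25), auc)
})

test_that("group_compare dispatches via the Shapiro-Wilk gate", {
  set.seed(53)
  a <- rnorm(50); b <- rnorm(50, 0.2)
  res <- group_compare(c(a, b), rep(1:2, each = 50))
  expect_identical(res$method, "ttest")
  sk <- rexp(60)^3
  res2 <- group_compare(c(sk, sk * 2), rep(1:2, each = 60))
  expect_true(grepl("mwu", res2$method))
  expect_warning(group_compare(c(1, 2, 5, 6), c(1, 1, 2, 2)), "small")
  vals <- c(1.2, 3, 4.5, 6, 2)
  same <- group_compare(c(vals, vals), rep(1:2, each = 5))
  expect_gt(same$p, 0.9)
})

test_that("logistic regression on the VCS table equals the 2x2 odds ratio", {
  # expand the reference cohort VCS counts into case-level data
  df <- data.frame(
    label = rep(c("MIA", "IAC"), c(53, 89)),
    vcs = c(rep(c(0, 1), c(44, 9)), rep(c(0, 1), c(49, 40))))
  df$label <- factor(df$label, levels = c("MIA", "IAC"))
  lr <- logistic_regression(df, "vcs", type = "univariate")
  expect_equal(round(lr$or, 3), 3.991)
  expect_equal(round(lr$ci_low, 3), 1.741)
  expect_equal(round(lr$ci_high, 3), 9.151)
})

test_that("logistic regression CIs cover the null and flag collinearity", {
  set.seed(54)
  cover <- 0
  for (r in 1:100) {
    df <- data.frame(label = rbinom(80, 1, 0.5), x = rnorm(80))
    lr <- logistic_regression(df, "x", type = "univariate")
    cover <- cover + (lr$ci_low <= 1 && 1 <= lr$ci_high)
  }
  expect_gte(cover, 90)
  df2 <- data.frame(label = rbinom(50, 1, 0.5), a = rnorm(50))
  df2$b <- 2 * df2$a
  expect_error(logistic_regression(df2, c("a", "b"), type = "multivariable"),
               "collinear")
})

test_that("clinical_summary applies the method policy", {
  set.seed(55)
  spec <- cohort_spec(n_mia = 30, n_iac = 40)
  tab <- simulate_clinical_table(spec, seed = 2)
  out <- clinical_summary(tab,
                          binary_covariates = c("vcs", "air_bronchogram"),
                          continuous_covariates = c("age"))
  expect_identical(nrow(out), 3L)
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(out$method[out$covariate == "vcs"] %in%
                c("pearson", "yates", "fisher"))
})
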