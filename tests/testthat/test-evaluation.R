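test_that("AUC equals the pair-counting oracle and pROC", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1) # rounding forces ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc(s, y))
    p <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1))))
    expect_equal(r$auc, as.numeric(p))
  }
})

test_that("AUC limiting and invariance properties", {
  y <- rep(c(0, 1), each = 10)
  s <- c(rnorm(10, 0), rnorm(10, 10))
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_equal(roc_auc(s, y)$auc, roc_auc(qlogis(plogis(s)), y)$auc)
  # monotone transform invariance
  expect_equal(roc_auc(exp(s / 3), y)$auc, roc_auc(s, y)$auc)
  expect_error(roc_auc(s, rep(1, 20)), "both classes")
  set.seed(32)
  s0 <- rnorm(2000)
  y0 <- rbinom(2000, 1, 0.5)
  expect_true(abs(roc_auc(s0, y0)$auc - 0.5) < 0.05)
})

test_that("Youden cutoff equals the exhaustive scan", {
  set.seed(33)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60) + y
  r <- roc_auc(s, y)
  grid <- sort(unique(s))
  j <- vapply(grid, function(t)
    mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1, numeric(1))
  expect_equal(youden_cutoff(r), grid[which.max(j)])
  # separable two-point case: cutoff sits at the positive score
  r2 <- roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(youden_cutoff(r2), 1)
})

test_that("DeLong agrees with pROC and detects identical scores", {
  set.seed(34)
  y <- rbinom(100, 1, 0.55)
  y[1:2] <- 0:1
  a <- rnorm(100) + y
  b <- 0.5 * a + rnorm(100)
  dt <- delong_test(a, b, y)
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(dt$z, as.numeric(pr$statistic), tolerance = 1e-8)
  expect_equal(dt$p, pr$p.value, tolerance = 1e-8)
  expect_equal(delong_var(a, y),
               as.numeric(pROC::var(pROC::roc(y, a, quiet = TRUE),
                                    method = "delong")),
               tolerance = 1e-8)
  same <- delong_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  expect_equal(delong_test(b, a, y)$z, -dt$z)
})

test_that("DeLong test holds its type-I error under the null", {
  set.seed(35)
  reps <- 1000
  rej <- 0
  y <- rep(c(0, 1), c(53, 89))
  for (r in seq_len(reps)) {
    a <- rnorm(142)
    b <- rnorm(142)
    rej <- rej + (delong_test(a, b, y)$p < 0.05)
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("DeLong and bootstrap CIs agree at cohort scale", {
  set.seed(36)
  y <- rep(c(0, 1), c(53, 89))
  s <- rnorm(142) + 0.9 * y
  ci_d <- delong_auc_ci(s, y)
  ci_b <- bootstrap_auc_ci(s, y, reps = 2000, seed = 9)
  expect_lt(max(abs(ci_d - ci_b)), 0.03)
  # determinism and perfect separation
  expect_identical(bootstrap_auc_ci(s, y, reps = 200, seed = 4),
                   bootstrap_auc_ci(s, y, reps = 200, seed = 4))
  ysep <- rep(c(0, 1), each = 20)
  ssep <- c(rnorm(20), rnorm(20) + 50)
  expect_equal(bootstrap_auc_ci(ssep, ysep, reps = 200, seed = 1)[2], 1)
})

test_that("bootstrap CI covers the true AUC at near-nominal rate", {
  set.seed(37)
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  cover <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    y <- rep(c(0, 1), c(30, 40))
    s <- rnorm(70) + mu * y
    ci <- bootstrap_auc_ci(s, y, reps = 300, seed = r)
    cover <- cover + (true_auc >= ci[1] && true_auc <= ci[2])
  }
  expect_gte(cover / reps, 0.90)
  expect_lte(cover / reps, 0.99)
})

test_that("Hosmer-Lemeshow matches a hand-computed 3-bin example", {
  # 12 cases in 3 bins of 4; per-bin expected = sum of probabilities
  p <- c(0.1, 0.1, 0.2, 0.2, 0.4, 0.5, 0.5, 0.6, 0.8, 0.8, 0.9, 0.9)
  y <- c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1)
  hl <- hosmer_lemeshow(p, y, g = 3)
  E <- c(sum(p[1:4]), sum(p[5:8]), sum(p[9:12]))
  O <- c(sum(y[1:4]), sum(y[5:8]), sum(y[9:12]))
  stat <- sum((O - E)^2 / (E * (1 - E / 4)))
  expect_equal(hl$statistic, stat, tolerance = 1e-12)
  expect_identical(hl$df, 1)
  # perfectly predicted binary probabilities give statistic 0
  hl0 <- suppressWarnings(hosmer_lemeshow(c(rep(0.0001, 5), rep(0.9999, 5)),
                                          rep(0:1, each = 5), g = 3))
  expect_lt(hl0$statistic, 1e-4)
})

test_that("Hosmer-Lemeshow holds its type-I error when calibrated", {
  set.seed(38)
  reps <- 500
  rej <- 0
  for (r in seq_len(reps)) {
    x <- rnorm(1000)
    p <- plogis(-0.3 + 0.8 * x)
    y <- rbinom(1000, 1, p)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    rej <- rej + (hosmer_lemeshow(fitted(fit), y)$p < 0.05)
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.08)
})

test_that("decision curve reproduces its closed forms", {
  y <- rep(c(0, 1), c(53, 89))
  p <- plogis(rnorm(142) + y)
  dc <- decision_curve(p, y)
  prev <- 89 / 142
  # treat-all at small p_t approaches prevalence
  expect_equal(dc$treat_all[1], prev - (1 - prev) * 0.01 / 0.99)
  i5 <- which(abs(dc$p_t - 0.5) < 1e-9)
  expect_equal(dc$treat_all[i5], 89 / 142 - (53 / 142) * 1)
  expect_true(all(dc$treat_none == 0))
  expect_true(all(dc$net_benefit <= prev + 1e-12))
  # direct recomputation at one threshold
  pt <- 0.3
  tp <- sum(p >= pt & y == 1) / 142
  fp <- sum(p >= pt & y == 0) / 142
  i3 <- which(abs(dc$p_t - 0.3) < 1e-9)
  expect_equal(dc$net_benefit[i3], tp - fp * 0.3 / 0.7)
})

test_that("oracle-probability model dominates treat-all in net benefit", {
  set.seed(39)
  x <- rnorm(4000)
  p_true <- plogis(-0.5 + 1.5 * x)
  y <- rbinom(4000, 1, p_true)
  dc <- decision_curve(p_true, y, p_t = seq(0.05, 0.95, by = 0.05))
  expect_true(all(dc$net_benefit >= dc$treat_all - 0.02))
  expect_true(all(dc$net_benefit >= -0.02))
})

test_that("pairwise comparison table is consistent with delong_test", {
  set.seed(40)
  y <- rbinom(90, 1, 0.5)
  y[1:2] <- 0:1
  scores <- list(m1 = rnorm(90) + 1.5 * y, m2 = rnorm(90) + 0.7 * y,
                 m3 = rnorm(90))
  tab <- compare_models(scores, y)
  expect_identical(nrow(tab), 3L)
  for (i in seq_len(nrow(tab))) {
    dt <- delong_test(scores[[tab$model_a[i]]], scores[[tab$model_b[i]]], y)
    expect_equal(tab$z[i], dt$z)
    expect_equal(tab$p[i], dt$p)
  }
  expect_error(compare_models(list(a = 1:5), y), "named|mismatch")
})
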