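test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    k <- sample(2:4, 1)
    subj <- rnorm(n, sd = 2)
    rater <- rnorm(k, sd = 0.5)
    ratings <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
      matrix(rnorm(n * k), n, k)
    # oracle: explicit two-way ANOVA decomposition via aov
    df <- data.frame(y = as.vector(ratings),
                     s = factor(rep(seq_len(n), k)),
                     r = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ s + r, data = df))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(icc_2_1(ratings), oracle, tolerance = 1e-10)
  }
})

test_that("ICC limiting cases are correct", {
  x <- rnorm(20)
  expect_equal(icc_2_1(cbind(x, x)), 1)
  expect_equal(icc_2_1(matrix(5, 10, 2)), 1) # zero-variance convention
  # equal-variance independent noise halves the ICC at large n
  set.seed(22)
  s <- rnorm(2000)
  r2 <- s + rnorm(2000)
  r1 <- s + rnorm(2000)
  expect_lt(abs(icc_2_1(cbind(r1, r2)) - 0.5), 0.05)
  expect_error(icc_2_1(matrix(1, 2, 2)), "at least 3")
})

test_that("stability filter keeps reproducible features only", {
  set.seed(23)
  n <- 142
  X1 <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(sprintf("c%03d", 1:n), paste0("f", 1:5)))
  X2 <- X1 + matrix(rnorm(n * 5, sd = 0.05), n, 5)
  X2[, 3] <- rnorm(n) # a feature replaced by independent noise
  kept <- stability_filter(X1, X2, threshold = 0.75)
  expect_true(all(c("f1", "f2", "f4", "f5") %in% kept))
  expect_false("f3" %in% kept)
  expect_identical(stability_filter(X1, X1), colnames(X1),
                   ignore_attr = TRUE)
  # threshold 1 with noise keeps only bit-identical columns
  X3 <- X2
  X3[, 1] <- X1[, 1]
  expect_identical(as.character(stability_filter(X1, X3, threshold = 1)),
                   "f1")
  X4 <- X2
  rownames(X4) <- rev(rownames(X4))
  expect_error(stability_filter(X1, X4), "case ids")
})

test_that("mRMR greedy trace matches an exhaustive recomputation oracle", {
  set.seed(24)
  n <- 60
  p <- 8
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 2] <- X[, 2] + y
  X[, 5] <- X[, 5] + 0.5 * y
  sel <- mrmr_select(X, y, k = p)
  # oracle: recompute relevance/redundancy from scratch at every step
  Xs <- scale(X)
  rel <- vapply(seq_len(p), function(j) {
    f <- summary(stats::aov(Xs[, j] ~ factor(y)))[[1]]$`F value`[1]
    f / (f + n - 2) # same squared-correlation scale as the redundancy term
  }, numeric(1))
  names(rel) <- colnames(X)
  chosen <- character(0)
  remaining <- colnames(X)
  for (step in seq_len(p)) {
    score <- vapply(remaining, function(f) {
      red <- if (length(chosen) == 0) 0
      else mean(abs(stats::cor(Xs[, f], Xs[, chosen, drop = FALSE])))
      rel[f] - red
    }, numeric(1))
    pick <- remaining[order(-score, remaining)][1]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  expect_identical(sel, chosen)
  # first pick is the relevance argmax
  expect_identical(sel[1], names(which.max(rel)))
})

test_that("duplicated informative feature is penalized by redundancy", {
  set.seed(25)
  n <- 100
  y <- rep(0:1, each = n / 2)
  a <- rnorm(n) + 2 * y
  b <- rnorm(n) + 1.2 * y
  X <- cbind(dup = a, indep = b, orig = a)
  sel <- mrmr_select(X, y, k = 2)
  # whichever twin goes first, its duplicate is never picked second
  expect_true(sel[1] %in% c("dup", "orig"))
  expect_identical(sel[2], "indep")
  expect_warning(mrmr_select(X, y, k = 10), "returning all")
})

test_that("lasso solution satisfies the KKT conditions", {
  set.seed(26)
  n <- 120
  p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  cfg <- selection_config(lasso_folds = 5, seed = 3)
  m <- lasso_cv(X, y, cfg)
  # KKT on the standardized problem glmnet solves:
  # (1/n) t(Xs) (y - p) has |.| <= lambda, with equality at active coords
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = m$lambda, standardize = TRUE,
                        thresh = 1e-14)
  eta <- as.numeric(stats::predict(fit, X))
  mu <- 1 / (1 + exp(-eta))
  Xs <- scale(X, scale = apply(X, 2, function(c)
    sqrt(mean((c - mean(c))^2))))
  grad <- as.numeric(crossprod(Xs, y - mu)) / n
  beta <- as.numeric(fit$beta)
  active <- beta != 0
  expect_true(all(abs(grad[!active]) <= m$lambda + 1e-6))
  if (any(active))
    expect_true(all(abs(abs(grad[active]) - m$lambda) < 1e-6))
})

test_that("lasso recovers planted informative features", {
  set.seed(27)
  hits <- 0
  total <- 0
  for (s in 1:20) {
    n <- 142
    p <- 100
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    beta <- rep(0, p)
    planted <- paste0("f", 1:5)
    beta[1:5] <- 1
    y <- rbinom(n, 1, plogis(X %*% beta))
    m <- lasso_cv(X, y, selection_config(seed = s))
    hits <- hits + sum(planted %in% m$features)
    total <- total + 5
  }
  expect_gte(hits / total, 0.8)
})

test_that("large lambda gives the intercept-only model", {
  set.seed(28)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, 0.6)
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = 10)
  expect_true(all(as.numeric(fit$beta) == 0))
  expect_equal(as.numeric(fit$a0), qlogis(mean(y)), tolerance = 1e-4)
  expect_error(lasso_cv(X, rep(1, n), selection_config()), "two classes")
})

test_that("radscore is the signature's predicted probability", {
  m <- structure(list(features = c("a", "b"),
                      coefficients = c(a = 0, b = 0), intercept = 0),
                 class = "radscore_model")
  expect_equal(radscore(m, c(a = 3, b = -2)), 0.5)
  m$coefficients <- c(a = 1.2, b = -0.4)
  m$intercept <- 0.3
  x <- c(a = 0.5, b = 1)
  expect_equal(radscore(m, x),
               plogis(0.3 + 1.2 * 0.5 - 0.4 * 1), tolerance = 1e-12)
  expect_equal(radscore(m, x, type = "link"),
               0.3 + 1.2 * 0.5 - 0.4 * 1, tolerance = 1e-12)
  # monotone in a positively weighted feature
  s1 <- radscore(m, c(a = 0.1, b = 1))
  s2 <- radscore(m, c(a = 0.9, b = 1))
  expect_gt(s2, s1)
  expect_error(radscore(m, c(a = 1)), "missing")
})

test_that("radscore model serializes through JSON losslessly", {
  set.seed(29)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(60, 1, plogis(X[, 1]))
  m <- lasso_cv(X, y, selection_config(lasso_folds = 5, seed = 1),
                roi_kind = "GTV")
  f <- withr::local_tempfile(fileext = ".json")
  write_radscore_model(m, f)
  m2 <- read_radscore_model(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(radscore(m2, X), radscore(m, X), tolerance = 1e-12)
})

test_that("fold assignment depends on ids and seed, not row order", {
  ids <- sprintf("case%02d", 1:40)
  y <- rep(0:1, 20)
  f1 <- stratified_folds(ids, y, k = 5, seed = 7)
  perm <- sample(40)
  f2 <- stratified_folds(ids[perm], y[perm], k = 5, seed = 7)
  expect_identical(f1[perm], f2)
  expect_false(identical(f1, stratified_folds(ids, y, k = 5, seed = 8)))
  # stratification: each fold has balanced classes
  expect_true(all(abs(tapply(y, f1, mean) - 0.5) < 0.26))
})
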