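test_that("the subset-formula LMG equals direct averaging over orderings", {
  set.seed(11)
  for (p in 3:6) {
    n <- 60
    x <- matrix(rnorm(n * p), n, p) %*% (diag(p) + 0.4)
    colnames(x) <- paste0("v", seq_len(p))
    beta <- seq_len(p) / p
    y <- as.numeric(x %*% beta) + rnorm(n)
    fast <- lmg_importance(x, y)
    slow <- lmg_by_orderings(x, y)
    expect_equal(fast, slow, tolerance = 1e-10)
    full_r2 <- summary(stats::lm(y ~ x))$r.squared
    expect_equal(sum(fast), full_r2, tolerance = 1e-8)
    expect_true(all(fast >= -1e-12))
  }
})

test_that("LMG degenerates correctly for single and orthogonal predictors", {
  set.seed(12)
  n <- 80
  # single predictor: the share is the model R2
  x1 <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "only"))
  y <- 2 * x1[, 1] + rnorm(n)
  expect_equal(unname(lmg_importance(x1, y)),
               summary(stats::lm(y ~ x1))$r.squared)
  # predictors orthogonal to each other and the intercept: shares equal the
  # marginal R2s
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  colnames(q) <- c("a", "b", "c")
  y2 <- 3 * q[, 1] + 1 * q[, 2] + rnorm(n, sd = 0.5)
  shares <- lmg_importance(q, y2)
  marginal <- vapply(colnames(q), function(v)
    summary(stats::lm(y2 ~ q[, v]))$r.squared, numeric(1))
  expect_equal(shares, marginal, tolerance = 1e-10)
  # perfectly collinear predictors are refused
  bad <- cbind(a = q[, 1], b = q[, 1])
  expect_error(lmg_importance(bad, y2), "collinear")
})

test_that("AICc selection penalizes overfitting and finds nested truth", {
  set.seed(13)
  n <- 105
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  colnames(x) <- paste0("v", 1:5)
  contains <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    y <- 2 * x$v1 - 1.5 * x$v2 + rnorm(n, sd = 1)
    sel <- aicc_select(x, y)
    # with this signal strength the winning model must carry both true
    # predictors; models missing either lose by a wide AICc margin
    if (all(c("v1", "v2") %in% sel$best)) contains <- contains + 1
    missing_true <- !grepl("v1", sel$table$subset) | !grepl("v2", sel$table$subset)
    expect_gt(min(sel$table$aicc[missing_true]), min(sel$table$aicc) + 10)
  }
  expect_gte(contains / reps, 0.9)
  # AICc exceeds AIC for any fitted model (positive correction term)
  y <- 2 * x$v1 + rnorm(n)
  fit <- stats::lm(y ~ v1 + v2, data = x)
  k <- length(coef(fit)) + 1
  aic_gauss <- n * log(sum(residuals(fit)^2) / n) + 2 * k
  expect_gt(frugnet:::aicc_value(fit), aic_gauss)
  # identical candidate subsets give identical AICc
  sel2 <- aicc_select(x, y, subsets = list("v1", "v1"))
  expect_equal(sel2$table$aicc[1], sel2$table$aicc[2])
  # undersized candidates are skipped with a warning
  tiny_x <- x[1:6, 1:3]
  tiny_y <- y[1:6]
  expect_warning(
    sel3 <- aicc_select(tiny_x, tiny_y, subsets = list("v1", c("v1", "v2", "v3"))),
    "skipped")
  expect_equal(sel3$best, "v1")
})

test_that("regression parameter recovery stays within two standard errors", {
  run <- strong_run()
  pred <- frugnet:::contribution_predictors(run$visit_matrix,
                                            run$inputs$species,
                                            run$inputs$plants)
  x <- cbind(1, as.matrix(pred))
  beta <- c(4, 0.0008, 0.002, 0.005, 0.003, 0.2, 2)
  set.seed(14)
  covered <- c()
  for (i in 1:300) {
    y <- as.numeric(x %*% beta) + rnorm(nrow(x), sd = 1)
    fit <- stats::lm(y ~ ., data = as.data.frame(pred))
    sm <- summary(fit)$coefficients
    covered <- c(covered, abs(sm[, 1] - beta) <= 2 * sm[, 2])
  }
  # exact per-coefficient coverage of a 2-se interval is 1 - 2 pt(-2, df)
  # (about 95.2% here); assert the observed rate is at least 95% up to
  # 3 Monte-Carlo standard errors
  mc_se <- sqrt(0.95 * 0.05 / length(covered))
  expect_gte(mean(covered), 0.95 - 3 * mc_se)
})
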