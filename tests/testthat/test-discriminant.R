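test_that("VIF pruning follows the closed form and drops duplicates", {
  set.seed(1)
  # columns exactly orthogonal to each other and to the intercept:
  # all VIFs are 1, nothing dropped
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 4), 60, 4))))[, -1]
  colnames(q) <- paste0("v", 1:4)
  rep1 <- vif_prune(q, threshold = 3)
  expect_equal(rep1$retained, colnames(q))
  expect_true(all(abs(rep1$rounds[[1]] - 1) < 1e-10))
  # a duplicated column explodes the VIF and one copy is dropped first
  x <- cbind(q, v5 = q[, 1])
  rep2 <- vif_prune(x, threshold = 3)
  expect_equal(length(rep2$dropped), 1)
  expect_true(rep2$dropped %in% c("v1", "v5"))
  # pairwise correlation r gives VIF = 1 / (1 - r^2); r = 0.9 -> 5.26
  z1 <- as.numeric(scale(rnorm(200)))
  z2 <- as.numeric(scale(residuals(lm(rnorm(200) ~ z1))))
  r <- 0.9
  pair <- cbind(a = z1, b = r * z1 + sqrt(1 - r^2) * z2)
  rep3 <- vif_prune(pair, threshold = 3)
  expect_equal(unname(rep3$rounds[[1]]["a"]), 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(length(rep3$retained), 1)
  expect_error(vif_prune(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("greedy Wilks selection orders variables by discriminating power", {
  set.seed(2)
  g <- rep(c("A", "B", "C"), each = 20)
  strong <- ifelse(g == "A", 0, ifelse(g == "B", 5, 10)) + rnorm(60, sd = 0.3)
  weak <- ifelse(g == "A", 0, 0.5) + rnorm(60)
  noise <- rnorm(60)
  x <- cbind(strong = strong, weak = weak, noise = noise)
  sel <- greedy_wilks(x, g, entry_alpha = 0.05)
  expect_equal(sel$selected[1], "strong")
  expect_lt(sel$lambda["strong"], 0.05)
  # lambda is non-increasing along the entry sequence
  expect_true(all(diff(sel$lambda) <= 1e-12))
  # a zero entry threshold admits nothing
  expect_equal(length(greedy_wilks(x, g, entry_alpha = 0)$selected), 0)
  # the first greedy pick matches exhaustive search over single variables
  lams <- vapply(colnames(x), function(v)
    frugnet:::wilks_lambda(x[, v, drop = FALSE], g), numeric(1))
  expect_equal(sel$selected[1], names(lams)[which.min(lams)])
})

test_that("Wilks' lambda equals the eigenvalue product form", {
  set.seed(3)
  g <- rep(c("A", "B", "C"), each = 15)
  x <- matrix(rnorm(45 * 3), 45, 3) + outer(as.numeric(factor(g)), c(1, 0.5, 0))
  lam <- frugnet:::wilks_lambda(x, g)
  # Lambda = prod 1 / (1 + eigenvalue of W^-1 B)
  W <- matrix(0, 3, 3)
  for (lev in unique(g)) {
    xi <- scale(x[g == lev, ], center = TRUE, scale = FALSE)
    W <- W + crossprod(xi)
  }
  Tm <- crossprod(scale(x, center = TRUE, scale = FALSE))
  ev <- Re(eigen(solve(W) %*% (Tm - W))$values)
  expect_equal(lam, prod(1 / (1 + ev)), tolerance = 1e-8)
})

test_that("LDA classifies separable data perfectly and chance data at 1/k", {
  set.seed(4)
  g <- rep(c("A", "B"), each = 25)
  x <- data.frame(v = ifelse(g == "A", 0, 10) + rnorm(50))
  fit <- lda_fit_classify(x, g)
  expect_equal(fit$accuracy, 1)
  # permuted labels over three balanced classes: accuracy near 1/3
  accs <- replicate(30, {
    g3 <- sample(rep(c("A", "B", "C"), each = 20))
    lda_fit_classify(data.frame(v = rnorm(60)), g3)$accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.08)
  # duplicating every observation changes neither assignments nor accuracy
  x2 <- rbind(x, x)
  fit2 <- lda_fit_classify(x2, c(g, g))
  expect_equal(fit2$accuracy, fit$accuracy)
  expect_equal(as.character(fit2$predicted), rep(as.character(fit$predicted), 2))
  # accuracy is invariant to affine rescaling of a variable
  x3 <- x
  x3$v <- 100 * x3$v - 7
  expect_equal(lda_fit_classify(x3, g)$accuracy, fit$accuracy)
})

test_that("the full trait screen finds the planted discriminators", {
  run <- strong_run()
  disc <- run$discrimination
  expect_true(all(disc$vif$rounds[[length(disc$vif$rounds)]] < 3))
  expect_true(all(c("neigh_density", "neigh_fecundity", "cone_diameter") %in%
                    disc$wilks$selected))
  expect_gt(disc$lda$accuracy, 0.8)
  expect_true(all(dim(disc$lda$confusion) >= 2))
})
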