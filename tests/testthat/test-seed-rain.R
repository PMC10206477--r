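test_that("the multiplicative estimator reproduces the reference arithmetic", {
  v <- matrix(5, 1, 1, dimnames = list("C106", "Vulpes_vulpes"))
  sp <- data.frame(species_id = "Vulpes_vulpes", feeding_rate = 7.4,
                   undamaged_fraction = 0.97)
  pl <- data.frame(plant_id = "C106", seeds_per_cone = 5.22, seed_viability = 0.21)
  est <- estimate_dispersed_seeds(v, sp, pl)
  expect_equal(round(unname(est$seeds[1, 1]), 1), 39.3)
  expect_equal(est$plant_totals, c(C106 = 5 * 7.4 * 5.22 * 0.97 * 0.21))
  # zero viability annihilates everything
  pl0 <- transform(pl, seed_viability = 0)
  expect_equal(sum(estimate_dispersed_seeds(v, sp, pl0)$seeds), 0)
  # exact multilinearity: scaling any factor scales the estimate
  expect_equal(estimate_dispersed_seeds(v * 2, sp, pl)$seeds, est$seeds * 2)
  sp2 <- transform(sp, feeding_rate = feeding_rate * 3)
  expect_equal(estimate_dispersed_seeds(v, sp2, pl)$seeds, est$seeds * 3)
  # missing parameters are reported by name
  expect_error(estimate_dispersed_seeds(v, sp[0, ], pl), "Vulpes_vulpes")
  expect_error(estimate_dispersed_seeds(v, sp, pl[0, ]), "C106")
})

test_that("species shares normalize the pooled seed rain", {
  seeds <- rbind(c(30, 10), c(50, 10))
  dimnames(seeds) <- list(c("p1", "p2"), c("s1", "s2"))
  shares <- species_shares(seeds)
  expect_equal(unname(shares), c(80, 20) / 100)
  expect_equal(sum(shares), 1)
  one <- matrix(7, 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  expect_equal(unname(species_shares(one)), 1)
  expect_error(species_shares(seeds * 0), "zero")
})

test_that("contribution regression recovers an exact linear signal", {
  run <- strong_run()
  pred <- frugnet:::contribution_predictors(run$visit_matrix,
                                            run$inputs$species,
                                            run$inputs$plants)
  expect_true("Turdus_philomelos" %in% colnames(pred))
  expect_false("focal" %in% colnames(pred))
  # response constructed exactly from the predictors: R2 = 1, coefficients
  # recovered to numerical precision
  beta <- c(2, 0.001, 0.004, 0.01, 0.002, 0.3, 3)
  stopifnot(length(beta) == ncol(pred) + 1)
  y <- as.numeric(cbind(1, as.matrix(pred)) %*% beta)
  rain <- run$seed_rain
  rain$plant_totals <- stats::setNames(exp(y) - 1, rownames(run$visit_matrix))
  reg <- suppressWarnings( # exact fit: summary warns about perfect R2
    contribution_regression(rain, run$visit_matrix, run$inputs$species,
                            run$inputs$plants))
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(reg$coefficients$estimate), unname(beta), tolerance = 1e-6)
  expect_equal(sum(reg$lmg), reg$r_squared, tolerance = 1e-8)
  # a constant predictor (aliased with the intercept) is rejected by name
  pl <- run$inputs$plants
  pl$seeds_per_cone <- 5
  expect_error(
    contribution_regression(rain, run$visit_matrix, run$inputs$species, pl),
    "aliased"
  )
})

test_that("one-way ANOVA and Tukey comparisons match direct arithmetic", {
  y <- c(1, 2, 3, 11, 12, 13, 24, 25, 23)
  g <- rep(c("a", "b", "c"), each = 3)
  names(y) <- paste0("p", 1:9)
  res <- group_anova_tukey(stats::setNames(exp(y) - 1, names(y)),
                           stats::setNames(g, names(y)))
  # F computed by hand from between/within sums of squares of log(y+1) = y
  gm <- mean(y)
  ssb <- 3 * sum((tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - rep(tapply(y, g, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova$F, f_hand)
  expect_equal(res$anova$df, c(2, 6))
  expect_equal(res$anova$r_squared, ssb / (ssb + ssw))
  # groups 10+ pooled sds apart are significant at any conventional level
  expect_true(all(res$tukey$p.adj < 0.001))
  # Tukey p-values agree with stats::TukeyHSD on the same fit
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]]
  expect_equal(res$tukey$p.adj, unname(ref[, "p adj"]))
})

test_that("null group differences keep the type-I error near alpha", {
  set.seed(6)
  rejections <- replicate(200, {
    y <- stats::setNames(exp(rnorm(30, 5, 1)), paste0("p", 1:30))
    g <- stats::setNames(rep(c("a", "b", "c"), each = 10), names(y))
    group_anova_tukey(y, g)$anova$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.04)
})

test_that("singleton groups are excluded with a warning", {
  y <- stats::setNames(c(1, 2, 3, 4, 10), paste0("p", 1:5))
  g <- stats::setNames(c("a", "a", "b", "b", "solo"), names(y))
  expect_warning(res <- group_anova_tukey(y, g), "singleton")
  expect_equal(nrow(res$tukey), 1)
})

test_that("stand z-scores centre to zero and rank cumulative shares", {
  plants <- data.frame(plant_id = paste0("p", 1:6),
                       stand = rep(c("MAR", "COL"), each = 3))
  totals <- stats::setNames(c(5, 10, 15, 100, 10, 10), plants$plant_id)
  rk <- stand_zscores(totals, plants)
  tab <- rk$table
  for (s in c("MAR", "COL")) {
    expect_lt(abs(sum(tab$z[tab$stand == s])), 1e-10)
    expect_equal(tab$cumulative_share[tab$stand == s][3], 1)
  }
  # stand (100, 10, 10): the top plant holds 100/120 of the stand seed rain
  col <- tab[tab$stand == "COL", ]
  expect_equal(col$cumulative_share[1], 100 / 120)
  expect_equal(unname(rk$plants_to_share["COL"]), 1L)
  # MAR totals (5, 10, 15): the top plant holds exactly half the stand total
  expect_equal(unname(rk$plants_to_share["MAR"]), 1L)
  # equal contributions: z collapses to zero with a warning
  eq <- stats::setNames(c(2, 2, 2, 1, 2, 3), plants$plant_id)
  expect_warning(rk0 <- stand_zscores(eq, plants), "spread")
  expect_true(all(rk0$table$z[rk0$table$stand == "MAR"] == 0))
})

test_that("log-log regression identifies exact power laws", {
  x <- stats::setNames(seq(2, 40, length.out = 25), paste0("p", 1:25))
  y <- x^2
  res <- suppressWarnings(loglog_regression(y, x, log_offset = 0))
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  # rescaling the covariate changes only the intercept
  res2 <- suppressWarnings(loglog_regression(y, x * 10, log_offset = 0))
  expect_equal(res2$slope, res$slope, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(res2$intercept, res$intercept)))
  expect_error(loglog_regression(y, x - 5, log_offset = 0), "positive")
  # permuting the covariate destroys the relationship
  set.seed(7)
  r2s <- replicate(50, loglog_regression(y, sample(unname(x)), log_offset = 0)$r_squared)
  expect_lt(mean(r2s), 0.1)
})

test_that("bootstrap totals are reproducible and positive", {
  run <- strong_run()
  bt <- species_totals_bootstrap(run$seed_rain, n_boot = 50, rng_seed = 3)
  expect_equal(bt$total, unname(run$seed_rain$species_totals))
  expect_true(all(bt$se >= 0))
  bt2 <- species_totals_bootstrap(run$seed_rain, n_boot = 50, rng_seed = 3)
  expect_equal(bt, bt2)
})
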