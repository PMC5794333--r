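test_that("Welch's t matches the hand formula and its symmetries", {
  r <- welch_t(group_summary(10, 1, 6), group_summary(12, 1, 6))
  expect_equal(r$t, -3.4641, tolerance = 1e-4)
  expect_equal(r$df, 10)
  expect_equal(r$p_value, 0.0060808, tolerance = 1e-4)

  same <- welch_t(group_summary(5, 2, 8), group_summary(5, 2, 8))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  fwd <- welch_t(group_summary(3, 1, 5), group_summary(4, 2, 7))
  rev <- welch_t(group_summary(4, 2, 7), group_summary(3, 1, 5))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p_value, rev$p_value)

  expect_error(welch_t(group_summary(1, NA, 1), group_summary(2, 1, 5)), "n >= 2")
})

test_that("Welch p-values agree with stats::t.test to 1e-6 on random samples", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    mine <- welch_t(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    # summary-based entry point gives the identical answer
    sm <- welch_t(group_summary(mean(x), sd(x), length(x)),
                  group_summary(mean(y), sd(y), length(y)))
    expect_equal(sm$p_value, mine$p_value, tolerance = 1e-12)
  }
})

test_that("Welch type-I error is calibrated at the nominal 5% level", {
  # 10,000 null simulations, both groups Normal(0,1), n = 6
  set.seed(202)
  n_sim <- 10000
  x <- matrix(rnorm(n_sim * 6), n_sim)
  y <- matrix(rnorm(n_sim * 6), n_sim)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  se2 <- vx / 6 + vy / 6
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / 6)^2 / 5 + (vy / 6)^2 / 5)
  p <- 2 * pt(-abs(t), df)
  # spot-check the vectorised replica against welch_t before trusting it
  k <- which.max(p)
  expect_equal(welch_t(x[k, ], y[k, ])$p_value, p[k], tolerance = 1e-10)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("linear fits recover exact lines and flag degenerate input", {
  x <- 1:10
  r <- linear_fit(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  # zero covariance -> R^2 = 0
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(4, 1, 0, 1, 4)
  expect_equal(linear_fit(x0, y0)$r_squared, 0, tolerance = 1e-12)

  expect_error(linear_fit(rep(3, 5), 1:5), "constant")
  expect_error(linear_fit(1:2, 1:2), "3 points")
})

test_that("linear fit matches the lm oracle and is affine-invariant in R^2", {
  set.seed(33)
  x <- runif(20); y <- 1.9 * x + rnorm(20, 0, 0.4)
  mine <- linear_fit(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(mine$slope, unname(coef(ref)["x", "Estimate"]), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(coef(ref)["x", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-10)
  scaled <- linear_fit(3 * x - 7, -2 * y + 11)
  expect_equal(scaled$r_squared, mine$r_squared, tolerance = 1e-12)
})

test_that("a population R^2 target is recovered within Monte-Carlo bounds", {
  # slope 1.9 with noise sd chosen so var explained / total = 0.85
  slope <- 1.9
  x_sd <- 1
  noise_sd <- sqrt(slope^2 * x_sd^2 * (1 - 0.85) / 0.85)
  set.seed(44)
  r2 <- replicate(200, {
    x <- rnorm(60, sd = x_sd)
    linear_fit(x, slope * x + rnorm(60, 0, noise_sd))$r_squared
  })
  expect_equal(mean(r2), 0.85, tolerance = 0.02)
})

test_that("one-way ANOVA reproduces the hand decomposition and the aov oracle", {
  d <- toy_anova_data()
  r <- one_way_anova(d)
  expect_equal(r$f, 21)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  expect_equal(r$p_value, 0.0019, tolerance = 1e-2)
  ref <- summary(aov(value ~ group, data = d))[[1]]
  expect_equal(r$f, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(r$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  r0 <- one_way_anova(tibble::tibble(value = rep(c(1, 2, 3), 2),
                                     group = rep(c("a", "b"), each = 3)))
  expect_equal(r0$f, 0)
  expect_equal(r0$p_value, 1)
})

test_that("two-group ANOVA equals the squared pooled t and shifts leave F alone", {
  set.seed(55)
  d <- tibble::tibble(value = c(rnorm(7), rnorm(8, 1)),
                      group = rep(c("a", "b"), c(7, 8)))
  f <- one_way_anova(d)$f
  t_pooled <- t.test(value ~ group, data = d, var.equal = TRUE)$statistic
  expect_equal(f, unname(t_pooled)^2, tolerance = 1e-10)
  d2 <- dplyr::mutate(d, value = value + 123.4)
  expect_equal(one_way_anova(d2)$f, f, tolerance = 1e-8)
})

test_that("Tukey HSD matches the TukeyHSD oracle and is conservative", {
  d <- toy_anova_data()
  mine <- tukey_hsd(d)
  ref <- TukeyHSD(aov(value ~ group, data = d))$group
  # ref rows are "b-a", "c-a", "c-b"
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_true(mine$p_adj[mine$group1 == "a" & mine$group2 == "c"] < 0.01)

  # adjusted p >= the unadjusted pooled-variance pairwise p (q = sqrt(2) t)
  set.seed(66)
  d2 <- tibble::tibble(value = rnorm(18, rep(c(0, 0.4, 1), each = 6)),
                       group = rep(c("a", "b", "c"), each = 6))
  adj <- tukey_hsd(d2)
  df2 <- nrow(d2) - 3
  p_raw <- 2 * pt(-adj$q / sqrt(2), df2)
  expect_true(all(adj$p_adj >= p_raw - 1e-12))
  identical_groups <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                                     group = rep(c("a", "b", "c"), each = 3))
  expect_true(all(tukey_hsd(identical_groups)$p_adj == 1))
})

test_that("fold change is the plain treatment/control ratio", {
  expect_equal(round(fold_change(3247, 280), 1), 11.6)
  expect_equal(round(fold_change(3247, 280)), 12)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(round(fold_change(983, 280), 2), 3.51)
  expect_error(fold_change(10, 0), "> 0")
})
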