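test_that("spearman matches the rank-then-Pearson oracle on permutations", {
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_equal(spearman_rho(1:5, 1:5)$rho, 1.0)
  expect_equal(spearman_rho(1:5, 5:1)$rho, -1.0)
  x <- 1:5
  perms <- rbind(5:1, c(2, 3, 1, 5, 4), c(1, 3, 2, 4, 5), c(4, 1, 5, 2, 3))
  for (i in seq_len(nrow(perms)))
    expect_equal(spearman_rho(x, perms[i, ])$rho,
                 spearman_brute(x, perms[i, ]))
  # ties handled through average ranks
  xt <- c(1, 1, 2, 3, 3, 4)
  yt <- c(2, 1, 1, 3, 4, 4)
  expect_equal(spearman_rho(xt, yt)$rho, spearman_brute(xt, yt))
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_lt(spearman_rho(1:100, c(2:100, 1))$p, 0.05)
})

test_that("gini matches brute force, closed forms, and scale invariance", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  for (n in 2:6) {
    w <- c(rep(0, n - 1), 7)        # one holder owns everything
    expect_equal(gini(w), (n - 1) / n)
    expect_equal(gini(w), gini_brute(w))
  }
  set.seed(3)
  for (i in 1:20) {
    w <- rgamma(sample(3:40, 1), shape = 0.8)
    expect_equal(gini(w), gini_brute(w), tolerance = 1e-12)
    expect_equal(gini(3.7 * w), gini(w), tolerance = 1e-12)
  }
  expect_error(gini(c(-1, 2)), "non-negative")
  expect_error(gini(c(0, 0)), "zero")
})

test_that("lorenz curve has the stated shape and reproduces gini by area", {
  lc <- lorenz_curve(c(0, 1))
  expect_equal(lc$pop_share, c(0, 0.5, 1))
  expect_equal(lc$wealth_share, c(0, 0, 1))
  eq <- lorenz_curve(rep(2, 5))
  expect_equal(eq$wealth_share, eq$pop_share)
  set.seed(8)
  for (i in 1:20) {
    w <- rlnorm(sample(3:50, 1), sdlog = runif(1, 0.1, 2))
    lc <- lorenz_curve(w)
    expect_true(all(diff(lc$wealth_share) >= -1e-12))       # non-decreasing
    expect_true(all(lc$wealth_share <= lc$pop_share + 1e-12)) # under diagonal
    expect_true(all(diff(lc$wealth_share, differences = 2) >= -1e-12)) # convex
    expect_equal(herdpool:::lorenz_gini(lc), gini(w), tolerance = 1e-9)
  }
  expect_error(lorenz_curve(c(0, 0)), "zero")
})

test_that("survival summaries are consistent and reproducible", {
  reps <- run_replicates(env_params(shock_rate = 0), nbt, nbt, n = 25,
                         base_seed = 5)
  s <- survival_summary(reps, n_boot = 50)
  expect_equal(s$median, 50)
  expect_equal(s$prop_alive, 1)
  expect_true(all(s$curve$prop_alive == 1))

  reps <- run_replicates(short_env, nbt, nbt, n = 400, base_seed = 6)
  set.seed(1); s1 <- survival_summary(reps, n_boot = 200)
  set.seed(1); s2 <- survival_summary(reps, n_boot = 200)
  expect_identical(s1, s2)
  # survival curve starts at 1 and never increases
  expect_equal(s1$curve$prop_alive[1], 1)
  expect_true(all(diff(s1$curve$prop_alive) <= 0))
  # median consistent with the curve: S drops below 0.5 after the median
  med <- ceiling(s1$median)
  expect_gte(s1$curve$prop_alive[s1$curve$year == med - 1], 0.5)
  # CIs bracket the point estimates
  expect_true(s1$mean_ci[1] <= s1$mean && s1$mean <= s1$mean_ci[2])
  expect_true(s1$prop_ci[1] <= s1$prop_alive &&
                s1$prop_alive <= s1$prop_ci[2])
})
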