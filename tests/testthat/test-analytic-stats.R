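st <- function(at, ah = 0.3, T = 100, p = 0.4, s = 0.5, bd = 1, br = bd)
  rw_setting(at, ah, T, p, sigma_eps = s, beta_delta = bd, beta_r = br)

test_that("closed-form moments match their definitions and a long simulation", {
  m <- rw_moments(st(0.5, 0.2, T = 1))
  expect_equal(m$S_r_r, 0.24)
  expect_identical(m$S_r_nVhat, 0)
  # all moments scale linearly in the trial count
  m100 <- rw_moments(st(0.5, 0.2, T = 100))
  expect_equal(unlist(m100), 100 * unlist(m), tolerance = 1e-12)

  # predicted correlation between true and refit RPE
  cor_closed <- m$S_d_dhat / sqrt(2 / 1.5 * 0.24 * m$S_dhat_dhat)
  expect_equal(cor_closed, 0.9585, tolerance = 1e-4)
  set.seed(31)
  r <- rbinom(2e5, 1, 0.4)
  cor_sim <- cor(simulate_rw(r, 0.5)$delta, simulate_rw(r, 0.2)$delta)
  expect_equal(cor_sim, cor_closed, tolerance = 0.005)

  expect_error(rw_moments(rw_setting(0.5, 0.2, 100, 1)),
               "strictly between")
})

test_that("GLM1 beta statistics: unbiased when matched, frozen values under misfit", {
  g_match <- beta_stats_glm1(st(0.3))
  expect_equal(g_match$expected[["delta"]], 1)

  g <- beta_stats_glm1(st(0.4))
  expect_equal(g$expected[["delta"]], 1.0258621, tolerance = 1e-6)
  expect_equal(g$variance[["delta"]], 0.00885417, tolerance = 1e-6)
})

test_that("GLM2 beta statistics: negative-value bias, alpha-independent reward beta", {
  expect_equal(beta_stats_glm2(st(0.3))$expected[["neg_value"]], 1)
  g <- beta_stats_glm2(st(0.2))
  expect_equal(g$expected[["neg_value"]], 0.7727273, tolerance = 1e-6)
  expect_equal(g$variance[["neg_value"]], 0.0590278, tolerance = 1e-6)
  expect_equal(g$variance[["reward"]], 0.01041667, tolerance = 1e-6)
  # reward-beta statistics do not depend on either learning rate
  g2 <- beta_stats_glm2(st(0.7, 0.6))
  expect_equal(g2$expected[["reward"]], g$expected[["reward"]])
  expect_equal(g2$variance[["reward"]], g$variance[["reward"]])
  expect_error(beta_stats_glm2(st(0.4, ah = 0)), "alpha_fit")
})

test_that("GLM2' statistics mirror GLM2 and absorb the misfit into the reward beta", {
  for (at in c(0.1, 0.3, 0.55)) {
    gp <- beta_stats_glm2prime(st(at))
    g2 <- beta_stats_glm2(st(at))
    expect_equal(gp$expected[["delta"]], g2$expected[["neg_value"]])
    expect_equal(gp$variance[["delta"]], g2$variance[["neg_value"]])
  }
  # matched rates: no misfit term in the reward beta
  expect_equal(beta_stats_glm2prime(st(0.3))$expected[["reward"]], 1)
  expect_equal(beta_stats_glm2prime(st(0.3))$variance[["reward"]],
               0.0694444, tolerance = 1e-6)
})

test_that("GLM2' reward variance matches a Monte-Carlo OLS oracle", {
  set.seed(32)
  vs <- vapply(1:15, function(s) {
    tr <- simulate_rw(make_conditioning_schedule(100, 0.4, seed = s), 0.3)
    X <- build_design(tr, "glm2prime")
    Y <- matrix(tr$delta, 100, 300) + matrix(rnorm(100 * 300, 0, 0.5), 100)
    var(fit_ols(Y, X)$betas["reward", ])
  }, numeric(1))
  expect_within_3se(mean(vs), 0.0694444, sd(vs) / sqrt(15))
})

test_that("general-design statistics reduce correctly and match the RW closed form", {
  set.seed(33)
  X <- cbind(a = rnorm(80), b = rnorm(80))
  bs <- beta_stats_general(X, X, c(2, -1), sigma_eps = 0.7)
  expect_equal(unname(bs$expected), c(2, -1))

  # single regressor: correlation-attenuation form
  xs <- rnorm(200)
  x <- xs + rnorm(200)
  b1 <- beta_stats_general(cbind(x), cbind(xs), 1.5, 1)
  xc <- x - mean(x); xsc <- xs - mean(xs)
  expect_equal(unname(b1$expected),
               cor(x, xs) * sqrt(sum(xsc^2) / sum(xc^2)) * 1.5)

  # realized designs from a long RW run agree with the closed form
  r <- make_conditioning_schedule(10000, 0.4, seed = 34)$rewards
  Xf <- build_design(simulate_rw(r, 0.3), "glm1")
  Xt <- build_design(simulate_rw(r, 0.4), "glm1")
  gen <- beta_stats_general(Xf, Xt, 1, 0.5)
  cf <- beta_stats_glm1(st(0.4, T = 10000))
  expect_equal(unname(gen$expected), cf$expected[["delta"]],
               tolerance = 0.02)
  expect_equal(unname(gen$variance), cf$variance[["delta"]],
               tolerance = 0.02)

  expect_error(beta_stats_general(cbind(x, 2 * x), cbind(x, 2 * x),
                                  c(1, 1), 1), "singular")
})

test_that("two-group effect sizes reproduce the headline values and scaling laws", {
  expect_equal(effect_size_two_group(beta_stats_glm1(st(0.3)),
                                     beta_stats_glm1(st(0.3)), "delta")$d2,
               0)
  d_glm1 <- effect_size_two_group(beta_stats_glm1(st(0.4)),
                                  beta_stats_glm1(st(0.2)), "delta")$d2
  d_nv <- effect_size_two_group(beta_stats_glm2(st(0.4)),
                                beta_stats_glm2(st(0.2)), "neg_value")$d2
  d_rew <- effect_size_two_group(beta_stats_glm2(st(0.4)),
                                 beta_stats_glm2(st(0.2)), "reward")$d2
  expect_equal(d_glm1, 0.6371430, tolerance = 1e-6)
  # one unit in the last printed digit (the exact value, 1.6451, sits on
  # the rounding boundary)
  expect_lt(abs(d_nv - 1.64), 0.01)
  expect_identical(d_rew, 0)

  # d2 scales exactly as sqrt(T)
  d_4T <- effect_size_two_group(beta_stats_glm1(st(0.4, T = 400)),
                                beta_stats_glm1(st(0.2, T = 400)),
                                "delta")$d2
  expect_equal(d_4T, 2 * d_glm1)

  # swapping the groups flips the sign
  d_swap <- effect_size_two_group(beta_stats_glm1(st(0.2)),
                                  beta_stats_glm1(st(0.4)), "delta")$d2
  expect_equal(d_swap, -d_glm1)
})

test_that("one-group effect size and its trial scaling", {
  d1 <- effect_size_one_group(beta_stats_glm1(st(0.3)), "delta")$d1
  expect_equal(d1, 10.63, tolerance = 1e-3)
  d1_4T <- effect_size_one_group(beta_stats_glm1(st(0.3, T = 400)),
                                 "delta")$d1
  expect_equal(d1_4T, 2 * d1)
  zero <- beta_stats_glm1(st(0.3))
  zero$expected["delta"] <- 0
  expect_equal(effect_size_one_group(zero, "delta")$d1, 0)
})

test_that("noncentral-t power: type-I calibration, headline values, limits", {
  expect_equal(power_two_sample(0, 20, 20, 0.05)$power, 0.05)
  expect_equal(power_one_sample(0, 20, 0.05)$power, 0.05)
  expect_equal(power_two_sample(0.6371430, 20, 20)$power, 0.502,
               tolerance = 5e-3)
  expect_equal(power_two_sample(1.6450957, 20, 20)$power, 0.999,
               tolerance = 5e-3)
  expect_gt(power_one_sample(50, 10)$power, 1 - 1e-6)
  expect_error(power_two_sample(0.5, 20, 20, alpha_sig = 1.5), "alpha_sig")
  expect_error(power_one_sample(0.5, 1), "subjects")
})

test_that("one-sample power matches a vectorized t-test simulation", {
  n <- 20; d1 <- 0.5; nrep <- 100000
  set.seed(35)
  X <- matrix(rnorm(n * nrep, mean = d1, sd = 1), n, nrep)
  m <- colMeans(X)
  s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  rej <- mean(abs(tstat) > qt(0.975, n - 1))
  pw <- power_one_sample(d1, n, 0.05)$power
  expect_within_3se(rej, pw, sqrt(pw * (1 - pw) / nrep))
})
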