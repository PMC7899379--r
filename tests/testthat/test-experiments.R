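test_that("Cohen's d: pooled-sd value, location invariance, degenerate input", {
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(61)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(cohens_d(a + 10, b + 10), cohens_d(a, b))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "samples")
})

test_that("group comparisons are pure functions of (config, seed)", {
  r1 <- run_group_comparison_rw(seed = 42)
  r2 <- run_group_comparison_rw(seed = 42)
  expect_identical(r1, r2)
  expect_identical(r1$df, rep(38, 5))
  expect_setequal(r1$glm_kind, c("glm1", "glm2", "glm2prime"))

  m1 <- run_misspecification(n_per_group = 4, n_restarts = 3,
                             fit_models = "standard", seed = 9)
  m2 <- run_misspecification(n_per_group = 4, n_restarts = 3,
                             fit_models = "standard", seed = 9)
  expect_identical(m1$report, m2$report)
})

test_that("rebuilding regressors with each subject's true rate removes the bias", {
  ds <- vapply(1:40, function(s) {
    r <- run_group_comparison_rw(alpha_fit = NULL, seed = s)
    r$cohens_d[r$glm_kind == "glm1"]
  }, numeric(1))
  expect_within_3se(mean(ds), 0, sd(ds) / sqrt(40))
})

test_that("heterogeneity: small spread reproduces the homogeneous effect sizes", {
  sw <- run_heterogeneity_sweep(sd_grid = c(0.001, 0.2, 0.5),
                                n_per_group = 700, seed = 3)
  d_glm1 <- effect_size_two_group(
    beta_stats_glm1(rw_setting(0.4, 0.3, 100, 0.4)),
    beta_stats_glm1(rw_setting(0.2, 0.3, 100, 0.4)), "delta")$d2
  d_nv <- effect_size_two_group(
    beta_stats_glm2(rw_setting(0.4, 0.3, 100, 0.4)),
    beta_stats_glm2(rw_setting(0.2, 0.3, 100, 0.4)), "neg_value")$d2
  expect_equal(sw$d_glm1_delta[1], d_glm1, tolerance = 0.25)
  expect_equal(sw$d_glm2_neg_value[1], d_nv, tolerance = 0.25)

  # heterogeneity weakens but does not remove the spurious difference
  expect_true(all(sw$d_glm1_delta > 0))
  expect_true(all(sw$d_glm2_neg_value > 0))
  expect_lt(sw$d_glm2_neg_value[3], sw$d_glm2_neg_value[1])

  # reported sd is computed after truncation to [0, 1]
  expect_lt(sw$sd_actual[3], 0.5)
  expect_equal(sw$sd_actual[1], 0.001, tolerance = 1e-3)
})

test_that("dimensional analysis: spurious trait correlations appear only under a common rate", {
  biased <- run_dimensional(seed = 5)
  expect_lt(biased$r[biased$measure == "alpha_true"], -0.7)
  expect_lt(biased$r[biased$measure == "glm1_delta"], 0)
  expect_lt(biased$p_value[biased$measure == "glm1_delta"], 0.01)
  expect_lt(biased$r[biased$measure == "glm2_neg_value"], 0)
  expect_lt(biased$p_value[biased$measure == "glm2_neg_value"], 0.01)
  expect_lt(abs(biased$r[biased$measure == "glm2_reward"]), 0.15)

  clean <- run_dimensional(alpha_fit = NULL, seed = 5)
  for (m in c("glm1_delta", "glm2_neg_value", "glm2_reward")) {
    expect_lt(abs(clean$r[clean$measure == m]), 0.2)
  }
})

test_that("trial sweep: sqrt(T) scaling, gap dependence, simulation agreement", {
  sw <- run_trial_sweep(trial_grid = c(100, 400),
                        alpha_pairs = list(c(0.4, 0.2), c(0.5, 0.1)),
                        n_reps = 40, seed = 6)
  r44 <- sw[sw$n_trials == 400 & sw$alpha_control == 0.4, ]
  r41 <- sw[sw$n_trials == 100 & sw$alpha_control == 0.4, ]
  expect_equal(r44$d2_glm1, 2 * r41$d2_glm1)
  # larger learning-rate gap, larger analytic effect
  r51 <- sw[sw$n_trials == 100 & sw$alpha_control == 0.5, ]
  expect_gt(r51$d2_glm1, r41$d2_glm1)
  # replicate means track the analytic curve
  expect_within_3se(r41$sim_d_glm1, r41$d2_glm1, r41$sim_se_glm1)
  expect_within_3se(r41$sim_d_neg_value, r41$d2_neg_value,
                    r41$sim_se_neg_value)
})

test_that("analytic alpha grid: zero diagonal, antisymmetry, gap dominance", {
  g <- run_alpha_grid(alpha_grid = seq(0.1, 0.7, by = 0.2))
  diag_rows <- g$alpha_control == g$alpha_patient
  expect_true(all(g$d2_glm1[diag_rows] == 0))
  expect_true(all(g$d2_neg_value[diag_rows] == 0))
  d_ab <- g$d2_glm1[g$alpha_control == 0.5 & g$alpha_patient == 0.3]
  d_ba <- g$d2_glm1[g$alpha_control == 0.3 & g$alpha_patient == 0.5]
  expect_equal(d_ab, -d_ba)
  # equal-gap pairs give comparable (same-sign, same-magnitude-order) d2
  gaps <- g[abs(g$alpha_control - g$alpha_patient - 0.2) < 1e-9,
            "d2_glm1"]
  expect_true(all(gaps > 0))
  expect_lt(max(gaps) / min(gaps), 2)
})

test_that("misspecification report: nesting, forgetting recovery, correlation drop", {
  res <- lapply(1:3, function(s)
    run_misspecification(n_per_group = 10, seed = 200 + s))
  subj <- do.call(rbind, lapply(res, `[[`, "subjects"))
  # forgetting-model likelihood is never worse than the standard one
  nll_f <- subj$nll[subj$fit_model == "forgetting"]
  nll_s <- subj$nll[subj$fit_model == "standard"]
  expect_true(all(nll_f <= nll_s + 1e-6))
  # the forgetting fit separates the groups on phi_hat
  ff <- subj[subj$fit_model == "forgetting", ]
  expect_gt(mean(ff$phi_hat[ff$group == "patient"]),
            mean(ff$phi_hat[ff$group == "control"]))
  # under the misspecified fit, the fitted-RPE/signal correlation is lower
  # in the high-forgetting group
  cors <- do.call(rbind, lapply(res, `[[`, "correlations"))
  cs <- cors[cors$fit_model == "standard", ]
  expect_gt(mean(cs$cor_delta_y[cs$group == "control"]),
            mean(cs$cor_delta_y[cs$group == "patient"]))
})

test_that("reversal sweep: reversals amplify the misspecification bias up to a point", {
  sw <- run_reversal_sweep(reversal_grid = c(0, 17, 35), n_reps = 12,
                           n_per_group = 12, n_restarts = 5, seed = 7)
  expect_gt(sw$d_glm2_neg_value[sw$n_reversals == 17],
            sw$d_glm2_neg_value[sw$n_reversals == 0])
  expect_lt(sw$d_glm2_neg_value[sw$n_reversals == 35],
            sw$d_glm2_neg_value[sw$n_reversals == 17])
  expect_equal(which.min(sw$d_glm1_delta), 1L)
})
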