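#' Cohen's d with pooled standard deviation
#'
#' \eqn{(\bar x_1 - \bar x_2)/s_p} with the pooled estimator weighting
#' the group variances by \eqn{(n_1-1, n_2-1)}, the estimator consistent
#' with the equal-variance two-sample t-test.
#'
#' @param group1,group2 numeric samples (each of length >= 2).
#' @return A single number.
#' @examples
#' cohens_d(c(0, 2), c(2, 4))  # -sqrt(2)
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples",
                             call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(group1) - mean(group2)) / sqrt(sp2)
}

# One row of a group-comparison report: equal-variance t-test plus
# pooled-sd Cohen's d, control minus patient.  Subjects whose fitted
# model renders a regressor degenerate carry NA betas and are dropped.
group_test_row <- function(b1, b2, glm_kind, regressor, seed) {
  b1 <- b1[is.finite(b1)]
  b2 <- b2[is.finite(b2)]
  tt <- stats::t.test(b1, b2, var.equal = TRUE)
  data.frame(glm_kind = glm_kind, regressor = regressor,
             mean_control = mean(b1), mean_patient = mean(b2),
             sd_control = stats::sd(b1), sd_patient = stats::sd(b2),
             t_stat = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, cohens_d = cohens_d(b1, b2),
             n1 = length(b1), n2 = length(b2), seed = seed)
}

# Per-subject beta values for conditioning subjects sharing one reward
# realization.  `alphas` holds each subject's true learning rate;
# `alpha_fit` is the common analysis learning rate (a scalar), or a
# per-subject vector (e.g., the true rates, for no-misfit controls).
# When the analysis rate is shared, all subjects share the design, so
# the OLS solves are done in one matrix operation.
rw_subject_betas <- function(schedule, alphas, alpha_fit, sigma_eps,
                             beta_delta, noise_seed) {
  r <- schedule$rewards
  n <- schedule$n_trials
  N <- length(alphas)
  d_true <- vapply(alphas, function(a) simulate_rw(r, a)$delta,
                   numeric(n))
  Y <- beta_delta * d_true +
    with_seed(noise_seed, matrix(stats::rnorm(n * N, 0, sigma_eps), n, N))
  if (length(alpha_fit) == 1L) {
    traj <- simulate_rw(r, alpha_fit)
    f1 <- fit_ols(Y, build_design(traj, "glm1"))$betas
    f2 <- fit_ols(Y, build_design(traj, "glm2"))$betas
    f2p <- fit_ols(Y, build_design(traj, "glm2prime"))$betas
    B <- rbind(f1["delta", ], f2["reward", ], f2["neg_value", ],
               f2p["reward", ], f2p["delta", ])
  } else {
    stopifnot(length(alpha_fit) == N)
    # a subject analyzed with a zero learning rate has a constant value
    # regressor; their multi-regressor betas are undefined -> NA
    B <- vapply(seq_len(N), function(i) {
      traj <- simulate_rw(r, alpha_fit[i])
      y <- Y[, i]
      tryCatch(
        c(fit_ols(y, build_design(traj, "glm1"))$betas["delta"],
          fit_ols(y, build_design(traj, "glm2"))$betas[c("reward",
                                                         "neg_value")],
          fit_ols(y, build_design(traj, "glm2prime"))$betas[c("reward",
                                                              "delta")]),
        error = function(e) rep(NA_real_, 5))
    }, numeric(5))
  }
  out <- as.data.frame(t(B))
  names(out) <- c("glm1_delta", "glm2_reward", "glm2_neg_value",
                  "glm2prime_reward", "glm2prime_delta")
  out$alpha_true <- alphas
  rownames(out) <- NULL
  out
}

#' Group comparison of beta values under learning-rate misfit
#'
#' Simulates the two-group classical-conditioning experiment: both
#' groups share one reward realization; each subject's neural signal is
#' generated from their group's true learning rate, while the GLM
#' regressors are rebuilt with a common analysis learning rate
#' (`alpha_fit`).  Beta values for GLM1, GLM2 and GLM2' are compared
#' between groups with unpaired equal-variance t-tests.
#'
#' @param alpha_control,alpha_patient true learning rates of the
#'   control (High-L) and patient (Low-L) groups.
#' @param alpha_fit common analysis learning rate, or `NULL` to rebuild
#'   each subject's regressors with their true rate (no-misfit control).
#' @param n_per_group subjects per group.
#' @param n_trials,p_reward conditioning schedule parameters.
#' @param sigma_eps,beta_delta signal noise sd and true
#'   prediction-error coefficient.
#' @param seed master seed; the schedule and every subject's noise
#'   derive child seeds from it.
#' @return A `"group_comparison"` data frame with one row per
#'   GLM/regressor (see [cohens_d()] sign convention: control minus
#'   patient), and the per-subject beta table in
#'   `attr(, "subjects")`.
#' @examples
#' rep <- run_group_comparison_rw(seed = 1)
#' rep[, c("glm_kind", "regressor", "cohens_d", "p_value")]
#' @export
run_group_comparison_rw <- function(alpha_control = 0.4,
                                    alpha_patient = 0.2,
                                    alpha_fit = 0.3,
                                    n_per_group = 20, n_trials = 100,
                                    p_reward = 0.4, sigma_eps = 0.5,
                                    beta_delta = 1, seed = 1) {
  sched <- make_conditioning_schedule(n_trials, p_reward,
                                      seed = child_seed(seed, 1))
  alphas <- rep(c(alpha_control, alpha_patient), each = n_per_group)
  afit <- if (is.null(alpha_fit)) alphas else alpha_fit
  sub <- rw_subject_betas(sched, alphas, afit, sigma_eps, beta_delta,
                          noise_seed = child_seed(seed, 2))
  g1 <- seq_len(n_per_group)
  g2 <- n_per_group + g1
  rows <- rbind(
    group_test_row(sub$glm1_delta[g1], sub$glm1_delta[g2],
                   "glm1", "delta", seed),
    group_test_row(sub$glm2_reward[g1], sub$glm2_reward[g2],
                   "glm2", "reward", seed),
    group_test_row(sub$glm2_neg_value[g1], sub$glm2_neg_value[g2],
                   "glm2", "neg_value", seed),
    group_test_row(sub$glm2prime_reward[g1], sub$glm2prime_reward[g2],
                   "glm2prime", "reward", seed),
    group_test_row(sub$glm2prime_delta[g1], sub$glm2prime_delta[g2],
                   "glm2prime", "delta", seed)
  )
  sub$group <- rep(c("control", "patient"), each = n_per_group)
  attr(rows, "subjects") <- sub
  class(rows) <- c("group_comparison", "data.frame")
  rows
}

#' Effect of within-group heterogeneity in true learning rates
#'
#' True learning rates are drawn from Gaussians (means
#' `alpha_mean_control` / `alpha_mean_patient`, common sd from
#' `sd_grid`) truncated to \[0, 1\]; regressors use the common analysis
#' rate `alpha_fit`.  Effect sizes of the group difference in the
#' learning rate itself, the GLM1 prediction-error beta and the GLM2
#' negative-value beta are computed numerically per sd level.  The
#' reported sd is the post-truncation within-group sd averaged across
#' groups.
#'
#' @param sd_grid grid of nominal within-group standard deviations.
#' @param alpha_mean_control,alpha_mean_patient group means of the true
#'   learning rate.
#' @param n_per_group simulated subjects per group (large by default so
#'   the numerical effect sizes are stable).
#' @inheritParams run_group_comparison_rw
#' @return Data frame with columns `sd_nominal`, `sd_actual`,
#'   `d_alpha`, `d_glm1_delta`, `d_glm2_neg_value`.
#' @export
run_heterogeneity_sweep <- function(sd_grid = seq(0.05, 0.5, by = 0.05),
                                    alpha_mean_control = 0.4,
                                    alpha_mean_patient = 0.2,
                                    n_per_group = 5000, alpha_fit = 0.3,
                                    n_trials = 100, p_reward = 0.4,
                                    sigma_eps = 0.5, beta_delta = 1,
                                    seed = 1) {
  sched <- make_conditioning_schedule(n_trials, p_reward,
                                      seed = child_seed(seed, 1))
  out <- lapply(seq_along(sd_grid), function(j) {
    s <- sd_grid[j]
    a1 <- with_seed(child_seed(seed, 100 + j),
                    pmin(pmax(stats::rnorm(n_per_group,
                                           alpha_mean_control, s), 0), 1))
    a2 <- with_seed(child_seed(seed, 200 + j),
                    pmin(pmax(stats::rnorm(n_per_group,
                                           alpha_mean_patient, s), 0), 1))
    sub <- rw_subject_betas(sched, c(a1, a2), alpha_fit, sigma_eps,
                            beta_delta,
                            noise_seed = child_seed(seed, 300 + j))
    g1 <- seq_len(n_per_group)
    g2 <- n_per_group + g1
    data.frame(
      sd_nominal = s,
      sd_actual = mean(c(stats::sd(a1), stats::sd(a2))),
      d_alpha = cohens_d(a1, a2),
      d_glm1_delta = cohens_d(sub$glm1_delta[g1], sub$glm1_delta[g2]),
      d_glm2_neg_value = cohens_d(sub$glm2_neg_value[g1],
                                  sub$glm2_neg_value[g2])
    )
  })
  do.call(rbind, out)
}

#' Dimensional (trait-correlation) analysis under a common learning rate
#'
#' Each subject's true learning rate is drawn from a truncated Gaussian
#' and a continuous trait (e.g., a symptom score) is constructed to
#' correlate negatively with it:
#' `trait = trait_intercept + trait_slope * alpha + noise`.  The neural
#' signal reflects the prediction error with the same coefficient for
#' everyone, so any trait-beta correlation is spurious.  Pearson
#' correlations between the trait and each beta value are reported with
#' 95\% confidence intervals.
#'
#' @param n_subjects number of subjects.
#' @param alpha_mean,alpha_sd distribution of the true learning rate
#'   (truncated to \[0, 1\]).
#' @param trait_intercept,trait_slope,trait_noise_sd trait construction
#'   (defaults give a trait-alpha correlation near -0.8).
#' @param alpha_fit common analysis learning rate, or `NULL` to use each
#'   subject's true rate (no-bias control).
#' @inheritParams run_group_comparison_rw
#' @return Data frame with one row per measure (`alpha_true`,
#'   `glm1_delta`, `glm2_reward`, `glm2_neg_value`): correlation with
#'   the trait, 95\% CI and p-value.  Per-subject data in
#'   `attr(, "subjects")`.
#' @export
run_dimensional <- function(n_subjects = 200, alpha_mean = 0.3,
                            alpha_sd = 0.1, trait_intercept = 50,
                            trait_slope = -100, trait_noise_sd = 7.5,
                            alpha_fit = 0.4, n_trials = 100,
                            p_reward = 0.4, sigma_eps = 0.5,
                            beta_delta = 1, seed = 1) {
  sched <- make_conditioning_schedule(n_trials, p_reward,
                                      seed = child_seed(seed, 1))
  alphas <- with_seed(child_seed(seed, 2),
                      pmin(pmax(stats::rnorm(n_subjects, alpha_mean,
                                             alpha_sd), 0), 1))
  trait <- trait_intercept + trait_slope * alphas +
    with_seed(child_seed(seed, 3),
              stats::rnorm(n_subjects, 0, trait_noise_sd))
  afit <- if (is.null(alpha_fit)) alphas else alpha_fit
  sub <- rw_subject_betas(sched, alphas, afit, sigma_eps, beta_delta,
                          noise_seed = child_seed(seed, 4))
  sub$trait <- trait
  one <- function(x, label) {
    ok <- is.finite(x)
    ct <- stats::cor.test(trait[ok], x[ok])
    data.frame(measure = label, r = unname(ct$estimate),
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               p_value = ct$p.value)
  }
  out <- rbind(one(alphas, "alpha_true"),
               one(sub$glm1_delta, "glm1_delta"),
               one(sub$glm2_reward, "glm2_reward"),
               one(sub$glm2_neg_value, "glm2_neg_value"))
  attr(out, "subjects") <- sub
  out
}

#' Group comparison under model misspecification (missing forgetting)
#'
#' Behavior is generated by the forgetting RL model on a probabilistic
#' reversal learning task, with the forgetting rate differing between a
#' Low-F (control) and a High-F (patient) group.  Each subject gets a
#' fresh task realization.  Model parameters are then estimated per
#' subject by maximum likelihood under each requested fit model
#' (`"standard"` lacks the forgetting process and is misspecified;
#' `"forgetting"` is correctly specified), regressors are rebuilt from
#' the fitted parameters, GLM1 and GLM2 are fit to the synthetic neural
#' signal, and beta values are compared between groups.
#'
#' @param n_per_group subjects per group.
#' @param phi_low,phi_high forgetting rates of the control and patient
#'   groups.
#' @param alpha_true,beta_it_true,mu shared generating parameters.
#' @param n_trials,n_reversals,p_high,p_low reversal-task parameters.
#' @param beta_delta,sigma_eps neural-signal generation parameters.
#' @param n_restarts random restarts per maximum-likelihood fit.
#' @param fit_models character subset of `c("standard", "forgetting")`.
#' @param seed master seed.
#' @return A `"misspecification_result"` list: `report` (group tests
#'   per fit model, GLM and regressor), `correlations` (mean
#'   correlation between the fitted prediction error and the signal per
#'   group and fit model), `subjects` (per-subject estimates and
#'   betas).
#' @export
run_misspecification <- function(n_per_group = 30, phi_low = 0.05,
                                 phi_high = 0.4, alpha_true = 0.5,
                                 beta_it_true = 4, mu = 0.5,
                                 n_trials = 180, n_reversals = 1,
                                 p_high = 0.8, p_low = 0.2,
                                 beta_delta = 1, sigma_eps = 0.5,
                                 n_restarts = 10,
                                 fit_models = c("standard", "forgetting"),
                                 seed = 1) {
  fit_models <- match.arg(fit_models, several.ok = TRUE)
  groups <- data.frame(
    group = rep(c("control", "patient"), each = n_per_group),
    phi = rep(c(phi_low, phi_high), each = n_per_group)
  )
  ns <- nrow(groups)
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    sched <- make_reversal_schedule(n_trials, p_high, p_low, n_reversals)
    beh <- simulate_forgetting_rl(sched, alpha_true, beta_it_true,
                                  groups$phi[i], mu,
                                  seed = child_seed(seed, 10 * i))
    y <- generate_signal(cbind(delta = beh$delta), beta_delta, sigma_eps,
                         seed = child_seed(seed, 10 * i + 1))
    res <- data.frame(subject = i, group = groups$group[i],
                      phi_true = groups$phi[i])
    fits <- lapply(seq_along(fit_models), function(k) {
      fm <- fit_models[k]
      fit <- fit_mle(beh, model = fm, n_restarts = n_restarts,
                     mu = mu, seed = child_seed(seed, 10 * i + 2 + k))
      lat <- recompute_latents(beh, alpha = fit$params[["alpha"]],
                               phi = fit$params[["phi"]], mu = mu,
                               model = fm)
      # a degenerate fit (e.g., alpha_hat = 0 making the value sequence
      # constant) leaves the corresponding betas undefined -> NA
      safe_betas <- function(design) {
        tryCatch(fit_ols(y, design)$betas, error = function(e) {
          stats::setNames(rep(NA_real_, ncol(design) + 1L),
                          c("(Intercept)", colnames(design)))
        })
      }
      b1 <- safe_betas(build_design(lat, "glm1"))
      b2 <- safe_betas(build_design(lat, "glm2"))
      data.frame(fit_model = fm,
                 alpha_hat = fit$params[["alpha"]],
                 beta_it_hat = fit$params[["beta_it"]],
                 phi_hat = fit$params[["phi"]],
                 nll = fit$nll, converged = fit$converged,
                 glm1_delta = unname(b1["delta"]),
                 glm2_reward = unname(b2["reward"]),
                 glm2_neg_value = unname(b2["neg_value"]),
                 cor_delta_y = stats::cor(lat$delta, y))
    })
    rows[[i]] <- cbind(res[rep(1L, length(fit_models)), , drop = FALSE],
                       do.call(rbind, fits))
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  report <- do.call(rbind, lapply(fit_models, function(fm) {
    d <- subjects[subjects$fit_model == fm, ]
    ctrl <- d$group == "control"
    r <- rbind(
      group_test_row(d$glm1_delta[ctrl], d$glm1_delta[!ctrl],
                     "glm1", "delta", seed),
      group_test_row(d$glm2_reward[ctrl], d$glm2_reward[!ctrl],
                     "glm2", "reward", seed),
      group_test_row(d$glm2_neg_value[ctrl], d$glm2_neg_value[!ctrl],
                     "glm2", "neg_value", seed)
    )
    r$fit_model <- fm
    r$any_nonconverged <- any(!d$converged)
    r
  }))
  correlations <- stats::aggregate(
    cor_delta_y ~ fit_model + group, data = subjects, FUN = mean)
  structure(list(report = report, correlations = correlations,
                 subjects = subjects, seed = seed),
            class = "misspecification_result")
}

#' @export
print.misspecification_result <- function(x, ...) {
  cat("Misspecification experiment (seed", x$seed, ")\n")
  print(x$report[, c("fit_model", "glm_kind", "regressor", "cohens_d",
                     "t_stat", "p_value")])
  invisible(x)
}

#' Effect size of the spurious group difference vs number of trials
#'
#' Analytic two-group effect sizes of the GLM1 prediction-error beta and
#' the GLM2 negative-value beta as a function of the trial count, with a
#' simulated check (`n_reps` replicate experiments per trial count, each
#' with a fresh reward realization).  When `n_trials * p_reward` is not
#' an integer the replicate schedules fall back to Bernoulli draws.
#'
#' @param trial_grid trial counts to evaluate.
#' @param alpha_pairs list of `c(control, patient)` true learning-rate
#'   pairs.
#' @param n_reps simulated replicates per grid point (0 for
#'   analytic-only).
#' @inheritParams run_group_comparison_rw
#' @return Data frame with analytic `d2_glm1` / `d2_neg_value` and,
#'   when simulated, replicate means and standard errors of the
#'   corresponding Cohen's d.
#' @export
run_trial_sweep <- function(trial_grid = c(3, 10, 25, seq(50, 500, 50)),
                            alpha_pairs = list(c(0.4, 0.2)),
                            alpha_fit = 0.3, n_reps = 100,
                            n_per_group = 20, p_reward = 0.4,
                            sigma_eps = 0.5, beta_delta = 1, seed = 1) {
  grid <- expand.grid(pair = seq_along(alpha_pairs),
                      n_trials = trial_grid)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    pr <- alpha_pairs[[grid$pair[g]]]
    tt <- grid$n_trials[g]
    st1 <- rw_setting(pr[1], alpha_fit, tt, p_reward, sigma_eps,
                      beta_delta)
    st2 <- rw_setting(pr[2], alpha_fit, tt, p_reward, sigma_eps,
                      beta_delta)
    row <- data.frame(
      n_trials = tt, alpha_control = pr[1], alpha_patient = pr[2],
      d2_glm1 = effect_size_two_group(beta_stats_glm1(st1),
                                      beta_stats_glm1(st2), "delta")$d2,
      d2_neg_value = effect_size_two_group(
        beta_stats_glm2(st1), beta_stats_glm2(st2), "neg_value")$d2
    )
    if (n_reps > 0) {
      exact <- abs(tt * p_reward - round(tt * p_reward)) < 1e-8
      sim <- vapply(seq_len(n_reps), function(rp) {
        sd_seed <- child_seed(seed, g * 100000 + rp)
        sched <- make_conditioning_schedule(tt, p_reward, seed = sd_seed,
                                            exact_counts = exact)
        alphas <- rep(pr, each = n_per_group)
        sub <- rw_subject_betas(sched, alphas, alpha_fit, sigma_eps,
                                beta_delta,
                                noise_seed = child_seed(seed,
                                  g * 100000 + 50000 + rp))
        i1 <- seq_len(n_per_group); i2 <- n_per_group + i1
        c(cohens_d(sub$glm1_delta[i1], sub$glm1_delta[i2]),
          cohens_d(sub$glm2_neg_value[i1], sub$glm2_neg_value[i2]))
      }, numeric(2))
      row$sim_d_glm1 <- mean(sim[1, ])
      row$sim_se_glm1 <- stats::sd(sim[1, ]) / sqrt(n_reps)
      row$sim_d_neg_value <- mean(sim[2, ])
      row$sim_se_neg_value <- stats::sd(sim[2, ]) / sqrt(n_reps)
    }
    row
  })
  do.call(rbind, out)
}

#' Effect size of the misspecification bias vs number of reversals
#'
#' Repeats the misspecification experiment with different numbers of
#' reward-contingency reversals and summarizes the mean Cohen's d (with
#' standard errors) of the GLM1 prediction-error and GLM2
#' negative-value betas across replicates.  More reversals emphasize
#' the forgetting process and hence the spurious group difference, up
#' to the point where very frequent reversals blur the behavioral
#' difference between groups.
#'
#' @param reversal_grid numbers of reversals to test.
#' @param n_reps replicate experiments per condition.
#' @param fit_models fit models passed to [run_misspecification()]
#'   (misspecified standard model by default).
#' @param ... further arguments for [run_misspecification()].
#' @param seed master seed.
#' @return Data frame with mean and standard error of Cohen's d per
#'   condition and regressor.
#' @export
run_reversal_sweep <- function(reversal_grid = c(0, 1, 2, 5, 8, 17, 35),
                               n_reps = 100, fit_models = "standard",
                               seed = 1, ...) {
  out <- lapply(seq_along(reversal_grid), function(j) {
    k <- reversal_grid[j]
    ds <- vapply(seq_len(n_reps), function(rp) {
      res <- run_misspecification(n_reversals = k,
                                  fit_models = fit_models,
                                  seed = child_seed(seed,
                                    j * 100000 + rp), ...)
      rep1 <- res$report
      c(rep1$cohens_d[rep1$glm_kind == "glm1"][1],
        rep1$cohens_d[rep1$glm_kind == "glm2" &
                        rep1$regressor == "neg_value"][1])
    }, numeric(2))
    data.frame(n_reversals = k,
               d_glm1_delta = mean(ds[1, ]),
               se_glm1_delta = stats::sd(ds[1, ]) / sqrt(n_reps),
               d_glm2_neg_value = mean(ds[2, ]),
               se_glm2_neg_value = stats::sd(ds[2, ]) / sqrt(n_reps))
  })
  do.call(rbind, out)
}

#' Analytic effect-size surface over true learning-rate pairs
#'
#' Evaluates the closed-form two-group effect sizes on a grid of
#' (control, patient) true learning rates, with the analysis rate set
#' to the pair mean (the convention of the group-comparison
#' experiments) unless given explicitly.
#'
#' @param alpha_grid grid of true learning rates.
#' @param alpha_fit analysis learning rate; `NULL` means the mean of
#'   each pair.
#' @inheritParams run_group_comparison_rw
#' @return Data frame with `alpha_control`, `alpha_patient`,
#'   `alpha_fit`, `d2_glm1`, `d2_neg_value`.
#' @export
run_alpha_grid <- function(alpha_grid = seq(0.1, 0.9, by = 0.1),
                           alpha_fit = NULL, n_trials = 100,
                           p_reward = 0.4, sigma_eps = 0.5,
                           beta_delta = 1) {
  grid <- expand.grid(alpha_control = alpha_grid,
                      alpha_patient = alpha_grid)
  grid$alpha_fit <- if (is.null(alpha_fit)) {
    (grid$alpha_control + grid$alpha_patient) / 2
  } else alpha_fit
  d <- vapply(seq_len(nrow(grid)), function(i) {
    s1 <- rw_setting(grid$alpha_control[i], grid$alpha_fit[i], n_trials,
                     p_reward, sigma_eps, beta_delta)
    s2 <- rw_setting(grid$alpha_patient[i], grid$alpha_fit[i], n_trials,
                     p_reward, sigma_eps, beta_delta)
    c(effect_size_two_group(beta_stats_glm1(s1), beta_stats_glm1(s2),
                            "delta")$d2,
      effect_size_two_group(beta_stats_glm2(s1), beta_stats_glm2(s2),
                            "neg_value")$d2)
  }, numeric(2))
  grid$d2_glm1 <- d[1, ]
  grid$d2_neg_value <- d[2, ]
  grid
}
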