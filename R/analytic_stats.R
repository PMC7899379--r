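#' Analysis setting for the Rescorla-Wagner closed forms
#'
#' Bundles the quantities the closed-form beta statistics depend on: the
#' generating ("true") and analysis ("fit") learning rates and reward
#' sensitivities, the trial count, the fixed reward probability, the
#' noise level of the neural signal, and the ground-truth coefficients.
#' `beta_r` is the true reward coefficient in the reward/negative-value
#' parameterization; a signal generated purely from the prediction error
#' with coefficient `beta_delta` corresponds to `beta_r = beta_delta`.
#'
#' The closed forms are large-`n_trials` approximations (the initial
#' transient of the value process is ignored); treat results for fewer
#' than ~50 trials as approximate.
#'
#' @param alpha_true,alpha_fit generating and analysis learning rates,
#'   in \[0, 1\].
#' @param n_trials number of trials.
#' @param p_reward fixed reward probability, strictly inside (0, 1).
#' @param sigma_eps noise standard deviation of the neural signal.
#' @param beta_delta true prediction-error coefficient.
#' @param beta_r true reward coefficient (defaults to `beta_delta`,
#'   the value implied by a purely prediction-error-driven signal).
#' @param rho_true,rho_fit generating and analysis reward sensitivities.
#' @return An object of class `"rw_setting"`.
#' @export
rw_setting <- function(alpha_true, alpha_fit, n_trials, p_reward,
                       sigma_eps = 0.5, beta_delta = 1,
                       beta_r = beta_delta, rho_true = 1, rho_fit = 1) {
  for (a in c(alpha_true, alpha_fit)) {
    if (a < 0 || a > 1) stop("learning rates must be in [0, 1]",
                             call. = FALSE)
  }
  if (rho_true <= 0 || rho_fit <= 0) {
    stop("reward sensitivities must be positive", call. = FALSE)
  }
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  stop_if_not_prob(p_reward, "p_reward")
  structure(
    list(alpha_true = alpha_true, alpha_fit = alpha_fit,
         n_trials = n_trials, p_reward = p_reward, sigma_eps = sigma_eps,
         beta_delta = beta_delta, beta_r = beta_r,
         rho_true = rho_true, rho_fit = rho_fit),
    class = "rw_setting"
  )
}

#' Closed-form cross moments of the Rescorla-Wagner regressors
#'
#' Long-run (centered) sums of squares and cross products of the true
#' and refit prediction errors, values and the reward sequence under a
#' fixed reward probability, e.g.
#' \deqn{S(\hat\delta,\hat\delta) = T \frac{2}{2-\hat\alpha}
#'   p_r(1-p_r)\hat\rho^2, \quad
#'   S(\delta,\hat\delta) = T \frac{\alpha^*+\hat\alpha}
#'   {\alpha^*+\hat\alpha-\alpha^*\hat\alpha} p_r(1-p_r)\rho^*\hat\rho,}
#' together with the value moments
#' \eqn{S(\hat V,\hat V) = T \hat\alpha/(2-\hat\alpha) p_r(1-p_r)
#' \hat\rho^2} and \eqn{S(V,\hat V) = T \alpha^*\hat\alpha /
#' (\alpha^*+\hat\alpha-\alpha^*\hat\alpha) p_r(1-p_r)\rho^*\hat\rho},
#' and \eqn{S(r,-\hat V) \approx 0}.  All scale linearly in the trial
#' count.
#'
#' @param setting an [rw_setting()].
#' @return Named list with elements `S_dhat_dhat`, `S_d_dhat`,
#'   `S_dhat_r`, `S_d_r`, `S_r_r`, `S_r_nVhat`, `S_nVhat_nVhat`,
#'   `S_nV_nVhat`.
#' @export
rw_moments <- function(setting) {
  s <- setting
  if (s$p_reward <= 0 || s$p_reward >= 1) {
    stop("`p_reward` must be strictly between 0 and 1 (degenerate ",
         "reward variance otherwise)", call. = FALSE)
  }
  c0 <- s$n_trials * s$p_reward * (1 - s$p_reward)
  at <- s$alpha_true; ah <- s$alpha_fit
  rt <- s$rho_true; rh <- s$rho_fit
  denom <- at + ah - at * ah
  list(
    S_dhat_dhat  = c0 * 2 / (2 - ah) * rh^2,
    S_d_dhat     = c0 * (at + ah) / denom * rt * rh,
    S_dhat_r     = c0 * rh,
    S_d_r        = c0 * rt,
    S_r_r        = c0,
    S_r_nVhat    = 0,
    S_nVhat_nVhat = c0 * ah / (2 - ah) * rh^2,
    S_nV_nVhat   = c0 * at * ah / denom * rt * rh
  )
}

new_beta_stats <- function(expected, variance, glm_kind, setting) {
  if (any(variance < 0)) stop("negative variance", call. = FALSE)
  structure(list(expected = expected, variance = variance,
                 glm_kind = glm_kind, setting = setting),
            class = "beta_stats")
}

#' @export
print.beta_stats <- function(x, ...) {
  cat("Closed-form beta statistics (", x$glm_kind, ")\n", sep = "")
  print(rbind(expected = x$expected, variance = x$variance))
  invisible(x)
}

#' Expected value and variance of the prediction-error beta in GLM1
#'
#' For the single-regressor GLM (prediction error only):
#' \deqn{E[\hat\beta_\delta] = \frac{(2-\hat\alpha)(\alpha^*+\hat\alpha)}
#'   {2(\alpha^*+\hat\alpha-\alpha^*\hat\alpha)}
#'   \frac{\rho^*}{\hat\rho}\beta_\delta, \qquad
#'   Var[\hat\beta_\delta] = \frac{(2-\hat\alpha)\sigma_\epsilon^2}
#'   {2 T p_r (1-p_r)\hat\rho^2}.}
#' The estimate is unbiased exactly when the analysis parameters match
#' the generating ones.
#'
#' @param setting an [rw_setting()].
#' @return A `"beta_stats"` object with the `delta` regressor.
#' @export
beta_stats_glm1 <- function(setting) {
  s <- setting
  m <- rw_moments(s)
  E <- c(delta = unname(m$S_d_dhat / m$S_dhat_dhat * s$beta_delta))
  V <- c(delta = unname(s$sigma_eps^2 / m$S_dhat_dhat))
  new_beta_stats(E, V, "glm1", s)
}

#' Beta statistics for GLM2 (reward and negative value)
#'
#' With reward and the (refit) negative value as regressors:
#' \deqn{E[\hat\beta_{NV}] = \frac{\alpha^*(2-\hat\alpha)}
#'   {\alpha^*+\hat\alpha-\alpha^*\hat\alpha}
#'   \frac{\rho^*}{\hat\rho}\beta_\delta, \qquad
#'   Var[\hat\beta_{NV}] = \frac{(2-\hat\alpha)\sigma_\epsilon^2}
#'   {T\hat\alpha\, p_r(1-p_r)\hat\rho^2},}
#' \deqn{E[\hat\beta_r] = \beta_r\rho^*, \qquad
#'   Var[\hat\beta_r] = \frac{\sigma_\epsilon^2}{T p_r(1-p_r)}.}
#' The reward beta does not depend on either learning rate, which is why
#' its group difference vanishes under learning-rate misfit.
#'
#' @param setting an [rw_setting()].
#' @return A `"beta_stats"` object with regressors `reward`,
#'   `neg_value`.
#' @export
beta_stats_glm2 <- function(setting) {
  s <- setting
  if (s$alpha_fit == 0) {
    stop("`alpha_fit` = 0: the refit value is constant and the ",
         "negative-value beta is undefined", call. = FALSE)
  }
  m <- rw_moments(s)
  # S(r, -Vhat) ~ 0, so each beta reduces to its simple-regression form
  E <- c(reward = s$beta_r * s$rho_true,
         neg_value = unname(m$S_nV_nVhat / m$S_nVhat_nVhat * s$beta_delta))
  V <- c(reward = unname(s$sigma_eps^2 / m$S_r_r),
         neg_value = unname(s$sigma_eps^2 / m$S_nVhat_nVhat))
  new_beta_stats(E, V, "glm2", s)
}

#' Beta statistics for GLM2' (reward and prediction error)
#'
#' The prediction-error beta of GLM2' has exactly the statistics of the
#' negative-value beta of GLM2.  The reward beta absorbs the
#' learning-rate misfit:
#' \deqn{E[\hat\beta_{r'}] = \frac{\hat\alpha-\alpha^*}
#'   {\alpha^*+\hat\alpha-\alpha^*\hat\alpha}\rho^*\beta_\delta +
#'   \beta_r\rho^*, \qquad
#'   Var[\hat\beta_{r'}] = \frac{2\sigma_\epsilon^2}
#'   {T\hat\alpha\, p_r(1-p_r)},}
#' so it is unbiased for \eqn{\beta_r\rho^*} only when the learning
#' rates match, and its variance exceeds the GLM2 reward variance (the
#' multicollinearity of reward and prediction error).
#'
#' @param setting an [rw_setting()].
#' @return A `"beta_stats"` object with regressors `reward`, `delta`.
#' @export
beta_stats_glm2prime <- function(setting) {
  s <- setting
  if (s$alpha_fit == 0) {
    stop("`alpha_fit` = 0: reward and refit prediction error are ",
         "collinear and the fit is undefined", call. = FALSE)
  }
  g2 <- beta_stats_glm2(s)
  at <- s$alpha_true; ah <- s$alpha_fit
  denom <- at + ah - at * ah
  E <- c(reward = (ah - at) / denom * s$rho_true * s$beta_delta +
           s$beta_r * s$rho_true,
         delta = unname(g2$expected["neg_value"]))
  V <- c(reward = 2 * s$sigma_eps^2 /
           (s$n_trials * ah * s$p_reward * (1 - s$p_reward)),
         delta = unname(g2$variance["neg_value"]))
  new_beta_stats(E, V, "glm2prime", s)
}

#' Beta statistics for an arbitrary pair of fit/true designs
#'
#' Matrix form of the expectation and covariance of OLS estimates when
#' the signal is generated from ground-truth regressors \eqn{X^*} but
#' fit with regressors \eqn{X}:
#' \deqn{E[\hat\beta] = (X'X)^{-1}X'X^*\beta, \qquad
#'   Cov[\hat\beta] = \sigma_\epsilon^2 (X'X)^{-1}.}
#' Columns are mean-centered by default, matching the convention of the
#' closed forms (equivalent to including an intercept).  With a single
#' column this reduces to
#' \eqn{E[\hat\beta_1] = Cor(x_1, x_1^*)\sqrt{S(x_1^*,x_1^*)/S(x_1,x_1)}
#' \beta_1}.
#'
#' @param design_fit,design_true numeric matrices with matching rows.
#' @param beta_true true coefficient per column of `design_true`.
#' @param sigma_eps noise standard deviation.
#' @param center logical; mean-center all columns first.
#' @return A `"beta_stats"` object (plus the full `covariance` matrix).
#' @export
beta_stats_general <- function(design_fit, design_true, beta_true,
                               sigma_eps, center = TRUE) {
  X <- as.matrix(design_fit)
  Xs <- as.matrix(design_true)
  if (nrow(X) != nrow(Xs)) {
    stop("fit and true designs must have the same number of rows",
         call. = FALSE)
  }
  if (length(beta_true) != ncol(Xs)) {
    stop("`beta_true` must have one entry per true regressor",
         call. = FALSE)
  }
  if (center) {
    X <- scale(X, center = TRUE, scale = FALSE)
    Xs <- scale(Xs, center = TRUE, scale = FALSE)
  }
  XtX <- crossprod(X)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    stop("fit design is (numerically) singular", call. = FALSE)
  }
  E <- drop(solve(XtX, crossprod(X, Xs) %*% beta_true))
  Cov <- sigma_eps^2 * solve(XtX)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  names(E) <- nm
  out <- new_beta_stats(E, stats::setNames(diag(Cov), nm), "general",
                        NULL)
  out$covariance <- Cov
  out
}

#' Two-group standardized effect size of a beta value
#'
#' \deqn{d_2 = \frac{E[\hat\beta^{(1)}] - E[\hat\beta^{(2)}]}
#'   {\sqrt{(Var[\hat\beta^{(1)}] + Var[\hat\beta^{(2)}])/2}}.}
#' By convention group 1 is the control group, so a positive \eqn{d_2}
#' means the beta value is diminished in the patient group.
#'
#' @param stats1,stats2 `"beta_stats"` for group 1 (control) and
#'   group 2 (patient); must share `glm_kind`.
#' @param regressor name of the regressor to compare.
#' @return An `"effect_size"` list with elements `d2`, `regressor`,
#'   `glm_kind`, `groups`.
#' @export
effect_size_two_group <- function(stats1, stats2, regressor) {
  if (!identical(stats1$glm_kind, stats2$glm_kind)) {
    stop("both groups must use the same GLM", call. = FALSE)
  }
  if (!regressor %in% names(stats1$expected) ||
      !regressor %in% names(stats2$expected)) {
    stop("regressor `", regressor, "` not present in both groups",
         call. = FALSE)
  }
  v1 <- stats1$variance[[regressor]]
  v2 <- stats2$variance[[regressor]]
  if (v1 + v2 == 0) stop("zero variance in both groups", call. = FALSE)
  d2 <- (stats1$expected[[regressor]] - stats2$expected[[regressor]]) /
    sqrt((v1 + v2) / 2)
  structure(list(d2 = d2, regressor = regressor,
                 glm_kind = stats1$glm_kind,
                 groups = list(stats1$setting, stats2$setting)),
            class = "effect_size")
}

#' One-group standardized effect size of a beta value
#'
#' \eqn{d_1 = E[\hat\beta] / \sqrt{Var[\hat\beta]}}, the effect size of
#' the second-level one-sample t-test against zero.
#'
#' @param stats a `"beta_stats"` object.
#' @param regressor regressor name.
#' @return An `"effect_size"` list with element `d1`.
#' @export
effect_size_one_group <- function(stats, regressor) {
  if (!regressor %in% names(stats$expected)) {
    stop("unknown regressor `", regressor, "`", call. = FALSE)
  }
  v <- stats$variance[[regressor]]
  if (v == 0) stop("zero variance", call. = FALSE)
  structure(list(d1 = stats$expected[[regressor]] / sqrt(v),
                 regressor = regressor, glm_kind = stats$glm_kind,
                 groups = list(stats$setting)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  lab <- if (!is.null(x$d2)) c("d2", x$d2) else c("d1", x$d1)
  cat(lab[1], "=", format(as.numeric(lab[2]), digits = 4), "for",
      x$regressor, "in", x$glm_kind, "\n")
  invisible(x)
}

power_t <- function(lambda, df, alpha_sig) {
  if (alpha_sig <= 0 || alpha_sig >= 1) {
    stop("`alpha_sig` must be in (0, 1)", call. = FALSE)
  }
  q <- stats::qt(1 - alpha_sig / 2, df)
  (1 - stats::pt(q, df, ncp = lambda)) + stats::pt(-q, df, ncp = lambda)
}

#' Power of the two-sided two-sample t-test for a beta value
#'
#' Under equal population variances the test statistic follows a
#' noncentral t-distribution with \eqn{n_1 + n_2 - 2} degrees of freedom
#' and noncentrality \eqn{\lambda = d_2\sqrt{n_1 n_2/(n_1+n_2)}}.
#'
#' @param d2 two-group effect size (numeric, or an
#'   [effect_size_two_group()] result).
#' @param n1,n2 subjects per group (>= 2).
#' @param alpha_sig two-sided significance level.
#' @return A `"power_result"` list: `power`, `lambda`, `df`,
#'   `alpha_sig`, `n1`, `n2`.
#' @examples
#' power_two_sample(0.64, 20, 20)$power  # ~0.50
#' @export
power_two_sample <- function(d2, n1, n2, alpha_sig = 0.05) {
  if (inherits(d2, "effect_size")) d2 <- d2$d2
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group",
                             call. = FALSE)
  df <- n1 + n2 - 2
  lambda <- d2 * sqrt(n1 * n2 / (n1 + n2))
  structure(list(power = power_t(lambda, df, alpha_sig),
                 lambda = lambda, df = df, alpha_sig = alpha_sig,
                 n1 = n1, n2 = n2),
            class = "power_result")
}

#' Power of the two-sided one-sample t-test for a beta value
#'
#' Noncentral-t power with \eqn{n - 1} degrees of freedom and
#' noncentrality \eqn{\lambda = d_1\sqrt{n}}.
#'
#' @param d1 one-group effect size (numeric or `effect_size`).
#' @param n number of subjects (>= 2).
#' @param alpha_sig two-sided significance level.
#' @return A `"power_result"` list.
#' @export
power_one_sample <- function(d1, n, alpha_sig = 0.05) {
  if (inherits(d1, "effect_size")) d1 <- d1$d1
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  lambda <- d1 * sqrt(n)
  structure(list(power = power_t(lambda, n - 1, alpha_sig),
                 lambda = lambda, df = n - 1, alpha_sig = alpha_sig,
                 n = n),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power = %.3f (lambda = %.3f, df = %d, alpha = %g)\n",
              x$power, x$lambda, x$df, x$alpha_sig))
  invisible(x)
}
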