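#' Simulate the Rescorla-Wagner model on a fixed reward sequence
#'
#' Runs the delta-rule value update forward over a passively experienced
#' reward sequence:
#' \deqn{\delta_t = \rho r_t - V_t, \qquad V_{t+1} = V_t + \alpha \delta_t,}
#' where \eqn{\alpha} is the learning rate and \eqn{\rho} an optional
#' reward-sensitivity scaling of the prediction error.  `V[t]` is the
#' value *before* the trial-t update, i.e., the quantity a trial-wise
#' regressor would use.
#'
#' @param rewards a numeric 0/1 vector or a
#'   [make_conditioning_schedule()] object.
#' @param alpha learning rate in \[0, 1\].
#' @param rho reward sensitivity (> 0, default 1).
#' @param v_init initial value \eqn{V_1} (default 0).
#' @return A `"latent_trajectory"` data frame with columns `trial`,
#'   `reward`, `V`, `delta`, and the generating parameters in
#'   `attr(, "params")`.
#' @examples
#' tr <- simulate_rw(make_conditioning_schedule(100, 0.4, seed = 1),
#'                   alpha = 0.5)
#' all.equal(tr$delta + tr$V, tr$reward)  # conservation identity
#' @export
simulate_rw <- function(rewards, alpha, rho = 1, v_init = 0) {
  if (inherits(rewards, "conditioning_schedule")) rewards <- rewards$rewards
  if (length(rewards) < 1L) stop("`rewards` must be non-empty", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  if (rho <= 0) stop("`rho` must be positive", call. = FALSE)
  n <- length(rewards)
  # V_{t+1} = (1 - alpha) V_t + alpha * rho * r_t is a first-order
  # recursive filter, so the whole trajectory vectorizes.
  post <- stats::filter(alpha * rho * rewards, 1 - alpha,
                        method = "recursive", init = v_init)
  V <- c(v_init, as.numeric(post)[-n])
  delta <- rho * rewards - V
  out <- data.frame(trial = seq_len(n), reward = rewards, V = V,
                    delta = delta)
  attr(out, "params") <- list(alpha = alpha, rho = rho, v_init = v_init,
                              model = "rw")
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

#' Simulate the two-armed RL model with forgetting
#'
#' Generates choices and rewards online from a Q-learning agent on a
#' bandit schedule.  The chosen option is updated by the delta rule; the
#' unchosen option's value decays towards the default value `mu` at the
#' forgetting rate `phi` (`phi = 0` recovers the standard model).
#' Choices follow a two-option softmax with inverse temperature
#' `beta_it`.  Both action values start at `mu`.
#'
#' @param schedule a [make_reversal_schedule()] object.
#' @param alpha learning rate in \[0, 1\].
#' @param beta_it softmax inverse temperature (>= 0).
#' @param phi forgetting rate in \[0, 1\].
#' @param mu default value the unchosen option decays towards.
#' @param seed optional integer seed.
#' @return A `"choice_data"` data frame with columns `trial`, `choice`,
#'   `reward`, `V1`, `V2` (values before the trial's update), `V`
#'   (chosen option's value) and `delta` (prediction error of the
#'   experienced outcome); parameters in `attr(, "params")`.
#' @export
simulate_forgetting_rl <- function(schedule, alpha, beta_it, phi,
                                   mu = 0.5, seed = NULL) {
  if (!inherits(schedule, "bandit_schedule")) {
    stop("`schedule` must be a bandit_schedule", call. = FALSE)
  }
  check_rl_params(alpha, beta_it, phi)
  sim <- with_seed(seed,
    rl_simulate_cpp(schedule$reward_probs, alpha, beta_it, phi, mu))
  out <- data.frame(trial = seq_len(schedule$n_trials),
                    choice = sim$choice, reward = sim$reward,
                    V1 = sim$V[, 1L], V2 = sim$V[, 2L],
                    V = sim$v_chosen, delta = sim$delta)
  attr(out, "params") <- list(alpha = alpha, beta_it = beta_it, phi = phi,
                              mu = mu, model = "forgetting")
  attr(out, "schedule") <- schedule
  class(out) <- c("choice_data", "latent_trajectory", "data.frame")
  out
}

#' Recompute latent values and prediction errors from observed behavior
#'
#' Replays a fixed sequence of choices and rewards through the learning
#' rule with the supplied (e.g., fitted or common) parameters, yielding
#' the regressors a model-based analysis would construct.  With
#' `model = "standard"` the forgetting rate is forced to 0, so the
#' unchosen option's value is frozen between its own choices.
#'
#' @param data a `"choice_data"` object, or a data frame with `choice`
#'   and `reward` columns.
#' @param alpha learning rate.
#' @param phi forgetting rate (ignored and forced to 0 for
#'   `model = "standard"`).
#' @param mu default/initial value.
#' @param model `"standard"` or `"forgetting"`.
#' @return A `"latent_trajectory"` data frame with columns `trial`,
#'   `choice`, `reward`, `V1`, `V2`, `V` (chosen option, pre-update) and
#'   `delta`.
#' @export
recompute_latents <- function(data, alpha, phi = 0, mu = 0.5,
                              model = c("forgetting", "standard")) {
  model <- match.arg(model)
  if (model == "standard") phi <- 0
  choice <- data$choice
  reward <- data$reward
  if (is.null(choice) || is.null(reward) ||
      length(choice) != length(reward)) {
    stop("`data` must provide equal-length `choice` and `reward` columns",
         call. = FALSE)
  }
  check_rl_params(alpha, 1, phi)
  lat <- rl_latents_cpp(as.integer(choice), as.numeric(reward),
                        alpha, phi, mu)
  out <- data.frame(trial = seq_along(choice), choice = choice,
                    reward = reward, V1 = lat$V[, 1L], V2 = lat$V[, 2L],
                    V = lat$v_chosen, delta = lat$delta)
  attr(out, "params") <- list(alpha = alpha, phi = phi, mu = mu,
                              model = model)
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

check_rl_params <- function(alpha, beta_it, phi) {
  if (any(is.na(c(alpha, beta_it, phi)))) {
    stop("model parameters must not be NA", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must be in [0, 1]", call. = FALSE)
  if (beta_it < 0) stop("`beta_it` must be >= 0", call. = FALSE)
  invisible(TRUE)
}
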