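#' Reward schedule for a classical conditioning task
#'
#' Builds the per-trial reward sequence of a conditioning paradigm in
#' which a reward (`1`) or no reward (`0`) is delivered passively on each
#' trial with nominal probability `p_reward`.  With
#' `exact_counts = TRUE` the sequence is a seeded permutation of a fixed
#' multiset containing exactly `round(n_trials * p_reward)` rewards
#' (e.g., 40 rewards shuffled among 100 trials), so every seed yields the
#' same reward total; otherwise each trial is an independent
#' Bernoulli(`p_reward`) draw.
#'
#' @param n_trials number of trials (>= 1).
#' @param p_reward nominal reward probability, in \[0, 1\].
#' @param seed optional integer seed; the caller's RNG state is left
#'   untouched.  `NULL` draws from the current RNG stream.
#' @param exact_counts logical; construct the sequence with an exact
#'   reward count (requires `n_trials * p_reward` to be an integer).
#' @return An object of class `"conditioning_schedule"`: a list with
#'   elements `rewards` (integer 0/1 vector of length `n_trials`),
#'   `n_trials`, `p_reward`, `seed` and `exact_counts`.
#' @examples
#' sched <- make_conditioning_schedule(100, 0.4, seed = 1)
#' sum(sched$rewards)  # exactly 40
#' @export
make_conditioning_schedule <- function(n_trials, p_reward, seed = NULL,
                                       exact_counts = TRUE) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials != round(n_trials)) {
    stop("`n_trials` must be a single integer >= 1", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  stop_if_not_prob(p_reward, "p_reward")
  if (exact_counts) {
    n_rew <- n_trials * p_reward
    if (abs(n_rew - round(n_rew)) > 1e-8) {
      stop("with `exact_counts = TRUE`, `n_trials * p_reward` must be an ",
           "integer (got ", n_trials, " * ", p_reward, " = ", n_rew, ")",
           call. = FALSE)
    }
    n_rew <- as.integer(round(n_rew))
    base <- rep(c(1L, 0L), c(n_rew, n_trials - n_rew))
    rewards <- with_seed(seed, sample(base))
  } else {
    rewards <- with_seed(seed, stats::rbinom(n_trials, 1L, p_reward))
  }
  structure(
    list(rewards = as.integer(rewards), n_trials = n_trials,
         p_reward = p_reward, seed = seed, exact_counts = exact_counts),
    class = "conditioning_schedule"
  )
}

#' @export
as.data.frame.conditioning_schedule <- function(x, ...) {
  data.frame(trial = seq_len(x$n_trials), reward = x$rewards)
}

#' @export
print.conditioning_schedule <- function(x, ...) {
  cat("Conditioning schedule:", x$n_trials, "trials, p_reward =",
      x$p_reward, if (x$exact_counts) "(exact counts)" else "(Bernoulli)",
      "\n  rewards delivered:", sum(x$rewards), "\n")
  invisible(x)
}

#' Reward-probability schedule for a two-armed reversal learning task
#'
#' Constructs the per-trial reward probabilities of a probabilistic
#' reversal learning task.  At every trial one option carries the high
#' contingency `p_high` and the other the low contingency `p_low`;
#' option 1 starts high.  The `n_reversals` contingency swaps are placed
#' at equal spacing `floor(n_trials / (n_reversals + 1))`, so one
#' reversal in a 180-trial task happens after trial 90.
#'
#' @param n_trials number of trials.
#' @param p_high,p_low the two reward-probability levels.
#' @param n_reversals number of contingency reversals (>= 0 and
#'   < `n_trials`).
#' @return An object of class `"bandit_schedule"`: a list with
#'   `reward_probs` (`n_trials` x 2 matrix), `reversal_trials` (last
#'   trial index of each block before a swap), `p_high`, `p_low`.
#' @examples
#' sched <- make_reversal_schedule(180, 0.8, 0.2, n_reversals = 1)
#' sched$reward_probs[c(90, 91), ]
#' @export
make_reversal_schedule <- function(n_trials, p_high, p_low, n_reversals = 1) {
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a single integer >= 1", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  stop_if_not_prob(p_high, "p_high")
  stop_if_not_prob(p_low, "p_low")
  if (n_reversals < 0 || n_reversals != round(n_reversals)) {
    stop("`n_reversals` must be a non-negative integer", call. = FALSE)
  }
  if (n_reversals >= n_trials) {
    stop("`n_reversals` must be smaller than `n_trials`", call. = FALSE)
  }
  n_reversals <- as.integer(n_reversals)
  block <- n_trials %/% (n_reversals + 1L)
  reversal_trials <- if (n_reversals > 0L) block * seq_len(n_reversals)
                     else integer(0)
  # block index of each trial; blocks alternate which option is high
  idx <- findInterval(seq_len(n_trials) - 1L, reversal_trials)
  opt1_high <- idx %% 2L == 0L
  probs <- cbind(opt1 = ifelse(opt1_high, p_high, p_low),
                 opt2 = ifelse(opt1_high, p_low, p_high))
  structure(
    list(reward_probs = probs, reversal_trials = reversal_trials,
         p_high = p_high, p_low = p_low, n_trials = n_trials),
    class = "bandit_schedule"
  )
}

#' @export
as.data.frame.bandit_schedule <- function(x, ...) {
  data.frame(trial = seq_len(x$n_trials),
             p_opt1 = x$reward_probs[, 1L],
             p_opt2 = x$reward_probs[, 2L])
}

#' @export
print.bandit_schedule <- function(x, ...) {
  cat("Bandit schedule:", x$n_trials, "trials, contingencies",
      x$p_high, "/", x$p_low, "with", length(x$reversal_trials),
      "reversal(s)\n")
  invisible(x)
}

#' Draw a single reward outcome from a bandit schedule
#'
#' Bernoulli draw with the scheduled reward probability of the chosen
#' option at the given trial, using the current RNG stream.
#'
#' @param schedule a [make_reversal_schedule()] object.
#' @param trial 1-based trial index.
#' @param choice option index, 1 or 2.
#' @return 0 or 1.
#' @export
sample_outcome <- function(schedule, trial, choice) {
  if (!inherits(schedule, "bandit_schedule")) {
    stop("`schedule` must be a bandit_schedule", call. = FALSE)
  }
  if (length(trial) != 1L || trial < 1 || trial > schedule$n_trials) {
    stop("`trial` must be a single index in 1..", schedule$n_trials,
         call. = FALSE)
  }
  if (!choice %in% c(1L, 2L)) {
    stop("`choice` must be 1 or 2", call. = FALSE)
  }
  stats::rbinom(1L, 1L, schedule$reward_probs[trial, choice])
}
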