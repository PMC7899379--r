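# Shared fixtures built in code.

# Small reversal task + forgetting agent used across behavioral tests.
make_test_behavior <- function(n_trials = 180, phi = 0.4, alpha = 0.5,
                               beta_it = 4, seed = 101) {
  sched <- make_reversal_schedule(n_trials, 0.8, 0.2, n_reversals = 1)
  simulate_forgetting_rl(sched, alpha = alpha, beta_it = beta_it,
                         phi = phi, seed = seed)
}

# |x - target| <= 3 * se, the Monte-Carlo agreement criterion.
expect_within_3se <- function(x, target, se) {
  expect_lt(abs(x - target), 3 * se)
}
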