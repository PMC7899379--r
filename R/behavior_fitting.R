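#' Negative log-likelihood of choice data under a Q-learning model
#'
#' \eqn{-\sum_t \log P(\mathrm{choice}_t)} with choice probabilities
#' from the two-option softmax and action values replayed forward from
#' the observed choices and rewards.  `model = "standard"` forces the
#' forgetting rate to zero.  Probabilities are floored at `1e-30`, so
#' the objective is finite for any finite inverse temperature.
#'
#' @param data `"choice_data"` or a data frame with `choice` (1/2) and
#'   `reward` (0/1) columns.
#' @param alpha learning rate.
#' @param beta_it softmax inverse temperature.
#' @param phi forgetting rate (forced to 0 for the standard model).
#' @param mu default/initial value.
#' @param model `"standard"` or `"forgetting"`.
#' @return The negative log-likelihood in nats (single number).
#' @examples
#' # with beta_it = 0 every choice has probability 1/2
#' d <- data.frame(choice = c(1, 2, 1), reward = c(1, 0, 1))
#' negative_log_likelihood(d, alpha = 0.3, beta_it = 0)  # 3 * log(2)
#' @export
negative_log_likelihood <- function(data, alpha, beta_it, phi = 0,
                                    mu = 0.5,
                                    model = c("forgetting", "standard")) {
  model <- match.arg(model)
  if (model == "standard") phi <- 0
  check_rl_params(alpha, beta_it, phi)
  if (length(data$choice) != length(data$reward)) {
    stop("`choice` and `reward` must have equal length", call. = FALSE)
  }
  rl_nll_cpp(as.integer(data$choice), as.numeric(data$reward),
             alpha, beta_it, phi, mu)
}

#' Maximum-likelihood fit of a Q-learning model to choice data
#'
#' Minimizes [negative_log_likelihood()] with a box-constrained
#' quasi-Newton optimizer (`optim(method = "L-BFGS-B")`), restarted from
#' `n_restarts` random initial points drawn uniformly within the bounds;
#' the restart with the lowest objective wins.  The default value `mu`
#' is fixed, not estimated.
#'
#' @param data `"choice_data"` or a data frame with `choice` and
#'   `reward`.
#' @param model `"standard"` (alpha, beta_it) or `"forgetting"`
#'   (alpha, beta_it, phi).
#' @param n_restarts number of random restarts (default 10).
#' @param bounds named list of `c(lower, upper)` for `alpha`, `beta_it`
#'   and (forgetting model) `phi`.
#' @param mu fixed default value.
#' @param seed optional integer seed for the restart initial values.
#' @return A `"fit_result"` list: `params` (named vector `alpha`,
#'   `beta_it`, `phi`), `nll`, `model`, `n_restarts`, `restart_nlls`,
#'   `converged` (TRUE if any restart converged; the best point is
#'   returned regardless).
#' @export
fit_mle <- function(data, model = c("forgetting", "standard"),
                    n_restarts = 10,
                    bounds = list(alpha = c(0, 1), beta_it = c(0, 20),
                                  phi = c(0, 1)),
                    mu = 0.5, seed = NULL) {
  model <- match.arg(model)
  if (n_restarts < 1) stop("`n_restarts` must be >= 1", call. = FALSE)
  choice <- as.integer(data$choice)
  reward <- as.numeric(data$reward)
  if (length(choice) != length(reward)) {
    stop("`choice` and `reward` must have equal length", call. = FALSE)
  }
  free <- if (model == "forgetting") c("alpha", "beta_it", "phi")
          else c("alpha", "beta_it")
  lo <- vapply(bounds[free], `[`, numeric(1), 1L)
  hi <- vapply(bounds[free], `[`, numeric(1), 2L)
  obj <- function(par) {
    phi <- if (model == "forgetting") par[[3L]] else 0
    rl_nll_cpp(choice, reward, par[[1L]], par[[2L]], phi, mu)
  }
  inits <- with_seed(seed, matrix(stats::runif(n_restarts * length(free),
                                               rep(lo, each = n_restarts),
                                               rep(hi, each = n_restarts)),
                                  nrow = n_restarts))
  best <- NULL
  restart_nlls <- numeric(n_restarts)
  any_conv <- FALSE
  for (k in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(inits[k, ], obj, method = "L-BFGS-B",
                   lower = lo, upper = hi),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      restart_nlls[k] <- Inf
      next
    }
    restart_nlls[k] <- fit$value
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)
  params <- c(alpha = best$par[[1L]], beta_it = best$par[[2L]],
              phi = if (model == "forgetting") best$par[[3L]] else 0)
  structure(
    list(params = params, nll = best$value, model = model,
         n_restarts = n_restarts, restart_nlls = restart_nlls,
         converged = any_conv, mu = mu),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MLE (", x$model, " model), nll = ", format(x$nll, digits = 6),
      if (!x$converged) " [no restart converged]", "\n", sep = "")
  print(round(x$params, 4))
  invisible(x)
}
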