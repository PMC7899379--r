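#' Assemble a trial-wise GLM design from a latent trajectory
#'
#' Builds the named regressor matrix of the GLM variants used for
#' model-based analysis of a trial-wise neural signal:
#' \describe{
#'   \item{`glm1`}{prediction error only (`delta`).}
#'   \item{`glm2`}{reward and negative value (`reward`, `neg_value`).}
#'   \item{`glm2prime`}{reward and prediction error (`reward`, `delta`).}
#'   \item{`value`}{value only (`value`).}
#' }
#' For bandit tasks the value/prediction-error columns refer to the
#' chosen option, the only one for which an experienced outcome (and
#' hence a prediction error) exists.  Regressors live in trial space and
#' are not convolved, centered or rescaled by default.
#'
#' @param trajectory a `"latent_trajectory"` (from [simulate_rw()],
#'   [simulate_forgetting_rl()] or [recompute_latents()]).
#' @param glm_kind one of `"glm1"`, `"glm2"`, `"glm2prime"`, `"value"`.
#' @param zscore logical; scale each regressor to unit sample standard
#'   deviation (off by default, and off in all replication presets).
#' @return A numeric matrix with named columns and attribute
#'   `"glm_kind"`.
#' @export
build_design <- function(trajectory,
                         glm_kind = c("glm1", "glm2", "glm2prime", "value"),
                         zscore = FALSE) {
  glm_kind <- match.arg(glm_kind)
  X <- switch(glm_kind,
    glm1      = cbind(delta = trajectory$delta),
    glm2      = cbind(reward = as.numeric(trajectory$reward),
                      neg_value = -trajectory$V),
    glm2prime = cbind(reward = as.numeric(trajectory$reward),
                      delta = trajectory$delta),
    value     = cbind(value = trajectory$V)
  )
  if (zscore) X <- sweep(X, 2L, apply(X, 2L, stats::sd), "/")
  attr(X, "glm_kind") <- glm_kind
  X
}

#' Generate a synthetic neural signal from a ground-truth GLM
#'
#' Draws \eqn{y_t = \sum_i \beta_i x^*_{ti} + \epsilon_t} with i.i.d.
#' Gaussian noise of standard deviation `sigma_eps`, where the
#' \eqn{x^*} are ground-truth regressors (e.g., the prediction errors of
#' the generating agent).
#'
#' @param design numeric matrix of ground-truth regressors (columns).
#' @param beta_true coefficient per column of `design`; recycled if a
#'   single value.
#' @param sigma_eps noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return Numeric vector `y` of length `nrow(design)` with attributes
#'   `beta_true` and `sigma_eps`.
#' @export
generate_signal <- function(design, beta_true, sigma_eps, seed = NULL) {
  design <- as.matrix(design)
  if (length(beta_true) == 1L) beta_true <- rep(beta_true, ncol(design))
  if (length(beta_true) != ncol(design)) {
    stop("`beta_true` must have one coefficient per regressor",
         call. = FALSE)
  }
  if (sigma_eps < 0) stop("`sigma_eps` must be >= 0", call. = FALSE)
  n <- nrow(design)
  y <- as.numeric(design %*% beta_true) +
    with_seed(seed, stats::rnorm(n, 0, sigma_eps))
  attr(y, "beta_true") <- beta_true
  attr(y, "sigma_eps") <- sigma_eps
  y
}

#' Ordinary least squares fit of a trial-wise GLM
#'
#' Exact least-squares estimates of the regression coefficients ("beta
#' values") of each named regressor.  An intercept is included by
#' default instead of mean-centering the variables.  `y` may be a matrix
#' with one column per subject/replicate sharing the same design, in
#' which case a coefficient matrix is returned.
#'
#' @param y numeric vector (length `nrow(design)`) or matrix of signals.
#' @param design named regressor matrix, e.g. from [build_design()].
#' @param include_intercept logical.
#' @return A `"glm_fit"` list: `betas` (named vector, or matrix with one
#'   column per signal), `residual_variance` (estimate of
#'   \eqn{\sigma_\epsilon^2}), `df_residual`, `glm_kind`.
#' @export
fit_ols <- function(y, design, include_intercept = TRUE) {
  design <- as.matrix(design)
  ymat <- as.matrix(y)
  n <- nrow(design)
  if (nrow(ymat) != n) {
    stop("`y` and `design` must have the same number of trials",
         call. = FALSE)
  }
  X <- if (include_intercept) cbind(`(Intercept)` = 1, design) else design
  p <- ncol(X)
  if (n <= p) stop("need more trials than coefficients", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    stop("design matrix is rank deficient (singular normal equations); ",
         "check for constant or collinear regressors", call. = FALSE)
  }
  betas <- qr.coef(qx, ymat)
  rownames(betas) <- colnames(X)
  res <- ymat - X %*% betas
  df_res <- n - p
  rv <- colSums(res^2) / df_res
  if (ncol(ymat) == 1L) {
    betas <- betas[, 1L]
    rv <- rv[[1L]]
  }
  structure(
    list(betas = betas, residual_variance = rv, df_residual = df_res,
         glm_kind = attr(design, "glm_kind")),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("OLS fit", if (!is.null(x$glm_kind)) paste0("(", x$glm_kind, ")"),
      "\n")
  print(x$betas)
  cat("residual variance:", format(x$residual_variance, digits = 4), "\n")
  invisible(x)
}

#' Tidy coefficient table of one or more GLM fits
#'
#' @param ... `"glm_fit"` objects (optionally named by subject).
#' @return A data frame with columns `subject`, `glm_kind`, `regressor`,
#'   `beta`, `residual_var`.
#' @export
glm_fit_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "glm_fit")) {
    fits <- fits[[1L]]
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- as.character(seq_along(fits))
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject = nm[i],
               glm_kind = if (is.null(f$glm_kind)) NA_character_
                          else f$glm_kind,
               regressor = names(f$betas), beta = unname(f$betas),
               residual_var = f$residual_variance)
  }))
}
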