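#' Delta-method interval for a smooth function of fitted coefficients
#'
#' Computes \eqn{SE = \sqrt{g' \Sigma g}} where \eqn{g} is the central
#' finite-difference gradient of a log odds-ratio functional with respect to
#' the concatenated (outcome, mediator) coefficient vector and \eqn{\Sigma}
#' is the joint coefficient covariance. The interval is symmetric on the log
#' scale: \eqn{\exp(\log OR \pm z \cdot SE)}.
#'
#' @param effect_fn function mapping the joint coefficient vector
#'   (theta, beta) to a log odds ratio.
#' @param models a \code{\link{fit_models}} result with finite
#'   \code{joint_cov}.
#' @param level confidence level (default 0.95).
#' @return list with \code{log_se}, \code{log_or}, and \code{interval}
#'   (length-2, odds-ratio scale).
#' @export
delta_ci <- function(effect_fn, models, level = 0.95) {
  stopifnot(inherits(models, "fitted_models") || inherits(models, "unified_fit"))
  Sigma <- models$joint_cov
  if (is.null(Sigma) || any(!is.finite(Sigma)))
    stop("joint coefficient covariance is unavailable or non-finite")
  par_hat <- c(models$outcome$coef, models$mediator$coef)
  g <- num_gradient(effect_fn, par_hat)
  var_log <- drop(t(g) %*% Sigma %*% g)
  if (var_log < 0) stop("joint covariance is not positive semi-definite along the gradient")
  se <- sqrt(var_log)
  log_or <- unname(effect_fn(par_hat))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(log_se = se, log_or = log_or,
       interval = exp(log_or + c(-1, 1) * z * se))
}

#' Bootstrap configuration
#'
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling stream.
#' @param stratified logical; resample cases and controls separately,
#'   preserving the design's fixed case:control split (default TRUE).
#' @return an object of class \code{bootstrap_config}.
#' @export
bootstrap_config <- function(reps = 1000, seed = 1L, stratified = TRUE) {
  stopifnot(reps >= 1)
  structure(list(reps = as.integer(reps), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "bootstrap_config")
}

## Subset a mediation_data by row index.
.data_subset <- function(data, idx) {
  mediation_data(y = data$y[idx], a = data$a[idx], m = data$m[idx],
                 c = if (ncol(data$c)) data$c[idx, , drop = FALSE] else NULL,
                 mediator_type = data$mediator_type)
}

#' Percentile-bootstrap intervals for natural effect odds ratios
#'
#' Resamples records with replacement (by default stratified on outcome
#' status so each replicate keeps the original case and control counts),
#' re-estimates the three effects per replicate, and returns percentile
#' intervals of the replicate odds ratios. Replicates whose fits fail are
#' dropped and counted; more than 50\% failures is an error.
#'
#' @param data a \code{\link{mediation_data}} object.
#' @param spec a \code{\link{design_spec}} (its ci_methods are ignored here).
#' @param contrast a \code{\link{contrast_spec}} with explicit covariate
#'   conditioning values (conditioning is held fixed across replicates, as
#'   the effects are conditional on c).
#' @param method "approximate" or "exact".
#' @param config a \code{\link{bootstrap_config}}.
#' @param level confidence level (default 0.95).
#' @return list with elements \code{NDE}, \code{NIE}, \code{TE} (length-2
#'   percentile intervals) and \code{n_failed}.
#' @export
bootstrap_ci <- function(data, spec, contrast, method, config, level = 0.95) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (is.null(contrast$c))
    contrast$c <- if (ncol(data$c)) colMeans(data$c) else numeric(0)
  spec_pt <- spec
  spec_pt$ci_methods <- character(0)
  cases <- which(data$y == 1)
  controls <- which(data$y == 0)
  draws <- matrix(NA_real_, nrow = config$reps, ncol = 3,
                  dimnames = list(NULL, c("NDE", "NIE", "TE")))
  n_failed <- 0L
  for (r in seq_len(config$reps)) {
    set.seed(split_seed(config$seed, r))
    idx <- if (config$stratified) {
      c(sample(cases, length(cases), replace = TRUE),
        sample(controls, length(controls), replace = TRUE))
    } else {
      sample.int(data$n, data$n, replace = TRUE)
    }
    draws[r, ] <- tryCatch({
      bd <- .data_subset(data, idx)
      models <- fit_models(bd, spec_pt)
      .point_effects(models, contrast, method)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      c(NA_real_, NA_real_, NA_real_)
    })
  }
  if (n_failed > config$reps / 2)
    stop("more than half of the bootstrap replicates failed (", n_failed,
         " of ", config$reps, ")")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- lapply(c(NDE = "NDE", NIE = "NIE", TE = "TE"), function(eff)
    unname(stats::quantile(draws[, eff], probs = probs, na.rm = TRUE)))
  out$n_failed <- n_failed
  out
}
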