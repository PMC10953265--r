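#' Inverse-probability design weights for case-control data
#'
#' Computes the two-valued weight vector that recovers population-level model
#' fits from a case-control sample: each case is weighted by \eqn{\pi/p} and
#' each control by \eqn{(1-\pi)/(1-p)}, where \eqn{p} is the proportion of
#' cases in the sample and \eqn{\pi} the outcome prevalence (or incidence) in
#' the population. The weighted case and control totals are exactly
#' \eqn{n\pi} and \eqn{n(1-\pi)}.
#'
#' @param data a \code{\link{mediation_data}} object with both cases and
#'   controls.
#' @param pi population outcome prevalence, in (0, 1).
#' @return numeric weight vector of length \code{data$n}, all positive.
#' @examples
#' d <- mediation_data(y = c(1, 1, 0, 0), a = c(1, 0, 1, 0), m = rnorm(4))
#' compute_weights(d, pi = 0.1)  # cases 0.2, controls 1.8
#' @export
compute_weights <- function(data, pi) {
  stopifnot(inherits(data, "mediation_data"))
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
    stop("pi must be a single probability strictly between 0 and 1")
  p <- mean(data$y == 1)
  if (p == 0 || p == 1)
    stop("case-control weights are undefined: sample contains ",
         if (p == 0) "no cases" else "no controls")
  ifelse(data$y == 1, pi / p, (1 - pi) / (1 - p))
}

## Shared IRLS settings (tolerance on deviance change, as in stats::glm).
.glm_control <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

## Weighted logistic fit on an explicit design matrix. Returns coefficients
## and the model-based covariance (inverse weighted information); optionally
## a sandwich covariance robust to the weighting. quasibinomial avoids the
## spurious non-integer-successes warning under fractional IPW weights; the
## dispersion is fixed at 1 as for a genuine binomial likelihood.
.weighted_logit <- function(X, y, w, sandwich = FALSE) {
  fit <- stats::glm.fit(X, y, weights = w, family = stats::quasibinomial(),
                        control = .glm_control())
  if (!fit$converged)
    stop(structure(class = c("medcc_fit_error", "error", "condition"),
                   list(message = "logistic fit did not converge within 100 IRLS iterations",
                        call = sys.call(-1))))
  mu <- fit$fitted.values
  if (any(abs(fit$coefficients) > 50) || any(mu < 1e-10) || any(mu > 1 - 1e-10))
    stop(structure(class = c("medcc_fit_error", "error", "condition"),
                   list(message = "(quasi-)complete separation detected in logistic fit",
                        call = sys.call(-1))))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  V <- solve(info)
  if (sandwich) {
    meat <- crossprod(X * (w * (y - mu)))
    V <- V %*% meat %*% V
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = stats::setNames(fit$coefficients, colnames(X)), cov = V)
}

## Weighted least-squares fit with sigma from the weighted residual sum of
## squares over (sum of weights - #coefficients).
.weighted_ls <- function(X, y, w, sandwich = FALSE) {
  fit <- stats::lm.wfit(X, y, w)
  coefs <- stats::setNames(fit$coefficients, colnames(X))
  res <- y - drop(X %*% coefs)
  k <- ncol(X)
  sigma2 <- sum(w * res^2) / (sum(w) - k)
  bread <- solve(crossprod(X, X * w))
  V <- if (sandwich) bread %*% crossprod(X * (w * res)) %*% bread else bread * sigma2
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = coefs, cov = V, sigma = sqrt(sigma2))
}

.outcome_design <- function(data) {
  X <- cbind(`(Intercept)` = 1, a = data$a, m = data$m, `a:m` = data$a * data$m)
  if (ncol(data$c)) X <- cbind(X, data$c)
  X
}

.mediator_design <- function(a, c) {
  X <- cbind(`(Intercept)` = 1, a = a)
  if (ncol(c)) X <- cbind(X, c)
  X
}

#' Fit the outcome logistic model
#'
#' Weighted maximum-likelihood fit of
#' \deqn{logit P(Y=1|A,M,C) = \theta_0 + \theta_1 a + \theta_2 m +
#'   \theta_3 a m + \theta_4' c.}
#' With unit weights this is ordinary logistic regression; with IPW weights
#' it recovers the population intercept from case-control data.
#'
#' @param data a \code{\link{mediation_data}} object.
#' @param weights strictly positive weight vector of length \code{data$n};
#'   defaults to unit weights.
#' @param sandwich logical; also return a sandwich (robust) covariance in
#'   place of the model-based one. Default FALSE (model-based).
#' @return an object of class \code{outcome_params}: named coefficients
#'   \code{theta0, theta1, theta2, theta3}, covariate vector \code{theta4},
#'   full coefficient vector \code{coef}, and covariance matrix \code{cov}.
#' @export
fit_outcome_model <- function(data, weights = rep(1, data$n), sandwich = FALSE) {
  stopifnot(inherits(data, "mediation_data"))
  if (length(weights) != data$n || any(weights <= 0))
    stop("weights must be strictly positive and of length n")
  X <- .outcome_design(data)
  fit <- .weighted_logit(X, data$y, weights, sandwich = sandwich)
  th <- fit$coef
  structure(list(theta0 = unname(th[1]), theta1 = unname(th[2]),
                 theta2 = unname(th[3]), theta3 = unname(th[4]),
                 theta4 = th[-(1:4)], coef = th, cov = fit$cov),
            class = "outcome_params")
}

#' Fit the mediator model under a design strategy
#'
#' Continuous mediator: weighted least squares for
#' \eqn{E(M|A,C) = \beta_0 + \beta_1 a + \beta_2' c} with residual SD
#' \eqn{\sigma}. Binary mediator: weighted logistic regression with the same
#' linear predictor. Strategies:
#' \itemize{
#'   \item \code{naive}: all records, unit weights;
#'   \item \code{controls_only}: records with \eqn{Y = 0} only, unit weights
#'     (the controls approximate the population mediator law when the
#'     outcome is rare);
#'   \item \code{ipw}: all records with \code{\link{compute_weights}}.
#' }
#'
#' @param data a \code{\link{mediation_data}} object.
#' @param spec a \code{\link{design_spec}} with strategy naive, controls_only
#'   or ipw.
#' @param sandwich logical; return a sandwich (robust) covariance, the
#'   design-consistent choice under informative IPW weights. Default FALSE
#'   (model-based).
#' @return an object of class \code{mediator_params}: \code{beta0},
#'   \code{beta1}, covariate vector \code{beta2}, residual SD \code{sigma}
#'   (continuous mediator only, else NULL), full \code{coef} vector and
#'   covariance \code{cov} (coefficients only).
#' @export
fit_mediator_model <- function(data, spec, sandwich = FALSE) {
  stopifnot(inherits(data, "mediation_data"), inherits(spec, "design_spec"))
  if (!spec$strategy %in% c("naive", "controls_only", "ipw"))
    stop("fit_mediator_model handles strategies naive, controls_only, ipw")
  if (spec$strategy == "controls_only") {
    keep <- data$y == 0
    if (!any(keep)) stop("controls_only strategy requires at least one control")
    a <- data$a[keep]; m <- data$m[keep]
    cc <- data$c[keep, , drop = FALSE]
    w <- rep(1, sum(keep))
  } else {
    a <- data$a; m <- data$m; cc <- data$c
    w <- if (spec$strategy == "ipw") compute_weights(data, spec$pi) else rep(1, data$n)
  }
  X <- .mediator_design(a, cc)
  if (data$mediator_type == "continuous") {
    fit <- .weighted_ls(X, m, w, sandwich = sandwich)
    sigma <- fit$sigma
  } else {
    fit <- .weighted_logit(X, m, w, sandwich = sandwich)
    sigma <- NULL
  }
  be <- fit$coef
  structure(list(beta0 = unname(be[1]), beta1 = unname(be[2]),
                 beta2 = be[-(1:2)], sigma = sigma,
                 coef = be, cov = fit$cov),
            class = "mediator_params")
}

#' Fit outcome and mediator models under a case-control strategy
#'
#' Dispatcher over the design-handling strategies. \code{naive} fits both
#' models with unit weights; \code{controls_only} fits the outcome model on
#' the full sample and the mediator model on controls only; \code{ipw}
#' applies the design weights to both models; \code{unified} jointly
#' maximizes the prospective likelihood via \code{\link{fit_unified}}.
#'
#' @param data a \code{\link{mediation_data}} object.
#' @param spec a \code{\link{design_spec}}.
#' @param sandwich logical, passed to the outcome and mediator fits for the
#'   separately fitted strategies; under IPW the sandwich form is the
#'   design-consistent covariance.
#' @return an object of class \code{fitted_models}: \code{outcome}
#'   (\code{outcome_params}), \code{mediator} (\code{mediator_params}),
#'   \code{joint_cov} over the concatenated (theta, beta) coefficient vector
#'   (block-diagonal for separately fitted likelihoods, full inverse observed
#'   information for unified), \code{strategy_used} and \code{mediator_type}.
#' @export
fit_models <- function(data, spec, sandwich = FALSE) {
  stopifnot(inherits(data, "mediation_data"), inherits(spec, "design_spec"))
  if (spec$strategy == "unified") {
    uf <- fit_unified(data)
    return(structure(list(outcome = uf$outcome, mediator = uf$mediator,
                          joint_cov = uf$joint_cov,
                          strategy_used = "unified",
                          mediator_type = data$mediator_type,
                          unified = uf),
                     class = "fitted_models"))
  }
  w_out <- if (spec$strategy == "ipw") compute_weights(data, spec$pi) else rep(1, data$n)
  outcome <- fit_outcome_model(data, w_out, sandwich = sandwich)
  mediator <- fit_mediator_model(data, spec, sandwich = sandwich)
  k1 <- length(outcome$coef); k2 <- length(mediator$coef)
  joint <- matrix(0, k1 + k2, k1 + k2)
  joint[seq_len(k1), seq_len(k1)] <- outcome$cov
  joint[k1 + seq_len(k2), k1 + seq_len(k2)] <- mediator$cov
  dimnames(joint) <- list(c(paste0("theta.", names(outcome$coef)),
                            paste0("beta.", names(mediator$coef))),
                          c(paste0("theta.", names(outcome$coef)),
                            paste0("beta.", names(mediator$coef))))
  structure(list(outcome = outcome, mediator = mediator, joint_cov = joint,
                 strategy_used = spec$strategy,
                 mediator_type = data$mediator_type),
            class = "fitted_models")
}

#' @export
print.fitted_models <- function(x, ...) {
  cat(sprintf("<fitted_models> strategy = %s, %s mediator\n",
              x$strategy_used, x$mediator_type))
  cat("outcome model (logit scale):\n")
  print(round(x$outcome$coef, 4))
  cat("mediator model:\n")
  print(round(x$mediator$coef, 4))
  if (!is.null(x$mediator$sigma))
    cat(sprintf("residual SD sigma = %.4f\n", x$mediator$sigma))
  invisible(x)
}
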