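## Cache Gauss-Hermite rules across calls (eigen decomposition is not free).
.gh_env <- new.env(parent = emptyenv())
.gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- gauss_hermite(n)
  .gh_env[[key]]
}

## Resolve the conditioning covariate vector for a contrast.
.contrast_c <- function(contrast, k) {
  c <- contrast$c
  if (is.null(c)) stop("no conditioning covariate values available")
  if (length(c) != k) stop("conditioning covariate vector length mismatch")
  as.numeric(c)
}

#' Approximate (rare-outcome) natural direct effect odds ratio
#'
#' Closed-form NDE odds ratio for the 1-vs-0 exposure contrast under the
#' rare outcome assumption. Continuous mediator:
#' \eqn{\exp(\theta_1 + \theta_3(\beta_0 + \beta_2'c + \theta_2\sigma^2) +
#'   0.5\theta_3^2\sigma^2)}; binary mediator:
#' \eqn{e^{\theta_1}(1+e^{\theta_2+\theta_3+\beta_0+\beta_2'c}) /
#'   (1+e^{\theta_2+\beta_0+\beta_2'c})}.
#'
#' @param models a \code{\link{fit_models}} result.
#' @param contrast a \code{\link{contrast_spec}}; must be the 1-vs-0 contrast
#'   (the closed forms are printed for a binary 0/1 exposure) with explicit
#'   covariate values.
#' @param mediator_type "continuous" or "binary"; defaults to the type
#'   recorded in \code{models}.
#' @return the NDE odds ratio (positive scalar).
#' @export
approx_nde <- function(models, contrast, mediator_type = models$mediator_type) {
  .check_unit_contrast(contrast)
  cvec <- .contrast_c(contrast, length(models$outcome$theta4))
  .approx_nde_value(models$outcome$coef, models$mediator$coef, cvec,
                    mediator_type, models$mediator$sigma)
}

#' Approximate (rare-outcome) natural indirect effect odds ratio
#'
#' Closed-form NIE odds ratio for the 1-vs-0 exposure contrast under the
#' rare outcome assumption. Continuous mediator:
#' \eqn{\exp(\beta_1(\theta_2+\theta_3))}; binary mediator: the four-term
#' expit ratio in \eqn{\beta_0, \beta_1, \beta_2'c, \theta_2, \theta_3}.
#'
#' @inheritParams approx_nde
#' @return the NIE odds ratio (positive scalar).
#' @export
approx_nie <- function(models, contrast, mediator_type = models$mediator_type) {
  .check_unit_contrast(contrast)
  cvec <- .contrast_c(contrast, length(models$outcome$theta4))
  .approx_nie_value(models$outcome$coef, models$mediator$coef, cvec,
                    mediator_type)
}

.check_unit_contrast <- function(contrast) {
  if (!(identical(as.numeric(contrast$a), 1) &&
        identical(as.numeric(contrast$a_star), 0)))
    stop("the approximate closed forms are defined for the 1-vs-0 exposure contrast")
}

## Raw formula evaluations on coefficient vectors (theta length 4+k with
## layout (theta0, theta1, theta2, theta3, theta4...), beta length 2+k).
.approx_nde_value <- function(th, be, cvec, mediator_type, sigma) {
  b2c <- if (length(cvec)) sum(be[-(1:2)] * cvec) else 0
  if (mediator_type == "continuous") {
    unname(exp(th[2] + th[4] * (be[1] + b2c + th[3] * sigma^2) +
                 0.5 * th[4]^2 * sigma^2))
  } else {
    unname(exp(th[2]) * (1 + exp(th[3] + th[4] + be[1] + b2c)) /
             (1 + exp(th[3] + be[1] + b2c)))
  }
}

.approx_nie_value <- function(th, be, cvec, mediator_type) {
  b2c <- if (length(cvec)) sum(be[-(1:2)] * cvec) else 0
  if (mediator_type == "continuous") {
    unname(exp(be[2] * (th[3] + th[4])))
  } else {
    unname((1 + exp(be[1] + b2c)) / (1 + exp(be[1] + be[2] + b2c)) *
             (1 + exp(th[3] + th[4] + be[1] + be[2] + b2c)) /
             (1 + exp(th[3] + th[4] + be[1] + b2c)))
  }
}

#' Exact nested counterfactual outcome probability
#'
#' Evaluates \eqn{P(Y(a, M(a^*)) = 1 | C = c)} from the fitted outcome and
#' mediator models without invoking the rare outcome assumption. For a
#' binary mediator this is the exact two-term closed form; for a continuous
#' (Gaussian) mediator the logistic-normal integral is evaluated by
#' Gauss-Hermite quadrature centered at the mediator mean under a*, with
#' node-doubling (64, 128, ..., 512) until successive values agree to the
#' absolute tolerance.
#'
#' @param models a \code{\link{fit_models}} result.
#' @param a exposure level for the outcome model.
#' @param a_star exposure level generating the mediator distribution.
#' @param c conditioning covariate vector.
#' @param mediator_type "continuous" or "binary".
#' @param tol absolute quadrature tolerance (default 1e-8).
#' @return a probability strictly inside (0, 1).
#' @export
exact_counterfactual_prob <- function(models, a, a_star, c = NULL,
                                      mediator_type = models$mediator_type,
                                      tol = 1e-8) {
  th <- models$outcome$coef
  be <- models$mediator$coef
  cvec <- if (is.null(c)) numeric(length(th) - 4L) else as.numeric(c)
  if (length(cvec) != length(th) - 4L)
    stop("conditioning covariate vector length mismatch")
  p <- .exact_prob_value(th, be, a, a_star, cvec, mediator_type,
                         sigma = models$mediator$sigma, tol = tol)
  if (p <= 1e-12 || p >= 1 - 1e-12)
    stop("counterfactual probability is numerically degenerate (", signif(p, 3),
         "); odds are undefined")
  p
}

.exact_prob_value <- function(th, be, a, a_star, cvec, mediator_type,
                              sigma = NULL, tol = 1e-8) {
  t4c <- if (length(cvec)) sum(th[-(1:4)] * cvec) else 0
  b2c <- if (length(cvec)) sum(be[-(1:2)] * cvec) else 0
  lpm <- be[1] + be[2] * a_star + b2c
  if (mediator_type == "binary") {
    pm <- expit(lpm)
    p1 <- expit(th[1] + th[2] * a + th[3] + th[4] * a + t4c)
    p0 <- expit(th[1] + th[2] * a + t4c)
    return(unname(p1 * pm + p0 * (1 - pm)))
  }
  integrand <- function(m) expit(th[1] + th[2] * a + (th[3] + th[4] * a) * m + t4c)
  gh_value <- function(n) {
    gh <- .gh_rule(n)
    sum(gh$weights * integrand(lpm + sigma * sqrt(2) * gh$nodes)) / sqrt(pi)
  }
  prev <- gh_value(64L)
  for (n in c(128L, 256L, 512L)) {
    cur <- gh_value(n)
    if (abs(cur - prev) < tol) return(unname(cur))
    prev <- cur
  }
  stop("quadrature did not stabilize to tolerance ", tol,
       " at 512 nodes (last change ", signif(abs(cur - prev), 3), ")")
}

#' Exact natural direct effect odds ratio
#'
#' Plugs the exact counterfactual probabilities into the natural-effect
#' definitions: \eqn{OR^{NDE} = odds\{P(a, M(a^*))\} / odds\{P(a^*, M(a^*))\}}
#' with \eqn{odds(p) = p/(1-p)}.
#'
#' @inheritParams approx_nde
#' @export
exact_nde <- function(models, contrast, mediator_type = models$mediator_type) {
  cvec <- .contrast_c(contrast, length(models$outcome$theta4))
  p_num <- exact_counterfactual_prob(models, contrast$a, contrast$a_star, cvec,
                                     mediator_type)
  p_den <- exact_counterfactual_prob(models, contrast$a_star, contrast$a_star,
                                     cvec, mediator_type)
  (p_num / (1 - p_num)) / (p_den / (1 - p_den))
}

#' Exact natural indirect effect odds ratio
#'
#' \eqn{OR^{NIE} = odds\{P(a, M(a))\} / odds\{P(a, M(a^*))\}}.
#'
#' @inheritParams approx_nde
#' @export
exact_nie <- function(models, contrast, mediator_type = models$mediator_type) {
  cvec <- .contrast_c(contrast, length(models$outcome$theta4))
  p_num <- exact_counterfactual_prob(models, contrast$a, contrast$a, cvec,
                                     mediator_type)
  p_den <- exact_counterfactual_prob(models, contrast$a, contrast$a_star, cvec,
                                     mediator_type)
  (p_num / (1 - p_num)) / (p_den / (1 - p_den))
}

#' Single natural-effect estimate
#'
#' Lightweight container for one effect estimate on the odds-ratio scale.
#'
#' @param effect one of "NDE", "NIE", "TE".
#' @param or_value odds ratio point estimate (> 0).
#' @param method "approximate", "exact" or "unified".
#' @param log_se standard error of the log odds ratio (optional).
#' @param ci_delta,ci_boot length-2 intervals (optional).
#' @param contrast the \code{\link{contrast_spec}} used (optional).
#' @return an object of class \code{effect_estimate}.
#' @export
effect_estimate <- function(effect, or_value, method,
                            log_se = NA_real_, ci_delta = NULL, ci_boot = NULL,
                            contrast = NULL) {
  stopifnot(effect %in% c("NDE", "NIE", "TE"), or_value > 0)
  structure(list(effect = effect, or_value = or_value, log_se = log_se,
                 ci_delta = ci_delta, ci_boot = ci_boot, method = method,
                 contrast = contrast),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): OR = %.4f", x$effect, x$method, x$or_value))
  if (is.finite(x$log_se)) cat(sprintf(", log-SE = %.4f", x$log_se))
  if (!is.null(x$ci_delta))
    cat(sprintf(", 95%% delta CI [%.4f, %.4f]", x$ci_delta[1], x$ci_delta[2]))
  cat("\n")
  invisible(x)
}

#' Total effect as the product of direct and indirect effect odds ratios
#'
#' \eqn{OR^{TE} = OR^{NDE} \times OR^{NIE}}. Both inputs must share the same
#' estimation method and exposure contrast.
#'
#' @param nde,nie \code{\link{effect_estimate}} objects for the NDE and NIE.
#' @return an \code{effect_estimate} for the TE (without interval; intervals
#'   for the TE are attached by the estimation driver, which has access to
#'   the joint covariance).
#' @examples
#' nde <- effect_estimate("NDE", 1.525, "approximate")
#' nie <- effect_estimate("NIE", 1.064, "approximate")
#' total_effect(nde, nie)$or_value  # 1.6226
#' @export
total_effect <- function(nde, nie) {
  stopifnot(inherits(nde, "effect_estimate"), inherits(nie, "effect_estimate"),
            nde$effect == "NDE", nie$effect == "NIE")
  if (!identical(nde$method, nie$method))
    stop("NDE and NIE were computed with different methods")
  if (!identical(nde$contrast, nie$contrast))
    stop("NDE and NIE use different contrasts or conditioning values")
  effect_estimate("TE", nde$or_value * nie$or_value, nde$method,
                  contrast = nde$contrast)
}

## log-OR of one effect as a function of the joint coefficient vector
## par = (theta, beta); sigma held fixed at its estimate. Used by the delta
## method and shared by the approximate and exact routes.
.effect_logor_fn <- function(effect, method, mediator_type, contrast, cvec,
                             sigma, k) {
  k1 <- 4L + k
  a <- contrast$a; a_star <- contrast$a_star
  function(par) {
    th <- par[seq_len(k1)]
    be <- par[-seq_len(k1)]
    if (method == "approximate") {
      l_nde <- log(.approx_nde_value(th, be, cvec, mediator_type, sigma))
      l_nie <- log(.approx_nie_value(th, be, cvec, mediator_type))
    } else {
      pr <- function(aa, aa_star)
        .exact_prob_value(th, be, aa, aa_star, cvec, mediator_type, sigma)
      p10 <- pr(a, a_star); p00 <- pr(a_star, a_star); p11 <- pr(a, a)
      l_nde <- (logit(p10) - logit(p00))
      l_nie <- (logit(p11) - logit(p10))
    }
    switch(effect, NDE = l_nde, NIE = l_nie, TE = l_nde + l_nie)
  }
}

## Point estimates of (NDE, NIE, TE) ORs for one fitted-models object at an
## explicit covariate vector. Returns a named numeric vector.
.point_effects <- function(models, contrast, method) {
  cvec <- .contrast_c(contrast, length(models$outcome$theta4))
  if (method == "approximate") {
    nde <- .approx_nde_value(models$outcome$coef, models$mediator$coef, cvec,
                             models$mediator_type, models$mediator$sigma)
    nie <- .approx_nie_value(models$outcome$coef, models$mediator$coef, cvec,
                             models$mediator_type)
  } else {
    nde <- exact_nde(models, contrast)
    nie <- exact_nie(models, contrast)
  }
  c(NDE = unname(nde), NIE = unname(nie), TE = unname(nde * nie))
}

#' Estimate natural direct, indirect and total effects from data
#'
#' End-to-end driver: fits the outcome and mediator models under the
#' requested design strategy, evaluates the approximate or exact natural
#' effect odds ratios at the conditioning covariate values, and attaches
#' delta-method and/or percentile-bootstrap confidence intervals.
#'
#' The six approaches benchmarked in the package map onto
#' (method, strategy) pairs: Approx_Naive = ("approximate", "naive"),
#' Approx_C = ("approximate", "controls_only"), Approx_IPW =
#' ("approximate", "ipw"), Exact_Naive = ("exact", "naive"), Exact_IPW =
#' ("exact", "ipw"), Unified = ("approximate", "unified") — the unified
#' likelihood estimates the coefficients jointly and the effects are then
#' read off the approximate closed forms.
#'
#' @param data a \code{\link{mediation_data}} object.
#' @param spec a \code{\link{design_spec}}.
#' @param contrast a \code{\link{contrast_spec}}; when its \code{c} is NULL
#'   the conditioning values are covariate means per \code{conditional_on}.
#' @param method "approximate" (rare-outcome closed forms) or "exact".
#' @param conditional_on how to fill unspecified conditioning covariates:
#'   "means" (sample-specific column means, the packages' default) or
#'   "ipw_means" (IPW-corrected means, requires a strategy with \code{pi}).
#' @param boot a \code{\link{bootstrap_config}}, required when
#'   \code{spec$ci_methods} includes "percentile_bootstrap".
#' @param level confidence level (default 0.95).
#' @param sandwich logical; use sandwich covariance for the separately
#'   fitted strategies.
#' @return an object of class \code{effect_table}: a list with
#'   \code{estimates} (NDE, NIE, TE \code{effect_estimate}s), \code{table}
#'   (a data.frame, one row per effect), \code{models}, \code{contrast} and
#'   \code{method}.
#' @export
estimate_effects <- function(data, spec, contrast = contrast_spec(),
                             method = c("approximate", "exact"),
                             conditional_on = c("means", "ipw_means"),
                             boot = NULL, level = 0.95, sandwich = FALSE) {
  method <- match.arg(method)
  conditional_on <- match.arg(conditional_on)
  stopifnot(inherits(data, "mediation_data"), inherits(spec, "design_spec"))
  contrast <- .fill_contrast(contrast, data, spec, conditional_on)
  models <- fit_models(data, spec, sandwich = sandwich)
  ors <- .point_effects(models, contrast, method)
  cvec <- .contrast_c(contrast, ncol(data$c))
  par_hat <- c(models$outcome$coef, models$mediator$coef)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- list()
  want_delta <- "delta" %in% spec$ci_methods
  for (eff in c("NDE", "NIE", "TE")) {
    fn <- .effect_logor_fn(eff, method, models$mediator_type, contrast, cvec,
                           models$mediator$sigma, ncol(data$c))
    dd <- delta_ci(fn, models, level = level)
    est[[eff]] <- effect_estimate(eff, unname(ors[eff]), method,
                                  log_se = dd$log_se,
                                  ci_delta = if (want_delta) dd$interval,
                                  contrast = contrast)
  }
  if ("percentile_bootstrap" %in% spec$ci_methods) {
    if (is.null(boot)) stop("percentile_bootstrap requested but no bootstrap_config supplied")
    bci <- bootstrap_ci(data, spec, contrast, method, boot, level = level)
    for (eff in names(est)) est[[eff]]$ci_boot <- bci[[eff]]
  }
  tab <- do.call(rbind, lapply(est, function(e) {
    data.frame(effect = e$effect, or = e$or_value, log_se = e$log_se,
               ci_delta_lower = if (is.null(e$ci_delta)) NA_real_ else e$ci_delta[1],
               ci_delta_upper = if (is.null(e$ci_delta)) NA_real_ else e$ci_delta[2],
               ci_boot_lower = if (is.null(e$ci_boot)) NA_real_ else e$ci_boot[1],
               ci_boot_upper = if (is.null(e$ci_boot)) NA_real_ else e$ci_boot[2],
               method = method, strategy = spec$strategy)
  }))
  rownames(tab) <- NULL
  structure(list(estimates = est, table = tab, models = models,
                 contrast = contrast, method = method),
            class = "effect_table")
}

## Fill contrast$c with (possibly IPW-corrected) sample covariate means.
.fill_contrast <- function(contrast, data, spec, conditional_on) {
  if (!is.null(contrast$c)) return(contrast)
  if (ncol(data$c) == 0L) {
    contrast$c <- numeric(0)
    return(contrast)
  }
  if (conditional_on == "ipw_means") {
    if (is.null(spec$pi))
      stop("conditional_on = 'ipw_means' requires a strategy with a prevalence pi")
    w <- compute_weights(data, spec$pi)
    contrast$c <- drop(crossprod(data$c, w)) / sum(w)
  } else {
    contrast$c <- colMeans(data$c)
  }
  contrast
}

#' @export
print.effect_table <- function(x, digits = 4, ...) {
  cat(sprintf("Natural effects (odds-ratio scale), method = %s, strategy = %s\n",
              x$method, x$models$strategy_used))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab[, colSums(!is.na(tab)) > 0 | !num, drop = FALSE], row.names = FALSE)
  invisible(x)
}
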