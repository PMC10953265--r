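## Pairwise log-sum-exp, vectorized.
.lse2 <- function(x, y) {
  m <- pmax(x, y)
  m + log1p(exp(pmin(x, y) - m))
}

## Linear predictors of the outcome and mediator models at (a, m, c).
.outcome_lp <- function(outcome, a, m, c) {
  outcome$theta0 + outcome$theta1 * a + outcome$theta2 * m +
    outcome$theta3 * a * m + drop(c %*% outcome$theta4)
}

.mediator_lp <- function(mediator, a, c) {
  mediator$beta0 + mediator$beta1 * a + drop(c %*% mediator$beta2)
}

## Coerce a covariate argument to a 1-row (or n-row) matrix so that the
## %*% in the linear predictors works for vector input.
.cmat <- function(c, k) {
  if (is.matrix(c)) return(c)
  if (is.null(c)) c <- numeric(k)
  matrix(c, nrow = 1, ncol = length(c))
}

#' Conditional outcome odds theta(a, m, c)
#'
#' The odds of the outcome given exposure, mediator and covariates under the
#' logistic outcome model:
#' \eqn{\theta(a,m,c) = \exp(\theta_0 + \theta_1 a + \theta_2 m +
#'   \theta_3 a m + \theta_4' c)}.
#'
#' @param params an \code{outcome_params} object.
#' @param a exposure level (0/1).
#' @param m mediator value (vectorized).
#' @param c covariate vector matching \code{params$theta4}.
#' @return positive odds, same length as \code{m}.
#' @export
theta_odds <- function(params, a, m, c = NULL) {
  c <- .cmat(c, length(params$theta4))
  if (ncol(c) != length(params$theta4))
    stop("covariate vector length does not match theta4")
  exp(.outcome_lp(params, a, m, c))
}

#' Marginal outcome odds theta(a, c)
#'
#' Integrates the conditional odds \code{\link{theta_odds}} over the
#' control-stratum mediator distribution:
#' \eqn{\theta(a,c) = \int \theta(a,m^*,c) P(M=m^*|Y=0,a,c) dm^*}.
#' For a continuous (Gaussian) mediator this has the closed form
#' \eqn{\exp(\theta_0+\theta_1 a+\theta_4'c)\exp((\theta_2+\theta_3 a)\mu +
#' (\theta_2+\theta_3 a)^2\sigma^2/2)} with \eqn{\mu = \beta_0+\beta_1 a+
#' \beta_2'c}; for a binary mediator it is the two-term sum weighted by
#' \eqn{expit(\beta_0+\beta_1 a+\beta_2'c)}. Computed on the log scale to
#' avoid overflow.
#'
#' @param outcome an \code{outcome_params} object.
#' @param mediator a \code{mediator_params} object.
#' @param a exposure level.
#' @param c covariate vector.
#' @param mediator_type "continuous" or "binary".
#' @return positive odds (scalar for a single covariate vector).
#' @export
marginal_odds <- function(outcome, mediator, a, c = NULL,
                          mediator_type = c("continuous", "binary")) {
  mediator_type <- match.arg(mediator_type)
  c <- .cmat(c, length(outcome$theta4))
  out <- exp(.log_theta_ac(outcome, mediator, a, c, mediator_type))
  if (any(!is.finite(out)))
    stop("marginal odds overflowed; consider rescaling the mediator or covariates")
  out
}

## Clean stable implementation used everywhere internally.
.log_theta_ac <- function(outcome, mediator, a, c, mediator_type,
                          sigma = mediator$sigma) {
  eta0 <- outcome$theta0 + outcome$theta1 * a + drop(c %*% outcome$theta4)
  s <- outcome$theta2 + outcome$theta3 * a
  lpm <- .mediator_lp(mediator, a, c)
  if (mediator_type == "continuous") {
    eta0 + s * lpm + 0.5 * s^2 * sigma^2
  } else {
    ## log(pm * e^s + (1 - pm)); log(pm) = lpm - log1pexp(lpm),
    ## log(1 - pm) = -log1pexp(lpm)
    lp1 <- lpm - log1pexp(lpm) + s
    lp0 <- -log1pexp(lpm)
    eta0 + .lse2(lp1, lp0)
  }
}

## log P(M = m | Y = 0, a, c): Gaussian density or Bernoulli mass with
## linear predictor beta0 + beta1 a + beta2'c.
.log_mediator_density <- function(mediator, m, a, c, mediator_type,
                                  sigma = mediator$sigma) {
  lpm <- .mediator_lp(mediator, a, c)
  if (mediator_type == "continuous") {
    stats::dnorm(m, mean = lpm, sd = sigma, log = TRUE)
  } else {
    m * lpm - log1pexp(lpm)
  }
}

#' Mediator density among the cases
#'
#' The case-stratum mediator law implied by the outcome odds and the
#' control-stratum mediator model:
#' \eqn{P(M=m|Y=1,a,c) = \theta(a,m,c) P(M=m|Y=0,a,c) / \theta(a,c)}.
#' Sums (binary) or integrates (continuous) to 1 over m.
#'
#' @inheritParams marginal_odds
#' @param m mediator value(s).
#' @return nonnegative mass (binary) or density (continuous) value(s).
#' @export
case_mediator_density <- function(outcome, mediator, m, a, c = NULL,
                                  mediator_type = c("continuous", "binary")) {
  mediator_type <- match.arg(mediator_type)
  c <- .cmat(c, length(outcome$theta4))
  log_th_ac <- .log_theta_ac(outcome, mediator, a, c, mediator_type)
  if (!is.finite(log_th_ac)) stop("marginal odds are degenerate")
  lp <- .outcome_lp(outcome, a, m, c) +
    .log_mediator_density(mediator, m, a, c, mediator_type) - log_th_ac
  exp(lp)
}

#' Joint prospective log-likelihood for case-control mediation data
#'
#' The log of the unified joint likelihood
#' \deqn{L_p = \prod_i P(M=m_i|Y=0,a_i,c_i)\,
#'   \theta(a_i,m_i,c_i)^{y_i} / (1 + \theta(a_i,c_i)),}
#' which models the control-stratum mediator distribution (rare-outcome
#' approximation) together with the prospective outcome odds, so that the
#' case-control design is accounted for without a user-supplied prevalence.
#'
#' @param outcome an \code{outcome_params} object.
#' @param mediator a \code{mediator_params} object (with \code{sigma} when
#'   the mediator is continuous).
#' @param data a \code{\link{mediation_data}} object.
#' @return the scalar log-likelihood (natural log).
#' @export
unified_loglik <- function(outcome, mediator, data) {
  stopifnot(inherits(data, "mediation_data"))
  c <- data$c
  ll_m <- .log_mediator_density(mediator, data$m, data$a, c, data$mediator_type)
  log_th_amc <- .outcome_lp(outcome, data$a, data$m, c)
  log_th_ac <- .log_theta_ac(outcome, mediator, data$a, c, data$mediator_type)
  terms <- ll_m + data$y * log_th_amc - log1pexp(log_th_ac)
  if (any(!is.finite(terms)))
    stop("non-finite log-likelihood contribution at record(s): ",
         paste(utils::head(which(!is.finite(terms)), 5L), collapse = ", "))
  sum(terms)
}

## Pack/unpack the unified parameter vector: theta (4 + k), beta (2 + k),
## and log(sigma) for a continuous mediator.
.unified_pack <- function(outcome, mediator, mediator_type) {
  par <- c(outcome$coef, mediator$coef)
  if (mediator_type == "continuous") par <- c(par, log(mediator$sigma))
  par
}

.unified_unpack <- function(par, k, mediator_type, cnames) {
  k1 <- 4L + k
  k2 <- 2L + k
  th <- unname(par[seq_len(k1)])
  be <- unname(par[k1 + seq_len(k2)])
  sigma <- if (mediator_type == "continuous") unname(exp(par[k1 + k2 + 1L])) else NULL
  outcome <- structure(list(theta0 = th[1], theta1 = th[2], theta2 = th[3],
                            theta3 = th[4],
                            theta4 = stats::setNames(th[-(1:4)], cnames),
                            coef = stats::setNames(th, c("(Intercept)", "a", "m", "a:m", cnames)),
                            cov = NULL),
                       class = "outcome_params")
  mediator <- structure(list(beta0 = be[1], beta1 = be[2],
                             beta2 = stats::setNames(be[-(1:2)], cnames),
                             sigma = sigma,
                             coef = stats::setNames(be, c("(Intercept)", "a", cnames)),
                             cov = NULL),
                        class = "mediator_params")
  list(outcome = outcome, mediator = mediator)
}

#' Fit the unified joint likelihood
#'
#' Jointly maximizes \code{\link{unified_loglik}} over the outcome
#' coefficients, mediator coefficients and (continuous mediator) residual SD,
#' with \eqn{\sigma} parametrized as \eqn{\log\sigma}. Starting values are
#' the controls-only mediator fit and the naive outcome fit; optimization is
#' BFGS followed by Newton polishing steps until the finite-difference
#' gradient is below tolerance. The joint covariance is the inverse of the
#' numerically evaluated observed information at the optimum.
#'
#' @param data a \code{\link{mediation_data}} object with both cases and
#'   controls.
#' @param grad_tol convergence tolerance on the maximum absolute gradient
#'   component (default 1e-6).
#' @return an object of class \code{unified_fit}: \code{outcome},
#'   \code{mediator} (with covariance sub-blocks filled in), \code{loglik},
#'   \code{converged}, \code{n_iter}, \code{joint_cov} over the concatenated
#'   (theta, beta) vector, and \code{full_cov} including \eqn{\log\sigma}.
#' @export
fit_unified <- function(data, grad_tol = 1e-6) {
  stopifnot(inherits(data, "mediation_data"))
  if (!any(data$y == 1) || !any(data$y == 0))
    stop("unified likelihood requires both cases and controls")
  k <- ncol(data$c)
  cnames <- colnames(data$c)
  start_out <- fit_outcome_model(data)
  start_med <- fit_mediator_model(data, design_spec("controls_only"))
  par0 <- .unified_pack(start_out, start_med, data$mediator_type)
  ## Out-of-range proposals (overflowing odds, sigma -> 0 or Inf) get a large
  ## finite penalty so the line search backs off instead of aborting.
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 200)) return(1e10)
    pr <- .unified_unpack(par, k, data$mediator_type, cnames)
    ll <- tryCatch(unified_loglik(pr$outcome, pr$mediator, data),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  gr <- function(par) num_gradient(negll, par)
  opt <- stats::optim(par0, negll, gr = gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- opt$par
  n_iter <- opt$counts[["function"]]
  ## Newton polish to drive the score to ~0 (BFGS can stall short of it)
  converged <- FALSE
  for (it in seq_len(25L)) {
    g <- num_gradient(negll, par)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    H <- num_hessian(negll, par)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
    f_cur <- negll(par)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      f_new <- tryCatch(negll(cand), error = function(e) Inf)
      if (f_new <= f_cur + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (f_new > f_cur) break
    par <- cand
    n_iter <- n_iter + 1L
  }
  if (!converged && max(abs(num_gradient(negll, par))) < 1e-4) converged <- TRUE
  if (!converged)
    warning("unified fit: gradient tolerance not reached; returning best-found state")
  H <- num_hessian(negll, par)
  full_cov <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular at the optimum")
    matrix(NA_real_, length(par), length(par))
  })
  pr <- .unified_unpack(par, k, data$mediator_type, cnames)
  k1 <- 4L + k; k2 <- 2L + k
  pr$outcome$cov <- full_cov[seq_len(k1), seq_len(k1), drop = FALSE]
  pr$mediator$cov <- full_cov[k1 + seq_len(k2), k1 + seq_len(k2), drop = FALSE]
  joint_cov <- full_cov[seq_len(k1 + k2), seq_len(k1 + k2), drop = FALSE]
  nm <- c(paste0("theta.", names(pr$outcome$coef)),
          paste0("beta.", names(pr$mediator$coef)))
  dimnames(joint_cov) <- list(nm, nm)
  structure(list(outcome = pr$outcome, mediator = pr$mediator,
                 loglik = -negll(par), converged = converged,
                 n_iter = n_iter, joint_cov = joint_cov, full_cov = full_cov,
                 par = par),
            class = "unified_fit")
}

#' @export
print.unified_fit <- function(x, ...) {
  cat(sprintf("<unified_fit> loglik = %.4f, converged = %s (%d evaluations)\n",
              x$loglik, x$converged, x$n_iter))
  cat("outcome coefficients:\n"); print(round(x$outcome$coef, 4))
  cat("mediator coefficients:\n"); print(round(x$mediator$coef, 4))
  if (!is.null(x$mediator$sigma))
    cat(sprintf("sigma = %.4f\n", x$mediator$sigma))
  invisible(x)
}
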