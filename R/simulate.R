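#' Generative scenario specification for case-control simulations
#'
#' Fully specifies one simulation scenario: covariates
#' \eqn{C_1 \sim Bernoulli(c_1prob)} and \eqn{C_2 \sim N(0, c_2sd^2)}
#' generated independently; binary exposure
#' \eqn{A \sim Bernoulli(expit(\alpha_0 + \alpha_1 c_1 + \alpha_2 c_2))};
#' mediator \eqn{M} from the linear model (plus Gaussian noise with SD
#' \code{sigma}) or logistic model with coefficients \code{beta}; and binary
#' outcome \eqn{Y \sim Bernoulli(expit(\theta_0 + \theta_1 a + \theta_2 m +
#' \theta_3 a m + \theta_{41} c_1 + \theta_{42} c_2))}.
#' The implied marginal outcome prevalence \code{pi_true} is computed by
#' deterministic nested quadrature at construction.
#'
#' @param name scenario label.
#' @param mediator_type "continuous" or "binary".
#' @param beta length-4 mediator coefficients (intercept, exposure, c1, c2).
#' @param theta length-6 outcome coefficients (intercept, exposure, mediator,
#'   exposure x mediator, c1, c2) on the logit scale.
#' @param sigma mediator residual SD (continuous mediator only).
#' @param c1_prob Bernoulli probability of the binary covariate
#'   (default 0.5).
#' @param c2_sd SD of the zero-mean Gaussian covariate (default 0.75 for a
#'   continuous mediator, 1 for a binary mediator).
#' @param exposure_coefs logit-scale exposure model coefficients
#'   (intercept, c1, c2); default c(-0.5, 0.1, -0.15).
#' @return an object of class \code{scenario_spec} with the above fields
#'   plus \code{pi_true}.
#' @export
scenario_spec <- function(name, mediator_type = c("continuous", "binary"),
                          beta, theta, sigma = NULL,
                          c1_prob = 0.5,
                          c2_sd = if (mediator_type == "continuous") 0.75 else 1,
                          exposure_coefs = c(-0.5, 0.1, -0.15)) {
  mediator_type <- match.arg(mediator_type)
  stopifnot(length(beta) == 4L, length(theta) == 6L,
            length(exposure_coefs) == 3L,
            c1_prob > 0, c1_prob < 1, c2_sd > 0)
  if (mediator_type == "continuous") {
    if (is.null(sigma) || sigma <= 0)
      stop("a continuous mediator requires sigma > 0")
  } else {
    sigma <- NULL
  }
  spec <- structure(list(name = name, mediator_type = mediator_type,
                         beta = unname(beta), theta = unname(theta),
                         sigma = sigma, c1_prob = c1_prob, c2_sd = c2_sd,
                         exposure_coefs = unname(exposure_coefs),
                         pi_true = NA_real_),
                    class = "scenario_spec")
  spec$pi_true <- .analytic_prevalence(spec)
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s (%s mediator)\n", x$name, x$mediator_type))
  cat("  beta  =", paste(format(x$beta), collapse = ", "),
      if (!is.null(x$sigma)) sprintf(" (sigma = %g)", x$sigma) else "", "\n")
  cat("  theta =", paste(format(x$theta), collapse = ", "), "\n")
  cat(sprintf("  implied marginal outcome prevalence = %.4f\n", x$pi_true))
  invisible(x)
}

## Marginal P(Y = 1) under a scenario by nested Gauss-Hermite quadrature
## over C2 (and M when continuous) and exact sums over C1, A (and binary M).
.analytic_prevalence <- function(spec) {
  gh <- gauss_hermite(40L)
  x2 <- spec$c2_sd * sqrt(2) * gh$nodes
  w2 <- gh$weights / sqrt(pi)
  th <- spec$theta; be <- spec$beta; al <- spec$exposure_coefs
  total <- 0
  for (c1 in c(0, 1)) {
    pc1 <- if (c1 == 1) spec$c1_prob else 1 - spec$c1_prob
    for (i in seq_along(x2)) {
      c2 <- x2[i]
      pa <- expit(al[1] + al[2] * c1 + al[3] * c2)
      for (a in c(0, 1)) {
        wa <- if (a == 1) pa else 1 - pa
        mu <- be[1] + be[2] * a + be[3] * c1 + be[4] * c2
        s <- th[3] + th[4] * a
        eta0 <- th[1] + th[2] * a + th[5] * c1 + th[6] * c2
        py <- if (spec$mediator_type == "continuous") {
          m <- mu + spec$sigma * sqrt(2) * gh$nodes
          sum(gh$weights * expit(eta0 + s * m)) / sqrt(pi)
        } else {
          pm <- expit(mu)
          pm * expit(eta0 + s) + (1 - pm) * expit(eta0)
        }
        total <- total + pc1 * w2[i] * wa * py
      }
    }
  }
  total
}

#' Bundled illustrative simulation scenarios
#'
#' Named scenario specifications spanning the outcome-prevalence regimes that
#' drive the behaviour of approximate natural-effect estimators:
#' \describe{
#'   \item{cont_rare / bin_rare}{outcome rare marginally and conditionally;
#'     all approaches, including naive ones, are expected to be nearly
#'     unbiased.}
#'   \item{cont_nonrare_conditional / bin_nonrare_strata}{outcome rare
#'     marginally but common in strata with high mediator values (large
#'     mediator coefficient in the outcome model), violating the rare
#'     outcome assumption conditionally.}
#'   \item{cont_common / bin_common}{outcome relatively common marginally.}
#'   \item{provaq_synthetic}{a synthetic stand-in loosely emulating the
#'     marginals of a published ovarian-cancer case-control analysis
#'     (protective exposure, mediator in hundreds of ovulatory cycles,
#'     age and education covariates); the outcome prevalence is inflated
#'     relative to a real cancer incidence so that finite simulated
#'     populations contain cases. Demo use only.}
#' }
#'
#' @param name one of the scenario names above; see
#'   \code{cc_scenario_names()}.
#' @return a \code{\link{scenario_spec}}.
#' @export
cc_scenario <- function(name) {
  switch(name,
    cont_rare = scenario_spec(
      "cont_rare", "continuous",
      beta = c(1, 0.4, 0.3, -0.2), sigma = 0.5,
      theta = c(-6, 0.4, 0.3, 0.1, 0.2, -0.3)),
    cont_nonrare_conditional = scenario_spec(
      "cont_nonrare_conditional", "continuous",
      beta = c(1, 0.5, 0.3, -0.2), sigma = 0.5,
      theta = c(-7, 0.35, 2.2, 0.25, 0.2, -0.3)),
    cont_common = scenario_spec(
      "cont_common", "continuous",
      beta = c(1, 0.4, 0.3, -0.2), sigma = 0.5,
      theta = c(-2.5, 0.4, 0.6, 0.1, 0.2, -0.3)),
    bin_rare = scenario_spec(
      "bin_rare", "binary",
      beta = c(-0.3, 0.6, 0.25, -0.2),
      theta = c(-6, 0.7, 0.4, 0.1, 0.3, -0.2)),
    bin_nonrare_strata = scenario_spec(
      "bin_nonrare_strata", "binary",
      beta = c(-0.5, 0.9, 0.25, -0.2),
      theta = c(-6.5, 1.1, 3.2, 0.3, 0.3, -0.2)),
    bin_common = scenario_spec(
      "bin_common", "binary",
      beta = c(-0.3, 0.6, 0.25, -0.2),
      theta = c(-2, 0.6, 0.8, 0.2, 0.3, -0.2)),
    provaq_synthetic = scenario_spec(
      "provaq_synthetic", "continuous",
      beta = c(3.72, -1.34, 0.25, 0.01), sigma = 1.1,
      theta = c(-6, -0.43, 0.12, 0, -0.2, 0.02),
      c1_prob = 0.69, c2_sd = 12.6,
      exposure_coefs = c(-1.0, 0, -0.01)),
    stop("unknown scenario '", name, "'; see cc_scenario_names()")
  )
}

#' @rdname cc_scenario
#' @export
cc_scenario_names <- function() {
  c("cont_rare", "cont_nonrare_conditional", "cont_common",
    "bin_rare", "bin_nonrare_strata", "bin_common", "provaq_synthetic")
}

#' Generate a population under a scenario
#'
#' Draws \code{n_pop} independent records from the scenario's generative
#' model. Reproducible under \code{seed}.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n_pop population size (>= 1).
#' @param seed integer seed.
#' @return a \code{\link{mediation_data}} with covariates \code{c1}, \code{c2}.
#' @export
generate_population <- function(spec, n_pop, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"), n_pop >= 1)
  set.seed(seed)
  c1 <- stats::rbinom(n_pop, 1L, spec$c1_prob)
  c2 <- stats::rnorm(n_pop, 0, spec$c2_sd)
  al <- spec$exposure_coefs
  a <- stats::rbinom(n_pop, 1L, expit(al[1] + al[2] * c1 + al[3] * c2))
  be <- spec$beta
  mu <- be[1] + be[2] * a + be[3] * c1 + be[4] * c2
  m <- if (spec$mediator_type == "continuous") {
    mu + stats::rnorm(n_pop, 0, spec$sigma)
  } else {
    stats::rbinom(n_pop, 1L, expit(mu))
  }
  th <- spec$theta
  y <- stats::rbinom(n_pop, 1L,
                     expit(th[1] + th[2] * a + th[3] * m + th[4] * a * m +
                             th[5] * c1 + th[6] * c2))
  mediation_data(y = y, a = a, m = m, c = cbind(c1 = c1, c2 = c2),
                 mediator_type = spec$mediator_type)
}

#' Draw a balanced case-control sample from a population
#'
#' Simple random sampling without replacement of \code{n/2} cases and
#' \code{n/2} controls, mirroring a balanced case-control design.
#'
#' @param population a \code{\link{mediation_data}} object.
#' @param n total sample size (even).
#' @param seed integer seed.
#' @param pi_true optional population prevalence to record alongside the
#'   sample (e.g. the scenario's \code{pi_true}).
#' @return an object of class \code{case_control_sample}: \code{data},
#'   \code{n_cases}, \code{n_controls}, \code{pi_true}.
#' @export
sample_case_control <- function(population, n, seed = 1L, pi_true = NA_real_) {
  stopifnot(inherits(population, "mediation_data"))
  if (n %% 2 != 0) stop("n must be even for a balanced case-control sample")
  n_half <- n / 2
  cases <- which(population$y == 1)
  controls <- which(population$y == 0)
  if (length(cases) < n_half || length(controls) < n_half)
    stop(sprintf("population has %d cases and %d controls; %d of each required",
                 length(cases), length(controls), n_half))
  set.seed(seed)
  idx <- c(sample(cases, n_half), sample(controls, n_half))
  structure(list(data = .data_subset(population, idx),
                 n_cases = n_half, n_controls = n_half, pi_true = pi_true),
            class = "case_control_sample")
}

#' True natural effects of a scenario
#'
#' Evaluates the approximate or exact natural effect odds ratios at the
#' scenario's true coefficients, conditioning on the population covariate
#' means \eqn{(E[C_1], E[C_2]) = (c_1prob, 0)} (known in closed form for the
#' stated covariate distributions). TE = NDE x NIE by construction.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param method "approximate" or "exact".
#' @return named vector \code{c(NDE, NIE, TE)} of odds ratios.
#' @export
true_effects <- function(spec, method = c("approximate", "exact")) {
  method <- match.arg(method)
  cvec <- c(spec$c1_prob, 0)
  th <- spec$theta; be <- spec$beta
  if (method == "approximate") {
    nde <- .approx_nde_value(th, be, cvec, spec$mediator_type, spec$sigma)
    nie <- .approx_nie_value(th, be, cvec, spec$mediator_type)
  } else {
    pr <- function(a, a_star)
      .exact_prob_value(th, be, a, a_star, cvec, spec$mediator_type, spec$sigma)
    p10 <- pr(1, 0); p00 <- pr(0, 0); p11 <- pr(1, 1)
    odds <- function(p) p / (1 - p)
    nde <- odds(p10) / odds(p00)
    nie <- odds(p11) / odds(p10)
  }
  c(NDE = unname(nde), NIE = unname(nie), TE = unname(nde * nie))
}

#' Monte-Carlo outcome prevalences of a scenario
#'
#' Estimates the marginal outcome prevalence and conditional prevalences by
#' strata: quartiles of the mediator for a continuous mediator, exposure x
#' mediator cells for a binary mediator. Used to characterize how rare the
#' outcome is marginally and conditionally in a scenario.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n_mc Monte-Carlo sample size (default 1e6).
#' @param seed integer seed.
#' @return list with \code{marginal} and a named \code{conditional} vector.
#' @export
scenario_prevalence <- function(spec, n_mc = 1e6, seed = 1L) {
  pop <- generate_population(spec, n_mc, seed = seed)
  marginal <- mean(pop$y)
  if (spec$mediator_type == "continuous") {
    q <- cut(pop$m, breaks = stats::quantile(pop$m, probs = seq(0, 1, 0.25)),
             include.lowest = TRUE, labels = paste0("M_q", 1:4))
    conditional <- tapply(pop$y, q, mean)
  } else {
    cell <- interaction(paste0("A", pop$a), paste0("M", pop$m), sep = ":")
    conditional <- tapply(pop$y, cell, mean)
  }
  list(marginal = marginal, conditional = conditional)
}
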