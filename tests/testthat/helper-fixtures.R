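# In-code fixtures: parameter objects built directly (bypassing fitting) so
# formula-level oracles can be tested in isolation, plus small deterministic
# datasets.

toy_outcome <- function(theta, cov = NULL) {
  structure(list(theta0 = theta[1], theta1 = theta[2], theta2 = theta[3],
                 theta3 = theta[4], theta4 = theta[-(1:4)],
                 coef = theta, cov = cov),
            class = "outcome_params")
}

toy_mediator <- function(beta, sigma = NULL, cov = NULL) {
  structure(list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[-(1:2)],
                 sigma = sigma, coef = beta, cov = cov),
            class = "mediator_params")
}

toy_models <- function(theta, beta, sigma = NULL,
                       mediator_type = if (is.null(sigma)) "binary" else "continuous",
                       joint_cov = NULL) {
  structure(list(outcome = toy_outcome(theta), mediator = toy_mediator(beta, sigma),
                 joint_cov = joint_cov, strategy_used = "naive",
                 mediator_type = mediator_type),
            class = "fitted_models")
}

# Small cohort-style dataset from a simple generative model (one binary
# covariate), deterministic under seed.
toy_data <- function(n = 200, seed = 42, mediator_type = "continuous",
                     theta = c(-1, 0.5, 0.4, 0.2, 0.3),
                     beta = c(0.2, 0.6, -0.3), sigma = 0.8) {
  set.seed(seed)
  c1 <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, 0.5)
  mu <- beta[1] + beta[2] * a + beta[3] * c1
  m <- if (mediator_type == "continuous") rnorm(n, mu, sigma) else rbinom(n, 1, plogis(mu))
  y <- rbinom(n, 1, plogis(theta[1] + theta[2] * a + theta[3] * m +
                             theta[4] * a * m + theta[5] * c1))
  # guarantee both outcome classes for weight-based code paths
  y[1] <- 1; y[2] <- 0
  mediation_data(y = y, a = a, m = m, c = cbind(c1 = c1),
                 mediator_type = mediator_type)
}

# Stratified (randomized-quantile) Monte-Carlo average of expit over a
# Gaussian mediator: an oracle for the logistic-normal integral that shares
# no code with the Gauss-Hermite path.
mc_counterfactual_prob <- function(theta, beta, a, a_star, cvec, sigma,
                                   n_draws = 1e6, seed = 1) {
  set.seed(seed)
  t4c <- if (length(cvec)) sum(theta[-(1:4)] * cvec) else 0
  b2c <- if (length(cvec)) sum(beta[-(1:2)] * cvec) else 0
  mu <- beta[1] + beta[2] * a_star + b2c
  u <- (seq_len(n_draws) - runif(n_draws)) / n_draws
  m <- mu + sigma * qnorm(u)
  mean(plogis(theta[1] + theta[2] * a + (theta[3] + theta[4] * a) * m + t4c))
}
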