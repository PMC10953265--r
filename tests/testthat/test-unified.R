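test_that("conditional outcome odds evaluate the exponential linear predictor", {
  expect_equal(theta_odds(toy_outcome(c(0, 0, 0, 0)), a = 1, m = 3.2), 1)
  expect_equal(theta_odds(toy_outcome(c(-1, 0, 0, 0)), a = 0, m = 0), exp(-1))
  # theta = (-2, 0.5, 0.3, 0.1, 0.2), a = 1, m = 2, c = 1
  expect_equal(theta_odds(toy_outcome(c(-2, 0.5, 0.3, 0.1, 0.2)),
                          a = 1, m = 2, c = 1),
               exp(-0.5), tolerance = 1e-12)
  expect_error(theta_odds(toy_outcome(c(0, 0, 0, 0, 0.2)), 1, 1, c = c(1, 2)),
               "does not match")
})

test_that("marginal odds reduce correctly in degenerate cases", {
  # theta2 = theta3 = 0: the mediator integrates out entirely
  out <- toy_outcome(c(-1.2, 0.7, 0, 0))
  for (ty in c("continuous", "binary")) {
    med <- toy_mediator(c(0.3, -0.4), sigma = if (ty == "continuous") 0.8)
    expect_equal(marginal_odds(out, med, a = 1, mediator_type = ty),
                 exp(-1.2 + 0.7))
  }
  # binary mediator pinned at 0 (expit(beta lp) ~ 0)
  out2 <- toy_outcome(c(-1, 0.5, 0.9, 0.2))
  med0 <- toy_mediator(c(-40, 0))
  expect_equal(marginal_odds(out2, med0, a = 1, mediator_type = "binary"),
               exp(-1 + 0.5), tolerance = 1e-10)
})

test_that("continuous marginal odds agree with a Monte-Carlo average of the conditional odds", {
  set.seed(5)
  out <- toy_outcome(c(-2, 0.4, 0.6, -0.3, 0.5))
  med <- toy_mediator(c(0.8, 0.5, -0.2), sigma = 0.7)
  th_ac <- marginal_odds(out, med, a = 1, c = 0.4, mediator_type = "continuous")
  m <- rnorm(1e6, mean = 0.8 + 0.5 * 1 + (-0.2) * 0.4, sd = 0.7)
  mc <- mean(theta_odds(out, a = 1, m = m, c = 0.4))
  expect_equal(th_ac, mc, tolerance = 2e-3)
})

test_that("case-stratum mediator law normalizes to one", {
  set.seed(8)
  for (i in 1:100) {
    out <- toy_outcome(runif(4, -1.5, 1.5))
    med <- toy_mediator(runif(2, -1.5, 1.5))
    tot <- case_mediator_density(out, med, m = 0, a = 1, mediator_type = "binary") +
      case_mediator_density(out, med, m = 1, a = 1, mediator_type = "binary")
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  for (i in 1:5) {
    out <- toy_outcome(runif(4, -1, 1))
    med <- toy_mediator(runif(2, -1, 1), sigma = runif(1, 0.4, 1.2))
    ig <- integrate(function(m)
      case_mediator_density(out, med, m = m, a = 0, mediator_type = "continuous"),
      -Inf, Inf, rel.tol = 1e-9)
    expect_equal(ig$value, 1, tolerance = 1e-6)
  }
  # theta2 = theta3 = 0: case and control mediator laws coincide
  out0 <- toy_outcome(c(0.5, -0.3, 0, 0))
  med <- toy_mediator(c(0.2, 0.7))
  expect_equal(case_mediator_density(out0, med, m = 1, a = 1,
                                     mediator_type = "binary"),
               plogis(0.2 + 0.7))
})

test_that("joint log-likelihood matches trivial closed forms", {
  # single record, binary mediator, all coefficients 0: log(1/2) + y*0 - log 2
  d1 <- mediation_data(y = 1, a = 1, m = 1, mediator_type = "binary")
  ll <- unified_loglik(toy_outcome(c(0, 0, 0, 0)), toy_mediator(c(0, 0)), d1)
  expect_equal(ll, log(0.5) - log(2))

  # controls only with vanishing outcome odds: reduces to the mediator loglik
  d0 <- toy_data(100, seed = 9, mediator_type = "binary")
  d0 <- mediation_data(y = rep(0, d0$n), a = d0$a, m = d0$m, c = d0$c,
                       mediator_type = "binary")
  out_tiny <- toy_outcome(c(-40, 0, 0, 0, 0))
  med <- toy_mediator(c(0.2, 0.5, -0.3))
  lp <- 0.2 + 0.5 * d0$a - 0.3 * d0$c[, 1]
  ll_med <- sum(dbinom(d0$m, 1, plogis(lp), log = TRUE))
  expect_equal(unified_loglik(out_tiny, med, d0), ll_med, tolerance = 1e-10)
})

test_that("joint log-likelihood matches a brute-force factorization of P(Y, M | A, C)", {
  # oracle: per record, unnormalized u(y, m) = theta(a,m,c)^y P(M=m|Y=0,a,c)
  # over the four (y, m) cells; P(y_i, m_i) = u(y_i, m_i) / sum_m u(., m)
  # where the normalizer is 1 + theta(a, c) by construction
  brute <- function(out, med, d) {
    ll <- 0
    for (i in seq_len(d$n)) {
      ci <- d$c[i, , drop = TRUE]
      pm <- plogis(med$beta0 + med$beta1 * d$a[i] + sum(med$beta2 * ci))
      u <- matrix(0, 2, 2, dimnames = list(y = 0:1, m = 0:1))
      for (m in 0:1) {
        th <- theta_odds(out, d$a[i], m, ci)
        pmm <- if (m == 1) pm else 1 - pm
        u["0", as.character(m)] <- pmm
        u["1", as.character(m)] <- th * pmm
      }
      ll <- ll + log(u[as.character(d$y[i]), as.character(d$m[i])] / sum(u))
    }
    ll
  }
  set.seed(17)
  for (rep in 1:10) {
    d <- toy_data(30, seed = rep, mediator_type = "binary")
    out <- toy_outcome(runif(5, -1, 1))
    med <- toy_mediator(runif(3, -1, 1))
    expect_equal(unified_loglik(out, med, d), brute(out, med, d),
                 tolerance = 1e-10)
  }
})

test_that("unified fit satisfies first-order conditions and the ascent property", {
  d <- toy_data(500, seed = 12)
  uf <- fit_unified(d)
  expect_true(uf$converged)
  expect_true(is.finite(uf$loglik))

  # score near zero at the reported optimum
  k <- ncol(d$c)
  negll <- function(par) {
    pr <- medcc:::.unified_unpack(par, k, d$mediator_type, colnames(d$c))
    -unified_loglik(pr$outcome, pr$mediator, d)
  }
  g <- medcc:::num_gradient(negll, uf$par)
  expect_lt(max(abs(g)), 1e-4)

  # at least as good as the (naive theta, controls-only beta) start
  start_ll <- unified_loglik(fit_outcome_model(d),
                             fit_mediator_model(d, design_spec("controls_only")),
                             d)
  expect_gte(uf$loglik, start_ll)

  # observed-information covariance is symmetric PSD with positive diagonal
  expect_true(all(diag(uf$joint_cov) > 0))
  expect_equal(uf$joint_cov, t(uf$joint_cov), tolerance = 1e-6)
})

test_that("unified mediator coefficients track the controls-only fit on rare-outcome data", {
  sp <- scenario_spec("null_mediator_effect", "continuous",
                      beta = c(1, 0.4, 0.3, -0.2), sigma = 0.5,
                      theta = c(-5, 0.4, 0, 0, 0.2, -0.3))
  pop <- generate_population(sp, 2e5, seed = 23)
  d <- sample_case_control(pop, 1000, seed = 24)$data
  uf <- fit_unified(d)
  co <- fit_mediator_model(d, design_spec("controls_only"))
  se <- sqrt(diag(co$cov))
  expect_lt(max(abs(uf$mediator$coef - co$coef) / se), 3)
  expect_equal(uf$mediator$sigma, co$sigma, tolerance = 0.05)
})
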