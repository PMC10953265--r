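test_that("case-control weights follow pi/p and (1-pi)/(1-p)", {
  d <- mediation_data(y = c(1, 1, 0, 0), a = c(1, 0, 1, 0), m = rnorm(4))
  w <- compute_weights(d, pi = 0.1)
  expect_equal(w, c(0.2, 0.2, 1.8, 1.8))

  # pi equal to the sample case fraction collapses to unit weights
  expect_equal(compute_weights(d, pi = 0.5), rep(1, 4))

  # weighted class totals match n*pi and n*(1-pi): a 1000-record balanced
  # sample at pi = 0.0425 gives case total 42.5 and control total 957.5
  d2 <- mediation_data(y = rep(c(1, 0), each = 500), a = rbinom(1000, 1, 0.5),
                       m = rnorm(1000))
  w2 <- compute_weights(d2, pi = 0.0425)
  expect_equal(sum(w2[d2$y == 1]), 42.5)
  expect_equal(sum(w2[d2$y == 0]), 957.5)
  expect_equal(sum(w2), 1000)

  d_all_case <- mediation_data(y = c(1, 1), a = c(0, 1), m = rnorm(2))
  expect_error(compute_weights(d_all_case, 0.1), "no controls")
})

test_that("weight conservation holds for arbitrary class splits", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:500, 1)
    y <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.1, 0.9)))
    pi <- runif(1, 0.001, 0.999)
    d <- mediation_data(y = y, a = rbinom(n, 1, 0.5), m = rnorm(n))
    w <- compute_weights(d, pi)
    expect_equal(sum(w[d$y == 1]), n * pi)
    expect_equal(sum(w[d$y == 0]), n * (1 - pi))
  }
})

test_that("unit-weight fits reproduce standard glm/lm estimates", {
  d <- toy_data(300, seed = 7)
  out <- fit_outcome_model(d)
  ref <- glm(d$y ~ d$a * d$m + d$c, family = binomial())
  expect_equal(unname(out$coef[c(1, 2, 3, 5, 4)]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(out$cov))[c(1, 2, 3, 5, 4)]),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)

  med <- fit_mediator_model(d, design_spec("naive"))
  refm <- lm(d$m ~ d$a + d$c)
  expect_equal(unname(med$coef), unname(coef(refm)), tolerance = 1e-10)
  expect_equal(med$sigma, summary(refm)$sigma, tolerance = 1e-10)

  db <- toy_data(300, seed = 8, mediator_type = "binary")
  medb <- fit_mediator_model(db, design_spec("naive"))
  refb <- glm(db$m ~ db$a + db$c, family = binomial())
  expect_equal(unname(medb$coef), unname(coef(refb)), tolerance = 1e-6)
})

test_that("null-model fit recovers the logit outcome frequency", {
  set.seed(3)
  n <- 20000
  d <- mediation_data(y = rbinom(n, 1, plogis(-1.5)), a = rbinom(n, 1, 0.5),
                      m = rnorm(n))
  fit <- fit_outcome_model(d)
  expect_equal(fit$theta0, qlogis(mean(d$y)), tolerance = 0.15)
  expect_lt(max(abs(fit$coef[-1])), 0.1)
})

test_that("controls-only equals naive when strata are exchangeable", {
  base <- data.frame(a = c(0, 0, 1, 1), m = c(0.1, 0.9, 0.4, 1.3),
                     c1 = c(0, 1, 0, 1))
  d <- mediation_data(y = rep(c(1, 0), each = 4),
                      a = rep(base$a, 2), m = rep(base$m, 2),
                      c = cbind(c1 = rep(base$c1, 2)))
  co <- fit_mediator_model(d, design_spec("controls_only"))
  na <- fit_mediator_model(d, design_spec("naive"))
  expect_equal(co$coef, na$coef, tolerance = 1e-10)
})

test_that("strategy dispatch: ipw at the sample case fraction equals naive; controls-only shares the outcome fit", {
  d <- toy_data(400, seed = 21)
  p <- mean(d$y)
  mn <- fit_models(d, design_spec("naive"))
  mi <- fit_models(d, design_spec("ipw", pi = p))
  expect_equal(mi$outcome$coef, mn$outcome$coef, tolerance = 1e-8)
  expect_equal(mi$mediator$coef, mn$mediator$coef, tolerance = 1e-8)

  mc <- fit_models(d, design_spec("controls_only"))
  expect_equal(mc$outcome$coef, mn$outcome$coef)
  # mediator coefficients must differ since M predicts Y here
  expect_gt(max(abs(mc$mediator$coef - mn$mediator$coef)), 1e-4)

  # block-diagonal joint covariance for separately fitted likelihoods
  k1 <- length(mn$outcome$coef)
  expect_true(all(mn$joint_cov[seq_len(k1), -seq_len(k1)] == 0))
})

test_that("IPW corrects the case-control bias of outcome intercept and mediator slope", {
  sp <- cc_scenario("cont_rare")
  pop <- generate_population(sp, 3e5, seed = 13)
  d <- sample_case_control(pop, 1000, seed = 14)$data
  naive <- fit_models(d, design_spec("naive"))
  ipw <- fit_models(d, design_spec("ipw", pi = sp$pi_true))
  # naive intercept is shifted by ~ logit(p) - logit(pi); IPW undoes it
  shift <- qlogis(0.5) - qlogis(sp$pi_true)
  expect_equal(naive$outcome$theta0, sp$theta[1] + shift, tolerance = 0.6)
  expect_lt(abs(ipw$outcome$theta0 - sp$theta[1]), 1)
  expect_lt(abs(ipw$outcome$theta0 - sp$theta[1]),
            abs(naive$outcome$theta0 - sp$theta[1]))
  # mediator slope: naive is biased upward here because M raises Y-risk
  expect_lt(abs(ipw$mediator$beta1 - sp$beta[2]),
            abs(naive$mediator$beta1 - sp$beta[2]) + 0.05)
})

test_that("weighted residual SD estimates the generative sigma", {
  set.seed(31)
  n <- 20000
  a <- rbinom(n, 1, 0.5)
  m <- 1 + 0.5 * a + rnorm(n, 0, 0.5)
  y <- c(1, 0, rbinom(n - 2, 1, 0.05))
  d <- mediation_data(y = y, a = a, m = m)
  fit <- fit_mediator_model(d, design_spec("ipw", pi = 0.05))
  expect_equal(fit$sigma, 0.5, tolerance = 0.01)
})

test_that("separation raises a typed error", {
  d <- mediation_data(y = c(rep(1, 20), rep(0, 20)),
                      a = c(rep(1, 20), rep(0, 20)),
                      m = c(rnorm(20, 5), rnorm(20, -5)))
  expect_error(fit_outcome_model(d), class = "medcc_fit_error")
})
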