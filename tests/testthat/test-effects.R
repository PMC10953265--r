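test_that("approximate NDE follows the closed forms and their reductions", {
  ctr <- contrast_spec(c = 0.5)
  # no interaction: exp(theta1) for both mediator types
  expect_equal(approx_nde(toy_models(c(-2, 0.7, 0.4, 0, 0.1), c(1, 0.5, 0.2), sigma = 0.5), ctr),
               exp(0.7))
  expect_equal(approx_nde(toy_models(c(-2, 0.7, 0.4, 0, 0.1), c(0.3, 0.5, 0.2)), ctr),
               exp(0.7))
  # null model
  ctr0 <- contrast_spec(c = numeric(0))
  expect_equal(approx_nde(toy_models(c(0, 0, 0, 0), c(0, 0), sigma = 1), ctr0), 1)
  # continuous with interaction: theta1=0.3, theta3=0.2, theta2=0.4,
  # beta0=1, beta2'c=0.5, sigma=0.5 -> exp(0.625)
  m <- toy_models(c(0, 0.3, 0.4, 0.2, 0.5), c(1, 0, 0.5), sigma = 0.5)
  expect_equal(approx_nde(m, contrast_spec(c = 1)), exp(0.625), tolerance = 1e-12)
  # closed forms are printed for the 1-vs-0 exposure contrast only
  expect_error(approx_nde(m, contrast_spec(a = 0, a_star = 1, c = 1)),
               "1-vs-0")
})

test_that("approximate NIE follows the closed forms and their reductions", {
  ctr <- contrast_spec(c = numeric(0))
  # beta1 = 0: no exposure-mediator path
  expect_equal(approx_nie(toy_models(c(-1, 0.2, 0.5, 0.1), c(0.4, 0), sigma = 0.6), ctr), 1)
  expect_equal(approx_nie(toy_models(c(-1, 0.2, 0.5, 0.1), c(0.4, 0)), ctr), 1)
  # theta2 + theta3 = 0, continuous
  expect_equal(approx_nie(toy_models(c(-1, 0.2, 0.5, -0.5), c(0.4, 0.8), sigma = 0.6), ctr), 1)
  # continuous: exp(beta1 (theta2 + theta3))
  expect_equal(approx_nie(toy_models(c(-1, 0, 0.5, 0.2), c(0, 0.4), sigma = 1), ctr),
               exp(0.4 * 0.7))
  # binary worked case: beta0=-1, beta1=1, theta2=0.5, theta3=0
  nie <- approx_nie(toy_models(c(0, 0, 0.5, 0), c(-1, 1)), ctr)
  expect_equal(nie,
               (1 + exp(-1)) / (1 + exp(0)) * (1 + exp(0.5)) / (1 + exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(nie, 1.1277, tolerance = 1e-4)
})

test_that("exact counterfactual probabilities reduce and integrate correctly", {
  # theta2 = theta3 = 0: expit(theta0 + theta1 a + theta4'c), free of a_star
  m <- toy_models(c(-1.5, 0.6, 0, 0, 0.3), c(0.5, 0.7, -0.2), sigma = 0.8)
  p_a0 <- exact_counterfactual_prob(m, a = 1, a_star = 0, c = 1)
  p_a1 <- exact_counterfactual_prob(m, a = 1, a_star = 1, c = 1)
  expect_equal(p_a0, plogis(-1.5 + 0.6 + 0.3), tolerance = 1e-9)
  expect_equal(p_a0, p_a1, tolerance = 1e-9)

  # binary mediator pinned at 1: expit(theta0 + theta1 a + theta2 + theta3 a + theta4'c)
  mb <- toy_models(c(-1, 0.4, 0.9, 0.2, 0.1), c(40, 0, 0))
  expect_equal(exact_counterfactual_prob(mb, 1, 0, c = 0.5),
               plogis(-1 + 0.4 + 0.9 + 0.2 + 0.05), tolerance = 1e-10)

  # quadrature vs stratified Monte-Carlo oracle at a random parameter draw
  set.seed(101)
  th <- c(-2.2, 0.5, 0.8, -0.3, 0.4)
  be <- c(0.6, 0.7, -0.2)
  m2 <- toy_models(th, be, sigma = 0.9)
  q <- exact_counterfactual_prob(m2, 1, 0, c = 0.3)
  mc <- mc_counterfactual_prob(th, be, 1, 0, cvec = 0.3, sigma = 0.9)
  expect_equal(q, mc, tolerance = 1e-4)

  # probabilities stay inside (0, 1) across random draws (binary closed form)
  set.seed(55)
  for (i in 1:50) {
    mm <- toy_models(runif(4, -2, 2), runif(2, -2, 2))
    p <- exact_counterfactual_prob(mm, 1, 0, c = NULL)
    expect_true(p > 0 && p < 1)
  }
})

test_that("exact natural effects have the null reductions of the definitions", {
  ctr <- contrast_spec(c = 0.2)
  # theta1 = theta3 = 0: no direct path
  m <- toy_models(c(-1, 0, 0.6, 0, 0.3), c(0.4, 0.8, 0.1), sigma = 0.7)
  expect_equal(exact_nde(m, ctr), 1, tolerance = 1e-9)
  # beta1 = 0: M(a) and M(a*) identically distributed
  m2 <- toy_models(c(-1, 0.5, 0.6, 0.2, 0.3), c(0.4, 0, 0.1), sigma = 0.7)
  expect_equal(exact_nie(m2, ctr), 1, tolerance = 1e-9)
})

test_that("exact effects converge to the approximate closed forms as the outcome becomes rare", {
  ctr <- contrast_spec(c = 0.5)
  for (ty in c("continuous", "binary")) {
    sigma <- if (ty == "continuous") 0.5 else NULL
    be <- c(0.6, 0.5, -0.2)
    gap <- sapply(c(-4, -8, -12), function(t0) {
      m <- toy_models(c(t0, 0.4, 0.7, 0.2, 0.3), be, sigma = sigma,
                      mediator_type = ty)
      c(nde = abs(log(exact_nde(m, ctr)) - log(approx_nde(m, ctr))),
        nie = abs(log(exact_nie(m, ctr)) - log(approx_nie(m, ctr))))
    })
    # monotone shrinkage of the log-scale gap along the tested range
    expect_true(all(diff(gap["nde", ]) < 0))
    expect_true(all(diff(gap["nie", ]) < 0))
    # relative difference below 1e-3 at theta0 = -12
    m12 <- toy_models(c(-12, 0.4, 0.7, 0.2, 0.3), be, sigma = sigma,
                      mediator_type = ty)
    expect_equal(exact_nde(m12, ctr), approx_nde(m12, ctr), tolerance = 1e-3)
    expect_equal(exact_nie(m12, ctr), approx_nie(m12, ctr), tolerance = 1e-3)
  }
})

test_that("the total effect is the product of NDE and NIE odds ratios", {
  # true-value rows of the published comparison tables, 3-decimal precision
  rows <- list(c(1.525, 1.064, 1.623), c(1.622, 1.585, 2.571),
               c(1.516, 1.105, 1.675), c(1.042, 1.927, 2.008),
               c(3.023, 2.213, 6.690))
  for (r in rows) {
    te <- total_effect(effect_estimate("NDE", r[1], "exact"),
                       effect_estimate("NIE", r[2], "exact"))
    expect_equal(round(te$or_value, 3), r[3])
  }
  # NIE = 1 leaves TE = NDE
  te <- total_effect(effect_estimate("NDE", 1.4, "exact"),
                     effect_estimate("NIE", 1, "exact"))
  expect_equal(te$or_value, 1.4)
  expect_error(total_effect(effect_estimate("NDE", 1.2, "exact"),
                            effect_estimate("NIE", 1.1, "approximate")),
               "different methods")
})

test_that("estimation driver composes strategies, methods and contrasts coherently", {
  d <- toy_data(400, seed = 33)
  p <- mean(d$y)
  for (method in c("approximate", "exact")) {
    naive <- estimate_effects(d, design_spec("naive"), method = method)
    ipw <- estimate_effects(d, design_spec("ipw", pi = p), method = method)
    expect_equal(ipw$table$or, naive$table$or, tolerance = 1e-8)
    # TE = NDE x NIE exactly, by construction
    expect_equal(naive$table$or[3], prod(naive$table$or[1:2]), tolerance = 1e-12)
  }
  # exchanging a and a_star inverts the exact TE odds ratio
  cvec <- colMeans(d$c)
  fwd <- estimate_effects(d, design_spec("naive"),
                          contrast_spec(a = 1, a_star = 0, c = cvec),
                          method = "exact")
  rev <- estimate_effects(d, design_spec("naive"),
                          contrast_spec(a = 0, a_star = 1, c = cvec),
                          method = "exact")
  expect_equal(rev$table$or[3], 1 / fwd$table$or[3], tolerance = 1e-9)

  # unified strategy feeds its coefficients through the approximate forms
  uni <- estimate_effects(d, design_spec("unified"), method = "approximate")
  um <- fit_models(d, design_spec("unified"))
  expect_equal(uni$table$or[1],
               approx_nde(um, contrast_spec(c = colMeans(d$c))),
               tolerance = 1e-8)
})
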