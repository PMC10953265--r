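## Map an approach label onto its (method, design) pair.
.approach_setup <- function(approach, pi) {
  switch(approach,
    Approx_Naive = list(method = "approximate", spec = design_spec("naive")),
    Approx_C     = list(method = "approximate", spec = design_spec("controls_only")),
    Approx_IPW   = list(method = "approximate", spec = design_spec("ipw", pi = pi)),
    Exact_Naive  = list(method = "exact", spec = design_spec("naive")),
    Exact_IPW    = list(method = "exact", spec = design_spec("ipw", pi = pi)),
    Unified      = list(method = "approximate", spec = design_spec("unified")),
    stop("unknown approach '", approach, "'")
  )
}

#' Benchmark approach labels
#' @return the six approach labels understood by the harness.
#' @export
cc_approaches <- function() {
  c("Approx_Naive", "Approx_C", "Approx_IPW",
    "Exact_Naive", "Exact_IPW", "Unified")
}

#' Replicate-level evaluation of the mediation approaches
#'
#' Generates one population under the scenario, draws \code{reps} balanced
#' case-control samples of size \code{n}, applies each requested approach
#' with covariates conditioned on sample-specific means, and records point
#' estimates and confidence-interval endpoints per replicate. IPW approaches
#' use the scenario's true marginal prevalence (\code{pi = spec$pi_true}) by
#' default. Replicate failures (non-convergence, separation) are recorded
#' and excluded, not fatal.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n case-control sample size (even).
#' @param reps number of replicate samples.
#' @param approaches subset of \code{\link{cc_approaches}()}.
#' @param boot_reps percentile-bootstrap replicates per sample (0 disables
#'   bootstrap intervals; the bootstrap is the slow path).
#' @param seed master seed; per-replicate seeds are derived with
#'   \code{\link{split_seed}} so any replicate is reproducible in isolation.
#' @param n_pop population size to simulate (default 2e6 so rare-outcome
#'   scenarios still contain enough cases).
#' @param pi prevalence passed to the IPW approaches (default the true one,
#'   \code{spec$pi_true}); override to study misspecification.
#' @param level confidence level for intervals.
#' @return data.frame with columns replicate, approach, effect, estimate,
#'   delta_lower/upper, boot_lower/upper; failed replicates carry NA
#'   estimates. Attribute \code{n_failed} counts failures per approach.
#' @export
run_replicates <- function(spec, n, reps, approaches = cc_approaches(),
                           boot_reps = 0, seed = 1L, n_pop = 2e6,
                           pi = spec$pi_true, level = 0.95) {
  stopifnot(inherits(spec, "scenario_spec"), length(approaches) >= 1)
  approaches <- match.arg(approaches, cc_approaches(), several.ok = TRUE)
  pop <- generate_population(spec, n_pop, seed = seed)
  rows <- vector("list", reps * length(approaches))
  n_failed <- stats::setNames(integer(length(approaches)), approaches)
  k <- 0L
  for (r in seq_len(reps)) {
    samp <- sample_case_control(pop, n, seed = split_seed(seed, r),
                                pi_true = spec$pi_true)
    d <- samp$data
    for (app in approaches) {
      k <- k + 1L
      setup <- .approach_setup(app, pi)
      setup$spec$ci_methods <- c("delta",
                                 if (boot_reps > 0) "percentile_bootstrap")
      res <- tryCatch({
        boot <- if (boot_reps > 0)
          bootstrap_config(reps = boot_reps,
                           seed = split_seed(seed, reps + r),
                           stratified = TRUE)
        et <- estimate_effects(d, setup$spec, contrast_spec(),
                               method = setup$method, boot = boot,
                               level = level,
                               sandwich = setup$spec$strategy == "ipw")
        tab <- et$table
        data.frame(replicate = r, approach = app, effect = tab$effect,
                   estimate = tab$or,
                   delta_lower = tab$ci_delta_lower,
                   delta_upper = tab$ci_delta_upper,
                   boot_lower = tab$ci_boot_lower,
                   boot_upper = tab$ci_boot_upper)
      }, error = function(e) {
        n_failed[app] <<- n_failed[app] + 1L
        data.frame(replicate = r, approach = app,
                   effect = c("NDE", "NIE", "TE"), estimate = NA_real_,
                   delta_lower = NA_real_, delta_upper = NA_real_,
                   boot_lower = NA_real_, boot_upper = NA_real_)
      })
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

#' RMSE from bias and spread
#'
#' The decomposition \eqn{RMSE = \sqrt{bias^2 + SD^2}} that links the three
#' replicate-level performance metrics.
#'
#' @param bias mean estimate minus truth.
#' @param sd replicate standard deviation.
#' @return the root mean squared error.
#' @export
rmse_from_bias_sd <- function(bias, sd) sqrt(bias^2 + sd^2)

#' Summarize replicate-level estimates into performance metrics
#'
#' Per approach and effect: replicate mean, bias (mean minus truth),
#' relative bias in percent, sample SD (n-1 denominator), RMSE computed from
#' replicate-level squared errors, and coverage probabilities of the delta
#' and bootstrap intervals in percent. Failed replicates are excluded, with
#' the count of usable replicates reported. The identity
#' rmse^2 = bias^2 + sd^2 holds up to the n vs n-1 SD convention.
#'
#' @param estimates output of \code{\link{run_replicates}}.
#' @param true_values named vector \code{c(NDE, NIE, TE)} of true odds
#'   ratios, e.g. from \code{\link{true_effects}}.
#' @return data.frame with one row per (approach, effect).
#' @export
summarize_replicates <- function(estimates, true_values) {
  stopifnot(all(c("NDE", "NIE", "TE") %in% names(true_values)))
  combos <- unique(estimates[c("approach", "effect")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    app <- combos$approach[i]; eff <- combos$effect[i]
    sub <- estimates[estimates$approach == app & estimates$effect == eff, ]
    est <- sub$estimate[!is.na(sub$estimate)]
    truth <- unname(true_values[eff])
    if (length(est) < 2)
      stop("fewer than 2 usable replicates for ", app, " / ", eff)
    m <- mean(est)
    bias <- m - truth
    sdv <- stats::sd(est)
    rmse <- sqrt(mean((est - truth)^2))
    cp <- function(lo, hi) {
      ok <- !is.na(lo) & !is.na(hi)
      if (!any(ok)) return(NA_real_)
      if (all(hi[ok] == lo[ok])) return(NA_real_)  # degenerate intervals
      100 * mean(lo[ok] <= truth & truth <= hi[ok])
    }
    data.frame(approach = app, effect = eff, true_value = truth,
               mean = m, bias = bias,
               relative_bias = 100 * bias / truth,
               sd = sdv, rmse = rmse,
               cp_delta = cp(sub$delta_lower, sub$delta_upper),
               cp_boot = cp(sub$boot_lower, sub$boot_upper),
               n_reps_used = length(est))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$effect, c("NDE", "NIE", "TE")),
                   match(out$approach, cc_approaches())), ]
  rownames(out) <- NULL
  out
}

## Fast point-estimate path (no intervals) used by the sweep and the
## coefficient-recovery harness.
.approach_point <- function(data, approach, pi) {
  setup <- .approach_setup(approach, pi)
  models <- fit_models(data, setup$spec)
  contrast <- .fill_contrast(contrast_spec(), data, setup$spec, "means")
  .point_effects(models, contrast, setup$method)
}

#' Prevalence-misspecification sweep
#'
#' Re-runs the IPW-based approaches across a grid of relative errors
#' \eqn{r} in the user-supplied prevalence, \eqn{\pi = \pi_{true}(1+r)},
#' averaging the natural effect estimates over the replicate samples at each
#' grid point. The controls-only and unified approaches do not use a
#' prevalence; their (constant) averages are reported for reference with
#' \code{rel_error = NA}. Grid points with \eqn{\pi(1+r) \ge 1} are skipped
#' with a warning.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n,reps,seed,n_pop as in \code{\link{run_replicates}}.
#' @param grid relative errors; default \{-99\%\} then -95\% to +100\% in
#'   5\% steps.
#' @param include_reference logical; also compute the Approx_C and Unified
#'   reference averages (the unified fit is the slow part).
#' @return data.frame with columns approach, rel_error, pi, NDE, NIE, TE
#'   (replicate-averaged odds ratios).
#' @export
misspecification_sweep <- function(spec, n, reps,
                                   grid = c(-0.99, seq(-0.95, 1, by = 0.05)),
                                   seed = 1L, n_pop = 2e6,
                                   include_reference = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), all(grid > -1))
  pop <- generate_population(spec, n_pop, seed = seed)
  samples <- lapply(seq_len(reps), function(r)
    sample_case_control(pop, n, seed = split_seed(seed, r))$data)
  avg_over <- function(approach, pi) {
    ests <- vapply(samples, function(d) {
      tryCatch(.approach_point(d, approach, pi),
               error = function(e) c(NDE = NA_real_, NIE = NA_real_, TE = NA_real_))
    }, numeric(3))
    rowMeans(ests, na.rm = TRUE)
  }
  rows <- list()
  for (r in grid) {
    pi_r <- spec$pi_true * (1 + r)
    if (pi_r >= 1) {
      warning("grid point ", r, " implies pi >= 1; skipped")
      next
    }
    for (app in c("Approx_IPW", "Exact_IPW")) {
      e <- avg_over(app, pi_r)
      rows[[length(rows) + 1L]] <-
        data.frame(approach = app, rel_error = r, pi = pi_r,
                   NDE = e["NDE"], NIE = e["NIE"], TE = e["TE"])
    }
  }
  if (include_reference) {
    for (app in c("Approx_C", "Unified")) {
      e <- avg_over(app, NULL)
      rows[[length(rows) + 1L]] <-
        data.frame(approach = app, rel_error = NA_real_, pi = NA_real_,
                   NDE = e["NDE"], NIE = e["NIE"], TE = e["TE"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient recovery across replicates with one-sample t-tests
#'
#' Fits the outcome and mediator models on each replicate sample under one
#' estimation strategy and reports the replicate-average coefficient with a
#' two-sided one-sample t-test against the scenario's true value. Estimates
#' exactly at truth in every replicate yield a p-value of 1 (zero
#' t-statistic convention).
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n,reps,seed,n_pop as in \code{\link{run_replicates}}.
#' @param strategy one of "naive", "ipw", "controls_only", "unified".
#' @return data.frame with columns coefficient, true, mean, sd, t, p_value,
#'   n_reps_used.
#' @export
coef_recovery_test <- function(spec, n, reps, strategy = "naive",
                               seed = 1L, n_pop = 2e6) {
  stopifnot(inherits(spec, "scenario_spec"), reps >= 2)
  dspec <- switch(strategy,
    naive = design_spec("naive"),
    ipw = design_spec("ipw", pi = spec$pi_true),
    controls_only = design_spec("controls_only"),
    unified = design_spec("unified"),
    stop("unknown strategy '", strategy, "'"))
  pop <- generate_population(spec, n_pop, seed = seed)
  true_coef <- c(theta0 = spec$theta[1], theta1 = spec$theta[2],
                 theta2 = spec$theta[3], theta3 = spec$theta[4],
                 theta41 = spec$theta[5], theta42 = spec$theta[6],
                 beta0 = spec$beta[1], beta1 = spec$beta[2],
                 beta21 = spec$beta[3], beta22 = spec$beta[4])
  draws <- matrix(NA_real_, nrow = reps, ncol = length(true_coef),
                  dimnames = list(NULL, names(true_coef)))
  for (r in seq_len(reps)) {
    d <- sample_case_control(pop, n, seed = split_seed(seed, r))$data
    fit <- tryCatch(fit_models(d, dspec), error = function(e) NULL)
    if (is.null(fit)) next
    draws[r, ] <- c(fit$outcome$coef, fit$mediator$coef)
  }
  used <- stats::complete.cases(draws)
  rows <- lapply(names(true_coef), function(nm) {
    x <- draws[used, nm]
    sdv <- stats::sd(x)
    if (sdv == 0) {
      at_truth <- isTRUE(all.equal(mean(x), unname(true_coef[nm])))
      tstat <- if (at_truth) 0 else Inf
      pval <- if (at_truth) 1 else 0
    } else {
      tt <- stats::t.test(x, mu = true_coef[nm])
      tstat <- unname(tt$statistic)
      pval <- tt$p.value
    }
    data.frame(coefficient = nm, true = unname(true_coef[nm]),
               mean = mean(x), sd = sdv, t = tstat, p_value = pval,
               n_reps_used = sum(used))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
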