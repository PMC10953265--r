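# medcc — natural effect odds ratios from case-control mediation data

`medcc` estimates natural direct, indirect and total effect odds ratios for
a binary outcome and a continuous or binary mediator when the data come from
a **case-control design**, where sampling on the outcome biases naive
regression fits. It is aimed at biostatisticians and epidemiologists running
regression-based causal mediation analyses on case-control studies, and at
methodologists who want a reproducible harness for comparing estimators.

## The models and estimands

With binary exposure `A`, mediator `M`, covariates `C` and binary outcome
`Y`, the working models are

    logit P(Y=1 | a, m, c) = θ0 + θ1 a + θ2 m + θ3 a·m + θ4'c
    E(M | a, c)  or  logit P(M=1 | a, c) = β0 + β1 a + β2'c

(Gaussian residual SD σ for a continuous mediator). The estimands are the
conditional natural effect odds ratios built from nested counterfactuals
`Y(a, M(a*))`:

    OR_NDE = odds P(Y(1, M(0))=1 | c) / odds P(Y(0, M(0))=1 | c)
    OR_NIE = odds P(Y(1, M(1))=1 | c) / odds P(Y(1, M(0))=1 | c)
    OR_TE  = OR_NDE × OR_NIE

Two estimation routes are implemented: the **approximate** closed forms,
valid under the rare outcome assumption (ROA), and the **exact** route that
evaluates the counterfactual probabilities directly (a logistic-normal
integral, by Gauss–Hermite quadrature, for a continuous mediator). Each
route is combined with a design strategy: **naive** (no correction),
**controls-only** (mediator model fit among controls), **IPW** (cases
weighted by π/p and controls by (1−π)/(1−p), applied to both models; needs
the population prevalence π), or the **unified** joint prospective
likelihood, which needs no π but relies on the ROA. Delta-method and
stratified percentile-bootstrap confidence intervals are provided, along
with a scenario simulator, a replicate-level benchmark
(bias/SD/RMSE/coverage), a prevalence-misspecification sweep and
coefficient-recovery t-tests.

## Worked example

Simulate a case-control study from a bundled scenario in which the outcome
is rare marginally (~7%) but common in high-mediator strata — the regime
where the ROA fails and the approximate route is known to drift:

```r
library(medcc)

spec <- cc_scenario("cont_nonrare_conditional")
pop  <- generate_population(spec, 2e6, seed = 1)
samp <- sample_case_control(pop, 1000, seed = 2, pi_true = spec$pi_true)

estimate_effects(samp$data, design_spec("ipw", pi = spec$pi_true),
                 method = "exact", sandwich = TRUE)
#> Natural effects (odds-ratio scale), method = exact, strategy = ipw
#>  effect     or log_se ci_delta_lower ci_delta_upper method strategy
#>     NDE 1.6892 0.1793         1.1886         2.4007  exact      ipw
#>     NIE 2.8600 0.1334         2.2019         3.7147  exact      ipw
#>      TE 4.8312 0.1850         3.3618         6.9428  exact      ipw

estimate_effects(samp$data, design_spec("ipw", pi = spec$pi_true),
                 method = "approximate", sandwich = TRUE)$table$or
#> [1] 1.771427 3.255036 5.766356

true_effects(spec, "exact")
#>   NDE   NIE   TE
#> 2.045 2.964 6.061
```

Each row is an odds ratio for the 1-vs-0 exposure contrast, conditional on
the sample covariate means, with the SE of its log and a 95% delta
interval. On this single sample the exact-IPW NIE (2.86) sits close to the
truth (2.96) while the approximate NIE overshoots (3.26); single-sample
point estimates carry replicate SDs of roughly 0.3, so systematic
comparisons belong to the replicate harness:

```r
est <- run_replicates(spec, n = 1000, reps = 200, seed = 1, n_pop = 6e5)
summarize_replicates(est, true_effects(spec, "exact"))
```

which reports, per approach and effect, the replicate mean, bias, relative
bias, SD, RMSE and interval coverage — in this scenario the approximate-IPW
total effect shows a relative bias around +30% while exact-IPW stays within
about 2%.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/medcc.R simulate  --scenario cont_rare --n 1000 --out sample.csv
Rscript inst/cli/medcc.R estimate  --data sample.csv --covariates c1,c2 \
        --strategy ipw --pi 0.0057 --method exact --out effects.csv
Rscript inst/cli/medcc.R benchmark --scenario cont_rare --reps 200 --out metrics.csv
Rscript inst/cli/medcc.R sweep     --scenario cont_rare --reps 200 --out sweep.csv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch: it simulates the rare
case-control scenario, applies all six (method, strategy) approaches across
replicate samples, prints the resulting bias/SD/RMSE/coverage table, and
writes the JSON report to `--out`.

## Package layout

- `R/` — data containers and design strategies, weighted model fitting, the
  unified joint likelihood, approximate and exact effect estimators,
  delta/bootstrap inference, the scenario simulator and the benchmark
  harness.
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (published-table arithmetic identities, the
  qualitative benchmark pattern, quadrature-vs-Monte-Carlo and
  likelihood-factorization oracles, IPW recovery).
- `vignettes/case-control-mediation.Rmd` — the methods vignette: model
  details, numerical choices, what the simulator does and does not emulate,
  limitations.
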