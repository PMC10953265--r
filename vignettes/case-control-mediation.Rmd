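---
title: "Natural effect odds ratios from case-control data: models, estimators and design corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural effect odds ratios from case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

Causal mediation analysis decomposes the effect of a binary exposure $A$ on a
binary outcome $Y$ into a natural direct effect (NDE) and a natural indirect
effect (NIE) through a mediator $M$, conditional on covariates $C = c$. On
the odds-ratio scale, with the nested counterfactual $Y(a, M(a^*))$ denoting
the outcome under exposure $a$ with the mediator at the value it would take
under $a^*$:

$$
OR^{NDE}_{a,a^*}(c) = \frac{\mathrm{odds}\,P(Y(a, M(a^*))=1 \mid c)}
                           {\mathrm{odds}\,P(Y(a^*, M(a^*))=1 \mid c)},
\qquad
OR^{NIE}_{a,a^*}(c) = \frac{\mathrm{odds}\,P(Y(a, M(a))=1 \mid c)}
                           {\mathrm{odds}\,P(Y(a, M(a^*))=1 \mid c)},
$$

and the total effect is their product, $OR^{TE} = OR^{NDE} \times OR^{NIE}$.

The working models are a logistic outcome model with exposure–mediator
interaction,

$$\mathrm{logit}\,P(Y=1\mid a,m,c) = \theta_0 + \theta_1 a + \theta_2 m +
\theta_3 am + \theta_4' c,$$

and a linear (Gaussian, residual SD $\sigma$) or logistic mediator model

$$E(M \mid a, c) \;\text{or}\; \mathrm{logit}\,P(M=1\mid a,c)
= \beta_0 + \beta_1 a + \beta_2' c.$$

Two things make case-control data hard here. First, the **approximate**
closed-form effect expressions require the rare outcome assumption (ROA) —
rarity not just marginally but within strata of exposure, mediator and
covariates. Second, outcome-dependent sampling biases naive fits: the
mediator model coefficients are distorted whenever $M$ predicts $Y$, and the
outcome intercept $\theta_0$ is shifted by approximately
$\mathrm{logit}(p) - \mathrm{logit}(\pi)$, where $p$ is the sample case
fraction and $\pi$ the population prevalence. The approximate expressions do
not involve $\theta_0$, but the **exact** estimators do, so the exact route
needs a design correction for *both* models.

## The six approaches

`estimate_effects()` composes a design strategy with an effect formula:

| label | strategy | effect formula |
|---|---|---|
| Approx_Naive | no correction | ROA closed forms |
| Approx_C | mediator model on controls only | ROA closed forms |
| Approx_IPW | weights $\pi/p$ (cases), $(1-\pi)/(1-p)$ (controls), both models | ROA closed forms |
| Exact_Naive | no correction | exact counterfactual probabilities |
| Exact_IPW | IPW, both models | exact counterfactual probabilities |
| Unified | joint prospective likelihood, no $\pi$ needed | ROA closed forms on joint estimates |

The exact counterfactual probability for a binary mediator is a two-term
closed form; for a Gaussian mediator it is the logistic-normal integral

$$P(Y(a,M(a^*))=1\mid c) = \int \mathrm{expit}(\theta_0 + \theta_1 a +
(\theta_2 + \theta_3 a) m + \theta_4'c)\,
\phi\!\left(\frac{m - (\beta_0+\beta_1 a^* + \beta_2'c)}{\sigma}\right)
\frac{dm}{\sigma},$$

which has no closed form and is evaluated by Gauss–Hermite quadrature (see
*Numerical choices*).

The unified likelihood models the control-stratum mediator law (a ROA-style
approximation) jointly with the prospective outcome odds
$\theta(a,m,c) = \exp(\theta_0+\theta_1 a+\theta_2 m+\theta_3 am+\theta_4'c)$:

$$L_p = \prod_i P(M=m_i \mid Y=0, a_i, c_i)\,
\frac{\theta(a_i,m_i,c_i)^{y_i}}{1+\theta(a_i,c_i)},$$

where $\theta(a,c)$ integrates $\theta(a,m,c)$ against the control mediator
law — in closed form for both mediator types (the Gaussian case uses the
moment generating function). Its appeal: all case information enters the
mediator-model estimation and no user-supplied prevalence is needed. Its
cost: it inherits the ROA through the control-stratum approximation, and the
retrospective sampling leaves $\theta_0$ shifted exactly as in the naive
fit, which is why the package feeds its coefficient estimates through the
approximate ($\theta_0$-free) effect formulas.

## Parameters that matter

* `pi` (`design_spec`): the population outcome prevalence (or incidence), a
  probability. Required only for IPW. The misspecification sweep
  (`misspecification_sweep`) quantifies sensitivity to it; as the supplied
  value is driven toward zero, the case weights vanish and the IPW mediator
  fit collapses onto the controls-only fit — controls-only is the implicit
  $\pi \to 0$ limit of IPW.
* `sigma`: residual SD of the continuous mediator, in mediator units.
  Estimated as weighted RSS over $(\sum w - k)$, a weighted-ML estimate with
  a degrees-of-freedom correction.
* Conditioning covariates: effects are conditional on $C=c$; by default $c$
  is the sample-specific covariate mean vector (the convention of the
  reference implementations), with an `ipw_means` option because the
  case-control sample's raw means need not estimate population means.
* `level` (default 0.95) and `bootstrap_config(reps, seed, stratified)`:
  interval settings. Stratified resampling (the default) preserves the fixed
  case:control ratio of the design.

## What the simulator emulates — and what it does not

`generate_population()` draws $C_1 \sim \mathrm{Bern}(0.5)$,
$C_2 \sim N(0, 0.75^2)$ (continuous-mediator case; SD 1 in the binary case),
exposure $A \sim \mathrm{Bern}(\mathrm{expit}(-0.5 + 0.1c_1 - 0.15c_2))$,
then $M$ and $Y$ from the working models — the same generative skeleton as
the evaluation design this package reproduces, with $\sigma = 0.5$ for the
continuous mediator. `sample_case_control()` draws exactly $n/2$ cases and
$n/2$ controls without replacement, the balanced design.

The exact mediator/outcome coefficients of the original five evaluation
scenarios live in a supplement that is not part of the package's sources.
The bundled scenarios (`cc_scenario()`) are therefore *illustrative* specs
chosen once — before any benchmark was run — to land in the prevalence
regimes that drive the phenomenon of interest, and verified by
`scenario_prevalence()`:

* `cont_rare` / `bin_rare`: outcome rare marginally (~0.6%) and in every
  stratum. Here the ROA holds and every approach, naive ones included,
  should be nearly unbiased — a green benchmark establishes agreement, not
  superiority.
* `cont_nonrare_conditional` / `bin_nonrare_strata`: rare marginally
  (~5–7%) but common (>15–20%) in high-mediator strata, via a large
  $\theta_2$. This is the regime where approximate estimators degrade while
  `Exact_IPW` should not.
* `cont_common` / `bin_common`: outcome common marginally (~22–26%).

A green qualitative benchmark on these scenarios establishes that the
*pattern* — near-nominal behaviour under the ROA, degradation of the
approximate route and robustness of the exact-IPW route when conditional
rarity fails — is reproduced. It does not certify the printed table values
of the original study, which would require the original scenario
coefficients. Other idealizations: covariates are exactly as stated (no
measurement error), models are correctly specified (no misspecification
arm), and sampling is exactly balanced with no matching.

The `provaq_synthetic` scenario is a labelled synthetic stand-in for the
published ovarian-cancer application (protective exposure, mediator in
hundreds of lifetime ovulatory cycles, age and education covariates). Its
outcome prevalence is deliberately inflated (~0.3% rather than a realistic
annual incidence of ~1/10,000) so that simulated populations of practical
size contain cases. Demo only; it supports no acceptance claim.

## Numerical choices

* **Quadrature.** Gauss–Hermite nodes/weights from the Golub–Welsch
  eigendecomposition, centered at the mediator mean under $a^*$ and scaled
  by $\sigma\sqrt{2}$; 64 nodes, verified by node-doubling (128, 256, 512)
  against an absolute tolerance of `1e-8`, error if unstable. The
  independent check in the test suite is a stratified Monte-Carlo average
  over $10^6$ Gaussian draws.
* **GLM fitting.** IRLS via `stats::glm.fit` with tolerance `1e-8` and at
  most 100 iterations; `quasibinomial` is used so fractional IPW weights do
  not trigger spurious warnings, with dispersion fixed at 1.
  Non-convergence and (quasi-)separation raise a typed condition
  (`medcc_fit_error`); the benchmark harness counts and excludes such
  replicates.
* **Unified optimization.** BFGS on the unconstrained parametrization
  ($\sigma \mapsto \log\sigma$) started from the controls-only mediator fit
  and naive outcome fit, followed by Newton polishing with
  finite-difference derivatives until the maximum score component is below
  `1e-6`. Proposals that overflow return a large finite penalty so line
  searches back off rather than abort. The covariance is the inverse
  observed information, evaluated by central differences with step
  `1e-5 * (1 + |coef|)`.
* **Overflow control.** All odds are composed on the log scale with
  `log1pexp`/log-sum-exp; $\theta(a,c)$ overflows easily for common
  outcomes otherwise.
* **Degenerate probabilities.** Counterfactual probabilities within `1e-12`
  of 0 or 1 raise an error (odds undefined) instead of being clipped, so
  degenerate fits surface rather than propagate.
* **Delta method.** Central finite-difference gradient (step
  `1e-6 * (1 + |coef|)`) of the log-OR with respect to the concatenated
  $(\theta, \beta)$ vector; $\sigma$ is held fixed at its estimate, as in
  the reference implementations — its uncertainty is captured by the
  bootstrap, not the delta interval.

## Design choices where the ground was open

* **Covariance under IPW.** The exported default is model-based (inverse
  information of the weighted likelihood), with a `sandwich` option. The
  model-based form ignores the design and proved grossly conservative for
  IPW (delta intervals covering essentially always); the sandwich form is
  the standard variance for weighted estimating equations, and the
  benchmark harness uses it for the IPW approaches. Both remain available
  so their coverage can be compared.
* **Bootstrap scheme.** Stratified by outcome by default: the design fixes
  the case:control split, so resampling should too. Unstratified resampling
  is available via `bootstrap_config(stratified = FALSE)`.
* **SD/RMSE conventions.** Replicate SD uses the $n-1$ denominator; RMSE is
  computed from replicate-level squared errors, so
  $\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{SD}^2$ holds exactly up to
  the $n$ vs $n-1$ convention (asserted in the tests).
* **Controls-only $\sigma$.** The whole mediator model, including
  $\sigma$, is fit on controls under the controls-only strategy.
* **Unified $\sigma$.** Maximized jointly (log-parametrized) rather than
  profiled.
* **Seeding.** A counter-based splitter (`split_seed`) derives
  per-replicate and per-bootstrap seeds from one master seed, so any
  replicate is reproducible in isolation and end-to-end runs are
  deterministic.
* **Non-binary contrasts.** The approximate closed forms are defined only
  for the printed 1-vs-0 exposure contrast and reject anything else; the
  exact estimators accept general $(a, a^*)$.

## Known limitations

* The delta interval for effects involving $\sigma$ (continuous-mediator
  NDE with interaction) understates uncertainty slightly because $\sigma$
  is treated as known; use the bootstrap when this matters.
* The unified fit's $\theta_0$ is not interpretable as the population
  intercept (retrospective sampling shifts it); only $\theta_0$-free
  functionals of the unified fit are meaningful.
* Frequency matching, incidence-density sampling subtleties, multiple
  mediators, and risk-ratio/risk-difference scales are out of scope.
* With very strong mediator effects and small samples, separation can
  occur; affected replicates are excluded and counted rather than imputed.

## A worked demo

```r
library(medcc)

spec <- cc_scenario("provaq_synthetic")   # synthetic stand-in, demo only
pop  <- generate_population(spec, 2e6, seed = 1)
samp <- sample_case_control(pop, 1300, seed = 2, pi_true = spec$pi_true)

est <- estimate_effects(samp$data,
                        design_spec("ipw", pi = spec$pi_true),
                        method = "exact")
est            # NDE, NIE, TE odds ratios with delta intervals
true_effects(spec, "exact")
```
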