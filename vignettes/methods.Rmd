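---
title: "Model and methods: the 45-49 year old health check cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkup45)
```

## The decision problem

Australia's Medicare-funded 45-49 year old health check is a one-off general
practice check-up targeting cardiovascular risk factors in otherwise healthy
adults. `checkup45` implements a decision-analytic evaluation of that program
against usual care (no health check), from the perspective of the Australian
health care system. The pipeline has four stages:

1. **Risk-factor microsimulation** — individual profiles (systolic blood
   pressure, total cholesterol, HDL, smoking status) are drawn from per-sex
   categorical distributions emulating the 2011 Australian National Health
   Survey for 45-49 year olds.
2. **Risk translation** — each profile is mapped to a 5-year probability of a
   first cardiovascular (CVD) event with the parametric Framingham risk
   equation; the cohort mean is the arm-level 5-year incidence. The health
   check acts only by re-allocating above-threshold probability mass
   (SBP > 140 mmHg, TC > 6 mmol/L, current smoking) to lower-risk bins, using
   meta-analytic relative risks of *remaining at high risk*.
3. **Markov extrapolation** — a 12-state annual-cycle cohort model follows
   both arms for 50 cycles, accumulating life-years, QALYs and costs.
4. **Decision analysis** — ICERs, a deterministic scenario grid, and a
   probabilistic sensitivity analysis (PSA) with cost-effectiveness
   acceptability curves (CEAC).

## Risk equation

The package hard-codes the published coefficient set of the parametric
(accelerated-failure-time) 5-year CVD equation of Anderson et al. (1991)
(`fre_coefficients()`); the location parameter is linear in log age, log SBP,
log (TC/HDL), smoking, diabetes and ECG-LVH indicators, with
female-specific age terms, and the event probability is
\(p = 1-\exp\{-\exp[(\log t-\mu)/\sigma]\}\) with \(\sigma =
\exp(0.9145-0.2784\,\mu)\) and \(t = 5\) years. Two published variants of the
Framingham equation exist (points-based and parametric); the parametric form
is adopted because it accepts continuous inputs and a 5-year horizon
directly. Diabetes and LVH are fixed absent: the target population is healthy
45-49 year olds. Profiles are evaluated at age 47, the band midpoint.

## The synthetic risk-factor distributions

The survey's exact bin boundaries and masses are not reproduced here; the
shipped distributions (`inst/extdata/default_config.yaml`) are **synthetic
emulations**. Bin structure (six SBP, seven TC, five HDL bins plus smoking
status, each with a representative value used as the equation input) was
fixed a priori at conventional clinical cut-points, and the masses were
calibrated once, by optimization, so that under the exact joint expectation
of the risk equation:

* the usual-care arm reproduces the published 5-year incidences — 3.7%
  (males) and 1.5% (females), and
* applying the published relative risks (TC 0.63, SBP 0.71, smoking 0.90)
  reproduces the published between-arm relative risks — 0.87 (males) and
  0.91 (females).

Both constraints are needed because the intervention effect depends on the
above-threshold masses, which the incidence constraint alone does not pin
down. Consequences for interpretation: passing checks against the published
results validates the *pipeline arithmetic*, not the survey representation;
the defaults are flagged as emulation, and users with access to the real
survey tables can substitute them in the configuration. Factors are sampled
independently (the survey reports marginals only); no correlation structure,
no time-varying risk factors within the 5-year window.

Reallocated high-risk mass is redistributed over the below-threshold bins
*proportionally to their existing masses*, preserving the shape of the
low-risk distribution; smokers moved by the smoking RR become non-smokers.
An alternative (moving mass to the adjacent bin only) would concentrate
reallocated patients just under the threshold and weaken the modelled
benefit; the proportional rule is the package's choice and is exercised by
the mass-conservation and monotone-benefit property tests.

## Markov model

States: alive without CVD; five single-cycle tunnel states for the first
event of stable angina (SA), unstable angina (UA), myocardial infarction
(MI), stroke and TIA; five post-event states; dead. No repeat events are
modelled: post-event occupancy flows only to itself or death.

* **Cycles 1-5**: the arm-specific 5-year incidence is converted to a
  constant annual probability \(1-(1-p_5)^{1/5}\) (round-trip exact) and
  split across subtypes with the 45-49 allocation shares. The published
  shares sum to slightly less than one (0.954 males, 0.975 females); they
  are applied as printed, the residual share representing presentations
  outside the five modelled subtypes, which generate no modelled event.
  `settings$normalize_allocation: true` rescales them to one instead.
* **Cycles 6+**: age-band annual subtype incidences, identical in both arms
  (the intervention is assumed to have no effect beyond five years).
* **Mortality**: CVD-free background mortality by age band; event and
  post-event states multiply it by the condition's standardized mortality
  ratio (SMR), capped at 1. The same SMR applies to the event year and the
  post-event years.
* **Ageing**: the cohort enters at age 45 and ages one year per cycle; ages
  beyond the last tabulated band reuse it. The arm-specific (FRE-derived)
  probabilities are used for all five initial cycles even as the cohort
  crosses age 50.

### Rewards and conventions

Occupancy is recorded at cycle end; rewards are discounted with exponent
equal to the cycle index (the first cycle is discounted once). No half-cycle
correction is applied. **Life-years are reported undiscounted; QALYs and
costs are discounted at 5%/year (3.5% in a scenario)** — the reporting
convention of the evaluation this package implements; `life_years()` takes
an explicit rate if discounted life-years are wanted.

Utilities: the CVD-free state carries the age-band population utility
\(u_{pop}\); the event-year tunnel states carry the absolute acute utility
weights (UA 0.770, SA 0.808, MI 0.760, stroke 0.629, TIA 1 — no decrement);
post-event states carry
\(u_{pop}\times\bigl(1-(1-\rho)(1-u_{acute})\bigr)\), where \(\rho\) is the
*reduction* of the acute disutility carried forward (base case \(\rho=0.5\),
"50% reduction"). The decrement is measured from full health and applied
multiplicatively to the age-matched population utility; this combination was
selected because it is the only one of the four natural conventions
(additive/multiplicative × decrement-from-population/decrement-from-full-health)
that reproduces the published scenario grid of incremental QALYs across
\(\rho \in \{0, 0.25, 0.5, 0.75, 1\}\).

Costs: each event-year occupancy incurs the subtype's acute hospitalization
cost; each post-event year costs a fraction \(f\) of the acute cost (base
0.15; scenarios 0.10/0.20). The intervention arm pays the direct
health-check cost once at entry, undiscounted (a time-zero outlay); usual
care carries no primary-care cost. The direct cost means ($393 male, $355
female) are reproduced by a service-bundle calculator — base check cost
$193 plus per-condition annual management bundles weighted by prevalence,
uptake and compliance — whose bundles are likewise synthetic and calibrated
to the published mean/minimum/maximum.

## Scenario analysis

One-way departures from the base case: \(\rho \in \{0, 0.25, 0.75, 1\}\),
\(f \in \{0.10, 0.20\}\), and a 3.5% discount rate. Expected behaviour,
verified by tests: the life-year difference responds only to the discount
rate; \$/LY is invariant to \(\rho\); the \$/QALY ICER increases with
\(\rho\), decreases with \(f\), and decreases at the lower discount rate.

## Probabilistic sensitivity analysis

One joint draw per iteration, 1,000 iterations by default, full Markov and
costing evaluation per draw, per sex and arm:

| Block | Family | Parameterization |
|---|---|---|
| SMRs, intervention RRs | lognormal | mean + 95% CI (log-scale SD = CI half-width / 1.96; location preserves the mean) |
| population & acute utilities | beta | mean + SE by moment matching |
| hospitalization costs | uniform | ±25% |
| health-check direct cost | uniform | printed (min, max) |
| allocation, age-band incidence, mortality | uniform | ±25% (unpublished ranges; mirrors the cost range) |
| arm-level 5-year incidence | uniform | within the 2.5-97.5 percentile interval of the repeated cohort simulation |

The two arms' incidences are sampled with a **shared quantile** by default,
preventing spurious reversals of the arm ordering that independent sampling
of two narrow overlapping intervals could produce; set
`psa$arm_correlation: independent` to decouple them. Perturbed allocation
shares are rescaled to preserve their original total. The PSA samples the
incidence summary rather than re-running the microsimulation per draw — the
microsimulation's sampling uncertainty enters through the incidence
intervals. The intervention RRs are therefore not separately sampled in the
PSA (their uncertainty is embodied in the health-check arm's interval).
CEACs report, at each willingness-to-pay \(\lambda\), the fraction of draws
with net monetary benefit \(\lambda\,\Delta QALY - \Delta cost \ge 0\), on a
$0-$150,000 grid that always includes the $28,000 and $50,000 thresholds.

## Numerical choices and degenerate inputs

* Exact arm incidences are computed by enumerating the joint bin grid
  (6×7×5×2 = 420 cells) — no Monte Carlo error in the deterministic base
  case; the microsimulation (`simulate_arms()`) exists to quantify sampling
  uncertainty and uses split seed streams per repetition.
* Transition-matrix rows are validated to sum to 1 within 1e-12 at build
  time; trace occupancy is checked to 1e-9 at reward time.
* Thresholds must align with bin boundaries, otherwise reallocation is
  rejected as ill-defined; bin masses must sum to 1 within 1e-6.
* Beta priors with SE = 0 (e.g. the fixed TIA utility) degenerate to their
  mean; an SE implying variance ≥ mean(1−mean) is a fit error.
* Zero effect differences yield an `undefined` ICER flag rather than an
  error; dominance is classified per standard CEA conventions.

## Problem sizes

The shipped defaults follow the study design: cohorts of 5,000 per sex per
arm, 50 annual cycles, 1,000 PSA draws. The test suite exercises the
microsimulation at 200 repetitions and the examples here use smaller sizes;
all sizes are arguments, and the acceptance script
(`scripts/acceptance.R`) uses the full 1,000-draw PSA.

## Known limitations

* The risk-factor distributions and service bundles are calibrated
  emulations, not survey or cost-collection extracts (see above).
* No risk-factor correlation, no repeat CVD events, no non-CVD morbidity,
  no treatment disutilities, no societal-perspective costs.
* The Framingham equation is known to underestimate cerebrovascular
  incidence; `validate_incidence()` supports an informational comparison
  against a user-supplied national reference table but no recalibration.
* Structural conventions the source evaluation left unstated (discount
  exponent, annualization, cost timing, start age) were fixed here by
  internal-consistency arguments; quantities that depend on them carry a
  tolerance of a few percent, which is why the package's checks use bands
  rather than exact equality.

```{r example, eval = FALSE}
config <- load_config()
base <- run_base_case(config)
base$table
scenarios <- run_scenarios(config)
draws <- run_psa(config, n_draws = 1000, seed = 1)
curve <- ceac(draws)
```
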