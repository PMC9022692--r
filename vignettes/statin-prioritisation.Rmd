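---
title: "Modelling statin prioritisation policies: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling statin prioritisation policies: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinpolicy)
```

## The problem

Statins for primary prevention of cardiovascular disease (CVD) are usually
allocated by a 10-year risk score: treat everyone whose predicted risk of a
first CVD event exceeds a threshold (20% or 10% in UK practice, using the
ASSIGN score in Scotland). Risk scoring has two well-known blind spots.
First, age dominates 10-year risk, so risk thresholds concentrate treatment
in the elderly — including people whose high risk is driven by the competing
hazard of non-CVD death, who have little to gain. Second, the benefit of a
statin is mediated by cholesterol lowering: two people with identical risk
but different baseline cholesterol obtain very different risk reductions.

`statinpolicy` implements a full decision-analytic pipeline for comparing
three prioritisation families at matched programme sizes:

* **fixed risk** — treat if 10-year CVD risk ≥ threshold;
* **age-stratified risk** — treat if risk is high *relative to age-group
  peers* (one within-band quantile shared across 5-year bands);
* **ARR-guided** — treat if the predicted 10-year *absolute risk reduction*
  from therapy exceeds a threshold.

## The ARR equation

Trial meta-analysis gives a near-constant relative risk reduction per
1.0 mmol/L of lipid lowering; a reduction of $\delta$ mmol/L therefore
carries hazard ratio $HR^{\delta}$ and RRR $= 1 - HR^{\delta}$. With
10-year untreated survival $S_{un}$, baseline lipid level $\ell$, and
proportional reduction $p$ on therapy, the predicted 10-year ARR is

$$\mathrm{ARR} = S_{un}^{\,x} - S_{un}, \qquad x = HR^{\,\ell \cdot p}.$$

The classical form uses LDL-C with $p = 0.40$; this package's pipeline is
non-HDL-C native ($p = 0.26$, matching the treatment effect axis of the
simulation model), because survey data provide TC and HDL-C but not LDL-C.
Since the equation needs a single combined-endpoint hazard ratio while the
evidence gives cause-specific relative risks (0.77 nonfatal CHD, 0.87
nonfatal stroke, 0.90 fatal CVD per mmol/L), `combined_cvd_hr()` takes a
risk-share-weighted geometric mean per profile — the only combination that
preserves the single-HR form of the equation while respecting each
individual's cause mix. `arr_score()` uses the engine's own competing-risk
event-free survival for $S_{un}$ (combined endpoint), so eligibility and
simulation are mutually consistent; a fatal-only variant would slot in via
the `arr_survival` argument.

A property worth knowing: $f(S) = S^x - S$ with $x < 1$ peaks at
$S^\ast = x^{1/(1-x)} \le 1/e$. ARR is therefore increasing in baseline risk
only while $S_{un} > 1/e$ (10-year risk below ≈63%) — always true in a
screening population, and the property-based tests restrict themselves to
that range deliberately.

## The multistate engine

Individuals enter CVD-free and face four competing primary events each
annual cycle: nonfatal CHD, nonfatal cerebrovascular disease, fatal CVD,
fatal non-CVD. Survivors of a nonfatal event occupy a chronic state
(CHD or CBVD) subject to elevated all-cause mortality into an absorbing
post-event death state. Within-cycle competition uses the exact
constant-hazard decomposition
$P(\text{event } c) = \frac{h_c}{\sum h}\bigl(1 - e^{-\sum h}\bigr)$.
Outcomes are deterministic expectations over state occupancy (cohort
method), not individual-level Monte Carlo; the implementation is vectorised
over profiles so a 10,000-profile cohort simulates in well under a second
per scenario.

Numerical and structural choices, made once:

* **Baseline hazards** are Gompertz in age (proportional hazards), the
  standard form for adult CVD and all-cause mortality; every parameter is
  configuration, and constant-hazard configurations (shape 0) are used by
  the matrix-product oracle tests.
* **Cycle accounting**: annual cycles, half-cycle correction for QALYs and
  costs (toggleable via `half_cycle = FALSE`, which the oracle tests use so
  expectations match explicit transition-matrix products exactly).
* **Lifetime horizon**: death is forced on reaching `max_age = 110`, with no
  accrual in the forced cycle, so zero hazards give life-years exactly
  `max_age - age`.
* **Discounting**: 3.5%/year, first cycle undiscounted ($t = 0$); either
  convention is defensible, this one is pinned for reproducibility.
* **Secondary events** (recurrent MI, stroke, TIA, heart failure, ...) are
  annual expected utility decrements and costs inside the chronic states,
  not explicit sub-states.
* **Risk factors are frozen at baseline** for the lifetime; cumulative
  exposure modelling is out of scope.
* Lifetime *cumulative* event probabilities are reported per cause; note
  that treatment can slightly raise the lifetime cumulative probability of a
  late competing event even as it lowers every CVD hazard — people live
  longer. Fixed-horizon risks always fall under treatment.

## Treatment representation

Statins lower each profile's non-HDL-C by 26%, multiplying the three CVD
cause-specific hazards by $rr_c^{\,\mathrm{nonHDL} \times 0.26}$ — so benefit
scales with baseline cholesterol, which is what makes ARR-guided
prioritisation differ from risk scoring. Side effects and costs: +0.5%
absolute new-onset diabetes risk at initiation (represented as an expected
annual management cost, the costs-only treatment the evidence supports),
0.002 QALY/year pill-taking disutility, £13.44/year generic atorvastatin
tariff (2020 price, exempt from inflation), plus monitoring costs. The
adherence scenario keeps 67% / 53% / 50% of initiators on therapy in years
1 / 2 / 3+; the engine blends the hazard multiplier per cycle as
$1 + (m - 1)\,pf_t$ rather than tracking stopping-time subgroups — an
approximation that is exact at $pf \in \{0, 1\}$ and conservative in
between; non-persistent patients incur first-year costs only, and the base
case assumes full adherence.

## The synthetic cohort

The generator stands in for a national health-survey extract (CVD-free
adults ≥40) whose microdata cannot be redistributed. What it emulates:
a majority-female adult age structure in 5-year bands; a sex-stratified
Gaussian copula over SBP, TC, HDL-C and deprivation with log-normal lipids;
point-mass-inflated smoking (75% non-smokers); age-graded diabetes,
prevalent CVD and statin use; block missingness of TC/HDL-C/SBP for a
nurse-visit refusal subgroup (25%) plus age-tilted (MAR) item missingness;
and statin users observed on the *treated* lipid scale so that detreatment
(dividing non-HDL-C by 0.74) recovers a coherent pre-treatment value. What
it does **not** emulate: survey weighting design, household clustering,
measurement error, or any real joint-distribution detail beyond the stated
copula — so a green test establishes that the *method* behaves as claimed on
a structurally faithful population, not that any published population-level
ICER is reproduced. Those headline numbers require the real survey microdata
and fitted registry survival/cost parameters, which are configuration inputs
here, shipped as clearly synthetic defaults with UK-plausible magnitudes.

The preprocessing order is fixed and tested: generate → impute (stochastic
regression of each sparse variable on the fully observed covariates plus a
residual draw; bounds SBP ∈ [70, 250], TC ∈ [2, 12], HDL-C ∈ [0.4, 4], 100
redraws then clip, truncations logged) → detreat current statin users →
exclude (age < 40, prevalent CVD, and the familial-hypercholesterolaemia
rule TC ≥ 7.5 with family history or TC ≥ 8.0, evaluated on detreated
cholesterol). "Premature" family history is collapsed to the single
family-history flag; cigarettes/day, diabetes and family history are never
imputed (only the three sparse nurse-visit variables are). The refusal
subgroup supports proper multiple imputation (`impute_multiple()`, m ≥ 2,
shared completion of non-refuser missingness); the orchestrated pipeline
uses a single stochastic-regression completion — analyses averaging over
multiple completions call `impute_multiple()` and pool downstream results
themselves.

## Calibration, uncertainty, synthesis

**Calibration** (`calibrate_to_count()`) matches programme sizes: thresholds
are weighted quantiles of the score (inclusive ≥ at the threshold, ties
included), tolerance ±0.5% of cohort weight, nearest-attainable with a
warning flag otherwise. The age-stratified family solves one within-band
quantile by bisection — the only rule consistent with "high risk relative to
age peers" plus a count constraint, given that published band thresholds are
not available.

**PSA** samples the treatment/cost measures (beta for proportions, gamma
for costs, normal-on-log-scale for relative risks — standard assignments
where families are unpublished) and the CVD log-hazard coefficients from a
multivariate normal via Cholesky decomposition. Baseline Gompertz
parameters are not sampled. Per-iteration seeds are counter-split from one
master seed; eligibility thresholds are calibrated at base case and held
fixed across iterations. Summaries follow the means convention: base-case
results are means over iterations, intervals are 2.5th/97.5th percentiles
(linear interpolation), and the ICER is the ratio of mean increments, never
the mean of ratios.

**CEA synthesis**: strict dominance, then extended dominance (a strategy
with a higher ICER than the next more effective alternative), pairwise
ICERs along the frontier — verified against an independent NMB-argmax
enumeration oracle on 1,000 random strategy sets. CEACs over a
£0–£50,000 grid in £500 steps; within-iteration NMB ties split equally and
are logged. Tornado analyses rerun the deterministic model one measure at a
time between its low/high bounds. Negative incremental QALYs are reported
as dominance flags, never as signed ICERs. Optional plot files are out of
scope: all curve/bar data are emitted as CSV for external plotting.

## Orchestration

`run_pipeline(config, output_dir)` is the package's command line: JSON
configuration (JSON rather than YAML, as the environment pins `jsonlite`),
validated before any computation, all randomness descending from one master
seed, CSV/JSON outputs plus a manifest with an FNV-1a config fingerprint.
Reruns are byte-identical. `scenario_runner()` covers the adherence,
diabetes-removal, pill-disutility-sweep and risk-threshold-sweep analyses;
the disutility sweep exploits the linearity of QALYs in the disutility
through discounted treated person-years rather than re-simulating.

## What the defaults show

On the default synthetic cohort (n = 10,000, seed 1), the count-matched
ARR strategies attain at least the QALYs of their fixed-risk counterparts
at essentially the same cost, the age-stratified strategies are dominated,
and raising pill-taking disutility flips the optimal programme size from
the larger to the smaller ARR programme (crossover between 0.002 and 0.01
QALY/year with the shipped synthetic parameters). These are the qualitative
orderings the acceptance suite checks; no population-level cost per QALY
from any published analysis is asserted, for the reasons above.

## Known limitations

* Default survival/utility/cost values are synthetic placeholders; absolute
  outputs are only meaningful relative to each other until real fitted
  parameters are supplied.
* Adherence blending is a per-cycle approximation (see above).
* The diabetes side effect carries costs but no utility decrement.
* Chronic-state costs are evaluated at current age rather than tracking the
  exact age-at-event distribution within the expectation engine.
* No value-of-information analysis, societal-perspective costs, or
  equity-weighted CEA.
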