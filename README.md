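# statinpolicy

Decision-analytic modelling of statin prioritisation policies for the
primary prevention of cardiovascular disease (CVD).

Most guidelines allocate preventive statins by a 10-year risk score: treat
everyone above a risk threshold. But 10-year risk is dominated by age and
ignores both the competing risk of non-CVD death and the fact that statin
benefit is mediated by cholesterol lowering. This package implements and
compares, at matched programme sizes, three prioritisation families:

* **fixed risk** — treat if 10-year CVD risk ≥ threshold (e.g. ≥20%, ≥10%);
* **age-stratified risk** — treat those at high risk relative to their
  age-group peers (a shared within-band quantile across 5-year age bands);
* **ARR-guided** — treat if the predicted 10-year absolute risk reduction
  from therapy exceeds a threshold.

At its core are:

1. a competing-risk multistate cohort simulator (CVD-free → {nonfatal CHD,
   nonfatal cerebrovascular disease, fatal CVD, fatal non-CVD} → chronic
   states → absorbing death), annual cycles with the exact constant-hazard
   decomposition *P*(event *c*) = (*h*<sub>c</sub>/Σ*h*)(1 − e<sup>−Σh</sup>),
   expectation-based and vectorised over profiles;
2. the ARR prioritisation equation
   **ARR = S<sub>un</sub><sup>x</sup> − S<sub>un</sub>,
   x = HR<sup>ℓ·p</sup>**, with S<sub>un</sub> the 10-year untreated
   event-free survival, HR the hazard ratio per 1.0 mmol/L lipid reduction,
   ℓ the baseline lipid level and *p* the proportional reduction on therapy
   (non-HDL-C native: *p* = 0.26, cause-specific RRs 0.77/0.87/0.90 per
   mmol/L combined by a risk-share-weighted geometric mean);
3. threshold calibration to matched treated counts, lifetime QALY/cost
   valuation (3.5% discounting, half-cycle correction), probabilistic
   sensitivity analysis with Cholesky-correlated hazard-ratio draws, and
   cost-effectiveness synthesis (ICER frontier with extended dominance,
   net monetary benefit, CEACs, tornado analyses, population projection);
4. a synthetic cohort generator emulating a national health survey of
   CVD-free adults ≥40 — joint risk-factor structure, nurse-visit refusal
   block-missingness, stochastic-regression and multiple imputation,
   detreatment of current statin users, and the familial-
   hypercholesterolaemia exclusion (TC ≥ 7.5 mmol/L with family history, or
   TC ≥ 8.0).

Shipped survival/utility/cost defaults are **synthetic** UK-plausible
placeholders: real fitted parameters are configuration inputs, so absolute
outputs are meaningful relative to each other, not as reproductions of any
published population-level figure.

## Worked example

```r
library(statinpolicy)

profile <- data.frame(id = 1, age = 58, sex = "male", diabetes = FALSE,
                      sbp = 148, tc = 6.8, hdl = 1.1, cpd = 10, simd = 45,
                      famhist = TRUE, on_statin = FALSE,
                      prevalent_cvd = FALSE, refused_nurse = FALSE,
                      weight = 1)

risk <- ten_year_risk(profile)   # competing-risk 10-year CVD risk
arr  <- arr_score(profile)       # predicted 10-year ARR from a statin
cat(sprintf("10-year CVD risk: %.1f%% | predicted 10-year ARR: %.1f%%\n",
            100 * risk, 100 * arr))
#> 10-year CVD risk: 37.4% | predicted 10-year ARR: 8.4%

simulate_lifetime(profile, "untreated")
#> <lifetime_outcome> untreated: 9.514 QALYs, 15.80 life-years, GBP 21884
simulate_lifetime(profile, "treated")
#> <lifetime_outcome> treated: 9.689 QALYs, 16.07 life-years, GBP 21557
```

A smoker with high non-HDL-C (5.7 mmol/L): lifetime treatment yields 0.176
discounted QALYs *and* saves £327 (averted CVD hospitalisation costs exceed
drug plus monitoring costs under the synthetic defaults) — treatment
dominates for this profile.

The full pipeline — generate, impute, detreat, exclude, calibrate the six
policies against no-treatment, simulate, PSA, CEA — runs from one JSON-able
configuration:

```r
res <- run_pipeline(default_config(n = 2000, seed = 1,
                                   psa_iterations = 50),
                    output_dir = "out")
res$psa_summary$frontier   # ICER frontier over PSA means
scenario_runner(default_config(n = 2000, seed = 1), "adherence")
```

Outputs (cohort, base case, eligibility tables, PSA draws and summaries,
frontier, CEAC) are written as CSV/JSON with a seeded, byte-reproducible
manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the worked relative-risk-reduction
examples (baseline LDL-C 4.0 and 2.0 mmol/L under a 40% proportional
reduction at a hazard ratio of 0.78 per mmol/L, reported as whole-percent
RRRs) and writes them as JSON.
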