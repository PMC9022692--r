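# Shared fixtures: toy profiles and constant-hazard parameter sets.

toy_profile <- function(age = 60, sex = "female", diabetes = FALSE,
                        sbp = 130, tc = 5, hdl = 1.3, cpd = 0, simd = 20,
                        famhist = FALSE, on_statin = FALSE, weight = 1) {
  data.frame(id = 1L, age = age, sex = sex, diabetes = diabetes, sbp = sbp,
             tc = tc, hdl = hdl, cpd = cpd, simd = simd, famhist = famhist,
             on_statin = on_statin, prevalent_cvd = FALSE,
             refused_nurse = FALSE, weight = weight,
             stringsAsFactors = FALSE)
}

# constant cause-specific hazards (no age dependence, no covariate effects)
constant_hazard_params <- function(h_chd = 0, h_cbvd = 0, h_fatal_cvd = 0,
                                   h_noncvd = 0, h_chronic_chd = 0.1,
                                   h_chronic_cbvd = 0.1, max_age = 110) {
  to_lr <- function(h) if (h > 0) log(h) else -745 # exp(-745) == 0
  survival_params(
    coef = matrix(0, 4, 8),
    gompertz = data.frame(
      cause = PRIMARY_CAUSES,
      log_rate = c(to_lr(h_chd), to_lr(h_cbvd), to_lr(h_fatal_cvd),
                   to_lr(h_noncvd)),
      shape = 0),
    chronic = list(chd = c(log_rate = to_lr(h_chronic_chd), shape = 0),
                   cbvd = c(log_rate = to_lr(h_chronic_cbvd), shape = 0)),
    centering = c(sbp = 130, tc = 5, hdl = 1.3, simd = 20),
    hr_covariance = matrix(0, 24, 24),
    max_age = max_age)
}

# flat utilities/costs so hand arithmetic is easy; no inflation
flat_econ <- function(utility = 1, discount = 0, ...) {
  econ_params(discount_rate = discount, inflation_factor = 0,
              wtp_threshold = 20000,
              bg_utility = list(intercept_female = utility,
                                intercept_male = utility,
                                age_slope = 0, floor = 0),
              chronic_decrement = c(chd = 0, cbvd = 0),
              secondary_decrement = c(chd = 0, cbvd = 0),
              screening_cost = 0, monitoring_cost = 0, diabetes_cost = 0,
              bg_cost = list(intercept = 0, age_slope = 0),
              event_cost_pre = c(intercept = 0, age = 0, simd = 0,
                                 famhist = 0),
              event_cost_post = c(intercept = 0, age = 0, simd = 0,
                                  famhist = 0),
              ...)
}

null_treatment <- function() {
  treatment_params(nonhdl_reduction = 0, rr_nonfatal_chd = 1,
                   rr_nonfatal_stroke = 1, rr_fatal_cvd = 1,
                   diabetes_abs_risk_increase = 0, pill_disutility = 0,
                   annual_drug_cost = 0)
}

small_cohort <- function(n = 400, seed = 99, ...) {
  prep <- preprocess_cohort(cohort_spec(n = n, seed = seed, ...))
  prep$cohort
}
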