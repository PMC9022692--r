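# Absolute / relative risk-reduction mathematics for statin prioritisation.
# The key identity: trial evidence gives a near-constant hazard ratio per
# 1.0 mmol/L lipid reduction, so a reduction of `delta` mmol/L carries
# HR^delta, an RRR of 1 - HR^delta, and a 10-year absolute risk reduction of
# S_un^x - S_un with x = HR^(baseline lipid x proportional reduction).

#' Relative risk reduction from a lipid reduction
#'
#' `1 - hr_per_mmol ^ delta`: the proportional CVD risk reduction implied by
#' lowering the lipid level by `delta` mmol/L when each 1.0 mmol/L reduction
#' carries hazard ratio `hr_per_mmol` (e.g. 0.78 for the canonical 22% RRR
#' per mmol/L of LDL-C).
#'
#' @param delta lipid reduction in mmol/L (>= 0).
#' @param hr_per_mmol hazard ratio per 1.0 mmol/L reduction, in (0, 1].
#' @return proportion in \[0, 1).
#' @export
rrr_from_lipid_reduction <- function(delta, hr_per_mmol) {
  if (any(delta < 0)) stop("delta must be non-negative")
  if (any(hr_per_mmol <= 0 | hr_per_mmol > 1)) {
    stop("hr_per_mmol must lie in (0, 1]")
  }
  1 - hr_per_mmol^delta
}

#' Absolute lipid reduction from a proportional one
#'
#' @param baseline baseline lipid level, mmol/L (> 0).
#' @param pct proportional reduction in \[0, 1) (e.g. 0.40 for atorvastatin
#'   20 mg on LDL-C, 0.26 for the non-HDL-C axis).
#' @return reduction in mmol/L, `baseline * pct`.
#' @export
lipid_reduction <- function(baseline, pct) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  if (any(pct < 0 | pct >= 1)) stop("pct must lie in [0, 1)")
  baseline * pct
}

#' Ten-year absolute risk reduction from statin therapy
#'
#' ARR = S_un^x - S_un with x = HR^(ldlb x reduction_pct), where S_un is the
#' 10-year untreated survival (of the CVD endpoint), HR the hazard ratio per
#' 1.0 mmol/L lipid reduction, and ldlb the baseline lipid level. In the
#' LDL-C form reduction_pct = 0.40; the non-HDL-C modification substitutes the
#' baseline non-HDL-C level and reduction_pct = 0.26.
#'
#' @param S_un 10-year untreated survival, in (0, 1].
#' @param HR hazard ratio per 1.0 mmol/L reduction, in (0, 1].
#' @param ldlb baseline lipid level, mmol/L (> 0).
#' @param reduction_pct proportional lipid reduction on treatment.
#' @return absolute risk reduction, a probability >= 0 when HR <= 1.
#' @export
arr_10yr <- function(S_un, HR, ldlb, reduction_pct = 0.40) {
  if (any(S_un <= 0)) stop("S_un = 0 is degenerate")
  if (any(S_un > 1)) stop("S_un must lie in (0, 1]")
  if (any(HR <= 0 | HR > 1)) stop("HR must lie in (0, 1]")
  if (any(ldlb <= 0)) stop("ldlb must be positive")
  x <- HR^(ldlb * reduction_pct)
  S_un^x - S_un
}

#' Combined CVD hazard ratio per mmol/L of non-HDL-C
#'
#' The ARR equation needs a single hazard ratio for the combined CVD endpoint,
#' while trial evidence gives cause-specific relative risks (nonfatal CHD,
#' nonfatal stroke, fatal CVD). This combines them as a risk-share-weighted
#' geometric mean: `exp(sum_c w_c * log(rr_c))` with `w_c` each cause's share
#' of the profile's 10-year CVD incidence (equal shares if none supplied).
#'
#' @param treatment a [treatment_params()].
#' @param shares matrix or vector of per-cause incidence shares in the order
#'   (nonfatal CHD, nonfatal CBVD, fatal CVD); rows are profiles.
#' @return hazard ratio(s) in (0, 1].
#' @export
combined_cvd_hr <- function(treatment = treatment_params(), shares = NULL) {
  log_rr <- log(c(treatment$rr_nonfatal_chd, treatment$rr_nonfatal_stroke,
                  treatment$rr_fatal_cvd))
  if (is.null(shares)) shares <- rep(1 / 3, 3)
  if (is.matrix(shares)) {
    sw <- shares / pmax(rowSums(shares), 1e-300)
    exp(drop(sw %*% log_rr))
  } else {
    exp(sum(shares / sum(shares) * log_rr))
  }
}

#' Per-profile ARR score on the non-HDL-C axis
#'
#' Evaluates the modified ARR equation for every profile in a cohort:
#' untreated 10-year CVD event-free survival from the competing-risk engine,
#' a per-profile combined hazard ratio (risk-share weighted), baseline
#' non-HDL-C and the treatment's proportional non-HDL-C reduction.
#'
#' @param cohort cohort data.frame with complete covariates.
#' @param params a [survival_params()].
#' @param treatment a [treatment_params()].
#' @param arr_survival `"combined"` uses CVD event-free survival
#'   `1 - ten_year_risk` (competing-risk cumulative incidence); configurable
#'   hook for alternative survival definitions.
#' @return numeric vector of 10-year ARR probabilities.
#' @export
arr_score <- function(cohort, params = default_survival_params(),
                      treatment = treatment_params(),
                      arr_survival = c("combined")) {
  arr_survival <- match.arg(arr_survival)
  inc <- ten_year_risk(cohort, params, by_cause = TRUE)
  S_un <- pmax(1 - inc[, "cvd"], 1e-12)
  hr <- combined_cvd_hr(treatment, shares = inc[, CVD_CAUSES, drop = FALSE])
  nonhdl <- cohort$tc - cohort$hdl
  arr_10yr(S_un, hr, nonhdl, reduction_pct = treatment$nonhdl_reduction)
}

#' Treatment modifiers for one profile
#'
#' Translates [treatment_params()] into the per-cycle modifiers the simulator
#' applies: per-cause hazard multipliers `rr_c ^ (non-HDL-C x reduction)`, the
#' annual pill disutility, the annual drug cost, and the expected annual
#' diabetes-management cost from the absolute incident-diabetes risk increase.
#'
#' @param profile single-row data.frame with complete risk factors.
#' @param params a [treatment_params()].
#' @return list with `hazard_multipliers` (named, nonfatal_chd /
#'   nonfatal_cbvd / fatal_cvd), `pill_disutility`, `annual_drug_cost`,
#'   `diabetes_abs_risk_increase`.
#' @export
apply_statin_modifiers <- function(profile, params = treatment_params()) {
  profile <- as.data.frame(profile)
  nonhdl <- profile$tc - profile$hdl
  if (any(is.na(nonhdl)) || any(nonhdl <= 0)) {
    stop("profile needs observed non-HDL-C > 0")
  }
  delta <- nonhdl * params$nonhdl_reduction
  mult <- c(nonfatal_chd = params$rr_nonfatal_chd^delta,
            nonfatal_cbvd = params$rr_nonfatal_stroke^delta,
            fatal_cvd = params$rr_fatal_cvd^delta)
  list(hazard_multipliers = mult,
       pill_disutility = params$pill_disutility,
       annual_drug_cost = params$annual_drug_cost,
       diabetes_abs_risk_increase = params$diabetes_abs_risk_increase)
}

#' Persistence fraction by year since statin initiation
#'
#' Base case: full adherence (1 in every year). Adherence scenario: 0.67 of
#' initiators remain on treatment in year 1, 0.53 in year 2, 0.50 in all
#' subsequent years.
#'
#' @param years_since_initiation integer year index, >= 1.
#' @param params a [treatment_params()].
#' @return proportion(s) in \[0, 1\].
#' @export
persistence_fraction <- function(years_since_initiation,
                                 params = treatment_params()) {
  if (any(years_since_initiation < 1)) {
    stop("years_since_initiation must be >= 1")
  }
  persistence_schedule(params, years_since_initiation)
}
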