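# Parameter containers: cause-specific survival model, statin treatment
# measures, and health-economic values. Default numeric values are SYNTHETIC
# stand-ins with UK-plausible magnitudes (the fitted cohort coefficients and
# national cost/utility tables are not redistributable); every field is a
# plain list element and can be replaced from a JSON config.

#' Model enumerations
#'
#' `PRIMARY_CAUSES`: the four competing primary event types leaving the
#' CVD-free state. `CVD_CAUSES`: the three statin-modifiable CVD causes.
#' `HEALTH_STATES`: the six model states; the three `DEAD_*` states are
#' absorbing.
#' @name enumerations
#' @aliases PRIMARY_CAUSES CVD_CAUSES HEALTH_STATES
#' @export PRIMARY_CAUSES CVD_CAUSES HEALTH_STATES
NULL

PRIMARY_CAUSES <- c("nonfatal_chd", "nonfatal_cbvd", "fatal_cvd",
                    "fatal_noncvd")
#' @rdname enumerations
CVD_CAUSES <- c("nonfatal_chd", "nonfatal_cbvd", "fatal_cvd")
#' @rdname enumerations
HEALTH_STATES <- c("CVD_FREE", "CHRONIC_CHD", "CHRONIC_CBVD",
                   "DEAD_CVD", "DEAD_NONCVD", "DEAD_POST_EVENT")
COVARIATES <- c("male", "diabetes", "sbp", "tc", "hdl", "cpd", "simd",
                "famhist")

#' Cause-specific survival parameters
#'
#' Container for the competing-risk multistate engine: a Gompertz baseline
#' hazard per primary cause (proportional hazards in age), log-hazard
#' coefficients over the ASSIGN-style risk factors, post-event (chronic state)
#' mortality, and a covariance matrix over the CVD log-hazard coefficients for
#' probabilistic analysis.
#'
#' The four primary causes are nonfatal coronary heart disease, nonfatal
#' cerebrovascular disease, fatal CVD and fatal non-CVD death. Baseline
#' hazards take the form `exp(log_rate + shape * (age - 60))`; covariate
#' effects are additive on the log-hazard scale with continuous covariates
#' centred at `centering`.
#'
#' @param coef numeric matrix (4 causes x 8 covariates) of log hazard ratios;
#'   rows named by cause, columns `male, diabetes, sbp, tc, hdl, cpd, simd,
#'   famhist`. Units: per mmHg (sbp), per mmol/L (tc, hdl), per cigarette/day
#'   (cpd), per deprivation-score unit (simd).
#' @param gompertz data.frame with columns `cause`, `log_rate`, `shape`.
#' @param chronic list with elements `chd` and `cbvd`, each `c(log_rate,
#'   shape)` for all-cause post-event mortality.
#' @param centering named numeric, reference values subtracted from the
#'   continuous covariates.
#' @param hr_covariance covariance matrix of the CVD log-hazard coefficient
#'   estimates (3 causes x 8 covariates = 24), symmetric positive
#'   semi-definite; `NULL` builds a default from `coef`.
#' @param max_age age at which death is forced (lifetime horizon).
#' @return object of class `survival_params`.
#' @export
survival_params <- function(coef, gompertz, chronic, centering,
                            hr_covariance = NULL, max_age = 110) {
  stopifnot(is.matrix(coef), nrow(coef) == 4, ncol(coef) == 8)
  rownames(coef) <- PRIMARY_CAUSES
  colnames(coef) <- COVARIATES
  stopifnot(all(PRIMARY_CAUSES %in% gompertz$cause))
  if (is.null(hr_covariance)) {
    hr_covariance <- default_hr_covariance(coef)
  }
  check_psd(hr_covariance, "hr_covariance")
  structure(list(coef = coef, gompertz = gompertz, chronic = chronic,
                 centering = centering, hr_covariance = hr_covariance,
                 max_age = max_age),
            class = "survival_params")
}

# exchangeable within-cause correlation 0.3, SE ~12% of |coef| (floor 0.005)
default_hr_covariance <- function(coef) {
  cvd <- coef[CVD_CAUSES, , drop = FALSE]
  se <- pmax(0.12 * abs(as.vector(t(cvd))), 0.005)
  k <- length(se)
  nm <- as.vector(t(outer(CVD_CAUSES, COVARIATES, paste, sep = ".")))
  per_cause <- ncol(coef)
  corr <- diag(k)
  for (c_idx in seq_along(CVD_CAUSES)) {
    idx <- (c_idx - 1) * per_cause + seq_len(per_cause)
    corr[idx, idx] <- 0.3
    diag(corr)[idx] <- 1
  }
  v <- diag(se) %*% corr %*% diag(se)
  dimnames(v) <- list(nm, nm)
  v
}

check_psd <- function(m, name) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10))) {
    stop("covariance matrix '", name, "' is not symmetric")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance matrix '", name, "' is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), ")")
  }
  invisible(TRUE)
}

#' Default synthetic survival parameters
#'
#' Gompertz baselines and log hazard ratios chosen once to give realistic
#' Scottish-adult magnitudes (roughly 10% mean 10-year CVD risk at age 60,
#' risk increasing in age, SBP, TC, smoking and deprivation, decreasing in
#' HDL-C). These are synthetic placeholders for fitted cohort coefficients,
#' which are configuration inputs, not package contents.
#'
#' @inheritParams survival_params
#' @return `survival_params` object.
#' @export
default_survival_params <- function(max_age = 110) {
  coef <- rbind(
    nonfatal_chd  = c(male = 0.45, diabetes = 0.65, sbp = 0.010, tc = 0.20,
                      hdl = -0.45, cpd = 0.022, simd = 0.008, famhist = 0.30),
    nonfatal_cbvd = c(male = 0.25, diabetes = 0.60, sbp = 0.014, tc = 0.08,
                      hdl = -0.30, cpd = 0.020, simd = 0.008, famhist = 0.20),
    fatal_cvd     = c(male = 0.40, diabetes = 0.70, sbp = 0.012, tc = 0.15,
                      hdl = -0.40, cpd = 0.025, simd = 0.010, famhist = 0.25),
    fatal_noncvd  = c(male = 0.30, diabetes = 0.25, sbp = 0.002, tc = 0.00,
                      hdl = -0.05, cpd = 0.020, simd = 0.012, famhist = 0.00)
  )
  gompertz <- data.frame(
    cause = PRIMARY_CAUSES,
    log_rate = c(-5.4, -6.1, -6.8, -5.0),
    shape = c(0.075, 0.085, 0.105, 0.095)
  )
  chronic <- list(chd = c(log_rate = -3.6, shape = 0.09),
                  cbvd = c(log_rate = -3.3, shape = 0.09))
  centering <- c(sbp = 130, tc = 5, hdl = 1.3, simd = 20)
  survival_params(coef, gompertz, chronic, centering, max_age = max_age)
}

#' Statin treatment measures
#'
#' Effect sizes, side effects and costs of intermediate-intensity statin
#' therapy. The lipid axis is non-HDL cholesterol: statins reduce non-HDL-C
#' by a fixed proportion and each 1.0 mmol/L reduction multiplies the
#' cause-specific hazards of nonfatal CHD, nonfatal stroke and fatal CVD by
#' the respective relative risks.
#'
#' Base values: 26% non-HDL-C reduction; relative risks 0.77, 0.87 and 0.90
#' per 1.0 mmol/L; +0.5% absolute new-onset diabetes risk; 0.002 QALY/year
#' pill-taking disutility; GBP 13.44/year generic atorvastatin 20 mg tariff
#' (2020 price, exempt from the 2014-based cost inflation). The adherence
#' scenario keeps 67% of initiators on treatment in year 1, 53% in year 2 and
#' 50% thereafter; the base case assumes full adherence.
#'
#' `lo`/`hi` are one-way sensitivity bounds per measure (synthetic defaults
#' where unpublished).
#'
#' @param nonhdl_reduction proportional non-HDL-C reduction on treatment.
#' @param rr_nonfatal_chd,rr_nonfatal_stroke,rr_fatal_cvd relative risk per
#'   1.0 mmol/L non-HDL-C reduction.
#' @param diabetes_abs_risk_increase absolute probability of new-onset
#'   diabetes attributable to statin initiation.
#' @param pill_disutility QALY decrement per treated year.
#' @param annual_drug_cost GBP/year (current tariff, not inflated).
#' @param adherence persistence fraction by year since initiation
#'   (year 1, year 2, year 3+); used only when `full_adherence = FALSE`.
#' @param full_adherence logical; base case assumes full persistence.
#' @param lo,hi named lists of sensitivity bounds.
#' @return object of class `treatment_params`.
#' @export
treatment_params <- function(nonhdl_reduction = 0.26,
                             rr_nonfatal_chd = 0.77,
                             rr_nonfatal_stroke = 0.87,
                             rr_fatal_cvd = 0.90,
                             diabetes_abs_risk_increase = 0.005,
                             pill_disutility = 0.002,
                             annual_drug_cost = 13.44,
                             adherence = c(0.67, 0.53, 0.50),
                             full_adherence = TRUE,
                             lo = NULL, hi = NULL) {
  rr <- c(rr_nonfatal_chd, rr_nonfatal_stroke, rr_fatal_cvd)
  if (any(rr <= 0) || any(rr > 1)) {
    stop("relative risks must lie in (0, 1]")
  }
  if (nonhdl_reduction < 0 || nonhdl_reduction >= 1) {
    stop("nonhdl_reduction must lie in [0, 1)")
  }
  if (length(adherence) < 3 || any(diff(adherence[-1]) > 1e-12)) {
    stop("adherence must give years 1, 2, 3+ and be non-increasing after ",
         "year 1")
  }
  lo <- modifyList(default_bounds()$lo, lo %||% list())
  hi <- modifyList(default_bounds()$hi, hi %||% list())
  structure(list(nonhdl_reduction = nonhdl_reduction,
                 rr_nonfatal_chd = rr_nonfatal_chd,
                 rr_nonfatal_stroke = rr_nonfatal_stroke,
                 rr_fatal_cvd = rr_fatal_cvd,
                 diabetes_abs_risk_increase = diabetes_abs_risk_increase,
                 pill_disutility = pill_disutility,
                 annual_drug_cost = annual_drug_cost,
                 adherence = adherence,
                 full_adherence = full_adherence,
                 lo = lo, hi = hi),
            class = "treatment_params")
}

default_bounds <- function() {
  list(
    lo = list(nonhdl_reduction = 0.20, rr_nonfatal_chd = 0.71,
              rr_nonfatal_stroke = 0.80, rr_fatal_cvd = 0.84,
              diabetes_abs_risk_increase = 0.002, pill_disutility = 0,
              annual_drug_cost = 10.00, monitoring_cost = 15,
              discount_rate = 0.015),
    hi = list(nonhdl_reduction = 0.32, rr_nonfatal_chd = 0.83,
              rr_nonfatal_stroke = 0.94, rr_fatal_cvd = 0.97,
              diabetes_abs_risk_increase = 0.010, pill_disutility = 0.010,
              annual_drug_cost = 40.00, monitoring_cost = 60,
              discount_rate = 0.060)
  )
}

#' Health-economic parameters
#'
#' Utilities, costs, discounting and inflation. Costs are in 2014 GBP unless
#' noted and are inflated by `inflation_factor` (12.5%, 2014 to 2020) at the
#' point of use; the statin drug tariff is already 2020-priced and is never
#' inflated. Background utility declines linearly with age from a sex-specific
#' intercept at age 40; chronic CVD states subtract a state decrement plus an
#' expected annual secondary-event decrement. Pre-event (acute hospitalisation,
#' one-off) and post-event (annual) costs are linear in age at event,
#' deprivation score and family history. All default values are synthetic,
#' UK-plausible placeholders.
#'
#' @param discount_rate annual discount rate for costs and QALYs (base 0.035).
#' @param inflation_factor proportional uplift applied to 2014-based costs
#'   (base 0.125).
#' @param wtp_threshold willingness to pay, GBP/QALY (base 20000).
#' @param bg_utility list: `intercept_female`, `intercept_male` (utility at
#'   age 40), `age_slope` (utility lost per year of age), `floor`.
#' @param chronic_decrement named numeric `c(chd=, cbvd=)` utility decrements.
#' @param secondary_decrement named numeric, expected annual decrement from
#'   secondary events within each chronic state.
#' @param screening_cost GBP one-off at model entry (2014 GBP).
#' @param monitoring_cost GBP/year while on statins (2014 GBP).
#' @param diabetes_cost GBP/year managing statin-attributable diabetes
#'   (2014 GBP).
#' @param bg_cost list: `intercept` (GBP/year at age 40), `age_slope`
#'   (GBP/year per year of age) — background non-CVD healthcare cost accruing
#'   in all alive states (2014 GBP).
#' @param event_cost_pre,event_cost_post named numeric coefficient vectors
#'   `c(intercept=, age=, simd=, famhist=)`; age is centred at 60 (2014 GBP).
#' @return object of class `econ_params`.
#' @export
econ_params <- function(discount_rate = 0.035,
                        inflation_factor = 0.125,
                        wtp_threshold = 20000,
                        bg_utility = list(intercept_female = 0.95,
                                          intercept_male = 0.93,
                                          age_slope = 0.0035,
                                          floor = 0.3),
                        chronic_decrement = c(chd = 0.08, cbvd = 0.12),
                        secondary_decrement = c(chd = 0.010, cbvd = 0.015),
                        screening_cost = 10.5,
                        monitoring_cost = 30,
                        diabetes_cost = 200,
                        bg_cost = list(intercept = 600, age_slope = 25),
                        event_cost_pre = c(intercept = 3200, age = -12,
                                           simd = 20, famhist = 150),
                        event_cost_post = c(intercept = 520, age = 4,
                                            simd = 6, famhist = 40)) {
  stopifnot(discount_rate >= 0, inflation_factor >= 0, wtp_threshold >= 0)
  stopifnot(all(chronic_decrement >= 0), all(secondary_decrement >= 0))
  structure(list(discount_rate = discount_rate,
                 inflation_factor = inflation_factor,
                 wtp_threshold = wtp_threshold,
                 bg_utility = bg_utility,
                 chronic_decrement = chronic_decrement,
                 secondary_decrement = secondary_decrement,
                 screening_cost = screening_cost,
                 monitoring_cost = monitoring_cost,
                 diabetes_cost = diabetes_cost,
                 bg_cost = bg_cost,
                 event_cost_pre = event_cost_pre,
                 event_cost_post = event_cost_post),
            class = "econ_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat("<survival_params> 4 primary causes, Gompertz baseline, max_age",
      x$max_age, "\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' @export
print.treatment_params <- function(x, ...) {
  cat("<treatment_params> non-HDL-C reduction", x$nonhdl_reduction,
      "| RR per mmol/L:", x$rr_nonfatal_chd, x$rr_nonfatal_stroke,
      x$rr_fatal_cvd, "\n",
      if (x$full_adherence) "full adherence" else
        paste("adherence", paste(x$adherence, collapse = "/")),
      "| drug cost", x$annual_drug_cost, "GBP/y\n")
  invisible(x)
}
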