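# Competing-risk multistate engine. Individuals enter CVD-free and may
# transition, in annual cycles, to one of four primary event types — nonfatal
# CHD, nonfatal cerebrovascular disease (CBVD), fatal CVD, fatal non-CVD —
# with within-cycle competition resolved by cause-specific hazard
# decomposition: P(cause c) = h_c / H * (1 - exp(-H)). Survivors of a
# nonfatal event occupy a chronic state until an absorbing post-event death.
# Outcomes are deterministic expectations over state occupancy (cohort
# method), vectorised over profiles.

state_index <- function(state) match(state, HEALTH_STATES)

# model matrix of centred covariates, n x 8, columns in COVARIATES order
covariate_matrix <- function(cohort, params) {
  ctr <- params$centering
  m <- cbind(male = as.numeric(cohort$sex == "male"),
             diabetes = as.numeric(cohort$diabetes),
             sbp = cohort$sbp - ctr[["sbp"]],
             tc = cohort$tc - ctr[["tc"]],
             hdl = cohort$hdl - ctr[["hdl"]],
             cpd = cohort$cpd,
             simd = cohort$simd - ctr[["simd"]],
             famhist = as.numeric(cohort$famhist))
  if (anyNA(m)) stop("profile has missing covariates; impute first")
  m
}

#' Covariate log-hazard offset for one profile and cause
#'
#' Additive linear predictor over the centred ASSIGN-style covariates, on the
#' log-hazard scale.
#'
#' @param profile single-row data.frame (or list) with the risk-factor fields.
#' @param cause one of `"nonfatal_chd"`, `"nonfatal_cbvd"`, `"fatal_cvd"`,
#'   `"fatal_noncvd"`.
#' @param params a [survival_params()].
#' @return finite scalar log-hazard offset.
#' @export
linear_predictor <- function(profile, cause, params = default_survival_params()) {
  cause <- match.arg(cause, PRIMARY_CAUSES)
  x <- covariate_matrix(as.data.frame(profile), params)
  drop(x %*% params$coef[cause, ])
}

baseline_hazard <- function(cause, age, params) {
  g <- params$gompertz[params$gompertz$cause == cause, ]
  exp(g$log_rate + g$shape * (age - 60))
}

# n x 4 matrix of cause-specific hazards at the given ages (vector, length n)
cause_hazard_matrix <- function(B, age, params) {
  g <- params$gompertz
  h <- matrix(0, length(age), 4, dimnames = list(NULL, PRIMARY_CAUSES))
  for (k in seq_len(4)) {
    h[, k] <- B[, k] *
      exp(g$log_rate[k] + g$shape[k] * (age - 60))
  }
  h
}

chronic_hazard <- function(which_state, age, params) {
  p <- params$chronic[[which_state]]
  exp(p[["log_rate"]] + p[["shape"]] * (age - 60))
}

#' One-cycle transition probabilities from a health state
#'
#' Cause-specific hazards over one annual cycle, with competing events
#' resolved by hazard decomposition; probabilities include the
#' stay-probability and sum to 1. Ages beyond `params$max_age` force death
#' (non-CVD death from the CVD-free state, post-event death from chronic
#' states).
#'
#' @param profile single-row data.frame with complete risk factors.
#' @param current_age age at the start of the cycle.
#' @param state a non-absorbing [HEALTH_STATES] name.
#' @param params a [survival_params()].
#' @param hazard_multipliers optional length-3 multiplier on the nonfatal CHD,
#'   nonfatal CBVD and fatal CVD hazards (treatment effect).
#' @return named probability vector over `HEALTH_STATES`.
#' @export
annual_transition_probs <- function(profile, current_age, state,
                                    params = default_survival_params(),
                                    hazard_multipliers = c(1, 1, 1)) {
  state <- match.arg(state, HEALTH_STATES)
  if (state %in% c("DEAD_CVD", "DEAD_NONCVD", "DEAD_POST_EVENT")) {
    stop("state '", state, "' is absorbing")
  }
  p <- stats::setNames(numeric(6), HEALTH_STATES)
  if (state == "CVD_FREE") {
    if (current_age >= params$max_age) {
      p["DEAD_NONCVD"] <- 1
      return(p)
    }
    x <- covariate_matrix(as.data.frame(profile), params)
    B <- exp(x %*% t(params$coef))
    h <- cause_hazard_matrix(B, current_age, params)
    h[, CVD_CAUSES] <- h[, CVD_CAUSES, drop = FALSE] *
      rep(hazard_multipliers, each = nrow(h))
    H <- rowSums(h)
    exit <- if (H > 0) (1 - exp(-H)) else 0
    share <- if (H > 0) h / H else h * 0
    p["CHRONIC_CHD"] <- exit * share[, "nonfatal_chd"]
    p["CHRONIC_CBVD"] <- exit * share[, "nonfatal_cbvd"]
    p["DEAD_CVD"] <- exit * share[, "fatal_cvd"]
    p["DEAD_NONCVD"] <- exit * share[, "fatal_noncvd"]
    p["CVD_FREE"] <- 1 - exit
  } else {
    if (current_age >= params$max_age) {
      p["DEAD_POST_EVENT"] <- 1
      return(p)
    }
    h <- chronic_hazard(if (state == "CHRONIC_CHD") "chd" else "cbvd",
                        current_age, params)
    p["DEAD_POST_EVENT"] <- 1 - exp(-h)
    p[state] <- exp(-h)
  }
  p
}

#' Ten-year cumulative CVD risk under competing risks
#'
#' Cumulative incidence, over ten annual cycles, of the combined primary CVD
#' endpoint (nonfatal CHD + nonfatal CBVD + fatal CVD) with fatal non-CVD
#' death as a competing risk. This score is used both for risk-threshold
#' eligibility and inside the lifetime simulation, consistently.
#'
#' @param cohort cohort data.frame (complete covariates) or single profile.
#' @param params a [survival_params()].
#' @param by_cause if `TRUE`, return a matrix with per-cause cumulative
#'   incidence columns (`nonfatal_chd`, `nonfatal_cbvd`, `fatal_cvd`,
#'   `fatal_noncvd`), the combined CVD risk and the event-free survival.
#' @return numeric vector of risks in \[0, 1\] (or matrix, see `by_cause`).
#' @export
ten_year_risk <- function(cohort, params = default_survival_params(),
                          by_cause = FALSE) {
  cohort <- as.data.frame(cohort)
  x <- covariate_matrix(cohort, params)
  B <- exp(x %*% t(params$coef))
  n <- nrow(cohort)
  alive <- rep(1, n)
  cum <- matrix(0, n, 4, dimnames = list(NULL, PRIMARY_CAUSES))
  for (t in 0:9) {
    age <- cohort$age + t
    h <- cause_hazard_matrix(B, age, params)
    H <- rowSums(h)
    exit <- ifelse(H > 0, 1 - exp(-H), 0)
    share <- h / ifelse(H > 0, H, 1)
    cum <- cum + alive * exit * share
    alive <- alive * (1 - exit)
  }
  cvd <- rowSums(cum[, CVD_CAUSES, drop = FALSE])
  if (by_cause) {
    cbind(cum, cvd = cvd, event_free_survival = 1 - rowSums(cum))
  } else {
    cvd
  }
}

# persistence fraction applying to efficacy/side-effects/monitoring in a
# given year since initiation (year >= 1)
persistence_schedule <- function(treatment, year) {
  if (isTRUE(treatment$full_adherence)) return(rep(1, length(year)))
  a <- treatment$adherence
  ifelse(year <= 2, a[pmax(year, 1)], a[3])
}

#' Expected lifetime outcomes for a cohort (vectorised)
#'
#' Deterministic cohort-expectation simulation from each profile's current age
#' to `params$max_age`, in annual cycles with optional half-cycle correction.
#' The treated scenario lowers the nonfatal CHD, nonfatal CBVD and fatal CVD
#' hazards via per-profile multipliers `rr_c ^ (non-HDL-C x reduction)`,
#' subtracts the pill disutility, and accrues drug, monitoring and
#' diabetes-risk costs while the profile remains CVD-free (and, under the
#' adherence scenario, persistent). Screening cost is charged to everyone at
#' entry.
#'
#' @param cohort cohort data.frame with complete covariates.
#' @param params a [survival_params()].
#' @param econ an [econ_params()].
#' @param treatment a [treatment_params()], used when `treated` has any TRUE.
#' @param treated logical vector (recycled) marking treated profiles.
#' @param discount annual discount rate; defaults to `econ$discount_rate`.
#'   Set 0 to disable discounting.
#' @param half_cycle logical, apply half-cycle correction to QALY and cost
#'   accrual (toggleable so exact matrix-product oracles can be used).
#' @return data.frame, one row per profile: discounted `qalys`, undiscounted
#'   `life_years`, disaggregated discounted costs (`cost_cvd`, `cost_noncvd`,
#'   `cost_statin`, `cost_monitoring`, `cost_screening`, `cost_diabetes`,
#'   `cost_total`), cumulative primary-event probabilities (`p_chd`, `p_cbvd`,
#'   `p_fatal_cvd`, `p_fatal_noncvd`), and `disc_treated_years` (discounted
#'   expected person-years on treatment, the lever for pill-disutility
#'   sweeps).
#' @export
simulate_cohort <- function(cohort, params = default_survival_params(),
                            econ = econ_params(),
                            treatment = treatment_params(),
                            treated = FALSE,
                            discount = econ$discount_rate,
                            half_cycle = TRUE) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  treated <- rep_len(as.logical(treated), n)
  x <- covariate_matrix(cohort, params)
  B <- exp(x %*% t(params$coef))
  nonhdl <- cohort$tc - cohort$hdl
  rr <- c(treatment$rr_nonfatal_chd, treatment$rr_nonfatal_stroke,
          treatment$rr_fatal_cvd)
  delta <- nonhdl * treatment$nonhdl_reduction
  # per-profile treatment hazard multipliers (1 for untreated rows)
  mult <- matrix(1, n, 3)
  for (k in 1:3) mult[treated, k] <- rr[k]^delta[treated]

  infl <- 1 + econ$inflation_factor
  u_int <- ifelse(cohort$sex == "male", econ$bg_utility$intercept_male,
                  econ$bg_utility$intercept_female)
  simd_c <- cohort$simd
  fam <- as.numeric(cohort$famhist)
  post_cost_of_age <- function(age) {
    pmax(econ$event_cost_post[["intercept"]] +
           econ$event_cost_post[["age"]] * (age - 60) +
           econ$event_cost_post[["simd"]] * simd_c +
           econ$event_cost_post[["famhist"]] * fam, 0) * infl
  }
  pre_cost_of_age <- function(age) {
    pmax(econ$event_cost_pre[["intercept"]] +
           econ$event_cost_pre[["age"]] * (age - 60) +
           econ$event_cost_pre[["simd"]] * simd_c +
           econ$event_cost_pre[["famhist"]] * fam, 0) * infl
  }

  occ <- matrix(0, n, 6, dimnames = list(NULL, HEALTH_STATES))
  occ[, 1] <- 1
  qalys <- numeric(n)
  life_years <- numeric(n)
  cost <- matrix(0, n, 6, dimnames = list(
    NULL, c("cvd", "noncvd", "statin", "monitoring", "screening", "diabetes")))
  cum_event <- matrix(0, n, 4, dimnames = list(NULL, PRIMARY_CAUSES))
  disc_treated_years <- numeric(n)

  cost[, "screening"] <- econ$screening_cost * infl
  t_max <- params$max_age - min(cohort$age)
  for (t in 0:t_max) {
    age <- cohort$age + t
    over <- age >= params$max_age # death forced on reaching max_age
    df <- 1 / (1 + discount)^t
    year <- t + 1
    pf <- persistence_schedule(treatment, year)
    costf <- if (year == 1) 1 else pf # non-persistent pay first-year costs

    h <- cause_hazard_matrix(B, age, params)
    m_eff <- 1 + (mult - 1) * pf # adherence blending
    h[, CVD_CAUSES] <- h[, CVD_CAUSES, drop = FALSE] * m_eff
    H <- rowSums(h)
    exit <- ifelse(H > 0, 1 - exp(-H), 0)
    share <- h / ifelse(H > 0, H, 1)
    p_evt <- exit * share
    p_evt[over, ] <- 0
    stay1 <- ifelse(over, 0, 1 - exit)
    # forced non-CVD death past max_age
    p_evt[over, "fatal_noncvd"] <- 1

    d_chd <- ifelse(over, 1, 1 - exp(-chronic_hazard("chd", age, params)))
    d_cbvd <- ifelse(over, 1, 1 - exp(-chronic_hazard("cbvd", age, params)))

    inc <- occ[, 1] * p_evt
    new <- occ
    new[, 1] <- occ[, 1] * stay1
    new[, 2] <- occ[, 2] * (1 - d_chd) + inc[, "nonfatal_chd"]
    new[, 3] <- occ[, 3] * (1 - d_cbvd) + inc[, "nonfatal_cbvd"]
    new[, 4] <- occ[, 4] + inc[, "fatal_cvd"]
    new[, 5] <- occ[, 5] + inc[, "fatal_noncvd"]
    new[, 6] <- occ[, 6] + occ[, 2] * d_chd + occ[, 3] * d_cbvd
    cum_event <- cum_event + inc

    w <- if (half_cycle) (occ + new) / 2 else occ
    w[over, 1:3] <- 0 # no accrual in the forced-death cycle
    u1 <- clip01(pmax(u_int - econ$bg_utility$age_slope * (age - 40),
                      econ$bg_utility$floor))
    u2 <- clip01(u1 - econ$chronic_decrement[["chd"]] -
                   econ$secondary_decrement[["chd"]])
    u3 <- clip01(u1 - econ$chronic_decrement[["cbvd"]] -
                   econ$secondary_decrement[["cbvd"]])
    q_t <- w[, 1] * u1 + w[, 2] * u2 + w[, 3] * u3
    treated_years <- w[, 1] * pf * treated
    q_t <- q_t - treated_years * treatment$pill_disutility
    qalys <- qalys + df * q_t
    life_years <- life_years + w[, 1] + w[, 2] + w[, 3]
    disc_treated_years <- disc_treated_years + df * treated_years

    bg <- pmax(econ$bg_cost$intercept +
                 econ$bg_cost$age_slope * (age - 40), 0) * infl
    cost[, "noncvd"] <- cost[, "noncvd"] + df * bg * (w[, 1] + w[, 2] + w[, 3])
    cost[, "cvd"] <- cost[, "cvd"] + df *
      (post_cost_of_age(age) * (w[, 2] + w[, 3]) +
         pre_cost_of_age(age) * (inc[, "nonfatal_chd"] +
                                   inc[, "nonfatal_cbvd"]))
    tw_cost <- w[, 1] * costf * treated
    cost[, "statin"] <- cost[, "statin"] +
      df * tw_cost * treatment$annual_drug_cost # 2020 tariff: no inflation
    cost[, "monitoring"] <- cost[, "monitoring"] +
      df * tw_cost * econ$monitoring_cost * infl
    cost[, "diabetes"] <- cost[, "diabetes"] +
      df * tw_cost * treatment$diabetes_abs_risk_increase *
      econ$diabetes_cost * infl

    occ <- new
    if (sum(occ[, 1:3]) < 1e-12) break
  }

  out <- data.frame(
    id = cohort$id %||% seq_len(n),
    qalys = qalys,
    life_years = life_years,
    cost_cvd = cost[, "cvd"],
    cost_noncvd = cost[, "noncvd"],
    cost_statin = cost[, "statin"],
    cost_monitoring = cost[, "monitoring"],
    cost_screening = cost[, "screening"],
    cost_diabetes = cost[, "diabetes"],
    p_chd = cum_event[, "nonfatal_chd"],
    p_cbvd = cum_event[, "nonfatal_cbvd"],
    p_fatal_cvd = cum_event[, "fatal_cvd"],
    p_fatal_noncvd = cum_event[, "fatal_noncvd"],
    disc_treated_years = disc_treated_years
  )
  out$cost_total <- rowSums(cost)
  out
}

#' Expected lifetime outcome for one profile
#'
#' Single-profile wrapper around [simulate_cohort()] that additionally records
#' the state-occupancy trajectory (cycle x state matrix; occupancy sums to 1
#' every cycle).
#'
#' @param profile single-row data.frame with complete risk factors.
#' @param scenario `"untreated"` or `"treated"`.
#' @inheritParams simulate_cohort
#' @return object of class `lifetime_outcome`: the [simulate_cohort()] row as
#'   a list, plus `trajectory`.
#' @export
simulate_lifetime <- function(profile, scenario = c("untreated", "treated"),
                              params = default_survival_params(),
                              econ = econ_params(),
                              treatment = treatment_params(),
                              discount = econ$discount_rate,
                              half_cycle = TRUE) {
  scenario <- match.arg(scenario)
  profile <- as.data.frame(profile)
  stopifnot(nrow(profile) == 1)
  res <- simulate_cohort(profile, params, econ, treatment,
                         treated = scenario == "treated",
                         discount = discount, half_cycle = half_cycle)
  traj <- occupancy_trajectory(profile, params, treatment,
                               treated = scenario == "treated")
  out <- c(as.list(res[1, ]), list(scenario = scenario, trajectory = traj))
  class(out) <- "lifetime_outcome"
  out
}

# cycle x state occupancy matrix for one profile
occupancy_trajectory <- function(profile, params, treatment, treated) {
  x <- covariate_matrix(profile, params)
  B <- exp(x %*% t(params$coef))
  nonhdl <- profile$tc - profile$hdl
  rr <- c(treatment$rr_nonfatal_chd, treatment$rr_nonfatal_stroke,
          treatment$rr_fatal_cvd)
  mult <- if (treated) rr^(nonhdl * treatment$nonhdl_reduction) else c(1, 1, 1)
  t_max <- params$max_age - profile$age
  occ <- stats::setNames(c(1, 0, 0, 0, 0, 0), HEALTH_STATES)
  traj <- matrix(NA_real_, t_max + 2, 6,
                 dimnames = list(NULL, HEALTH_STATES))
  traj[1, ] <- occ
  for (t in 0:t_max) {
    age <- profile$age + t
    pf <- persistence_schedule(treatment, t + 1)
    p1 <- annual_transition_probs(profile, age, "CVD_FREE", params,
                                  hazard_multipliers = 1 + (mult - 1) * pf)
    p2 <- annual_transition_probs(profile, age, "CHRONIC_CHD", params)
    p3 <- annual_transition_probs(profile, age, "CHRONIC_CBVD", params)
    occ <- occ[1] * p1 + occ[2] * p2 + occ[3] * p3 +
      occ[4] * c(0, 0, 0, 1, 0, 0) + occ[5] * c(0, 0, 0, 0, 1, 0) +
      occ[6] * c(0, 0, 0, 0, 0, 1)
    traj[t + 2, ] <- occ
  }
  traj
}

#' @export
print.lifetime_outcome <- function(x, ...) {
  cat(sprintf("<lifetime_outcome> %s: %.3f QALYs, %.2f life-years, GBP %.0f\n",
              x$scenario, x$qalys, x$life_years, x$cost_total))
  invisible(x)
}
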