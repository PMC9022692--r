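# Competing-risk multistate engine: linear predictors, 10-year risk,
# transition probabilities and the lifetime expectation simulator.

test_that("linear predictor is an additive dot product over centred
           covariates", {
  params <- default_survival_params()
  p0 <- toy_profile() # all covariates at centring values
  expect_equal(linear_predictor(p0, "nonfatal_chd", params), 0)
  # hand-computed 3-covariate toy: male + sbp 150 + tc 6.5
  p <- toy_profile(sex = "male", sbp = 150, tc = 6.5)
  expected <- 0.45 + 0.010 * 20 + 0.20 * 1.5
  expect_equal(linear_predictor(p, "nonfatal_chd", params), expected)
  # doubling a coefficient doubles its additive contribution
  params2 <- params
  params2$coef["nonfatal_chd", "sbp"] <- 2 * params$coef["nonfatal_chd", "sbp"]
  expect_equal(linear_predictor(p, "nonfatal_chd", params2) -
                 linear_predictor(p0, "nonfatal_chd", params2),
               expected + 0.010 * 20)
  expect_error(linear_predictor(toy_profile(tc = NA), "nonfatal_chd", params),
               "missing")
})

test_that("ten-year risk matches the constant-hazard closed form and edge
           cases", {
  p <- toy_profile(age = 60)
  # h_cvd = 0.02 (all on CHD), h_other = 0.01:
  # risk = h_cvd/(h_cvd+h_other) * (1 - exp(-0.3))
  params <- constant_hazard_params(h_chd = 0.02, h_noncvd = 0.01)
  expect_equal(ten_year_risk(p, params),
               (0.02 / 0.03) * (1 - exp(-0.3)), tolerance = 1e-12)
  # all CVD hazards zero -> 0
  expect_equal(ten_year_risk(p, constant_hazard_params(h_noncvd = 0.01)), 0)
  # overwhelming competing non-CVD hazard absorbs everyone
  expect_lt(ten_year_risk(p, constant_hazard_params(h_chd = 0.02,
                                                    h_noncvd = 50)), 1e-3)
  # by-cause decomposition sums to the combined endpoint
  params3 <- constant_hazard_params(h_chd = 0.01, h_cbvd = 0.005,
                                    h_fatal_cvd = 0.002, h_noncvd = 0.01)
  m <- ten_year_risk(p, params3, by_cause = TRUE)
  expect_equal(unname(m[, "cvd"]),
               unname(rowSums(m[, CVD_CAUSES, drop = FALSE])))
  expect_equal(unname(m[, "cvd"] + m[, "fatal_noncvd"] +
                        m[, "event_free_survival"]), 1)
})

test_that("ten-year risk is weakly increasing in CVD coefficients times
           positive covariates", {
  params <- default_survival_params()
  p <- toy_profile(sbp = 150, tc = 6, cpd = 10)
  base <- ten_year_risk(p, params)
  for (cv in c("sbp", "tc", "cpd")) {
    up <- params
    up$coef[CVD_CAUSES, cv] <- up$coef[CVD_CAUSES, cv] * 1.5
    expect_gte(ten_year_risk(p, up), base)
  }
})

test_that("annual transition probabilities are a proper distribution and
           match exponential closed forms", {
  p <- toy_profile(age = 70)
  params <- constant_hazard_params(h_chd = 0.03)
  pr <- annual_transition_probs(p, 70, "CVD_FREE", params)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr["CHRONIC_CHD"]), 1 - exp(-0.03)) # single cause
  # zero hazards -> stay with probability 1
  pr0 <- annual_transition_probs(p, 70, "CVD_FREE", constant_hazard_params())
  expect_equal(unname(pr0["CVD_FREE"]), 1)
  # chronic state: exit probability 1 - exp(-h)
  prc <- annual_transition_probs(p, 70, "CHRONIC_CBVD",
                                 constant_hazard_params(h_chronic_cbvd = 0.2))
  expect_equal(unname(prc["DEAD_POST_EVENT"]), 1 - exp(-0.2))
  # random parameter draws still sum to 1
  set.seed(5)
  for (i in 1:20) {
    params_r <- constant_hazard_params(h_chd = runif(1), h_cbvd = runif(1),
                                       h_fatal_cvd = runif(1),
                                       h_noncvd = runif(1))
    expect_equal(sum(annual_transition_probs(p, 70, "CVD_FREE", params_r)), 1)
  }
  # absorbing states and forced death
  expect_error(annual_transition_probs(p, 70, "DEAD_CVD", params),
               "absorbing")
  prf <- annual_transition_probs(p, 110, "CVD_FREE", params)
  expect_equal(unname(prf["DEAD_NONCVD"]), 1)
})

test_that("lifetime simulation matches the explicit matrix-chain oracle on
           constant-hazard toys", {
  set.seed(7)
  for (i in 1:10) {
    h <- runif(4, 0, 0.08)
    hc <- runif(2, 0.02, 0.3)
    age0 <- sample(40:80, 1)
    disc <- sample(c(0, 0.035), 1)
    params <- constant_hazard_params(h[1], h[2], h[3], h[4], hc[1], hc[2],
                                     max_age = 100)
    u <- runif(1, 0.6, 1)
    econ <- flat_econ(utility = u, discount = disc)
    res <- simulate_cohort(toy_profile(age = age0), params, econ,
                           null_treatment(), treated = FALSE,
                           discount = disc, half_cycle = FALSE)
    oracle <- matrix_chain_oracle(age0, h, hc, utilities = c(u, u, u, 0, 0, 0),
                                  discount = disc, max_age = 100)
    expect_equal(res$qalys, oracle$qaly, tolerance = 1e-6)
    expect_equal(res$life_years, oracle$life_years, tolerance = 1e-6)
  }
})

test_that("state occupancy sums to one every cycle and respects absorbing
           states", {
  set.seed(11)
  for (i in 1:25) {
    params <- constant_hazard_params(runif(1, 0, .1), runif(1, 0, .1),
                                     runif(1, 0, .1), runif(1, 0, .1),
                                     runif(1, .02, .5), runif(1, .02, .5),
                                     max_age = 95)
    traj <- statinpolicy:::occupancy_trajectory(
      toy_profile(age = sample(40:85, 1)), params, null_treatment(),
      treated = FALSE)
    expect_true(all(abs(rowSums(traj) - 1) < 1e-9))
    # absorbing: dead-state occupancy never decreases
    for (s in c("DEAD_CVD", "DEAD_NONCVD", "DEAD_POST_EVENT")) {
      expect_true(all(diff(traj[, s]) > -1e-12))
    }
  }
})

test_that("zero hazards with utility one and no discounting yield
           life-years = max_age - age", {
  params <- constant_hazard_params(max_age = 100)
  res <- simulate_cohort(toy_profile(age = 60), params, flat_econ(),
                         null_treatment(), discount = 0, half_cycle = FALSE)
  expect_equal(res$life_years, 40)
  expect_equal(res$qalys, 40)
})

test_that("increasing any cause-specific hazard weakly decreases life
           expectancy", {
  base <- constant_hazard_params(0.01, 0.01, 0.01, 0.01)
  p <- toy_profile(age = 50)
  ly0 <- simulate_cohort(p, base, flat_econ(), null_treatment())$life_years
  for (k in 1:4) {
    h <- c(0.01, 0.01, 0.01, 0.01)
    h[k] <- 0.03
    up <- constant_hazard_params(h[1], h[2], h[3], h[4])
    expect_lte(simulate_cohort(p, up, flat_econ(),
                               null_treatment())$life_years, ly0)
  }
})

test_that("null treatment effects reproduce untreated health outcomes exactly,
           shifted only by treatment costs and pill disutility", {
  co <- small_cohort(n = 150)
  params <- default_survival_params()
  econ <- econ_params()
  trt <- null_treatment()
  trt$annual_drug_cost <- 13.44
  trt$pill_disutility <- 0.002
  untreated <- simulate_cohort(co, params, econ, trt, treated = FALSE)
  treated <- simulate_cohort(co, params, econ, trt, treated = TRUE)
  expect_equal(treated$life_years, untreated$life_years)
  expect_equal(treated$p_chd, untreated$p_chd)
  expect_equal(treated$cost_cvd, untreated$cost_cvd)
  # QALYs differ exactly by pill disutility x discounted treated years
  expect_equal(treated$qalys,
               untreated$qalys - 0.002 * treated$disc_treated_years)
  # cost difference is exactly the statin/monitoring/diabetes categories
  expect_equal(treated$cost_total - untreated$cost_total,
               treated$cost_statin + treated$cost_monitoring +
                 treated$cost_diabetes)
})

test_that("treatment lowers CVD event probabilities and single-profile
           wrapper records a conserved trajectory", {
  p <- toy_profile(age = 55, tc = 6.5, hdl = 1.1, sbp = 150, cpd = 15)
  untr <- simulate_lifetime(p, "untreated")
  trt <- simulate_lifetime(p, "treated")
  expect_s3_class(untr, "lifetime_outcome")
  expect_lt(trt$p_chd, untr$p_chd)
  # note: lifetime cumulative fatal-CVD probability need not fall (treated
  # individuals live longer and remain exposed); the fixed-horizon risk must
  mult <- apply_statin_modifiers(p)$hazard_multipliers
  params_trt <- default_survival_params()
  params_trt$coef <- params_trt$coef # unchanged; apply via baseline shift
  params_trt$gompertz$log_rate[1:3] <-
    params_trt$gompertz$log_rate[1:3] + log(unname(mult))
  expect_lt(ten_year_risk(p, params_trt), ten_year_risk(p))
  expect_gt(trt$life_years, untr$life_years)
  expect_true(all(abs(rowSums(untr$trajectory) - 1) < 1e-9))
})
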