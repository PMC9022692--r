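# Cost-effectiveness synthesis: frontier, NMB, CEAC, tornado, projection.

test_that("the frontier resolves the worked dominance example", {
  df <- data.frame(strategy = c("none", "a", "b", "c"),
                   cost = c(0, 100, 500, 400),
                   qaly = c(0, 10, 12, 13))
  fr <- icer_frontier(df)
  expect_equal(fr$frontier$strategy, c("none", "a", "c"))
  expect_equal(fr$frontier$icer, c(NA, 10, 100))
  expect_equal(fr$dominated$strategy, "b")
  expect_equal(fr$dominated$dominance, "strict")
  # two strategies, one strictly dominated
  df2 <- data.frame(strategy = c("A", "B"), cost = c(10, 20),
                    qaly = c(5, 4))
  fr2 <- icer_frontier(df2)
  expect_equal(fr2$frontier$strategy, "A")
  expect_equal(fr2$dominated$dominance, "strict")
})

test_that("the frontier agrees with NMB-argmax enumeration on random
           strategy sets and has strictly increasing ICERs", {
  set.seed(17)
  for (i in 1:300) {
    k <- sample(2:6, 1)
    df <- data.frame(strategy = paste0("s", 1:k),
                     cost = round(runif(k, 0, 1000), 4),
                     qaly = round(runif(k, 0, 10), 4))
    fr <- icer_frontier(df)
    oracle <- frontier_oracle(df)
    expect_equal(fr$frontier$strategy, oracle$strategy)
    expect_equal(fr$frontier$icer, oracle$icer)
    icers <- fr$frontier$icer[-1]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
    # frontier invariance: adding a strictly dominated strategy changes
    # nothing
    worst <- which.max(df$cost)
    extra <- data.frame(strategy = "dom", cost = df$cost[worst] + 1,
                        qaly = min(df$qaly))
    fr2 <- icer_frontier(rbind(df, extra))
    expect_equal(fr2$frontier$icer, fr$frontier$icer)
  }
})

test_that("net monetary benefit is linear and decision-equivalent to the
           ICER rule", {
  expect_equal(nmb(20000, 1, 20000), 0) # break-even
  expect_equal(nmb(2 * 300, 2 * 0.1, 5000), 2 * nmb(300, 0.1, 5000))
  set.seed(23)
  for (i in 1:50) {
    c1 <- runif(1, 0, 100); q1 <- runif(1, 0, 5)
    c2 <- c1 + runif(1, 0, 100); q2 <- q1 + runif(1, 0.01, 5)
    lambda <- runif(1, 0, 100)
    icer <- (c2 - c1) / (q2 - q1)
    prefers_2 <- nmb(c2, q2, lambda) > nmb(c1, q1, lambda)
    expect_equal(prefers_2, icer < lambda)
  }
})

test_that("acceptability curves follow hand-computed NMB orderings and sum
           to one", {
  # 2 strategies x 4 iterations with known orderings: at wtp 0, A (cheaper)
  # wins all 4; at wtp 100, B wins iterations where dq * 100 > dc
  df <- data.frame(iteration = rep(1:4, 2),
                   strategy = rep(c("A", "B"), each = 4),
                   cost = c(0, 0, 0, 0, 50, 150, 250, 350),
                   qaly = c(1, 1, 1, 1, 2, 3, 3, 4))
  cc <- ceac(df, wtp_grid = c(0, 100, 1000))
  expect_equal(cc$B[cc$wtp == 0], 0)
  # dc = 50,150,250,350; dq = 1,2,2,3 -> at 100: B wins iters 1,2 -> 0.5
  expect_equal(cc$B[cc$wtp == 100], 0.5)
  expect_equal(cc$B[cc$wtp == 1000], 1)
  expect_true(all(abs(rowSums(cc[, c("A", "B")]) - 1) < 1e-12))
  # ties split equally
  df_tie <- data.frame(iteration = rep(1:2, 2),
                       strategy = rep(c("A", "B"), each = 2),
                       cost = c(1, 1, 1, 1), qaly = c(1, 1, 1, 1))
  cc_tie <- ceac(df_tie, wtp_grid = c(0, 500))
  expect_true(all(cc_tie$A == 0.5 & cc_tie$B == 0.5))
  expect_equal(attr(cc_tie, "ties"), 4L)
  # single treating strategy -> probability 1 everywhere
  one <- df[df$strategy == "A", ]
  cc1 <- ceac(one, wtp_grid = c(0, 100))
  expect_true(all(cc1$A == 1))
})

test_that("tornado bars match one-at-a-time reruns and sort by width", {
  co <- small_cohort(n = 200, seed = 13)
  risk <- ten_year_risk(co)
  arr <- arr_score(co)
  strategies <- list(none = strategy_def("none"),
                     treat = strategy_def("fixed_risk", 0.2))
  prep <- list(cohort = co, risk = risk, arr = arr, strategies = strategies)
  model_fn <- function(trt, ec) {
    statinpolicy:::deterministic_outcomes(prep, default_survival_params(),
                                          ec, trt)
  }
  trt <- treatment_params()
  econ <- econ_params()
  tor <- tornado(model_fn, trt, econ, strategy = "treat",
                 comparator = "none",
                 measures = c("annual_drug_cost", "pill_disutility",
                              "nonhdl_reduction"))
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$width) <= 1e-12))
  # independent rerun at the drug-cost high bound
  trt_hi <- trt
  trt_hi$annual_drug_cost <- trt$hi$annual_drug_cost
  r_hi <- model_fn(trt_hi, econ)
  r_base <- model_fn(trt, econ)
  inc_hi <- nmb(r_hi$cost[2] - r_hi$cost[1], r_hi$qaly[2] - r_hi$qaly[1],
                econ$wtp_threshold)
  expect_equal(tor$nmb_hi[tor$measure == "annual_drug_cost"], inc_hi)
  # raising drug cost lowers the treating strategy's incremental NMB
  expect_lt(inc_hi, attr(tor, "base_nmb"))
  # lo = hi = base gives a zero-width bar
  trt0 <- trt
  trt0$lo$annual_drug_cost <- trt$annual_drug_cost
  trt0$hi$annual_drug_cost <- trt$annual_drug_cost
  tor0 <- tornado(model_fn, trt0, econ, "treat", "none",
                  measures = "annual_drug_cost")
  expect_equal(tor0$width, 0)
  expect_error(tornado(model_fn, trt, econ, "treat", "none",
                       measures = "nonexistent"), "bounds")
})

test_that("population projection multiplies group means, counts and CVD-free
           fractions", {
  out <- data.frame(band = c("40-44", "45-49", "50-54"),
                    qaly_gain = c(0.1, 0.2, 0.3),
                    events_prevented = c(0.01, 0.02, 0.03))
  pop <- data.frame(band = c("40-44", "45-49", "50-54"),
                    count = c(1000, 2000, 3000))
  cf <- data.frame(band = c("40-44", "45-49", "50-54"),
                   fraction = c(1, 0.9, 0.8))
  tot <- project_population(out, pop, cf)
  expect_equal(tot$qaly_gain, 0.1 * 1000 + 0.2 * 1800 + 0.3 * 2400)
  expect_equal(tot$events_prevented, 0.01 * 1000 + 0.02 * 1800 + 0.03 * 2400)
  expect_equal(tot$eligible_population, 1000 + 1800 + 2400)
  # single group sanity: 1000 eligible x 0.1 QALY = 100 QALYs
  tot1 <- project_population(data.frame(band = "a", q = 0.1),
                             data.frame(band = "a", count = 1000),
                             data.frame(band = "a", fraction = 1))
  expect_equal(tot1$q, 100)
  # zero population -> zero totals
  pop0 <- transform(pop, count = 0)
  expect_equal(project_population(out, pop0, cf)$qaly_gain, 0)
  expect_error(project_population(out, pop[1:2, ], cf), "misaligned")
})
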