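# Probabilistic sensitivity analysis: moment-matched parametric distributions
# for the treatment/cost measures (beta for proportions and utilities, gamma
# for costs, normal-on-log-scale for relative risks), correlated multivariate
# normal draws of the CVD log-hazard coefficients via Cholesky decomposition,
# and percentile summaries across iterations.

#' Default PSA measure distributions
#'
#' One entry per sampled measure: `list(dist, mean, sd)` with `dist` in
#' `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`, `"fixed"`. Zero `sd` (or
#' `"fixed"`) reproduces the base case exactly, without consuming random
#' numbers. Lognormal entries are parameterised by the mean and sd of the
#' measure's logarithm.
#'
#' @param treatment a [treatment_params()] supplying base values.
#' @param econ an [econ_params()].
#' @return named list of distribution specs.
#' @export
default_psa_distributions <- function(treatment = treatment_params(),
                                      econ = econ_params()) {
  ln_sd <- function(lo, hi) (log(hi) - log(lo)) / (2 * 1.96)
  list(
    nonhdl_reduction = list(dist = "beta", mean = treatment$nonhdl_reduction,
                            sd = 0.02),
    rr_nonfatal_chd = list(dist = "lognormal",
                           mean = log(treatment$rr_nonfatal_chd),
                           sd = ln_sd(0.71, 0.83),
                           base = treatment$rr_nonfatal_chd),
    rr_nonfatal_stroke = list(dist = "lognormal",
                              mean = log(treatment$rr_nonfatal_stroke),
                              sd = ln_sd(0.80, 0.94),
                              base = treatment$rr_nonfatal_stroke),
    rr_fatal_cvd = list(dist = "lognormal",
                        mean = log(treatment$rr_fatal_cvd),
                        sd = ln_sd(0.84, 0.97),
                        base = treatment$rr_fatal_cvd),
    pill_disutility = list(dist = "beta", mean = treatment$pill_disutility,
                           sd = 0.001),
    diabetes_abs_risk_increase = list(
      dist = "beta", mean = treatment$diabetes_abs_risk_increase, sd = 0.002),
    annual_drug_cost = list(dist = "gamma",
                            mean = treatment$annual_drug_cost,
                            sd = 0.2 * treatment$annual_drug_cost),
    monitoring_cost = list(dist = "gamma", mean = econ$monitoring_cost,
                           sd = 0.2 * econ$monitoring_cost)
  )
}

draw_measure <- function(spec, n = 1) {
  if (spec$dist == "fixed" || spec$sd == 0) {
    base <- spec$base %||%
      (if (spec$dist == "lognormal") exp(spec$mean) else spec$mean)
    return(rep(base, n))
  }
  switch(spec$dist,
    beta = {
      m <- spec$mean
      v <- spec$sd^2
      k <- m * (1 - m) / v - 1
      if (k <= 0) stop_config("beta sd too large for mean ", m)
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    gamma = {
      shape <- (spec$mean / spec$sd)^2
      stats::rgamma(n, shape = shape, rate = shape / spec$mean)
    },
    lognormal = exp(stats::rnorm(n, spec$mean, spec$sd)),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    stop_config("unknown distribution '", spec$dist, "'")
  )
}

#' Correlated log-hazard-ratio draw
#'
#' `mean + t(L) %*% z` with `L` the (upper-triangular) Cholesky factor of the
#' covariance and `z` iid standard normal; a zero covariance returns the mean
#' exactly. Positive semi-definite (singular) covariances fall back to an
#' eigendecomposition square root.
#'
#' @param mean_log_hrs numeric vector of mean log hazard ratios/coefficients.
#' @param covariance covariance matrix, symmetric PSD.
#' @param seed optional integer seed for this draw.
#' @return numeric vector, one draw.
#' @export
correlated_hr_draw <- function(mean_log_hrs, covariance, seed = NULL) {
  k <- length(mean_log_hrs)
  stopifnot(nrow(covariance) == k, ncol(covariance) == k)
  check_psd(covariance, deparse(substitute(covariance)))
  if (all(covariance == 0)) return(mean_log_hrs)
  draw <- function() {
    z <- stats::rnorm(k)
    u <- tryCatch(chol(covariance), error = function(e) NULL)
    if (!is.null(u)) {
      mean_log_hrs + drop(crossprod(u, z))
    } else {
      e <- eigen(covariance, symmetric = TRUE)
      mean_log_hrs + drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * z))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample PSA parameter sets
#'
#' Draws `n_iter` independent parameter sets: every declared measure from its
#' distribution and the CVD log-hazard coefficient vector from its
#' multivariate normal (Cholesky). Per-iteration seeds are derived from the
#' master seed by counter-based splitting, so iteration `i` is reproducible
#' in isolation.
#'
#' @param distributions named list of measure distributions
#'   ([default_psa_distributions()]).
#' @param n_iter number of iterations.
#' @param master_seed integer master seed.
#' @param params a [survival_params()] (mean coefficients + covariance).
#' @param treatment a [treatment_params()] to instantiate per draw.
#' @return list of `psa_sample` objects: `index`, `measures` (named numeric),
#'   `treatment` (updated [treatment_params()]), `coef` (sampled CVD
#'   coefficient matrix), `seed`.
#' @export
sample_parameters <- function(distributions, n_iter, master_seed,
                              params = default_survival_params(),
                              treatment = treatment_params()) {
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    if (is.null(d$dist)) stop_config("measure '", nm, "' has no distribution")
  }
  mean_log <- as.vector(t(params$coef[CVD_CAUSES, , drop = FALSE]))
  lapply(seq_len(n_iter), function(i) {
    seed_i <- derive_seed(master_seed, i)
    with_seed(seed_i, {
      meas <- vapply(distributions, draw_measure, numeric(1))
      log_hr <- correlated_hr_draw(mean_log, params$hr_covariance)
      coef <- params$coef
      coef[CVD_CAUSES, ] <- matrix(log_hr, nrow = 3, byrow = TRUE)
      trt <- treatment
      for (nm in intersect(names(meas),
                           c("nonhdl_reduction", "rr_nonfatal_chd",
                             "rr_nonfatal_stroke", "rr_fatal_cvd",
                             "pill_disutility", "diabetes_abs_risk_increase",
                             "annual_drug_cost"))) {
        trt[[nm]] <- min(unname(meas[[nm]]), if (startsWith(nm, "rr_")) 1
                         else Inf)
      }
      structure(list(index = i, measures = meas, treatment = trt,
                     coef = coef, seed = seed_i),
                class = "psa_sample")
    })
  })
}

#' Run the probabilistic sensitivity analysis
#'
#' For each sampled parameter set, re-simulates untreated and treated
#' lifetime outcomes for the whole cohort and blends them per strategy by the
#' base-case eligibility (thresholds are calibrated once, at base case, and
#' held fixed across iterations). Returns weighted per-person mean discounted
#' cost and QALYs per strategy per iteration.
#'
#' @param cohort analysis-ready cohort.
#' @param strategies named list of [strategy_def()]s.
#' @param risk,arr base-case per-profile scores used for eligibility.
#' @param params,econ,treatment base-case parameter objects.
#' @param n_iter number of iterations.
#' @param master_seed integer master seed.
#' @param distributions measure distributions; default
#'   [default_psa_distributions()].
#' @return data.frame with columns `iteration`, `strategy`, `cost`, `qaly`
#'   (per-person weighted means).
#' @export
run_psa <- function(cohort, strategies, risk, arr,
                    params = default_survival_params(),
                    econ = econ_params(), treatment = treatment_params(),
                    n_iter = 1000, master_seed = 1L,
                    distributions = default_psa_distributions(treatment,
                                                              econ)) {
  samples <- sample_parameters(distributions, n_iter, master_seed, params,
                               treatment)
  elig <- lapply(strategies, eligible, cohort = cohort, risk = risk,
                 arr = arr)
  w <- cohort$weight / sum(cohort$weight)
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    s <- samples[[i]]
    params_i <- params
    params_i$coef <- s$coef
    econ_i <- econ
    if ("monitoring_cost" %in% names(s$measures)) {
      econ_i$monitoring_cost <- unname(s$measures[["monitoring_cost"]])
    }
    untr <- simulate_cohort(cohort, params_i, econ_i, s$treatment,
                            treated = FALSE)
    trt <- simulate_cohort(cohort, params_i, econ_i, s$treatment,
                           treated = TRUE)
    rows[[i]] <- do.call(rbind, lapply(names(strategies), function(nm) {
      e <- elig[[nm]]
      cost <- sum(w * ifelse(e, trt$cost_total, untr$cost_total))
      qaly <- sum(w * ifelse(e, trt$qalys, untr$qalys))
      data.frame(iteration = i, strategy = nm, cost = cost, qaly = qaly)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise PSA iterations
#'
#' Per-strategy means of cost and QALYs ("base case results were derived from
#' the mean values of the probabilistic analyses"), the ICER frontier over
#' those means, and 2.5th/97.5th percentile intervals (linear interpolation
#' between order statistics) of the per-iteration incremental costs, QALYs
#' and ICERs along the frontier.
#'
#' @param psa_df output of [run_psa()].
#' @return list: `strategy_summary` (means + percentile intervals of cost and
#'   QALYs), `frontier` (a [icer_frontier()] result over the means),
#'   `incremental` (per adjacent frontier pair: mean increments, ICER of
#'   means, percentile CIs of increments and of the ICER distribution).
#' @export
summarize_psa <- function(psa_df) {
  stopifnot(length(unique(psa_df$iteration)) >= 2)
  pct <- function(x, p) unname(stats::quantile(x, p, type = 7))
  strategies <- unique(psa_df$strategy)
  summ <- do.call(rbind, lapply(strategies, function(nm) {
    d <- psa_df[psa_df$strategy == nm, ]
    data.frame(strategy = nm, cost = mean(d$cost), qaly = mean(d$qaly),
               cost_lo = pct(d$cost, 0.025), cost_hi = pct(d$cost, 0.975),
               qaly_lo = pct(d$qaly, 0.025), qaly_hi = pct(d$qaly, 0.975))
  }))
  fr <- icer_frontier(summ[, c("strategy", "cost", "qaly")])
  front <- fr$frontier
  inc <- NULL
  if (nrow(front) >= 2) {
    inc <- do.call(rbind, lapply(seq_len(nrow(front) - 1), function(k) {
      a <- psa_df[psa_df$strategy == front$strategy[k], ]
      b <- psa_df[psa_df$strategy == front$strategy[k + 1], ]
      a <- a[order(a$iteration), ]
      b <- b[order(b$iteration), ]
      dc <- b$cost - a$cost
      dq <- b$qaly - a$qaly
      icers <- dc / dq
      data.frame(comparator = front$strategy[k],
                 strategy = front$strategy[k + 1],
                 d_cost = mean(dc), d_qaly = mean(dq),
                 icer = mean(dc) / mean(dq),
                 d_cost_lo = pct(dc, 0.025), d_cost_hi = pct(dc, 0.975),
                 d_qaly_lo = pct(dq, 0.025), d_qaly_hi = pct(dq, 0.975),
                 icer_lo = pct(icers, 0.025), icer_hi = pct(icers, 0.975))
    }))
  }
  list(strategy_summary = summ, frontier = fr, incremental = inc)
}
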