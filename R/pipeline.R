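# Orchestration: a single JSON-configurable entry point running the full
# chain — generate, impute, detreat, exclude, score, calibrate the six
# policies, base-case simulation, PSA, CEA — and writing CSV/JSON outputs
# with a reproducibility manifest. This function surface (plus
# scenario_runner) is the package's command-line equivalent; all randomness
# descends from the single master seed in the config.

#' Default pipeline configuration
#'
#' A complete configuration list, serialisable to JSON. Strategy entries name
#' an eligibility family and either a fixed threshold or a `match` field
#' naming the strategy whose treated count they are calibrated to.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param psa_iterations number of PSA iterations.
#' @return nested list.
#' @export
default_config <- function(n = 2000, seed = 1L, psa_iterations = 50) {
  list(
    seed = as.integer(seed),
    cohort = list(n = n),
    strategies = list(
      none = list(family = "none"),
      assign20 = list(family = "fixed_risk", threshold = 0.20),
      assign10 = list(family = "fixed_risk", threshold = 0.10),
      age20 = list(family = "age_stratified", match = "assign20"),
      age10 = list(family = "age_stratified", match = "assign10"),
      arr20 = list(family = "arr", match = "assign20"),
      arr10 = list(family = "arr", match = "assign10")
    ),
    psa = list(iterations = psa_iterations),
    wtp_grid = list(from = 0, to = 50000, by = 500)
  )
}

validate_config <- function(config) {
  for (f in c("seed", "cohort", "strategies")) {
    if (is.null(config[[f]])) stop_config("config is missing field '", f, "'")
  }
  fams <- c("fixed_risk", "age_stratified", "arr", "none")
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    if (is.null(s$family) || !(s$family %in% fams)) {
      stop_config("strategies$", nm, "$family: unknown strategy family '",
                  s$family %||% "NULL", "'")
    }
    if (s$family != "none" && is.null(s$threshold) && is.null(s$match)) {
      stop_config("strategies$", nm, ": needs 'threshold' or 'match'")
    }
  }
  invisible(config)
}

# generate -> impute -> detreat -> exclude -> score -> calibrate
prepare_analysis <- function(config, params, econ, treatment) {
  spec_args <- config$cohort
  spec_args$seed <- spec_args$seed %||% config$seed
  spec <- do.call(cohort_spec, spec_args)
  prep <- preprocess_cohort(spec, treatment)
  cohort <- prep$cohort
  risk <- ten_year_risk(cohort, params)
  arr <- arr_score(cohort, params, treatment)
  strategies <- list()
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    if (s$family == "none") {
      strategies[[nm]] <- strategy_def("none", label = nm)
    } else if (!is.null(s$threshold)) {
      strategies[[nm]] <- strategy_def(s$family, s$threshold, label = nm)
    } else {
      ref <- strategies[[s$match]]
      if (is.null(ref)) {
        stop_config("strategies$", nm, ": match target '", s$match,
                    "' must be defined first")
      }
      target <- sum(cohort$weight[eligible(ref, cohort, risk, arr)])
      strategies[[nm]] <- calibrate_to_count(s$family, cohort, target,
                                             risk = risk, arr = arr,
                                             label = nm)
    }
  }
  list(cohort = cohort, risk = risk, arr = arr, strategies = strategies,
       exclusion_log = prep$exclusion_log,
       imputation_log = prep$imputation_log)
}

# per-strategy weighted per-person means under given parameter objects
deterministic_outcomes <- function(prep, params, econ, treatment) {
  untr <- simulate_cohort(prep$cohort, params, econ, treatment,
                          treated = FALSE)
  trt <- simulate_cohort(prep$cohort, params, econ, treatment, treated = TRUE)
  w <- prep$cohort$weight / sum(prep$cohort$weight)
  do.call(rbind, lapply(names(prep$strategies), function(nm) {
    e <- eligible(prep$strategies[[nm]], prep$cohort, prep$risk, prep$arr)
    data.frame(strategy = nm,
               cost = sum(w * ifelse(e, trt$cost_total, untr$cost_total)),
               qaly = sum(w * ifelse(e, trt$qalys, untr$qalys)),
               life_years = sum(w * ifelse(e, trt$life_years,
                                           untr$life_years)),
               p_cvd_event = sum(w * ifelse(
                 e,
                 trt$p_chd + trt$p_cbvd + trt$p_fatal_cvd,
                 untr$p_chd + untr$p_cbvd + untr$p_fatal_cvd)),
               eligible_weight = sum(prep$cohort$weight[e]),
               disc_treated_years = sum(w * ifelse(
                 e, trt$disc_treated_years, 0)))
  }))
}

#' Run the full analysis pipeline
#'
#' Validates the configuration, runs preprocessing, calibration, the
#' deterministic base case, the PSA and the CEA synthesis, and writes all
#' tabular outputs (CSV, UTF-8) plus JSON logs and a run manifest to
#' `output_dir`. Reruns with the same config are byte-identical (manifest
#' timestamp aside).
#'
#' @param config configuration list ([default_config()]) or path to a JSON
#'   file.
#' @param output_dir directory for outputs (created if needed).
#' @param params,econ,treatment parameter objects; defaults are the shipped
#'   synthetic values.
#' @return invisibly, a list with the in-memory results (`prep`, `base_case`,
#'   `psa`, `psa_summary`, `ceac`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), output_dir,
                         params = default_survival_params(),
                         econ = econ_params(),
                         treatment = treatment_params()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  prep <- prepare_analysis(config, params, econ, treatment)
  base_case <- deterministic_outcomes(prep, params, econ, treatment)
  n_iter <- config$psa$iterations %||% 0
  psa_df <- NULL
  psa_summary <- NULL
  ceac_df <- NULL
  if (n_iter >= 2) {
    psa_df <- run_psa(prep$cohort, prep$strategies, prep$risk, prep$arr,
                      params, econ, treatment, n_iter = n_iter,
                      master_seed = derive_seed(config$seed, 7))
    psa_summary <- summarize_psa(psa_df)
    g <- config$wtp_grid
    ceac_df <- ceac(psa_df, wtp_grid = seq(g$from, g$to, by = g$by))
  }
  elig_tabs <- do.call(rbind, lapply(names(prep$strategies), function(nm) {
    cbind(strategy = nm,
          eligibility_summary(prep$strategies[[nm]], prep$cohort,
                              prep$risk, prep$arr))
  }))

  files <- c(cohort = "cohort.csv", base_case = "base_case.csv",
             eligibility = "eligibility.csv",
             exclusion_log = "exclusion_log.json")
  write_cohort(prep$cohort, file.path(output_dir, "cohort.csv"))
  utils::write.csv(base_case, file.path(output_dir, "base_case.csv"),
                   row.names = FALSE)
  utils::write.csv(elig_tabs, file.path(output_dir, "eligibility.csv"),
                   row.names = FALSE)
  jsonlite::write_json(prep$exclusion_log,
                       file.path(output_dir, "exclusion_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(psa_df)) {
    utils::write.csv(psa_df, file.path(output_dir, "psa.csv"),
                     row.names = FALSE)
    utils::write.csv(psa_summary$strategy_summary,
                     file.path(output_dir, "psa_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(psa_summary$frontier$frontier,
                     file.path(output_dir, "frontier.csv"),
                     row.names = FALSE)
    if (!is.null(psa_summary$incremental)) {
      utils::write.csv(psa_summary$incremental,
                       file.path(output_dir, "incremental.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(ceac_df, file.path(output_dir, "ceac.csv"),
                     row.names = FALSE)
    files <- c(files, psa = "psa.csv", psa_summary = "psa_summary.csv",
               frontier = "frontier.csv", ceac = "ceac.csv")
    if (!is.null(psa_summary$incremental)) {
      files <- c(files, incremental = "incremental.csv")
    }
  }
  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    master_seed = config$seed,
    package_version = as.character(utils::packageVersion("statinpolicy")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(prep = prep, base_case = base_case, psa = psa_df,
                 psa_summary = psa_summary, ceac = ceac_df,
                 manifest = manifest))
}

#' Run a named scenario analysis
#'
#' Deterministic re-analyses of the base configuration:
#' * `adherence` — persistence fractions (0.67 / 0.53 / 0.50) applied to
#'   treatment efficacy, side effects and post-first-year costs;
#' * `exclude_diabetes` — diabetic profiles are treated regardless of
#'   prioritisation criteria and removed from the calibration population;
#' * `pill_disutility_sweep` — incremental NMB of every treating strategy
#'   over a grid of pill-taking disutilities;
#' * `threshold_sweep` — incremental ICERs for fixed-risk thresholds from 20%
#'   down to treat-all in 1% steps.
#'
#' @param config configuration list or JSON path (see [run_pipeline()]).
#' @param scenario one of `"adherence"`, `"exclude_diabetes"`,
#'   `"pill_disutility_sweep"`, `"threshold_sweep"`.
#' @param params,econ,treatment base-case parameter objects.
#' @param disutility_grid grid for the sweep scenario.
#' @return scenario-specific data.frame (see Details).
#' @export
scenario_runner <- function(config = default_config(),
                            scenario = c("adherence", "exclude_diabetes",
                                         "pill_disutility_sweep",
                                         "threshold_sweep"),
                            params = default_survival_params(),
                            econ = econ_params(),
                            treatment = treatment_params(),
                            disutility_grid = seq(0, 0.03, by = 0.002)) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  scenario <- match.arg(scenario)
  validate_config(config)
  prep <- prepare_analysis(config, params, econ, treatment)
  switch(scenario,
    adherence = {
      trt <- treatment
      trt$full_adherence <- FALSE
      deterministic_outcomes(prep, params, econ, trt)
    },
    exclude_diabetes = {
      sub <- prep
      dia <- prep$cohort$diabetes
      # recalibrate matched strategies on the non-diabetic population
      cfg2 <- config
      strategies <- list()
      risk <- prep$risk
      arr <- prep$arr
      for (nm in names(config$strategies)) {
        s <- config$strategies[[nm]]
        if (s$family == "none") {
          strategies[[nm]] <- strategy_def("none", label = nm)
        } else if (!is.null(s$threshold)) {
          strategies[[nm]] <- strategy_def(s$family, s$threshold, label = nm)
        } else {
          ref <- strategies[[s$match]]
          base_el <- eligible(ref, prep$cohort, risk, arr) & !dia
          target <- sum(prep$cohort$weight[base_el])
          strategies[[nm]] <- calibrate_to_count(
            s$family, prep$cohort[!dia, , drop = FALSE], target,
            risk = risk[!dia], arr = arr[!dia], label = nm)
        }
      }
      sub$strategies <- strategies
      out <- deterministic_outcomes_with_override(
        sub, params, econ, treatment, force_treated = dia)
      out
    },
    pill_disutility_sweep = {
      base <- deterministic_outcomes(prep, params, econ, treatment)
      ref <- base[base$strategy == names(prep$strategies)[1], ]
      do.call(rbind, lapply(disutility_grid, function(d) {
        # QALYs are linear in the disutility through discounted treated years
        adj <- base
        adj$qaly <- base$qaly +
          (treatment$pill_disutility - d) * base$disc_treated_years
        data.frame(pill_disutility = d, strategy = adj$strategy,
                   cost = adj$cost, qaly = adj$qaly,
                   nmb = nmb(adj$cost - ref$cost, adj$qaly - ref$qaly,
                             econ$wtp_threshold))
      }))
    },
    threshold_sweep = {
      untr <- simulate_cohort(prep$cohort, params, econ, treatment,
                              treated = FALSE)
      trt <- simulate_cohort(prep$cohort, params, econ, treatment,
                             treated = TRUE)
      w <- prep$cohort$weight / sum(prep$cohort$weight)
      thresholds <- seq(0.20, 0, by = -0.01)
      rows <- lapply(thresholds, function(th) {
        e <- prep$risk >= th
        data.frame(threshold = th,
                   eligible_weight = sum(prep$cohort$weight[e]),
                   cost = sum(w * ifelse(e, trt$cost_total, untr$cost_total)),
                   qaly = sum(w * ifelse(e, trt$qalys, untr$qalys)))
      })
      out <- do.call(rbind, rows)
      out$incr_icer <- c(NA_real_, diff(out$cost) / diff(out$qaly))
      out
    }
  )
}

# deterministic outcomes where some profiles are treated regardless of
# strategy eligibility (diabetes-removal scenario)
deterministic_outcomes_with_override <- function(prep, params, econ,
                                                 treatment, force_treated) {
  untr <- simulate_cohort(prep$cohort, params, econ, treatment,
                          treated = FALSE)
  trt <- simulate_cohort(prep$cohort, params, econ, treatment, treated = TRUE)
  w <- prep$cohort$weight / sum(prep$cohort$weight)
  do.call(rbind, lapply(names(prep$strategies), function(nm) {
    e <- eligible(prep$strategies[[nm]], prep$cohort, prep$risk, prep$arr) |
      force_treated
    data.frame(strategy = nm,
               cost = sum(w * ifelse(e, trt$cost_total, untr$cost_total)),
               qaly = sum(w * ifelse(e, trt$qalys, untr$qalys)),
               eligible_weight = sum(prep$cohort$weight[e]))
  }))
}
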