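# Synthetic cohort generation and preprocessing. The generator stands in for
# a national health-survey extract of CVD-free adults >= 40 y: sex-stratified
# Gaussian copula over {SBP, TC, HDL-C, SIMD} with log-normal lipid marginals,
# point-mass-inflated smoking, age-graded diabetes / prevalent CVD / statin
# use, a nurse-visit refusal block with all three blood/pressure measures
# missing, plus additional covariate-dependent (MAR) missingness.

#' Specification of a synthetic cohort
#'
#' Collects every knob of the generator. Defaults describe the stated world
#' the analysis assumes: a survey-like adult population, majority female,
#' with sparse TC/HDL-C/SBP (only a minority received nurse visits) and
#' age-increasing statin use and prevalent CVD.
#'
#' @param n number of profiles to generate.
#' @param seed integer RNG seed.
#' @param prop_female proportion female.
#' @param age_band_probs probabilities over the 9 age bands
#'   ([age_band_labels()]); must sum to 1.
#' @param missing_rates named numeric, marginal missingness of `tc`, `hdl`,
#'   `sbp` among non-refusers (MAR: realised probability tilts with age).
#' @param refusal_fraction fraction refusing the nurse visit (all of tc, hdl,
#'   sbp missing as a block).
#' @param statin_prev_by_band statin-use prevalence per age band.
#' @param famhist_prob probability of family history of premature CVD.
#' @param copula_corr 4x4 correlation matrix over latent (sbp, tc, hdl, simd).
#' @param weight_mean mean expansion weight (weights are 1 when `weight_cv` is
#'   0, otherwise gamma-distributed with this mean).
#' @param weight_cv coefficient of variation of expansion weights.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 10000,
                        seed = 2011L,
                        prop_female = 0.54,
                        age_band_probs = c(0.16, 0.15, 0.14, 0.13, 0.12,
                                           0.10, 0.08, 0.06, 0.06),
                        missing_rates = c(tc = 0.10, hdl = 0.10, sbp = 0.08),
                        refusal_fraction = 0.25,
                        statin_prev_by_band = c(0.02, 0.04, 0.08, 0.12, 0.18,
                                                0.25, 0.30, 0.33, 0.35),
                        famhist_prob = 0.25,
                        copula_corr = default_copula_corr(),
                        weight_mean = 1,
                        weight_cv = 0) {
  if (abs(sum(age_band_probs) - 1) > 1e-8) {
    stop_config("age_band_probs must sum to 1")
  }
  if (any(age_band_probs < 0)) stop_config("age_band_probs must be >= 0")
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop_config("missing_rates must lie in [0, 1]")
  }
  if (refusal_fraction < 0 || refusal_fraction > 1) {
    stop_config("refusal_fraction must lie in [0, 1]")
  }
  if (any(statin_prev_by_band < 0 | statin_prev_by_band > 1)) {
    stop_config("statin_prev_by_band must lie in [0, 1]")
  }
  stopifnot(length(age_band_probs) == 9, length(statin_prev_by_band) == 9)
  structure(list(n = n, seed = as.integer(seed), prop_female = prop_female,
                 age_band_probs = age_band_probs,
                 missing_rates = missing_rates,
                 refusal_fraction = refusal_fraction,
                 statin_prev_by_band = statin_prev_by_band,
                 famhist_prob = famhist_prob,
                 copula_corr = copula_corr,
                 weight_mean = weight_mean, weight_cv = weight_cv),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_copula_corr <- function() {
  r <- diag(4)
  dimnames(r) <- list(c("sbp", "tc", "hdl", "simd"),
                      c("sbp", "tc", "hdl", "simd"))
  r["sbp", "tc"] <- r["tc", "sbp"] <- 0.20
  r["sbp", "hdl"] <- r["hdl", "sbp"] <- -0.10
  r["tc", "hdl"] <- r["hdl", "tc"] <- 0.15
  r["sbp", "simd"] <- r["simd", "sbp"] <- 0.05
  r["tc", "simd"] <- r["simd", "tc"] <- 0.05
  r["hdl", "simd"] <- r["simd", "hdl"] <- -0.10
  r
}

#' Generate a synthetic risk-factor cohort
#'
#' Draws `spec$n` profiles with the joint structure described in
#' [cohort_spec()]. Statin users' observed non-HDL-C is generated on the
#' treated scale (26% below the latent untreated level) so that downstream
#' detreatment recovers a coherent pre-treatment cholesterol. Prevalent-CVD
#' flags and under-40 ages are retained for [apply_exclusions()].
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `cohort` with columns `id, age, sex, diabetes,
#'   sbp, tc, hdl, cpd, simd, famhist, on_statin, prevalent_cvd,
#'   refused_nurse, weight`. Missing tc/hdl/sbp are `NA`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    band <- sample.int(9, n, replace = TRUE, prob = spec$age_band_probs)
    age <- ifelse(band < 9,
                  40 + (band - 1) * 5 + sample.int(5, n, replace = TRUE) - 1,
                  80 + pmin(stats::rgeom(n, 0.25), 14))
    sex <- ifelse(stats::runif(n) < spec$prop_female, "female", "male")
    diabetes <- stats::runif(n) < stats::plogis(-3.8 + 0.045 * (age - 40))
    famhist <- stats::runif(n) < spec$famhist_prob
    prevalent_cvd <- stats::runif(n) < stats::plogis(-4.6 + 0.07 * (age - 40))
    on_statin <- stats::runif(n) < spec$statin_prev_by_band[band]
    cpd <- ifelse(stats::runif(n) < 0.75, 0,
                  round(stats::rgamma(n, shape = 2.2, scale = 5.5)))
    z <- matrix(stats::rnorm(4 * n), n, 4) %*% chol(spec$copula_corr)
    sbp <- pmax(125 + 0.4 * (age - 60) + 3 * (sex == "male") + 15 * z[, 1],
                80)
    tc <- exp(log(5.3) + 0.003 * (age - 60) + 0.18 * z[, 2])
    mu_hdl <- ifelse(sex == "female", log(1.45), log(1.25))
    hdl <- exp(mu_hdl + 0.22 * z[, 3])
    bad <- which(tc < hdl + 0.5)
    for (i in seq_len(50)) {
      if (!length(bad)) break
      tc[bad] <- exp(log(5.3) + 0.003 * (age[bad] - 60) +
                       0.18 * stats::rnorm(length(bad)))
      bad <- bad[tc[bad] < hdl[bad] + 0.5]
    }
    if (length(bad)) tc[bad] <- hdl[bad] + 0.5
    simd <- 100 * stats::pnorm(z[, 4])
    # statin users observed on the treated lipid scale
    treated <- which(on_statin)
    tc[treated] <- hdl[treated] + (tc[treated] - hdl[treated]) * (1 - 0.26)
    refused <- stats::runif(n) < spec$refusal_fraction
    miss <- function(rate) {
      p <- stats::plogis(stats::qlogis(pmax(pmin(rate, 1 - 1e-9), 1e-9)) +
                           0.02 * (age - 60))
      !refused & stats::runif(n) < p & rate > 0
    }
    tc[refused | miss(spec$missing_rates[["tc"]])] <- NA_real_
    hdl[refused | miss(spec$missing_rates[["hdl"]])] <- NA_real_
    sbp[refused | miss(spec$missing_rates[["sbp"]])] <- NA_real_
    weight <- if (spec$weight_cv > 0) {
      shape <- 1 / spec$weight_cv^2
      stats::rgamma(n, shape = shape, rate = shape / spec$weight_mean)
    } else {
      rep(spec$weight_mean, n)
    }
    cohort <- data.frame(id = seq_len(n), age = as.integer(age), sex = sex,
                         diabetes = diabetes, sbp = sbp, tc = tc, hdl = hdl,
                         cpd = as.numeric(cpd), simd = simd,
                         famhist = famhist, on_statin = on_statin,
                         prevalent_cvd = prevalent_cvd,
                         refused_nurse = refused, weight = weight,
                         stringsAsFactors = FALSE)
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Back-calculate pre-treatment cholesterol for current statin users
#'
#' Divides observed non-HDL-C by `1 - nonhdl_reduction` for profiles with
#' `on_statin = TRUE`; HDL-C is unchanged and TC is updated so that
#' `tc = hdl + detreated non-HDL-C`. Profiles with missing cholesterol are
#' left untouched (the pipeline imputes before detreating).
#'
#' @param cohort a cohort data.frame.
#' @param nonhdl_reduction proportional non-HDL-C reduction attributable to
#'   treatment, in (0, 1); 0 is a no-op.
#' @return the cohort with adjusted `tc`.
#' @export
detreat_statin_users <- function(cohort, nonhdl_reduction = 0.26) {
  stopifnot(nonhdl_reduction >= 0, nonhdl_reduction < 1)
  if (nonhdl_reduction == 0) return(cohort)
  idx <- which(cohort$on_statin & !is.na(cohort$tc) & !is.na(cohort$hdl))
  nonhdl <- (cohort$tc[idx] - cohort$hdl[idx]) / (1 - nonhdl_reduction)
  cohort$tc[idx] <- cohort$hdl[idx] + nonhdl
  cohort
}

#' Apply cohort exclusions
#'
#' Removes profiles aged under 40, with prevalent CVD, or meeting the
#' familial-hypercholesterolaemia rule: TC >= 7.5 mmol/L with a family
#' history of premature CVD, or TC >= 8.0 mmol/L regardless. The FH rule is
#' evaluated on (detreated) TC, so the pipeline calls this last. Idempotent.
#'
#' @param cohort a cohort data.frame with observed or imputed `tc`.
#' @return the retained cohort, with an `exclusion_log` attribute: counts
#'   removed by reason and rows retained.
#' @export
apply_exclusions <- function(cohort) {
  under40 <- cohort$age < 40
  cvd <- !under40 & cohort$prevalent_cvd
  fh <- !under40 & !cvd &
    ((!is.na(cohort$tc) & cohort$tc >= 7.5 & cohort$famhist) |
       (!is.na(cohort$tc) & cohort$tc >= 8.0))
  keep <- !(under40 | cvd | fh)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- list(generated = nrow(cohort),
              removed_age_under_40 = sum(under40),
              removed_prevalent_cvd = sum(cvd),
              removed_fh_rule = sum(fh),
              retained = sum(keep))
  stopifnot(log$retained + log$removed_age_under_40 +
              log$removed_prevalent_cvd + log$removed_fh_rule ==
              log$generated)
  attr(out, "exclusion_log") <- log
  out
}

imputation_vars <- c("tc", "hdl", "sbp")
imputation_rhs <- "age + I(sex == \"male\") + diabetes + cpd + simd + famhist + on_statin"
imputation_bounds <- list(sbp = c(70, 250), tc = c(2, 12), hdl = c(0.4, 4))

#' Stochastic-regression imputation of sparse covariates
#'
#' Each missing TC, HDL-C or SBP value is replaced by the fitted value from a
#' linear regression on the fully observed covariates (age, sex, diabetes,
#' cigarettes/day, deprivation, family history, statin use) plus a residual
#' draw. Imputed values are redrawn (up to 100 times, then clipped) into
#' plausibility bounds — SBP in \[70, 250\] mmHg, TC in \[2, 12\] and HDL-C in
#' \[0.4, 4\] mmol/L — and TC > HDL-C is enforced; truncations are logged.
#'
#' @param cohort a cohort data.frame.
#' @param seed integer seed for the residual draws.
#' @return completed cohort with an `imputation_log` attribute (counts imputed
#'   and clipped per variable).
#' @export
impute_stochastic_regression <- function(cohort, seed = 1L) {
  n_missing <- vapply(imputation_vars, function(v) sum(is.na(cohort[[v]])),
                      integer(1))
  if (all(n_missing == 0)) {
    attr(cohort, "imputation_log") <- list(imputed = n_missing,
                                           clipped = n_missing)
    return(cohort)
  }
  with_seed(seed, {
    clipped <- c(tc = 0L, hdl = 0L, sbp = 0L)
    for (v in imputation_vars) {
      miss <- which(is.na(cohort[[v]]))
      if (!length(miss)) next
      cc <- which(!is.na(cohort[[v]]))
      if (length(cc) < 30) {
        stop("too few complete cases (", length(cc), ") to impute '", v, "'")
      }
      fit <- stats::lm(stats::as.formula(paste(v, "~", imputation_rhs)),
                       data = cohort[cc, , drop = FALSE])
      sigma <- stats::sigma(fit)
      mu <- stats::predict(fit, newdata = cohort[miss, , drop = FALSE])
      b <- imputation_bounds[[v]]
      draw <- mu + stats::rnorm(length(miss), sd = sigma)
      out_of_bounds <- which(draw < b[1] | draw > b[2])
      for (i in seq_len(100)) {
        if (!length(out_of_bounds)) break
        draw[out_of_bounds] <- mu[out_of_bounds] +
          stats::rnorm(length(out_of_bounds), sd = sigma)
        out_of_bounds <- out_of_bounds[draw[out_of_bounds] < b[1] |
                                         draw[out_of_bounds] > b[2]]
      }
      if (length(out_of_bounds)) {
        draw[out_of_bounds] <- pmin(pmax(draw[out_of_bounds], b[1]), b[2])
        clipped[[v]] <- clipped[[v]] + length(out_of_bounds)
      }
      cohort[[v]][miss] <- draw
    }
    # enforce TC > HDL-C where either side was imputed
    viol <- which(cohort$tc <= cohort$hdl)
    if (length(viol)) {
      cohort$tc[viol] <- cohort$hdl[viol] + 0.1
      clipped[["tc"]] <- clipped[["tc"]] + length(viol)
    }
    attr(cohort, "imputation_log") <- list(imputed = n_missing,
                                           clipped = clipped)
    cohort
  })
}

#' Multiple imputation for the nurse-visit refusal subgroup
#'
#' Non-refusers' missing values are completed once by stochastic regression
#' (shared across imputations); the block-missing refusal subgroup is then
#' completed `m` times with independent residual draws, giving `m` cohorts
#' whose downstream results should be averaged.
#'
#' @param cohort a cohort data.frame with a `refused_nurse` flag.
#' @param m number of imputations (>= 2).
#' @param seed integer master seed.
#' @return list of `m` completed cohorts.
#' @export
impute_multiple <- function(cohort, m = 5, seed = 1L) {
  if (m < 2) stop_config("m must be >= 2 for multiple imputation")
  refusers <- which(cohort$refused_nurse)
  base <- cohort
  # complete non-refuser missingness once, identically across imputations
  nonref <- cohort
  for (v in imputation_vars) {
    nonref[[v]][refusers] <- NA_real_
  }
  mask_nonref_missing <- lapply(imputation_vars, function(v) {
    setdiff(which(is.na(cohort[[v]])), refusers)
  })
  names(mask_nonref_missing) <- imputation_vars
  if (any(lengths(mask_nonref_missing) > 0)) {
    done <- impute_stochastic_regression(cohort, seed = derive_seed(seed, 0))
    for (v in imputation_vars) {
      base[[v]][mask_nonref_missing[[v]]] <- done[[v]][mask_nonref_missing[[v]]]
    }
  }
  lapply(seq_len(m), function(k) {
    impute_stochastic_regression(base, seed = derive_seed(seed, k))
  })
}

#' Run the full preprocessing chain
#'
#' Fixed pipeline order: generate, impute (stochastic regression), detreat
#' current statin users, then apply exclusions (the FH rule sees detreated
#' cholesterol).
#'
#' @param spec a [cohort_spec()].
#' @param treatment a [treatment_params()] supplying the detreatment scale.
#' @return list with elements `cohort` (analysis-ready), `exclusion_log`,
#'   `imputation_log`.
#' @export
preprocess_cohort <- function(spec, treatment = treatment_params()) {
  raw <- generate_cohort(spec)
  imp <- impute_stochastic_regression(raw, seed = derive_seed(spec$seed, 101))
  det <- detreat_statin_users(imp, treatment$nonhdl_reduction)
  out <- apply_exclusions(det)
  list(cohort = out,
       exclusion_log = attr(out, "exclusion_log"),
       imputation_log = attr(imp, "imputation_log"))
}

#' Read/write a cohort as CSV
#'
#' UTF-8, header row, one profile per row, missing values as empty fields.
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  for (v in c("diabetes", "famhist", "on_statin", "prevalent_cvd",
              "refused_nurse")) {
    if (v %in% names(x)) x[[v]] <- as.logical(x[[v]])
  }
  class(x) <- c("cohort", "data.frame")
  x
}
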