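# Eligibility rules and threshold calibration. Three families: a fixed
# 10-year risk threshold, age-stratified risk thresholds (high risk relative
# to age-group peers, one within-band quantile shared across bands), and an
# ARR threshold. Calibration finds thresholds whose eligible weighted count
# matches a target (e.g. the same number treated as under risk >= 20%).

#' Define an eligibility strategy
#'
#' @param family `"fixed_risk"`, `"age_stratified"`, `"arr"` or `"none"`.
#' @param threshold scalar threshold (risk or ARR probability) for
#'   `fixed_risk` / `arr`, or named per-age-band vector
#'   (names [age_band_labels()]) for `age_stratified`.
#' @param label display label; defaults to a family/threshold string.
#' @return object of class `strategy_def`.
#' @export
strategy_def <- function(family = c("fixed_risk", "age_stratified", "arr",
                                    "none"),
                         threshold = NULL, label = NULL) {
  family <- match.arg(family)
  if (family == "none") {
    threshold <- NULL
  } else if (family == "age_stratified") {
    if (is.null(names(threshold)) ||
        !setequal(names(threshold), age_band_labels())) {
      stop_config("age_stratified threshold must be named by age band")
    }
    threshold <- threshold[age_band_labels()]
    if (any(threshold < 0 | threshold > 1)) {
      stop_config("thresholds must lie in [0, 1]")
    }
  } else {
    stopifnot(length(threshold) == 1)
    if (threshold < 0 || threshold > 1) {
      stop_config("thresholds must lie in [0, 1]")
    }
  }
  label <- label %||% switch(family,
    none = "no treatment",
    fixed_risk = sprintf("risk >= %g%%", 100 * threshold),
    arr = sprintf("ARR >= %g%%", 100 * threshold),
    age_stratified = "age-stratified risk")
  structure(list(family = family, threshold = threshold, label = label,
                 calibration = NULL),
            class = "strategy_def")
}

#' Eligibility of profiles under a strategy
#'
#' Inclusive comparisons throughout: a score exactly at the threshold is
#' eligible.
#'
#' @param strategy a [strategy_def()].
#' @param cohort cohort data.frame (needed for ages under `age_stratified`).
#' @param risk per-profile 10-year CVD risk (from [ten_year_risk()]).
#' @param arr per-profile ARR (from [arr_score()]); only needed for the `arr`
#'   family.
#' @return logical vector.
#' @export
eligible <- function(strategy, cohort, risk = NULL, arr = NULL) {
  stopifnot(inherits(strategy, "strategy_def"))
  n <- nrow(cohort)
  switch(strategy$family,
    none = rep(FALSE, n),
    fixed_risk = {
      stopifnot(length(risk) == n)
      risk >= strategy$threshold
    },
    arr = {
      stopifnot(length(arr) == n)
      arr >= strategy$threshold
    },
    age_stratified = {
      stopifnot(length(risk) == n)
      band <- as.character(age_band(cohort$age))
      thr <- strategy$threshold[band]
      if (anyNA(thr)) stop("age outside all bands")
      risk >= unname(thr)
    }
  )
}

# largest threshold value (taken from the observed scores, +Inf, and 0) whose
# inclusive eligible weight is closest to the target without exceeding
# target + tol; ties at the threshold are included by >=
calibrate_scalar_threshold <- function(score, weight, target, tol) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  w <- weight[o]
  cw <- cumsum(w)
  # candidate thresholds: each distinct score (eligible weight = cumulative
  # weight at the last tied row)
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  cand_thr <- s[last_of_run]
  cand_w <- cw[last_of_run]
  err <- abs(cand_w - target)
  best <- which.min(err)
  thr <- cand_thr[best]
  achieved <- cand_w[best]
  if (target >= cw[length(cw)]) {
    thr <- 0
    achieved <- cw[length(cw)]
  }
  list(threshold = thr, achieved = achieved,
       within_tol = abs(achieved - target) <= tol)
}

#' Calibrate a strategy to a target treated count
#'
#' Finds thresholds such that the weighted eligible count matches
#' `target_count` (tolerance 0.5% of total cohort weight by default).
#' `fixed_risk` and `arr` use a weighted quantile of the respective score.
#' `age_stratified` solves for a single within-band quantile q applied to
#' every band's risk distribution — targeting individuals at high risk
#' relative to their age-group peers — such that total eligible weight matches
#' the target. If ties make the target unattainable, the nearest attainable
#' threshold is returned with `calibration$within_tol = FALSE`.
#'
#' @param family strategy family to calibrate (`"fixed_risk"`,
#'   `"age_stratified"` or `"arr"`).
#' @param cohort cohort data.frame with a `weight` column.
#' @param target_count target weighted number treated (<= total weight).
#' @param risk,arr per-profile scores as in [eligible()].
#' @param tol_frac tolerance as a fraction of total cohort weight.
#' @param label optional label.
#' @return a [strategy_def()] with a `calibration` element (`target`,
#'   `achieved`, `within_tol`).
#' @export
calibrate_to_count <- function(family, cohort, target_count,
                               risk = NULL, arr = NULL, tol_frac = 0.005,
                               label = NULL) {
  family <- match.arg(family, c("fixed_risk", "age_stratified", "arr"))
  w <- cohort$weight
  total <- sum(w)
  if (target_count > total + 1e-9) {
    stop_config("target_count exceeds total cohort weight")
  }
  tol <- tol_frac * total
  if (family %in% c("fixed_risk", "arr")) {
    score <- if (family == "fixed_risk") risk else arr
    stopifnot(length(score) == nrow(cohort))
    cal <- calibrate_scalar_threshold(score, w, target_count, tol)
    out <- strategy_def(family, threshold = cal$threshold, label = label)
  } else {
    stopifnot(length(risk) == nrow(cohort))
    band <- as.character(age_band(cohort$age))
    bands <- age_band_labels()
    # eligible weight as a function of the within-band top-quantile q:
    # in each band, threshold = weighted (1-q) quantile of risk
    thr_of_q <- function(q) {
      vapply(bands, function(b) {
        i <- band == b
        if (!any(i)) return(Inf)
        weighted_quantile(risk[i], w[i], 1 - q)
      }, numeric(1))
    }
    elig_weight <- function(q) {
      thr <- thr_of_q(q)
      sum(w[risk >= thr[band]])
    }
    lo <- 0
    hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (elig_weight(mid) < target_count) lo <- mid else hi <- mid
    }
    q <- hi
    thr <- thr_of_q(q)
    achieved <- sum(w[risk >= thr[band]])
    # among the bracketing endpoints pick the closer one
    thr_lo <- thr_of_q(lo)
    ach_lo <- sum(w[risk >= thr_lo[band]])
    if (abs(ach_lo - target_count) < abs(achieved - target_count)) {
      q <- lo
      thr <- thr_lo
      achieved <- ach_lo
    }
    out <- strategy_def("age_stratified", threshold = clip01(thr),
                        label = label)
    cal <- list(threshold = out$threshold, achieved = achieved,
                within_tol = abs(achieved - target_count) <= tol,
                quantile = q)
  }
  out$calibration <- list(target = target_count, achieved = cal$achieved,
                          within_tol = cal$within_tol,
                          quantile = cal$quantile %||% NA_real_)
  if (!out$calibration$within_tol) {
    warning("calibration off target by ",
            format(cal$achieved - target_count), " (ties?)")
  }
  out
}

# weighted quantile of type "left-continuous inverse CDF": smallest x with
# cumulative weight >= p * total
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= p * cw[length(cw)])[1]]
}

#' Eligibility prevalence by age band
#'
#' Weighted eligible counts and percentages per age band and overall.
#'
#' @inheritParams eligible
#' @return data.frame with columns `band`, `weight`, `eligible_weight`,
#'   `pct_eligible`; last row is `overall`.
#' @export
eligibility_summary <- function(strategy, cohort, risk = NULL, arr = NULL) {
  el <- eligible(strategy, cohort, risk, arr)
  band <- age_band(cohort$age)
  w <- cohort$weight
  tab <- data.frame(band = age_band_labels(),
                    weight = as.numeric(tapply(w, band, sum, default = 0)),
                    eligible_weight = as.numeric(
                      tapply(w * el, band, sum, default = 0)))
  tab <- rbind(tab, data.frame(band = "overall", weight = sum(w),
                               eligible_weight = sum(w * el)))
  tab$pct_eligible <- ifelse(tab$weight > 0,
                             100 * tab$eligible_weight / tab$weight, 0)
  tab
}

#' @export
print.strategy_def <- function(x, ...) {
  cat("<strategy_def>", x$label, "\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated: target %.1f achieved %.1f (%s)\n",
                x$calibration$target, x$calibration$achieved,
                if (x$calibration$within_tol) "within tol" else "OFF TARGET"))
  }
  invisible(x)
}
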