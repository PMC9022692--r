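# Utility, cost, discounting and inflation primitives. The simulator calls
# vectorised inline versions of these for speed; the exported functions are
# the module surface and the single source of the conventions (first cycle
# undiscounted, 2014-based costs inflated at point of use).

#' Annual utility of a health state
#'
#' Background utility (sex-specific intercept declining linearly in age) minus
#' the chronic-state decrement and the expected annual secondary-event
#' decrement, clipped to \[0, 1\]. Dead states have utility 0.
#'
#' @param age age in years.
#' @param sex `"female"` or `"male"`.
#' @param state a [HEALTH_STATES] name.
#' @param params an [econ_params()].
#' @return utility per year in \[0, 1\].
#' @export
state_utility <- function(age, sex, state, params = econ_params()) {
  state <- match.arg(state, HEALTH_STATES)
  if (state %in% c("DEAD_CVD", "DEAD_NONCVD", "DEAD_POST_EVENT")) return(0)
  int <- if (sex == "male") params$bg_utility$intercept_male else
    params$bg_utility$intercept_female
  bg <- pmax(int - params$bg_utility$age_slope * (age - 40),
             params$bg_utility$floor)
  u <- switch(state,
    CVD_FREE = bg,
    CHRONIC_CHD = bg - params$chronic_decrement[["chd"]] -
      params$secondary_decrement[["chd"]],
    CHRONIC_CBVD = bg - params$chronic_decrement[["cbvd"]] -
      params$secondary_decrement[["cbvd"]])
  clip01(u)
}

#' Hospitalisation cost linear equation
#'
#' Pre-event (acute, one-off) or post-event (annual) hospitalisation cost,
#' linear in age at primary event (centred at 60), deprivation score and
#' family history; floored at zero. Returned in 2014 GBP — apply
#' [inflate_cost()] for 2020 prices.
#'
#' @param age_at_event age when the primary event occurs.
#' @param simd deprivation score.
#' @param famhist logical family history flag.
#' @param phase `"pre"` or `"post"`.
#' @param params an [econ_params()].
#' @return cost in GBP (per event for `"pre"`, per year for `"post"`).
#' @export
event_cost <- function(age_at_event, simd, famhist, phase = c("pre", "post"),
                       params = econ_params()) {
  phase <- match.arg(phase)
  cf <- if (phase == "pre") params$event_cost_pre else params$event_cost_post
  pmax(cf[["intercept"]] + cf[["age"]] * (age_at_event - 60) +
         cf[["simd"]] * simd + cf[["famhist"]] * as.numeric(famhist), 0)
}

#' Present value of a per-cycle stream
#'
#' `sum(values[t] / (1 + rate)^(t - 1))`: the first cycle is undiscounted
#' (t = 0 convention).
#'
#' @param values numeric vector of per-cycle amounts (cycle 1 first).
#' @param rate annual discount rate (>= 0).
#' @return present value.
#' @export
discount_stream <- function(values, rate) {
  stopifnot(rate >= 0)
  sum(values / (1 + rate)^(seq_along(values) - 1))
}

#' Inflate a 2014-based cost to current prices
#'
#' Multiplies by `1 + inflation_factor` (12.5% for 2014 to 2020 health
#' services pay and price inflation). Only 2014-based model costs are
#' inflated; the statin drug tariff is already current-priced and must not be
#' passed through this function.
#'
#' @param cost_2014 cost in 2014 GBP (>= 0).
#' @param params an [econ_params()].
#' @return cost in current GBP.
#' @export
inflate_cost <- function(cost_2014, params = econ_params()) {
  stopifnot(all(cost_2014 >= 0))
  cost_2014 * (1 + params$inflation_factor)
}
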