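# Cost-effectiveness synthesis: the ICER frontier with strict and extended
# dominance, net monetary benefit, acceptability curves over a willingness-
# to-pay grid, one-way (tornado) sensitivity analyses, and projection of
# per-person simulation outcomes onto population counts.

#' ICER frontier with dominance classification
#'
#' Sorts strategies by cost, removes strictly dominated ones (weakly more
#' costly and weakly less effective than some other strategy, strict in at
#' least one dimension), then removes extendedly dominated ones (a higher
#' incremental cost-effectiveness ratio than the next more effective
#' alternative), and reports pairwise ICERs between adjacent frontier members.
#' Frontier ICERs are strictly increasing by construction.
#'
#' @param outcomes data.frame with columns `strategy` (label), `cost`, `qaly`.
#' @return list of class `frontier_result`: `frontier` (ordered data.frame
#'   with `icer` vs the previous frontier member, `NA` for the cheapest) and
#'   `dominated` (data.frame with a `dominance` flag, `"strict"` or
#'   `"extended"`). Exactly tied (cost, qaly) pairs keep their input order and
#'   are flagged in `ties`.
#' @export
icer_frontier <- function(outcomes) {
  outcomes <- as.data.frame(outcomes)
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(outcomes)),
            nrow(outcomes) >= 2)
  o <- outcomes[order(outcomes$cost, outcomes$qaly), , drop = FALSE]
  ties <- duplicated(o[, c("cost", "qaly")])
  n <- nrow(o)
  strict <- vapply(seq_len(n), function(i) {
    any(o$cost <= o$cost[i] & o$qaly >= o$qaly[i] &
          (o$cost < o$cost[i] | o$qaly > o$qaly[i]))
  }, logical(1))
  cand <- o[!strict, , drop = FALSE]
  extended <- character(0)
  repeat {
    k <- nrow(cand)
    if (k < 3) break
    icers <- diff(cand$cost) / diff(cand$qaly)
    bad <- which(diff(icers) < 0) # ICER to next-better alternative is lower
    if (!length(bad)) break
    drop_idx <- bad[1] + 1
    extended <- c(extended, cand$strategy[drop_idx])
    cand <- cand[-drop_idx, , drop = FALSE]
  }
  cand$icer <- c(NA_real_, diff(cand$cost) / diff(cand$qaly))
  rownames(cand) <- NULL
  dominated <- o[!(o$strategy %in% cand$strategy), , drop = FALSE]
  dominated$dominance <- ifelse(dominated$strategy %in% extended,
                                "extended", "strict")
  rownames(dominated) <- NULL
  structure(list(frontier = cand, dominated = dominated,
                 ties = o$strategy[ties]),
            class = "frontier_result")
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: linear in both arguments, so at willingness-to-pay
#' `wtp` a strategy with positive incremental QALYs is preferred over a
#' comparator exactly when its ICER against that comparator is below `wtp`.
#'
#' @param cost discounted cost, GBP.
#' @param qaly discounted QALYs.
#' @param wtp willingness to pay, GBP/QALY (>= 0).
#' @return net monetary benefit in GBP.
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qaly - cost
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the fraction of PSA iterations in which
#' each strategy attains the maximal net monetary benefit. Within-iteration
#' ties split the count equally (and are tallied in the `ties` attribute), so
#' the fractions sum to 1 at every grid point.
#'
#' @param psa_df output of [run_psa()]: `iteration`, `strategy`, `cost`,
#'   `qaly`.
#' @param wtp_grid numeric vector of willingness-to-pay values; default
#'   GBP 0 to 50,000 in steps of 500.
#' @return data.frame with columns `wtp` and one probability column per
#'   strategy.
#' @export
ceac <- function(psa_df, wtp_grid = seq(0, 50000, by = 500)) {
  its <- sort(unique(psa_df$iteration))
  stopifnot(length(its) >= 2)
  strategies <- unique(psa_df$strategy)
  cost <- matrix(NA_real_, length(its), length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (nm in strategies) {
    d <- psa_df[psa_df$strategy == nm, ]
    d <- d[order(d$iteration), ]
    cost[, nm] <- d$cost
    qaly[, nm] <- d$qaly
  }
  n_ties <- 0L
  out <- matrix(0, length(wtp_grid), length(strategies),
                dimnames = list(NULL, strategies))
  for (g in seq_along(wtp_grid)) {
    b <- wtp_grid[g] * qaly - cost
    best <- b == apply(b, 1, max)
    n_best <- rowSums(best)
    n_ties <- n_ties + sum(n_best > 1)
    out[g, ] <- colSums(best / n_best) / length(its)
  }
  res <- data.frame(wtp = wtp_grid, out, check.names = FALSE)
  attr(res, "ties") <- n_ties
  res
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs a deterministic model at each measure's low and high bound, holding
#' every other measure at base, and reports the incremental net monetary
#' benefit of `strategy` vs `comparator` at each extreme. Bars are sorted by
#' width (absolute NMB swing) descending.
#'
#' @param model_fn function(treatment, econ) returning a data.frame with
#'   columns `strategy`, `cost`, `qaly` (per-person means) — typically a
#'   closure over a prepared cohort (see [run_pipeline()]).
#' @param treatment,econ base-case parameter objects; `treatment$lo` /
#'   `treatment$hi` supply the bounds (measures absent from a bounds list are
#'   an error).
#' @param measures character vector of measures to vary; defaults to all
#'   bounded measures.
#' @param strategy,comparator strategy labels compared by incremental NMB.
#' @param wtp willingness to pay, GBP/QALY.
#' @return data.frame: `measure`, `lo`, `hi` (input values), `nmb_lo`,
#'   `nmb_hi` (incremental NMB at each extreme), `width`; sorted by `width`
#'   descending. Base-case incremental NMB in attribute `base_nmb`.
#' @export
tornado <- function(model_fn, treatment, econ, strategy, comparator,
                    wtp = econ$wtp_threshold,
                    measures = names(treatment$lo)) {
  inc_nmb <- function(trt, ec) {
    r <- model_fn(trt, ec)
    a <- r[r$strategy == comparator, ]
    b <- r[r$strategy == strategy, ]
    stopifnot(nrow(a) == 1, nrow(b) == 1)
    nmb(b$cost - a$cost, b$qaly - a$qaly, wtp)
  }
  base_nmb <- inc_nmb(treatment, econ)
  rows <- lapply(measures, function(m) {
    if (is.null(treatment$lo[[m]]) || is.null(treatment$hi[[m]])) {
      stop_config("no sensitivity bounds for measure '", m, "'")
    }
    at <- function(value) {
      trt <- treatment
      ec <- econ
      if (m %in% c("monitoring_cost", "discount_rate")) {
        ec[[m]] <- value
      } else {
        trt[[m]] <- value
      }
      inc_nmb(trt, ec)
    }
    data.frame(measure = m, lo = treatment$lo[[m]], hi = treatment$hi[[m]],
               nmb_lo = at(treatment$lo[[m]]), nmb_hi = at(treatment$hi[[m]]))
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$nmb_hi - out$nmb_lo)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base_nmb
  out
}

#' Project simulation outcomes onto a population
#'
#' National totals: for each age group, mean per-person outcome times the
#' population count times the CVD-free fraction, summed over groups.
#'
#' @param agegroup_outcomes data.frame with a `band` column and one or more
#'   numeric mean-outcome columns.
#' @param population_counts data.frame with columns `band`, `count`.
#' @param cvdfree_fractions data.frame with columns `band`, `fraction`.
#' @return one-row data.frame of totals (plus `eligible_population`, the
#'   weighted CVD-free population).
#' @export
project_population <- function(agegroup_outcomes, population_counts,
                               cvdfree_fractions) {
  bands <- agegroup_outcomes$band
  if (!setequal(bands, population_counts$band) ||
      !setequal(bands, cvdfree_fractions$band)) {
    stop("age bands are misaligned between outcome and population tables")
  }
  pc <- population_counts[match(bands, population_counts$band), ]
  cf <- cvdfree_fractions[match(bands, cvdfree_fractions$band), ]
  n_eff <- pc$count * cf$fraction
  value_cols <- setdiff(names(agegroup_outcomes), "band")
  totals <- vapply(value_cols, function(v) {
    sum(agegroup_outcomes[[v]] * n_eff)
  }, numeric(1))
  out <- as.data.frame(as.list(totals))
  out$eligible_population <- sum(n_eff)
  out
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("<frontier_result>\n")
  print(x$frontier)
  if (nrow(x$dominated)) {
    cat("dominated:\n")
    print(x$dominated[, c("strategy", "dominance")])
  }
  invisible(x)
}
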