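# Independent oracles used to pin the engine and the frontier algorithm.

# Explicit transition-matrix-product expectation for constant cause-specific
# hazards: builds the 6x6 one-cycle matrix from the hazard-decomposition
# formulas directly and accumulates rewards by matrix-vector products.
# Conventions mirror the engine's stated design (start-of-cycle accrual when
# half-cycle correction is off, death forced on reaching max_age with no
# accrual in the forced cycle, first cycle undiscounted).
matrix_chain_oracle <- function(age0, h, h_chronic, utilities, discount = 0,
                                max_age = 110) {
  H <- sum(h)
  exit <- 1 - exp(-H)
  share <- if (H > 0) h / H else rep(0, 4)
  T_live <- rbind(
    c(1 - exit, exit * share[1], exit * share[2], exit * share[3],
      exit * share[4], 0),
    c(0, exp(-h_chronic[1]), 0, 0, 0, 1 - exp(-h_chronic[1])),
    c(0, 0, exp(-h_chronic[2]), 0, 0, 1 - exp(-h_chronic[2])),
    c(0, 0, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 0, 1))
  T_dead <- rbind(
    c(0, 0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 0, 1),
    c(0, 0, 0, 0, 0, 1),
    c(0, 0, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 0, 1))
  v <- c(1, 0, 0, 0, 0, 0)
  qaly <- 0
  ly <- 0
  for (t in 0:(max_age - age0)) {
    over <- (age0 + t) >= max_age
    if (!over) {
      qaly <- qaly + sum(v * utilities) / (1 + discount)^t
      ly <- ly + sum(v[1:3])
    }
    v <- drop(v %*% (if (over) T_dead else T_live))
  }
  list(qaly = qaly, life_years = ly, final = v)
}

# A strategy lies on the cost-effectiveness frontier iff it maximises net
# monetary benefit for some willingness-to-pay lambda >= 0. Enumerates
# midpoints between all pairwise incremental ratios (plus extremes) and
# collects the argmax at each; independent of the dominance-elimination
# algorithm under test.
frontier_oracle <- function(df) {
  n <- nrow(df)
  ratios <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dq <- df$qaly[j] - df$qaly[i]
      dc <- df$cost[j] - df$cost[i]
      if (dq != 0) {
        r <- dc / dq
        if (is.finite(r) && r > 0) ratios <- c(ratios, r)
      }
    }
  }
  ratios <- sort(unique(ratios))
  grid <- if (length(ratios)) {
    c(ratios[1] / 2,
      if (length(ratios) > 1) (ratios[-1] + ratios[-length(ratios)]) / 2,
      ratios[length(ratios)] * 2)
  } else {
    1
  }
  # lambda -> 0 limit: least cost, ties broken by QALYs
  ref <- order(df$cost, -df$qaly)[1]
  on <- unique(c(ref, vapply(grid, function(l) {
    which.max(l * df$qaly - df$cost)
  }, integer(1))))
  out <- df[on, , drop = FALSE]
  out <- out[order(out$cost), , drop = FALSE]
  out$icer <- c(NA_real_, diff(out$cost) / diff(out$qaly))
  rownames(out) <- NULL
  out
}
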