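# Independent oracles used across test files.

# Brute-force enumeration of the one-cycle branch tree from the event-free
# state, written directly from the parameter table (independent of the
# kernel builder).
enumerate_min_row <- function(risks, is_split, ich_split, ech_fate, mi_fate) {
  p <- as.list(risks)
  to_death <- p$p_death +
    p$p_is * is_split[["die"]] + p$p_ich * ich_split[["die"]] +
    p$p_ech * ech_fate + p$p_mi * mi_fate
  to_min <- (1 - (p$p_is + p$p_ich + p$p_ech + p$p_mi + p$p_death)) +
    p$p_is * is_split[["light"]] + p$p_ich * ich_split[["light"]] +
    p$p_ech * (1 - ech_fate) + p$p_mi * (1 - mi_fate)
  to_mod <- p$p_is * is_split[["moderate"]] + p$p_ich * ich_split[["moderate"]]
  to_sev <- p$p_is * is_split[["severe"]] + p$p_ich * ich_split[["severe"]]
  c(Min = to_min, Mod = to_mod, Sev = to_sev, Death = to_death)
}

# Explicit geometric-series accumulation for the two-state model (loop, no
# closed form) — independent check on both the engine and the closed form.
loop_two_state <- function(p_death, u, cost, r, T_, discount_first_cycle = FALSE) {
  tot_c <- tot_q <- 0
  alive <- 1
  for (t in seq_len(T_)) {
    df <- (1 + r)^(-(if (discount_first_cycle) t else t - 1))
    tot_c <- tot_c + alive * cost * df
    tot_q <- tot_q + alive * u * df
    alive <- alive * (1 - p_death)
  }
  c(cost = tot_c, qaly = tot_q)
}

# Exhaustive dominance classification on the cost-effectiveness plane.
# A point is strictly dominated if a single other point weakly improves on
# it (strictly in one dimension); extendedly dominated if some convex blend
# of two other points attains its QALYs at strictly lower cost.
oracle_dominance <- function(cost, qaly) {
  n <- length(cost)
  status <- rep("on_frontier", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    strict <- any(cost[others] < cost[i] - 1e-9 & qaly[others] >= qaly[i] - 1e-9) ||
      any(cost[others] <= cost[i] + 1e-9 & qaly[others] > qaly[i] + 1e-9)
    if (strict) { status[i] <- "strictly_dominated"; next }
    ext <- FALSE
    for (j in others) for (k in others) {
      if (j == k || abs(qaly[j] - qaly[k]) < 1e-12) next
      lam <- (qaly[i] - qaly[k]) / (qaly[j] - qaly[k])
      if (lam < 0 || lam > 1) next
      blend_cost <- lam * cost[j] + (1 - lam) * cost[k]
      if (blend_cost < cost[i] - 1e-9) { ext <- TRUE; break }
    }
    if (ext) status[i] <- "extendedly_dominated"
  }
  status
}

# Published per-strategy totals (cost $, QALY) of the original analysis,
# used as printed inputs for the arithmetic checks.
published_totals <- function() {
  list(
    warfarin      = list(total_cost = 5317.31,  total_qaly = 11.07),
    rivaroxaban   = list(total_cost = 29673.33, total_qaly = 15.46),
    dabigatran110 = list(total_cost = 23615.48, total_qaly = 12.40),
    dabigatran150 = list(total_cost = 34324.91, total_qaly = 15.00)
  )
}

fake_psa <- function(cost, qaly, strategies = colnames(cost)) {
  structure(list(cost = cost, qaly = qaly, strategies = strategies,
                 n_draws = nrow(cost), seed = NA_integer_),
            class = "af_psa")
}
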