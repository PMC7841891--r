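# Markov engine: per-strategy cycle kernel, cohort propagation, discounted
# accrual, and an individual-level microsimulation whose expectation is the
# cohort model.
#
# Accrual convention: a patient occupies one state for the whole cycle and
# transitions at cycle end. The cycle in which a fatal event occurs accrues
# the pre-event state utility and (by default) the event cost; survivors of
# an event accrue their destination-state utility in the event cycle,
# multiplied by the within-cycle multiplier for ICH/ECH/MI. The Death state
# accrues nothing.

.state_index <- function(s) match(s, .af_states)

# One-cycle branch decomposition from a single origin state. Each row is a
# mutually exclusive branch: stay, all-cause death, or one clinical event
# with one outcome. `to` is the end-of-cycle state.
.branches_from <- function(origin, risks, is_split, ich_split, ech_fate,
                           mi_fate, events_active) {
  if (origin == "Death")
    return(data.frame(type = "stay", event = NA_character_, to = "Death",
                      prob = 1, stringsAsFactors = FALSE))
  if (!events_active) {
    p_d <- risks[["p_death"]]
    return(data.frame(
      type = c("stay", "acdeath"), event = NA_character_,
      to = c(origin, "Death"), prob = c(1 - p_d, p_d),
      stringsAsFactors = FALSE))
  }
  # nonfatal destination given the origin: severities can only worsen
  sev_to <- function(outcome) {
    dest <- c(light = "Min", moderate = "Mod", severe = "Sev")[outcome]
    .af_states[max(.state_index(origin), .state_index(dest))]
  }
  surv_to <- .af_states[max(.state_index(origin), 1L)]  # ECH/MI survivors
  rows <- list()
  add <- function(type, event, to, prob)
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, event = event, to = to, prob = prob,
      stringsAsFactors = FALSE)
  p_ev <- risks[c("p_is", "p_ich", "p_ech", "p_mi")]
  p_d <- risks[["p_death"]]
  stay <- 1 - sum(unlist(p_ev)) - p_d
  if (stay < -1e-12)
    stop("competing event probabilities exceed 1 from state ", origin,
         call. = FALSE)
  add("stay", NA_character_, origin, max(stay, 0))
  add("acdeath", NA_character_, "Death", p_d)
  for (nm in c("light", "moderate", "severe"))
    add("event", "IS", sev_to(nm), risks[["p_is"]] * is_split[[nm]])
  add("event_fatal", "IS", "Death", risks[["p_is"]] * is_split[["die"]])
  for (nm in c("light", "moderate", "severe"))
    add("event", "ICH", sev_to(nm), risks[["p_ich"]] * ich_split[[nm]])
  add("event_fatal", "ICH", "Death", risks[["p_ich"]] * ich_split[["die"]])
  add("event", "ECH", surv_to, risks[["p_ech"]] * (1 - ech_fate))
  add("event_fatal", "ECH", "Death", risks[["p_ech"]] * ech_fate)
  add("event", "MI", surv_to, risks[["p_mi"]] * (1 - mi_fate))
  add("event_fatal", "MI", "Death", risks[["p_mi"]] * mi_fate)
  do.call(rbind, rows)
}

#' Build the one-cycle transition kernel for a strategy
#'
#' Constructs the competing-event partition of a one-year cycle: from the
#' event-free state (`Min`) the patient experiences at most one of ischemic
#' stroke, intracranial hemorrhage, extracranial hemorrhage, myocardial
#' infarction, or background all-cause death; stroke and ICH outcomes follow
#' their severity splits, ECH and MI are fatal or fully recovered. The severe
#' state is absorbing apart from death; the moderate state faces only
#' all-cause mortality unless `config$events_from_moderate` is `TRUE`, in
#' which case it faces the same event partition with nonfatal outcomes mapped
#' to the worse of the current and new severity.
#'
#' @param risks named vector of annual probabilities `p_is`, `p_ich`,
#'   `p_ech`, `p_mi`, `p_death` for one strategy.
#' @param is_split,ich_split named severity splits (`light`, `moderate`,
#'   `severe`, `die`) summing to 1.
#' @param ech_fate,mi_fate case fatality of ECH / MI (survivors recover).
#' @param config run configuration, see [default_run_config()].
#' @param strategy optional label carried in the kernel.
#' @return An object of class `af_cycle_kernel` with elements `transition`
#'   (4x4 matrix over Min, Mod, Sev, Death), `event_incidence` (state x
#'   event matrix of per-cycle event probabilities) and the per-state branch
#'   decompositions used for accrual.
#' @export
build_cycle_kernel <- function(risks, is_split, ich_split, ech_fate, mi_fate,
                               config = default_run_config(),
                               strategy = NA_character_) {
  branches <- lapply(.af_states, function(st) {
    active <- (st == "Min") ||
      (st == "Mod" && isTRUE(config$events_from_moderate))
    br <- tryCatch(
      .branches_from(st, risks, is_split, ich_split, ech_fate, mi_fate, active),
      error = function(e) stop(conditionMessage(e),
                               if (!is.na(strategy)) paste0(" (strategy ", strategy, ")") else "",
                               call. = FALSE))
    br
  })
  names(branches) <- .af_states
  transition <- t(vapply(branches, function(br)
    vapply(.af_states, function(to) sum(br$prob[br$to == to]), 0),
    numeric(4)))
  dimnames(transition) <- list(.af_states, .af_states)
  event_incidence <- t(vapply(branches, function(br)
    vapply(.af_events, function(e)
      sum(br$prob[!is.na(br$event) & br$event == e]), 0),
    numeric(4)))
  dimnames(event_incidence) <- list(.af_states, .af_events)
  structure(list(strategy = strategy, transition = transition,
                 event_incidence = event_incidence, branches = branches),
            class = "af_cycle_kernel")
}

#' @export
print.af_cycle_kernel <- function(x, ...) {
  cat("Cycle kernel", if (!is.na(x$strategy)) paste0("(", x$strategy, ")"),
      "\nTransition matrix:\n")
  print(round(x$transition, 6))
  invisible(x)
}

# Branch-level utility under the accrual convention (see file header).
.branch_utilities <- function(branches, utilities) {
  u_state <- c(Min = utilities$u_min, Mod = utilities$u_mod,
               Sev = utilities$u_sev, Death = 0)
  mult <- c(IS = 1, ICH = utilities$m_ich, ECH = utilities$m_ech,
            MI = utilities$m_mi)
  lapply(.af_states, function(st) {
    br <- branches[[st]]
    u <- ifelse(br$type %in% c("stay", "acdeath", "event_fatal"),
                u_state[[st]],
                u_state[br$to] * mult[br$event])
    if (st == "Death") u[] <- 0
    unname(u)
  }) |> stats::setNames(.af_states)
}

.branch_costs <- function(branches, costs, charge_fatal) {
  lapply(.af_states, function(st) {
    br <- branches[[st]]
    ec <- ifelse(is.na(br$event), 0, costs$event[br$event])
    if (!charge_fatal) ec[br$type == "event_fatal"] <- 0
    unname(ec)
  }) |> stats::setNames(.af_states)
}

# Expected per-cycle accrual coefficients per origin state.
.cycle_coefs <- function(kernel, costs, utilities, config) {
  bu <- .branch_utilities(kernel$branches, utilities)
  bc <- .branch_costs(kernel$branches, costs, config$charge_fatal_event)
  ucoef <- vapply(.af_states, function(st)
    sum(kernel$branches[[st]]$prob * bu[[st]]), 0)
  annual <- if (!is.na(kernel$strategy)) costs$annual[[kernel$strategy]]
            else costs$annual[[1]]
  ccoef <- vapply(.af_states, function(st) {
    alive <- st != "Death"
    alive * annual + sum(kernel$branches[[st]]$prob * bc[[st]])
  }, 0)
  list(ucoef = ucoef, ccoef = ccoef)
}

#' Run the Markov cohort
#'
#' Propagates the full cohort (initially 100\% event-free) through
#' `config$horizon_cycles` annual cycles and records undiscounted per-cycle
#' cost, QALY and life-year accruals plus expected event incidence.
#'
#' @inheritParams build_cycle_kernel
#' @param kernel an `af_cycle_kernel`.
#' @param costs the `costs` element of the model inputs (annual per strategy
#'   and one-time per event).
#' @param utilities the `utilities` element of the model inputs.
#' @return An object of class `af_cohort_trace`: occupancy matrix
#'   (`horizon + 1` rows including the initial distribution), per-cycle
#'   accrual vectors and an event-incidence matrix.
#' @export
run_cohort <- function(kernel, costs, utilities, config = default_run_config()) {
  T_ <- as.integer(config$horizon_cycles)
  coefs <- .cycle_coefs(kernel, costs, utilities, config)
  occ <- matrix(0, nrow = T_ + 1L, ncol = 4L,
                dimnames = list(0:T_, .af_states))
  occ[1L, "Min"] <- 1
  for (t in seq_len(T_))
    occ[t + 1L, ] <- occ[t, ] %*% kernel$transition
  start <- occ[seq_len(T_), , drop = FALSE]
  weight <- if (isTRUE(config$half_cycle_correction))
    (start + occ[-1L, , drop = FALSE]) / 2 else start
  cost_per_cycle <- as.vector(weight %*% coefs$ccoef)
  qaly_per_cycle <- as.vector(weight %*% coefs$ucoef)
  ly_per_cycle <- rowSums(weight[, c("Min", "Mod", "Sev"), drop = FALSE])
  events_per_cycle <- start %*% kernel$event_incidence
  structure(list(occupancy = occ, cost_per_cycle = cost_per_cycle,
                 qaly_per_cycle = qaly_per_cycle, ly_per_cycle = ly_per_cycle,
                 events_per_cycle = events_per_cycle,
                 strategy = kernel$strategy, config = config),
            class = "af_cohort_trace")
}

#' @describeIn run_cohort flatten a trace to a data frame (one row per
#'   cycle: occupancy, event incidence, undiscounted and discounted
#'   accruals), suitable for CSV export.
#' @param x an `af_cohort_trace`.
#' @param ... ignored.
#' @export
as.data.frame.af_cohort_trace <- function(x, ...) {
  T_ <- length(x$cost_per_cycle)
  dfc <- .discount_factors(T_, x$config$discount_rate,
                           x$config$discount_first_cycle)
  dfe <- .discount_factors(T_, .effect_rate(x$config),
                           x$config$discount_first_cycle)
  occ <- x$occupancy[seq_len(T_), , drop = FALSE]
  colnames(occ) <- paste0("occ_", .af_states)
  ev <- x$events_per_cycle
  colnames(ev) <- paste0("inc_", .af_events)
  data.frame(
    cycle = seq_len(T_), occ, ev,
    cost = x$cost_per_cycle, qaly = x$qaly_per_cycle,
    life_years = x$ly_per_cycle,
    cost_disc = x$cost_per_cycle * dfc, qaly_disc = x$qaly_per_cycle * dfe,
    row.names = NULL
  )
}

.discount_factors <- function(T_, rate, discount_first_cycle) {
  expo <- if (isTRUE(discount_first_cycle)) seq_len(T_) else seq_len(T_) - 1L
  (1 + rate)^(-expo)
}

#' Summarize a cohort trace into discounted totals
#'
#' Applies the discounting convention (cycle t weighted by
#' `(1 + r)^-(t-1)` unless `config$discount_first_cycle`) to per-cycle
#' accruals. Effects use `config$discount_rate_effects` when set, otherwise
#' the common rate. Event totals are undiscounted expected counts.
#'
#' @param trace an `af_cohort_trace`.
#' @param config run configuration (defaults to the trace's own).
#' @return An object of class `af_strategy_outcome` with `total_cost`,
#'   `total_qaly`, `life_years` and `event_totals`.
#' @export
summarize_trace <- function(trace, config = trace$config) {
  T_ <- length(trace$cost_per_cycle)
  dfc <- .discount_factors(T_, config$discount_rate, config$discount_first_cycle)
  dfe <- .discount_factors(T_, .effect_rate(config), config$discount_first_cycle)
  structure(list(
    strategy = trace$strategy,
    total_cost = sum(trace$cost_per_cycle * dfc),
    total_qaly = sum(trace$qaly_per_cycle * dfe),
    life_years = sum(trace$ly_per_cycle * dfe),
    event_totals = colSums(trace$events_per_cycle),
    mc_stderr = NULL
  ), class = "af_strategy_outcome")
}

#' @export
print.af_strategy_outcome <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f, %.4f QALYs, %.4f life-years\n",
              if (is.na(x$strategy)) "strategy" else x$strategy,
              x$total_cost, x$total_qaly, x$life_years))
  if (!is.null(x$mc_stderr))
    cat(sprintf("  MC stderr: cost %.2f, QALY %.5f (n = %d)\n",
                x$mc_stderr[["cost"]], x$mc_stderr[["qaly"]], x$n_patients))
  invisible(x)
}

.kernel_for <- function(inputs, strategy) {
  build_cycle_kernel(inputs$risks[[strategy]], inputs$splits$is,
                     inputs$splits$ich, inputs$fatality$ech,
                     inputs$fatality$mi, inputs$config, strategy = strategy)
}

#' Run one strategy (or all) through the cohort model
#'
#' @param inputs validated `af_model_inputs`.
#' @param strategy a strategy label (see [strategy_names()]).
#' @return `run_strategy`: an `af_strategy_outcome` (the trace is attached as
#'   attribute `"trace"`). `run_base_case`: a named list of outcomes, one per
#'   strategy.
#' @export
run_strategy <- function(inputs, strategy) {
  strategy <- canonical_strategy(strategy)
  kernel <- .kernel_for(inputs, strategy)
  trace <- run_cohort(kernel, inputs$costs, inputs$utilities, inputs$config)
  out <- summarize_trace(trace)
  attr(out, "trace") <- trace
  out
}

#' @rdname run_strategy
#' @export
run_base_case <- function(inputs) {
  .assert_valid(inputs)
  stats::setNames(lapply(.af_strategies, run_strategy, inputs = inputs),
                  .af_strategies)
}

#' Individual-level microsimulation
#'
#' Simulates `n_patients` independent patient trajectories under the same
#' branch decomposition and accrual rules as [run_cohort()]; the cohort model
#' is the exact expectation of this simulation, which makes the pair a
#' two-route consistency check. Reproducible given `seed`.
#'
#' @inheritParams run_cohort
#' @param n_patients number of simulated patients (>= 1).
#' @param seed integer seed.
#' @return An `af_strategy_outcome` whose `mc_stderr` element carries Monte
#'   Carlo standard errors of the cost and QALY means.
#' @export
run_microsim <- function(kernel, costs, utilities,
                         config = default_run_config(), n_patients, seed) {
  stopifnot(n_patients >= 1)
  if (isTRUE(config$half_cycle_correction))
    stop("half-cycle correction is a cohort-level adjustment; ",
         "not supported in the microsimulation", call. = FALSE)
  set.seed(seed)
  T_ <- as.integer(config$horizon_cycles)
  bu <- .branch_utilities(kernel$branches, utilities)
  bc <- .branch_costs(kernel$branches, costs, config$charge_fatal_event)
  annual <- if (!is.na(kernel$strategy)) costs$annual[[kernel$strategy]]
            else costs$annual[[1]]
  tabs <- lapply(.af_states, function(st) {
    br <- kernel$branches[[st]]
    list(cum = cumsum(br$prob), to = match(br$to, .af_states),
         util = bu[[st]], ecost = bc[[st]],
         event = match(br$event, .af_events))
  })
  dfc <- .discount_factors(T_, config$discount_rate, config$discount_first_cycle)
  dfe <- .discount_factors(T_, .effect_rate(config), config$discount_first_cycle)

  state <- rep(1L, n_patients)
  cost_i <- numeric(n_patients)
  qaly_i <- numeric(n_patients)
  ly_i <- numeric(n_patients)
  ev_tot <- stats::setNames(numeric(4), .af_events)
  for (t in seq_len(T_)) {
    alive_states <- which(tabulate(state, 4L)[1:3] > 0)
    if (!length(alive_states)) break
    new_state <- state
    for (s in alive_states) {
      idx <- which(state == s)
      tab <- tabs[[s]]
      k <- findInterval(stats::runif(length(idx)), tab$cum,
                        rightmost.closed = TRUE) + 1L
      k[k > length(tab$cum)] <- length(tab$cum)
      cost_i[idx] <- cost_i[idx] + (annual + tab$ecost[k]) * dfc[t]
      qaly_i[idx] <- qaly_i[idx] + tab$util[k] * dfe[t]
      ly_i[idx] <- ly_i[idx] + dfe[t]
      ev <- tab$event[k]
      if (any(!is.na(ev)))
        ev_tot <- ev_tot + tabulate(ev[!is.na(ev)], 4L)
      new_state[idx] <- tab$to[k]
    }
    state <- new_state
  }
  structure(list(
    strategy = kernel$strategy,
    total_cost = mean(cost_i),
    total_qaly = mean(qaly_i),
    life_years = mean(ly_i),
    event_totals = ev_tot / n_patients,
    mc_stderr = c(cost = stats::sd(cost_i) / sqrt(n_patients),
                  qaly = stats::sd(qaly_i) / sqrt(n_patients)),
    n_patients = as.integer(n_patients)
  ), class = "af_strategy_outcome")
}
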