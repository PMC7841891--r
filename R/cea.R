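# Incremental cost-effectiveness analysis: pairwise ICERs with dominance
# flags, strict/extended dominance frontier, net monetary benefit and the
# willingness-to-pay decision rule.

.outcome_cq <- function(x) {
  if (inherits(x, "af_strategy_outcome") ||
      (is.list(x) && !is.null(x$total_cost)))
    c(cost = x$total_cost, qaly = x$total_qaly)
  else stop("expected a strategy outcome with total_cost and total_qaly",
            call. = FALSE)
}

#' Incremental cost-effectiveness ratio of two strategies
#'
#' Computes `(cost_ref - cost_comp) / (qaly_ref - qaly_comp)`. Degenerate
#' cases never divide: when the reference is cheaper and more effective the
#' status is `"dominant"`, costlier and less effective `"dominated"`, and
#' exact ties in QALYs (or in both dimensions) yield `"dominated"` /
#' `"dominant"` / `"indifferent"` flags.
#'
#' @param reference,comparator strategy outcomes (anything with `total_cost`
#'   and `total_qaly`, e.g. from [run_strategy()]).
#' @param tol absolute tolerance for treating a difference as zero.
#' @return An object of class `af_icer`: list with `delta_cost`,
#'   `delta_qaly`, `value` (`NA` when flagged) and `status` (`"icer"`,
#'   `"dominant"`, `"dominated"` or `"indifferent"`).
#' @examples
#' icer(list(total_cost = 29673.33, total_qaly = 15.46),
#'      list(total_cost = 5317.31,  total_qaly = 11.07))
#' @export
icer <- function(reference, comparator, tol = 1e-9) {
  a <- .outcome_cq(reference); b <- .outcome_cq(comparator)
  dc <- a[["cost"]] - b[["cost"]]
  dq <- a[["qaly"]] - b[["qaly"]]
  zc <- abs(dc) <= tol; zq <- abs(dq) <= tol
  status <- if (zc && zq) "indifferent"
    else if (zq) if (dc > 0) "dominated" else "dominant"
    else if (dc < -tol && dq > tol) "dominant"
    else if (dc > tol && dq < -tol) "dominated"
    else "icer"
  structure(list(delta_cost = dc, delta_qaly = dq,
                 value = if (status == "icer") dc / dq else NA_real_,
                 status = status),
            class = "af_icer")
}

#' @export
print.af_icer <- function(x, ...) {
  if (x$status == "icer")
    cat(sprintf("ICER: %.2f $/QALY (dCost %.2f, dQALY %.4f)\n",
                x$value, x$delta_cost, x$delta_qaly))
  else cat("ICER:", x$status, sprintf("(dCost %.2f, dQALY %.4f)\n",
                                      x$delta_cost, x$delta_qaly))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * total_qaly - total_cost`; the strategy maximizing it is optimal at
#' the willingness-to-pay threshold `wtp`.
#'
#' @param outcome a strategy outcome.
#' @param wtp willingness to pay, $ per QALY (>= 0).
#' @return Numeric, $.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  cq <- .outcome_cq(outcome)
  wtp * cq[["qaly"]] - cq[["cost"]]
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Maximizes net monetary benefit; ties are broken by lower cost, then by
#' the order the outcomes are supplied in.
#'
#' @param outcomes named list of strategy outcomes.
#' @param wtp willingness to pay, $ per QALY.
#' @return The winning strategy's name.
#' @export
optimal_strategy <- function(outcomes, wtp) {
  stopifnot(length(outcomes) >= 1)
  nmb <- vapply(outcomes, net_monetary_benefit, 0, wtp = wtp)
  cost <- vapply(outcomes, function(o) .outcome_cq(o)[["cost"]], 0)
  best <- which(nmb > max(nmb) - 1e-9)
  best <- best[order(cost[best])]
  names(outcomes)[best[1]]
}

# strict dominance: some other point has cost <= and qaly >= with at least
# one strict inequality (exact ties excluded: those are "indifferent")
.strictly_dominated <- function(cost, qaly, tol = 1e-9) {
  n <- length(cost)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (j == i) return(FALSE)
      tie <- abs(cost[j] - cost[i]) <= tol && abs(qaly[j] - qaly[i]) <= tol
      !tie && cost[j] <= cost[i] + tol && qaly[j] >= qaly[i] - tol
    }, logical(1)))
  }, logical(1))
}

#' Incremental analysis over a set of strategies
#'
#' Orders strategies by total cost, removes strictly dominated strategies
#' (costlier and no more effective than another), iteratively removes
#' extendedly dominated ones (the frontier's consecutive ICERs must be
#' strictly increasing), and reports — as published cost-effectiveness
#' tables do — pairwise increments versus a fixed comparator for every
#' strategy alongside the frontier status and frontier ICERs. The
#' recommended strategy maximizes net monetary benefit at `wtp`.
#'
#' @param outcomes named list of strategy outcomes (>= 2, unique names).
#' @param comparator name of the comparator strategy (default the cheapest).
#' @param wtp willingness to pay, $ per QALY.
#' @return A data frame of class `af_cea_table` with one row per strategy:
#'   totals, increments vs the comparator (`delta_cost`, `delta_qaly`,
#'   `icer_vs_comparator`, `flag_vs_comparator`), `status` (`on_frontier`,
#'   `strictly_dominated`, `extendedly_dominated` or `indifferent`),
#'   `frontier_icer` (vs the previous frontier strategy) and `nmb`.
#'   Attributes `comparator`, `wtp`, `recommended`.
#' @export
incremental_analysis <- function(outcomes, comparator = NULL, wtp) {
  nms <- names(outcomes)
  if (is.null(nms) || anyDuplicated(nms))
    stop("outcomes must be a named list with unique strategy labels",
         call. = FALSE)
  stopifnot(length(outcomes) >= 2)
  cost <- vapply(outcomes, function(o) .outcome_cq(o)[["cost"]], 0)
  qaly <- vapply(outcomes, function(o) .outcome_cq(o)[["qaly"]], 0)
  if (is.null(comparator)) comparator <- nms[which.min(cost)]
  comparator <- canonical_match(comparator, nms)

  ord <- order(cost, -qaly)
  status <- stats::setNames(rep("on_frontier", length(nms)), nms)

  # exact-tie handling: later duplicates are indifferent, not dominated
  key <- paste(signif(cost, 12), signif(qaly, 12))
  dup <- duplicated(key)
  status[dup] <- "indifferent"
  cand <- !dup
  status[cand & .strictly_dominated(cost, qaly)] <- "strictly_dominated"

  repeat {
    fr <- nms[status == "on_frontier"]
    fr <- fr[order(cost[fr], -qaly[fr])]
    if (length(fr) < 3) break
    ic <- diff(cost[fr]) / diff(qaly[fr])
    viol <- which(diff(ic) <= 0)
    if (!length(viol)) break
    status[fr[viol[1] + 1L]] <- "extendedly_dominated"
  }
  fr <- nms[status == "on_frontier"]
  fr <- fr[order(cost[fr], -qaly[fr])]
  frontier_icer <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (length(fr) > 1)
    frontier_icer[fr[-1]] <- diff(cost[fr]) / diff(qaly[fr])

  pair <- lapply(nms, function(s)
    if (s == comparator) NULL else icer(outcomes[[s]], outcomes[[comparator]]))
  names(pair) <- nms
  nmb <- vapply(outcomes, net_monetary_benefit, 0, wtp = wtp)

  tab <- data.frame(
    strategy = nms[ord],
    total_cost = cost[ord],
    total_qaly = qaly[ord],
    delta_cost = vapply(nms, function(s)
      if (s == comparator) NA_real_ else pair[[s]]$delta_cost, 0)[ord],
    delta_qaly = vapply(nms, function(s)
      if (s == comparator) NA_real_ else pair[[s]]$delta_qaly, 0)[ord],
    icer_vs_comparator = vapply(nms, function(s)
      if (s == comparator) NA_real_ else pair[[s]]$value, 0)[ord],
    flag_vs_comparator = vapply(nms, function(s)
      if (s == comparator) "comparator" else pair[[s]]$status, "")[ord],
    status = status[ord],
    frontier_icer = frontier_icer[ord],
    nmb = nmb[ord],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(tab, class = c("af_cea_table", "data.frame"),
            comparator = comparator, wtp = wtp,
            recommended = optimal_strategy(outcomes, wtp))
}

# match a possibly-aliased strategy label against the available names
canonical_match <- function(label, available) {
  hit <- tryCatch(canonical_strategy(label), error = function(e) label)
  if (!hit %in% available)
    stop("comparator '", label, "' not among the supplied strategies",
         call. = FALSE)
  hit
}

#' @export
print.af_cea_table <- function(x, ...) {
  cat("Cost-effectiveness comparison (comparator:", attr(x, "comparator"),
      "| WTP", sprintf("%.2f", attr(x, "wtp")), "$/QALY)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = 2)
  print(y, row.names = FALSE)
  cat("Recommended at WTP:", attr(x, "recommended"), "\n")
  invisible(x)
}

#' Frontier of a CEA table
#'
#' @param table an `af_cea_table`.
#' @return Character vector of on-frontier strategies, cheapest first.
#' @export
frontier_strategies <- function(table) {
  fr <- table$strategy[table$status == "on_frontier"]
  fr[order(table$total_cost[match(fr, table$strategy)])]
}
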