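# One-way (tornado) and probabilistic sensitivity analysis.
#
# PSA distributions follow the standard second-order convention:
# probabilities, severity fractions and utilities are beta-distributed,
# costs log-normal, each fitted by the method of moments with mean equal to
# the base-case value and sd derived from the plausible range (read as a
# 95% interval by default, so sd = width / 3.92).

.param_family <- function(id) {
  if (startsWith(id, "costs.")) "lognormal" else "beta"
}

#' Fit a second-order parameter distribution from a plausible range
#'
#' Method-of-moments fit with mean = `base` and sd = `(high - low) / 3.92`
#' (the range read as a 95\% interval; with
#' `interpretation = "support"`, sd = width / sqrt(12), a uniform over the
#' range). Beta: `k = m(1-m)/v - 1`, `shape1 = m k`, `shape2 = (1-m) k`.
#' Log-normal: `sdlog^2 = log(1 + v/m^2)`, `meanlog = log(m) - sdlog^2/2`.
#' A degenerate range (`low == high`) yields the `fixed` family.
#'
#' @param range list or vector with `base`, `low`, `high` (low <= base <= high).
#' @param family `"beta"`, `"lognormal"` or `"fixed"`.
#' @param interpretation `"ci95"` (default) or `"support"`.
#' @return List of class `af_psa_dist`: `family`, `base`, `mean`, `sd` and
#'   the family's shape parameters.
#' @examples
#' fit_psa_distribution(list(base = 0.5, low = 0.5 - 1.96 * 0.1,
#'                           high = 0.5 + 1.96 * 0.1), "beta")  # shape1 = shape2 = 12
#' @export
fit_psa_distribution <- function(range, family = c("beta", "lognormal", "fixed"),
                                 interpretation = c("ci95", "support")) {
  family <- match.arg(family)
  interpretation <- match.arg(interpretation)
  base <- range[["base"]]; low <- range[["low"]]; high <- range[["high"]]
  stopifnot(low <= base, base <= high)
  if (low == high || family == "fixed")
    return(structure(list(family = "fixed", base = base, mean = base, sd = 0),
                     class = "af_psa_dist"))
  sdv <- (high - low) / if (interpretation == "ci95") 3.92 else sqrt(12)
  v <- sdv^2
  if (family == "beta") {
    if (base <= 0 || base >= 1)
      stop("beta fit needs base in (0, 1), got ", base, call. = FALSE)
    if (v >= base * (1 - base))
      stop("variance infeasible for beta (v >= m(1-m))", call. = FALSE)
    k <- base * (1 - base) / v - 1
    structure(list(family = "beta", base = base, mean = base, sd = sdv,
                   shape1 = base * k, shape2 = (1 - base) * k),
              class = "af_psa_dist")
  } else {
    if (base <= 0) stop("log-normal fit needs a positive mean", call. = FALSE)
    s2 <- log(1 + v / base^2)
    structure(list(family = "lognormal", base = base, mean = base, sd = sdv,
                   meanlog = log(base) - s2 / 2, sdlog = sqrt(s2)),
              class = "af_psa_dist")
  }
}

#' @describeIn fit_psa_distribution draw `n` variates from a fitted
#'   distribution.
#' @param dist an `af_psa_dist`.
#' @param n number of draws.
#' @export
draw_psa_distribution <- function(dist, n) {
  switch(dist$family,
    fixed = rep(dist$base, n),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog)
  )
}

# fitted distribution for every non-degenerate parameter
.psa_dists <- function(inputs) {
  interp <- inputs$config$range_interpretation
  ids <- names(inputs$ranges)
  dists <- lapply(ids, function(id) {
    rg <- inputs$ranges[[id]]
    fit_psa_distribution(list(base = param_get(inputs, id),
                              low = rg[["low"]], high = rg[["high"]]),
                         family = if (rg[["low"]] == rg[["high"]]) "fixed"
                                  else .param_family(id),
                         interpretation = interp)
  })
  stats::setNames(dists, ids)
}

#' Matrix of raw PSA parameter draws
#'
#' One row per draw, one column per model parameter; fixed (degenerate-range)
#' parameters are constant at their base value. This is the raw sample before
#' severity-split renormalization.
#'
#' @param inputs validated `af_model_inputs`.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return Numeric matrix `n_draws x n_parameters` with parameter ids as
#'   column names; fitted distributions attached as attribute `"dists"`.
#' @export
sample_parameter_draws <- function(inputs, n_draws, seed) {
  stopifnot(n_draws >= 1)
  dists <- .psa_dists(inputs)
  set.seed(seed)
  m <- vapply(dists, draw_psa_distribution, numeric(n_draws), n = n_draws)
  if (n_draws == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(dists)))
  attr(m, "dists") <- dists
  m
}

# after perturbing parameters, stretch each plausible range to cover the
# realized value so the low <= base <= high invariant keeps holding
.widen_ranges <- function(inputs) {
  for (id in names(inputs$ranges)) {
    base <- param_get(inputs, id)
    rg <- inputs$ranges[[id]]
    inputs$ranges[[id]] <- c(low = min(rg[["low"]], base),
                             high = max(rg[["high"]], base))
  }
  inputs
}

# apply one draw (row of the matrix) to the inputs, renormalizing severity
# splits so they keep summing to 1
.materialize_draw <- function(inputs, draw) {
  for (id in names(draw)) inputs <- param_set(inputs, id, draw[[id]])
  for (ev in c("is", "ich"))
    inputs$splits[[ev]] <- inputs$splits[[ev]] / sum(inputs$splits[[ev]])
  # utilities may cross after independent draws; restore the ordering
  u <- sort(c(inputs$utilities$u_min, inputs$utilities$u_mod,
              inputs$utilities$u_sev), decreasing = TRUE)
  inputs$utilities[c("u_min", "u_mod", "u_sev")] <- as.list(u)
  .widen_ranges(inputs)
}

#' Sample complete parameter sets for probabilistic sensitivity analysis
#'
#' Draws every parameter with a non-degenerate range independently from its
#' fitted distribution ([fit_psa_distribution()]), renormalizes severity
#' splits to sum to 1, restores the utility ordering, and validates each
#' set. An invalid draw is resampled (at most 100 attempts before erroring).
#'
#' @inheritParams sample_parameter_draws
#' @return List of `n_draws` validated `af_model_inputs` objects.
#' @export
sample_psa <- function(inputs, n_draws = inputs$config$psa_draws,
                       seed = inputs$config$seed) {
  m <- sample_parameter_draws(inputs, n_draws, seed)
  dists <- attr(m, "dists")
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    draw <- m[i, ]
    for (attempt in seq_len(100L)) {
      cand <- .materialize_draw(inputs, draw)
      if (is_valid(cand)) break
      if (attempt == 100L)
        stop("could not obtain a valid parameter draw after 100 attempts",
             call. = FALSE)
      draw <- vapply(dists, draw_psa_distribution, numeric(1), n = 1)
    }
    out[[i]] <- cand
  }
  attr(out, "seed") <- seed
  out
}

#' Run the cohort model over PSA parameter draws
#'
#' Second-order uncertainty only: the deterministic cohort engine is run
#' once per sampled parameter set per strategy (no patient-level noise).
#'
#' @param samples list of `af_model_inputs`, e.g. from [sample_psa()].
#' @param config run configuration applied to every draw (defaults to the
#'   first sample's).
#' @return Object of class `af_psa`: matrices `cost` and `qaly`
#'   (`n_draws x n_strategies`), the strategy names, draw count and seed.
#' @export
run_psa <- function(samples, config = NULL) {
  stopifnot(length(samples) >= 1)
  n <- length(samples)
  cost <- matrix(NA_real_, n, length(.af_strategies),
                 dimnames = list(NULL, .af_strategies))
  qaly <- cost
  for (i in seq_len(n)) {
    inp <- samples[[i]]
    if (!is.null(config)) inp$config <- config
    for (s in .af_strategies) {
      o <- run_strategy(inp, s)
      cost[i, s] <- o$total_cost
      qaly[i, s] <- o$total_qaly
    }
  }
  structure(list(cost = cost, qaly = qaly, strategies = .af_strategies,
                 n_draws = n, seed = attr(samples, "seed")),
            class = "af_psa")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' each strategy attains the maximal net monetary benefit; exact ties are
#' split equally so each row sums to 1.
#'
#' @param psa an `af_psa` object.
#' @param wtp_grid ascending vector of WTP values ($/QALY).
#' @return Data frame of class `af_ceac`: `wtp` plus one probability column
#'   per strategy.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1, !is.unsorted(wtp_grid))
  res <- matrix(0, length(wtp_grid), length(psa$strategies),
                dimnames = list(NULL, psa$strategies))
  for (g in seq_along(wtp_grid)) {
    nmb <- wtp_grid[g] * psa$qaly - psa$cost
    mx <- apply(nmb, 1, max)
    win <- nmb >= mx - 1e-9
    res[g, ] <- colMeans(win / rowSums(win))
  }
  structure(data.frame(wtp = wtp_grid, res), class = c("af_ceac", "data.frame"))
}

#' Incremental cost-effectiveness plane scatter with covariance ellipse
#'
#' Per-draw (dQALY, dCost) pairs of `reference` vs `comparator`, with the
#' mean-centered normal-theory ellipse at the chi-square(2) quantile of the
#' requested coverage.
#'
#' @param psa an `af_psa` object.
#' @param reference,comparator strategy labels.
#' @param coverage ellipse coverage probability in (0, 1), default 0.95.
#' @return List of class `af_ice`: `points` (data frame `dqaly`, `dcost`),
#'   `center`, `cov`, `radius2` (chi-square quantile), `ellipse` (polygon of
#'   the ellipse boundary) and `coverage`.
#' @export
ice_scatter <- function(psa, reference = "rivaroxaban",
                        comparator = "warfarin", coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  reference <- canonical_strategy(reference)
  comparator <- canonical_strategy(comparator)
  if (psa$n_draws < 3)
    stop("need at least 3 draws for a covariance ellipse", call. = FALSE)
  dq <- psa$qaly[, reference] - psa$qaly[, comparator]
  dc <- psa$cost[, reference] - psa$cost[, comparator]
  pts <- data.frame(dqaly = dq, dcost = dc)
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  r2 <- stats::qchisq(coverage, df = 2)
  eig <- eigen(S, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = 181)
  circ <- rbind(cos(theta), sin(theta))
  axes <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0) * r2), 2)
  ell <- t(axes %*% circ + ctr)
  structure(list(points = pts, center = ctr, cov = S, radius2 = r2,
                 ellipse = data.frame(dqaly = ell[, 1], dcost = ell[, 2]),
                 coverage = coverage,
                 reference = reference, comparator = comparator),
            class = "af_ice")
}

# re-run the model with one parameter pinned; severity-split components are
# compensated by scaling the other three fractions so the split stays
# normalized
.run_pair_at <- function(inputs, id, value, reference, comparator) {
  inputs <- param_set(inputs, id, value)
  if (startsWith(id, "splits.")) {
    ev <- strsplit(id, ".", fixed = TRUE)[[1]][2]
    comp <- strsplit(id, ".", fixed = TRUE)[[1]][3]
    sp <- inputs$splits[[ev]]
    others <- setdiff(.af_split_fields, comp)
    rest <- sum(sp[others])
    if (rest > 0) sp[others] <- sp[others] * (1 - sp[[comp]]) / rest
    inputs$splits[[ev]] <- sp
  }
  inputs <- .widen_ranges(inputs)
  .assert_valid(inputs)
  icer(run_strategy(inputs, reference), run_strategy(inputs, comparator))
}

#' One-way (tornado) sensitivity analysis
#'
#' For each parameter, re-runs the full cohort model with that parameter at
#' its lower and upper plausible bound (everything else at base) and records
#' the reference-vs-comparator ICER. When a severity-split fraction is
#' varied, the remaining three fractions are rescaled proportionally so the
#' split keeps summing to 1. Entries are sorted by decreasing ICER swing.
#'
#' @param inputs validated `af_model_inputs`.
#' @param parameters parameter ids (see [list_parameters()]); default: every
#'   parameter with a non-degenerate range.
#' @param reference,comparator the strategy pair whose ICER is tracked.
#' @return Data frame of class `af_tornado`: `parameter`, `low`, `high`,
#'   `base_icer`, `icer_at_low`, `icer_at_high` (NA when the case is
#'   dominance-flagged, with the flag in `flag_low` / `flag_high`),
#'   `swing`, and `degenerate`.
#' @export
one_way_sensitivity <- function(inputs, parameters = NULL,
                                reference = "rivaroxaban",
                                comparator = "warfarin") {
  .assert_valid(inputs)
  reference <- canonical_strategy(reference)
  comparator <- canonical_strategy(comparator)
  if (reference == comparator)
    stop("reference and comparator must differ", call. = FALSE)
  if (is.null(parameters)) {
    w <- vapply(inputs$ranges, function(r) r[["low"]] < r[["high"]], logical(1))
    parameters <- names(inputs$ranges)[w]
  }
  unknown <- setdiff(parameters, list_parameters(inputs))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "\navailable: ", paste(list_parameters(inputs), collapse = ", "),
         call. = FALSE)
  base <- icer(run_strategy(inputs, reference), run_strategy(inputs, comparator))
  rows <- lapply(parameters, function(id) {
    rg <- inputs$ranges[[id]]
    if (rg[["low"]] == rg[["high"]])
      return(data.frame(parameter = id, low = rg[["low"]], high = rg[["high"]],
                        base_icer = base$value, icer_at_low = base$value,
                        icer_at_high = base$value, flag_low = base$status,
                        flag_high = base$status, swing = 0, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    lo <- .run_pair_at(inputs, id, rg[["low"]], reference, comparator)
    hi <- .run_pair_at(inputs, id, rg[["high"]], reference, comparator)
    swing <- if (lo$status == "icer" && hi$status == "icer")
      abs(hi$value - lo$value) else Inf
    data.frame(parameter = id, low = rg[["low"]], high = rg[["high"]],
               base_icer = base$value, icer_at_low = lo$value,
               icer_at_high = hi$value, flag_low = lo$status,
               flag_high = hi$status, swing = swing, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("af_tornado", "data.frame"),
            reference = reference, comparator = comparator)
}
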