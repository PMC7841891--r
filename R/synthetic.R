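# Synthetic parameter sets and analytically solvable toy models.
#
# The generator emulates the statistical structure of a literature-derived
# input table: small annual event probabilities, severity fractions summing
# to one, ordered health-state utilities, positive log-normal-scale costs,
# and a plausible range around every value. The two-state model (alive /
# dead, constant hazard) has a closed-form solution used as an independent
# oracle for the engine.

#' Generate a randomized valid parameter set
#'
#' Starts from the base case and perturbs every parameter multiplicatively
#' (log-normal with relative scale `jitter`), truncating into its legal
#' domain: event probabilities into (0, 0.2), severity splits renormalized
#' to sum to 1, state utilities re-ordered so u_min >= u_mod >= u_sev,
#' costs kept positive. Plausible ranges are regenerated around the new
#' base values. `jitter = 0` returns exactly the base case.
#'
#' @param seed integer seed.
#' @param jitter relative perturbation scale (>= 0); default 0.10.
#' @param config optional run configuration.
#' @return A validated `af_model_inputs`.
#' @export
generate_inputs <- function(seed, jitter = 0.10,
                            config = default_run_config()) {
  stopifnot(jitter >= 0)
  inputs <- base_case_inputs(config)
  if (jitter == 0) return(inputs)
  set.seed(seed)
  shake <- function(x) x * exp(stats::rnorm(length(x), sd = jitter))
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  for (s in .af_strategies) {
    r <- clip(shake(inputs$risks[[s]]), 1e-6, 0.2)
    if (sum(r) >= 0.999) r <- r * 0.9 / sum(r)  # keep a stay-well margin
    inputs$risks[[s]] <- r
  }
  for (ev in c("is", "ich")) {
    sp <- clip(shake(inputs$splits[[ev]]), 1e-6, 1)
    inputs$splits[[ev]] <- sp / sum(sp)
  }
  inputs$fatality <- lapply(inputs$fatality, function(f) clip(shake(f), 1e-6, 1))
  inputs$costs$annual <- shake(inputs$costs$annual)
  inputs$costs$event <- shake(inputs$costs$event)
  u <- sort(clip(shake(unlist(inputs$utilities[c("u_min", "u_mod", "u_sev")])),
                 1e-3, 0.999), decreasing = TRUE)
  inputs$utilities[c("u_min", "u_mod", "u_sev")] <- as.list(unname(u))
  for (f in c("m_ich", "m_ech", "m_mi"))
    inputs$utilities[[f]] <- clip(shake(inputs$utilities[[f]]), 1e-3, 1)

  # fresh plausible ranges around the perturbed bases
  for (id in names(inputs$ranges)) {
    base <- param_get(inputs, id)
    hw <- 1.96 * jitter * base
    dom_hi <- if (startsWith(id, "costs.")) Inf else 1
    inputs$ranges[[id]] <- c(low = max(base - hw, 0),
                             high = min(base + hw, dom_hi))
  }
  .assert_valid(inputs)
  inputs
}

#' Two-state (alive/dead) degenerate model inputs
#'
#' All clinical event probabilities zero, the same all-cause mortality
#' `p_death` for every strategy, a single utility `u` for every alive state,
#' annual treatment cost `c` and zero event costs. The engine run on these
#' inputs has the closed form [closed_form_two_state()].
#'
#' @param p_death annual mortality probability in \[0, 1\].
#' @param u annual utility of being alive.
#' @param cost annual treatment cost, $.
#' @param config optional run configuration.
#' @return A validated `af_model_inputs`.
#' @export
two_state_inputs <- function(p_death, u = 0.76, cost = 1000,
                             config = default_run_config()) {
  stopifnot(p_death >= 0, p_death <= 1)
  inputs <- base_case_inputs(config)
  for (s in .af_strategies)
    inputs$risks[[s]] <- c(p_is = 0, p_ich = 0, p_ech = 0, p_mi = 0,
                           p_death = p_death)
  inputs$costs$annual[] <- cost
  inputs$costs$event[] <- 0
  inputs$utilities[c("u_min", "u_mod", "u_sev")] <- list(u, u, u)
  inputs$utilities[c("m_ich", "m_ech", "m_mi")] <- list(1, 1, 1)
  for (id in names(inputs$ranges)) {
    base <- param_get(inputs, id)
    inputs$ranges[[id]] <- c(low = base, high = base)
  }
  .assert_valid(inputs)
  inputs
}

#' Closed-form totals of the two-state model
#'
#' With constant annual mortality `p_death`, utility `u` and annual cost
#' `cost`, the expected discounted totals over `T` cycles are
#' `sum_{t=1..T} (1 - p_death)^(t-1) * (1 + r)^-(t-1)` times `cost` and `u`
#' respectively (first cycle undiscounted; set
#' `discount_first_cycle = TRUE` for exponents `t`). This is the exact
#' expectation of the engine's accrual rules on [two_state_inputs()].
#'
#' @param p_death annual mortality probability.
#' @param u annual utility.
#' @param cost annual cost, $.
#' @param r discount rate (applied to both costs and effects).
#' @param T_ number of annual cycles (>= 1).
#' @param discount_first_cycle logical, default `FALSE`.
#' @return Named vector `c(cost = , qaly = )`.
#' @export
closed_form_two_state <- function(p_death, u, cost, r, T_,
                                  discount_first_cycle = FALSE) {
  stopifnot(p_death >= 0, p_death <= 1, r >= 0, T_ >= 1)
  t <- seq_len(T_)
  expo <- if (discount_first_cycle) t else t - 1L
  s <- sum((1 - p_death)^(t - 1) * (1 + r)^(-expo))
  c(cost = cost * s, qaly = u * s)
}
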