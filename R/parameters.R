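# Model parameter set: per-strategy event risks, event-outcome severity
# splits, costs, utilities, plausible ranges and run configuration.

.af_strategies <- c("warfarin", "rivaroxaban", "dabigatran110", "dabigatran150")
.af_events <- c("IS", "ICH", "ECH", "MI")
.af_states <- c("Min", "Mod", "Sev", "Death")
.af_risk_fields <- c("p_is", "p_ich", "p_ech", "p_mi", "p_death")
.af_split_fields <- c("light", "moderate", "severe", "die")
.af_utility_fields <- c("u_min", "u_mod", "u_sev", "m_ich", "m_ech", "m_mi")

#' Strategy labels understood by the model
#'
#' @return Character vector of the four canonical strategy identifiers.
#' @export
strategy_names <- function() .af_strategies

#' Canonicalize a strategy label
#'
#' Labels are matched case-insensitively and ignoring spaces, hyphens and a
#' trailing "mg" (so `"Dabigatran 150 mg"` maps to `"dabigatran150"`).
#'
#' @param x character vector of labels.
#' @return Canonical labels; errors on anything unrecognized.
#' @export
canonical_strategy <- function(x) {
  key <- gsub("mg$", "", gsub("[^a-z0-9]", "", tolower(as.character(x))))
  tab <- gsub("mg$", "", gsub("[^a-z0-9]", "", .af_strategies))
  idx <- match(key, tab)
  if (anyNA(idx)) {
    stop("unknown strategy label(s): ", paste(x[is.na(idx)], collapse = ", "),
         "; expected one of ", paste(.af_strategies, collapse = ", "),
         call. = FALSE)
  }
  .af_strategies[idx]
}

#' Default run configuration
#'
#' @param ... named overrides of any configuration field.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{horizon_cycles}{30 annual cycles.}
#'   \item{discount_rate}{0.03 per year, applied to costs (and to effects
#'     unless `discount_rate_effects` is set).}
#'   \item{discount_rate_effects}{`NULL` (use `discount_rate`); set to 0 to
#'     leave QALYs and life-years undiscounted.}
#'   \item{wtp}{willingness-to-pay threshold, 3 x 9481.88 = 28445.64 $/QALY
#'     (three times 2018 China GDP per capita).}
#'   \item{discount_first_cycle}{`FALSE`: cycle 1 is undiscounted, cycle t
#'     gets factor (1+r)^-(t-1).}
#'   \item{events_from_moderate}{`FALSE`: the moderate-disability state faces
#'     only all-cause mortality, mirroring the severe state's rule.}
#'   \item{half_cycle_correction}{`FALSE`: no mid-cycle occupancy averaging.}
#'   \item{charge_fatal_event}{`TRUE`: the acute event cost is charged even
#'     when the event is fatal.}
#'   \item{range_interpretation}{`"ci95"`: plausible ranges are read as 95\%
#'     intervals (sd = width/3.92) when fitting PSA distributions;
#'     `"support"` reads them as near-full support (sd = width/sqrt(12)).}
#'   \item{psa_draws}{1000 second-order Monte Carlo draws.}
#'   \item{seed}{1, the default random seed recorded in run metadata.}
#' }
#' @return A list of class `af_run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    horizon_cycles = 30L,
    discount_rate = 0.03,
    discount_rate_effects = NULL,
    wtp = 3 * 9481.88,
    discount_first_cycle = FALSE,
    events_from_moderate = FALSE,
    half_cycle_correction = FALSE,
    charge_fatal_event = TRUE,
    range_interpretation = "ci95",
    psa_draws = 1000L,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown run config field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "af_run_config")
}

# effect discount rate, falling back to the common rate
.effect_rate <- function(config) {
  if (is.null(config$discount_rate_effects)) config$discount_rate
  else config$discount_rate_effects
}

#' Base-case model inputs
#'
#' The full published base-case parameter set: annual event probabilities per
#' strategy, event-outcome severity splits, annual treatment and one-time
#' event costs (US $), health-state utilities, and the plausible range of
#' every parameter that has one (parameters without a published range carry a
#' degenerate range `low = base = high` and are held fixed in sensitivity
#' analyses).
#'
#' @param config optional run configuration (see [default_run_config()]).
#' @return An object of class `af_model_inputs`.
#' @examples
#' inp <- base_case_inputs()
#' inp$risks$warfarin[["p_is"]]     # 0.04
#' inp$utilities$u_sev              # 0.16
#' inp$costs$event[["MI"]]          # 3875.18
#' @export
base_case_inputs <- function(config = default_run_config()) {
  risks <- list(
    warfarin      = c(p_is = 0.0400, p_ich = 0.01210, p_ech = 0.0270,
                      p_mi = 0.0098, p_death = 0.0260),
    rivaroxaban   = c(p_is = 0.0193, p_ich = 0.00257, p_ech = 0.0300,
                      p_mi = 0.0098, p_death = 0.0164),
    dabigatran110 = c(p_is = 0.0183, p_ich = 0.00359, p_ech = 0.0070,
                      p_mi = 0.0072, p_death = 0.0333),
    dabigatran150 = c(p_is = 0.0137, p_ich = 0.00270, p_ech = 0.0217,
                      p_mi = 0.0074, p_death = 0.0219)
  )
  splits <- list(
    is  = c(light = 0.091, moderate = 0.425, severe = 0.402, die = 0.082),
    ich = c(light = 0.120, moderate = 0.270, severe = 0.430, die = 0.180)
  )
  fatality <- list(ech = 0.0147, mi = 0.166)
  costs <- list(
    annual = c(warfarin = 253.30, rivaroxaban = 1787.00,
               dabigatran110 = 1718.21, dabigatran150 = 2206.93),
    event = c(IS = 1351.20, ICH = 2605.43, ECH = 1216.72, MI = 3875.18)
  )
  utilities <- list(u_min = 0.76, u_mod = 0.39, u_sev = 0.16,
                    m_ich = 0.80, m_ech = 0.80, m_mi = 0.84)

  ranged <- list(
    "risks.warfarin.p_is"         = c(0.0230, 0.0453),
    "risks.warfarin.p_ich"        = c(0.0057, 0.0294),
    "risks.warfarin.p_death"      = c(0.0258, 0.0261),
    "risks.rivaroxaban.p_ich"     = c(0.0021, 0.0033),
    "risks.dabigatran110.p_is"    = c(0.0167, 0.0189),
    "risks.dabigatran110.p_ich"   = c(0.0028, 0.0039),
    "splits.is.light"             = c(0.091, 0.133),
    "splits.is.moderate"          = c(0.348, 0.425),
    "splits.is.severe"            = c(0.402, 0.417),
    "splits.is.die"               = c(0.082, 0.101),
    "fatality.ech"                = c(0.010, 0.040),
    "fatality.mi"                 = c(0.158, 0.174),
    "costs.annual.warfarin"       = c(239.70, 280.51),
    "costs.annual.rivaroxaban"    = c(1435.86, 2844.52),
    "costs.annual.dabigatran110"  = c(1711.17, 2206.93),
    "costs.annual.dabigatran150"  = c(1711.17, 2206.93),
    "costs.event.IS"              = c(851.36, 2681.69),
    "costs.event.ICH"             = c(1935.86, 3862.05),
    "costs.event.ECH"             = c(867.23, 2516.68),
    "costs.event.MI"              = c(1805.02, 5529.89),
    "utilities.u_min"             = c(0.70, 0.90),
    "utilities.u_mod"             = c(0.10, 0.50),
    "utilities.u_sev"             = c(0.00, 0.32),
    "utilities.m_ich"             = c(0.79, 0.84),
    "utilities.m_ech"             = c(0.79, 0.84),
    "utilities.m_mi"              = c(0.67, 0.96)
  )

  inputs <- structure(
    list(risks = risks, splits = splits, fatality = fatality,
         costs = costs, utilities = utilities,
         ranges = list(), config = config),
    class = "af_model_inputs"
  )
  # every parameter gets a range; those without a published one are degenerate
  ranges <- list()
  for (id in list_parameters(inputs)) {
    base <- param_get(inputs, id)
    rg <- ranged[[id]]
    ranges[[id]] <- if (is.null(rg)) c(low = base, high = base)
                    else c(low = rg[[1]], high = rg[[2]])
  }
  inputs$ranges <- ranges
  inputs
}

#' Enumerate parameter identifiers
#'
#' Dotted-path identifiers for every scalar model parameter, e.g.
#' `"risks.warfarin.p_is"`, `"splits.ich.severe"`, `"costs.annual.rivaroxaban"`,
#' `"utilities.u_min"`. These are the names used by `ranges`, by
#' [one_way_sensitivity()] and by the PSA sampler.
#'
#' @param inputs an `af_model_inputs` object.
#' @return character vector of identifiers.
#' @export
list_parameters <- function(inputs) {
  c(
    as.vector(outer(paste0("risks.", .af_strategies), .af_risk_fields,
                    paste, sep = ".")),
    paste0("splits.is.", .af_split_fields),
    paste0("splits.ich.", .af_split_fields),
    c("fatality.ech", "fatality.mi"),
    paste0("costs.annual.", .af_strategies),
    paste0("costs.event.", .af_events),
    paste0("utilities.", .af_utility_fields)
  )
}

#' Get / set a parameter by dotted path
#'
#' @param inputs an `af_model_inputs` object.
#' @param id dotted-path identifier, see [list_parameters()].
#' @param value replacement value (for `param_set`).
#' @return `param_get`: the scalar value. `param_set`: the modified inputs.
#' @export
param_get <- function(inputs, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  node <- inputs
  for (p in parts) {
    node <- tryCatch(node[[p]], error = function(e) NULL)
    if (is.null(node)) stop("unknown parameter id: ", id, call. = FALSE)
  }
  unname(node)
}

#' @rdname param_get
#' @export
param_set <- function(inputs, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  rec <- function(node, parts) {
    if (is.null(tryCatch(node[[parts[1]]], error = function(e) NULL)))
      stop("unknown parameter id: ", id, call. = FALSE)
    if (length(parts) == 1L) {
      node[[parts]] <- value
    } else {
      node[[parts[1]]] <- rec(node[[parts[1]]], parts[-1])
    }
    node
  }
  out <- rec(inputs, parts)
  structure(out, class = class(inputs))
}

#' Validate a model parameter set
#'
#' Checks every structural invariant: probabilities and utilities in
#' \[0, 1\], per-strategy competing risks summing to at most 1, severity
#' splits summing to 1, nonnegative costs, utility ordering
#' u_min >= u_mod >= u_sev, well-ordered ranges and a sane run
#' configuration.
#'
#' @param inputs an `af_model_inputs` object.
#' @return A data frame of class `af_validation` with columns `code` and
#'   `message`, one row per violated invariant; zero rows when valid.
#' @export
validate_inputs <- function(inputs) {
  bad <- list()
  flag <- function(code, message) bad[[length(bad) + 1L]] <<-
    data.frame(code = code, message = message, stringsAsFactors = FALSE)

  for (s in .af_strategies) {
    r <- inputs$risks[[s]]
    if (is.null(r) || !all(.af_risk_fields %in% names(r))) {
      flag("missing_strategy", paste0("strategy block incomplete or missing: ", s))
      next
    }
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
      flag("prob_out_of_range",
           paste0(s, ": probability outside [0,1]"))
    if (sum(r) > 1 + 1e-12)
      flag("risk_sum_exceeds_1",
           paste0(s, ": event + mortality probabilities sum to ",
                  format(sum(r)), " > 1"))
    if (is.null(inputs$costs$annual) || is.na(inputs$costs$annual[s]))
      flag("missing_strategy", paste0("annual cost missing for ", s))
  }
  for (ev in c("is", "ich")) {
    sp <- inputs$splits[[ev]]
    if (is.null(sp) || !all(.af_split_fields %in% names(sp))) {
      flag("missing_field", paste0("severity split missing: ", ev))
      next
    }
    if (any(sp < 0) || any(sp > 1))
      flag("prob_out_of_range", paste0(toupper(ev), " severity fraction outside [0,1]"))
    if (abs(sum(sp) - 1) > 1e-9)
      flag("severity_split_not_normalized",
           paste0(toupper(ev), " severity split not normalized (sums to ",
                  format(sum(sp)), ")"))
  }
  for (ev in c("ech", "mi")) {
    fd <- inputs$fatality[[ev]]
    if (is.null(fd)) flag("missing_field", paste0("fatality missing: ", ev))
    else if (fd < 0 || fd > 1)
      flag("prob_out_of_range", paste0(toupper(ev), " case fatality outside [0,1]"))
  }
  if (!all(.af_events %in% names(inputs$costs$event)))
    flag("missing_field", "event cost block incomplete")
  allc <- c(inputs$costs$annual, inputs$costs$event)
  if (any(!is.finite(allc)) || any(allc < 0))
    flag("negative_cost", "costs must be finite and >= 0")
  u <- inputs$utilities
  if (!all(.af_utility_fields %in% names(u))) {
    flag("missing_field", "utility block incomplete")
  } else {
    uv <- unlist(u[.af_utility_fields])
    if (any(uv < 0) || any(uv > 1))
      flag("utility_out_of_range", "utility or multiplier outside [0,1]")
    if (!(u$u_min >= u$u_mod && u$u_mod >= u$u_sev))
      flag("utility_order", "utility ordering violated: need u_min >= u_mod >= u_sev")
  }
  for (id in names(inputs$ranges)) {
    rg <- inputs$ranges[[id]]
    base <- tryCatch(param_get(inputs, id), error = function(e) NA_real_)
    if (is.na(base)) { flag("unknown_range_id", paste0("range for unknown parameter: ", id)); next }
    if (!(rg[["low"]] <= base + 1e-12 && base <= rg[["high"]] + 1e-12))
      flag("range_order", paste0(id, ": need low <= base <= high"))
  }
  cfg <- inputs$config
  if (cfg$horizon_cycles < 1) flag("config_invalid", "horizon_cycles must be >= 1")
  if (cfg$discount_rate < 0) flag("config_invalid", "discount_rate must be >= 0")
  if (cfg$wtp < 0) flag("config_invalid", "wtp must be >= 0")
  if (cfg$psa_draws < 1) flag("config_invalid", "psa_draws must be >= 1")

  out <- if (length(bad)) do.call(rbind, bad)
         else data.frame(code = character(), message = character(),
                         stringsAsFactors = FALSE)
  structure(out, class = c("af_validation", "data.frame"))
}

#' @rdname validate_inputs
#' @export
is_valid <- function(inputs) nrow(validate_inputs(inputs)) == 0L

.assert_valid <- function(inputs) {
  rep <- validate_inputs(inputs)
  if (nrow(rep))
    stop("invalid model inputs:\n  ",
         paste(rep$message, collapse = "\n  "), call. = FALSE)
  invisible(inputs)
}

# ---- configuration file I/O -------------------------------------------------

.leaf <- function(value, range) {
  if (is.null(range) || (range[["low"]] == value && range[["high"]] == value))
    list(value = value)
  else list(value = value, range = c(range[["low"]], range[["high"]]))
}

.read_leaf <- function(node, where) {
  if (is.null(node)) stop("missing configuration key: ", where, call. = FALSE)
  if (is.numeric(node) && length(node) == 1L)
    return(list(value = as.numeric(node), range = NULL))
  if (!is.list(node) || is.null(node$value))
    stop("malformed configuration value at key: ", where, call. = FALSE)
  rg <- node$range
  if (!is.null(rg) && length(rg) != 2L)
    stop("range must have two entries at key: ", where, call. = FALSE)
  list(value = as.numeric(node$value),
       range = if (is.null(rg)) NULL else as.numeric(rg))
}

#' Load model inputs from a YAML configuration file
#'
#' The schema has top-level sections `strategies` (one block per strategy
#' with `p_is`, `p_ich`, `p_ech`, `p_mi`, `p_death`, `annual_cost`),
#' `event_outcomes` (`is_severity`, `ich_severity`, `ech_fatality`,
#' `mi_fatality`), `costs` (`events`), `utilities` and `run`. Each numeric
#' leaf is either a bare number or a `{value, range: [low, high]}` mapping.
#' The shipped fixture `system.file("extdata", "table1_base_case.yaml",
#' package = "afibcea")` reproduces the published base case and round-trips
#' to [base_case_inputs()].
#'
#' @param source path to a YAML file, or a single string of YAML text.
#' @return A validated `af_model_inputs` object.
#' @export
load_model_inputs <- function(source) {
  doc <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    yaml::read_yaml(source)
  else yaml::yaml.load(paste(source, collapse = "\n"))
  if (!is.list(doc)) stop("configuration did not parse to a mapping", call. = FALSE)
  for (sec in c("strategies", "event_outcomes", "costs", "utilities"))
    if (is.null(doc[[sec]]))
      stop("missing configuration section: ", sec, call. = FALSE)

  got <- canonical_strategy(names(doc$strategies))
  missing <- setdiff(.af_strategies, got)
  if (length(missing))
    stop("missing strategy block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  names(doc$strategies) <- got

  cfg <- default_run_config()
  if (!is.null(doc$run)) {
    bad <- setdiff(names(doc$run), names(cfg))
    if (length(bad)) stop("unknown run config key(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(doc$run)] <- doc$run
  }
  inputs <- base_case_inputs(cfg)  # template for structure; all values replaced
  ranges <- list()

  take <- function(id, node, where) {
    lf <- .read_leaf(node, where)
    inputs <<- param_set(inputs, id, lf$value)
    ranges[[id]] <<- if (is.null(lf$range)) c(low = lf$value, high = lf$value)
                     else c(low = lf$range[1], high = lf$range[2])
  }
  for (s in .af_strategies) {
    blk <- doc$strategies[[s]]
    for (f in .af_risk_fields)
      take(paste0("risks.", s, ".", f), blk[[f]], paste0("strategies.", s, ".", f))
    take(paste0("costs.annual.", s), blk$annual_cost,
         paste0("strategies.", s, ".annual_cost"))
  }
  eo <- doc$event_outcomes
  for (ev in c("is", "ich")) {
    blk <- eo[[paste0(ev, "_severity")]]
    for (f in .af_split_fields)
      take(paste0("splits.", ev, ".", f), blk[[f]],
           paste0("event_outcomes.", ev, "_severity.", f))
  }
  take("fatality.ech", eo$ech_fatality, "event_outcomes.ech_fatality")
  take("fatality.mi", eo$mi_fatality, "event_outcomes.mi_fatality")
  for (e in .af_events)
    take(paste0("costs.event.", e), doc$costs$events[[e]],
         paste0("costs.events.", e))
  for (f in .af_utility_fields)
    take(paste0("utilities.", f), doc$utilities[[f]], paste0("utilities.", f))

  inputs$ranges <- ranges[list_parameters(inputs)]
  .assert_valid(inputs)
  inputs
}

#' Write model inputs to a YAML configuration file
#'
#' Inverse of [load_model_inputs()]: `load_model_inputs(write_model_inputs(x, f))`
#' reproduces `x` field-for-field.
#'
#' @param inputs an `af_model_inputs` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_inputs <- function(inputs, path) {
  strat <- lapply(.af_strategies, function(s) {
    blk <- lapply(.af_risk_fields, function(f)
      .leaf(inputs$risks[[s]][[f]], inputs$ranges[[paste0("risks.", s, ".", f)]]))
    names(blk) <- .af_risk_fields
    blk$annual_cost <- .leaf(inputs$costs$annual[[s]],
                             inputs$ranges[[paste0("costs.annual.", s)]])
    blk
  })
  names(strat) <- .af_strategies
  sev <- function(ev) {
    blk <- lapply(.af_split_fields, function(f)
      .leaf(inputs$splits[[ev]][[f]], inputs$ranges[[paste0("splits.", ev, ".", f)]]))
    names(blk) <- .af_split_fields
    blk
  }
  evc <- lapply(.af_events, function(e)
    .leaf(inputs$costs$event[[e]], inputs$ranges[[paste0("costs.event.", e)]]))
  names(evc) <- .af_events
  utl <- lapply(.af_utility_fields, function(f)
    .leaf(inputs$utilities[[f]], inputs$ranges[[paste0("utilities.", f)]]))
  names(utl) <- .af_utility_fields

  cfg <- unclass(inputs$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  doc <- list(
    strategies = strat,
    event_outcomes = list(is_severity = sev("is"), ich_severity = sev("ich"),
                          ech_fatality = .leaf(inputs$fatality$ech,
                                               inputs$ranges[["fatality.ech"]]),
                          mi_fatality = .leaf(inputs$fatality$mi,
                                              inputs$ranges[["fatality.mi"]])),
    costs = list(events = evc),
    utilities = utl,
    run = cfg
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' @export
print.af_model_inputs <- function(x, ...) {
  cat("Model inputs:", length(.af_strategies), "strategies,",
      x$config$horizon_cycles, "annual cycles, discount rate",
      x$config$discount_rate, "\n")
  cat("Annual event probabilities:\n")
  print(do.call(rbind, x$risks))
  cat("Annual treatment cost ($):\n")
  print(x$costs$annual)
  invisible(x)
}
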