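test_that("cycle kernel matches brute-force branch enumeration", {
  inp <- base_case_inputs()
  for (s in strategy_names()) {
    k <- build_cycle_kernel(inp$risks[[s]], inp$splits$is, inp$splits$ich,
                            inp$fatality$ech, inp$fatality$mi, inp$config,
                            strategy = s)
    oracle <- enumerate_min_row(inp$risks[[s]], inp$splits$is, inp$splits$ich,
                                inp$fatality$ech, inp$fatality$mi)
    expect_equal(k$transition["Min", ], oracle, tolerance = 1e-12)
  }
  # warfarin one-cycle death probability, enumerated by hand from the table
  kw <- build_cycle_kernel(inp$risks$warfarin, inp$splits$is, inp$splits$ich,
                           inp$fatality$ech, inp$fatality$mi, inp$config)
  expect_equal(kw$transition["Min", "Death"],
               0.026 + 0.04 * 0.082 + 0.0121 * 0.18 + 0.027 * 0.0147 +
                 0.0098 * 0.166,
               tolerance = 1e-12)
  expect_equal(kw$transition["Min", "Min"],
               1 - 0.1149 + 0.04 * 0.091 + 0.0121 * 0.12 +
                 0.027 * (1 - 0.0147) + 0.0098 * (1 - 0.166),
               tolerance = 1e-12)
})

test_that("degenerate kernels behave: identity, certain death, overload", {
  inp <- base_case_inputs()
  zero <- c(p_is = 0, p_ich = 0, p_ech = 0, p_mi = 0, p_death = 0)
  k <- build_cycle_kernel(zero, inp$splits$is, inp$splits$ich, 0.1, 0.1)
  expect_equal(unname(k$transition), diag(4), tolerance = 1e-15)

  over <- c(p_is = 0.5, p_ich = 0.4, p_ech = 0.3, p_mi = 0.2, p_death = 0.1)
  expect_error(
    build_cycle_kernel(over, inp$splits$is, inp$splits$ich, 0.1, 0.1,
                       strategy = "warfarin"),
    "exceed 1.*warfarin")
})

test_that("kernel invariants hold across randomly generated inputs", {
  for (seed in 1:25) {
    inp <- generate_inputs(seed, jitter = 0.25)
    for (s in strategy_names()) {
      k <- build_cycle_kernel(inp$risks[[s]], inp$splits$is, inp$splits$ich,
                              inp$fatality$ech, inp$fatality$mi, inp$config)
      expect_equal(unname(rowSums(k$transition)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(k$transition >= 0 & k$transition <= 1))
      expect_equal(unname(k$transition["Death", ]), c(0, 0, 0, 1))
      expect_equal(unname(k$event_incidence["Death", ]), rep(0, 4))
      # severe state: only staying or dying
      expect_equal(unname(k$transition["Sev", c("Min", "Mod")]), c(0, 0))
    }
  }
})

test_that("cohort accrual matches hand-computable cases", {
  inp <- two_state_inputs(0, u = 0.76, cost = 100,
                          config = default_run_config(discount_rate = 0))
  out <- run_strategy(inp, "warfarin")
  expect_equal(out$total_qaly, 0.76 * 30, tolerance = 1e-12)  # 22.8
  expect_equal(out$total_cost, 100 * 30, tolerance = 1e-12)

  # discounted, first cycle undiscounted: geometric series
  inp2 <- two_state_inputs(0, u = 0.76, cost = 100)
  out2 <- run_strategy(inp2, "warfarin")
  expect_equal(out2$total_qaly, 0.76 * sum(1.03^(-(0:29))), tolerance = 1e-12)

  # certain death: exactly one cycle of accrual
  inp3 <- two_state_inputs(1, u = 0.5, cost = 200)
  out3 <- run_strategy(inp3, "warfarin")
  expect_equal(out3$total_qaly, 0.5, tolerance = 1e-12)
  expect_equal(out3$total_cost, 200, tolerance = 1e-12)
  tr <- attr(out3, "trace")
  expect_equal(unname(tr$occupancy[2, ]), c(0, 0, 0, 1))
})

test_that("engine equals the two-state closed form and the loop oracle", {
  for (p in c(0, 0.1, 0.5, 1)) for (r in c(0, 0.03, 0.07)) for (T_ in c(1, 7, 30)) {
    cfg <- default_run_config(horizon_cycles = T_, discount_rate = r)
    inp <- two_state_inputs(p, u = 0.7, cost = 1234, config = cfg)
    out <- run_strategy(inp, "rivaroxaban")
    cf <- closed_form_two_state(p, 0.7, 1234, r, T_)
    lp <- loop_two_state(p, 0.7, 1234, r, T_)
    expect_equal(out$total_qaly, cf[["qaly"]], tolerance = 1e-9)
    expect_equal(out$total_cost, cf[["cost"]], tolerance = 1e-9)
    expect_equal(cf, lp, tolerance = 1e-12)
  }
  # alternative first-cycle convention
  cfg <- default_run_config(horizon_cycles = 12, discount_rate = 0.05,
                            discount_first_cycle = TRUE)
  inp <- two_state_inputs(0.2, u = 0.9, cost = 10, config = cfg)
  out <- run_strategy(inp, "warfarin")
  expect_equal(out$total_qaly,
               closed_form_two_state(0.2, 0.9, 10, 0.05, 12, TRUE)[["qaly"]],
               tolerance = 1e-9)
})

test_that("trace invariants: occupancy rows sum to 1, death nondecreasing", {
  for (seed in c(3, 11, 42)) {
    inp <- generate_inputs(seed, jitter = 0.2)
    tr <- attr(run_strategy(inp, "dabigatran110"), "trace")
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 31), tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
    expect_equal(unname(tr$occupancy[1, ]), c(1, 0, 0, 0))
  }
})

test_that("QALYs fall with event risk and rise with utility", {
  inp <- base_case_inputs()
  base <- run_strategy(inp, "warfarin")$total_qaly
  for (id in c("risks.warfarin.p_is", "risks.warfarin.p_ich",
               "risks.warfarin.p_death")) {
    worse <- param_set(inp, id, param_get(inp, id) + 0.01)
    worse <- afibcea:::.widen_ranges(worse)
    expect_lt(run_strategy(worse, "warfarin")$total_qaly, base)
  }
  better <- param_set(inp, "utilities.u_min", 0.80)
  expect_gt(run_strategy(better, "warfarin")$total_qaly, base)
})

test_that("fatal-event cycles charge the event cost only when configured", {
  # certain fatal stroke in cycle 1: cost = annual + event cost when charged
  inp <- base_case_inputs()
  for (s in strategy_names())
    inp$risks[[s]] <- c(p_is = 1, p_ich = 0, p_ech = 0, p_mi = 0, p_death = 0)
  inp$splits$is <- c(light = 0, moderate = 0, severe = 0, die = 1)
  inp <- afibcea:::.widen_ranges(inp)
  out <- run_strategy(inp, "warfarin")
  expect_equal(out$total_cost, 253.30 + 1351.20, tolerance = 1e-9)
  expect_equal(unname(out$event_totals[["IS"]]), 1, tolerance = 1e-12)

  inp$config <- default_run_config(charge_fatal_event = FALSE)
  out2 <- run_strategy(inp, "warfarin")
  expect_equal(out2$total_cost, 253.30, tolerance = 1e-9)
})

test_that("event-cycle utilities use destination state and multipliers", {
  # certain nonfatal ICH with a severe outcome: year one accrues u_sev * m_ich
  inp <- base_case_inputs(default_run_config(horizon_cycles = 1))
  for (s in strategy_names())
    inp$risks[[s]] <- c(p_is = 0, p_ich = 1, p_ech = 0, p_mi = 0, p_death = 0)
  inp$splits$ich <- c(light = 0, moderate = 0, severe = 1, die = 0)
  inp <- afibcea:::.widen_ranges(inp)
  out <- run_strategy(inp, "warfarin")
  expect_equal(out$total_qaly, 0.16 * 0.8, tolerance = 1e-12)
})

test_that("microsimulation is reproducible and agrees with the cohort", {
  inp <- base_case_inputs()
  k <- afibcea:::.kernel_for(inp, "warfarin")
  a <- run_microsim(k, inp$costs, inp$utilities, inp$config,
                    n_patients = 500, seed = 99)
  b <- run_microsim(k, inp$costs, inp$utilities, inp$config,
                    n_patients = 500, seed = 99)
  expect_identical(a$total_cost, b$total_cost)
  expect_identical(a$total_qaly, b$total_qaly)

  coh <- run_strategy(inp, "warfarin")
  m <- run_microsim(k, inp$costs, inp$utilities, inp$config,
                    n_patients = 20000, seed = 7)
  expect_lt(abs(m$total_cost - coh$total_cost), 3 * m$mc_stderr[["cost"]])
  expect_lt(abs(m$total_qaly - coh$total_qaly), 3 * m$mc_stderr[["qaly"]])

  # certain death after one cycle: zero variance, exact accrual
  inp2 <- two_state_inputs(1, u = 0.5, cost = 200)
  k2 <- afibcea:::.kernel_for(inp2, "warfarin")
  m2 <- run_microsim(k2, inp2$costs, inp2$utilities, inp2$config,
                     n_patients = 50, seed = 1)
  expect_equal(m2$total_qaly, 0.5, tolerance = 1e-12)
  expect_equal(unname(m2$mc_stderr), c(0, 0), tolerance = 1e-15)
})

test_that("trace exports one row per cycle with discounted columns", {
  inp <- base_case_inputs()
  df <- as.data.frame(attr(run_strategy(inp, "rivaroxaban"), "trace"))
  expect_equal(nrow(df), 30)
  expect_true(all(c("occ_Min", "inc_IS", "cost", "qaly_disc") %in% names(df)))
  expect_equal(df$cost_disc, df$cost * 1.03^(-(0:29)), tolerance = 1e-12)
})
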