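test_that("method-of-moments fits recover known distributions", {
  # mean 0.5, sd 0.1 (range read as 95% interval) -> Beta(12, 12)
  d <- fit_psa_distribution(list(base = 0.5, low = 0.5 - 1.96 * 0.1,
                                 high = 0.5 + 1.96 * 0.1), "beta")
  expect_equal(d$shape1, 12, tolerance = 1e-9)
  expect_equal(d$shape2, 12, tolerance = 1e-9)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.5)

  # log-normal: analytic moments equal the targets
  dl <- fit_psa_distribution(list(base = 2605.43, low = 1935.86, high = 3862.05),
                             "lognormal")
  m <- exp(dl$meanlog + dl$sdlog^2 / 2)
  s <- m * sqrt(exp(dl$sdlog^2) - 1)
  expect_equal(m, 2605.43, tolerance = 1e-9)
  expect_equal(s, (3862.05 - 1935.86) / 3.92, tolerance = 1e-9)

  # degenerate range -> fixed, constant draws
  df <- fit_psa_distribution(list(base = 0.3, low = 0.3, high = 0.3), "beta")
  expect_equal(df$family, "fixed")
  expect_equal(draw_psa_distribution(df, 5), rep(0.3, 5))

  expect_error(fit_psa_distribution(list(base = 0.5, low = 0, high = 4), "beta"),
               "variance infeasible")
  expect_error(fit_psa_distribution(list(base = -1, low = -2, high = 3),
                                    "lognormal"), "positive")
})

test_that("parameter draws hit their target moments", {
  inp <- base_case_inputs()
  m <- sample_parameter_draws(inp, n_draws = 20000, seed = 31)
  # warfarin stroke probability: mean 0.04, sd = range width / 3.92
  x <- m[, "risks.warfarin.p_is"]
  sd_t <- (0.0453 - 0.023) / 3.92
  expect_lt(abs(mean(x) - 0.04), 3 * sd_t / sqrt(length(x)))
  expect_equal(stats::sd(x), sd_t, tolerance = 0.05)
  # degenerate parameters stay fixed
  expect_equal(unname(m[, "risks.rivaroxaban.p_is"]), rep(0.0193, 20000))
  # costs are log-normal: all positive, right-skewed
  y <- m[, "costs.annual.rivaroxaban"]
  expect_true(all(y > 0))
  expect_gt(mean((y - mean(y))^3), 0)
})

test_that("sampled parameter sets are valid, normalized, reproducible", {
  inp <- base_case_inputs()
  s1 <- sample_psa(inp, n_draws = 30, seed = 11)
  s2 <- sample_psa(inp, n_draws = 30, seed = 11)
  expect_equal(s1, s2)
  for (smp in s1[1:10]) {
    expect_equal(nrow(validate_inputs(smp)), 0L)
    expect_equal(sum(smp$splits$is), 1, tolerance = 1e-12)
    expect_equal(sum(smp$splits$ich), 1, tolerance = 1e-12)
  }
  expect_false(identical(s1[[1]]$risks$warfarin, s1[[2]]$risks$warfarin))

  # all ranges degenerate -> the sample is the base case itself
  fixed <- inp
  for (id in names(fixed$ranges)) {
    b <- param_get(fixed, id)
    fixed$ranges[[id]] <- c(low = b, high = b)
  }
  s3 <- sample_psa(fixed, n_draws = 1, seed = 1)
  expect_equal(s3[[1]]$risks, fixed$risks, tolerance = 1e-12)
  expect_equal(s3[[1]]$utilities, fixed$utilities, tolerance = 1e-12)
})

test_that("PSA outcomes have full shape and degenerate draws collapse", {
  inp <- base_case_inputs()
  samples <- sample_psa(inp, n_draws = 25, seed = 3)
  psa <- run_psa(samples)
  expect_equal(dim(psa$cost), c(25, 4))
  expect_equal(dim(psa$qaly), c(25, 4))
  expect_false(anyNA(psa$cost) || anyNA(psa$qaly))
  # mean incremental cost keeps the deterministic sign (rivaroxaban costlier)
  expect_gt(mean(psa$cost[, "rivaroxaban"] - psa$cost[, "warfarin"]), 0)

  fixed <- inp
  for (id in names(fixed$ranges)) {
    b <- param_get(fixed, id)
    fixed$ranges[[id]] <- c(low = b, high = b)
  }
  psa0 <- run_psa(sample_psa(fixed, n_draws = 3, seed = 1))
  det <- run_base_case(inp)
  for (s in strategy_names())
    expect_equal(unname(psa0$cost[, s]), rep(det[[s]]$total_cost, 3),
                 tolerance = 1e-9)
})

test_that("acceptability curves are proper probabilities", {
  inp <- base_case_inputs()
  psa <- run_psa(sample_psa(inp, n_draws = 40, seed = 17))
  grid <- seq(0, 6e4, length.out = 25)
  cc <- ceac(psa, grid)
  pm <- as.matrix(cc[, strategy_names()])
  expect_equal(unname(rowSums(pm)), rep(1, 25), tolerance = 1e-9)
  expect_true(all(pm >= 0 & pm <= 1))
  # at wtp = 0 the cheapest strategy wins almost surely
  expect_gt(pm[1, "warfarin"], 0.9)
  # rivaroxaban more acceptable at the top of the grid than at zero
  expect_gt(pm[25, "rivaroxaban"], pm[1, "rivaroxaban"])

  # single-strategy and exact-tie cases
  one <- fake_psa(cost = matrix(1:5, 5, 1, dimnames = list(NULL, "warfarin")),
                  qaly = matrix(1, 5, 1, dimnames = list(NULL, "warfarin")))
  expect_equal(ceac(one, c(0, 1e4))$warfarin, c(1, 1))
  two <- fake_psa(
    cost = matrix(1, 4, 2, dimnames = list(NULL, c("warfarin", "rivaroxaban"))),
    qaly = matrix(2, 4, 2, dimnames = list(NULL, c("warfarin", "rivaroxaban"))))
  tied <- ceac(two, 5000)
  expect_equal(tied$warfarin, 0.5)
  expect_equal(tied$rivaroxaban, 0.5)
  expect_error(ceac(psa, c(3, 2, 1)))
})

test_that("step-function acceptability under degenerate parameter draws", {
  inp <- base_case_inputs()
  fixed <- inp
  for (id in names(fixed$ranges)) {
    b <- param_get(fixed, id)
    fixed$ranges[[id]] <- c(low = b, high = b)
  }
  psa <- run_psa(sample_psa(fixed, n_draws = 3, seed = 1))
  det <- run_base_case(inp)
  tab <- incremental_analysis(det, "warfarin", wtp = inp$config$wtp)
  fr_icer <- min(tab$frontier_icer, na.rm = TRUE)
  cc <- ceac(psa, c(fr_icer - 500, fr_icer + 500))
  expect_equal(cc$warfarin, c(1, 0))
  expect_equal(cc$rivaroxaban, c(0, 1))
})

test_that("tornado entries: degenerate ranges, swing ordering, errors", {
  inp <- base_case_inputs()
  tor <- one_way_sensitivity(
    inp, parameters = c("risks.warfarin.p_is", "risks.rivaroxaban.p_is",
                        "costs.annual.rivaroxaban"))
  expect_s3_class(tor, "af_tornado")
  deg <- tor[tor$parameter == "risks.rivaroxaban.p_is", ]
  expect_true(deg$degenerate)
  expect_equal(deg$swing, 0)
  expect_equal(deg$icer_at_low, deg$base_icer)
  expect_true(all(diff(tor$swing) <= 0))  # sorted by swing, descending

  single <- one_way_sensitivity(inp, parameters = "utilities.u_min")
  expect_equal(nrow(single), 1L)

  expect_error(one_way_sensitivity(inp, parameters = "utilities.u_max"),
               "unknown parameter")
  expect_error(one_way_sensitivity(inp, reference = "warfarin",
                                   comparator = "warfarin"), "differ")

  # all-degenerate inputs: every swing zero
  tor0 <- one_way_sensitivity(two_state_inputs(0.1),
                              parameters = c("risks.warfarin.p_is",
                                             "utilities.u_min"))
  expect_true(all(tor0$swing == 0))
})

test_that("varying a severity fraction keeps the split normalized", {
  inp <- base_case_inputs()
  res <- afibcea:::.run_pair_at(inp, "splits.is.light", 0.133,
                                "rivaroxaban", "warfarin")
  expect_s3_class(res, "af_icer")  # ran without validation failure
})

test_that("the ICE ellipse scales with coverage and degenerates on ties", {
  inp <- base_case_inputs()
  psa <- run_psa(sample_psa(inp, n_draws = 50, seed = 23))
  e95 <- ice_scatter(psa, "rivaroxaban", "warfarin", coverage = 0.95)
  e50 <- ice_scatter(psa, "rivaroxaban", "warfarin", coverage = 0.50)
  expect_equal(nrow(e95$points), 50)
  expect_gt(e95$radius2, e50$radius2)
  # the 50% ellipse boundary lies strictly inside the 95% one
  md <- mahalanobis(e50$ellipse, e95$center, e95$cov)
  expect_true(all(md < e95$radius2))

  tiny <- fake_psa(
    cost = matrix(c(0, 0, 100, 100), 2, 2,
                  dimnames = list(NULL, c("warfarin", "rivaroxaban"))),
    qaly = matrix(1, 2, 2, dimnames = list(NULL, c("warfarin", "rivaroxaban"))))
  expect_error(ice_scatter(tiny, "rivaroxaban", "warfarin"), "at least 3")

  const <- fake_psa(
    cost = matrix(rep(c(0, 100), each = 5), 5, 2,
                  dimnames = list(NULL, c("warfarin", "rivaroxaban"))),
    qaly = matrix(rep(c(1, 2), each = 5), 5, 2,
                  dimnames = list(NULL, c("warfarin", "rivaroxaban"))))
  e0 <- ice_scatter(const, "rivaroxaban", "warfarin")
  expect_equal(unname(e0$cov), matrix(0, 2, 2))
  expect_equal(max(dist(e0$ellipse)), 0, tolerance = 1e-9)
})
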