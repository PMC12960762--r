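test_that("relative risks act on the rate scale and stay in [0, 1)", {
  expect_identical(adjust_probability(0.3, 1), 0.3)
  expect_identical(adjust_probability(0, 2.5), 0)
  expect_equal(adjust_probability(0.3, 0.5), 1 - 0.7^0.5)
  expect_error(adjust_probability(0.3, 0), "rr must be > 0")
  expect_error(adjust_probability(1, 2), "cannot be adjusted")
  expect_no_error(adjust_probability(1, 1))

  set.seed(99)
  p <- runif(10000)
  rr <- exp(runif(10000, -3, 3))
  adj <- adjust_probability(p, rr)
  expect_true(all(adj >= 0 & adj < 1))
  # identity at rr = 1 is exact
  expect_identical(adjust_probability(p, rep(1, 10000)), p)
  # direction: rr < 1 strictly decreases, rr > 1 strictly increases
  inner <- p > 0 & p < 1
  expect_true(all(adj[inner & rr < 1] < p[inner & rr < 1]))
  expect_true(all(adj[inner & rr > 1] > p[inner & rr > 1]))
})

test_that("strategy effects apply locally and revert exactly", {
  gen <- generate_parameter_set(fixture_spec(4))
  elig <- c("mild|no_formal_care", "mild|home_care")
  strat <- strategy(
    "tech",
    effects = list(
      transition_effect("home_care", "institutional_care", rr = 0.5),
      state_value_effect("patient_utility", delta = 0.05,
                         states = "mild|no_formal_care")
    ),
    eligibility = elig, persistence_cycles = 4, intervention_cost = 100
  )

  eff <- build_strategy_parameters(gen$params, gen$values, strat, 0)
  # locality of the value effect
  expect_equal(eff$values$patient_utility[["mild|no_formal_care"]],
               gen$values$patient_utility[["mild|no_formal_care"]] + 0.05)
  untouched <- setdiff(living_states(), "mild|no_formal_care")
  expect_identical(eff$values$patient_utility[untouched],
                   gen$values$patient_utility[untouched])
  expect_identical(eff$values$formal_cost, gen$values$formal_cost)

  # transition effect touches only eligible source rows
  expect_equal(eff$params$p_care["mild", "home_care", "institutional_care"],
               adjust_probability(
                 gen$params$p_care["mild", "home_care", "institutional_care"],
                 0.5))
  expect_identical(eff$params$p_care["moderate", , ],
                   gen$params$p_care["moderate", , ])
  expect_identical(eff$params$p_care["severe", , ],
                   gen$params$p_care["severe", , ])
  expect_identical(eff$params$p_death, gen$params$p_death)

  # reversion beyond the persistence window is exact (same objects)
  for (cycle in c(4, 5, 10, 1000)) {
    post <- build_strategy_parameters(gen$params, gen$values, strat, cycle)
    expect_identical(post$params, gen$params)
    expect_identical(post$values, gen$values)
  }

  # the null strategy changes nothing at any cycle
  null_strat <- strategy("null", persistence_cycles = 10)
  at0 <- build_strategy_parameters(gen$params, gen$values, null_strat, 0)
  expect_identical(at0$params, gen$params)
  expect_identical(at0$values, gen$values)
})

test_that("effects cannot target structurally impossible transitions", {
  gen <- generate_parameter_set(fixture_spec(4))
  strat <- strategy(
    "bad",
    effects = list(transition_effect("home_care", "no_formal_care", rr = 0.5)),
    eligibility = living_states(), persistence_cycles = 4
  )
  expect_error(build_strategy_parameters(gen$params, gen$values, strat, 0),
               "structurally-zero")
  expect_error(transition_effect("home_care", "home_care", 0.5), "residual")
})

test_that("utility clamping and cost flooring warn and bound the result", {
  gen <- generate_parameter_set(fixture_spec(4))
  strat <- strategy(
    "big",
    effects = list(state_value_effect("patient_utility", delta = 0.9)),
    eligibility = living_states(), persistence_cycles = 1
  )
  expect_warning(
    eff <- build_strategy_parameters(gen$params, gen$values, strat, 0),
    "clamped")
  expect_true(all(eff$values$patient_utility <= 1))

  strat2 <- strategy(
    "cut",
    effects = list(state_value_effect("informal_hours", delta = -1000)),
    eligibility = living_states(), persistence_cycles = 1
  )
  expect_warning(
    eff2 <- build_strategy_parameters(gen$params, gen$values, strat2, 0),
    "floored")
  expect_true(all(eff2$values$informal_hours >= 0))
})

test_that("linear waning interpolates deltas and log-rr toward baseline", {
  gen <- generate_parameter_set(fixture_spec(4))
  strat <- strategy(
    "wane",
    effects = list(
      transition_effect("home_care", "institutional_care", rr = 0.5),
      state_value_effect("patient_utility", delta = 0.04)
    ),
    eligibility = living_states(), persistence_cycles = 2,
    waning = "linear", waning_cycles = 3, intervention_cost = 0
  )
  p0 <- gen$params$p_care["mild", "home_care", "institutional_care"]
  u0 <- gen$values$patient_utility[["mild|no_formal_care"]]
  fracs <- c(1, 1, 3 / 4, 2 / 4, 1 / 4, 0, 0)
  for (i in seq_along(fracs)) {
    eff <- build_strategy_parameters(gen$params, gen$values, strat, i - 1)
    expect_equal(
      eff$params$p_care["mild", "home_care", "institutional_care"],
      1 - (1 - p0)^(0.5^fracs[i]), tolerance = 1e-12)
    expect_equal(eff$values$patient_utility[["mild|no_formal_care"]],
                 u0 + 0.04 * fracs[i], tolerance = 1e-14)
  }
  # beyond the tail: bitwise baseline
  post <- build_strategy_parameters(gen$params, gen$values, strat, 5)
  expect_identical(post$params, gen$params)
})

test_that("intervention cost accrues over eligible occupancy in the window", {
  strat <- strategy("tech", effects = list(),
                    eligibility = c("mild|no_formal_care", "mild|home_care"),
                    persistence_cycles = 3, intervention_cost = 1200)
  # 100% occupancy in an eligible state, monthly cycles: 100 per cycle
  tr <- run_cohort(diag(10), unit_init(), n_cycles = 6, cycle_length = 1 / 12)
  stream <- intervention_cost_stream(strat, tr)
  expect_equal(stream, c(100, 100, 100, 0, 0, 0))

  # occupancy split 0.6 eligible / 0.4 ineligible
  init <- stats::setNames(rep(0, 10), state_names())
  init["mild|no_formal_care"] <- 0.6
  init["severe|institutional_care"] <- 0.4
  tr2 <- run_cohort(diag(10), init, n_cycles = 2, cycle_length = 1 / 12)
  expect_equal(intervention_cost_stream(strat, tr2), c(60, 60))

  # zero cost gives a zero stream
  free <- strategy("free", effects = list(), eligibility = "mild|home_care",
                   persistence_cycles = 3, intervention_cost = 0)
  expect_equal(intervention_cost_stream(free, tr), rep(0, 6))
})

test_that("lower institutionalization risk never reduces community time", {
  for (seed in 1:20) {
    gen <- generate_parameter_set(fixture_spec(seed))
    settings <- analysis_settings(n_cycles = 240)
    community <- c(outer(c("mild", "moderate", "severe"),
                         c("no_formal_care", "home_care"), paste, sep = "|"))
    strat <- strategy(
      "defer",
      effects = list(transition_effect("home_care", "institutional_care",
                                       rr = 0.7)),
      eligibility = community, persistence_cycles = settings$n_cycles
    )
    base <- evaluate_strategy(gen$params, gen$values, settings = settings)
    trt <- evaluate_strategy(gen$params, gen$values, strat,
                             settings = settings)
    base_time <- time_in_state(base$trace, care = c("no_formal_care",
                                                    "home_care"))
    trt_time <- time_in_state(trt$trace, care = c("no_formal_care",
                                                  "home_care"))
    expect_gte(trt_time, base_time - 1e-12)
  }
})
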