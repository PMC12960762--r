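test_that("prior draws are seed-deterministic and moment-matched", {
  priors <- list(
    parameter_prior("params/p_death/mild/home_care", "beta",
                    mean = 0.3, se = 0.05),
    parameter_prior("values/unit_wage", "gamma", mean = 15, se = 3),
    parameter_prior("params/p_care/mild/home_care", "dirichlet",
                    counts = c(no_formal_care = 0, home_care = 90,
                               institutional_care = 10))
  )
  d1 <- sample_parameters(priors, n = 50, seed = 11)
  d2 <- sample_parameters(priors, n = 50, seed = 11)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_parameters(priors, n = 50, seed = 12)))

  big <- sample_parameters(priors, n = 10000, seed = 5)
  beta_draws <- vapply(big, function(d) d[["params/p_death/mild/home_care"]],
                       0.0)
  # CLT bound on the sample mean of a moment-matched beta
  expect_lt(abs(mean(beta_draws) - 0.3), 3 * 0.05 / sqrt(10000))
  expect_true(all(beta_draws >= 0 & beta_draws <= 1))
  gamma_draws <- vapply(big, function(d) d[["values/unit_wage"]], 0.0)
  expect_lt(abs(mean(gamma_draws) - 15), 3 * 3 / sqrt(10000))
  # dirichlet rows live on the simplex
  dir_draws <- t(vapply(big, function(d) d[["params/p_care/mild/home_care"]],
                        numeric(3)))
  expect_lt(max(abs(rowSums(dir_draws) - 1)), 1e-12)
  expect_true(all(dir_draws[, "no_formal_care"] == 0))

  expect_error(parameter_prior("x", "beta", mean = 0.3, se = 0.5),
               "infeasible")
  expect_error(parameter_prior("x", "dirichlet", counts = c(a = 1)),
               "named by the three care settings")
})

test_that("parameter paths address scalars, slices and strategy fields", {
  m <- toy_model(1)
  expect_equal(get_param(m, "params/p_progress/mild_to_moderate"),
               m$params$p_progress[["mild_to_moderate"]])
  m2 <- set_param(m, "params/p_death/mild/home_care", 0.123)
  expect_equal(m2$params$p_death["mild", "home_care"], 0.123)
  expect_equal(m$params$p_death["mild", "home_care"],
               get_param(m, "params/p_death/mild/home_care"))  # untouched
  m3 <- set_param(m, "values/patient_utility/severe|home_care", 0.21)
  expect_equal(m3$values$patient_utility[["severe|home_care"]], 0.21)
  m4 <- set_param(m, "strategy/intervention_cost", 999)
  expect_equal(m4$strategy$intervention_cost, 999)
  expect_error(get_param(m, "params/p_death/mild/bogus"), "unknown parameter")
  expect_error(set_param(m, "nope/x", 1), "unknown parameter")
})

test_that("PSA: degenerate priors reproduce the base case; null strategy
           gives zero increments; seeds are reproducible", {
  model <- toy_model(1, n_cycles = 60)
  base <- run_model(model)
  degenerate <- list(
    parameter_prior("values/unit_wage", "gamma",
                    mean = get_param(model, "values/unit_wage"), se = 0),
    parameter_prior("params/p_death/mild/no_formal_care", "beta",
                    mean = get_param(model,
                                     "params/p_death/mild/no_formal_care"),
                    se = 0)
  )
  psa <- run_psa(model, degenerate, n = 5, seed = 3)
  expect_true(all(psa$draws$delta_qaly == base$delta_qaly))
  expect_true(all(psa$draws$delta_cost == base$delta_cost))

  # null strategy: increments identically zero across draws
  null_model <- model
  null_model$strategy <- strategy("null", persistence_cycles = 0)
  psa0 <- run_psa(null_model, degenerate, n = 5, seed = 3)
  expect_true(all(psa0$draws$delta_qaly == 0))
  expect_true(all(psa0$draws$delta_cost == 0))

  # bitwise reproducibility
  priors <- list(parameter_prior("values/unit_wage", "gamma",
                                 mean = 15, se = 2))
  a <- run_psa(model, priors, n = 20, seed = 7)
  b <- run_psa(model, priors, n = 20, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
})

test_that("CEAC equals a brute-force NMB count and handles extremes", {
  fake <- function(dq, dc) {
    structure(list(draws = data.frame(draw = seq_along(dq), delta_qaly = dq,
                                      delta_cost = dc),
                   n = length(dq), seed = 0, wtp_grid = NULL, ceac = NULL),
              class = "psa_result")
  }
  # hand-counted: one of two draws cost-effective at 20000
  mixed <- ceac(fake(c(0.1, 0.1), c(1000, 3000)), 20000)
  expect_equal(mixed$probability, 0.5)
  # all dominant / all dominated
  expect_equal(ceac(fake(c(0.1, 0.2), c(-1, -2)), c(0, 5e4))$probability,
               c(1, 1))
  expect_equal(ceac(fake(c(-0.1, -0.2), c(10, 20)), c(0, 5e4))$probability,
               c(0, 0))
  # a tie (NMB exactly 0) counts as not cost-effective
  expect_equal(ceac(fake(0.1, 2000), 20000)$probability, 0)
  expect_error(ceac(fake(0.1, 1), numeric(0)), "non-empty")
  # monotone in WTP when all draws gain QALYs
  set.seed(8)
  curve <- ceac(fake(runif(50, 0.01, 0.2), rnorm(50, 1000, 800)),
                seq(0, 1e5, 1e4))
  expect_true(all(diff(curve$probability) >= 0))
})

test_that("PSA increments recover the base case on average", {
  model <- toy_model(1, n_cycles = 24)
  base <- run_model(model)
  rr_idx <- which(vapply(model$strategy$effects, inherits, TRUE,
                         "transition_effect"))[1]
  priors <- list(
    parameter_prior("values/unit_wage", "gamma",
                    mean = get_param(model, "values/unit_wage"), se = 1.5),
    parameter_prior(paste0("strategy/effects/", rr_idx, "/rr"), "lognormal",
                    mean = get_param(model, paste0("strategy/effects/",
                                                   rr_idx, "/rr")),
                    se = 0.05)
  )
  psa <- run_psa(model, priors, n = 1000, seed = 21)
  se_q <- stats::sd(psa$draws$delta_qaly) / sqrt(psa$n)
  se_c <- stats::sd(psa$draws$delta_cost) / sqrt(psa$n)
  # lognormal rr enters the model nonlinearly, so allow the CLT band
  expect_lt(abs(mean(psa$draws$delta_qaly) - base$delta_qaly), 3 * se_q)
  expect_lt(abs(mean(psa$draws$delta_cost) - base$delta_cost), 3 * se_c)
})

test_that("tornado orders parameters by NMB swing and respects locality", {
  model <- toy_model(2, n_cycles = 60)
  rr_idx <- which(vapply(model$strategy$effects, inherits, TRUE,
                         "transition_effect"))[1]
  rr_path <- paste0("strategy/effects/", rr_idx, "/rr")
  wage <- get_param(model, "values/unit_wage")
  ranges <- list(
    list(path = "values/unit_wage", low = wage * 0.5, high = wage * 1.5),
    list(path = rr_path, low = get_param(model, rr_path) * 0.7, high = 1),
    # cohort starts mild and cannot regress; zero-width by construction
    list(path = "values/unit_wage", low = wage, high = wage)
  )
  tor <- tornado(model, ranges, wtp = 20000)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$width) <= 0))
  expect_equal(tor$width[3], 0)

  # ordering matches an independent recomputation of all six runs
  nmb_of <- function(path, v) {
    r <- run_model(set_param(model, path, v))
    20000 * r$delta_qaly - r$delta_cost
  }
  for (i in seq_len(nrow(tor))) {
    expect_equal(tor$nmb_low[i], nmb_of(tor$path[i], tor$low[i]),
                 tolerance = 1e-12)
    expect_equal(tor$nmb_high[i], nmb_of(tor$path[i], tor$high[i]),
                 tolerance = 1e-12)
  }
  expect_error(tornado(model, list(list(path = rr_path, low = 2, high = 3))),
               "low <= base <= high")
})

test_that("scenario bundles override parameters before validation", {
  model <- toy_model(3, n_cycles = 60)
  rr_idx <- which(vapply(model$strategy$effects, inherits, TRUE,
                         "transition_effect"))
  null_overrides <- c(
    stats::setNames(as.list(rep(1, length(rr_idx))),
                    paste0("strategy/effects/", rr_idx, "/rr")),
    lapply(stats::setNames(
      paste0("strategy/effects/",
             setdiff(seq_along(model$strategy$effects), rr_idx), "/delta"),
      paste0("strategy/effects/",
             setdiff(seq_along(model$strategy$effects), rr_idx), "/delta")),
      function(p) 0)
  )
  names(null_overrides) <- c(paste0("strategy/effects/", rr_idx, "/rr"),
                             paste0("strategy/effects/",
                                    setdiff(seq_along(model$strategy$effects),
                                            rr_idx), "/delta"))
  res <- run_scenarios(
    model,
    list(
      unchanged = list(),
      best = stats::setNames(
        list(get_param(model, paste0("strategy/effects/", rr_idx[1],
                                     "/rr")) * 0.7),
        paste0("strategy/effects/", rr_idx[1], "/rr")),
      worst = null_overrides
    ),
    wtp = 20000
  )
  expect_equal(res$scenario, c("base_case", "unchanged", "best", "worst"))
  # empty scenario equals the base case exactly
  expect_equal(res$delta_qaly[2], res$delta_qaly[1])
  expect_equal(res$delta_cost[2], res$delta_cost[1])
  # worst case: effects nulled, only the intervention cost remains
  expect_equal(res$delta_qaly[4], 0, tolerance = 1e-12)
  expect_gt(res$delta_cost[4], 0)
  expect_match(res$icer_label[4], "undefined")
  # best case is at least as good as worst at fixed WTP
  expect_gte(res$nmb[3], res$nmb[4])
})
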