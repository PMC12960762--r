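test_that("surrogate translation follows the link pathway and scale", {
  links <- default_surrogate_links()

  # the functional-ability exemplar: +1 ADCS-ADL point -> 0.008 utility
  adl <- surrogate_effect("adcs_adl", 1, follow_up_weeks = 8)
  eff <- translate_effect(adl, links$adcs_adl_to_utility)
  expect_s3_class(eff, "state_value_effect")
  expect_equal(eff$stream, "patient_utility")
  expect_equal(eff$delta, 0.008)

  # transition pathway is log-linear: burden -2 at 0.1 log-RR/point
  burden_link <- surrogate_link("caregiver_burden", "to_transition",
                                coefficient = 0.1,
                                target = c(from = "home_care",
                                           to = "institutional_care"))
  tr <- translate_effect(surrogate_effect("caregiver_burden", -2,
                                          follow_up_weeks = 6),
                         burden_link)
  expect_s3_class(tr, "transition_effect")
  expect_equal(tr$rr, exp(-0.2))

  # zero effect is the null on both scales
  expect_equal(translate_effect(surrogate_effect("adcs_adl", 0,
                                                 follow_up_weeks = 8),
                                links$adcs_adl_to_utility)$delta, 0)
  expect_equal(translate_effect(surrogate_effect("caregiver_burden", 0,
                                                 follow_up_weeks = 8),
                                burden_link)$rr, 1)

  # care-hours pathway
  hrs <- translate_effect(surrogate_effect("behavioral_symptoms", -2,
                                           follow_up_weeks = 4),
                          links$behavior_to_hours)
  expect_equal(hrs$stream, "informal_hours")
  expect_equal(hrs$delta, -0.6)

  # outcome mismatch is refused
  expect_error(translate_effect(adl, burden_link), "outcome mismatch")
})

test_that("translation is linear (log-linear for transitions) in effect size", {
  links <- default_surrogate_links()
  lin <- function(e) translate_effect(
    surrogate_effect("adcs_adl", e, follow_up_weeks = 8),
    links$adcs_adl_to_utility)$delta
  rr <- function(e) translate_effect(
    surrogate_effect("adcs_adl", e, follow_up_weeks = 8),
    links$adcs_adl_to_admission)$rr
  for (pair in list(c(1, 2), c(-0.5, 3), c(0.25, 0.75))) {
    expect_equal(lin(pair[1] + pair[2]), lin(pair[1]) + lin(pair[2]),
                 tolerance = 1e-15)
    expect_equal(rr(pair[1] + pair[2]), rr(pair[1]) * rr(pair[2]),
                 tolerance = 1e-12)
  }
})

test_that("double-counting guard flags duplicated pathways", {
  # direct QoL measured + surrogate-to-utility link enabled
  reg_a <- pathway_registry(
    data.frame(outcome = "adcs_adl", pathway = "to_utility"),
    direct_qol_measured = TRUE
  )
  chk_a <- check_double_counting(reg_a)
  expect_false(chk_a$ok)
  expect_match(chk_a$violations, "directly measured", all = FALSE)

  # same outcome on both utility and transition pathways
  reg_b <- pathway_registry(
    data.frame(outcome = c("adcs_adl", "adcs_adl"),
               pathway = c("to_utility", "to_transition"))
  )
  chk_b <- check_double_counting(reg_b)
  expect_false(chk_b$ok)
  expect_match(chk_b$violations, "both utility and transition", all = FALSE)

  # functional outcome feeding only transitions is fine, even with QoL
  reg_c <- pathway_registry(
    data.frame(outcome = "adcs_adl", pathway = "to_transition"),
    direct_qol_measured = TRUE
  )
  expect_true(check_double_counting(reg_c)$ok)
  expect_true(check_double_counting(pathway_registry())$ok)
})

test_that("assemble_strategy applies direct outcomes verbatim and
           composes transition effects multiplicatively", {
  elig <- c("mild|no_formal_care", "mild|home_care")

  # direct utility effect needs no link
  st <- assemble_strategy(
    effects = list(surrogate_effect("utility", 0.03, follow_up_weeks = 8)),
    registry = pathway_registry(),
    eligibility = elig, persistence_cycles = 6
  )
  expect_length(st$effects, 1)
  expect_equal(st$effects[[1]]$stream, "patient_utility")
  expect_equal(st$effects[[1]]$delta, 0.03)

  # no effects: a valid null strategy
  st0 <- assemble_strategy(effects = list(), registry = pathway_registry(),
                           eligibility = elig, persistence_cycles = 6)
  expect_length(st0$effects, 0)

  # two surrogate effects on the same transition compose on the rr scale
  reg <- pathway_registry(
    data.frame(outcome = c("adcs_adl", "caregiver_burden"),
               pathway = "to_transition")
  )
  st2 <- assemble_strategy(
    effects = list(surrogate_effect("adcs_adl", 2, follow_up_weeks = 8),
                   surrogate_effect("caregiver_burden", -3,
                                    follow_up_weeks = 8)),
    registry = reg, eligibility = elig, persistence_cycles = 6
  )
  trs <- Filter(function(e) inherits(e, "transition_effect"), st2$effects)
  expect_length(trs, 1)
  links <- default_surrogate_links()
  rr_seq <- exp(2 * links$adcs_adl_to_admission$coefficient) *
    exp(-3 * links$burden_to_admission$coefficient)
  expect_equal(trs[[1]]$rr, rr_seq, tolerance = 1e-14)

  # sequential application of the two rrs equals the composed one
  p0 <- 0.05
  seq_applied <- adjust_probability(
    adjust_probability(p0, exp(2 * links$adcs_adl_to_admission$coefficient)),
    exp(-3 * links$burden_to_admission$coefficient))
  expect_equal(adjust_probability(p0, trs[[1]]$rr), seq_applied,
               tolerance = 1e-14)

  # surrogate without an enabled pathway or link is refused
  expect_error(
    assemble_strategy(
      effects = list(surrogate_effect("caregiver_burden", -1,
                                      follow_up_weeks = 8)),
      registry = pathway_registry(),
      eligibility = elig, persistence_cycles = 6),
    "no enabled pathway")

  # a direct utility effect forces the direct-QoL double-counting check
  expect_error(
    assemble_strategy(
      effects = list(surrogate_effect("utility", 0.03, follow_up_weeks = 8),
                     surrogate_effect("adcs_adl", 1, follow_up_weeks = 8)),
      registry = pathway_registry(
        data.frame(outcome = "adcs_adl", pathway = "to_utility")),
      eligibility = elig, persistence_cycles = 6),
    "double-counting")
})

test_that("null pilot effects reproduce control exactly end to end", {
  spec <- fixture_spec(6, pilot_scale = 0)
  gen <- generate_parameter_set(spec)
  st <- assemble_strategy(
    effects = generate_pilot_effects(spec),
    registry = pathway_registry(
      data.frame(outcome = c("adcs_adl", "caregiver_burden"),
                 pathway = "to_transition"),
      direct_qol_measured = TRUE),
    eligibility = c("mild|no_formal_care", "mild|home_care"),
    persistence_cycles = 12, intervention_cost = 0
  )
  settings <- analysis_settings(n_cycles = 120)
  ctrl <- evaluate_strategy(gen$params, gen$values, settings = settings)
  trt <- evaluate_strategy(gen$params, gen$values, st, settings = settings)
  expect_identical(ctrl$trace$occupancy, trt$trace$occupancy)
  expect_identical(ctrl$qalys, trt$qalys)
  expect_identical(ctrl$costs, trt$costs)
})
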