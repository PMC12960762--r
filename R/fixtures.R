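#' Specification for synthetic parameter and pilot-effect fixtures
#'
#' The generators emulate the structure the dementia care pathway is
#' known to have — utility declining with severity, total cost rising
#' steeply with care intensity, mortality and institutionalization risk
#' rising with severity — without reproducing any registry's values.
#' All magnitudes are ILLUSTRATIVE defaults; gradient strengths scale
#' the built-in baselines.
#'
#' @param seed Integer seed; the generators are deterministic given it.
#' @param utility_decline Utility lost per severity step (per year).
#' @param care_utility_penalty Utility lost per care-intensity step.
#' @param cost_rise Multiplier shaping the cost gradient over care
#'   settings (>= 1).
#' @param mortality_rise Multiplier on death risk per severity step
#'   (>= 1).
#' @param care_gradient Multiplier on care-transition risk per severity
#'   step (>= 1).
#' @param pilot_scale Scales all pilot effect magnitudes (0 gives all
#'   null effects).
#' @param pilot_se_scale Scales pilot standard errors (small-pilot
#'   noise).
#' @param jitter Relative jitter applied to every generated magnitude.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         utility_decline = 0.18,
                         care_utility_penalty = 0.025,
                         cost_rise = 2.0,
                         mortality_rise = 1.8,
                         care_gradient = 2.0,
                         pilot_scale = 1,
                         pilot_se_scale = 1,
                         jitter = 0.05) {
  stopifnot(utility_decline >= 0, care_utility_penalty >= 0,
            cost_rise >= 0, mortality_rise >= 0, care_gradient >= 0,
            pilot_scale >= 0, pilot_se_scale >= 0,
            jitter >= 0, jitter < 0.5)
  structure(
    list(seed = as.integer(seed), utility_decline = utility_decline,
         care_utility_penalty = care_utility_penalty, cost_rise = cost_rise,
         mortality_rise = mortality_rise, care_gradient = care_gradient,
         pilot_scale = pilot_scale, pilot_se_scale = pilot_se_scale,
         jitter = jitter),
    class = "fixture_spec"
  )
}

#' Generate a structurally valid baseline parameter set and state values
#'
#' Guaranteed orderings (strict where stated): patient utility decreases
#' with severity within each care setting; total annual cost (formal
#' plus valued informal care) increases with care intensity within each
#' severity; death risk is non-decreasing in severity; the risk of
#' moving toward institutional care is non-decreasing in severity.
#' Monotonicity is enforced by jittering positive increments and
#' cumulating them, so it holds for every seed. Probabilities are per
#' monthly cycle.
#'
#' @param spec A [fixture_spec()].
#' @return List with `params` ([baseline_parameters()]) and `values`
#'   ([state_values()]).
#' @export
generate_parameter_set <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    jit <- function(x) x * stats::runif(length(x), 1 - spec$jitter,
                                        1 + spec$jitter)
    inc_cum <- function(base, incs) cumsum(c(jit(base), jit(incs)))

    p_progress <- c(mild_to_moderate = jit(0.015),
                    moderate_to_severe = jit(0.012))

    # death: severity gradient built from positive increments, scaled by
    # a care multiplier constant across severities
    death_sev <- inc_cum(0.0025, 0.0025 * (spec$mortality_rise - 1) * c(1, 1.6))
    care_mult <- c(1, jit(1.08), jit(1.22))
    p_death <- outer(death_sev, care_mult)
    dimnames(p_death) <- list(severity = severity_levels(),
                              care = care_levels())

    # care transitions, rising with severity via cumulated increments
    g <- max(spec$care_gradient - 1, 0)
    p_care <- zero_care_array()
    p_care[, "no_formal_care", "home_care"] <-
      inc_cum(0.010, 0.010 * g * c(1, 1.4))
    p_care[, "no_formal_care", "institutional_care"] <-
      inc_cum(0.002, 0.002 * g * c(1, 2.5))
    p_care[, "home_care", "institutional_care"] <-
      inc_cum(0.004, 0.004 * g * c(1.5, 3))

    params <- baseline_parameters(
      p_progress = p_progress, p_care = p_care, p_death = p_death,
      cycle_length = 1 / 12
    )

    # utilities: strict severity decline, mild care penalty
    sev_drop <- inc_cum(0, rep(spec$utility_decline, 2))
    care_drop <- inc_cum(0, rep(spec$care_utility_penalty, 2))
    u <- pmax(outer(jit(0.82) - sev_drop, rep(1, 3)) -
                matrix(care_drop, 3, 3, byrow = TRUE), 0.05)

    cg <- -(outer(inc_cum(0.02, c(0.02, 0.02)), c(1, jit(1.3), 0)) +
              matrix(c(0, 0, 0.015), 3, 3, byrow = TRUE))

    cost_step <- max(spec$cost_rise, 1)
    formal <- outer(c(1, jit(1.2), jit(1.4)),
                    c(jit(1200), jit(9000) * cost_step,
                      jit(30000) * cost_step^1.5))
    hours <- cbind(jit(c(12, 20, 30)), jit(c(10, 16, 24)), jit(c(1, 1.5, 2)))

    flat <- function(m) {  # severity-major flatten matching living_states()
      stats::setNames(as.vector(t(m)), living_states())
    }
    values <- state_values(
      patient_utility = flat(u),
      caregiver_utility_delta = flat(cg),
      formal_cost = flat(formal),
      informal_hours = flat(hours),
      unit_wage = jit(15),
      currency = "EUR"
    )
    list(params = params, values = values)
  })
}

#' Generate pilot-study effect estimates for the implemented outcomes
#'
#' Emits one [surrogate_effect()] per outcome in the implemented list
#' (utility, caregiving hours, resource use, admission risk, ADCS-ADL,
#' behavioral symptoms, caregiver burden), with follow-up lengths drawn
#' uniformly in 2-12 weeks and standard errors at small-pilot
#' magnitudes. Effect sizes scale with `pilot_scale` (0 gives all-null
#' effects); for `admission_risk` the effect is a log relative risk, so
#' 0 is the null there too.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of [surrogate_effect()] objects.
#' @export
generate_pilot_effects <- function(spec = fixture_spec()) {
  base <- c(
    utility = 0.02,
    caregiving_hours = -2.0,
    resource_use = -400,
    admission_risk = -0.10,       # log relative risk
    adcs_adl = 1.2,
    behavioral_symptoms = -1.5,
    caregiver_burden = -3.0
  )
  with_seed(spec$seed + 1L, {
    jit <- function(x) x * stats::runif(length(x), 1 - spec$jitter,
                                        1 + spec$jitter)
    out <- lapply(names(base), function(o) {
      eff <- jit(base[[o]]) * spec$pilot_scale
      surrogate_effect(
        outcome = o,
        effect = eff,
        se = (abs(base[[o]]) / 1.5) * spec$pilot_se_scale,
        follow_up_weeks = stats::runif(1, 2, 12)
      )
    })
    stats::setNames(out, names(base))
  })
}

#' A complete illustrative model: parameters, values, strategy, settings
#'
#' Convenience wrapper assembling a full [ce_model()] from the fixture
#' generators: the usual-care baseline, a technology strategy built from
#' pilot effects through non-conflicting surrogate pathways (ADCS-ADL
#' and caregiver burden to institutionalization risk; utility,
#' caregiving hours and resource use applied directly), eligibility in
#' mild/moderate community states, two years of persistence, and an
#' intervention cost of 1200 per year.
#'
#' @param seed Integer seed passed to [fixture_spec()].
#' @param ... Further arguments to [fixture_spec()].
#' @return A [ce_model()].
#' @export
fixture_model <- function(seed = 1L, ...) {
  spec <- fixture_spec(seed = seed, ...)
  gen <- generate_parameter_set(spec)
  pilot <- generate_pilot_effects(spec)

  registry <- pathway_registry(
    pairs = data.frame(
      outcome = c("adcs_adl", "caregiver_burden", "behavioral_symptoms"),
      pathway = c("to_transition", "to_transition", "to_care_hours"),
      stringsAsFactors = FALSE
    ),
    direct_qol_measured = TRUE  # utility is in the pilot outcome set
  )
  eligibility <- c("mild|no_formal_care", "mild|home_care",
                   "moderate|no_formal_care", "moderate|home_care")
  strat <- assemble_strategy(
    effects = pilot,
    links = default_surrogate_links(),
    registry = registry,
    eligibility = eligibility,
    persistence_cycles = 24L,
    intervention_cost = 1200,
    name = "care_technology"
  )
  ce_model(params = gen$params, values = gen$values, strategy = strat,
           settings = analysis_settings(cycle_length = gen$params$cycle_length))
}
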