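#' A short-term pilot effect estimate on an outcome
#'
#' Early technology evidence typically comes from small, short
#' (2-12 week) pilot studies measuring outcomes close to the
#' intervention's target domain: utility, caregiving hours, resource
#' use, admission risk (directly applicable), or surrogate scales such
#' as ADCS-ADL, behavioral symptoms and caregiver burden (which must be
#' mapped onto model parameters through a [surrogate_link()]).
#'
#' Effect sizes are in the outcome's own units and signed; for
#' `admission_risk` the effect is a log relative risk so that 0 is the
#' null for every outcome.
#'
#' @param outcome Outcome name (e.g. `"adcs_adl"`, `"caregiver_burden"`,
#'   `"utility"`, `"caregiving_hours"`).
#' @param effect Signed effect size in the outcome's units.
#' @param se Standard error (same units), optional.
#' @param follow_up_weeks Pilot follow-up length in weeks (> 0).
#' @return An object of class `surrogate_effect`.
#' @export
surrogate_effect <- function(outcome, effect, se = NULL, follow_up_weeks) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.numeric(effect), length(effect) == 1L,
            follow_up_weeks > 0)
  if (!is.null(se) && se < 0) stop("se must be >= 0")
  structure(list(outcome = outcome, effect = effect, se = se,
                 follow_up_weeks = follow_up_weeks),
            class = "surrogate_effect")
}

#' A literature link mapping a surrogate outcome onto a model parameter
#'
#' Exactly one pathway per link: `to_utility` (utility points per unit
#' of the outcome), `to_transition` (log relative risk per unit, applied
#' to a named care transition), or `to_care_hours` (informal hours/week
#' per unit). Coefficients are data, not code: each link carries a
#' citation label.
#'
#' @param outcome Outcome name the link translates.
#' @param pathway One of `"to_utility"`, `"to_transition"`,
#'   `"to_care_hours"`.
#' @param coefficient Per-unit mapping coefficient (finite).
#' @param target For `to_transition`: `c(from =, to =)` care settings;
#'   ignored otherwise.
#' @param source Citation label for the coefficient.
#' @return An object of class `surrogate_link`.
#' @export
surrogate_link <- function(outcome,
                           pathway = c("to_utility", "to_transition",
                                       "to_care_hours"),
                           coefficient, target = NULL, source = "") {
  pathway <- match.arg(pathway)
  if (!is.finite(coefficient)) stop("coefficient must be finite")
  if (pathway == "to_transition") {
    if (is.null(target) || !all(c("from", "to") %in% names(target))) {
      stop("to_transition links need target = c(from =, to =)")
    }
    if (!all(unlist(target[c("from", "to")]) %in% care_levels())) {
      stop("target must name care settings")
    }
  }
  structure(list(outcome = outcome, pathway = pathway,
                 coefficient = coefficient, target = target, source = source),
            class = "surrogate_link")
}

#' Exemplar surrogate links shipped with the package
#'
#' The functional-ability link is the literature-cited exemplar: one
#' ADCS-ADL point corresponds to a utility gain of 0.008. The remaining
#' links (ADCS-ADL and caregiver burden to institutionalization risk,
#' behavioral symptoms to caregiving hours) carry ILLUSTRATIVE
#' coefficients for fixtures and examples, labeled as such.
#'
#' @return Named list of [surrogate_link()] objects.
#' @export
default_surrogate_links <- function() {
  list(
    adcs_adl_to_utility = surrogate_link(
      "adcs_adl", "to_utility", coefficient = 0.008,
      source = "mapping of ADCS-ADL onto utility-based quality of life (0.008/point)"
    ),
    adcs_adl_to_admission = surrogate_link(
      "adcs_adl", "to_transition", coefficient = -0.05,
      target = c(from = "home_care", to = "institutional_care"),
      source = "ILLUSTRATIVE: functional ability vs nursing-home placement risk"
    ),
    burden_to_admission = surrogate_link(
      "caregiver_burden", "to_transition", coefficient = 0.08,
      target = c(from = "home_care", to = "institutional_care"),
      source = "ILLUSTRATIVE: caregiver burden / perseverance time vs placement risk"
    ),
    behavior_to_hours = surrogate_link(
      "behavioral_symptoms", "to_care_hours", coefficient = 0.3,
      source = "ILLUSTRATIVE: behavioral symptoms vs informal care hours"
    )
  )
}

#' Translate a pilot effect through a surrogate link
#'
#' `to_utility` and `to_care_hours` links are linear in the effect size
#' (delta = effect x coefficient); `to_transition` links are log-linear
#' (`rr = exp(effect x coefficient)`), so effects compose
#' multiplicatively on the relative-risk scale.
#'
#' @param effect A [surrogate_effect()].
#' @param link A [surrogate_link()] for the same outcome.
#' @return A [state_value_effect()] or [transition_effect()].
#' @examples
#' # one ADCS-ADL point of functional improvement as a utility gain
#' translate_effect(
#'   surrogate_effect("adcs_adl", 1, follow_up_weeks = 8),
#'   default_surrogate_links()$adcs_adl_to_utility
#' )$delta  # 0.008
#' @export
translate_effect <- function(effect, link) {
  if (!identical(effect$outcome, link$outcome)) {
    stop("outcome mismatch: effect is '", effect$outcome,
         "', link translates '", link$outcome, "'")
  }
  switch(
    link$pathway,
    to_utility = state_value_effect("patient_utility",
                                    delta = effect$effect * link$coefficient),
    to_care_hours = state_value_effect("informal_hours",
                                       delta = effect$effect * link$coefficient),
    to_transition = transition_effect(
      from = link$target[["from"]], to = link$target[["to"]],
      rr = exp(effect$effect * link$coefficient)
    )
  )
}

#' Registry of enabled (outcome, pathway) pairs for a strategy
#'
#' @param pairs Data frame with columns `outcome` and `pathway`, one row
#'   per enabled surrogate pathway. May be empty.
#' @param direct_qol_measured Was quality of life measured directly
#'   (e.g. EQ-5D) in the pilot?
#' @return An object of class `pathway_registry`.
#' @export
pathway_registry <- function(pairs = data.frame(outcome = character(),
                                                pathway = character()),
                             direct_qol_measured = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("outcome", "pathway") %in% names(pairs)))
  ok <- pairs$pathway %in% c("to_utility", "to_transition", "to_care_hours")
  if (!all(ok)) stop("unknown pathway: ", paste(pairs$pathway[!ok], collapse = ", "))
  structure(list(pairs = pairs,
                 direct_qol_measured = isTRUE(direct_qol_measured)),
            class = "pathway_registry")
}

#' Check a pathway registry for double counting
#'
#' Two configurations duplicate an effect: (a) quality of life is
#' directly measured while a surrogate-to-utility link is also enabled
#' (the surrogate would re-count the measured QoL change); (b) the same
#' outcome feeds both a utility pathway and a transition pathway
#' (conflating QoL decline from e.g. functional loss with QoL change
#' from delayed institutionalization). Functional or behavioral
#' outcomes feeding only transitions are always acceptable.
#'
#' @param registry A [pathway_registry()].
#' @return List with logical `ok` and character `violations`.
#' @export
check_double_counting <- function(registry) {
  v <- character()
  p <- registry$pairs
  if (registry$direct_qol_measured && any(p$pathway == "to_utility")) {
    bad <- unique(p$outcome[p$pathway == "to_utility"])
    v <- c(v, sprintf(
      "quality of life is directly measured; surrogate-to-utility link for '%s' would duplicate the effect",
      bad))
  }
  for (o in unique(p$outcome)) {
    pw <- unique(p$pathway[p$outcome == o])
    if (all(c("to_utility", "to_transition") %in% pw)) {
      v <- c(v, sprintf(
        "outcome '%s' feeds both utility and transition pathways", o))
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

# outcomes that map onto model parameters without a link
direct_outcomes <- function() {
  c("utility", "caregiving_hours", "resource_use", "admission_risk")
}

#' Assemble a strategy from pilot effects and surrogate links
#'
#' Directly-applicable outcomes (utility, caregiving hours, resource
#' use, admission risk) become model effects verbatim; every other
#' outcome must pass through a matching [surrogate_link()]. Multiple
#' transition effects landing on the same transition compose
#' multiplicatively on the relative-risk scale. The registry must pass
#' [check_double_counting()].
#'
#' @param effects List of [surrogate_effect()] objects.
#' @param links Named list of [surrogate_link()] objects to translate
#'   non-direct outcomes (an outcome uses every link whose
#'   `(outcome, pathway)` pair is enabled in the registry).
#' @param registry A [pathway_registry()] enabling pathways. When a
#'   direct utility effect is present, the check is run with
#'   `direct_qol_measured = TRUE` regardless of the registry's flag.
#' @param eligibility,persistence_cycles,intervention_cost,waning,waning_cycles
#'   Passed to [strategy()].
#' @param name Strategy label.
#' @return A [strategy()] object.
#' @export
assemble_strategy <- function(effects, links = default_surrogate_links(),
                              registry = pathway_registry(),
                              eligibility, persistence_cycles,
                              intervention_cost = 0,
                              waning = "none", waning_cycles = 0L,
                              name = "technology") {
  if (any(vapply(effects, function(e) e$outcome == "utility", TRUE))) {
    registry$direct_qol_measured <- TRUE
  }
  chk <- check_double_counting(registry)
  if (!chk$ok) {
    stop("double-counting violation:\n",
         paste0("  - ", chk$violations, collapse = "\n"))
  }

  model_effects <- list()
  for (e in effects) {
    if (e$effect == 0) next
    if (e$outcome %in% direct_outcomes()) {
      me <- switch(
        e$outcome,
        utility = state_value_effect("patient_utility", delta = e$effect),
        caregiving_hours = state_value_effect("informal_hours",
                                              delta = e$effect),
        resource_use = state_value_effect("formal_cost", delta = e$effect),
        # effect is a log relative risk of institutionalization
        admission_risk = transition_effect("home_care", "institutional_care",
                                           rr = exp(e$effect))
      )
      model_effects <- c(model_effects, list(me))
    } else {
      enabled <- registry$pairs[registry$pairs$outcome == e$outcome, ,
                                drop = FALSE]
      if (nrow(enabled) == 0L) {
        stop("surrogate outcome '", e$outcome,
             "' has no enabled pathway in the registry")
      }
      for (i in seq_len(nrow(enabled))) {
        match_link <- Filter(function(l) {
          l$outcome == e$outcome && l$pathway == enabled$pathway[i]
        }, links)
        if (length(match_link) == 0L) {
          stop("no surrogate link for outcome '", e$outcome,
               "' on pathway '", enabled$pathway[i], "'")
        }
        for (l in match_link) {
          model_effects <- c(model_effects, list(translate_effect(e, l)))
        }
      }
    }
  }
  model_effects <- compose_transition_effects(model_effects)
  strategy(name = name, effects = model_effects, eligibility = eligibility,
           persistence_cycles = persistence_cycles, waning = waning,
           waning_cycles = waning_cycles, intervention_cost = intervention_cost)
}

# merge transition effects sharing a target by multiplying their rr
# (rate additivity under an independence assumption)
compose_transition_effects <- function(effects) {
  is_tr <- vapply(effects, inherits, TRUE, "transition_effect")
  trs <- effects[is_tr]
  if (length(trs) <= 1L) return(effects)
  key <- vapply(trs, function(e) {
    paste(e$from, e$to, paste(sort(e$severity %||% "all"), collapse = "+"),
          sep = "|")
  }, "")
  merged <- lapply(split(trs, key), function(group) {
    out <- group[[1L]]
    out$rr <- prod(vapply(group, `[[`, 1.0, "rr"))
    out
  })
  c(effects[!is_tr], unname(merged))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
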