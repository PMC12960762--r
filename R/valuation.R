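#' Per-state annual values: utilities, costs, informal-care hours
#'
#' Each living state carries a mean patient utility (per year), a
#' caregiver utility increment attributable to the caregiving situation
#' (per year, usually negative, one caregiver per patient, ceasing at
#' patient death), an annual formal care cost, and weekly informal-care
#' hours valued at a single opportunity-cost wage. Death carries
#' all-zero values.
#'
#' Vectors may be length 1 (recycled over the nine living states) or
#' length 9; when named they are matched to [living_states()] by name.
#'
#' @param patient_utility Utility per year, in `[-1, 1]`.
#' @param caregiver_utility_delta Caregiver utility increment per year,
#'   in `[-1, 1]`.
#' @param formal_cost Formal care cost per year (currency, >= 0).
#' @param informal_hours Informal care hours per week (>= 0).
#' @param unit_wage Wage per hour used to value informal care (>= 0).
#' @param currency Currency label (bookkeeping only).
#' @return An object of class `state_values`.
#' @export
state_values <- function(patient_utility,
                         caregiver_utility_delta = 0,
                         formal_cost = 0,
                         informal_hours = 0,
                         unit_wage = 0,
                         currency = "EUR") {
  expand <- function(x, what) {
    ls <- living_states()
    if (!is.null(names(x))) {
      unknown <- setdiff(names(x), ls)
      if (length(unknown)) {
        stop(what, ": unknown state name(s): ", paste(unknown, collapse = ", "))
      }
      out <- stats::setNames(rep(0, 9L), ls)
      out[names(x)] <- x
      return(out)
    }
    if (length(x) == 1L) x <- rep(x, 9L)
    if (length(x) != 9L) stop(what, " must have length 1 or 9, or be named")
    stats::setNames(as.numeric(x), ls)
  }
  v <- structure(
    list(
      patient_utility = expand(patient_utility, "patient_utility"),
      caregiver_utility_delta = expand(caregiver_utility_delta,
                                       "caregiver_utility_delta"),
      formal_cost = expand(formal_cost, "formal_cost"),
      informal_hours = expand(informal_hours, "informal_hours"),
      unit_wage = unit_wage,
      currency = currency
    ),
    class = "state_values"
  )
  validate_values(v)
  v
}

validate_values <- function(v) {
  if (any(abs(v$patient_utility) > 1)) {
    stop("patient_utility outside [-1, 1]")
  }
  if (any(abs(v$caregiver_utility_delta) > 1)) {
    stop("caregiver_utility_delta outside [-1, 1]")
  }
  if (any(v$formal_cost < 0)) stop("formal_cost must be >= 0")
  if (any(v$informal_hours < 0)) stop("informal_hours must be >= 0")
  if (v$unit_wage < 0) stop("unit_wage must be >= 0")
  invisible(v)
}

# map a per-living-state vector onto the 10-state ordering (death = 0)
values_to_weights <- function(x) c(x, 0)

# stack per-cycle value vectors into the weight matrix accumulate_stream
# expects; `per_cycle` is a list of length-9 vectors (one per cycle)
stack_weights <- function(per_cycle) {
  do.call(rbind, lapply(per_cycle, values_to_weights))
}

#' Discounted QALYs from a cohort trace
#'
#' Per-cycle contribution is the occupancy-weighted utility times the
#' cycle length, discounted and half-cycle-corrected exactly as in
#' [life_years()]. The caregiver stream is computed identically from
#' `caregiver_utility_delta` and reported separately.
#'
#' @param trace A `cohort_trace` over the canonical 10 states.
#' @param values A [state_values()] object.
#' @param discount_rate Annual discount rate for effects.
#' @param half_cycle Apply the half-cycle correction.
#' @param include_caregiver Compute the caregiver stream (else 0).
#' @param values_by_cycle Optional list of `state_values`, one per
#'   cycle, overriding `values` cycle by cycle (used while intervention
#'   effects on state values are active).
#' @return List with `patient` and `caregiver` QALYs.
#' @export
accumulate_qalys <- function(trace, values, discount_rate = 0.015,
                             half_cycle = TRUE, include_caregiver = TRUE,
                             values_by_cycle = NULL) {
  if (is.null(values_by_cycle)) {
    w_pat <- values_to_weights(values$patient_utility)
    w_cg <- values_to_weights(values$caregiver_utility_delta)
  } else {
    w_pat <- stack_weights(lapply(values_by_cycle, `[[`, "patient_utility"))
    w_cg <- stack_weights(lapply(values_by_cycle, `[[`,
                                 "caregiver_utility_delta"))
  }
  list(
    patient = accumulate_stream(trace, w_pat, discount_rate, half_cycle),
    caregiver = if (include_caregiver) {
      accumulate_stream(trace, w_cg, discount_rate, half_cycle)
    } else 0
  )
}

#' Discounted societal costs from a cohort trace
#'
#' Formal costs accrue per occupancy at the annual state cost; informal
#' care accrues as `hours/week * 52.18 * wage` per year of occupancy
#' (societal perspective); the intervention stream, when given, is a
#' per-cycle currency amount already pro-rated to the cycle (see
#' [intervention_cost_stream()]) and is discounted with the same
#' `(1 + rate)^(-t * cycle_length)` factors but without half-cycle
#' correction (it is an accrual over the cycle, not a boundary stock).
#'
#' @inheritParams accumulate_qalys
#' @param intervention_stream Optional numeric vector, one undiscounted
#'   cost per cycle.
#' @param discount_rate Annual discount rate for costs.
#' @return List with `formal`, `informal`, `intervention`, `total`.
#' @export
accumulate_costs <- function(trace, values, intervention_stream = NULL,
                             discount_rate = 0.04, half_cycle = TRUE,
                             values_by_cycle = NULL) {
  informal_annual <- function(v) {
    v$informal_hours * WEEKS_PER_YEAR * v$unit_wage
  }
  if (is.null(values_by_cycle)) {
    w_formal <- values_to_weights(values$formal_cost)
    w_informal <- values_to_weights(informal_annual(values))
  } else {
    w_formal <- stack_weights(lapply(values_by_cycle, `[[`, "formal_cost"))
    w_informal <- stack_weights(lapply(values_by_cycle, informal_annual))
  }
  formal <- accumulate_stream(trace, w_formal, discount_rate, half_cycle)
  informal <- accumulate_stream(trace, w_informal, discount_rate, half_cycle)
  intervention <- 0
  if (!is.null(intervention_stream)) {
    if (any(intervention_stream < 0)) stop("intervention costs must be >= 0")
    n <- nrow(trace$occupancy) - 1L
    if (length(intervention_stream) != n) {
      stop("intervention_stream must have one entry per cycle")
    }
    cl <- trace$cycle_length
    disc <- (1 + discount_rate)^(-(seq_len(n)) * cl)
    intervention <- sum(intervention_stream * disc)
  }
  list(formal = formal, informal = informal, intervention = intervention,
       total = formal + informal + intervention)
}

#' Analysis settings shared by the strategies being compared
#'
#' Defaults follow the Dutch guideline context: effects discounted at
#' 1.5%/year and costs at 4%/year, half-cycle correction on, a 40-year
#' horizon, and a willingness-to-pay grid from 0 to 100,000 per QALY.
#'
#' @param cycle_length Cycle duration in years.
#' @param horizon_years Maximum horizon in years (realizes "lifetime").
#' @param n_cycles Number of cycles; default `horizon_years / cycle_length`.
#' @param discount_qaly,discount_cost Annual discount rates.
#' @param half_cycle Apply the half-cycle correction.
#' @param include_caregiver Include the caregiver QALY stream.
#' @param wtp_grid Willingness-to-pay grid (currency per QALY).
#' @return A list of class `analysis_settings`.
#' @export
analysis_settings <- function(cycle_length = 1 / 12,
                              horizon_years = 40,
                              n_cycles = NULL,
                              discount_qaly = 0.015,
                              discount_cost = 0.04,
                              half_cycle = TRUE,
                              include_caregiver = TRUE,
                              wtp_grid = seq(0, 100000, by = 20000)) {
  if (is.null(n_cycles)) n_cycles <- as.integer(round(horizon_years / cycle_length))
  structure(
    list(cycle_length = cycle_length, n_cycles = as.integer(n_cycles),
         discount_qaly = discount_qaly, discount_cost = discount_cost,
         half_cycle = half_cycle, include_caregiver = include_caregiver,
         wtp_grid = wtp_grid),
    class = "analysis_settings"
  )
}

default_init <- function() {
  init <- stats::setNames(rep(0, 10L), state_names())
  init[["mild|no_formal_care"]] <- 1
  init
}

#' Run one strategy (or usual care) and value the trace
#'
#' Builds the per-cycle transition matrices (baseline, or modified by
#' the strategy while its effects persist), runs the cohort, and
#' accumulates discounted QALYs and costs. With `strategy = NULL` (or a
#' strategy with no effects and zero cost) this is the usual-care arm.
#'
#' @param params A [baseline_parameters()] object.
#' @param values A [state_values()] object.
#' @param strategy A [strategy()] object, or NULL for usual care.
#' @param init Initial distribution over the 10 states (default: all
#'   mass in mild dementia with no formal care).
#' @param settings An [analysis_settings()] object; its `cycle_length`
#'   is taken from `params`.
#' @return An object of class `strategy_outcome`: trace, QALY and cost
#'   breakdowns, and the settings used.
#' @export
evaluate_strategy <- function(params, values, strategy = NULL,
                              init = default_init(),
                              settings = analysis_settings(params$cycle_length)) {
  settings$cycle_length <- params$cycle_length
  n <- settings$n_cycles
  base_matrix <- build_cycle_matrix(params)

  active <- 0L
  if (!is.null(strategy)) {
    active <- min(n, strategy$persistence_cycles +
                    if (strategy$waning == "linear") strategy$waning_cycles else 0L)
  }
  has_value_effects <- active > 0L &&
    any(vapply(strategy$effects, inherits, TRUE, "state_value_effect"))

  matrices <- vector("list", n)
  values_by_cycle <- NULL
  if (active > 0L) {
    if (has_value_effects) values_by_cycle <- rep(list(values), n)
    for (t in seq_len(active)) {
      eff <- build_strategy_parameters(params, values, strategy, t - 1L)
      matrices[[t]] <- if (identical(eff$params, params)) base_matrix else {
        build_cycle_matrix(eff$params)
      }
      if (has_value_effects) values_by_cycle[[t]] <- eff$values
    }
  }
  if (active < n) for (t in (active + 1L):n) matrices[[t]] <- base_matrix
  if (has_value_effects &&
      all(vapply(values_by_cycle, identical, TRUE, values))) {
    values_by_cycle <- NULL  # effects were numerically null
  }

  trace <- run_cohort(matrices, init, n_cycles = n,
                      cycle_length = params$cycle_length)
  q <- accumulate_qalys(trace, values,
                        discount_rate = settings$discount_qaly,
                        half_cycle = settings$half_cycle,
                        include_caregiver = settings$include_caregiver,
                        values_by_cycle = values_by_cycle)
  stream <- if (!is.null(strategy)) {
    intervention_cost_stream(strategy, trace)
  } else NULL
  costs <- accumulate_costs(trace, values, intervention_stream = stream,
                            discount_rate = settings$discount_cost,
                            half_cycle = settings$half_cycle,
                            values_by_cycle = values_by_cycle)
  structure(
    list(
      name = if (is.null(strategy)) "usual_care" else strategy$name,
      trace = trace,
      qalys = list(patient = q$patient, caregiver = q$caregiver,
                   total = q$patient + q$caregiver),
      costs = costs,
      settings = settings
    ),
    class = "strategy_outcome"
  )
}

#' Compare an intervention strategy against control
#'
#' Computes incremental discounted costs and QALYs, the ICER (or a
#' dominance label when a ratio is not informative), and net monetary
#' benefit over a willingness-to-pay grid. Both outcomes must have been
#' produced under identical analysis settings.
#'
#' @param control,intervention `strategy_outcome` objects from
#'   [evaluate_strategy()].
#' @param wtp_grid Willingness-to-pay grid; defaults to the grid in the
#'   shared settings.
#' @return An object of class `cea_result`.
#' @export
compare_strategies <- function(control, intervention, wtp_grid = NULL) {
  if (!identical(control$settings, intervention$settings)) {
    stop("strategies were run under different analysis settings")
  }
  if (is.null(wtp_grid)) wtp_grid <- control$settings$wtp_grid
  dq <- intervention$qalys$total - control$qalys$total
  dc <- intervention$costs$total - control$costs$total
  if (abs(dq) > 1e-12) {
    icer <- dc / dq
    label <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "ICER"
  } else {
    icer <- NA_real_
    label <- "undefined (zero QALY difference)"
  }
  nmb <- wtp_grid * dq - dc
  structure(
    list(
      control = control, intervention = intervention,
      delta_qaly = dq, delta_cost = dc,
      delta_qaly_patient = intervention$qalys$patient - control$qalys$patient,
      delta_qaly_caregiver = intervention$qalys$caregiver - control$qalys$caregiver,
      icer = icer, icer_label = label,
      nmb = data.frame(wtp = wtp_grid, nmb = nmb)
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 4)
  cat("Cost-effectiveness comparison:",
      x$intervention$name, "vs", x$control$name, "\n")
  cat(sprintf("  %-14s %12s %12s\n", "", x$control$name, x$intervention$name))
  row <- function(lbl, a, b, digits = 2) {
    cat(sprintf("  %-14s %12s %12s\n", lbl,
                formatC(a, format = "f", digits = digits),
                formatC(b, format = "f", digits = digits)))
  }
  row("QALY patient", x$control$qalys$patient, x$intervention$qalys$patient, 4)
  row("QALY caregiver", x$control$qalys$caregiver,
      x$intervention$qalys$caregiver, 4)
  row("cost formal", x$control$costs$formal, x$intervention$costs$formal)
  row("cost informal", x$control$costs$informal, x$intervention$costs$informal)
  row("cost interv.", x$control$costs$intervention,
      x$intervention$costs$intervention)
  row("cost total", x$control$costs$total, x$intervention$costs$total)
  cat(sprintf("  delta QALY: %s   delta cost: %s\n",
              fmt(x$delta_qaly), formatC(x$delta_cost, format = "f", digits = 2)))
  if (x$icer_label == "ICER") {
    cat(sprintf("  ICER: %s per QALY\n",
                formatC(x$icer, format = "f", digits = 0)))
  } else {
    cat("  ICER:", x$icer_label, "\n")
  }
  for (i in seq_len(nrow(x$nmb))) {
    cat(sprintf("  NMB @ WTP %-7s %s\n",
                formatC(x$nmb$wtp[i], format = "d"),
                formatC(x$nmb$nmb[i], format = "f", digits = 2)))
  }
  invisible(x)
}
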