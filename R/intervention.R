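#' Apply a relative risk to a per-cycle probability on the rate scale
#'
#' The reported relative risk is treated as a hazard ratio under a
#' cycle-constant rate: `p_adj = 1 - (1 - p)^rr`. Unlike naive
#' multiplication `p * rr`, the result is a valid probability in
#' `[0, 1)` for any `rr > 0`, reduces to `p` at `rr = 1`, and is
#' strictly monotone in `rr` for `p` in `(0, 1)`.
#'
#' @param p Per-cycle probability in `[0, 1)` (`p = 1` only with `rr = 1`).
#' @param rr Relative risk, `> 0`.
#' @return Adjusted probability, same length as `p`.
#' @examples
#' adjust_probability(0.3, 0.5)  # 1 - 0.7^0.5
#' @export
adjust_probability <- function(p, rr) {
  if (any(rr <= 0)) stop("rr must be > 0")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(p == 1 & rr != 1)) stop("p = 1 cannot be adjusted by rr != 1")
  n <- max(length(p), length(rr))
  p <- rep_len(p, n)
  rr <- rep_len(rr, n)
  out <- -expm1(rr * log1p(-p))
  # p < 1 maps below 1 mathematically; keep it so under underflow
  out[p < 1 & out >= 1] <- 1 - .Machine$double.eps / 2
  out[rr == 1] <- p[rr == 1]  # the identity must hold exactly
  out
}

#' A relative-risk effect on one care transition
#'
#' @param from,to Care settings naming the targeted transition (e.g.
#'   home care to institutional care). Must be distinct; `to` must be a
#'   more intensive setting than `from` unless the baseline allows care
#'   reversal.
#' @param rr Relative risk (> 0) applied via [adjust_probability()].
#' @param severity Optional severity level(s) restricting the effect;
#'   default all.
#' @return An object of class `transition_effect`.
#' @export
transition_effect <- function(from, to, rr, severity = NULL) {
  stopifnot(from %in% care_levels(), to %in% care_levels())
  if (from == to) stop("the stay probability is residual, not a transition target")
  if (!is.null(severity) && !all(severity %in% severity_levels())) {
    stop("unknown severity level")
  }
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0) stop("rr must be > 0")
  structure(list(from = from, to = to, rr = rr, severity = severity),
            class = "transition_effect")
}

#' An absolute effect on one state-value stream
#'
#' @param stream One of `"patient_utility"`, `"caregiver_utility_delta"`,
#'   `"informal_hours"`, `"formal_cost"`.
#' @param delta Absolute change per year in the stream's units (utility,
#'   hours/week, currency). Resulting utilities are clamped to
#'   `[-1, 1]` and hours/costs floored at 0, each with a warning.
#' @param states Optional state names restricting the effect within the
#'   strategy's eligibility; default all eligible states.
#' @return An object of class `state_value_effect`.
#' @export
state_value_effect <- function(stream, delta, states = NULL) {
  streams <- c("patient_utility", "caregiver_utility_delta",
               "informal_hours", "formal_cost")
  if (!stream %in% streams) {
    stop("stream must be one of: ", paste(streams, collapse = ", "))
  }
  if (!is.null(states)) {
    unknown <- setdiff(states, living_states())
    if (length(unknown)) stop("unknown state(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(stream = stream, delta = delta, states = states),
            class = "state_value_effect")
}

#' A named intervention strategy
#'
#' A strategy bundles the technology's effects (transition relative
#' risks and state-value deltas), the set of living states in which the
#' technology is in use, how many cycles the effects persist after
#' which the cohort reverts to baseline ("effective only during active
#' use"), an optional linear waning tail, and the per-year cost while
#' active.
#'
#' @param name Strategy label.
#' @param effects List of [transition_effect()] / [state_value_effect()]
#'   objects.
#' @param eligibility Character vector of living-state names where the
#'   technology is in use; must be non-empty if any effect is present.
#' @param persistence_cycles Number of cycles the effects remain fully
#'   active (>= 0). Deliberately has no default: persistence is a
#'   scenario choice that must be made explicitly.
#' @param waning `"none"` (effects stop dead at the window's end) or
#'   `"linear"` (deltas scaled, and `rr` interpolated toward 1 on the
#'   log scale, over `waning_cycles` additional cycles).
#' @param waning_cycles Length of the linear waning tail, in cycles.
#' @param intervention_cost Cost per year while active in an eligible
#'   state (>= 0).
#' @return An object of class `strategy`.
#' @export
strategy <- function(name, effects = list(), eligibility = character(),
                     persistence_cycles, waning = c("none", "linear"),
                     waning_cycles = 0L, intervention_cost = 0) {
  waning <- match.arg(waning)
  stopifnot(
    is.character(name), length(name) == 1L,
    is.list(effects),
    persistence_cycles >= 0,
    waning_cycles >= 0,
    intervention_cost >= 0
  )
  for (e in effects) {
    if (!inherits(e, c("transition_effect", "state_value_effect"))) {
      stop("effects must be transition_effect or state_value_effect objects")
    }
  }
  unknown <- setdiff(eligibility, living_states())
  if (length(unknown)) {
    stop("unknown eligibility state(s): ", paste(unknown, collapse = ", "))
  }
  if (length(effects) > 0L && length(eligibility) == 0L) {
    stop("eligibility must be non-empty when the strategy has effects")
  }
  structure(
    list(name = name, effects = effects, eligibility = eligibility,
         persistence_cycles = as.integer(persistence_cycles),
         waning = waning, waning_cycles = as.integer(waning_cycles),
         intervention_cost = intervention_cost),
    class = "strategy"
  )
}

# fraction of the full effect in force at a 0-based cycle index:
# 1 inside the persistence window, linearly decreasing over the waning
# tail, 0 (baseline) beyond
effect_fraction <- function(strat, cycle_index) {
  p <- strat$persistence_cycles
  if (cycle_index < p) return(1)
  if (strat$waning == "linear" && strat$waning_cycles > 0L) {
    k <- cycle_index - p
    if (k < strat$waning_cycles) {
      return(1 - (k + 1) / (strat$waning_cycles + 1))
    }
  }
  0
}

#' Effective parameters and state values for one cycle under a strategy
#'
#' Applies the strategy's effects to the baseline for the given 0-based
#' cycle index. Transition effects touch only rows whose source state
#' (severity, from-care) is eligible; value effects touch only eligible
#' states. Beyond the persistence window (including any waning tail)
#' the baseline objects themselves are returned, so reversion to usual
#' care is exact, not approximate.
#'
#' @param params A [baseline_parameters()] object.
#' @param values A [state_values()] object.
#' @param strat A [strategy()] object (or NULL).
#' @param cycle_index 0-based cycle index.
#' @return List with elements `params` and `values`.
#' @export
build_strategy_parameters <- function(params, values, strat, cycle_index) {
  if (is.null(strat) || length(strat$effects) == 0L) {
    return(list(params = params, values = values))
  }
  frac <- effect_fraction(strat, cycle_index)
  if (frac == 0) return(list(params = params, values = values))

  elig <- split_state_name(strat$eligibility)
  care_order <- care_levels()

  for (e in strat$effects) {
    if (inherits(e, "transition_effect")) {
      if (match(e$to, care_order) < match(e$from, care_order) &&
          !params$allow_care_reversal) {
        stop("effect targets the structurally-zero transition ",
             e$from, " -> ", e$to)
      }
      rr_eff <- exp(frac * log(e$rr))
      sevs <- if (is.null(e$severity)) severity_levels() else e$severity
      for (s in sevs) {
        # only rows whose source state is eligible
        if (!any(elig$severity == s & elig$care == e$from)) next
        params$p_care[s, e$from, e$to] <-
          adjust_probability(params$p_care[s, e$from, e$to], rr_eff)
      }
    } else {
      targets <- if (is.null(e$states)) strat$eligibility else {
        intersect(e$states, strat$eligibility)
      }
      if (length(targets) == 0L) next
      x <- values[[e$stream]]
      x[targets] <- x[targets] + e$delta * frac
      if (e$stream %in% c("patient_utility", "caregiver_utility_delta")) {
        if (any(abs(x) > 1)) {
          warning(e$stream, " clamped to [-1, 1] after applying effect")
          x <- pmin(pmax(x, -1), 1)
        }
      } else if (any(x < 0)) {
        warning(e$stream, " floored at 0 after applying effect")
        x <- pmax(x, 0)
      }
      values[[e$stream]] <- x
    }
  }
  list(params = params, values = values)
}

#' Per-cycle intervention cost contributions
#'
#' The technology's cost accrues only over occupancy of eligible states
#' and only within the persistence window (not the waning tail, during
#' which the technology is discontinued). Cycle `t` accrues cost on the
#' start-of-cycle occupancy, pro-rated by cycle length.
#'
#' @param strat A [strategy()] object.
#' @param trace A `cohort_trace` over the canonical 10 states.
#' @return Numeric vector, one undiscounted cost per cycle.
#' @export
intervention_cost_stream <- function(strat, trace) {
  n <- nrow(trace$occupancy) - 1L
  out <- numeric(n)
  if (strat$intervention_cost == 0 || length(strat$eligibility) == 0L) {
    return(out)
  }
  cols <- match(strat$eligibility, colnames(trace$occupancy))
  active <- seq_len(min(n, strat$persistence_cycles))
  for (t in active) {
    occ <- sum(trace$occupancy[t, cols])
    out[t] <- occ * strat$intervention_cost * trace$cycle_length
  }
  out
}
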