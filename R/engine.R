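#' Propagate a cohort through per-cycle transition matrices
#'
#' Deterministic cohort propagation: `occupancy[t + 1] = occupancy[t] %*% M[t]`.
#' Matrices may vary by cycle (needed when intervention effects persist
#' for a limited window); a single matrix is recycled over the horizon.
#' The function is dimension-agnostic so that small toy chains can be
#' run against closed-form oracles; for the full model use the 10 x 10
#' matrix from [build_cycle_matrix()].
#'
#' @param matrices A single square row-stochastic matrix, or a list of
#'   them (one per cycle, length `n_cycles`).
#' @param init Initial distribution over states (non-negative, sums to
#'   1; any mass on a state named `"death"` must be 0).
#' @param n_cycles Number of cycles to run (defaults to the length of
#'   `matrices` when a list is given).
#' @param cycle_length Cycle duration in years.
#' @param stop_tol If positive, stop early once living mass falls below
#'   this tolerance (trace is truncated at that boundary). Default 0
#'   (off) so that strategies compared against each other share an
#'   identical horizon.
#' @return A `cohort_trace`: list with `occupancy` (matrix, one row per
#'   cycle boundary `0..n`), `cycle_length`, `death_state`.
#' @export
run_cohort <- function(matrices, init, n_cycles = NULL,
                       cycle_length = 1 / 12, stop_tol = 0) {
  if (is.matrix(matrices)) {
    if (is.null(n_cycles)) stop("n_cycles must be given with a single matrix")
    get_matrix <- function(t) matrices
    check <- list(matrices)
  } else if (is.list(matrices)) {
    if (is.null(n_cycles)) n_cycles <- length(matrices)
    if (length(matrices) < n_cycles) {
      stop("need one matrix per cycle: ", length(matrices), " < ", n_cycles)
    }
    get_matrix <- function(t) matrices[[t]]
    check <- unique(matrices)
  } else {
    stop("matrices must be a matrix or a list of matrices")
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1")

  k <- length(init)
  for (m in check) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrices must be square")
    if (nrow(m) != k) {
      stop("dimension mismatch: init has length ", k, ", matrix is ",
           nrow(m), " x ", ncol(m))
    }
    if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-12)) {
      stop("invalid transition matrix: rows must be stochastic")
    }
  }
  if (any(init < 0) || abs(sum(init) - 1) > 1e-12) {
    stop("init must be a non-negative distribution summing to 1")
  }
  nm <- colnames(get_matrix(1L))
  if (is.null(nm)) nm <- names(init)  # unnamed matrices take init's names
  if (!is.null(nm) && is.null(names(init))) names(init) <- nm
  dth <- if (!is.null(nm) && death_state() %in% nm) death_state() else NA_character_
  if (!is.na(dth) && init[[dth]] != 0) stop("init must place no mass on death")

  occ <- matrix(NA_real_, n_cycles + 1L, k, dimnames = list(NULL, nm))
  occ[1L, ] <- init
  last <- n_cycles
  for (t in seq_len(n_cycles)) {
    occ[t + 1L, ] <- occ[t, ] %*% get_matrix(t)
    if (stop_tol > 0 && !is.na(dth) && 1 - occ[t + 1L, dth] < stop_tol) {
      last <- t
      break
    }
  }
  occ <- occ[seq_len(last + 1L), , drop = FALSE]
  rownames(occ) <- as.character(seq_len(nrow(occ)) - 1L)
  structure(
    list(occupancy = occ, cycle_length = cycle_length, death_state = dth),
    class = "cohort_trace"
  )
}

# weights for the living states (1) vs death (0) of a trace
living_weights <- function(trace) {
  k <- ncol(trace$occupancy)
  w <- rep(1, k)
  if (!is.na(trace$death_state)) {
    w[match(trace$death_state, colnames(trace$occupancy))] <- 0
  }
  w
}

# Core accumulation shared by life-years, QALYs and costs.
# `weights` is either a length-k vector (time-invariant state values) or
# an n_cycles x k matrix (row t = values in force during cycle t).
# Cycle t (boundary t-1 -> t) contributes the end-boundary weighted
# occupancy, or the trapezoid of both boundaries under the half-cycle
# correction, discounted by (1 + rate)^(-t * cycle_length); the first
# cycle is discounted (t = 1 convention).
accumulate_stream <- function(trace, weights, discount_rate = 0,
                              half_cycle = TRUE) {
  occ <- trace$occupancy
  cl <- trace$cycle_length
  n <- nrow(occ) - 1L
  if (n < 1L) return(0)
  if (is.matrix(weights)) {
    if (nrow(weights) != n || ncol(weights) != ncol(occ)) {
      stop("per-cycle weights must be an n_cycles x n_states matrix")
    }
    v_end <- rowSums(occ[2:(n + 1L), , drop = FALSE] * weights)
    contrib <- if (half_cycle) {
      v_start <- rowSums(occ[1:n, , drop = FALSE] * weights)
      (v_start + v_end) / 2
    } else {
      v_end
    }
  } else {
    v <- as.vector(occ %*% weights)
    contrib <- if (half_cycle) (v[1:n] + v[2:(n + 1L)]) / 2 else v[2:(n + 1L)]
  }
  disc <- (1 + discount_rate)^(-(seq_len(n)) * cl)
  sum(contrib * disc) * cl
}

#' Life-years lived by the cohort
#'
#' Sums living occupancy over cycles, in years. Without the half-cycle
#' correction, cycle `t` credits the occupancy at boundary `t`; with it,
#' the trapezoid of boundaries `t - 1` and `t`. Discounting multiplies
#' cycle `t`'s contribution by `(1 + rate)^(-t * cycle_length)`.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param half_cycle Apply the half-cycle (trapezoid) correction.
#' @param discount_rate Annual discount rate (fraction, >= 0).
#' @return Life-years (scalar).
#' @export
life_years <- function(trace, half_cycle = TRUE, discount_rate = 0) {
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  accumulate_stream(trace, living_weights(trace), discount_rate, half_cycle)
}

#' Time spent in selected states
#'
#' Same accumulation convention as [life_years()], restricted to a
#' selection: explicit state names, a severity slice, and/or a care
#' slice (slices intersect when both are given). Summed over all living
#' states this equals [life_years()] exactly.
#'
#' @inheritParams life_years
#' @param states Character vector of state names (e.g.
#'   `"mild|no_formal_care"`), or NULL.
#' @param severity Severity level(s) selecting all states at that
#'   severity, or NULL.
#' @param care Care setting(s) selecting all states in that setting, or
#'   NULL.
#' @return Years (scalar).
#' @export
time_in_state <- function(trace, states = NULL, severity = NULL, care = NULL,
                          half_cycle = TRUE, discount_rate = 0) {
  nm <- colnames(trace$occupancy)
  if (is.null(nm)) stop("trace has unnamed states; select by index instead")
  sel <- rep(TRUE, length(nm))
  if (!is.na(trace$death_state)) sel[nm == trace$death_state] <- FALSE
  used <- FALSE
  if (!is.null(states)) {
    unknown <- setdiff(states, nm)
    if (length(unknown)) stop("unknown state(s): ", paste(unknown, collapse = ", "))
    sel <- sel & nm %in% states
    used <- TRUE
  }
  if (!is.null(severity) || !is.null(care)) {
    parts <- split_state_name(nm)
    if (!is.null(severity)) {
      if (!all(severity %in% severity_levels())) {
        stop("unknown severity selector")
      }
      sel <- sel & !is.na(parts$severity) & parts$severity %in% severity
    }
    if (!is.null(care)) {
      if (!all(care %in% care_levels())) stop("unknown care selector")
      sel <- sel & !is.na(parts$care) & parts$care %in% care
    }
    used <- TRUE
  }
  if (!used) stop("give at least one of states, severity, care")
  accumulate_stream(trace, as.numeric(sel), discount_rate, half_cycle)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  cat(sprintf("<cohort_trace> %d cycles of %.4g years (%d states)\n",
              n, x$cycle_length, ncol(x$occupancy)))
  if (!is.na(x$death_state)) {
    cat(sprintf("  living mass at final boundary: %.6g\n",
                1 - x$occupancy[n + 1L, x$death_state]))
  }
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle boundary; columns `cycle`, `years`, then one per
#' state name. Numbers are written with 12 significant digits so that
#' repeated runs are byte-identical.
#'
#' @param trace A `cohort_trace`.
#' @param path File path to write.
#' @export
write_trace_csv <- function(trace, path) {
  occ <- trace$occupancy
  n <- nrow(occ) - 1L
  df <- data.frame(
    cycle = 0:n,
    years = (0:n) * trace$cycle_length,
    occ,
    check.names = FALSE
  )
  write_csv12(df, path)
}
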