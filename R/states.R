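#' Dementia severity levels, in order of progression
#'
#' @return Character vector `c("mild", "moderate", "severe")`.
#' @export
severity_levels <- function() c("mild", "moderate", "severe")

#' Care settings, in order of intensity
#'
#' @return Character vector
#'   `c("no_formal_care", "home_care", "institutional_care")`.
#' @export
care_levels <- function() c("no_formal_care", "home_care", "institutional_care")

#' Name of the absorbing death state
#' @export
death_state <- function() "death"

#' Enumerate the model state space
#'
#' The state space is the Cartesian product of three dementia severity
#' levels and three care settings (nine living states), plus one
#' absorbing death state. Ordering is canonical and stable:
#' severity-major, care-minor, death last.
#'
#' @return An object of class `state_space`: a list with `states`
#'   (a data frame with columns `name`, `severity`, `care`), `n_living`
#'   and `death_index`.
#' @examples
#' ss <- state_space()
#' nrow(ss$states)    # 10
#' ss$death_index     # 10
#' @export
state_space <- function() {
  grid <- expand.grid(
    care = care_levels(), severity = severity_levels(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  states <- data.frame(
    name = c(paste(grid$severity, grid$care, sep = "|"), death_state()),
    severity = c(grid$severity, NA_character_),
    care = c(grid$care, NA_character_),
    stringsAsFactors = FALSE
  )
  structure(
    list(states = states, n_living = 9L, death_index = 10L),
    class = "state_space"
  )
}

#' Canonical state names
#'
#' @param ss A `state_space` object.
#' @return Character vector of the ten state names, death last.
#' @export
state_names <- function(ss = state_space()) ss$states$name

#' Names of the nine living states
#' @inheritParams state_names
#' @export
living_states <- function(ss = state_space()) {
  ss$states$name[seq_len(ss$n_living)]
}

# parse "severity|care" names back into components
split_state_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)
  data.frame(
    severity = vapply(parts, `[`, "", 1L),
    care = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

zero_care_array <- function() {
  array(0, dim = c(3L, 3L, 3L),
        dimnames = list(severity = severity_levels(),
                        from = care_levels(), to = care_levels()))
}

zero_death_matrix <- function() {
  matrix(0, 3L, 3L,
         dimnames = list(severity = severity_levels(), care = care_levels()))
}

#' Baseline (usual care) per-cycle transition parameters
#'
#' All probabilities are per cycle; no rate rescaling is applied to the
#' inputs. Severity progression is stepwise (mild to moderate, moderate
#' to severe); regression of severity is structurally impossible. Care
#' transitions are conditional on dementia severity; within a care row
#' the stay probability is the residual `1 - sum(moves)` and is not an
#' input. Death risk is conditional on both severity and care setting.
#'
#' @param p_progress Named numeric of length 2,
#'   `c(mild_to_moderate =, moderate_to_severe =)`, per-cycle severity
#'   progression probabilities.
#' @param p_care 3 x 3 x 3 numeric array with dimensions
#'   `severity x from x to` holding per-cycle care-move probabilities.
#'   Diagonal (`from == to`) entries must be 0: staying is the residual.
#'   Entries moving to a less intensive setting must be 0 unless
#'   `allow_care_reversal = TRUE`.
#' @param p_death 3 x 3 numeric matrix (`severity x care`) of per-cycle
#'   death probabilities.
#' @param cycle_length Cycle duration in years (default monthly, 1/12).
#' @param allow_care_reversal Permit transitions to less intensive care.
#' @return An object of class `baseline_parameters`.
#' @export
baseline_parameters <- function(p_progress = c(mild_to_moderate = 0,
                                               moderate_to_severe = 0),
                                p_care = zero_care_array(),
                                p_death = zero_death_matrix(),
                                cycle_length = 1 / 12,
                                allow_care_reversal = FALSE) {
  if (is.null(names(p_progress)) && length(p_progress) == 2L) {
    names(p_progress) <- c("mild_to_moderate", "moderate_to_severe")
  }
  stopifnot(
    length(p_progress) == 2L,
    setequal(names(p_progress), c("mild_to_moderate", "moderate_to_severe")),
    identical(dim(p_care), c(3L, 3L, 3L)),
    identical(dim(p_death), c(3L, 3L)),
    is.numeric(cycle_length), length(cycle_length) == 1L
  )
  p_progress <- p_progress[c("mild_to_moderate", "moderate_to_severe")]
  dimnames(p_care) <- list(severity = severity_levels(),
                           from = care_levels(), to = care_levels())
  dimnames(p_death) <- list(severity = severity_levels(), care = care_levels())
  structure(
    list(p_progress = p_progress, p_care = p_care, p_death = p_death,
         cycle_length = cycle_length,
         allow_care_reversal = isTRUE(allow_care_reversal)),
    class = "baseline_parameters"
  )
}

#' Validate baseline transition parameters
#'
#' Report-based validation: returns every violated invariant rather than
#' stopping at the first. A passing report guarantees that
#' [build_cycle_matrix()] succeeds and produces a row-stochastic matrix.
#'
#' @param params A [baseline_parameters()] object.
#' @return An object of class `validation_report`: list with logical
#'   `ok` and character `messages` (one per violation).
#' @export
validate_parameters <- function(params) {
  msgs <- character()
  sev <- severity_levels()
  care <- care_levels()

  if (!is.numeric(params$cycle_length) || params$cycle_length <= 0) {
    msgs <- c(msgs, sprintf("cycle_length = %s must be a positive number",
                            format(params$cycle_length)))
  }
  for (nm in names(params$p_progress)) {
    p <- params$p_progress[[nm]]
    if (!is.finite(p) || p < 0 || p > 1) {
      msgs <- c(msgs, sprintf("p_progress[%s] = %g outside [0, 1]", nm, p))
    }
  }
  for (s in sev) for (cc in care) {
    p <- params$p_death[s, cc]
    if (!is.finite(p) || p < 0 || p > 1) {
      msgs <- c(msgs, sprintf("p_death[%s,%s] = %g outside [0, 1]", s, cc, p))
    }
  }
  for (s in sev) for (from in care) {
    for (to in care) {
      p <- params$p_care[s, from, to]
      if (!is.finite(p) || p < 0 || p > 1) {
        msgs <- c(msgs, sprintf("p_care[%s,%s,%s] = %g outside [0, 1]",
                                s, from, to, p))
      } else if (from == to && p != 0) {
        msgs <- c(msgs, sprintf(
          "p_care[%s,%s,%s] = %g: stay probability is the residual and must be entered as 0",
          s, from, to, p))
      } else if (match(to, care) < match(from, care) && p != 0 &&
                 !params$allow_care_reversal) {
        msgs <- c(msgs, sprintf(
          "p_care[%s,%s,%s] = %g: care reversal is structurally 0 (set allow_care_reversal to permit)",
          s, from, to, p))
      }
    }
    out <- sum(params$p_care[s, from, setdiff(care, from)])
    if (is.finite(out) && out > 1 + 1e-12) {
      msgs <- c(msgs, sprintf(
        "p_care[%s,%s,]: outgoing probabilities sum to %g > 1", s, from, out))
    }
  }
  structure(list(ok = length(msgs) == 0L, messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("Parameter validation: PASS\n")
  } else {
    cat("Parameter validation: FAIL\n")
    cat(paste0("  - ", x$messages, collapse = "\n"), "\n")
  }
  invisible(x)
}

# 3x3 severity progression kernel (stepwise, no regression, no skips)
severity_kernel <- function(p_progress) {
  p1 <- p_progress[["mild_to_moderate"]]
  p2 <- p_progress[["moderate_to_severe"]]
  matrix(c(1 - p1, p1, 0,
           0, 1 - p2, p2,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(severity_levels(), severity_levels()))
}

# 3x3 care kernel for one severity level; stay is the residual
care_kernel <- function(p_care, severity) {
  care <- care_levels()
  k <- p_care[severity, , ]
  diag(k) <- 1 - rowSums(k)
  k
}

#' Assemble the one-cycle 10 x 10 transition matrix
#'
#' Within a cycle the components compose as: death first, then severity
#' progression among survivors, then a care move conditioned on the
#' severity held at the start of the cycle. The entry from living state
#' `(s, c)` to `(s', c')` is
#' `(1 - p_death(s, c)) * P_sev(s -> s') * P_care(c -> c' | s)` and the
#' entry to death is `p_death(s, c)`. Death is absorbing.
#'
#' @param params A [baseline_parameters()] object passing
#'   [validate_parameters()].
#' @return A 10 x 10 row-stochastic matrix with canonical state names as
#'   dimnames.
#' @examples
#' m <- build_cycle_matrix(baseline_parameters())
#' all(diag(m)[1:9] == 1)  # no transitions configured
#' @export
build_cycle_matrix <- function(params) {
  report <- validate_parameters(params)
  if (!report$ok) {
    stop("invalid baseline parameters:\n",
         paste0("  - ", report$messages, collapse = "\n"))
  }
  ss <- state_space()
  nm <- state_names(ss)
  m <- matrix(0, 10L, 10L, dimnames = list(from = nm, to = nm))
  sev_k <- severity_kernel(params$p_progress)
  care_k <- lapply(severity_levels(), function(s) care_kernel(params$p_care, s))
  names(care_k) <- severity_levels()

  living <- ss$states[seq_len(ss$n_living), ]
  for (i in seq_len(ss$n_living)) {
    s <- living$severity[i]
    cc <- living$care[i]
    pd <- params$p_death[s, cc]
    # outer product of the severity and care kernels, scaled by survival
    block <- (1 - pd) * outer(sev_k[s, ], care_k[[s]][cc, ])
    for (j in seq_len(ss$n_living)) {
      m[i, j] <- block[living$severity[j], living$care[j]]
    }
    m[i, ss$death_index] <- pd
  }
  m[ss$death_index, ss$death_index] <- 1
  m
}
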