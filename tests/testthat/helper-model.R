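# builders shared across the test files; all randomness is seeded

# a random structurally valid baseline parameter set
random_valid_params <- function(seed, cycle_length = 1 / 12) {
  set.seed(seed)
  p_progress <- c(mild_to_moderate = runif(1, 0, 0.3),
                  moderate_to_severe = runif(1, 0, 0.3))
  p_death <- matrix(runif(9, 0, 0.2), 3, 3)
  p_care <- dempath::baseline_parameters()$p_care  # zero array with dimnames
  care <- care_levels()
  for (s in severity_levels()) {
    for (from in care) {
      tos <- care[match(care, care) > match(from, care)]
      if (!length(tos)) next
      raw <- runif(length(tos))
      total <- runif(1, 0, 0.9)
      p_care[s, from, tos] <- raw / sum(raw) * total
    }
  }
  baseline_parameters(p_progress = p_progress, p_care = p_care,
                      p_death = p_death, cycle_length = cycle_length)
}

# initial distribution: all mass in mild dementia, no formal care
unit_init <- function() {
  init <- stats::setNames(rep(0, 10), state_names())
  init[["mild|no_formal_care"]] <- 1
  init
}

# a random initial distribution over the living states
random_init <- function(seed) {
  set.seed(seed)
  x <- runif(9)
  c(stats::setNames(x / sum(x), living_states()), death = 0)
}

# independent repeated-multiplication matrix power
mat_power <- function(m, t) {
  out <- diag(nrow(m))
  for (i in seq_len(t)) out <- out %*% m
  out
}

# single-living-state collapse: constant per-cycle death probability
single_state_params <- function(p_death, cycle_length = 1) {
  baseline_parameters(p_death = matrix(p_death, 3, 3),
                      cycle_length = cycle_length)
}

# a small everything-nonzero model for valuation tests
toy_model <- function(seed = 1, n_cycles = 120) {
  m <- fixture_model(seed)
  m$settings <- analysis_settings(n_cycles = n_cycles)
  m
}

expect_no_error <- function(expr) expect_error(expr, NA)
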