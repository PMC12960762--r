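# Declarative model configuration: YAML accepted, JSON canonical.
# The canonical in-memory form is a plain nested list ("model_config")
# whose leaves are scalars/vectors; normalization (defaults injected,
# keys checked, numbers coerced) is idempotent, so
# dump(load(x)) == load(dump(load(x))).

CONFIG_SCHEMA_VERSION <- 1L

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("dempath_validation_error",
                                             "error", "condition")))
}

#' Default model configuration
#'
#' The documented defaults injected into any loaded configuration:
#' monthly cycles, no transitions (all probabilities 0), a flat patient
#' utility of 0.7, zero costs, Dutch-guideline discount rates (4% costs,
#' 1.5% effects), half-cycle correction on, a 40-year horizon, the
#' cohort starting in mild dementia with no formal care, and no
#' strategy.
#'
#' @return A `model_config` list.
#' @export
default_config <- function() {
  zero_states <- function(v) as.list(stats::setNames(rep(v, 9), living_states()))
  care_map <- function() {
    out <- list()
    for (s in severity_levels()) {
      out[[s]] <- list()
      for (from in care_levels()) {
        tos <- care_levels()[match(care_levels(), care_levels()) >
                               match(from, care_levels())]
        if (length(tos)) {
          out[[s]][[from]] <- as.list(stats::setNames(rep(0, length(tos)), tos))
        }
      }
    }
    out
  }
  death_map <- function() {
    out <- list()
    for (s in severity_levels()) {
      out[[s]] <- as.list(stats::setNames(rep(0, 3), care_levels()))
    }
    out
  }
  structure(list(
    schema_version = CONFIG_SCHEMA_VERSION,
    parameters = list(
      cycle_length = 1 / 12,
      allow_care_reversal = FALSE,
      p_progress = list(mild_to_moderate = 0, moderate_to_severe = 0),
      p_death = death_map(),
      p_care = care_map()
    ),
    values = list(
      patient_utility = zero_states(0.7),
      caregiver_utility_delta = zero_states(0),
      formal_cost = zero_states(0),
      informal_hours = zero_states(0),
      unit_wage = 0,
      currency = "EUR"
    ),
    strategy = NULL,
    surrogate = NULL,
    uncertainty = NULL,
    settings = list(
      horizon_years = 40, n_cycles = NULL,
      discount_qaly = 0.015, discount_cost = 0.04,
      half_cycle = TRUE, include_caregiver = TRUE,
      wtp_grid = as.list(seq(0, 100000, by = 20000)),
      init = list(`mild|no_formal_care` = 1),
      seed = 1L
    )
  ), class = "model_config")
}

# merge user keys over defaults, rejecting keys absent from the default
# skeleton; `open` marks subtrees whose keys are free-form (validated
# separately against vocabularies)
merge_config <- function(default, user, path = "") {
  if (!is.list(user)) return(user)
  open_here <- path %in% c("strategy", "surrogate", "uncertainty",
                           "settings/init")
  if (is.null(default) || !is.list(default) || open_here) return(user)
  if (is.null(names(user))) return(user)  # an array, not a mapping
  for (key in names(user)) {
    sub <- paste0(if (nzchar(path)) paste0(path, "/"), key)
    if (!key %in% names(default)) {
      validation_error("unknown key '", sub, "' in configuration")
    }
    default[[key]] <- merge_config(default[[key]], user[[key]], sub)
  }
  default
}

num_at <- function(x, path) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) {
    validation_error("'", path, "' must be a single number")
  }
  v
}

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    validation_error("unknown key '", paste0(path, "/", bad[1L]),
                     "' in configuration")
  }
}

#' Load and validate a model configuration
#'
#' Reads YAML (`.yml`/`.yaml`) or JSON, merges the document over the
#' documented defaults, rejects unknown keys, and validates every
#' module-level invariant, reporting the path of the offending field.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `model_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  normalize_config(raw)
}

#' Normalize a raw configuration list
#'
#' @param raw Nested list as parsed from YAML/JSON.
#' @return A validated `model_config`.
#' @export
normalize_config <- function(raw) {
  if (!is.list(raw)) validation_error("configuration must be a mapping")
  cfg <- merge_config(default_config(), raw)
  if (num_at(cfg$schema_version, "schema_version") != CONFIG_SCHEMA_VERSION) {
    validation_error("schema_version must be ", CONFIG_SCHEMA_VERSION)
  }
  cfg$schema_version <- CONFIG_SCHEMA_VERSION

  # --- parameters ---
  p <- cfg$parameters
  p$cycle_length <- num_at(p$cycle_length, "parameters/cycle_length")
  p$allow_care_reversal <- isTRUE(p$allow_care_reversal)
  check_keys(p$p_progress, c("mild_to_moderate", "moderate_to_severe"),
             "parameters/p_progress")
  p$p_progress <- lapply(p$p_progress, num_at, "parameters/p_progress")
  check_keys(p$p_death, severity_levels(), "parameters/p_death")
  for (s in names(p$p_death)) {
    check_keys(p$p_death[[s]], care_levels(),
               paste0("parameters/p_death/", s))
    p$p_death[[s]] <- lapply(p$p_death[[s]], num_at,
                             paste0("parameters/p_death/", s))
  }
  check_keys(p$p_care, severity_levels(), "parameters/p_care")
  for (s in names(p$p_care)) {
    check_keys(p$p_care[[s]], care_levels(),
               paste0("parameters/p_care/", s))
    for (from in names(p$p_care[[s]])) {
      sub <- paste0("parameters/p_care/", s, "/", from)
      check_keys(p$p_care[[s]][[from]], setdiff(care_levels(), from), sub)
      p$p_care[[s]][[from]] <- lapply(p$p_care[[s]][[from]], num_at, sub)
    }
  }
  cfg$parameters <- p

  # --- values ---
  v <- cfg$values
  check_keys(v, c("patient_utility", "caregiver_utility_delta",
                  "formal_cost", "informal_hours", "unit_wage", "currency"),
             "values")
  for (stream in c("patient_utility", "caregiver_utility_delta",
                   "formal_cost", "informal_hours")) {
    check_keys(v[[stream]], living_states(), paste0("values/", stream))
    v[[stream]] <- lapply(v[[stream]], num_at, paste0("values/", stream))
  }
  v$unit_wage <- num_at(v$unit_wage, "values/unit_wage")
  cfg$values <- v

  # --- strategy ---
  if (!is.null(cfg$strategy)) {
    st <- cfg$strategy
    check_keys(st, c("name", "eligibility", "persistence_cycles", "waning",
                     "waning_cycles", "intervention_cost", "effects"),
               "strategy")
    if (is.null(st$persistence_cycles)) {
      validation_error("'strategy/persistence_cycles' is required ",
                       "(persistence is an explicit scenario choice)")
    }
    st$name <- as.character(st$name %||% "technology")
    st$eligibility <- as.character(unlist(st$eligibility))
    st$persistence_cycles <- num_at(st$persistence_cycles,
                                    "strategy/persistence_cycles")
    st$waning <- as.character(st$waning %||% "none")
    st$waning_cycles <- num_at(st$waning_cycles %||% 0,
                               "strategy/waning_cycles")
    st$intervention_cost <- num_at(st$intervention_cost %||% 0,
                                   "strategy/intervention_cost")
    st$effects <- lapply(seq_along(st$effects %||% list()), function(i) {
      e <- st$effects[[i]]
      sub <- paste0("strategy/effects/", i)
      type <- e$type %||% validation_error("'", sub, "/type' is required")
      if (type == "transition") {
        check_keys(e, c("type", "from", "to", "rr", "severity"), sub)
        list(type = "transition", from = as.character(e$from),
             to = as.character(e$to), rr = num_at(e$rr, paste0(sub, "/rr")),
             severity = if (is.null(e$severity)) NULL else
               as.character(unlist(e$severity)))
      } else if (type == "value") {
        check_keys(e, c("type", "stream", "delta", "states"), sub)
        list(type = "value", stream = as.character(e$stream),
             delta = num_at(e$delta, paste0(sub, "/delta")),
             states = if (is.null(e$states)) NULL else
               as.character(unlist(e$states)))
      } else {
        validation_error("'", sub, "/type' must be 'transition' or 'value'")
      }
    })
    cfg$strategy <- st
  }

  # --- surrogate ---
  if (!is.null(cfg$surrogate)) {
    su <- cfg$surrogate
    check_keys(su, c("direct_qol_measured", "links", "effects", "registry"),
               "surrogate")
    su$direct_qol_measured <- isTRUE(su$direct_qol_measured)
    su$links <- lapply(seq_along(su$links %||% list()), function(i) {
      l <- su$links[[i]]
      sub <- paste0("surrogate/links/", i)
      check_keys(l, c("outcome", "pathway", "coefficient", "target",
                      "source"), sub)
      list(outcome = as.character(l$outcome),
           pathway = as.character(l$pathway),
           coefficient = num_at(l$coefficient, paste0(sub, "/coefficient")),
           target = if (is.null(l$target)) NULL else
             list(from = as.character(l$target$from),
                  to = as.character(l$target$to)),
           source = as.character(l$source %||% ""))
    })
    su$effects <- lapply(seq_along(su$effects %||% list()), function(i) {
      e <- su$effects[[i]]
      sub <- paste0("surrogate/effects/", i)
      check_keys(e, c("outcome", "effect", "se", "follow_up_weeks"), sub)
      list(outcome = as.character(e$outcome),
           effect = num_at(e$effect, paste0(sub, "/effect")),
           se = if (is.null(e$se)) NULL else num_at(e$se, paste0(sub, "/se")),
           follow_up_weeks = num_at(e$follow_up_weeks,
                                    paste0(sub, "/follow_up_weeks")))
    })
    su$registry <- lapply(seq_along(su$registry %||% list()), function(i) {
      r <- su$registry[[i]]
      sub <- paste0("surrogate/registry/", i)
      check_keys(r, c("outcome", "pathway"), sub)
      list(outcome = as.character(r$outcome),
           pathway = as.character(r$pathway))
    })
    cfg$surrogate <- su
  }

  # --- uncertainty ---
  if (!is.null(cfg$uncertainty)) {
    un <- cfg$uncertainty
    check_keys(un, c("priors", "psa", "tornado", "scenarios"), "uncertainty")
    un$priors <- lapply(seq_along(un$priors %||% list()), function(i) {
      pr <- un$priors[[i]]
      sub <- paste0("uncertainty/priors/", i)
      check_keys(pr, c("path", "family", "mean", "se", "counts"), sub)
      list(path = as.character(pr$path), family = as.character(pr$family),
           mean = if (is.null(pr$mean)) NULL else
             num_at(pr$mean, paste0(sub, "/mean")),
           se = if (is.null(pr$se)) NULL else
             num_at(pr$se, paste0(sub, "/se")),
           counts = if (is.null(pr$counts)) NULL else
             lapply(pr$counts, num_at, paste0(sub, "/counts")))
    })
    if (!is.null(un$psa)) {
      check_keys(un$psa, c("n", "seed"), "uncertainty/psa")
      un$psa <- list(n = num_at(un$psa$n %||% 1000, "uncertainty/psa/n"),
                     seed = num_at(un$psa$seed %||% 1,
                                   "uncertainty/psa/seed"))
    }
    if (!is.null(un$tornado)) {
      check_keys(un$tornado, c("wtp", "ranges"), "uncertainty/tornado")
      un$tornado$wtp <- num_at(un$tornado$wtp %||% 20000,
                               "uncertainty/tornado/wtp")
      un$tornado$ranges <- lapply(
        seq_along(un$tornado$ranges %||% list()), function(i) {
          r <- un$tornado$ranges[[i]]
          sub <- paste0("uncertainty/tornado/ranges/", i)
          check_keys(r, c("path", "low", "high"), sub)
          list(path = as.character(r$path),
               low = num_at(r$low, paste0(sub, "/low")),
               high = num_at(r$high, paste0(sub, "/high")))
        })
    }
    if (!is.null(un$scenarios)) {
      un$scenarios <- lapply(un$scenarios, function(sc) {
        lapply(sc, function(x) if (is.numeric(x) || is.character(x)) x else
          unlist(x))
      })
    }
    cfg$uncertainty <- un
  }

  # --- settings ---
  se <- cfg$settings
  check_keys(se, c("horizon_years", "n_cycles", "discount_qaly",
                   "discount_cost", "half_cycle", "include_caregiver",
                   "wtp_grid", "init", "seed"), "settings")
  se$horizon_years <- num_at(se$horizon_years, "settings/horizon_years")
  if (!is.null(se$n_cycles)) {
    se$n_cycles <- num_at(se$n_cycles, "settings/n_cycles")
  }
  se$discount_qaly <- num_at(se$discount_qaly, "settings/discount_qaly")
  se$discount_cost <- num_at(se$discount_cost, "settings/discount_cost")
  se$half_cycle <- isTRUE(se$half_cycle)
  se$include_caregiver <- isTRUE(se$include_caregiver)
  se$wtp_grid <- lapply(se$wtp_grid, num_at, "settings/wtp_grid")
  check_keys(se$init, living_states(), "settings/init")
  se$init <- lapply(se$init, num_at, "settings/init")
  se$seed <- as.integer(num_at(se$seed, "settings/seed"))
  cfg$settings <- se[!vapply(se, is.null, TRUE)]

  # canonical form: NULL sections dropped, fixed section order
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  order <- intersect(c("schema_version", "parameters", "values", "strategy",
                       "surrogate", "uncertainty", "settings"), names(cfg))
  cfg <- cfg[order]
  class(cfg) <- "model_config"
  # fail early, with paths, on invalid probabilities/values
  model <- tryCatch(config_to_model(cfg), error = function(e) {
    validation_error("invalid configuration: ", conditionMessage(e))
  })
  rep <- validate_parameters(model$params)
  if (!rep$ok) {
    validation_error("invalid configuration:\n",
                     paste0("  - parameters/", rep$messages, collapse = "\n"))
  }
  cfg
}

#' Write a configuration as canonical JSON
#'
#' @param config A `model_config`.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Build a runnable model from a configuration
#'
#' Converts the declarative document into [baseline_parameters()],
#' [state_values()], an optional [strategy()] (assembling any surrogate
#' section through [assemble_strategy()] semantics and appending the
#' translated effects to the strategy's explicit effects), the initial
#' distribution, and [analysis_settings()].
#'
#' @param config A `model_config` from [load_config()].
#' @return A [ce_model()].
#' @export
config_to_model <- function(config) {
  p <- config$parameters
  p_care <- zero_care_array()
  for (s in names(p$p_care)) {
    for (from in names(p$p_care[[s]])) {
      for (to in names(p$p_care[[s]][[from]])) {
        p_care[s, from, to] <- p$p_care[[s]][[from]][[to]]
      }
    }
  }
  p_death <- zero_death_matrix()
  for (s in names(p$p_death)) {
    for (cc in names(p$p_death[[s]])) {
      p_death[s, cc] <- p$p_death[[s]][[cc]]
    }
  }
  params <- baseline_parameters(
    p_progress = unlist(p$p_progress),
    p_care = p_care, p_death = p_death,
    cycle_length = p$cycle_length,
    allow_care_reversal = p$allow_care_reversal
  )
  values <- state_values(
    patient_utility = unlist(config$values$patient_utility),
    caregiver_utility_delta = unlist(config$values$caregiver_utility_delta),
    formal_cost = unlist(config$values$formal_cost),
    informal_hours = unlist(config$values$informal_hours),
    unit_wage = config$values$unit_wage,
    currency = config$values$currency
  )

  strat <- NULL
  if (!is.null(config$strategy)) {
    effects <- lapply(config$strategy$effects, function(e) {
      if (e$type == "transition") {
        transition_effect(e$from, e$to, e$rr, severity = e$severity)
      } else {
        state_value_effect(e$stream, e$delta, states = e$states)
      }
    })
    if (!is.null(config$surrogate)) {
      su <- config$surrogate
      links <- lapply(su$links, function(l) {
        surrogate_link(l$outcome, l$pathway, l$coefficient,
                       target = if (is.null(l$target)) NULL else
                         c(from = l$target$from, to = l$target$to),
                       source = l$source)
      })
      s_effects <- lapply(su$effects, function(e) {
        surrogate_effect(e$outcome, e$effect, se = e$se,
                         follow_up_weeks = e$follow_up_weeks)
      })
      registry <- pathway_registry(
        pairs = if (length(su$registry)) {
          data.frame(
            outcome = vapply(su$registry, `[[`, "", "outcome"),
            pathway = vapply(su$registry, `[[`, "", "pathway"),
            stringsAsFactors = FALSE
          )
        } else data.frame(outcome = character(), pathway = character()),
        direct_qol_measured = su$direct_qol_measured
      )
      assembled <- assemble_strategy(
        effects = s_effects, links = links, registry = registry,
        eligibility = config$strategy$eligibility,
        persistence_cycles = config$strategy$persistence_cycles,
        intervention_cost = 0, name = "surrogate_assembled"
      )
      effects <- c(effects, assembled$effects)
    }
    strat <- strategy(
      name = config$strategy$name, effects = effects,
      eligibility = config$strategy$eligibility,
      persistence_cycles = config$strategy$persistence_cycles,
      waning = config$strategy$waning,
      waning_cycles = config$strategy$waning_cycles,
      intervention_cost = config$strategy$intervention_cost
    )
  }

  se <- config$settings
  settings <- analysis_settings(
    cycle_length = params$cycle_length,
    horizon_years = se$horizon_years,
    n_cycles = se$n_cycles,
    discount_qaly = se$discount_qaly, discount_cost = se$discount_cost,
    half_cycle = se$half_cycle, include_caregiver = se$include_caregiver,
    wtp_grid = unlist(se$wtp_grid)
  )
  init <- stats::setNames(rep(0, 10L), state_names())
  for (nm in names(se$init)) init[[nm]] <- se$init[[nm]]

  ce_model(params = params, values = values, strategy = strat,
           init = init, settings = settings)
}

#' Express a model as a configuration document
#'
#' Inverse of [config_to_model()] for the parameters, values, strategy
#' and settings sections (surrogate sections, once assembled into
#' effects, are emitted as explicit strategy effects).
#'
#' @param model A [ce_model()].
#' @param uncertainty Optional uncertainty section to embed (priors,
#'   psa, tornado, scenarios), already in config form.
#' @return A `model_config`.
#' @export
model_to_config <- function(model, uncertainty = NULL) {
  cfg <- default_config()
  p <- model$params
  cfg$parameters$cycle_length <- p$cycle_length
  cfg$parameters$allow_care_reversal <- p$allow_care_reversal
  cfg$parameters$p_progress <- as.list(p$p_progress)
  for (s in severity_levels()) {
    for (cc in care_levels()) {
      cfg$parameters$p_death[[s]][[cc]] <- unname(p$p_death[s, cc])
    }
    for (from in names(cfg$parameters$p_care[[s]])) {
      for (to in names(cfg$parameters$p_care[[s]][[from]])) {
        cfg$parameters$p_care[[s]][[from]][[to]] <-
          unname(p$p_care[s, from, to])
      }
    }
  }
  v <- model$values
  for (stream in c("patient_utility", "caregiver_utility_delta",
                   "formal_cost", "informal_hours")) {
    cfg$values[[stream]] <- as.list(v[[stream]])
  }
  cfg$values$unit_wage <- v$unit_wage
  cfg$values$currency <- v$currency

  if (!is.null(model$strategy)) {
    st <- model$strategy
    cfg$strategy <- list(
      name = st$name,
      eligibility = as.list(st$eligibility),
      persistence_cycles = st$persistence_cycles,
      waning = st$waning, waning_cycles = st$waning_cycles,
      intervention_cost = st$intervention_cost,
      effects = lapply(st$effects, function(e) {
        if (inherits(e, "transition_effect")) {
          list(type = "transition", from = e$from, to = e$to, rr = e$rr,
               severity = if (is.null(e$severity)) NULL else
                 as.list(e$severity))
        } else {
          list(type = "value", stream = e$stream, delta = e$delta,
               states = if (is.null(e$states)) NULL else as.list(e$states))
        }
      })
    )
  }
  se <- model$settings
  cfg$settings$horizon_years <- se$n_cycles * se$cycle_length
  cfg$settings$n_cycles <- se$n_cycles
  cfg$settings$discount_qaly <- se$discount_qaly
  cfg$settings$discount_cost <- se$discount_cost
  cfg$settings$half_cycle <- se$half_cycle
  cfg$settings$include_caregiver <- se$include_caregiver
  cfg$settings$wtp_grid <- as.list(se$wtp_grid)
  init <- model$init[model$init != 0]
  cfg$settings$init <- as.list(init)
  cfg$uncertainty <- uncertainty
  normalize_config(unclass(cfg))
}

# CSV writer with 12 significant digits for byte-stable outputs
write_csv12 <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 12, format = "g") else
      as.character(x)
  }
  out <- as.data.frame(lapply(df, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
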