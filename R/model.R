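#' A complete decision model: baseline, values, strategy, settings
#'
#' Bundles everything needed to run the usual-care and technology arms
#' on a common basis. This is the object the uncertainty machinery
#' (PSA, tornado, scenarios) perturbs through parameter paths.
#'
#' @param params A [baseline_parameters()] object.
#' @param values A [state_values()] object.
#' @param strategy A [strategy()] object (or NULL for a usual-care-only
#'   model).
#' @param init Initial distribution over the 10 states.
#' @param settings An [analysis_settings()] object.
#' @return An object of class `ce_model`.
#' @export
ce_model <- function(params, values, strategy = NULL,
                     init = default_init(),
                     settings = analysis_settings(params$cycle_length)) {
  stopifnot(inherits(params, "baseline_parameters"),
            inherits(values, "state_values"))
  if (!is.null(strategy)) stopifnot(inherits(strategy, "strategy"))
  structure(
    list(params = params, values = values, strategy = strategy,
         init = init, settings = settings),
    class = "ce_model"
  )
}

#' Run both arms of a model and compare them
#'
#' @param model A [ce_model()].
#' @return A `cea_result` from [compare_strategies()], with the two
#'   `strategy_outcome` objects attached.
#' @export
run_model <- function(model) {
  control <- evaluate_strategy(model$params, model$values, strategy = NULL,
                               init = model$init, settings = model$settings)
  intervention <- evaluate_strategy(model$params, model$values,
                                    strategy = model$strategy,
                                    init = model$init,
                                    settings = model$settings)
  compare_strategies(control, intervention)
}

# ---- parameter paths ------------------------------------------------------
# A path addresses one model input as slash-separated components, e.g.
#   params/p_progress/mild_to_moderate
#   params/p_death/mild/home_care
#   params/p_care/mild/home_care/institutional_care
#   values/patient_utility/mild|no_formal_care
#   values/unit_wage
#   strategy/intervention_cost
#   strategy/effects/1/rr
# Arrays and matrices are indexed by dimnames in dimension order; a path
# may stop short of the last array dimension to address a whole slice.

resolve_path <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

#' Read one model input by path
#'
#' @param model A [ce_model()].
#' @param path Slash-separated parameter path (see Details in
#'   [set_param()]).
#' @return The addressed value (scalar or array slice).
#' @export
get_param <- function(model, path) {
  walk_path(model, resolve_path(path), path, setter = NULL)
}

#' Set one model input by path
#'
#' Paths are slash-separated: list components by name (or position for
#' unnamed lists such as `strategy/effects/1`), array and matrix
#' components by dimnames in dimension order. A path stopping one
#' dimension short of an array addresses the whole slice (used for
#' Dirichlet-drawn care-transition rows).
#'
#' @inheritParams get_param
#' @param value Replacement value, conformable with the addressed slot.
#' @return The modified model.
#' @export
set_param <- function(model, path, value) {
  walk_path(model, resolve_path(path), path, setter = value)
}

walk_path <- function(node, parts, full, setter) {
  if (length(parts) == 0L) {
    if (is.null(setter)) return(node)
    if (is.numeric(node) && !is.numeric(setter)) {
      stop("non-numeric value for numeric parameter '", full, "'")
    }
    return(setter)
  }
  p <- parts[[1L]]
  if (is.matrix(node) || is.array(node)) {
    dn <- dimnames(node)
    nd <- length(dim(node))
    idx <- parts[seq_len(min(length(parts), nd))]
    for (d in seq_along(idx)) {
      if (!idx[[d]] %in% dn[[d]]) {
        stop("unknown parameter path component '", idx[[d]], "' in '",
             full, "'")
      }
    }
    rest <- parts[-seq_along(idx)]
    if (length(rest) > 0L) stop("path '", full, "' goes past the array")
    args <- c(list(node), as.list(idx),
              rep(list(quote(expr = )), nd - length(idx)))
    if (is.null(setter)) {
      return(do.call(`[`, c(args, list(drop = TRUE))))
    }
    return(do.call(`[<-`, c(args, list(value = setter))))
  }
  if (is.list(node)) {
    key <- if (is.null(names(node)) || !p %in% names(node)) {
      i <- suppressWarnings(as.integer(p))
      if (is.na(i) || i < 1L || i > length(node)) {
        stop("unknown parameter path component '", p, "' in '", full, "'")
      }
      i
    } else p
    child <- walk_path(node[[key]], parts[-1L], full, setter)
    if (is.null(setter)) return(child)
    node[[key]] <- child
    return(node)
  }
  if (is.numeric(node)) {
    if (!is.null(names(node)) && p %in% names(node)) {
      if (length(parts) > 1L) stop("path '", full, "' goes past a vector")
      if (is.null(setter)) return(node[[p]])
      node[[p]] <- setter
      return(node)
    }
  }
  stop("unknown parameter path component '", p, "' in '", full, "'")
}
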