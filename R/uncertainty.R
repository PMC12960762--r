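#' A sampling distribution for one model input
#'
#' Families follow standard health-economic convention: beta for
#' probabilities and utilities in `[0, 1]`, gamma for non-negative
#' costs and hours, lognormal for positive ratios (relative risks),
#' Dirichlet for whole care-transition rows. Beta, gamma and lognormal
#' are moment-matched to `(mean, se)`; `se = 0` is degenerate (every
#' draw equals the mean). A Dirichlet prior addresses a
#' `params/p_care/<severity>/<from>` row and takes pseudo-counts over
#' the three destination settings (the `from` component is the stay
#' mass).
#'
#' @param path Parameter path (see [set_param()]).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet"`.
#' @param mean,se Moments for the first three families.
#' @param counts Named pseudo-counts over [care_levels()] for
#'   `"dirichlet"`.
#' @return An object of class `parameter_prior`.
#' @export
parameter_prior <- function(path, family = c("beta", "gamma", "lognormal",
                                             "dirichlet"),
                            mean = NULL, se = NULL, counts = NULL) {
  family <- match.arg(family)
  if (family == "dirichlet") {
    if (is.null(counts) || is.null(names(counts)) ||
        !setequal(names(counts), care_levels())) {
      stop("dirichlet priors need counts named by the three care settings")
    }
    if (any(counts < 0)) stop("counts must be >= 0")
  } else {
    if (is.null(mean) || is.null(se)) stop(family, " priors need mean and se")
    if (se < 0) stop("se must be >= 0")
    if (family == "beta" && (mean < 0 || mean > 1)) {
      stop("beta prior mean must be in [0, 1]")
    }
    if (family %in% c("gamma", "lognormal") && mean < 0) {
      stop(family, " prior mean must be >= 0")
    }
    if (family == "beta" && se > 0 && se^2 >= mean * (1 - mean)) {
      stop("infeasible beta prior: se too large for mean ", mean)
    }
  }
  structure(list(path = path, family = family, mean = mean, se = se,
                 counts = counts),
            class = "parameter_prior")
}

# n draws from one prior; dirichlet returns an n x 3 matrix of simplex
# rows over the care settings
draw_prior <- function(prior, n) {
  m <- prior$mean
  s <- prior$se
  switch(
    prior$family,
    beta = if (s == 0) rep(m, n) else {
      nu <- m * (1 - m) / s^2 - 1
      stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    gamma = if (s == 0 || m == 0) rep(m, n) else {
      stats::rgamma(n, shape = m^2 / s^2, rate = m / s^2)
    },
    lognormal = if (s == 0) rep(m, n) else {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    dirichlet = {
      cts <- prior$counts[care_levels()]
      g <- vapply(cts, function(a) {
        if (a == 0) rep(0, n) else stats::rgamma(n, shape = a, rate = 1)
      }, numeric(n))
      if (n == 1L) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(cts)))
      sweep(g, 1L, rowSums(g), "/")
    }
  )
}

#' Draw parameter sets from a list of priors
#'
#' Deterministic given the seed: the same `(priors, n, seed)` always
#' yields identical draws, independently of the caller's RNG state.
#'
#' @param priors List of [parameter_prior()] objects.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return List of `n` draws; each draw is a named list mapping
#'   parameter paths to drawn values (a length-3 simplex for Dirichlet
#'   rows).
#' @export
sample_parameters <- function(priors, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    per_prior <- lapply(priors, draw_prior, n = n)
    lapply(seq_len(n), function(i) {
      draw <- lapply(per_prior, function(d) {
        if (is.matrix(d)) d[i, ] else d[[i]]
      })
      names(draw) <- vapply(priors, `[[`, "", "path")
      draw
    })
  })
}

# apply one draw to a model; dirichlet rows set the off-diagonal care
# moves (stay remains the residual and its slot stays structurally 0)
apply_draw <- function(model, draw) {
  for (path in names(draw)) {
    value <- draw[[path]]
    if (length(value) == 3L && !is.null(names(value))) {
      parts <- resolve_path(path)
      from <- parts[[length(parts)]]
      value[[from]] <- 0
    }
    model <- set_param(model, path, value)
  }
  model
}

#' Probabilistic sensitivity analysis
#'
#' Each draw perturbs the SHARED baseline, re-runs both the usual-care
#' and technology arms on it, and records the incremental cost and QALY
#' pair (common random baseline: control and intervention are
#' correlated within a draw, which removes baseline noise from the
#' increments). Every drawn parameter set must pass
#' [validate_parameters()]; a failing draw aborts with its index.
#'
#' @param model A [ce_model()] with a strategy.
#' @param priors List of [parameter_prior()] objects.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC (defaults to
#'   the model settings' grid).
#' @return An object of class `psa_result`: `draws` (data frame with
#'   `delta_qaly`, `delta_cost`), `n`, `seed`, `wtp_grid`, `ceac`.
#' @export
run_psa <- function(model, priors, n, seed, wtp_grid = NULL) {
  if (is.null(model$strategy)) stop("run_psa needs a model with a strategy")
  if (is.null(wtp_grid)) wtp_grid <- model$settings$wtp_grid
  draws <- sample_parameters(priors, n, seed)
  dq <- dc <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      run_model(apply_draw(model, draws[[i]])),
      error = function(e) stop("PSA draw ", i, " failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    dq[i] <- res$delta_qaly
    dc[i] <- res$delta_cost
  }
  out <- structure(
    list(draws = data.frame(draw = seq_len(n), delta_qaly = dq,
                            delta_cost = dc),
         n = n, seed = seed, wtp_grid = wtp_grid, ceac = NULL),
    class = "psa_result"
  )
  out$ceac <- ceac(out, wtp_grid)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the technology's net monetary benefit is strictly
#' positive at each willingness-to-pay value; ties (`NMB = 0`) count as
#' not cost-effective.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty numeric grid of willingness-to-pay values.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0L) stop("wtp_grid must be non-empty")
  if (nrow(psa$draws) == 0L) stop("psa has no draws")
  prob <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, 0.0)
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean delta QALY: %.5f   mean delta cost: %.2f\n",
              mean(x$draws$delta_qaly), mean(x$draws$delta_cost)))
  invisible(x)
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each parameter alone to its low and high value, recomputes the
#' net monetary benefit of the technology at a fixed willingness to
#' pay, and orders parameters by the width `|high NMB - low NMB|`,
#' widest first.
#'
#' @param model A [ce_model()] with a strategy.
#' @param ranges List of `list(path =, low =, high =)` entries; each
#'   range must bracket the base-case value (`low <= base <= high`).
#' @param wtp Willingness to pay at which NMB is evaluated.
#' @return An object of class `tornado_result`: data frame with columns
#'   `path`, `base_value`, `low`, `high`, `nmb_low`, `nmb_high`,
#'   `width`, sorted by decreasing width; the base-case NMB is attached
#'   as attribute `nmb_base`.
#' @export
tornado <- function(model, ranges, wtp = 20000) {
  if (is.null(model$strategy)) stop("tornado needs a model with a strategy")
  base_res <- run_model(model)
  nmb_base <- wtp * base_res$delta_qaly - base_res$delta_cost
  rows <- lapply(ranges, function(r) {
    stopifnot(all(c("path", "low", "high") %in% names(r)))
    base_value <- get_param(model, r$path)
    if (!(r$low <= base_value && base_value <= r$high)) {
      stop("range for '", r$path, "' must satisfy low <= base <= high")
    }
    nmb_at <- function(v) {
      res <- run_model(set_param(model, r$path, v))
      wtp * res$delta_qaly - res$delta_cost
    }
    data.frame(path = r$path, base_value = base_value,
               low = r$low, high = r$high,
               nmb_low = nmb_at(r$low), nmb_high = nmb_at(r$high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$nmb_high - out$nmb_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tornado_result", "data.frame"),
            nmb_base = nmb_base, wtp = wtp)
}

#' Scenario analysis
#'
#' Each scenario is a named bundle of parameter overrides (paths to
#' values, including surrogate-link coefficients via the strategy's
#' effects and persistence assumptions). Overrides are applied before
#' validation, which happens when the matrices are rebuilt. The base
#' case is reported as the first row.
#'
#' @param model A [ce_model()] with a strategy.
#' @param scenarios Named list; each element is a named list of
#'   `path = value` overrides (may be empty).
#' @param wtp Willingness to pay for the reported NMB column.
#' @return Data frame, one row per scenario plus `base_case`, with
#'   incremental QALYs and costs, ICER label and NMB.
#' @export
run_scenarios <- function(model, scenarios, wtp = 20000) {
  if (is.null(model$strategy)) stop("run_scenarios needs a model with a strategy")
  one <- function(name, overrides) {
    m <- model
    for (path in names(overrides)) {
      m <- set_param(m, path, overrides[[path]])
    }
    res <- run_model(m)
    data.frame(
      scenario = name,
      delta_qaly = res$delta_qaly, delta_cost = res$delta_cost,
      icer = res$icer, icer_label = res$icer_label,
      nmb = wtp * res$delta_qaly - res$delta_cost,
      stringsAsFactors = FALSE
    )
  }
  rows <- c(list(one("base_case", list())),
            mapply(one, names(scenarios), scenarios,
                   SIMPLIFY = FALSE, USE.NAMES = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
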