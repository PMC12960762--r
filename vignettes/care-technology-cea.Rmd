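---
title: "Modelling dementia care technologies with dempath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dementia care technologies with dempath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dempath)
```

## The model

`dempath` implements a cohort Markov state-transition model of the
dementia care pathway, built for *early* health technology assessment of
care technologies (assistive devices, social robots, monitoring systems)
whose primary mechanism is not disease modification but support of daily
functioning, caregiver relief, and deferral of more intensive care.

The state space crosses three dementia severity levels (mild, moderate,
severe — the cognitive domain only) with three care settings (no formal
care, home care, institutional care), giving nine living states plus one
absorbing death state. Severity progresses stepwise and never regresses;
care intensity moves forward (skipping a setting is allowed, e.g. direct
admission from no formal care) and by default never reverses, matching
the one-directional structure of the dementia care pathway; a
`allow_care_reversal` flag exists for systems where discharge back to
the community is a real event. Care-transition risks are conditional on
dementia severity; death risk is conditional on both severity and care
setting.

Each living state carries a mean patient utility, a caregiver utility
increment (one caregiver per patient, tied to the patient's state and
ceasing at the patient's death), an annual formal-care cost, and weekly
informal-care hours valued at an opportunity-cost wage (societal
perspective, `hours/week × 52.18 × wage`). The cohort is propagated
cycle by cycle; discounted QALYs and costs accumulate into the standard
decision metrics (incremental costs and QALYs, ICER, net monetary
benefit, acceptability curves).

### Within-cycle composition

A single cycle composes three conditional components, in a fixed,
documented order: death first, then severity progression among
survivors, then a care move conditioned on the severity held at the
*start* of the cycle:

$$P\big[(s,c) \to (s',c')\big] = (1 - p_{death}(s,c))\; P_{sev}(s \to s')\;
  P_{care}(c \to c' \mid s),$$

with the entry into death equal to $p_{death}(s,c)$. Conditioning the
care move on start-of-cycle severity keeps the matrix an exact product
of the three supplied components and avoids an ambiguity that a
post-progression convention would introduce (the two conventions differ
only at second order in the per-cycle probabilities, which is one reason
we default to short cycles). This choice is fixed, not configurable.
Within a care row, the probability of *staying* is the residual
`1 − sum(moves)`, so a row can never be mis-specified to sum above 1
without `validate_parameters()` flagging it.

### Cycles, horizon, discounting

* **Cycle length** defaults to monthly (1/12 year). Pilot studies of
  care technologies run 2–12 weeks; a monthly cycle makes such
  persistence windows representable as 1–3 cycles. All probabilities in
  a configuration are *per cycle*; no automatic rate rescaling is
  applied to inputs.
* **Horizon**: "lifetime" is realized as a fixed maximum (default 40
  years) at which residual living mass is negligible for realistic
  mortality inputs; `run_cohort()` also offers an early stop once
  living mass falls below a tolerance. Strategies compared against each
  other always share one fixed horizon.
* **Discounting** follows the Dutch guideline convention the model was
  conceived in: 4%/year for costs and 1.5%/year for effects, both
  overridable. Cycle *t* is discounted by
  $(1+r)^{-t \cdot \text{cycle length}}$ — the first cycle is
  discounted.
* **Half-cycle correction**: occupancy is recorded at cycle boundaries;
  reported results use the trapezoid of adjacent boundaries (default
  on). The closed-form checks in the test-suite switch it off to match
  geometric-series oracles exactly.

## Intervention strategies

A strategy is a named bundle of effects, an eligibility set, a
persistence assumption and a running cost.

* **State-value effects** add an absolute delta to one stream (patient
  utility, caregiver utility, informal hours, formal cost) in eligible
  states. Results are clamped to valid ranges with a warning.
* **Transition effects** apply a relative risk to one named care
  transition. The reported RR is treated as a hazard ratio under a
  cycle-constant rate: `p' = 1 − (1 − p)^rr`. Unlike `p × rr` this is a
  valid probability for every `rr > 0`, is exact at `rr = 1`, and is
  monotone in `rr`. After the change, the row is re-closed through the
  *stay* probability, so untargeted transitions are untouched.
* **Eligibility** is a set of living states (e.g. mild/moderate
  community states for a cooking assistant); effects never leak outside
  it — transition effects only touch rows whose source state is
  eligible.
* **Persistence** is deliberately a required field with no default:
  care technologies are assumed effective only during active use, so
  how long effects persist is an explicit scenario choice. Beyond the
  persistence window (plus any waning tail) the effective parameters
  are the baseline objects themselves — reversion is exact, not a
  numerical approximation. An optional linear waning tail scales deltas
  toward 0 and interpolates RRs toward 1 on the log scale.
* **Intervention cost** accrues per year over eligible-state occupancy
  during the persistence window only (the waning tail represents
  discontinued use), pro-rated by cycle length, discounted at the cost
  rate without half-cycle correction (it is an accrual over the cycle,
  not a boundary stock).

## Surrogate translation

Short pilot studies rarely measure lifetime quantities. Directly
applicable outcomes — utility, caregiving hours, resource use, admission
risk — enter the strategy verbatim. Everything else (ADCS-ADL
functional score, behavioral symptom scales, caregiver burden) must
pass through a `surrogate_link()`: a literature coefficient mapping one
unit of the outcome onto a utility delta, a log-RR on a named care
transition, or a change in care hours. Links are *data* with citation
labels, not code constants; the one literature-anchored exemplar shipped
is the functional-ability link (one ADCS-ADL point ↔ 0.008 utility),
the remaining shipped links are labeled illustrative.

Two safeguards against double counting are enforced by
`check_double_counting()`: a surrogate-to-utility link is rejected when
quality of life was measured directly, and no outcome may feed both the
utility and the transition pathway. Functional and behavioral measures
feeding only care transitions are always acceptable — in this model
they deliberately do *not* touch disease progression, so a technology
whose effect wanes cannot bank a permanent progression benefit or an
indirect mortality gain.

Translation is linear in the effect size on the value pathways and
log-linear on the transition pathway, so independent effects compose
multiplicatively on the RR scale; `assemble_strategy()` merges multiple
effects landing on the same transition that way. This rate-additivity
is an independence assumption, stated here because it is not an
empirical claim.

One scale convention: pilot effects on `admission_risk` are encoded as
*log* relative risks, so that an effect of 0 is the null for every
outcome in the pilot set.

## Synthetic fixtures

No parameter table ships with the model — the package is a simulator, not
a country dataset. `generate_parameter_set()` produces structurally
valid baselines that emulate what is robustly known about the pathway:
utility declines strictly with severity, total annual cost (formal plus
valued informal care) rises strictly with care intensity, death and
institutionalization risks rise with severity. Monotonicity is enforced
by jittering positive *increments* and cumulating them, so it holds for
every seed, and every generated set passes `validate_parameters()`.
Default magnitudes (utilities around 0.8/0.6/0.4 across severities,
institutional costs a multiple of home-care costs, monthly death risks
of a few per mille) are ILLUSTRATIVE choices of plausible magnitude,
never estimates of any registry. Consequently, passing tests show that
the machinery is correct and directionally sound on structurally
realistic inputs — they do not validate any country's parameterization,
effect size, or a real technology's cost-effectiveness.

`generate_pilot_effects()` emits small pilot-scale effects for the seven
implemented outcomes with follow-ups drawn in 2–12 weeks and
small-study standard errors; `fixture_model()` assembles the full
illustrative model (two years' persistence, €1200/year intervention
cost, eligibility in mild/moderate community states).

## Uncertainty machinery

* **PSA** (`run_psa()`): standard families — beta for probabilities,
  gamma for costs/hours, lognormal for RRs, Dirichlet for whole
  care-transition rows — moment-matched to `(mean, SE)`; `SE = 0` is
  degenerate. Each draw perturbs the *shared* baseline and re-runs both
  arms on it, so increments are computed under common random baselines;
  this correlated design removes baseline noise from ΔQ and ΔC. Draws
  are bitwise reproducible given the seed.
* **CEAC** (`ceac()`): the fraction of draws with strictly positive net
  monetary benefit per willingness-to-pay; ties count as not
  cost-effective.
* **Tornado** (`tornado()`): one parameter at a time to its low/high
  value at fixed WTP, ordered by NMB swing.
* **Scenarios** (`run_scenarios()`): named override bundles (surrogate
  coefficients, persistence, costs) applied by parameter path before
  validation; the shipped best/worst exemplar pair in the illustrative
  configuration varies the surrogate coefficient and persistence and is
  labeled illustrative.

Expected value of information, efficiency frontiers over more than two
strategies, and equity weighting are deliberately out of scope.

## Numerical choices and degenerate inputs

* Row-stochasticity is validated to 1e−12 on entry to `run_cohort()`;
  mass conservation holds to 1e−10 over any horizon used in the tests.
* `adjust_probability()` uses `-expm1(rr * log1p(-p))` for accuracy near
  the endpoints and pins two exactness guarantees: the `rr = 1`
  identity returns `p` itself, and results stay strictly below 1 even
  when the power underflows.
* ICERs are only formed when `|ΔQALY| > 1e−12`; otherwise the result is
  labeled (dominant / dominated / undefined) and NMB is still reported.
* The Markov cohort is deterministic given parameters; the only random
  number generators in the package are the fixture generators and the
  PSA, both seeded and isolated from the caller's RNG state.

## Problem sizes used in the test-suite

The suite favors exact oracles on small problems: matrix-power and
fundamental-matrix checks on ≤10-state chains up to 50 cycles (100
random parameter sets), direction-of-effect checks over 20 fixture
seeds at 240 monthly cycles, a 500-draw PSA against a brute-force CEAC
count, and 10⁴-case property sweeps of the RR transform. These sizes
were chosen as the smallest at which the properties are meaningfully
exercised.

## Known limitations

* One caregiver per patient, no bereavement stream, and no separate
  caregiver state space; caregiver effects ride on the patient's state.
* No individual-level heterogeneity: subgroup analysis means re-running
  with subgroup inputs, and adherence is folded into eligibility and
  effect size.
* Supervision time, productivity losses and fiscal spillovers are not
  costed; informal care is valued by a single wage.
* Care reversal is expressible through the API flag but not through the
  configuration surface, which only carries forward transitions.
* Surrogate links assume fully causal, severity-invariant associations;
  the scenario machinery exists precisely to stress that assumption.

## A worked run

```{r example, eval = FALSE}
model <- fixture_model(seed = 1)
result <- run_model(model)
result
```

The printed comparison reports discounted patient and caregiver QALYs,
the cost breakdown (formal, informal, intervention), increments, the
ICER or dominance label, and NMB over the willingness-to-pay grid. The
same run is available from a shell via the bundled CLI:

```sh
Rscript inst/cli/dempath fixtures --seed 1 --out config.json
Rscript inst/cli/dempath run config.json --out results/
```
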