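---
title: "Modelling the cost of chronic musculoskeletal pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost of chronic musculoskeletal pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincost)
```

`paincost` implements a cost-of-illness analysis of chronic pain due to
musculoskeletal diseases (MSKD): a monthly-cycle cohort Markov model of
pain severity, per-disease cost accrual across five domains, sick-leave
subsidy and human-capital productivity-loss estimation from record-level
data, QALY and episode consequences via attributable fractions, and a
Monte-Carlo probabilistic sensitivity analysis (PSA). This vignette is the
package's account of the model, its assumptions, and the design choices
made where the published description left the design open.

## The severity model

Patients with chronic MSKD pain occupy one of four states: *mild* (VAS
1–3), *moderate* (VAS 4–6), *severe* (VAS 7–10) or *dead from other
causes*. Chronic pain itself is assumed non-fatal; the single monthly death
probability applies identically to every alive state, competing with the
elicited severity transitions. The stay probability is the residual:

$$P(s \to s) = 1 - \sum_{s' \neq s} P(s \to s') - d.$$

This uniform-hazard reading is the only one consistent with a single
death parameter, and it yields a useful exact invariant: the total alive
after $t$ cycles is $N (1-d)^t$ regardless of the severity transitions,
which the test suite asserts to $10^{-9}$.

Occupancy is evaluated at cycle end with no half-cycle correction; the
source analysis gives no indication of one, and for a one-year horizon of
twelve short cycles the correction is second-order. We chose not to carry
an optional correction switch: it would change every cost and QALY figure
by a hard-to-audit half-cycle of exposure while the package's comparisons
are all against end-of-cycle arithmetic.

The cohort is closed — prevalent cases only, no incidence during the year —
and runs for 12 one-month cycles with no discounting (annual budget
perspective).

**Seeding the state vector.** Two published figures could seed severity:
the per-severity prevalence estimates, or the 7.5% / 32.5% / 60%
mild/moderate/severe split observed at first consultation. Both are
plausible readings and neither is stated to be the computation actually
performed, so `evaluate_model()` exposes both (`init_mode = "consultation"`,
the default, and `"prevalence"`) and the package asserts nothing about
which reproduces the published dollar totals.

`stationary_alive_distribution()` is a diagnostic for the severity process
conditional on survival: the alive 3×3 submatrix is row-renormalized and
its left fixed vector extracted by eigendecomposition. Tests check it
against an independent brute-force power-iteration oracle and against the
empirical cycle-$10^4$ cohort mix.

## Costs

Five domains per disease:

* **Pain management** — the monthly health-basket cost of each severity
  state times state occupancy, summed over cycles 1..12. Baskets arrive
  pre-aggregated (USD/person-month); item-level composition is out of
  scope.
* **Depression** and **anxiety** — attached to prevalent cases, not to the
  trace: `cases × PAF × monthly cost × 12`. The published per-disease
  fractions are bound as depression PAFs and the single all-MSKD 5.30%
  fraction as the anxiety PAF applied uniformly across diseases, following
  the running text; the table labelling is ambiguous and the schema keeps
  the two mappings separate so a caller can re-bind them.
* **Absenteeism** (sick-leave subsidies, a direct cost to insurers) and
  **productivity losses** (an indirect cost to society) — see below.

`aggregate_cost_report()` assembles the results table: per-disease totals,
the named-disease sum, a rest-of-MSKD residual (the all-MSKD figure minus
the named sum, for domains where an all-MSKD estimate exists), the grand
total, and unrounded percentage shares. Zero denominators yield `NA`
("undefined"), never 0.

## Work loss

The Chilean subsidy rule: insurers pay from the 4th day of a sick leave
(days 4–10 for leaves up to 10 days; the first three days fall on the
employer), and the *entire* period from day 1 once a leave reaches 11
days. `paid_subsidy_days()` is therefore 0 / `d − 3` / `d` on the three
duration ranges, producing the characteristic jump from 7 paid days at
duration 10 to 11 at duration 11 — property-tested against a day-by-day
payment oracle.

Productivity losses use the human capital approach: the full absence
valued at the individual's daily income, first three days included, so for
every record productivity loss ≥ subsidy cost. Because these two estimates
come from record-level data rather than the PSA, they carry
normal-approximation 95% *confidence* intervals (`mean ± 1.96·SE`); no
interval method was published for them, and at the database sample sizes
involved the normal approximation is innocuous.

Public-insurer records carry a FONASA income category (A–D) instead of a
wage; `impute_daily_wage()` resolves them from a category wage table.
Private records keep their observed wage.

When no records are supplied, `run_pipeline()` falls back to expected
totals: published per-leave subsidy/productivity costs times annual leave
counts. Only the low-back-pain leave count is published; the remaining
counts in the bundled table are back-calculated from published annual
subsidy totals divided by per-leave costs — a procedure that reproduces the
published low-back-pain count to within rounding, which is what justifies
it.

## Consequences

QALY losses (loss in health-state utilities) are

$$\mathrm{LHSU} = \sum_{t=1}^{T}\sum_{s} \mathrm{disutility}(s)
  \times \mathrm{PAF} \times n_t(s) \times \tfrac{1}{12}.$$

The published formula has no explicit cycle-length factor; we scale each
monthly cycle by 1/12 year so that a cohort spending the full year in a
state loses exactly `disutility × PAF` QALYs per person — the reading under
which "utilities multiplied by one [year] become QALYs" holds. PAF enters
as a scalar per disease (severity-specific fractions are not published)
and defaults to 1.

Attributable depression/anxiety episodes are `cases × fraction`, returned
unrounded.

## Parameter uncertainty

Published parameters carry a distribution family plus mean and standard
error. The fitting rule is never stated; we adopt the standard
method-of-moments PSA convention:

* beta: $\nu = m(1-m)/se^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$,
  feasible iff $se^2 < m(1-m)$;
* gamma: shape $= m^2/se^2$, rate $= m/se^2$;
* lognormal: $\sigma^2 = \log(1 + se^2/m^2)$, $\mu = \log m - \sigma^2/2$.

Each fit reproduces its inputs analytically to $10^{-10}$ and empirically
within 4 Monte-Carlo standard errors at $10^5$ draws (tested).

Transition probabilities are published with a "bootstrap" uncertainty
label, but the elicitation data behind them are unavailable, so they
default to fixed point estimates. An optional `transition_ess` turns on
joint Dirichlet uncertainty per matrix row (alive-conditional exits and
stay, concentration = probabilities × effective sample size) for users who
want to propagate an assumed precision.

`run_psa()` re-runs the deterministic pipeline per draw and summarizes
each outcome by its mean and 2.5/97.5 empirical percentiles (linear
interpolation between order statistics, `quantile()` type 7 — the common
default, documented because no percentile definition was published). Each
parameter draws from its own RNG stream seeded by a stable hash of its
name combined with the master seed, so adding a parameter never shuffles
another's draws and summaries are a pure function of
`(table, n_sims, seed)`. Draws whose pipeline evaluation fails (e.g. a
sampled death probability making a row infeasible) are discarded and
counted; more than 1% discards aborts the run. The default is 10,000
simulations; tests and the acceptance script use 50–2,000 to stay within
time budgets, which widens Monte-Carlo noise but changes nothing
structurally.

One acceptance property deserves a note: "the 95% interval of a known
gamma parameter's draws contains the true mean in ≈95% of repeated seeds"
cannot refer to the percentile interval of the draws themselves — for any
gamma, $P(X < \text{mean})$ is strictly inside $(0.025, 0.975)$, so that
interval contains the mean with probability approaching 1. The property
with 95% nominal coverage is the normal-approximation interval for the
Monte-Carlo *mean*, $\bar x \pm 1.96\, s/\sqrt{n}$, and that is what the
test checks (200 seeds, tolerance ±4%).

## Synthetic data: what it does and does not emulate

Insurer microdata (FONASA/ISAPRE sick-leave databases) are not deposited,
so `generate_sick_leave_dataset()` fabricates record-level data calibrated
to the published per-leave summaries: lognormal durations (ceiling-rounded
to whole days ≥ 1, with a −0.5 continuity correction on the fitted mean so
the rounded mean still hits the target) and independent lognormal wages.
Record-level dispersion is not published — the published SEs are standard
errors of database means — so it is explicit configuration with defaults
of CV 1.0 for durations and 0.8 for wages, typical of claims data.
Insurer membership is sampled with a 0.78 public share (the public
insurer's approximate population coverage), and the category wage table
bundled with scenarios is synthetic (the real category averages come from
household-survey microdata, out of scope).

The generator does *not* emulate: correlation between wage and duration,
seasonality, within-person repeat leaves, real FONASA/ISAPRE file layouts,
or survey expansion weights. A green test on synthetic data therefore
establishes that the estimators recover the moments the generator was told
to produce — not that the package reproduces the published work-loss
totals, which depend on microdata we do not have.

## Transcription choices in the bundled parameter set

* The lower-back-pain "very severe" prevalence stratum is merged into
  severe (means summed, SEs combined root-sum-of-squares): the model has
  three alive states.
* Shoulder pain's prevalence and disutility are published as a combined
  moderate/severe figure. The prevalence mass is carried under moderate
  (severe starts empty and fills via transitions — only the per-disease
  total matters for prevalent-case arithmetic); the combined disutility
  applies to both states; monthly costs are published separately per
  severity and kept as such.
* Fibromyalgia has no mild prevalence (fixed 0) but a published mild cost,
  which is retained: the mild state is reachable via transitions. Its mild
  disutility defaults to 0.
* `adult_population` is not published; the bundled value (15 million) is
  an assumption documented as such, and nothing in the test suite depends
  on it — shares and ratios are the comparable quantities.
* The bundled `reported_results()` transcription keeps the source's
  printed aggregates even where they are internally inconsistent (the
  five-disease sick-leave-days components sum to 3,675,258 against a
  printed total of 3,147,509); the tests reproduce both numbers and flag
  the disagreement rather than resolving it. Summary-table dollar values
  are interpreted as millions USD with a comma decimal separator, the only
  reading consistent with the exact dollar figures in the running text.

## Numerical choices

* Transition-matrix rows must sum to 1 within $10^{-12}$; traces conserve
  mass within $10^{-9}$ relative.
* The stationary distribution uses `eigen()`; the power-iteration
  implementation lives only in the tests as the independent oracle.
* Display rounding is half-up to one decimal for percentages and ratios;
  stored values are never rounded.
* Degenerate inputs: `se = 0` (or family `fixed`) is a point mass; an
  empty cohort yields zero costs and QALYs; zero denominators yield `NA`.
* Configuration files are JSON (one file = one parameter table); unknown
  keys are rejected rather than ignored, and every load re-validates all
  invariants.

## Known limitations

Closed prevalent cohort (no incidence); one death hazard for all states
and diseases; no discounting, currency conversion or inflation adjustment;
no friction-cost alternative for productivity losses; severity-specific
attributable fractions unavailable; absolute dollar totals conditional on
the assumed population size; credibility intervals of the published
analysis are not reproducible without the unstated population size and
per-draw pipeline composition, so interval values are not asserted
anywhere — only interval *machinery* is tested.
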