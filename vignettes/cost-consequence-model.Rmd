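---
title: "A Markov cohort cost-consequence model for continuous denosumab therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-consequence model for continuous denosumab therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteocca)
```

## The decision problem

Korean reimbursement rules stop covering osteoporosis drugs once a
patient's BMD T-score rises above −2.5, although international guidance
recommends continuing antiresorptive therapy. This package models the
downstream consequences of that rule for patients whose T-score recovered
into the (−2.5, −2.0] band under denosumab: a *continuation* strategy
(`dmab_c()`, treatment maintained until the T-score exceeds −2.0) versus a
*discontinuation* strategy (`dmab_d()`, all drugs stopped). Because the
evaluation is a cost-consequence analysis, costs and each clinical outcome
are reported side by side — there is deliberately no QALY weighting and no
incremental cost-effectiveness ratio.

## Model structure and assumptions

The cohort is deterministic and advances in 6-month cycles (the denosumab
dosing interval) over four main states:

* `S` — starting state, T-score in (−2.5, −2.0];
* `D` — T-score decreased below −2.5; patients receive subsequent therapy
  weighted by market share;
* `I_mid` — T-score increase band (−2.5, −2.0], reached from `D` (the
  transition probability from `D` was derived for recovery into this band,
  so all `D → I` flow lands here);
* `I_high` — T-score above −2.0, reached from `S` while on treatment;
* death.

The increase states are absorbing apart from death: the model assumes a
single rebound opportunity (from `S`) and no fracture-history memory. Both
are simplifications; they understate recurrent-fracture risk in long-lived
patients.

Within a cycle events occur in a fixed order: (1) background death from
the life table; (2) among survivors, at most one incident fracture —
vertebral (VF) and non-vertebral (non-VF) are mutually exclusive
sub-states with residual "well"; (3) fracture-related excess death,
`incidence × (min(1, q·SMR) − q)`, applied only in the fracture's own
cycle; (4) main-state transitions. Fractures are attributed to the state
occupied at cycle start. Applying the SMR as an *excess* on top of the
background draw keeps all-cause mortality exactly consistent with the life
table; the standard alternative (fractured patients die at `q·SMR`
outright) inflates all-cause death whenever fractures occur.

Two reporting conventions for the fracture-related-death sub-state are
provided, because "deaths related to fracture" is ambiguous: `"all"`
(default) credits the sub-state with `incidence × min(1, q·SMR)` — every
death attributed to an incident-fracture patient — while `"excess"`
reports only the SMR excess. The choice moves mass between the background
and fracture columns of the ledger and rescales the productivity-loss
base; it never changes the cohort dynamics. The all-deaths convention is
the default because it is how fracture-related mortality is conventionally
tabulated in fracture cost-of-illness summaries (the excess convention
roughly halves the reported counts).

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| cycle length | 0.5 | years | denosumab dosing interval |
| starting age | 55 | years | postmenopausal eligibility population |
| sex mix | 100% female | — | pivotal trials enrolled postmenopausal women |
| discount rate | 0.045 | /year | Korean pharmacoeconomic guideline; applied to costs *and* events |
| treatment duration | 6 | cycles | 3 years of persistent denosumab use |
| offset window | 2 | years | duration of waning protection after stopping |
| cumulative rebound | 0.999 | probability | calibration constant, see below |
| `S→I` on treatment | 0.108 | /cycle | trial share reaching T-score > −2.0 |
| `D→I` | 0.033 | /cycle | market-share-weighted subsequent therapy |
| VF probability | 0.004/0.013 (S, treated/discontinued) | /cycle | trial incidence by T-score band; discontinued = treated × risk ratio |
| SMR after VF | 2.99 (F), 4.56 (M) | ratio | registry estimates, 6 months post fracture |
| SMR after non-VF | 3.29 (F), 5.02 (M) | ratio | VF SMR × site-weighted hazard ratio |
| drug + admin cost | e.g. denosumab 177,650 + 4,843 | KRW/cycle | national price lists, 2022 KRW |
| fracture cost | VF 2,717,095; non-VF 2,684,098 | KRW/event | national fact-sheet costing |
| terminal age | 110 | years | operationalizes the lifetime horizon |

The **rebound calibration** deserves a note. Published inputs give a
single per-cycle `S→D` probability of 0.822 after treatment stops, tied to
a 2-year offset window. We parameterize the whole family by one constant:
the cumulative probability of rebounding across the window,
`R = 0.999`, with per-cycle value `1 − (1 − R)^(c/ω)`. At `ω = 2` years
this reproduces 0.822 exactly; sensitivity offsets of 1 and 3 years reuse
the same `R` (0.968 and 0.684 per cycle), preserving "nearly everyone
rebounds across the window" rather than freezing the per-cycle number.

The 49.1% non-denosumab share of subsequent therapy is split equally
between oral bisphosphonate, IV bisphosphonate and SERM, because the split
is not published; it is configurable (`default_subsequent_mix()`). Patients
in the increase states are assumed to take (and cost) nothing. `D→I` uses
the same 0.033 for both strategies, with an optional risk-ratio multiplier
(`rr_D_to_I`) for users who prefer to derive the discontinuation value.

## Cost accrual and discounting

Costs accrue on **end-of-cycle** occupancy: continuous drug +
administration to mass in `S` during the treatment window, subsequent
therapy (market-share-weighted per-cycle cost) to mass in `D`, and
fracture treatment once per incident event. Discounting uses
`(1 + r)^(−t·c)` at end-of-cycle times, identically for costs and event
counts. There is no half-cycle correction. End-of-cycle accrual was chosen
over start-of-cycle because the two differ materially (about 11% on the
continuous-drug component) and end-of-cycle is the internally consistent
choice when transitions resolve before costing; users wanting start-of-cycle
behaviour can shift the trace by one cycle. Short-horizon cost differences
are quite sensitive to this timing convention — a caveat when comparing
against figures produced by other implementations of the same structure —
and to how quickly subsequent therapy is assumed to start after the
T-score falls.

Productivity losses (societal perspective) follow the human capital
approach: each fracture-related death before the retirement age forfeits,
for every whole year of age up to retirement, that year's average income ×
employment rate, discounted from the cycle of death. The packaged
income/employment profile is synthetic (`make_productivity_profile()`);
real wage statistics should be substituted for policy use.

## Life tables and synthetic inputs

Background mortality is read from a CSV life table (`age,sex,q_annual`),
with fractional mid-cycle ages floored to match annual granularity and a
terminal age (110) at which `q = 1`. Annual probabilities convert to
cycles assuming a constant hazard within the year,
`1 − (1 − q)^c` — exactly invertible, so two half-year cycles recompose
the annual probability to machine precision.

`make_life_table()` generates a Gompertz–Makeham stand-in,
`q(a) = 1 − exp(−(λ + B e^{θa}))`, with defaults `λ = 10⁻⁴`,
`B = 1.8×10⁻⁶`, `θ = 0.12` (female) chosen once to match the broad shape
of published Korean female mortality — `q(55) ≈ 0.0014` and
`q(85) ≈ 0.05` — and a doubled Gompertz scale for men. It deliberately
does not mimic any specific national table vintage; absolute lifetime
results (which integrate mortality over five decades) therefore differ
from published figures computed on a specific vintage, while
short-horizon results and cost-per-cycle anchors are essentially
table-independent. Event counts, by contrast, are *very* sensitive to the
table at old ages.

`sample_params()` draws full configurations from plausible ranges,
constructed so every draw passes all validators (probabilities in range,
VF + non-VF ≤ 1 per state, discontinued fracture risk ≥ treated, shares
summing to 1). Passing the property suite on these draws demonstrates
structural correctness — mass conservation, monotonicity, oracle
agreement — not calibration to any real population: synthetic tables have
smooth parametric hazards, no cohort effects, and no correlation between
fracture risk and mortality beyond the SMR mechanism.

## Validation against the microsimulation oracle

`microsim()` re-implements the identical decision sequence patient by
patient with one random draw per decision point, so it validates the
cohort engine's event *ordering*, not merely its totals. Agreement is
asserted within 3 Monte Carlo standard errors for every summary at
n = 200,000 in the acceptance suite (and at n = 20,000, including on a
random parameter draw, in the unit suite). Under the all-deaths reporting
convention the oracle credits each incident fracture with its background
share `q` — an unbiased individual-level estimator of the cohort
attribution. The deterministic problem sizes used throughout (112 cycles
for a lifetime at age 55; 1,000 random draws for the conservation sweep)
were chosen as the smallest sizes that exercise every code path over a
full lifetime.

## Numerical choices

* Mass conservation is checked every cycle to 1e−12 and violations abort
  with the cycle index.
* Mixed-sex cohorts run per sex and blend by weight — exact, because sex
  is fixed within patient.
* Fractional starting ages (e.g. 72.3) age continuously by 0.5-year
  cycles; only the life-table lookup floors.
* A lifetime horizon compiles `⌈(110 + 1 − age)/0.5⌉` cycles; the terminal
  row absorbs any survivors.
* Currency is kept floating internally; printed tables round to 2 d.p.
* Totals (`total_fractures`, `cost_total`) are computed once, in
  `outcome_block()`, as exact sums of their components, so the layout
  identities hold bitwise on every run — including on difference tables.

## Known limitations

* No fracture-history states and at most one fracture per cycle; repeat
  rebounds from the increase states are excluded by construction.
* All `D→I` recovery flows into the mid band; the published derivation
  supports this, but a split between the two increase bands cannot be
  ruled out and would lower fracture counts.
* The comparator strategies (`comparator_c()`) ship as structure only —
  their transition and fracture inputs must be supplied.
* The continuous-treatment-to-−1.5 scenario is expressible as a custom
  `strategy_spec()` but has no packaged defaults, as its inputs are not
  published.
* Reproduction of published absolute results depends on the life-table
  vintage and on unpublished accrual-timing details of the original
  implementation; the package fixes one documented convention and exposes
  the levers (`offset_years`, `fracture_deaths`, unit costs, the life
  table) rather than chasing any single figure.
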