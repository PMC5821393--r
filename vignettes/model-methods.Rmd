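---
title: "Model and methods: early intervention for subthreshold panic disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: early intervention for subthreshold panic disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(paniccea)
```

## The decision problem

About 2% of the Dutch adult population experiences clinically relevant
panic symptoms without meeting the diagnostic criteria for panic disorder
(PD) — subthreshold panic disorder (STHPD). STHPD carries substantial
quality-of-life loss and societal cost, and a large share of STHPD
patients progress to full-blown PD, yet early interventions are not
systematically offered. `paniccea` implements a health-economic model
asking: is it cost-effective, from a societal perspective, to add a
CBT-based group course for STHPD (10% uptake) to the care PD patients
already receive?

## The Markov cohort model

Four mutually exclusive states: panic-free (`PF`), `STHPD`, `PD` and
`DEAD`. Cycles are annual; the base-case horizon is five years. STHPD is
the obligatory intermediate — direct `PF <-> PD` transitions are
structurally zero — and at most one switch happens per cycle. Death is
absorbing and reached from every alive state at the same background
probability (0.0028/year, the 18–65 population average); the model adds
no excess mortality for panic states, matching its single any-state
death input.

Annual transition probabilities (all treated as fixed, not sampled):

| transition | probability |
|---|---|
| PF to STHPD | 0.0016 |
| STHPD to PF | 0.0815 |
| STHPD to PD | 0.6037 |
| PD to STHPD | 0.5214 |
| any alive state to DEAD | 0.0028 |

Each state's stay probability is one minus its exit probabilities.

### Intervention logic

Usual care offers PD occupants CBT (uptake 8.8%), SSRIs (9.2%), TCAs
(2.4%) and combination therapy (9.0%). All interventions have 70% trial
adherence, thinned by dropout for pharmacotherapy (18% SSRI, 30% TCA),
giving effective adherence `a = adherence x (1 - dropout)` (0.574 and
0.49 — printed as 57% / 49%). The alternative arm adds the early
intervention for STHPD occupants at 10% uptake.

Adherent recipients gain utility (per-cycle additive increments:
0.0327 CBT, 0.0450 SSRI, 0.0445 TCA, 0.0568 combination, 0.0655 early
intervention); non-adherent recipients gain nothing but incur full
intervention costs, so cost terms are weighted by uptake alone and
utility terms by `uptake x a`. The early intervention additionally
lowers STHPD-to-PD progression by risk ratio 0.538 for its
treated-and-adherent recipients; at the cohort level the blended
probability is `p x (1 - u a (1 - RR))`, with the removed mass added to
the STHPD stay probability (the course prevents progression; it is not
modelled as inducing remission).

Uptake and adherence are applied as memoryless cohort-level blending
weights each cycle, not persistent individual assignments — the Markov
cohort is memoryless by construction, and the microsimulation (below)
mirrors that by redrawing assignment every cycle.

### Rewards, costing and discounting

State utilities (EQ-5D based): PF 0.869, STHPD 0.730, PD 0.660, DEAD 0.
The STHPD and PD values are the disease-specific utilities multiplied by
the general-population (PF) utility so that recovery reflects
burden-of-disease gains; the "uncorrected utility values" sensitivity
scenario divides them back by 0.869. The Table of annual societal costs
sums three categories per state (direct medical + direct non-medical +
indirect non-medical): PF 340 + 99 + 6,643; STHPD 1,503 + 494 + 9,741;
PD 666 + 858 + 16,771 (EUR, 2014 price level; no internal indexation).

Costs are discounted at 4%/year and effects at 1.5%/year (Dutch
guideline differential discounting). Rewards are attributed at cycle
end — occupancy after each annual transition, discount exponents
1..horizon, no half-cycle correction. The source model does not state
its timing convention; cycle-end is conventional for annual-cycle models
without a stated correction and is closest to the published magnitudes.
`settings$reward_timing = "start"` switches to start-of-cycle
attribution so the sensitivity of results to this choice is testable.

**Early-intervention cost timing.** The four PD treatments are priced
per treatment year (defined daily doses plus therapy sessions) and recur
every cycle for the uptake fraction of PD occupants. The early
intervention's EUR 905 is the per-patient price of a single eight-week
group course; the package charges it once, in the first model cycle, to
the uptake fraction of STHPD occupants (`cost_timing = "once"` on that
intervention row). This is a deliberate design choice: charging the
course price annually to the re-drawn 10% makes the reference-case ICER
about -9,000 EUR/QALY and inverts the published horizon ordering of the
one-way sensitivity ICERs (the 1-year horizon becomes more negative than
the reference), whereas one-off costing reproduces both the published
dominance pattern and the 1-year < reference < 10-year negativity
ordering. Setting the row to `"recurring"` restores annual charging.
Consistency caveat: the transition benefit and utility gain still recur
(each year's treated 10% realise them), so one-off costing amounts to
assuming course capacity is funded once at programme introduction.

## Probabilistic sensitivity analysis

10,000 iterations; each iteration draws one joint parameter set and
evaluates both arms on it (common random numbers). Families follow the
published distribution assignments:

* **Utilities** — normal with the published standard errors (PF 0.0054,
  STHPD 0.037, PD 0.030), truncated to [0, 1] by resampling. The means
  sit many standard errors from the bounds, so truncation bias is
  negligible.
* **Utility gains** — normal, truncated at 0. The source reports no
  spreads; the default standard error is 0.20 x mean (`gain_se_frac`),
  an explicit assumption exposed in the configuration.
* **Costs** — gamma, one independent parameter per cost category per
  state (nine parameters) plus the five intervention costs,
  mean-preserving with `shape = 1/CV^2`, `scale = mean x CV^2`. The
  source reports no cost spreads; the default coefficient of variation
  is 0.25 (`cost_cv`), chosen to reproduce the roughly +/-25% span of
  the published cost credible intervals, and exposed in the
  configuration.
* **Transition probabilities, risk ratio, uptake/adherence, discount
  rates** — fixed.

The summary ICER is the ratio of mean incremental cost to mean
incremental QALY; per-iteration ICERs are also summarised by their
2.5%/97.5% percentiles, which reproduce the wide sign-crossing interval
the ratio's instability near zero QALY difference produces. The CEAC
reports, on a willingness-to-pay grid of 0 to 80,000 EUR/QALY in
1,000-EUR steps (bracketing the 20,000 EUR Dutch threshold generously),
the fraction of iterations with positive net monetary benefit
`wtp x dQALY - dCost`.

## One-way sensitivity scenarios

Eight shipped scenarios (`dsa_scenarios()`), each a full PSA with a
single structured change, reseeded identically so scenarios differ only
through their overrides: horizons of 1 and 10 years; early-intervention
uptake 5% and 15%; the treated (post-risk-ratio) STHPD-to-PD
probability multiplied by 0.9 / 1.1; all four PD-intervention uptakes
scaled proportionally so they total 100% (preserving the published
treatment mix — raising each to literal 100% simultaneously would exceed
the patient population); and uncorrected utility values.

## The microsimulation oracle

`simulate_population()` is a brute-force individual-level simulator
under the identical stochastic assumptions: annual state transitions by
per-person multinomial draws, per-cycle intervention assignment by
uptake, adherence as a per-assignment coin flip, per-cycle reward
ledgers, end-of-cycle discounting. Assignment is redrawn independently
every cycle so the microsimulation estimates the same estimand as the
memoryless cohort blend — that equivalence is asserted by test (cohort
vs microsimulation means within three Monte-Carlo standard errors at
n = 200,000 for both arms and both starting cohorts), not assumed.

What the simulator emulates is exactly the model's stated world: it
shares the model's structural assumptions (no individual heterogeneity
in baseline utility or cost, no persistent treatment status, no
comorbidity, flat background mortality). A green equivalence test
therefore establishes that the cohort arithmetic is a correct
expectation of the stated stochastic process — not that the stated
process is a correct description of Dutch panic-disorder epidemiology.

Randomness uses a single seeded stream with a fixed draw layout (a
fixed number of uniform vectors per cycle point, in fixed intervention
order), giving bit-identical results under a seed independent of person
enumeration; per-person streams were rejected because they would force
an interpreted per-person loop at n = 200,000.

## Numerical choices and degenerate inputs

* Transition rows are validated to sum to 1 within 1e-12; any blended
  probability outside [0, 1] is an error, not clamped.
* Unrounded effective adherences (0.574, 0.49) enter all calculations;
  the printed table percentages are presentational rounding.
* Zero spreads degenerate every sampler to its point value, so a
  zero-spread PSA equals the deterministic run exactly.
* An ICER is `NA` when the QALY difference is exactly zero; the
  cost-effectiveness-plane quadrant is still classified from the delta
  signs.
* Zero early-intervention uptake (or risk ratio 1) makes the
  alternative arm bit-identical to usual care.
* The initial cohort is the prevalent STHPD + PD population split
  1.9 : 2.2 by the published prevalences; nobody starts panic-free,
  so the panic-free state's (high, population-level) indirect costs
  enter only as patients recover.

## Known limitations

* The printed sub-cohort results for patients starting in STHPD are not
  linearly consistent with the mixed-cohort results under any linear
  cohort model with the published inputs; their pattern (a QALY gain of
  0.11 and a cost increase of about 1,400 EUR) is quantitatively
  consistent with the early intervention being offered to all STHPD
  patients rather than 10%. The package follows the scenario definition
  (10% uptake) for the STHPD-only cohort, so it reproduces the
  sub-cohort QALYs but shows modest cost savings rather than added
  cost there.
* The 10-year-horizon sensitivity ICER is substantially more negative
  in the source (about 2.5 x its reference case) than this
  implementation produces (about 1.1 x); sign and ordering reproduce,
  magnitude does not, and no variant of the timing or costing choices
  above closes that gap.
* Transition probabilities are consumed as printed; they are not
  re-derived from the underlying incidence/chronicity/recurrence
  evidence, and no age or sex stratification, comorbidity, or excess
  mortality is modelled.

## A worked run

```{r, eval = FALSE}
params <- default_parameters()
base <- evaluate_scenario(params, scenario_spec(params, "usual_care"))
alt <- evaluate_scenario(params,
                         scenario_spec(params, "early_intervention"))
incremental(base, alt)

psa <- run_psa(params, cohort = "mixed", seed = 1)
psa
run_dsa(params, seed = 3)
```
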