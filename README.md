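# paniccea

Cost-effectiveness modelling of adding a CBT-based early intervention for
subthreshold panic disorder (STHPD) to usual care for panic disorder (PD)
in the Netherlands, from a societal perspective.

## The problem and who this is for

Roughly 1.9% of Dutch adults have clinically relevant panic symptoms below
the PD diagnostic threshold, with quality-of-life loss and societal costs
approaching those of full-blown PD — yet early interventions for STHPD are
not systematically offered. This package is for health-economic modellers
and mental-health policy analysts who want to reproduce, stress-test or
extend the decision model behind that question.

## The model

A four-state Markov cohort model over states
`S = {PF, STHPD, PD, DEAD}` with annual cycles and a 5-year horizon.
STHPD is the obligatory intermediate (`PF <-> STHPD <-> PD`; direct
`PF <-> PD` transitions are structurally zero), death is absorbing with a
flat background probability 0.0028 from every alive state, and occupancy
evolves as `x_t = x_{t-1} P`.

Interventions enter through uptake `u` and effective adherence
`a = adherence x (1 - dropout)`: state occupants accrue
`utility + sum u a g` (gains `g` only for adherent recipients) and
`cost + sum u c` (full intervention costs regardless of adherence). The
early intervention additionally lowers STHPD-to-PD progression by risk
ratio `RR = 0.538` for treated-adherent patients, blended at cohort level
as `p(1 - u a (1 - RR))`. Its EUR 905 course price is charged once, in
the first cycle (see the methods vignette for why; a `cost_timing` switch
restores annual charging).

Outputs: discounted QALYs (1.5%/year) and societal costs (4%/year) per
patient, the incremental cost-effectiveness ratio
`ICER = dC / dE`, net monetary benefit `wtp x dE - dC`, a 10,000-iteration
probabilistic sensitivity analysis (normal utilities, gamma costs, fixed
transitions), the cost-effectiveness acceptability curve, eight one-way
sensitivity scenarios, and an individual-level microsimulation oracle that
validates the cohort engine by Monte Carlo.

## Worked example

```r
library(paniccea)
params <- default_parameters()

base <- evaluate_scenario(params, scenario_spec(params, "usual_care"))
alt  <- evaluate_scenario(params, scenario_spec(params, "early_intervention"))
base
#> usual_care (mixed cohort): 3.3858 QALYs, EUR 65131.39 per patient
alt
#> early_intervention (mixed cohort): 3.3977 QALYs, EUR 64899.52 per patient
incremental(base, alt)
#> early_intervention vs usual_care (mixed cohort)
#>   delta QALYs 0.01192, delta cost EUR -231.88
#>   ICER EUR -19447 per QALY (dominant)

psa <- run_psa(params, cohort = "mixed", n_iter = 10000, seed = 1)
psa
#> PSA (10000 iterations, mixed cohort, seed 1)
#>   usual care: 3.385 QALYs, EUR 64956
#>   + early intervention: 3.397 QALYs, EUR 64726
#>   mean dQALY 0.01192, mean dCost EUR -230.3, ICER EUR -19313
#>   P(cost-effective | WTP 20000) = 1.000
```

Reading: adding the early intervention yields slightly more QALYs at
slightly lower societal cost per patient — it *dominates* usual care (a
negative ICER in the lower-right quadrant of the cost-effectiveness
plane), and essentially all PSA iterations are cost-effective at the
Dutch willingness-to-pay threshold of EUR 20,000 per QALY.

One-way sensitivity scenarios and the microsimulation check:

```r
run_dsa(params, seed = 3)          # reference case + 8 scenarios
cfg <- run_config(out_dir = "out", seed = 7, microsim_n = 200000)
cmd_microsim(cfg)                  # cohort vs microsimulation, 3-SE verdict
```

A thin command-line front-end ships at `inst/cli/paniccea`
(`paniccea <base|psa|dsa|microsim> --out DIR ...`); every command writes
CSV tables plus a manifest that suffices to re-run it, byte-identically
under the same seed.

All model inputs live in a JSON configuration
(`default_config_path()`, round-tripping via `read_config()` /
`write_config()`), so scenarios beyond the shipped ones are plain edits.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline quantities from scratch with the installed
package — the paired 10,000-iteration PSA of both arms for the mixed and
STHPD-only cohorts (mean QALYs and societal costs per arm, summary ICER,
CEAC probability at EUR 20,000/QALY) and the 1-year and 10-year horizon
sensitivity ICERs — and writes them as JSON.
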