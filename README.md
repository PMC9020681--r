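# noacce

A Markov cohort cost-effectiveness model of oral anticoagulation for stroke
prevention in non-valvular atrial fibrillation (NVAF), built entirely on
real-world-evidence inputs and evaluated from the Spanish National Health
System perspective. The package compares three non-vitamin-K oral
anticoagulants (NOACs) — rivaroxaban, dabigatran and apixaban — each against
vitamin K antagonist (VKA) therapy.

It is aimed at health economists and HTA analysts who want a fully
reproducible, scriptable implementation of this class of model: a validated
parameter data model, the cohort engine, deterministic and probabilistic
sensitivity analysis, scenario analyses, and a patient-level
microsimulation used as the engine's Monte-Carlo oracle.

## The model

Patients enter at age 73.4 in stable AF and move in 3-month cycles over a
30-year horizon through acute/post states for minor and major ischaemic
stroke, myocardial infarction, intracranial haemorrhage, a gastrointestinal
bleeding tunnel state, and death. Event risks are derived from VKA-arm
rates per 100 patient-years by the constant-hazard conversion
*p* = 1 − exp(−(*r*/100)·*t*), modified in the rate domain
(*p*′ = 1 − (1 − *p*)^*h*) by per-arm hazard ratios and age-specific stroke
relative risks. Background mortality comes from a life table and combines
with event case fatality as independent risks. Treatment status
(on initial drug / switched to VKA / off treatment) evolves through
time-varying discontinuation probabilities (four persistence bands) with
per-arm hazard ratios and switch proportions. Costs (€2018: acquisition,
administration, event management) and utilities accrue at cycle start,
discounted at 3% per annum. Arms are compared by the incremental
cost-effectiveness ratio ICER = ΔC/ΔQALY against a €22,000/QALY
willingness-to-pay reference.

See `vignettes/model-methods.Rmd` for the full model description, the
structural assumptions, and the documented calibration of inputs the source
material does not print.

## Worked example

```r
library(noacce)

params <- load_parameters()        # packaged inputs + synthetic life table
bc <- run_base_case(params)        # all four arms + incrementals vs VKA

bc$arms$vka
#> <noacce_arm> vka
#>   total cost EUR 20,966 (drug 124, admin 1,345, events 19,497)
#>   QALYs 7.30, LYs 10.12; events: IS 0.36, MI 0.09, ICH 0.02, GI 0.06

bc$incremental$rivaroxaban
#> <noacce_comparison> rivaroxaban vs vka
#>   dCost EUR 202, dQALY 0.056, dLY 0.064 (trade-off)
#>   ICER 3,588 EUR/QALY; 3,136 EUR/LYG
```

A VKA patient accrues 7.30 discounted QALYs over 10.12 discounted
life-years at a lifetime cost of €20,966, dominated by event management.
Rivaroxaban buys 0.056 extra QALYs for €202 extra cost — €3,588 per QALY
gained, well under the €22,000 reference. Dabigatran and apixaban come out
at €4,356 and €28,813 per QALY, so the cost-effectiveness ranking is
rivaroxaban < dabigatran < apixaban, with apixaban above the threshold.

Sensitivity and scenario analyses follow the same pattern:

```r
tor <- tornado(params, "rivaroxaban")          # one-way DSA, sorted by spread
psa <- run_psa(params, n_draws = 1000, seed = 1)
prob_ce(psa, wtp = 22000)                      # P(cost-effective) per NOAC
run_scenario(params, "horizon_10")$icer_qaly   # published scenario analyses
```

A thin command-line wrapper with subcommands `run`, `psa`, `dsa`,
`scenario` and `synth-lifetable` is installed at
`inst/cli/noacce-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "noacce-cli.R", package = "noacce"))')" psa --n 1000 --seed 1
```

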