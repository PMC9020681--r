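---
title: "Model methods: a real-world-evidence Markov model of oral anticoagulation in atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noacce)
```

## The decision problem

`noacce` implements a Markov cohort state-transition model comparing three
non-vitamin-K oral anticoagulants (NOACs) — rivaroxaban, dabigatran and
apixaban — each against vitamin K antagonist (VKA) therapy for stroke
prevention in non-valvular atrial fibrillation (NVAF), from the Spanish
National Health System perspective with all inputs drawn from real-world
evidence. The cohort enters at a mean age of 73.4 years and is simulated in
3-month cycles over a 30-year (lifetime) horizon; costs (€2018) and health
outcomes are discounted at 3% per annum. Results are reported as discounted
costs by category, QALYs, life-years, expected lifetime event counts, and
incremental cost-effectiveness ratios (ICERs) against a willingness-to-pay
reference of €22,000 per QALY.

## State space

Health states: stable AF; acute and post states for minor ischaemic stroke,
major ischaemic stroke, myocardial infarction (MI) and intracranial
haemorrhage (ICH); an acute gastrointestinal (GI) bleeding state with no
post state (survivors return to stable AF); and absorbing death. Acute
states are tunnel states occupied for exactly one cycle.

Crossed with the health state, each patient carries a treatment status:

* `on_initial` — on the arm's drug, event risks scaled by the arm's hazard
  ratios;
* `switched_vka` — on VKA after discontinuing the initial drug (for the VKA
  arm this is a VKA-to-VKA switch, which changes nothing clinically);
* `off_treatment` — stopped anticoagulation entirely.

Because the whole cohort initiates treatment at cycle 0, the
time-since-initiation band that drives discontinuation (0–3, 3–6, 6–12, 12+
months) is a deterministic function of the cycle index and needs no extra
state dimension.

## Transition construction

**Event probabilities.** Baseline VKA-arm 3-month probabilities are derived
from event rates per 100 patient-years by the constant-hazard conversion
$p = 1 - e^{-(r/100)t}$ (`rate_to_prob()`); a linear mode exists for audit.
The exponential form reproduces the published per-cycle cells (GI 0.260%,
ICH 0.085%) at printed precision; the residual 0.001-percentage-point gap on
the MI cell traces to rounding of the printed source rate. The minor/major
ischaemic-stroke split is 0.41/0.59, chosen so the two derived cells (0.114%
and 0.163%) match their printed values. Hazard ratios and all other risk
modifiers act in the rate domain, $p' = 1-(1-p)^{h}$, which composes
multiplicatively and is consistent with the conversion convention.
Ischaemic-stroke probabilities are age-adjusted by the published relative
risks per 5-year band (reference 70–74).

**Mortality.** Background mortality comes from an annual life table,
converted per cycle as $1-(1-q_x)^{0.25}$ with the age floored. It combines
with acute case fatality (in the acute cycle) or post-state excess
mortality (every post cycle) as independent risks,
$q = 1-(1-q_{bg})(1-q_{event})$. The published inputs list post-state excess
mortality alongside per-event probabilities; we read it as per cycle, which
is the reading consistent with its placement, and flag it as a calibration
assumption.

**Subsequent events.** Patients in post-event states remain at risk of all
acute events at treatment-independent VKA baseline probabilities
(age-adjusted for stroke); a new event moves them to its acute state
(last event dominates).

**Discontinuation.** While `on_initial`, the per-cycle discontinuation
probability is the VKA band probability with the arm's discontinuation
hazard ratio applied. A discontinuing patient switches to VKA with the
arm's switch proportion and stops treatment otherwise. Two structural
choices matter here:

* *Patients on VKA after a switch keep discontinuing* at the VKA schedule,
  re-splitting by the VKA switch proportion (a VKA-to-VKA switch retains
  treatment). Without this, arms with high switch proportions would retain
  anticoagulation (and its costs and protection) forever, which is
  clinically untenable and incompatible with the published results; it also
  renders VKA-to-VKA switching meaningless. Config flag
  `switched_vka_discontinues`.
* *Major ischaemic stroke and ICH trigger permanent discontinuation* of
  anticoagulation (standard practice after intracranial bleeding and in the
  predecessor NICE-submission model). Config key
  `discontinue_after_events`.

**Off-treatment event risk.** The published inputs give no event rates for
patients who stop anticoagulation. Treating them as retaining VKA-level
risk is demonstrably inconsistent with the published lifetime event counts
(it roughly doubles the GI bleeding count and cannot reproduce the stroke
count), so the packaged default applies rate-domain multipliers to the VKA
baseline once a patient is off treatment: ischaemic stroke ×2.95 — in the
range implied by the classic meta-analytic warfarin-versus-no-treatment
stroke risk ratio (≈1/0.36 ≈ 2.8) — MI ×1, and GI/ICH bleeding ×0, since
the published bleeding counts are consistent with bleeding risk being
modelled only while anticoagulated. The stroke multiplier was fixed by a
documented grid calibration (`scripts/calibrate_admin.R`) against the
published ICERs, rank order and event counts, constrained to the clinically
plausible interval [1.5, 3.5]. Setting all multipliers to 1 restores fully
treatment-independent risk after stopping.

## Outcome accrual

All quantities are evaluated at cycle start with no half-cycle correction
(the convention of the predecessor model; a correction is deliberately not
applied in the base case). Per cycle: QALYs are occupancy × state utility ×
0.25 years × discount factor $(1.03)^{-t}$; life-years use utility 1; drug
acquisition cost is daily cost × 91.3125 days (365.25/4) for on-treatment
occupancy (the initial drug, or VKA after a switch); administration cost is
a per-cycle amount per on-treatment cycle; event-management costs charge
each acute-state occupancy the acute cost plus the event's rehabilitation
proportion × rehabilitation cost, and each post-state occupancy three
monthly follow-up costs (the post-ICH state carries the bleeding follow-up
cost). Event counts accumulate acute-state occupancy undiscounted. Events
of the final cycle fall outside the horizon and are neither costed nor
counted — a negligible end effect of the cycle-start convention.

**Administration costs.** The per-cycle administration/INR-monitoring
costs behind the published per-arm administration totals are not printed.
They are required config inputs; the packaged defaults (€98.87 per VKA
cycle, €44.9/€44.4/€45.4 per NOAC cycle) were solved exactly from the
published lifetime discounted administration totals given the model's
occupancy, in the same documented calibration script.

## Uncertainty analysis

**DSA (tornado).** Every parameter carrying a published range is varied one
at a time to its bounds, both arms re-run each time, and entries ordered by
ICER spread. Parameters specific to another comparator are excluded from an
arm's tornado — they cannot affect its comparison. The published MI monthly
follow-up cost range (129–215 around a mean of 516) does not bracket its
mean; it is stored verbatim, flagged, and used as printed.

**PSA.** Ranges are read as 95% intervals (spread = range/3.92).
Probabilities, proportions and utilities get beta distributions by method
of moments (mean = base); costs get gammas (shape = mean²/sd²). The source
table nominally assigns betas to hazard ratios, but a beta on [0, 1] cannot
represent HRs above 1 (e.g. GI 1.22), so hazard ratios default to lognormal
with median = base and log-sd from the range read as a 95% CI. Parameters
are drawn independently; the source states no correlation structure. The
default draw count is 1,000 (the published iteration count is unstated);
the CEAC reports, per threshold λ, the fraction of draws with positive net
monetary benefit λ·ΔQALY − ΔCost versus VKA.

**Scenarios.** `older_population` (entry age 77), `horizon_10`,
`horizon_20`, and `alternative_hr`, which requires a user-supplied
hazard-ratio table because the alternative treatment-effect estimates are
not part of the packaged inputs.

## Synthetic life table

The packaged life table is synthetic (filename says so): a Gompertz-Makeham
schedule $q_x = 1-\exp(-(a + b e^{cx}))$ with defaults $a=5\times10^{-4}$,
$b=5\times10^{-6}$, $c=0.114$, giving $q_{73}\approx0.021$ and period life
expectancy at 73 of about 14 years — matching Spanish national tables for
this cohort's entry age. It emulates the *level and slope* of elderly
all-cause mortality; it does not reproduce sex-specific schedules, cohort
trends, or the old-age mortality deceleration of real tables, so absolute
survival-dependent results (total QALYs, life-years) carry a percent-level
transfer error relative to runs on official tables. Users can substitute a
real national life table as a two-column CSV (`age,qx`).

## The microsimulation oracle

`microsimulate()` replays the cohort engine's own per-cycle transition
matrices patient by patient and accrues identical per-state utilities and
costs. It validates the cohort arithmetic (occupancy propagation, accrual
bookkeeping) by Monte-Carlo convergence — agreement within three standard
errors across random perturbed parameter sets — not the clinical content,
which both share by construction.

## Numerical choices and problem sizes

* Occupancy conservation is enforced to 1e-10 per cycle; event
  probabilities that would sum above 1 raise an error rather than being
  renormalised.
* Transition matrices are cached per (persistence band, integer age): they
  change only when the band, the stroke-risk age band, or the life-table
  year changes.
* Degenerate uncertainty (zero-width ranges) collapses to point masses;
  infeasible beta moments fall back to the flattest mean-preserving shape
  with parameters ≥ 1, with a warning.
* The test suite runs the full 120-cycle model for base-case checks, the
  microsimulation oracle at 10⁵ patients (single run) and 4,000–20,000
  patients (repeated perturbed runs at shorter horizons), and the PSA
  acceptance check at 200 draws; these sizes give Monte-Carlo error well
  inside the tolerances they are tested against.

## Known limitations

* The published model's full internals are not printed; unprinted inputs
  (administration costs, off-treatment risk, post-switch persistence) were
  fixed by the documented calibration above. The base case reproduces the
  published rank order and the dabigatran/apixaban ICERs within 25%, but
  the rivaroxaban ICER — whose published incremental cost of €77 is ~0.4%
  of total per-patient cost — remains hypersensitive to those internals and
  lands near €3,600 rather than €952.
* No treatment re-initiation after stopping, no individual covariate
  progression (renal function, dose adjustment), no treatment-related
  utility decrements, and no half-cycle correction.
* Sex and CHA₂DS₂-VASc composition are carried as cohort metadata only; the
  published inputs provide no risk stratification by them.
* Costs are consumed as printed €2018 values; no inflation or currency
  arithmetic is performed.
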