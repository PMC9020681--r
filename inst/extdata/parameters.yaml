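# Model inputs for the anticoagulant cost-effectiveness model (EUR 2018,
# Spanish NHS perspective). Scalar entries are {base, dsa_low, dsa_high, psa};
# entries without a range are fixed in DSA and PSA.

settings:
  cycle_length: 0.25          # years (3-month cycles)
  horizon: 30                 # years simulated (lifetime)
  discount_rate: 0.03         # per annum, costs and effects
  wtp_threshold: 22000        # EUR per QALY
  half_cycle_correction: false
  rate_conversion: exponential
  minor_is_fraction: 0.41     # minor share of ischaemic strokes (US RWE split)
  discontinue_after_events: [major_is, ich]
  switched_vka_discontinues: true   # VKA persistence applies after a switch

cohort:
  entry_age: 73.4
  male_fraction: 0.517
  cha2ds2vasc_high_fraction: 0.822

# Baseline event rates per 100 patient-years, VKA arm. Their uncertainty
# enters the model through the derived 3-month probabilities below, so the
# rates themselves carry no DSA range here.
clinical_rates:
  is:  {base: 1.11}
  gi:  {base: 1.04}
  ich: {base: 0.34}
  mi:  {base: 0.77}

# Printed DSA ranges of the derived 3-month probabilities (VKA arm); the
# base values are recomputed from the rates at load time.
cycle_probability_ranges:
  minor_is: {dsa_low: 0.00100, dsa_high: 0.00130, psa: beta}
  major_is: {dsa_low: 0.00144, dsa_high: 0.00187, psa: beta}
  mi:       {dsa_low: 0.00181, dsa_high: 0.00205, psa: beta}
  gi:       {dsa_low: 0.00225, dsa_high: 0.00297, psa: beta}
  ich:      {dsa_low: 0.00072, dsa_high: 0.00132, psa: beta}

# 3-month probabilities of discontinuation (VKA), by time since initiation.
discontinuation:
  m0_3:  {base: 0.1500, dsa_low: 0.1419, dsa_high: 0.1581, psa: beta}
  m3_6:  {base: 0.1059, dsa_low: 0.0989, dsa_high: 0.1128, psa: beta}
  m6_12: {base: 0.0823, dsa_low: 0.0761, dsa_high: 0.0885, psa: beta}
  m12p:  {base: 0.0640, dsa_low: 0.0586, dsa_high: 0.0695, psa: beta}

treatments:
  vka:
    daily_drug_cost: {base: 0.10}
    # per-cycle INR monitoring/administration cost; calibrated once so that
    # lifetime discounted administration costs approximate the published
    # per-arm totals (see scripts/calibrate_admin.R)
    admin_cost_per_cycle: {base: 98.8684}
    switch_proportion: {base: 0.258, dsa_low: 0.2193, dsa_high: 0.2967, psa: beta}
  rivaroxaban:
    daily_drug_cost: {base: 1.79}
    admin_cost_per_cycle: {base: 44.9417}
    switch_proportion: {base: 0.232, dsa_low: 0.1972, dsa_high: 0.2668, psa: beta}
    hazard_ratios:     # versus VKA; 'is' covers minor and major stroke
      is:  {base: 0.83, dsa_low: 0.75, dsa_high: 0.93, psa: lognormal}
      mi:  {base: 0.96, dsa_low: 0.80, dsa_high: 1.14, psa: lognormal}
      gi:  {base: 1.22, dsa_low: 1.12, dsa_high: 1.33, psa: lognormal}
      ich: {base: 0.68, dsa_low: 0.52, dsa_high: 0.90, psa: lognormal}
      discontinuation: {base: 0.62, dsa_low: 0.60, dsa_high: 0.65, psa: lognormal}
  dabigatran:
    daily_drug_cost: {base: 1.79}
    admin_cost_per_cycle: {base: 44.3937}
    switch_proportion: {base: 0.354, dsa_low: 0.3009, dsa_high: 0.4071, psa: beta}
    hazard_ratios:
      is:  {base: 0.79, dsa_low: 0.65, dsa_high: 0.97, psa: lognormal}
      mi:  {base: 0.84, dsa_low: 0.71, dsa_high: 1.00, psa: lognormal}
      gi:  {base: 1.12, dsa_low: 1.02, dsa_high: 1.24, psa: lognormal}
      ich: {base: 0.45, dsa_low: 0.36, dsa_high: 0.58, psa: lognormal}
      discontinuation: {base: 0.91, dsa_low: 0.53, dsa_high: 1.24, psa: lognormal}
  apixaban:
    daily_drug_cost: {base: 1.79}
    admin_cost_per_cycle: {base: 45.3945}
    switch_proportion: {base: 0.367, dsa_low: 0.3120, dsa_high: 0.4221, psa: beta}
    hazard_ratios:
      is:  {base: 1.01, dsa_low: 0.87, dsa_high: 1.17, psa: lognormal}
      mi:  {base: 1.00}    # no range published
      gi:  {base: 0.52, dsa_low: 0.38, dsa_high: 0.70, psa: lognormal}
      ich: {base: 0.41, dsa_low: 0.28, dsa_high: 0.60, psa: lognormal}
      discontinuation: {base: 1.08, dsa_low: 0.81, dsa_high: 1.45, psa: lognormal}

mortality:
  case_fatality:      # in-hospital death probability per acute event
    minor_is: {base: 0.0289, dsa_low: 0.0257, dsa_high: 0.0320, psa: beta}
    major_is: {base: 0.1260, dsa_low: 0.0940, dsa_high: 0.1570, psa: beta}
    mi:       {base: 0.0969, dsa_low: 0.0727, dsa_high: 0.1211, psa: beta}
    ich:      {base: 0.3885, dsa_low: 0.2914, dsa_high: 0.4856, psa: beta}
    gi:       {base: 0.0733, dsa_low: 0.0692, dsa_high: 0.0774, psa: beta}
  post_excess:        # per-cycle excess mortality in post-event states
    post_major_is: {base: 0.0263, dsa_low: 0.0091, dsa_high: 0.1350, psa: beta}
    post_mi:       {base: 0.0268, dsa_low: 0.0000, dsa_high: 0.0675, psa: beta}
    post_ich:      {base: 0.0263, dsa_low: 0.0091, dsa_high: 0.1350, psa: beta}

utilities:
  stable_af:     {base: 0.73, dsa_low: 0.71, dsa_high: 0.75, psa: beta}
  minor_is:      {base: 0.73, dsa_low: 0.55, dsa_high: 0.91, psa: beta}
  major_is:      {base: 0.41, dsa_low: 0.31, dsa_high: 0.51, psa: beta}
  post_minor_is: {base: 0.76, dsa_low: 0.57, dsa_high: 0.95, psa: beta}
  post_major_is: {base: 0.56, dsa_low: 0.42, dsa_high: 0.70, psa: beta}
  mi:            {base: 0.66, dsa_low: 0.53, dsa_high: 0.79, psa: beta}
  post_mi:       {base: 0.73, dsa_low: 0.58, dsa_high: 0.88, psa: beta}
  ich:           {base: 0.56, dsa_low: 0.45, dsa_high: 0.67, psa: beta}
  post_ich:      {base: 0.67, dsa_low: 0.54, dsa_high: 0.80, psa: beta}
  gi:            {base: 0.70, dsa_low: 0.56, dsa_high: 0.84, psa: beta}

costs:                # EUR 2018
  acute:              # per event
    minor_is: {base: 5258, dsa_low: 3953, dsa_high: 6572, psa: gamma}
    major_is: {base: 7208, dsa_low: 5406, dsa_high: 9010, psa: gamma}
    mi:       {base: 5174, dsa_low: 3880, dsa_high: 6467, psa: gamma}
    gi:       {base: 3579, dsa_low: 2685, dsa_high: 4474, psa: gamma}
    ich:      {base: 7793, dsa_low: 5845, dsa_high: 9741, psa: gamma}
  monthly_followup:   # EUR per month in the post-event state
    minor_is: {base: 124,  dsa_low: 93,   dsa_high: 156,  psa: gamma}
    major_is: {base: 2159, dsa_low: 1619, dsa_high: 2699, psa: gamma}
    # published range does not bracket the mean; stored verbatim and flagged
    mi:       {base: 516,  dsa_low: 129,  dsa_high: 215,  psa: gamma,
               range_inconsistent: true}
    bleeding: {base: 191,  dsa_low: 143,  dsa_high: 238,  psa: gamma}
  rehabilitation:     # one-off, weighted by the proportions below
    is:       {base: 3015, dsa_low: 2261, dsa_high: 3768, psa: gamma}
    bleeding: {base: 2874, dsa_low: 2155, dsa_high: 3592, psa: gamma}
  rehabilitation_proportions:
    minor_is: {base: 0.050, dsa_low: 0.0425, dsa_high: 0.0575, psa: beta}
    major_is: {base: 0.374, dsa_low: 0.3179, dsa_high: 0.4301, psa: beta}
    gi:       {base: 0.106, dsa_low: 0.0901, dsa_high: 0.1219, psa: beta}
    ich:      {base: 0.450, dsa_low: 0.3825, dsa_high: 0.5175, psa: beta}

# Event-risk multipliers (rate domain, versus VKA baseline) applied to
# patients who stopped anticoagulation: stroke risk rises towards the
# untreated level, bleeding risk falls. Set all to 1 for treatment-
# independent risk after stopping.
off_treatment_multipliers:
  is:  {base: 2.95}
  mi:  {base: 1.00}
  gi:  {base: 0.00}
  ich: {base: 0.00}

age_relative_risk:    # ischaemic stroke relative risk by age band
  - {age_min: 55, age_max: 59, rr: 0.667}
  - {age_min: 60, age_max: 64, rr: 0.760}
  - {age_min: 65, age_max: 69, rr: 0.854}
  - {age_min: 70, age_max: 74, rr: 1.000}
  - {age_min: 75, age_max: 79, rr: 1.146}
  - {age_min: 80, age_max: 84, rr: 1.281}
  - {age_min: 85, age_max: 89, rr: 1.480}
  - {age_min: 90, age_max: 120, rr: 1.719}
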