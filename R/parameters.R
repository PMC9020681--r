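# Parameter model: every clinical, treatment, utility and cost input of the
# decision model, held as a flat named-value registry (for DSA/PSA) plus
# structured settings. Loaded from a YAML config whose sections mirror the
# published input tables.

EVENTS <- c("minor_is", "major_is", "mi", "gi", "ich")
ARMS <- c("vka", "rivaroxaban", "dabigatran", "apixaban")

#' Path to the packaged default parameter configuration
#' @return File path of the YAML config shipped with the package.
#' @export
default_parameters_path <- function() {
  system.file("extdata", "parameters.yaml", package = "noacce", mustWork = TRUE)
}

#' Path to the packaged synthetic Spanish-style life table
#' @return File path of the two-column CSV life table shipped with the package.
#' @export
default_life_table_path <- function() {
  system.file("extdata", "life_table_synthetic_es.csv",
              package = "noacce", mustWork = TRUE)
}

ylist <- function(node, key) {
  if (is.null(node[[key]]))
    stop("parameter config: missing key '", key, "'", call. = FALSE)
  node[[key]]
}

# One registry entry: base value plus optional DSA range and PSA distribution.
reg_entry <- function(id, node, group) {
  if (is.numeric(node) && length(node) == 1L)
    node <- list(base = node)
  base <- node$base
  if (is.null(base) || !is.numeric(base))
    stop("parameter config: '", id, "' has no numeric 'base'", call. = FALSE)
  low <- if (is.null(node$dsa_low)) NA_real_ else as.numeric(node$dsa_low)
  high <- if (is.null(node$dsa_high)) NA_real_ else as.numeric(node$dsa_high)
  dist <- if (is.null(node$psa)) "fixed" else as.character(node$psa)
  if (!dist %in% c("fixed", "beta", "gamma", "lognormal"))
    stop("parameter config: '", id, "' has unknown psa distribution '",
         dist, "'", call. = FALSE)
  flagged <- isTRUE(node$range_inconsistent)
  if (!flagged && !is.na(low) && !is.na(high) &&
      (low > base + 1e-12 || high < base - 1e-12))
    stop("parameter config: DSA range of '", id,
         "' does not bracket its base value", call. = FALSE)
  data.frame(id = id, base = base, dsa_low = low, dsa_high = high,
             dist = dist, group = group,
             range_inconsistent = flagged, stringsAsFactors = FALSE)
}

#' Load and validate a model parameter set
#'
#' Reads the structured YAML configuration (sections mirroring the published
#' input tables: baseline event rates, 3-month probabilities, discontinuation,
#' switch proportions, hazard ratios, mortality, utilities, costs,
#' rehabilitation) together with a life table, and returns a validated
#' `noacce_params` object. The baseline per-cycle event probabilities are
#' derived from the event rates per 100 patient-years via [rate_to_prob()]
#' and the minor/major ischaemic-stroke split.
#'
#' @param path Path to the YAML config; defaults to the packaged fixture.
#' @param life_table A life table as returned by [read_life_table()] /
#'   [make_life_table()], or a path to a two-column CSV; defaults to the
#'   packaged synthetic table.
#' @return An object of class `noacce_params`.
#' @export
load_parameters <- function(path = default_parameters_path(),
                            life_table = default_life_table_path()) {
  if (!file.exists(path))
    stop("parameter config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)

  settings <- ylist(cfg, "settings")
  cohort <- ylist(cfg, "cohort")
  set <- list(
    cycle_length = as.numeric(ylist(settings, "cycle_length")),
    horizon = as.numeric(ylist(settings, "horizon")),
    discount_rate = as.numeric(ylist(settings, "discount_rate")),
    wtp_threshold = as.numeric(ylist(settings, "wtp_threshold")),
    half_cycle_correction = isTRUE(settings$half_cycle_correction),
    rate_conversion = if (is.null(settings$rate_conversion)) "exponential"
                      else settings$rate_conversion,
    minor_is_fraction = as.numeric(ylist(settings, "minor_is_fraction")),
    discontinue_after_events = as.character(
      if (is.null(settings$discontinue_after_events)) c("major_is", "ich")
      else settings$discontinue_after_events),
    switched_vka_discontinues =
      if (is.null(settings$switched_vka_discontinues)) TRUE
      else isTRUE(settings$switched_vka_discontinues),
    entry_age = as.numeric(ylist(cohort, "entry_age")),
    male_fraction = as.numeric(ylist(cohort, "male_fraction")),
    cha2ds2vasc_high_fraction = as.numeric(
      ylist(cohort, "cha2ds2vasc_high_fraction"))
  )
  if (set$cycle_length <= 0 || set$cycle_length > set$horizon)
    stop("settings: need 0 < cycle_length <= horizon", call. = FALSE)
  if (set$discount_rate < 0)
    stop("settings: discount_rate must be non-negative", call. = FALSE)
  if (set$minor_is_fraction < 0 || set$minor_is_fraction > 1)
    stop("settings: minor_is_fraction must lie in [0, 1]", call. = FALSE)
  if (set$entry_age <= 0)
    stop("cohort: entry_age must be positive", call. = FALSE)
  for (f in c("male_fraction", "cha2ds2vasc_high_fraction"))
    if (set[[f]] < 0 || set[[f]] > 1)
      stop("cohort: ", f, " must lie in [0, 1]", call. = FALSE)

  reg <- list()
  add <- function(id, node, group) reg[[length(reg) + 1L]] <<-
    reg_entry(id, node, group)

  # Baseline event rates (per 100 patient-years, VKA arm) and the derived
  # 3-month probabilities. DSA/PSA act on the probabilities, whose printed
  # ranges are stored in the config alongside the source rates.
  rates <- ylist(cfg, "clinical_rates")
  pr <- ylist(cfg, "cycle_probability_ranges")
  conv <- function(r) rate_to_prob(r, set$cycle_length,
                                   method = set$rate_conversion)
  rate_of <- function(ev) as.numeric(ylist(rates, ev)$base)
  p_is <- conv(rate_of("is"))
  base_p <- c(minor_is = set$minor_is_fraction * p_is,
              major_is = (1 - set$minor_is_fraction) * p_is,
              mi = conv(rate_of("mi")),
              gi = conv(rate_of("gi")),
              ich = conv(rate_of("ich")))
  for (ev in EVENTS) {
    node <- ylist(pr, ev)
    node$base <- unname(base_p[[ev]])
    add(paste0("p_", ev), node, "cycle_probability")
  }
  for (rn in c("is", "gi", "ich", "mi"))
    add(paste0("rate_", rn), ylist(rates, rn), "event_rate")

  disc <- ylist(cfg, "discontinuation")
  for (band in c("m0_3", "m3_6", "m6_12", "m12p"))
    add(paste0("disc_", band), ylist(disc, band), "discontinuation")

  trts <- ylist(cfg, "treatments")
  for (arm in ARMS) {
    tn <- ylist(trts, arm)
    add(paste0("daily_cost_", arm), ylist(tn, "daily_drug_cost"), "drug_cost")
    add(paste0("admin_cycle_", arm), ylist(tn, "admin_cost_per_cycle"),
        "admin_cost")
    add(paste0("switch_", arm), ylist(tn, "switch_proportion"), "switch")
    hrs <- if (is.null(tn$hazard_ratios)) list() else tn$hazard_ratios
    for (h in c("is", "mi", "gi", "ich", "discontinuation")) {
      node <- if (arm == "vka") list(base = 1) else ylist(hrs, h)
      add(paste0("hr_", h, "_", arm), node, "hazard_ratio")
    }
  }

  mort <- ylist(cfg, "mortality")
  cf <- ylist(mort, "case_fatality")
  for (ev in EVENTS)
    add(paste0("cf_", ev), ylist(cf, ev), "case_fatality")
  px <- ylist(mort, "post_excess")
  for (st in c("post_major_is", "post_mi", "post_ich"))
    add(paste0("excess_", st), ylist(px, st), "post_excess_mortality")

  ut <- ylist(cfg, "utilities")
  for (st in c("stable_af", "minor_is", "major_is", "post_minor_is",
               "post_major_is", "mi", "post_mi", "ich", "post_ich", "gi"))
    add(paste0("u_", st), ylist(ut, st), "utility")

  co <- ylist(cfg, "costs")
  ac <- ylist(co, "acute")
  for (ev in EVENTS)
    add(paste0("c_acute_", ev), ylist(ac, ev), "cost")
  fu <- ylist(co, "monthly_followup")
  for (st in c("minor_is", "major_is", "mi", "bleeding"))
    add(paste0("c_fu_", st), ylist(fu, st), "cost")
  rh <- ylist(co, "rehabilitation")
  add("c_rehab_is", ylist(rh, "is"), "cost")
  add("c_rehab_bleeding", ylist(rh, "bleeding"), "cost")
  rp <- ylist(co, "rehabilitation_proportions")
  for (ev in c("minor_is", "major_is", "gi", "ich"))
    add(paste0("rehab_", ev), ylist(rp, ev), "rehab_proportion")

  om <- ylist(cfg, "off_treatment_multipliers")
  for (ev in c("is", "mi", "gi", "ich"))
    add(paste0("offmult_", ev), ylist(om, ev), "off_treatment")

  meta <- do.call(rbind, reg)
  if (anyDuplicated(meta$id))
    stop("parameter config: duplicated parameter id", call. = FALSE)
  values <- stats::setNames(meta$base, meta$id)

  arr <- ylist(cfg, "age_relative_risk")
  age_rr <- do.call(rbind, lapply(arr, function(b)
    data.frame(age_min = as.numeric(b$age_min),
               age_max = as.numeric(b$age_max),
               rr = as.numeric(b$rr))))
  age_rr <- age_rr[order(age_rr$age_min), , drop = FALSE]

  lt <- if (is.character(life_table)) read_life_table(life_table) else life_table

  obj <- structure(list(values = values, meta = meta, settings = set,
                        age_rr = age_rr, life_table = lt,
                        arms = ARMS, config_path = normalizePath(path)),
                   class = "noacce_params")
  validate_parameters(obj)
  obj
}

#' Validate a parameter set
#'
#' Checks every invariant of the data model: probabilities, proportions and
#' utilities in \[0, 1\]; event probabilities summing below 1; positive hazard
#' ratios (all exactly 1 for the VKA arm); non-negative costs; a reference
#' age band with relative risk 1 and strictly increasing relative risks; and
#' a valid life table. Errors name the offending key.
#'
#' @param params A `noacce_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "noacce_params"))
  v <- params$values
  chk01 <- function(ids) {
    bad <- ids[v[ids] < 0 | v[ids] > 1]
    if (length(bad))
      stop("parameter '", bad[[1L]], "' must lie in [0, 1] (got ",
           v[[bad[[1L]]]], ")", call. = FALSE)
  }
  grp <- function(g) params$meta$id[params$meta$group == g]
  chk01(grp("cycle_probability"))
  chk01(grp("discontinuation"))
  chk01(grp("switch"))
  chk01(grp("case_fatality"))
  chk01(grp("post_excess_mortality"))
  chk01(grp("utility"))
  chk01(grp("rehab_proportion"))
  if (sum(v[paste0("p_", EVENTS)]) > 1)
    stop("baseline per-cycle event probabilities sum above 1", call. = FALSE)
  hr_ids <- grp("hazard_ratio")
  if (any(v[hr_ids] <= 0))
    stop("parameter '", hr_ids[v[hr_ids] <= 0][[1L]],
         "' : hazard ratios must be positive", call. = FALSE)
  vka_hr <- v[paste0("hr_", c("is", "mi", "gi", "ich", "discontinuation"),
                     "_vka")]
  if (any(vka_hr != 1))
    stop("VKA arm hazard ratios must all equal 1", call. = FALSE)
  cost_ids <- c(grp("cost"), grp("drug_cost"), grp("admin_cost"))
  if (any(v[cost_ids] < 0))
    stop("parameter '", cost_ids[v[cost_ids] < 0][[1L]],
         "' : costs must be non-negative", call. = FALSE)
  off_ids <- grp("off_treatment")
  if (any(v[off_ids] < 0))
    stop("off-treatment risk multipliers must be non-negative", call. = FALSE)
  arr <- params$age_rr
  if (!any(abs(arr$rr - 1) < 1e-12))
    stop("age_relative_risk: no reference band with RR exactly 1", call. = FALSE)
  if (any(diff(arr$rr) <= 0))
    stop("age_relative_risk: relative risks must be strictly increasing",
         call. = FALSE)
  validate_life_table(params$life_table,
                      entry_age = params$settings$entry_age)
  invisible(params)
}

#' Working values of all model parameters
#' @param params A `noacce_params` object.
#' @return Named numeric vector of the current parameter values.
#' @export
param_values <- function(params) params$values

#' Replace working values of model parameters
#'
#' Used by the sensitivity machinery: any subset of registry ids can be set;
#' the result is re-validated.
#'
#' @param params A `noacce_params` object.
#' @param values Named numeric vector; names must be registry ids.
#' @return The modified, validated `noacce_params` object.
#' @export
set_param_values <- function(params, values) {
  unknown <- setdiff(names(values), names(params$values))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params$values[names(values)] <- values
  validate_parameters(params)
  params
}

#' Registry of parameters with DSA ranges and PSA distributions
#' @param params A `noacce_params` object.
#' @param varied_only If `TRUE`, keep only parameters with a DSA range.
#' @return Data frame with columns id, base, dsa_low, dsa_high, dist, group.
#' @export
param_table <- function(params, varied_only = FALSE) {
  m <- params$meta
  m$base <- unname(params$values[m$id])  # reflect working values
  if (varied_only)
    m <- m[!is.na(m$dsa_low) & !is.na(m$dsa_high), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Age-specific relative risk of ischaemic stroke
#'
#' Looks up the relative risk of the age band containing `floor(age)`.
#' Ages below the first band clamp to the first band; ages at or above the
#' open-ended top band return its relative risk.
#'
#' @param age Age in years (non-negative); vectorised.
#' @param table Data frame with columns `age_min`, `age_max`, `rr`
#'   (as in `params$age_rr`).
#' @return Relative risk(s).
#' @export
age_stroke_rr <- function(age, table) {
  if (any(age < 0)) stop("'age' must be non-negative", call. = FALSE)
  a <- floor(age)
  idx <- findInterval(a, table$age_min)  # 0 when below the first band
  idx[idx < 1L] <- 1L
  table$rr[idx]
}

#' Per-cycle probability of treatment discontinuation
#'
#' Selects the persistence band containing `months` since treatment
#' initiation (0-3, 3-6, 6-12, 12+ months) and applies the treatment's
#' discontinuation hazard ratio via [apply_hr()].
#'
#' @param months Months since treatment initiation (non-negative); vectorised.
#' @param schedule Numeric vector of four per-cycle probabilities, in band
#'   order (0-3, 3-6, 6-12, 12+ months).
#' @param hr Discontinuation hazard ratio versus VKA (default 1).
#' @return Per-cycle discontinuation probability.
#' @export
discontinuation_probability <- function(months, schedule, hr = 1) {
  if (any(months < 0)) stop("'months' must be non-negative", call. = FALSE)
  if (length(schedule) != 4L || any(schedule < 0) || any(schedule > 1))
    stop("'schedule' must be four probabilities in [0, 1]", call. = FALSE)
  band <- findInterval(months, c(0, 3, 6, 12))
  apply_hr(schedule[band], hr)
}

#' @export
print.noacce_params <- function(x, ...) {
  s <- x$settings
  cat("<noacce_params>\n")
  cat(sprintf("  cohort entry age %.1f y; %d-cycle horizon (%.0f y, %.2f-y cycles)\n",
              s$entry_age, as.integer(round(s$horizon / s$cycle_length)),
              s$horizon, s$cycle_length))
  cat(sprintf("  discount %.1f%%/y; WTP threshold %s EUR/QALY\n",
              100 * s$discount_rate, format(s$wtp_threshold, big.mark = ",")))
  cat(sprintf("  %d registered parameters (%d with DSA ranges); life table ages %d-%d\n",
              nrow(x$meta), nrow(param_table(x, varied_only = TRUE)),
              min(x$life_table$age), max(x$life_table$age)))
  invisible(x)
}
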