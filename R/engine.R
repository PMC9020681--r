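# Markov cohort engine. Composite state space: 10 health states crossed with
# 3 treatment statuses, plus the absorbing death state. Acute event states
# are tunnel states occupied for exactly one cycle; the persistence band is a
# deterministic function of the cycle index (the whole cohort initiates
# treatment at cycle 0), so it needs no extra state dimension.

HEALTH <- c("stable_af", "acute_minor_is", "post_minor_is", "acute_major_is",
            "post_major_is", "acute_mi", "post_mi", "acute_ich", "post_ich",
            "acute_gi")
TX <- c("on_initial", "switched_vka", "off_treatment")
N_HEALTH <- length(HEALTH)
N_STATES <- N_HEALTH * length(TX) + 1L  # + dead
DEAD <- N_STATES

state_index <- function(health, tx) {
  h <- match(health, HEALTH)
  t <- match(tx, TX)
  (t - 1L) * N_HEALTH + h
}

#' Names of the composite model states
#' @return Character vector of the 31 state labels (health x treatment
#'   status, plus `dead`).
#' @export
model_states <- function() {
  c(as.vector(outer(HEALTH, TX, paste, sep = ".")), "dead")
}

ACUTE_OF <- c(minor_is = "acute_minor_is", major_is = "acute_major_is",
              mi = "acute_mi", gi = "acute_gi", ich = "acute_ich")
POST_OF <- c(acute_minor_is = "post_minor_is", acute_major_is = "post_major_is",
             acute_mi = "post_mi", acute_ich = "post_ich",
             acute_gi = "stable_af")  # GI bleeding has no post state

# Resolve everything the engine needs for one arm into plain vectors.
model_inputs <- function(params, arm) {
  arm <- match.arg(arm, params$arms)
  v <- params$values
  s <- params$settings
  n_cycles <- s$horizon / s$cycle_length
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("horizon must be a whole number of cycles", call. = FALSE)
  n_cycles <- as.integer(round(n_cycles))

  hr_is <- v[[paste0("hr_is_", arm)]]
  list(
    arm = arm, n_cycles = n_cycles, cycle_length = s$cycle_length,
    entry_age = s$entry_age, discount = s$discount_rate,
    p_base = c(minor_is = v[["p_minor_is"]], major_is = v[["p_major_is"]],
               mi = v[["p_mi"]], gi = v[["p_gi"]], ich = v[["p_ich"]]),
    hr = c(minor_is = hr_is, major_is = hr_is, mi = v[[paste0("hr_mi_", arm)]],
           gi = v[[paste0("hr_gi_", arm)]], ich = v[[paste0("hr_ich_", arm)]]),
    offmult = c(minor_is = v[["offmult_is"]], major_is = v[["offmult_is"]],
                mi = v[["offmult_mi"]], gi = v[["offmult_gi"]],
                ich = v[["offmult_ich"]]),
    cf = c(acute_minor_is = v[["cf_minor_is"]],
           acute_major_is = v[["cf_major_is"]], acute_mi = v[["cf_mi"]],
           acute_ich = v[["cf_ich"]], acute_gi = v[["cf_gi"]]),
    excess = c(post_minor_is = 0, post_major_is = v[["excess_post_major_is"]],
               post_mi = v[["excess_post_mi"]],
               post_ich = v[["excess_post_ich"]]),
    disc_sched = unname(v[paste0("disc_", c("m0_3", "m3_6", "m6_12", "m12p"))]),
    hr_disc = v[[paste0("hr_discontinuation_", arm)]],
    switch_prop = v[[paste0("switch_", arm)]],
    switch_vka = v[["switch_vka"]],
    switched_discontinues = isTRUE(s$switched_vka_discontinues),
    disc_after = s$discontinue_after_events,
    daily_cost = c(arm = v[[paste0("daily_cost_", arm)]],
                   vka = v[["daily_cost_vka"]]),
    admin_cost = c(arm = v[[paste0("admin_cycle_", arm)]],
                   vka = v[["admin_cycle_vka"]]),
    u_health = c(stable_af = v[["u_stable_af"]],
                 acute_minor_is = v[["u_minor_is"]],
                 post_minor_is = v[["u_post_minor_is"]],
                 acute_major_is = v[["u_major_is"]],
                 post_major_is = v[["u_post_major_is"]],
                 acute_mi = v[["u_mi"]], post_mi = v[["u_post_mi"]],
                 acute_ich = v[["u_ich"]], post_ich = v[["u_post_ich"]],
                 acute_gi = v[["u_gi"]]),
    acute_cost = c(
      acute_minor_is = v[["c_acute_minor_is"]] +
        v[["rehab_minor_is"]] * v[["c_rehab_is"]],
      acute_major_is = v[["c_acute_major_is"]] +
        v[["rehab_major_is"]] * v[["c_rehab_is"]],
      acute_mi = v[["c_acute_mi"]],
      acute_gi = v[["c_acute_gi"]] + v[["rehab_gi"]] * v[["c_rehab_bleeding"]],
      acute_ich = v[["c_acute_ich"]] +
        v[["rehab_ich"]] * v[["c_rehab_bleeding"]]),
    cycle_fu_cost = c(post_minor_is = 3 * v[["c_fu_minor_is"]],
                      post_major_is = 3 * v[["c_fu_major_is"]],
                      post_mi = 3 * v[["c_fu_mi"]],
                      post_ich = 3 * v[["c_fu_bleeding"]]),
    age_rr = params$age_rr, life_table = params$life_table
  )
}

# Per-cycle stroke relative risk, background mortality and discontinuation
# probability; the matrix cache key below collapses cycles sharing all three.
cycle_band <- function(k) {
  months <- 3 * k
  findInterval(months, c(0, 3, 6, 12))
}

#' Transition matrix of the cohort model for one cycle
#'
#' Builds the full transition probability matrix over the 31 composite
#' states for cycle `cycle` (0-based) of treatment arm `arm`. Construction:
#' event probabilities from the stable state depend on treatment exposure
#' (initial drug via its hazard ratios; switched-to-VKA at VKA baseline;
#' off-treatment at VKA baseline scaled by the off-treatment risk
#' multipliers), with ischaemic-stroke probabilities age-adjusted; death
#' combines background mortality with acute case fatality or post-state
#' excess mortality as independent risks; acute states resolve in one cycle
#' to their post state (GI bleeding back to stable AF); discontinuation of
#' the initial treatment splits by the switch proportion into
#' switched-to-VKA versus off-treatment; major ischaemic stroke and
#' intracranial haemorrhage trigger permanent treatment discontinuation.
#' Patients in post-event states face subsequent events at treatment-
#' independent VKA baseline probabilities.
#'
#' @param params A `noacce_params` object.
#' @param arm Arm name (`"vka"`, `"rivaroxaban"`, `"dabigatran"`,
#'   `"apixaban"`).
#' @param cycle 0-based cycle index.
#' @return A 31 x 31 row-stochastic matrix with dimnames [model_states()].
#' @export
transition_matrix <- function(params, arm, cycle) {
  mi_ <- model_inputs(params, arm)
  build_transition_matrix(mi_, cycle)
}

#' Transition distribution from a single state
#'
#' Row of [transition_matrix()] for one origin state.
#'
#' @param state A state label as in [model_states()].
#' @param cycle 0-based cycle index.
#' @inheritParams transition_matrix
#' @return Named numeric vector over the 31 destination states (sums to 1).
#' @export
transition_distribution <- function(state, cycle, params, arm) {
  M <- transition_matrix(params, arm, cycle)
  if (!state %in% rownames(M))
    stop("unknown state '", state, "'", call. = FALSE)
  M[state, ]
}

build_transition_matrix <- function(mi_, k) {
  age <- mi_$entry_age + k * mi_$cycle_length
  rr <- age_stroke_rr(age, mi_$age_rr)
  bg <- annual_to_cycle_prob(life_table_qx(mi_$life_table, age),
                             mi_$cycle_length)
  d <- apply_hr(mi_$disc_sched[cycle_band(k)], mi_$hr_disc)
  sw <- mi_$switch_prop

  # hazard multipliers act in the rate domain; stroke events also carry the age RR
  is_stroke <- EVENTS %in% c("minor_is", "major_is")
  fac_age <- ifelse(is_stroke, rr, 1)
  padj <- function(mult) 1 - (1 - mi_$p_base)^(mult * fac_age)
  ev_by_tx <- list(on_initial = padj(mi_$hr),
                   switched_vka = padj(rep(1, 5)),
                   off_treatment = padj(mi_$offmult))
  for (e in ev_by_tx)
    if (sum(e) > 1)
      stop("event probabilities sum above 1 in cycle ", k,
           "; inconsistent inputs", call. = FALSE)

  # treatment-status transition weights from each current status. Patients
  # on VKA after a switch keep discontinuing at the VKA schedule (a VKA->VKA
  # switch retains treatment); configurable off for audit.
  d_sw <- if (mi_$switched_discontinues)
    mi_$disc_sched[cycle_band(k)] * (1 - mi_$switch_vka) else 0
  w_tx <- list(
    on_initial = c(on_initial = 1 - d, switched_vka = d * sw,
                   off_treatment = d * (1 - sw)),
    switched_vka = c(on_initial = 0, switched_vka = 1 - d_sw,
                     off_treatment = d_sw),
    off_treatment = c(on_initial = 0, switched_vka = 0, off_treatment = 1))

  forced_off <- ACUTE_OF[mi_$disc_after]  # acute states entered off treatment

  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(model_states(), model_states()))
  add <- function(i, health, tx, p) {
    j <- state_index(health, tx)
    M[i, j] <<- M[i, j] + p
  }

  for (tx in TX) {
    w <- w_tx[[tx]]
    # --- stable AF: at risk of first/new events under current exposure
    i <- state_index("stable_af", tx)
    ev <- ev_by_tx[[tx]]
    surv <- 1 - bg
    for (e in EVENTS) {
      dest <- ACUTE_OF[[e]]
      if (dest %in% forced_off) {
        add(i, dest, "off_treatment", surv * ev[[e]])
      } else {
        for (t2 in TX) if (w[[t2]] > 0) add(i, dest, t2, surv * ev[[e]] * w[[t2]])
      }
    }
    for (t2 in TX) if (w[[t2]] > 0)
      add(i, "stable_af", t2, surv * (1 - sum(ev)) * w[[t2]])
    M[i, DEAD] <- bg

    # --- acute tunnel states: resolve to post state or die
    for (a in names(mi_$cf)) {
      i <- state_index(a, tx)
      q <- 1 - (1 - bg) * (1 - mi_$cf[[a]])
      dest <- POST_OF[[a]]
      for (t2 in TX) if (w[[t2]] > 0) add(i, dest, t2, (1 - q) * w[[t2]])
      M[i, DEAD] <- q
    }

    # --- post-event states: subsequent events at VKA baseline, excess death
    ev_post <- ev_by_tx$switched_vka  # treatment-independent baseline
    for (p in names(mi_$excess)) {
      i <- state_index(p, tx)
      q <- 1 - (1 - bg) * (1 - mi_$excess[[p]])
      for (e in EVENTS) {
        dest <- ACUTE_OF[[e]]
        if (dest %in% forced_off) {
          add(i, dest, "off_treatment", (1 - q) * ev_post[[e]])
        } else {
          for (t2 in TX) if (w[[t2]] > 0)
            add(i, dest, t2, (1 - q) * ev_post[[e]] * w[[t2]])
        }
      }
      for (t2 in TX) if (w[[t2]] > 0)
        add(i, p, t2, (1 - q) * (1 - sum(ev_post)) * w[[t2]])
      M[i, DEAD] <- q
    }
  }
  M[DEAD, DEAD] <- 1
  M
}

# Transition matrices for all cycles, cached by (band, integer age): the
# matrix changes only when the persistence band, the age band of the stroke
# RR, or the life-table year changes.
transition_matrices <- function(mi_) {
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(mi_$n_cycles) - 1L, function(k) {
    key <- paste(cycle_band(k), floor(mi_$entry_age + k * mi_$cycle_length))
    if (is.null(cache[[key]])) cache[[key]] <- build_transition_matrix(mi_, k)
    cache[[key]]
  })
}

#' Run the Markov cohort for one treatment arm
#'
#' Iterates the cohort (starting 100% in stable AF, on initial treatment)
#' over the full horizon and accumulates discounted outcomes. Per cycle,
#' evaluated at cycle start (no half-cycle correction): QALYs as occupancy
#' times state utility times cycle length; life-years analogously with
#' utility 1; drug acquisition cost as daily cost times 91.3125 days for
#' on-treatment occupancy (initial drug or VKA after a switch);
#' administration cost per on-treatment cycle; event management costs as
#' acute-state occupancy times (acute cost + rehabilitation proportion times
#' rehabilitation cost) plus post-state occupancy times three monthly
#' follow-up costs; event counts (undiscounted) as acute-state occupancy.
#'
#' @inheritParams transition_matrix
#' @return A `noacce_arm` object: discounted cost components and totals,
#'   QALYs, life-years, expected event counts, and the cohort trace
#'   (occupancy per cycle with cohort age).
#' @export
run_cohort <- function(params, arm) {
  mi_ <- model_inputs(params, arm)
  Ts <- transition_matrices(mi_)
  n <- mi_$n_cycles
  trace <- matrix(0, n + 1L, N_STATES,
                  dimnames = list(NULL, model_states()))
  trace[1L, state_index("stable_af", "on_initial")] <- 1
  for (k in seq_len(n))
    trace[k + 1L, ] <- trace[k, , drop = FALSE] %*% Ts[[k]]

  occ <- trace[seq_len(n), , drop = FALSE]  # cycle-start occupancy
  t_years <- (seq_len(n) - 1L) * mi_$cycle_length
  df <- discount_factor(t_years, mi_$discount)

  u_state <- c(rep(mi_$u_health[HEALTH], length(TX)), 0)
  alive <- c(rep(1, N_STATES - 1L), 0)
  qalys <- sum(df * (occ %*% u_state) * mi_$cycle_length)
  lys <- sum(df * (occ %*% alive) * mi_$cycle_length)

  on_cols <- state_index(HEALTH, rep("on_initial", N_HEALTH))
  sw_cols <- state_index(HEALTH, rep("switched_vka", N_HEALTH))
  occ_on <- rowSums(occ[, on_cols, drop = FALSE])
  occ_sw <- rowSums(occ[, sw_cols, drop = FALSE])
  days <- 365.25 / 4 * (mi_$cycle_length / 0.25)
  drug_cost <- sum(df * days * (mi_$daily_cost[["arm"]] * occ_on +
                                  mi_$daily_cost[["vka"]] * occ_sw))
  admin_cost <- sum(df * (mi_$admin_cost[["arm"]] * occ_on +
                            mi_$admin_cost[["vka"]] * occ_sw))

  health_occ <- function(h) {
    cols <- state_index(rep(h, length(TX)), TX)
    rowSums(occ[, cols, drop = FALSE])
  }
  event_cost <- 0
  for (a in names(mi_$acute_cost))
    event_cost <- event_cost + sum(df * health_occ(a) * mi_$acute_cost[[a]])
  for (p in names(mi_$cycle_fu_cost))
    event_cost <- event_cost + sum(df * health_occ(p) * mi_$cycle_fu_cost[[p]])

  events <- c(
    ischaemic_stroke = sum(health_occ("acute_minor_is")) +
      sum(health_occ("acute_major_is")),
    mi = sum(health_occ("acute_mi")),
    ich = sum(health_occ("acute_ich")),
    gi = sum(health_occ("acute_gi")))

  structure(list(
    arm = arm,
    costs = c(drug_acquisition = drug_cost, administration = admin_cost,
              event_management = event_cost,
              total = drug_cost + admin_cost + event_cost),
    qalys = qalys, lys = lys, events = events,
    trace = structure(list(occupancy = trace,
                           age = mi_$entry_age + (0:n) * mi_$cycle_length),
                      class = "noacce_trace"),
    settings = params$settings), class = "noacce_arm")
}

#' @export
print.noacce_arm <- function(x, ...) {
  cat(sprintf("<noacce_arm> %s\n", x$arm))
  cat(sprintf("  total cost EUR %s (drug %s, admin %s, events %s)\n",
              format(round(x$costs[["total"]]), big.mark = ","),
              format(round(x$costs[["drug_acquisition"]]), big.mark = ","),
              format(round(x$costs[["administration"]]), big.mark = ","),
              format(round(x$costs[["event_management"]]), big.mark = ",")))
  cat(sprintf("  QALYs %.2f, LYs %.2f; events: IS %.2f, MI %.2f, ICH %.2f, GI %.2f\n",
              x$qalys, x$lys, x$events[["ischaemic_stroke"]],
              x$events[["mi"]], x$events[["ich"]], x$events[["gi"]]))
  invisible(x)
}

#' Incremental comparison of two arms
#'
#' Computes incremental cost, QALYs and life-years of `comparator` versus
#' `reference`, and the ICERs per QALY and per life-year gained. The
#' comparison is labelled `dominant` (cheaper and more effective),
#' `dominated` (costlier and less effective) or `undefined` (no QALY
#' difference); the ICER is reported only where the QALY difference is
#' non-zero.
#'
#' @param reference,comparator `noacce_arm` results from identical settings.
#' @return A `noacce_comparison` list: `delta_cost`, `delta_qalys`,
#'   `delta_lys`, `icer_qaly`, `icer_ly`, `dominance`.
#' @export
compare_arms <- function(reference, comparator) {
  stopifnot(inherits(reference, "noacce_arm"), inherits(comparator, "noacce_arm"))
  if (!identical(reference$settings, comparator$settings))
    stop("arms were run under different model settings", call. = FALSE)
  dc <- comparator$costs[["total"]] - reference$costs[["total"]]
  dq <- comparator$qalys - reference$qalys
  dl <- comparator$lys - reference$lys
  dominance <- if (dq == 0 && dc == 0) "equivalent"
    else if (dc <= 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dq == 0) "undefined"
    else "trade-off"
  structure(list(
    reference = reference$arm, comparator = comparator$arm,
    delta_cost = dc, delta_qalys = dq, delta_lys = dl,
    icer_qaly = if (dq != 0) dc / dq else NA_real_,
    icer_ly = if (dl != 0) dc / dl else NA_real_,
    dominance = dominance), class = "noacce_comparison")
}

#' @export
print.noacce_comparison <- function(x, ...) {
  cat(sprintf("<noacce_comparison> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  dCost EUR %.0f, dQALY %.3f, dLY %.3f (%s)\n",
              x$delta_cost, x$delta_qalys, x$delta_lys, x$dominance))
  if (is.finite(x$icer_qaly))
    cat(sprintf("  ICER %s EUR/QALY; %s EUR/LYG\n",
                format(round(x$icer_qaly), big.mark = ","),
                format(round(x$icer_ly), big.mark = ",")))
  invisible(x)
}

#' Run all arms and compare each NOAC with VKA
#'
#' @param params A `noacce_params` object.
#' @return A `noacce_base_case` list with per-arm `noacce_arm` results
#'   (`$arms`) and per-NOAC `noacce_comparison` objects (`$incremental`).
#' @export
run_base_case <- function(params) {
  arms <- lapply(stats::setNames(params$arms, params$arms),
                 function(a) run_cohort(params, a))
  inc <- lapply(arms[setdiff(params$arms, "vka")],
                function(r) compare_arms(arms$vka, r))
  structure(list(arms = arms, incremental = inc), class = "noacce_base_case")
}
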