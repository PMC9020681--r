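# Synthetic inputs and the patient-level oracle: random parameter sets with
# the model's uncertainty structure, and a microsimulation that replays the
# cohort engine's own per-cycle transition distributions patient by patient.
# (The synthetic Gompertz-Makeham life-table generator lives in
# life_table.R as make_life_table().)

#' Randomly perturb a parameter set
#'
#' Draws every PSA-tagged parameter from its fitted uncertainty distribution
#' with the spread multiplied by `scale`; `scale = 0` returns the input
#' unchanged. Reproducible given `seed`.
#'
#' @param params A `noacce_params` object.
#' @param seed Integer seed.
#' @param scale Non-negative multiplier on each distribution's spread.
#' @return A perturbed, validated `noacce_params` object.
#' @export
perturb_parameters <- function(params, seed = 1L, scale = 1) {
  if (scale < 0) stop("'scale' must be non-negative", call. = FALSE)
  if (scale == 0) return(params)
  specs <- psa_specs(params, scale = scale)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  set_param_values(params, draw_values(specs))
}

#' Patient-level microsimulation of one treatment arm
#'
#' Simulates individual trajectories by sampling each cycle's transition
#' from the cohort engine's own transition matrices, accruing exactly the
#' same per-cycle utilities and costs. Serves as a Monte-Carlo oracle for
#' [run_cohort()]: with matching inputs the microsimulation means converge
#' to the cohort expectations at rate 1/sqrt(n).
#'
#' @param params A `noacce_params` object.
#' @param arm Arm name.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @return A `noacce_microsim` list: `$mean` and `$se` (named: qalys, lys,
#'   total_cost, ischaemic_stroke, mi, ich, gi) plus `$n_patients`, `$seed`.
#' @export
microsimulate <- function(params, arm, n_patients = 10000L, seed = 1L) {
  stopifnot(n_patients >= 1L)
  mi_ <- model_inputs(params, arm)
  Ts <- transition_matrices(mi_)
  n_cyc <- mi_$n_cycles

  # per-state per-cycle accrual vectors, identical to the cohort engine's
  u_state <- c(rep(mi_$u_health[HEALTH], length(TX)), 0)
  alive <- c(rep(1, N_STATES - 1L), 0)
  days <- 365.25 / 4 * (mi_$cycle_length / 0.25)
  tx_of_state <- c(rep(seq_along(TX), each = N_HEALTH), NA)
  cost_state <- numeric(N_STATES)
  on_tx <- which(tx_of_state == 1L)
  sw_tx <- which(tx_of_state == 2L)
  cost_state[on_tx] <- mi_$daily_cost[["arm"]] * days + mi_$admin_cost[["arm"]]
  cost_state[sw_tx] <- mi_$daily_cost[["vka"]] * days + mi_$admin_cost[["vka"]]
  for (a in names(mi_$acute_cost)) {
    idx <- state_index(rep(a, length(TX)), TX)
    cost_state[idx] <- cost_state[idx] + mi_$acute_cost[[a]]
  }
  for (p in names(mi_$cycle_fu_cost)) {
    idx <- state_index(rep(p, length(TX)), TX)
    cost_state[idx] <- cost_state[idx] + mi_$cycle_fu_cost[[p]]
  }
  ev_state <- matrix(0, N_STATES, 4,
                     dimnames = list(NULL, c("ischaemic_stroke", "mi",
                                             "ich", "gi")))
  for (tx in TX) {
    ev_state[state_index("acute_minor_is", tx), "ischaemic_stroke"] <- 1
    ev_state[state_index("acute_major_is", tx), "ischaemic_stroke"] <- 1
    ev_state[state_index("acute_mi", tx), "mi"] <- 1
    ev_state[state_index("acute_ich", tx), "ich"] <- 1
    ev_state[state_index("acute_gi", tx), "gi"] <- 1
  }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  state <- rep(state_index("stable_af", "on_initial"), n_patients)
  qalys <- numeric(n_patients)
  lys <- numeric(n_patients)
  cost <- numeric(n_patients)
  events <- matrix(0, n_patients, 4)
  for (k in seq_len(n_cyc)) {
    df <- discount_factor((k - 1L) * mi_$cycle_length, mi_$discount)
    qalys <- qalys + df * mi_$cycle_length * u_state[state]
    lys <- lys + df * mi_$cycle_length * alive[state]
    cost <- cost + df * cost_state[state]
    events <- events + ev_state[state, , drop = FALSE]
    Tk <- Ts[[k]]
    new_state <- state  # transition everyone off the same cycle-start state
    for (s in unique(state)) {
      if (s == DEAD) next
      idx <- which(state == s)
      new_state[idx] <- sample.int(N_STATES, length(idx), replace = TRUE,
                                   prob = Tk[s, ])
    }
    state <- new_state
  }

  agg <- cbind(qalys = qalys, lys = lys, total_cost = cost, events)
  structure(list(
    mean = colMeans(agg),
    se = apply(agg, 2, stats::sd) / sqrt(n_patients),
    n_patients = n_patients, seed = seed, arm = arm),
    class = "noacce_microsim")
}

#' @export
print.noacce_microsim <- function(x, ...) {
  cat(sprintf("<noacce_microsim> %s, %d patients (seed %d)\n",
              x$arm, x$n_patients, x$seed))
  cat(sprintf("  QALYs %.3f (SE %.4f), cost EUR %.0f (SE %.0f)\n",
              x$mean[["qalys"]], x$se[["qalys"]],
              x$mean[["total_cost"]], x$se[["total_cost"]]))
  invisible(x)
}
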