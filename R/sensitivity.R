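# Sensitivity analyses: one-way deterministic (tornado), probabilistic with
# beta/gamma/lognormal uncertainty, CEAC, and the published scenarios.
# DSA ranges are read as 95% intervals, so distribution spreads use
# sd = (high - low) / 3.92.

RANGE_Z <- 3.92  # 95% interval width in normal sd units

#' Fit a beta distribution from a base value and range
#'
#' Method of moments with mean = `base` and
#' sd = (`high` - `low`) / 3.92 (the range read as a 95% interval).
#' A zero-width range gives a point mass. Infeasible moments (sd too large
#' for the mean) fall back to the flattest mean-preserving beta with
#' shape parameters at least 1, with a warning.
#'
#' @param base Mean, strictly inside (0, 1).
#' @param low,high Range bounds.
#' @return A distribution spec: `list(dist, ...)` usable with [draw_dist()].
#' @export
fit_beta_from_range <- function(base, low, high) {
  if (!is.finite(base) || base <= 0 || base >= 1)
    stop("beta fit needs 0 < base < 1", call. = FALSE)
  s <- (high - low) / RANGE_Z
  if (!is.finite(s) || s <= 0)
    return(list(dist = "point", value = base))
  v <- s^2
  if (v >= base * (1 - base)) {
    warning("beta fit: sd too large for mean ", base,
            "; falling back to shape parameters >= 1")
    k <- 1 / min(base, 1 - base)
  } else {
    k <- base * (1 - base) / v - 1
  }
  list(dist = "beta", shape1 = base * k, shape2 = (1 - base) * k)
}

#' Fit a gamma distribution from a base value and range
#'
#' Method of moments with mean = `base`,
#' sd = (`high` - `low`) / 3.92: shape = mean^2/sd^2, scale = sd^2/mean.
#' A degenerate range (`low >= high`) gives a point mass with a warning.
#'
#' @param base Mean, positive.
#' @param low,high Range bounds.
#' @return A distribution spec usable with [draw_dist()].
#' @export
fit_gamma_from_range <- function(base, low, high) {
  if (!is.finite(base) || base <= 0)
    stop("gamma fit needs base > 0", call. = FALSE)
  s <- (high - low) / RANGE_Z
  if (!is.finite(s) || s <= 0) {
    if (is.finite(s) && s < 0) warning("gamma fit: low >= high; point mass")
    return(list(dist = "point", value = base))
  }
  list(dist = "gamma", shape = base^2 / s^2, scale = s^2 / base)
}

#' Fit a lognormal distribution from a base value and range
#'
#' Used for hazard ratios, whose support (0, Inf) a beta cannot represent:
#' median = `base` and log-sd = (log(`high`) - log(`low`)) / 3.92 (the range
#' read as a 95% CI on the log scale).
#'
#' @param base Median, positive.
#' @param low,high Range bounds, positive.
#' @return A distribution spec usable with [draw_dist()].
#' @export
fit_lnorm_from_range <- function(base, low, high) {
  if (!is.finite(base) || base <= 0)
    stop("lognormal fit needs base > 0", call. = FALSE)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    return(list(dist = "point", value = base))
  list(dist = "lnorm", meanlog = log(base),
       sdlog = (log(high) - log(low)) / RANGE_Z)
}

#' Draw random variates from a fitted distribution spec
#' @param spec A spec from one of the `fit_*_from_range()` functions.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L) {
  switch(spec$dist,
    point = rep(spec$value, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    lnorm = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unknown distribution '", spec$dist, "'", call. = FALSE))
}

# Distribution specs for every PSA-tagged parameter; sd scaled by `scale`.
psa_specs <- function(params, scale = 1) {
  tab <- param_table(params)
  tab <- tab[tab$dist != "fixed", , drop = FALSE]
  specs <- vector("list", nrow(tab))
  names(specs) <- tab$id
  for (i in seq_len(nrow(tab))) {
    b <- tab$base[i]
    lo <- tab$dsa_low[i]; hi <- tab$dsa_high[i]
    if (is.na(lo) || is.na(hi)) {
      specs[[i]] <- list(dist = "point", value = b)
      next
    }
    half <- (hi - lo) / 2 * scale
    mid_lo <- (lo + hi) / 2 - half
    mid_hi <- (lo + hi) / 2 + half
    specs[[i]] <- switch(tab$dist[i],
      beta = fit_beta_from_range(b, mid_lo, mid_hi),
      gamma = fit_gamma_from_range(b, mid_lo, mid_hi),
      lognormal = fit_lnorm_from_range(b, max(mid_lo, 1e-12), mid_hi))
  }
  specs
}

draw_values <- function(specs) {
  vapply(specs, function(sp) draw_dist(sp, 1L), numeric(1))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For every parameter carrying a DSA range and relevant to the comparison
#' of `arm` versus VKA (shared parameters plus the arm's own hazard ratios
#' and switch proportion), both arms are re-run with the parameter set to
#' its low and then high bound, all else held at base. Entries are ordered
#' by descending ICER spread.
#'
#' @param params A `noacce_params` object.
#' @param arm A NOAC arm name.
#' @return A `noacce_tornado` data frame (parameter, low, high, icer_low,
#'   icer_high, spread) with the base-case ICER as attribute `base_icer`.
#' @export
tornado <- function(params, arm) {
  arm <- match.arg(arm, setdiff(params$arms, "vka"))
  icer_at <- function(p) {
    cmp <- compare_arms(run_cohort(p, "vka"), run_cohort(p, arm))
    cmp$icer_qaly
  }
  base_icer <- icer_at(params)
  tab <- param_table(params, varied_only = TRUE)
  # keep shared parameters plus this arm's own (and VKA's) arm-specific ones
  own <-!grepl(paste0("_(", paste(params$arms, collapse = "|"), ")$"), tab$id) |
    grepl(paste0("_(vka|", arm, ")$"), tab$id)
  tab <- tab[own, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$id[i]
    ic <- vapply(c(tab$dsa_low[i], tab$dsa_high[i]), function(val) {
      if (val == tab$base[i]) return(base_icer)
      icer_at(set_param_values(params, stats::setNames(val, id)))
    }, numeric(1))
    data.frame(parameter = id, low = tab$dsa_low[i], high = tab$dsa_high[i],
               icer_low = ic[1L], icer_high = ic[2L],
               spread = abs(ic[2L] - ic[1L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "arm") <- arm
  class(out) <- c("noacce_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every PSA-tagged parameter from its fitted distribution (beta for
#' probabilities, proportions and utilities; gamma for costs; lognormal for
#' hazard ratios), re-runs all four arms per draw, and records incremental
#' costs and QALYs of each NOAC versus VKA. The CEAC gives, per threshold
#' lambda, the fraction of draws with positive net monetary benefit
#' (lambda * dQALY - dCost > 0) versus VKA.
#'
#' @param params A `noacce_params` object.
#' @param n_draws Number of parameter draws (default 1000).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @param lambdas Willingness-to-pay grid for the CEAC (EUR/QALY).
#' @return A `noacce_psa` object: `$samples` (draw, arm, delta_cost,
#'   delta_qalys), `$ceac` (lambda, arm, probability), `$n_draws`, `$seed`.
#' @export
run_psa <- function(params, n_draws = 1000L, seed = 1L,
                    lambdas = seq(0, 50000, by = 1000)) {
  stopifnot(n_draws >= 1L)
  specs <- psa_specs(params)
  noacs <- setdiff(params$arms, "vka")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(d) draw_values(specs))
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    p <- set_param_values(params, draws[[d]])
    ref <- run_cohort(p, "vka")
    rows[[d]] <- do.call(rbind, lapply(noacs, function(a) {
      cmp <- compare_arms(ref, run_cohort(p, a))
      data.frame(draw = d, arm = a, delta_cost = cmp$delta_cost,
                 delta_qalys = cmp$delta_qalys, stringsAsFactors = FALSE)
    }))
  }
  samples <- do.call(rbind, rows)
  ceac <- ceac_curve(samples, lambdas)
  structure(list(samples = samples, ceac = ceac, n_draws = n_draws,
                 seed = seed,
                 draws = do.call(rbind, draws)), class = "noacce_psa")
}

#' Cost-effectiveness acceptability curve from PSA samples
#'
#' @param samples Data frame with columns `arm`, `delta_cost`, `delta_qalys`
#'   (incrementals versus the common reference).
#' @param lambdas Willingness-to-pay thresholds (EUR/QALY).
#' @return Data frame (lambda, arm, probability): per threshold, the
#'   fraction of draws with positive net monetary benefit.
#' @export
ceac_curve <- function(samples, lambdas = seq(0, 50000, by = 1000)) {
  out <- expand.grid(lambda = lambdas, arm = unique(samples$arm),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$probability <- mapply(function(l, a) {
    s <- samples[samples$arm == a, ]
    mean(l * s$delta_qalys - s$delta_cost > 0)
  }, out$lambda, out$arm)
  out
}

#' Probability of cost-effectiveness at one threshold
#' @param psa A `noacce_psa` object.
#' @param wtp Willingness-to-pay threshold (EUR/QALY), default 22000.
#' @return Named vector of probabilities, one per NOAC.
#' @export
prob_ce <- function(psa, wtp = 22000) {
  arms <- unique(psa$samples$arm)
  vapply(stats::setNames(arms, arms), function(a) {
    s <- psa$samples[psa$samples$arm == a, ]
    mean(wtp * s$delta_qalys - s$delta_cost > 0)
  }, numeric(1))
}

#' @export
print.noacce_psa <- function(x, ...) {
  cat(sprintf("<noacce_psa> %d draws (seed %d)\n", x$n_draws, x$seed))
  p <- prob_ce(x)
  cat("  P(cost-effective at EUR 22,000/QALY):",
      paste(sprintf("%s=%.0f%%", names(p), 100 * p), collapse = ", "), "\n")
  invisible(x)
}

#' Scenario analyses
#'
#' Re-runs the full base case under one of the published scenarios:
#' `older_population` (cohort entry age 77), `horizon_10` / `horizon_20`
#' (shortened time horizons), `horizon_30` (identical to the base case), or
#' `alternative_hr` (a user-supplied hazard-ratio table, since the
#' alternative treatment-effect estimates are not part of the packaged
#' inputs).
#'
#' @param params A `noacce_params` object.
#' @param scenario Scenario identifier (see above).
#' @param hr_table For `alternative_hr`: a named list, one element per NOAC,
#'   each a named vector with entries among `is`, `mi`, `gi`, `ich`,
#'   `discontinuation`.
#' @return A `noacce_scenario` list: the scenario name, the full
#'   `noacce_base_case`, and a named vector `icer_qaly` per NOAC.
#' @export
run_scenario <- function(params, scenario, hr_table = NULL) {
  scenario <- match.arg(scenario, c("older_population", "horizon_10",
                                    "horizon_20", "horizon_30",
                                    "alternative_hr"))
  p <- params
  if (scenario == "older_population") {
    p$settings$entry_age <- 77
  } else if (scenario %in% c("horizon_10", "horizon_20", "horizon_30")) {
    p$settings$horizon <- as.numeric(sub("horizon_", "", scenario))
  } else {
    if (is.null(hr_table))
      stop("scenario 'alternative_hr' needs a user-supplied 'hr_table'",
           call. = FALSE)
    upd <- numeric(0)
    for (arm in names(hr_table))
      for (h in names(hr_table[[arm]]))
        upd[paste0("hr_", h, "_", arm)] <- hr_table[[arm]][[h]]
    p <- set_param_values(p, upd)
  }
  bc <- run_base_case(p)
  structure(list(scenario = scenario, base_case = bc,
                 icer_qaly = vapply(bc$incremental, `[[`, numeric(1),
                                    "icer_qaly")),
            class = "noacce_scenario")
}

#' Table of scenario ICERs across all NOACs
#' @param params A `noacce_params` object.
#' @param scenarios Scenario identifiers to run.
#' @param hr_table Passed to [run_scenario()] for `alternative_hr`.
#' @return Data frame: one row per scenario, one ICER column per NOAC.
#' @export
scenario_table <- function(params,
                           scenarios = c("older_population", "horizon_10",
                                         "horizon_20"),
                           hr_table = NULL) {
  rows <- lapply(scenarios, function(sc) {
    res <- run_scenario(params, sc, hr_table = hr_table)
    cbind(data.frame(scenario = sc, stringsAsFactors = FALSE),
          as.data.frame(as.list(res$icer_qaly)))
  })
  do.call(rbind, rows)
}
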