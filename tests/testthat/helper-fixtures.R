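# Shared fixtures: the packaged parameter set is loaded once; helpers build
# degenerate inputs (no events, no mortality) for closed-form checks.

fixture_params <- function() {
  if (is.null(.fixture_cache$params))
    .fixture_cache$params <- load_parameters()
  .fixture_cache$params
}
.fixture_cache <- new.env(parent = emptyenv())

# immortal life table: zero death probability at every age
null_life_table <- function() make_life_table(a = 0, b = 0, ages = 55:110)

# no events, no case fatality, no excess mortality, utility 1 everywhere
null_params <- function(discount = 0, discontinuation = TRUE) {
  p <- load_parameters(life_table = null_life_table())
  ids <- p$meta$id
  zero <- ids[grepl("^(p_|cf_|excess_)", ids)]
  ones <- ids[grepl("^u_", ids)]
  vals <- c(stats::setNames(rep(0, length(zero)), zero),
            stats::setNames(rep(1, length(ones)), ones))
  if (!discontinuation) {
    d <- ids[grepl("^disc_", ids)]
    vals <- c(vals, stats::setNames(rep(0, length(d)), d))
  }
  p <- set_param_values(p, vals)
  p$settings$discount_rate <- discount
  p
}

# a pseudo-NOAC: rivaroxaban with all hazard ratios 1 and VKA costs/switch
neutralise_arm <- function(p, arm = "rivaroxaban") {
  v <- p$values
  set_param_values(p, stats::setNames(
    c(1, 1, 1, 1, 1, v[["daily_cost_vka"]], v[["admin_cycle_vka"]],
      v[["switch_vka"]]),
    c(paste0("hr_", c("is", "mi", "gi", "ich", "discontinuation"), "_", arm),
      paste0(c("daily_cost_", "admin_cycle_", "switch_"), arm))))
}

# collapse every DSA range and PSA distribution onto the base value
collapse_uncertainty <- function(p) {
  has <- !is.na(p$meta$dsa_low)
  p$meta$dsa_low[has] <- p$values[p$meta$id[has]]
  p$meta$dsa_high[has] <- p$values[p$meta$id[has]]
  p
}
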