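# Markov cohort engine: transition construction, closed forms, conservation,
# neutrality, monotonicity, incremental comparison.

test_that("transition matrices are row-stochastic with an absorbing death state", {
  p <- fixture_params()
  for (arm in c("vka", "rivaroxaban")) {
    for (k in c(0, 1, 3, 40, 119)) {
      M <- transition_matrix(p, arm, k)
      expect_true(all(M >= 0))
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
      expect_identical(unname(M["dead", "dead"]), 1)
    }
  }
})

test_that("stable AF exit probabilities reproduce the baseline inputs", {
  # immortal life table isolates the event probabilities from background death
  p <- null_params()
  p <- set_param_values(p, stats::setNames(
    param_values(fixture_params())[paste0("p_", c("minor_is", "major_is",
                                                  "mi", "gi", "ich"))],
    paste0("p_", c("minor_is", "major_is", "mi", "gi", "ich"))))
  d <- transition_distribution("stable_af.on_initial", 0, p, "vka")
  gi_exit <- sum(d[grep("^acute_gi", names(d))])
  expect_equal(round(gi_exit, 5), 0.00260)  # printed GI bleeding cell
  ich_exit <- sum(d[grep("^acute_ich", names(d))])
  expect_equal(ich_exit, rate_to_prob(0.34, 0.25), tolerance = 1e-12)
  # age 73.4 sits in the reference band, so no stroke adjustment at cycle 0
  is_exit <- sum(d[grep("^acute_(minor|major)_is", names(d))])
  expect_equal(is_exit, rate_to_prob(1.11, 0.25), tolerance = 1e-12)
})

test_that("degenerate cohorts give exact closed-form life-years and QALYs", {
  # no events, no mortality, utility 1, zero discount: 30 undiscounted years
  p0 <- null_params(discount = 0)
  r0 <- run_cohort(p0, "vka")
  expect_equal(r0$qalys, 30, tolerance = 1e-12)
  expect_equal(r0$lys, 30, tolerance = 1e-12)
  expect_equal(unname(r0$events), rep(0, 4))
  # 3% discounting: quarterly annuity-due geometric series
  p3 <- null_params(discount = 0.03)
  r3 <- run_cohort(p3, "vka")
  series <- 0.25 * sum(1.03^(-0.25 * (0:119)))
  expect_equal(r3$qalys, series, tolerance = 1e-10)
  expect_equal(r3$lys, series, tolerance = 1e-10)
})

test_that("occupancy is conserved and death occupancy never decreases", {
  p <- fixture_params()
  for (arm in p$arms) {
    tr <- run_cohort(p, arm)$trace$occupancy
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
    expect_true(all(diff(tr[, "dead"]) >= -1e-12))
  }
  # also under random parameter draws
  for (s in 1:3) {
    pp <- perturb_parameters(p, seed = s)
    tr <- run_cohort(pp, "apixaban")$trace$occupancy
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
  }
})

test_that("with positive background mortality the cohort is eventually absorbed", {
  p <- fixture_params()
  p$settings$horizon <- 60
  tr <- run_cohort(p, "vka")$trace$occupancy
  expect_gt(tr[nrow(tr), "dead"], 0.999)
})

test_that("a neutral pseudo-NOAC is outcome-identical to VKA", {
  p <- neutralise_arm(fixture_params(), "rivaroxaban")
  ref <- run_cohort(p, "vka")
  neu <- run_cohort(p, "rivaroxaban")
  cmp <- compare_arms(ref, neu)
  expect_equal(cmp$delta_cost, 0, tolerance = 1e-9)
  expect_equal(cmp$delta_qalys, 0, tolerance = 1e-12)
  expect_equal(cmp$delta_lys, 0, tolerance = 1e-12)
  expect_equal(unname(neu$events), unname(ref$events), tolerance = 1e-12)
})

test_that("ICER responds monotonically to drug cost and stroke hazard", {
  p <- fixture_params()
  base <- compare_arms(run_cohort(p, "vka"), run_cohort(p, "rivaroxaban"))
  costly <- set_param_values(p, c(daily_cost_rivaroxaban = 2.5))
  cmp2 <- compare_arms(run_cohort(costly, "vka"),
                       run_cohort(costly, "rivaroxaban"))
  expect_gt(cmp2$icer_qaly, base$icer_qaly)
  riskier <- set_param_values(p, c(hr_is_rivaroxaban = 0.95))
  cmp3 <- compare_arms(run_cohort(riskier, "vka"),
                       run_cohort(riskier, "rivaroxaban"))
  expect_lt(cmp3$delta_qalys, base$delta_qalys)
})

test_that("cost components add up and QALYs never exceed life-years", {
  bc <- run_base_case(fixture_params())
  for (r in bc$arms) {
    expect_equal(r$costs[["total"]],
                 sum(r$costs[c("drug_acquisition", "administration",
                               "event_management")]), tolerance = 1e-6)
    expect_lte(r$qalys, r$lys)
  }
})

test_that("compare_arms computes ICERs and dominance labels", {
  mk <- function(cost, q, l = q) structure(list(
    arm = "x", costs = c(total = cost), qalys = q, lys = l,
    settings = list(a = 1)), class = "noacce_arm")
  expect_equal(compare_arms(mk(0, 1), mk(100, 2))$icer_qaly, 100)
  expect_identical(compare_arms(mk(5, 1), mk(0, 1.1))$dominance, "dominant")
  expect_identical(compare_arms(mk(0, 1.1), mk(5, 1))$dominance, "dominated")
  und <- compare_arms(mk(0, 1), mk(50, 1))
  expect_identical(und$dominance, "undefined")
  expect_true(is.na(und$icer_qaly))
  # division of the published rounded increments
  expect_equal(compare_arms(mk(0, 1), mk(77, 1.08))$icer_qaly, 962.5)
})

test_that("horizon must be a whole number of cycles", {
  p <- fixture_params()
  p$settings$horizon <- 10.1
  expect_error(run_cohort(p, "vka"), "whole number")
})
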