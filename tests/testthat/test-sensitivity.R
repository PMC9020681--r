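# Distribution fitting, tornado, PSA/CEAC, scenarios.

test_that("fit_beta_from_range matches method-of-moments closed forms", {
  # the 0-3 month discontinuation probability: 15.00% [14.19%; 15.81%]
  sp <- fit_beta_from_range(0.15, 0.1419, 0.1581)
  sd <- (0.1581 - 0.1419) / 3.92
  expect_equal(sd, 0.004133, tolerance = 1e-4)
  expect_equal(sp$shape1, 0.15 * (0.15 * 0.85 / sd^2 - 1), tolerance = 1e-12)
  expect_equal(sp$shape1, 1119.6, tolerance = 1e-3)
  # mean and sd recovered from the fitted parameters
  m <- sp$shape1 / (sp$shape1 + sp$shape2)
  expect_equal(m, 0.15, tolerance = 1e-12)
  expect_identical(fit_beta_from_range(0.5, 0.3, 0.3)$dist, "point")
  expect_warning(fit_beta_from_range(0.01, 0, 0.9), "sd too large")
  expect_error(fit_beta_from_range(1.2, 1, 1.4), "0 < base < 1")
  x <- draw_dist(fit_beta_from_range(0.3, 0.1, 0.5), 500)
  expect_true(all(x > 0 & x < 1))
})

test_that("fit_gamma_from_range matches method-of-moments closed forms", {
  sp <- fit_gamma_from_range(5258, 3953, 6572)
  sd <- (6572 - 3953) / 3.92
  expect_equal(sd, 668.1, tolerance = 1e-4)
  expect_equal(sp$shape, 5258^2 / sd^2, tolerance = 1e-12)
  expect_equal(sp$shape, 61.94, tolerance = 1e-3)
  expect_equal(sp$shape * sp$scale, 5258, tolerance = 1e-9)  # mean preserved
  expect_identical(fit_gamma_from_range(100, 50, 50)$dist, "point")
  x <- draw_dist(sp, 500)
  expect_true(all(x > 0))
})

test_that("fit_lnorm_from_range has the base as median and correct log spread", {
  sp <- fit_lnorm_from_range(1.22, 1.12, 1.33)
  expect_equal(exp(sp$meanlog), 1.22)
  expect_equal(sp$sdlog, (log(1.33) - log(1.12)) / 3.92)
  x <- draw_dist(sp, 2000)
  expect_true(all(x > 0))  # supports HRs above 1, unlike a beta
})

test_that("PSA draws recover the input uncertainty model", {
  p <- fixture_params()
  specs <- noacce:::psa_specs(p)
  set.seed(7)
  for (id in c("p_gi", "u_stable_af", "c_acute_major_is", "cf_ich")) {
    sp <- specs[[id]]
    x <- draw_dist(sp, 5000)
    base <- param_values(p)[[id]]
    expect_equal(mean(x), base, tolerance = 3 * sd(x) / sqrt(5000) / base)
    sd_target <- (p$meta$dsa_high[p$meta$id == id] -
                    p$meta$dsa_low[p$meta$id == id]) / 3.92
    expect_equal(sd(x), sd_target, tolerance = 0.1)
  }
  # hazard ratios are median-parameterised (lognormal)
  x <- draw_dist(specs[["hr_gi_rivaroxaban"]], 5000)
  expect_equal(median(x), 1.22, tolerance = 0.02)
})

test_that("tornado orders by spread, collapses degenerate ranges, and isolates arms", {
  p <- fixture_params()
  p$settings$horizon <- 10  # smaller model keeps the full DSA quick
  tor <- tornado(p, "rivaroxaban")
  expect_true(all(diff(tor$spread) <= 1e-9))
  expect_true(all(c("cf_major_is", "excess_post_major_is", "c_fu_major_is")
                  %in% tor$parameter))
  # no parameter specific to another NOAC is varied
  expect_false(any(grepl("dabigatran|apixaban", tor$parameter)))
  # collapsed ranges reproduce the base ICER with zero spread
  tor0 <- tornado(collapse_uncertainty(p), "rivaroxaban")
  expect_equal(tor0$spread, rep(0, nrow(tor0)))
  expect_equal(tor0$icer_low,
               rep(attr(tor0, "base_icer"), nrow(tor0)), tolerance = 1e-12)
})

test_that("major-stroke mortality and follow-up cost are top tornado drivers", {
  p <- fixture_params()
  p$settings$horizon <- 10
  tor <- tornado(p, "rivaroxaban")
  top <- tor$parameter[seq_len(8)]
  expect_true(any(c("cf_major_is", "excess_post_major_is") %in% top))
  expect_true("c_fu_major_is" %in% top)
})

test_that("PSA is seed-reproducible and degenerates to the base case", {
  p <- fixture_params()
  p$settings$horizon <- 5  # tiny horizon: this checks mechanics, not results
  a <- run_psa(p, n_draws = 5, seed = 11)
  b <- run_psa(p, n_draws = 5, seed = 11)
  expect_identical(a$samples, b$samples)
  c_ <- run_psa(p, n_draws = 5, seed = 12)
  expect_false(identical(a$samples$delta_cost, c_$samples$delta_cost))
  # all distributions collapsed: incrementals equal the base case exactly
  p0 <- collapse_uncertainty(p)
  one <- run_psa(p0, n_draws = 1, seed = 1)
  bc <- run_base_case(p)
  for (arm in names(bc$incremental)) {
    s <- one$samples[one$samples$arm == arm, ]
    expect_equal(s$delta_cost, bc$incremental[[arm]]$delta_cost,
                 tolerance = 1e-9)
    expect_equal(s$delta_qalys, bc$incremental[[arm]]$delta_qalys,
                 tolerance = 1e-12)
  }
})

test_that("CEAC follows the net-monetary-benefit definition", {
  samples <- data.frame(
    draw = rep(1:4, 2), arm = rep(c("a", "b"), each = 4),
    delta_cost = c(-10, 5, 20, 30, -5, -1, 2, 4),
    delta_qalys = c(0.01, 0.02, 0.01, -0.01, 0.001, 0.002, 0.001, 0.002))
  cc <- ceac_curve(samples, lambdas = c(0, 1000, 5000))
  at <- function(l, a) cc$probability[cc$lambda == l & cc$arm == a]
  expect_equal(at(0, "a"), 0.25)   # fraction with negative incremental cost
  expect_equal(at(0, "b"), 0.50)
  expect_equal(at(1000, "a"), 0.50)
  # an arm that is more effective in every draw has a non-decreasing CEAC
  more_eff <- samples[samples$arm == "b", ]
  cc2 <- ceac_curve(more_eff, lambdas = seq(0, 20000, 2000))
  expect_true(all(diff(cc2$probability) >= 0))
})

test_that("scenarios modify the intended settings and nothing else", {
  p <- fixture_params()
  p$settings$horizon <- 10
  base <- run_base_case(p)
  s30 <- run_scenario(p, "horizon_10")  # same as this fixture's base
  expect_equal(s30$icer_qaly[["rivaroxaban"]],
               base$incremental$rivaroxaban$icer_qaly, tolerance = 1e-12)
  older <- run_scenario(p, "older_population")
  expect_equal(older$base_case$arms$vka$trace$age[1], 77)
  expect_error(run_scenario(p, "alternative_hr"), "hr_table")
  alt <- run_scenario(p, "alternative_hr",
                      hr_table = list(rivaroxaban = c(is = 0.70)))
  expect_lt(alt$base_case$arms$rivaroxaban$events[["ischaemic_stroke"]],
            base$arms$rivaroxaban$events[["ischaemic_stroke"]])
  expect_error(run_scenario(p, "bogus"))
  st <- scenario_table(p, scenarios = c("horizon_10", "older_population"))
  expect_identical(st$scenario, c("horizon_10", "older_population"))
  expect_true(all(c("rivaroxaban", "dabigatran", "apixaban") %in% names(st)))
})
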