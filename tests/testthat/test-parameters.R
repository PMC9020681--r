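# Parameter loading, validation, age adjustment, discontinuation schedule.

test_that("the packaged fixture reproduces the published input values", {
  p <- fixture_params()
  v <- param_values(p)
  expect_equal(v[["rate_gi"]], 1.04)
  expect_equal(v[["rate_is"]], 1.11)
  expect_equal(v[["hr_ich_rivaroxaban"]], 0.68)
  expect_equal(v[["hr_discontinuation_dabigatran"]], 0.91)
  expect_equal(v[["switch_apixaban"]], 0.367)
  expect_equal(v[["cf_ich"]], 0.3885)
  expect_equal(v[["u_post_major_is"]], 0.56)
  expect_equal(v[["c_acute_minor_is"]], 5258)
  expect_equal(v[["c_fu_major_is"]], 2159)
  expect_equal(v[["rehab_ich"]], 0.45)
  expect_equal(v[["daily_cost_vka"]], 0.1)
  expect_equal(p$settings$entry_age, 73.4)
  expect_equal(p$settings$wtp_threshold, 22000)
})

test_that("derived 3-month probabilities match the printed cells", {
  v <- param_values(fixture_params())
  # exact at printed precision (three decimals of percent)
  expect_equal(round(100 * v[["p_gi"]], 3), 0.260)
  expect_equal(round(100 * v[["p_ich"]], 3), 0.085)
  # within 0.001 percentage points (printed source rates are rounded)
  expect_equal(100 * v[["p_minor_is"]], 0.114, tolerance = 0.001 / 0.114)
  expect_equal(100 * v[["p_major_is"]], 0.163, tolerance = 0.001 / 0.163)
  expect_equal(100 * v[["p_mi"]], 0.193, tolerance = 0.0011 / 0.193)
  # minor + major recompose the full ischaemic-stroke probability
  expect_equal(v[["p_minor_is"]] + v[["p_major_is"]],
               rate_to_prob(1.11, 0.25), tolerance = 1e-12)
})

test_that("DSA ranges bracket base values and carry distribution tags", {
  tab <- param_table(fixture_params(), varied_only = TRUE)
  ok <- tab$range_inconsistent |
    (tab$dsa_low <= tab$base & tab$base <= tab$dsa_high)
  expect_true(all(ok))
  # the flagged entry is the published MI follow-up cost with its verbatim range
  expect_identical(tab$id[tab$range_inconsistent], "c_fu_mi")
  expect_true(all(tab$dist %in% c("beta", "gamma", "lognormal")))
})

test_that("malformed configs are rejected with the offending key named", {
  p <- fixture_params()
  expect_error(set_param_values(p, c(switch_rivaroxaban = 1.5)),
               "switch_rivaroxaban")
  expect_error(set_param_values(p, c(u_stable_af = -0.1)), "u_stable_af")
  expect_error(set_param_values(p, c(hr_is_vka = 1.2)), "VKA")
  expect_error(set_param_values(p, c(nonexistent = 1)), "unknown")
  # config file with an out-of-range value
  cfg <- yaml::read_yaml(default_parameters_path())
  cfg$treatments$rivaroxaban$switch_proportion$base <- 1.5
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(load_parameters(bad), "switch")
  cfg$treatments$rivaroxaban$switch_proportion <- NULL
  yaml::write_yaml(cfg, bad)
  expect_error(load_parameters(bad), "switch_proportion")
})

test_that("age_stroke_rr looks up the published age bands with clamping", {
  tab <- fixture_params()$age_rr
  expect_identical(age_stroke_rr(72, tab), 1.000)
  expect_identical(age_stroke_rr(91, tab), 1.719)
  expect_identical(age_stroke_rr(57, tab), 0.667)
  expect_identical(age_stroke_rr(40, tab), 0.667)   # clamps below
  expect_identical(age_stroke_rr(105, tab), 1.719)  # open-ended top band
  expect_identical(age_stroke_rr(74.9, tab), 1.000) # floor(age)
  expect_true(all(diff(tab$rr) > 0))
})

test_that("discontinuation_probability selects bands and applies the HR", {
  sched <- c(0.15, 0.1059, 0.0823, 0.064)
  expect_equal(discontinuation_probability(2, sched), 0.15)
  expect_equal(discontinuation_probability(14, sched), 0.064)
  expect_equal(discontinuation_probability(4.5, sched), 0.1059)
  expect_equal(discontinuation_probability(6, sched), 0.0823)
  expect_equal(discontinuation_probability(2, sched, hr = 0.62),
               1 - 0.85^0.62, tolerance = 1e-12)
  expect_equal(round(discontinuation_probability(2, sched, 0.62), 4), 0.0959)
  expect_error(discontinuation_probability(-1, sched), "non-negative")
})

test_that("life tables read, write, validate and convert", {
  lt <- make_life_table()
  path <- tempfile(fileext = ".csv")
  write_life_table(lt, path)
  back <- read_life_table(path)
  expect_equal(back$qx, lt$qx, tolerance = 1e-12)
  expect_identical(back$age, as.numeric(lt$age))
  # clamped lookup
  expect_identical(life_table_qx(lt, 30), lt$qx[1])
  expect_identical(life_table_qx(lt, 200), lt$qx[nrow(lt)])
  # annual -> per-cycle conversion closed form
  expect_equal(annual_to_cycle_prob(0.04, 0.25), 1 - 0.96^0.25,
               tolerance = 1e-15)
  expect_equal(annual_to_cycle_prob(0.04, 0.25), 0.01015, tolerance = 5e-4)
  expect_identical(annual_to_cycle_prob(0, 0.25), 0)
  expect_identical(annual_to_cycle_prob(1, 0.25), 1)
  # malformed tables
  bad <- data.frame(age = c(60, 62, 63), qx = c(0.01, 0.02, 0.03))
  expect_error(noacce:::validate_life_table(bad), "contiguous")
  bad2 <- data.frame(age = 60:62, qx = c(0.01, 1.2, 0.03))
  expect_error(noacce:::validate_life_table(bad2), "\\[0, 1\\]")
})
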