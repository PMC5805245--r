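school_spec <- function(value = 0.02, from = 2011, to = 2030,
                        groups = c("5-9", "10-14")) {
  scenario_spec(list(
    list(age_groups = groups, tau = "tau3", value = value,
         from = from, to = to),
    list(age_groups = groups, tau = "tau4", value = value,
         from = from, to = to)
  ), label = "school-age recovery")
}

test_that("overrides are active only inside their window, as floors", {
  base <- zero_tr_table()
  base$tau3[2] <- 0.05 # already above the floor in group 5-9
  spec <- school_spec()
  expect_equal(apply_scenario(base, spec, 2010), base) # before the window
  eff <- apply_scenario(base, spec, 2015)
  expect_equal(eff$tau3[2], 0.05)  # floor keeps the larger baseline
  expect_equal(eff$tau3[3], 0.02)  # raised from 0
  expect_equal(eff$tau4[2:3], c(0.02, 0.02))
  expect_equal(eff$tau3[c(1, 4:12)], base$tau3[c(1, 4:12)]) # untouched
  expect_equal(apply_scenario(base, spec, 2031), base) # after the window
  # empty override list is the identity
  expect_equal(apply_scenario(base, scenario_spec(list()), 2015), base)
})

test_that("scenario specs validate their fields", {
  expect_error(scenario_spec(list(list(age_groups = "5-9", tau = "tau9",
                                       value = 0.1, from = 2011, to = 2030))),
               "unknown rate")
  expect_error(scenario_spec(list(list(age_groups = "banana", tau = "tau3",
                                       value = 0.1, from = 2011, to = 2030))),
               "age group")
  expect_error(scenario_spec(list(list(age_groups = "5-9", tau = "tau3",
                                       value = 1.5, from = 2011, to = 2030))),
               "\\[0, 1\\]")
  expect_error(scenario_spec(list(list(age_groups = "5-9", tau = "tau3",
                                       value = 0.1, from = 2031, to = 2030))),
               "from > to")
  # an override that breaks tau2 + tau4 <= 1 errors when applied
  base <- zero_tr_table(); base$tau2[3] <- 0.99
  spec <- scenario_spec(list(list(age_groups = "10-14", tau = "tau4",
                                  value = 0.05, from = 2011, to = 2030)))
  expect_error(apply_scenario(base, spec, 2015), "tau2 \\+ tau4")
})

test_that("comparison of a run with itself is zero everywhere", {
  ci <- colombia_synthetic_inputs()
  init <- stocks_from_prevalence(ci$prevalence$all, ci$demography$pop)
  base <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2015)
  cmp <- compare_projections(base, base, year = 2015)
  expect_equal(cmp$diff_points, rep(0, 3))
  expect_equal(cmp$rel_change_pct, rep(0, 3))
  expect_error(compare_projections(base, base, year = 2050), "not present")
})

test_that("raising recovery rates never increases overweight in affected ages", {
  ci <- colombia_synthetic_inputs()
  init <- stocks_from_prevalence(ci$prevalence$all, ci$demography$pop)
  base <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030)
  scen <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030,
                         scenario = school_spec())
  for (y in seq(2011, 2030, by = 2)) {
    cmp <- compare_projections(base, scen, c("5-9", "10-14"), y)
    expect_lte(cmp$diff_points[cmp$category == "overweight"], 1e-12)
    expect_lte(cmp$diff_points[cmp$category == "obese"], 1e-12)
  }
  # overrides touch only internal transfers: totals identical to baseline
  tot_b <- tapply(base$count, base$year, sum)
  tot_s <- tapply(scen$count, scen$year, sum)
  expect_equal(as.numeric(tot_s), as.numeric(tot_b), tolerance = 1e-9)
})

test_that("relative and point differences are both reported", {
  # frozen arithmetic: baseline 20.5%, scenario 18.8% -> -8.2927% relative
  base <- data.frame(year = 2030, ses = "all", age_group = "15-19",
                     category = bmi_categories(),
                     count = c(76.7, 20.5, 2.8),
                     prevalence = c(0.767, 0.205, 0.028))
  scen <- base
  scen$count <- c(78.4, 18.8, 2.8)
  scen$prevalence <- c(0.784, 0.188, 0.028)
  class(base) <- class(scen) <- c("projection", "data.frame")
  cmp <- compare_projections(base, scen, "15-19", 2030)
  ow <- cmp[cmp$category == "overweight", ]
  expect_equal(ow$diff_points, -0.017, tolerance = 1e-9)
  expect_equal(ow$rel_change_pct, 100 * (18.8 - 20.5) / 20.5,
               tolerance = 1e-9)
})
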