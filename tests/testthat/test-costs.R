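test_that("expected_annual_cost applies the severe relative-risk weighting", {
  gp <- list(rate = 7.70, unit_cost = 39.23, rr = 1.86,
             applies_to_moderate = FALSE)
  occ0 <- c(not_lonely = 0, moderately_lonely = 0.56,
            severely_lonely = 0.44, dead = 0)
  expect_equal(expected_annual_cost(gp, occ0),
               7.70 * 39.23 * (0.56 + 0.44 * 1.86))

  ## the dead accrue nothing
  all_dead <- c(not_lonely = 0, moderately_lonely = 0,
                severely_lonely = 0, dead = 1)
  expect_equal(expected_annual_cost(gp, all_dead), 0)

  ## self-harm's elevated risk covers moderate loneliness too
  sh <- list(rate = 0.001, unit_cost = 895, rr = 17.37,
             applies_to_moderate = TRUE)
  expect_equal(expected_annual_cost(sh, occ0),
               0.001 * 895 * (0.56 + 0.44) * 17.37)
})

test_that("the one-off intervention cost reconstructs the published cell", {
  p <- loneliness_params()
  expect_equal(intervention_cost(p), 752 * 0.89)  # prints as 669
  expect_equal(intervention_cost(p, "control"), 0)
  expect_equal(intervention_cost(update_params(p,
    misc.sustained_participation = 1)), 752)
})

test_that("cost breakdowns are additive and nest across perspectives", {
  p <- update_params(loneliness_params(), misc.volunteer_wage_hour = 8.21)
  for (arm in c("intervention", "control")) {
    tr <- run_cohort(p, arm)
    hsc <- arm_costs(tr, p, "health_social_care")
    brd <- arm_costs(tr, p, "broader")
    expect_equal(attr(hsc, "total"), sum(hsc), tolerance = 1e-9)
    expect_equal(attr(brd, "total"), sum(brd), tolerance = 1e-9)
    ## broader = health+social + informal care + volunteering, exactly
    extra <- c("informal_care_stroke", "informal_care_dementia",
               "volunteering_offset")
    expect_equal(attr(brd, "total") - sum(brd[extra]), attr(hsc, "total"))
    expect_true(all(brd[setdiff(names(brd), "volunteering_offset")] >= 0))
  }
  ## the offset is the only negative category, and only while engaged
  tri <- run_cohort(p, "intervention")
  expect_lt(arm_costs(tri, p, "broader")[["volunteering_offset"]], 0)
  trc <- run_cohort(p, "control")
  expect_equal(arm_costs(trc, p, "broader")[["volunteering_offset"]], 0)

  ## additivity under randomised parameters as well
  for (seed in 1:8) {
    q <- random_parameter_set(seed)
    tr <- run_cohort(q, "intervention")
    cb <- arm_costs(tr, q, "broader")
    expect_equal(attr(cb, "total"), sum(cb), tolerance = 1e-9)
  }
})

test_that("with all event rates zeroed only the intervention cost remains", {
  p <- loneliness_params(calibrate = FALSE)
  rate_ids <- c(grep("^incidence\\.", p$table$id, value = TRUE),
                "misc.gp_contacts_per_year")
  p <- update_params(p, setNames(rep(0, length(rate_ids)), rate_ids))
  p <- calibrate_other_contacts(p, c(intervention = 0, control = 0))
  ti <- arm_costs(run_cohort(p, "intervention"), p)
  tc <- arm_costs(run_cohort(p, "control"), p)
  expect_equal(attr(ti, "total"), 752 * 0.89)
  expect_equal(attr(tc, "total"), 0)
})

test_that("zero cost discounting reduces to plain sums on a frozen cohort", {
  p <- random_parameter_set(11, force_identity_transitions = TRUE,
                            zero_mortality = TRUE)
  p <- update_params(p, misc.cost_discount = 0)
  tr <- run_cohort(p, "control")
  costs <- arm_costs(tr, p)
  ## occupancy is frozen at the initial mix, so each category is its annual
  ## expectation times the number of charged cycles
  occ <- tr$occupancy[1, ]
  m <- param_values(p)
  gp_annual <- m[["misc.gp_contacts_per_year"]] * m[["costs.gp_contact"]] *
    (occ[["not_lonely"]] + occ[["moderately_lonely"]] +
       occ[["severely_lonely"]] * m[["rr.gp_contact"]])
  expect_equal(costs[["gp_visits"]], gp_annual * 4)
})

test_that("raising a severe relative risk never lowers costs", {
  p <- loneliness_params()
  tot <- sapply(c(1, 1.86, 3, 6), function(rr) {
    q <- update_params(p, rr.gp_contact = rr)
    c(attr(arm_costs(run_cohort(q, "intervention"), q), "total"),
      attr(arm_costs(run_cohort(q, "control"), q), "total"))
  })
  expect_true(all(diff(tot[1, ]) >= 0))
  expect_true(all(diff(tot[2, ]) >= 0))
  ## the intervention reduces severe occupancy, so the arm gap widens too
  expect_true(all(diff(tot[2, ] - tot[1, ]) >= 0))
})

test_that("other-contact calibration reproduces both published cells", {
  p <- loneliness_params()
  expect_equal(unname(p$calibration$fitted_cells),
               c(799, 818), tolerance = 0.005)
  ## and the category actually lands there in the full breakdown
  ci <- arm_costs(run_cohort(p, "intervention"), p)
  cc <- arm_costs(run_cohort(p, "control"), p)
  expect_equal(ci[["other_hospital_contacts"]], 799, tolerance = 0.005)
  expect_equal(cc[["other_hospital_contacts"]], 818, tolerance = 0.005)
})

test_that("root-finding calibration agrees with a grid-search oracle", {
  p <- loneliness_params(calibrate = FALSE)
  targets <- c(intervention = 799, control = 818)
  fit <- calibrate_other_contacts(p, targets)
  oracle <- calibration_grid_oracle(p, targets)
  expect_equal(param_value(fit, "rr.other_hospital_contact"), oracle$rr,
               tolerance = 0.005)
  expect_equal(param_value(fit, "incidence.other_hospital_contact"),
               oracle$rate, tolerance = 0.005)
})

test_that("degenerate calibration targets behave as specified", {
  p <- loneliness_params(calibrate = FALSE)
  z <- calibrate_other_contacts(p, c(intervention = 0, control = 0))
  expect_equal(param_value(z, "incidence.other_hospital_contact"), 0)
  ## a severe-independent category cannot differ across arms by this much
  expect_error(calibrate_other_contacts(p, c(intervention = 799, control = 818),
                                        rr = 1),
               "calibration failed")
  expect_error(calibrate_other_contacts(p, c(intervention = 0, control = 818)),
               "calibration failed")
})
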