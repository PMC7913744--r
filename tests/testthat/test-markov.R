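test_that("transition_matrix composes survival and loneliness movement", {
  zero <- setNames(rep(0, 6), names(baseline_transitions("control")))
  expect_equal(transition_matrix(zero, p_death = 0), diag(4),
               ignore_attr = TRUE)

  ## control severe row: death 0.015 x 1.30, printed flows scaled by survival
  M <- transition_matrix(baseline_transitions("control"), 0.015, 1.30)
  expect_equal(M["severely_lonely", "dead"], 0.0195)
  expect_equal(M["severely_lonely", "moderately_lonely"], 0.549 * (1 - 0.0195))
  expect_equal(M["severely_lonely", "not_lonely"], 0)
  expect_equal(M["severely_lonely", "severely_lonely"],
               1 - 0.0195 - 0.549 * (1 - 0.0195))
  expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(M["dead", ]), c(0, 0, 0, 1))

  ## intervention severe row uses the printed flows before survival scaling
  Mi <- transition_matrix(baseline_transitions("intervention"), 0.015, 1.30)
  expect_equal(Mi["severely_lonely", "moderately_lonely"] / (1 - 0.0195), 0.444)
  expect_equal(Mi["severely_lonely", "not_lonely"] / (1 - 0.0195), 0.187)

  expect_error(transition_matrix(baseline_transitions("control"), 0.9, 1.3),
               "exceeds 1")
})

test_that("the expanded intervention matrix nests its limiting cases", {
  p <- loneliness_params(calibrate = FALSE)
  m <- param_values(p)
  Mi <- transition_matrix(baseline_transitions("intervention"), 0.015, 1.30)
  Mc <- transition_matrix(baseline_transitions("control"), 0.015, 1.30)

  ## full retention: engaged block is exactly the 4-state intervention matrix,
  ## disengaged states unreachable
  M1 <- intervention_matrix(p, keep = 1)
  expect_equal(M1[1:3, 1:3], Mi[1:3, 1:3], ignore_attr = TRUE)
  expect_equal(unname(M1[1:3, 4:6]), matrix(0, 3, 3))
  ## zero retention: all survivors land in disengaged states that follow
  ## control dynamics
  M0 <- intervention_matrix(p, keep = 0)
  expect_equal(unname(M0[1:3, 1:3]), matrix(0, 3, 3))
  expect_equal(M0[4:6, 4:6], Mc[1:3, 1:3], ignore_attr = TRUE)
  expect_equal(unname(rowSums(M0)), rep(1, 7), tolerance = 1e-12)
})

test_that("engaged mass decays geometrically among survivors", {
  ## no mortality isolates the dropout process: after the first boundary the
  ## engaged share must shrink by exactly the retention probability per cycle
  p <- update_params(loneliness_params(calibrate = FALSE), misc.p_death = 0)
  tr <- run_cohort(p, "intervention")
  eng <- unname(tr$engaged)
  keep <- param_value(p, "misc.sustained_participation")
  for (k in 3:length(eng)) expect_equal(eng[k] / eng[k - 1], keep)
  expect_equal(eng[2], keep^(1 - 7.5 / 12))
})

test_that("cohort traces conserve mass and die monotonically", {
  p <- loneliness_params()
  for (arm in c("control", "intervention")) {
    tr <- run_cohort(p, arm)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 6), tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
  }
  ## first-cycle deaths in the control arm, by hand
  tr <- run_cohort(p, "control")
  expect_equal(tr$occupancy["1", "dead"], 0.44 * 0.0195 + 0.56 * 0.015)
  expect_equal(unname(tr$occupancy["0", ]), c(0, 0.56, 0.44, 0))

  ## the same invariants under randomised parameter sets
  for (seed in 1:15) {
    q <- random_parameter_set(seed)
    expect_length(validate_params(q), 0)
    for (arm in c("control", "intervention")) {
      tr <- run_cohort(q, arm)
      expect_equal(unname(rowSums(tr$occupancy)),
                   rep(1, nrow(tr$occupancy)), tolerance = 1e-10)
      expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
    }
  }
})

test_that("a frozen cohort stays put", {
  p <- random_parameter_set(3, force_identity_transitions = TRUE,
                            zero_mortality = TRUE)
  tr <- run_cohort(p, "control")
  for (k in 2:nrow(tr$occupancy))
    expect_equal(tr$occupancy[k, ], tr$occupancy[1, ])
})

test_that("microsimulation oracle reproduces cohort occupancy within 3 SE", {
  p <- loneliness_params()
  n_persons <- 10000
  for (arm in c("control", "intervention")) {
    cohort <- run_cohort(p, arm)$occupancy
    micro <- microsim_occupancy(p, arm, n_persons = n_persons, seed = 99)
    se <- sqrt(pmax(cohort * (1 - cohort), 1e-12) / n_persons)
    expect_true(all(abs(micro - cohort) <= 3 * se + 1e-9),
                info = paste(arm, "max z:",
                             max(abs(micro - cohort) / se)))
  }
})

test_that("loneliness-free years follow the weighting and discounting rules", {
  ## a cohort permanently not-lonely with no deaths accrues one LFY per cycle
  p <- random_parameter_set(5, force_identity_transitions = TRUE,
                            zero_mortality = TRUE)
  p <- update_params(p, misc.initial_severe = 1e-9,
                     misc.initial_moderate = 1 - 1e-9)
  tr <- run_cohort(p, "control")
  tr$occupancy[, "not_lonely"] <- 1
  tr$occupancy[, c("moderately_lonely", "severely_lonely", "dead")] <- 0
  expect_equal(loneliness_free_years(tr, rate = 0), 5)
  ## discounting shrinks
  expect_lt(loneliness_free_years(tr, rate = 0.015),
            loneliness_free_years(tr, rate = 0))

  ## missing weight errors
  expect_error(loneliness_free_years(tr, weights = c(not_lonely = 1)),
               "weights are missing")

  ## base-case values against the published table
  base <- loneliness_params()
  expect_equal(loneliness_free_years(run_cohort(base, "intervention")), 1.77,
               tolerance = 0.02 / 1.77)
  expect_equal(loneliness_free_years(run_cohort(base, "control")), 1.31,
               tolerance = 0.02 / 1.31)
})

test_that("raising the death relative risk never increases either arm's LFY", {
  p <- loneliness_params()
  lfys <- sapply(c(1, 1.3, 2, 5), function(rr) {
    q <- update_params(p, rr.death = rr)
    c(loneliness_free_years(run_cohort(q, "intervention")),
      loneliness_free_years(run_cohort(q, "control")))
  })
  expect_true(all(diff(lfys[1, ]) <= 1e-12))
  expect_true(all(diff(lfys[2, ]) <= 1e-12))
})

test_that("frozen control with no mortality hits the closed-form LFY", {
  p <- frozen_control_variant(loneliness_params(calibrate = FALSE))
  p <- update_params(p, misc.p_death = 0)
  tr <- run_cohort(p, "control")
  ## 0.56 moderately lonely x weight 0.5 x 5 undiscounted cycles
  expect_equal(loneliness_free_years(tr, rate = 0), 0.56 * 0.5 * 5)
  ## and the annuity form at the outcome discount rate
  expect_equal(loneliness_free_years(tr, rate = 0.015),
               0.28 * sum(1.015^-(0:4)))
  ## the variant leaves the intervention transitions alone: while everyone
  ## stays engaged the intervention arm cannot tell the difference (dropouts
  ## do inherit the frozen dynamics, so full retention isolates the check)
  base <- loneliness_params(calibrate = FALSE)
  expect_equal(run_cohort(update_params(p, misc.sustained_participation = 1),
                          "intervention")$occupancy,
               run_cohort(update_params(base, misc.p_death = 0,
                                        misc.sustained_participation = 1),
                          "intervention")$occupancy)
})

test_that("trace export has the documented tidy shape", {
  tr <- run_cohort(loneliness_params(), "intervention")
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "state", "occupancy", "discounted_lfy_increment"))
  expect_equal(nrow(df), 6 * 4)
  expect_equal(sum(df$occupancy[df$cycle == 3]), 1, tolerance = 1e-10)
})
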