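test_that("the effectiveness lever is the identity at factor 1 and errors when inadmissible", {
  p <- loneliness_params()
  expect_identical(scale_effectiveness(p, 1), p)
  ## pushing effectiveness negative is rejected
  expect_error(scale_effectiveness(p, 0.5), "inadmissible")
  expect_error(scale_effectiveness(p, -1), "factor > 0")
})

test_that("the effectiveness lever moves every intervention flow toward control", {
  p <- loneliness_params()
  q <- scale_effectiveness(p, 0.9)
  ## lonely-to-lonely flows scale by (2 - factor), exits by e'/e
  expect_equal(param_value(q, "transitions.intervention.severe_to_moderate"),
               0.444 * 1.1)
  e0 <- 0.191
  e1 <- 1 - (1 - e0) * 1.1
  expect_equal(param_value(q, "transitions.intervention.severe_to_not"),
               0.187 * e1 / e0)
  expect_equal(param_value(q, "misc.p_not_lonely_after_intervention"), e1)
  ## control untouched
  expect_equal(param_value(q, "transitions.control.severe_to_moderate"), 0.549)
  ## just below factor 0.8 the intervention dynamics coincide with control:
  ## the implied exit probability reaches zero
  f0 <- 2 - 1 / (1 - e0)
  q0 <- scale_effectiveness(p, f0 + 1e-9)
  expect_equal(param_value(q0, "misc.p_not_lonely_after_intervention"), 0,
               tolerance = 1e-6)
})

test_that("a larger effectiveness factor never worsens the ICER", {
  p <- loneliness_params()
  icers <- sapply(c(0.85, 0.95, 1, 1.1, 1.2),
                  function(f) lonely_cea(scale_effectiveness(p, f))$result$icer)
  expect_true(all(diff(icers) < 0))
  ## pushed far enough, the intervention saves more than it costs
  expect_equal(lonely_cea(scale_effectiveness(p, 1.3))$result$dominance,
               "dominant")
})

test_that("tornado is one-at-a-time, flags invalid entries, and sorts by spread", {
  p <- loneliness_params()
  snapshot <- p
  tn <- tornado(p, ids = c("effectiveness", "costs.intervention_per_client",
                           "costs.ae_visit", "misc.initial_severe"))
  ## purity: the input set is bit-identical afterwards
  expect_identical(p, snapshot)
  ## a cost with no modelled driver has zero influence
  ae <- tn[tn$parameter == "costs.ae_visit", ]
  expect_equal(ae$icer_low, ae$icer_high)
  expect_equal(ae$spread, 0)
  ## the effectiveness lever dominates the diagram
  expect_equal(tn$parameter[1], "effectiveness")
  expect_true(all(diff(tn$spread[!is.na(tn$spread)]) <= 0))
  ## perturbing the initial mix alone breaks the mix invariant: flagged,
  ## not dropped
  im <- tn[tn$parameter == "misc.initial_severe", ]
  expect_true(is.na(im$icer_low) && is.na(im$icer_high))
  expect_match(im$note, "must equal 1")
  ## the full multiplier grid rides along
  expect_s3_class(attr(tn, "grid"), "data.frame")
})

test_that("sampled parameters honour their families, bounds and ties", {
  p <- loneliness_params()
  set.seed(123)
  draws <- replicate(400, param_values(sample_parameters(p)))
  ids <- rownames(draws)

  ## strict positivity for the lognormal relative risks
  expect_true(all(draws[ids == "rr.self_harm", ] > 0))
  ## beta draws stay in (0, 1)
  expect_true(all(draws[ids == "misc.sustained_participation", ] >= 0 &
                    draws[ids == "misc.sustained_participation", ] <= 1))
  ## fixed parameters pass through untouched
  expect_true(all(draws[ids == "misc.cost_discount", ] == 0.035))
  expect_true(all(draws[ids == "transitions.control.severe_to_not", ] == 0))
  ## the initial mix stays tied
  expect_equal(draws[ids == "misc.initial_severe", ] +
                 draws[ids == "misc.initial_moderate", ],
               rep(1, 400))
  ## transition rows stay admissible
  s2m <- draws[ids == "transitions.intervention.severe_to_moderate", ]
  s2n <- draws[ids == "transitions.intervention.severe_to_not", ]
  expect_true(all(s2m + s2n <= 1))

  ## central-limit check per family: sample means near the table means
  for (id in c("costs.intervention_per_client",    # gamma
               "incidence.residential_care",       # beta
               "rr.gp_contact")) {                  # lognormal
    mu <- param_value(p, id)
    x <- draws[ids == id, ]
    expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("PSA is seed-reproducible and order-independent", {
  p <- loneliness_params()
  a <- run_psa(p, n = 60, seed = 11)
  b <- run_psa(p, n = 60, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_equal(a$n, 60)
  ## replications own their substreams: a shorter run is a prefix
  c <- run_psa(p, n = 20, seed = 11)
  expect_equal(c$draws, a$draws[1:20, ])
  ## a different seed moves the cloud
  expect_false(identical(run_psa(p, n = 20, seed = 12)$draws, c$draws))
  ## the caller's RNG state is untouched
  set.seed(5); before <- .Random.seed
  invisible(run_psa(p, n = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("PSA means converge to the deterministic increments as CV shrinks", {
  p <- loneliness_params()
  det <- lonely_cea(p)$result
  dev <- sapply(c(0.2, 0.05, 0.01), function(cv) {
    q <- p; q$cv_default <- cv
    psa <- run_psa(q, n = 300, seed = 21)
    c(abs(mean(psa$draws$dcost) - det$dcost),
      abs(mean(psa$draws$dlfy) - det$deffect))
  })
  expect_true(all(dev[, 3] < dev[, 1]))
  expect_lt(dev[1, 3], 0.02 * abs(det$dcost))
  expect_lt(dev[2, 3], 0.02 * abs(det$deffect))
  ## a single replication at (near) zero dispersion is the base case
  q <- p; q$cv_default <- 1e-9
  one <- run_psa(q, n = 1, seed = 3)
  expect_equal(one$draws$dcost, det$dcost, tolerance = 1e-4)
  expect_equal(one$draws$dlfy, det$deffect, tolerance = 1e-4)
})

test_that("discount-rate variant reduces to the default and is monotone", {
  p <- loneliness_params()
  base <- lonely_cea(p)$result$icer
  expect_equal(discount_rate_variant(p, 0.015)$icer, base)
  icers <- sapply(c(0, 0.015, 0.035, 0.06),
                  function(r) discount_rate_variant(p, r)$icer)
  expect_true(all(diff(icers) > 0))
})
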