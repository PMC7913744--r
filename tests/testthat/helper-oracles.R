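## Independent oracles used across the suite.

## Individual-level microsimulation: n_persons stepped through the same
## annual matrices with a seeded RNG; returns occupancy fractions over the
## four collapsed states at each cycle boundary.
microsim_occupancy <- function(params, arm, n_persons = 10000, seed = 99) {
  m <- param_values(params)
  n <- as.integer(m[["misc.n_cycles"]])
  set.seed(seed)
  if (arm == "control") {
    tr <- setNames(m[sprintf("transitions.control.%s",
      c("severe_to_moderate", "severe_to_not", "moderate_to_severe",
        "moderate_to_not", "not_to_severe", "not_to_moderate"))],
      c("severe_to_moderate", "severe_to_not", "moderate_to_severe",
        "moderate_to_not", "not_to_severe", "not_to_moderate"))
    mats <- rep(list(transition_matrix(tr, m[["misc.p_death"]], m[["rr.death"]])), n)
    init_probs <- c(0, m[["misc.initial_moderate"]], m[["misc.initial_severe"]], 0)
    nstate <- 4L; collapse <- diag(4)
  } else {
    keep1 <- m[["misc.sustained_participation"]]^(1 - m[["misc.support_months"]] / 12)
    M1 <- intervention_matrix(params, keep = keep1)
    Mk <- intervention_matrix(params)
    mats <- c(list(M1), rep(list(Mk), n - 1L))
    init_probs <- c(0, m[["misc.initial_moderate"]], m[["misc.initial_severe"]],
                    0, 0, 0, 0)
    nstate <- 7L
    collapse <- rbind(diag(3), diag(3), 0)
    collapse <- cbind(collapse, c(0, 0, 0, 0, 0, 0, 1))
  }
  state <- sample.int(nstate, n_persons, replace = TRUE, prob = init_probs)
  frac <- function(st) {
    cnt <- tabulate(st, nbins = nstate)
    drop(cnt %*% collapse) / n_persons
  }
  occ <- matrix(0, n + 1L, 4L)
  occ[1L, ] <- frac(state)
  for (k in seq_len(n)) {
    M <- mats[[k]]
    new <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      new[idx] <- sample.int(nstate, length(idx), replace = TRUE, prob = M[s, ])
    }
    state <- new
    occ[k + 1L, ] <- frac(state)
  }
  colnames(occ) <- c("not_lonely", "moderately_lonely", "severely_lonely", "dead")
  occ
}

## brute-force acceptability: explicit double loop over samples and grid
ceac_bruteforce <- function(dcost, dlfy, wtp) {
  sapply(wtp, function(l) {
    hits <- 0
    for (i in seq_along(dcost)) if (l * dlfy[i] - dcost[i] > 0) hits <- hits + 1
    hits / length(dcost)
  })
}

## grid-search oracle for the other-contact calibration: scan the severe RR,
## solve the rate from the intervention cell, score the control cell
calibration_grid_oracle <- function(params, targets, rr_grid = seq(0.5, 5, by = 0.002)) {
  m <- param_values(params)
  unit <- m[["costs.hospital_admission"]]
  disc <- m[["misc.cost_discount"]]
  n <- as.integer(m[["misc.n_cycles"]])
  df <- (1 + disc)^-(seq.int(2L, n) - 1L)
  sums <- function(arm) {
    occ <- run_cohort(params, arm)$occupancy[seq.int(2L, n), , drop = FALSE]
    c(base = sum((occ[, "not_lonely"] + occ[, "moderately_lonely"]) * df),
      sev = sum(occ[, "severely_lonely"] * df))
  }
  si <- sums("intervention"); sc <- sums("control")
  err <- sapply(rr_grid, function(r) {
    rate <- targets[["intervention"]] / (unit * (si[["base"]] + r * si[["sev"]]))
    abs(rate * unit * (sc[["base"]] + r * sc[["sev"]]) - targets[["control"]])
  })
  best <- which.min(err)
  list(rr = rr_grid[best],
       rate = targets[["intervention"]] /
         (unit * (si[["base"]] + rr_grid[best] * si[["sev"]])),
       control_error = err[best])
}

baseline_transitions <- function(arm) {
  p <- loneliness_params(calibrate = FALSE)
  ids <- sprintf("transitions.%s.%s", arm,
                 c("severe_to_moderate", "severe_to_not", "moderate_to_severe",
                   "moderate_to_not", "not_to_severe", "not_to_moderate"))
  setNames(param_value(p, ids),
           c("severe_to_moderate", "severe_to_not", "moderate_to_severe",
             "moderate_to_not", "not_to_severe", "not_to_moderate"))
}
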