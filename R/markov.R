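## Cohort engine.  Internal core functions operate on the named vector of
## parameter means (param_values()) so the probabilistic analysis can avoid
## rebuilding data frames per replication.

STATES <- c("not_lonely", "moderately_lonely", "severely_lonely", "dead")
STATES7 <- c("engaged.not_lonely", "engaged.moderately_lonely",
             "engaged.severely_lonely", "disengaged.not_lonely",
             "disengaged.moderately_lonely", "disengaged.severely_lonely",
             "dead")
TRANS_KEYS <- c("severe_to_moderate", "severe_to_not", "moderate_to_severe",
                "moderate_to_not", "not_to_severe", "not_to_moderate")

.arm_transitions <- function(m, arm)
  stats::setNames(m[sprintf("transitions.%s.%s", arm, TRANS_KEYS)], TRANS_KEYS)

#' Annual transition matrix for one arm
#'
#' Builds the four-state row-stochastic annual matrix from the six
#' conditional loneliness transitions, the baseline annual death
#' probability, and the severe-loneliness death relative risk. The printed
#' loneliness transitions are treated as conditional on surviving the year
#' and are scaled by (1 - death probability); the residual mass remains in
#' the current state; the dead state is absorbing.
#'
#' @param transitions named numeric vector with elements
#'   `severe_to_moderate`, `severe_to_not`, `moderate_to_severe`,
#'   `moderate_to_not`, `not_to_severe`, `not_to_moderate`
#' @param p_death baseline annual death probability (applies to the not and
#'   moderately lonely)
#' @param rr_death_severe death relative risk for the severely lonely
#' @return a 4x4 matrix over `not_lonely`, `moderately_lonely`,
#'   `severely_lonely`, `dead`
#' @export
transition_matrix <- function(transitions, p_death, rr_death_severe = 1) {
  miss <- setdiff(TRANS_KEYS, names(transitions))
  if (length(miss)) stop("missing transitions: ", paste(miss, collapse = ", "))
  tr <- transitions
  pd_sev <- p_death * rr_death_severe
  if (pd_sev > 1) stop("p_death x rr_death_severe exceeds 1")
  M <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  fill <- function(state, pd, to, pr) {
    pr <- pr * (1 - pd)
    M[state, to] <<- pr
    M[state, "dead"] <<- pd
    stay <- 1 - pd - sum(pr)
    if (stay < -1e-12)
      stop(sprintf("transition row '%s' has negative residual mass (%.4g)",
                   state, stay))
    M[state, state] <<- max(stay, 0)
  }
  fill("severely_lonely", pd_sev,
       c("moderately_lonely", "not_lonely"),
       c(tr[["severe_to_moderate"]], tr[["severe_to_not"]]))
  fill("moderately_lonely", p_death,
       c("severely_lonely", "not_lonely"),
       c(tr[["moderate_to_severe"]], tr[["moderate_to_not"]]))
  fill("not_lonely", p_death,
       c("severely_lonely", "moderately_lonely"),
       c(tr[["not_to_severe"]], tr[["not_to_moderate"]]))
  M["dead", "dead"] <- 1
  M
}

## 7-state expansion: engaged participants transition by the intervention
## matrix then retain engagement with probability `keep`; disengaged
## participants follow control dynamics; dead absorbing.
.expand7 <- function(Mi, Mc, keep) {
  M <- matrix(0, 7, 7, dimnames = list(STATES7, STATES7))
  M[1:3, 1:3] <- Mi[1:3, 1:3] * keep
  M[1:3, 4:6] <- Mi[1:3, 1:3] * (1 - keep)
  M[1:3, 7] <- Mi[1:3, 4]
  M[4:6, 4:6] <- Mc[1:3, 1:3]
  M[4:6, 7] <- Mc[1:3, 4]
  M[7, 7] <- 1
  M
}

#' Expanded intervention-arm transition matrix
#'
#' Seven-state matrix (engaged and disengaged copies of the three alive
#' states, plus dead). Engaged states transition by the intervention
#' matrix and then retain engagement with probability `keep`; disengaged
#' states follow control dynamics.
#'
#' @param params an `lc_params` object
#' @param keep probability of sustaining participation across the cycle
#'   boundary; defaults to `misc.sustained_participation`
#' @return a 7x7 row-stochastic matrix
#' @export
intervention_matrix <- function(params, keep = NULL) {
  m <- param_values(params)
  if (is.null(keep)) keep <- m[["misc.sustained_participation"]]
  Mi <- transition_matrix(.arm_transitions(m, "intervention"),
                          m[["misc.p_death"]], m[["rr.death"]])
  Mc <- transition_matrix(.arm_transitions(m, "control"),
                          m[["misc.p_death"]], m[["rr.death"]])
  .expand7(Mi, Mc, keep)
}

## First-cycle retention: the support period covers the first
## `misc.support_months` of year one, so the annual sustained-participation
## probability acts only over the remaining fraction of that year.
.first_cycle_keep <- function(m) {
  frac <- max(0, 1 - m[["misc.support_months"]] / 12)
  m[["misc.sustained_participation"]]^frac
}

.run_cohort_core <- function(m, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  n <- as.integer(m[["misc.n_cycles"]])
  init <- c(0, m[["misc.initial_moderate"]], m[["misc.initial_severe"]], 0)
  if (arm == "control") {
    M <- transition_matrix(.arm_transitions(m, "control"),
                           m[["misc.p_death"]], m[["rr.death"]])
    occ <- matrix(0, n + 1L, 4L, dimnames = list(0:n, STATES))
    occ[1L, ] <- init
    for (k in seq_len(n)) occ[k + 1L, ] <- occ[k, ] %*% M
    list(occupancy = occ, engaged = rep(0, n + 1L))
  } else {
    Mi <- transition_matrix(.arm_transitions(m, "intervention"),
                            m[["misc.p_death"]], m[["rr.death"]])
    Mc <- transition_matrix(.arm_transitions(m, "control"),
                            m[["misc.p_death"]], m[["rr.death"]])
    keep <- m[["misc.sustained_participation"]]
    M1 <- .expand7(Mi, Mc, .first_cycle_keep(m))
    Mk <- .expand7(Mi, Mc, keep)
    occ7 <- matrix(0, n + 1L, 7L, dimnames = list(0:n, STATES7))
    occ7[1L, ] <- c(0, init[2L], init[3L], 0, 0, 0, 0)
    for (k in seq_len(n)) occ7[k + 1L, ] <- occ7[k, ] %*% (if (k == 1L) M1 else Mk)
    occ <- cbind(occ7[, 1:3, drop = FALSE] + occ7[, 4:6, drop = FALSE],
                 occ7[, 7, drop = FALSE])
    dimnames(occ) <- list(0:n, STATES)
    list(occupancy = occ, occupancy7 = occ7, engaged = rowSums(occ7[, 1:3, drop = FALSE]))
  }
}

.state_weights <- function(m)
  c(not_lonely = m[["misc.weight_not"]],
    moderately_lonely = m[["misc.weight_moderate"]],
    severely_lonely = m[["misc.weight_severe"]],
    dead = 0)

.lfy_increments <- function(occ, weights, rate, accrual = c("start", "end")) {
  accrual <- match.arg(accrual)
  n <- nrow(occ) - 1L
  w <- weights[colnames(occ)]
  if (anyNA(w)) stop("state weights are missing for: ",
                     paste(colnames(occ)[is.na(w)], collapse = ", "))
  rows <- if (accrual == "start") seq_len(n) else seq_len(n) + 1L
  drop(occ[rows, , drop = FALSE] %*% w) / (1 + rate)^(seq_len(n) - 1L)
}

#' Run the cohort simulation for one arm
#'
#' Propagates the cohort from the initial severity mix (no one starts
#' not-lonely) through `misc.n_cycles` annual transitions. The intervention
#' arm starts fully engaged and uses the expanded engaged/disengaged
#' process: retention is applied after each cycle's transition, at
#' `misc.sustained_participation^(1 - misc.support_months/12)` across the
#' first boundary (dropout can only begin once the support period ends) and
#' at `misc.sustained_participation` thereafter; disengaged survivors
#' follow control dynamics.
#'
#' @param params an `lc_params` object
#' @param arm `"control"` or `"intervention"`
#' @return an `lc_trace`: per-cycle occupancy (rows are cycle boundaries
#'   0..n), discounted loneliness-free-year increments, and the engaged
#'   fraction at each boundary
#' @export
run_cohort <- function(params, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  assert_valid_params(params)
  m <- param_values(params)
  core <- .run_cohort_core(m, arm)
  structure(list(occupancy = core$occupancy,
                 occupancy7 = core$occupancy7,
                 engaged = core$engaged,
                 lfy_per_cycle = .lfy_increments(core$occupancy,
                                                 .state_weights(m),
                                                 m[["misc.outcome_discount"]]),
                 arm = arm,
                 n_cycles = as.integer(m[["misc.n_cycles"]]),
                 outcome_discount = m[["misc.outcome_discount"]],
                 weights = .state_weights(m)),
            class = "lc_trace")
}

#' @export
print.lc_trace <- function(x, ...) {
  cat(sprintf("<lc_trace> %s arm, %d cycles; discounted LFY %.4f\n",
              x$arm, x$n_cycles, sum(x$lfy_per_cycle)))
  print(round(x$occupancy, 4))
  invisible(x)
}

#' @export
as.data.frame.lc_trace <- function(x, ...) {
  occ <- x$occupancy
  cyc <- as.integer(rownames(occ))
  data.frame(cycle = rep(cyc, each = ncol(occ)),
             state = rep(colnames(occ), times = nrow(occ)),
             occupancy = as.vector(t(occ)),
             discounted_lfy_increment =
               rep(c(NA, x$lfy_per_cycle), each = ncol(occ)),
             row.names = NULL)
}

#' Discounted loneliness-free years of a cohort trace
#'
#' Sums the weighted state occupancy over cycles, discounted at the outcome
#' rate with exponent k - 1 (the first cycle is undiscounted). By default
#' occupancy entering each cycle is rewarded (`accrual = "start"`); cycle-end
#' accrual is available for convention sensitivity checks.
#'
#' @param trace an `lc_trace` from [run_cohort()]
#' @param weights named state-value map; defaults to the weights the trace
#'   was run with (1 not lonely, 0.5 moderately lonely, 0 severe or dead)
#' @param rate annual outcome discount rate; defaults to the trace's
#' @param accrual reward occupancy at cycle `"start"` or `"end"`
#' @return total discounted loneliness-free years (scalar)
#' @export
loneliness_free_years <- function(trace, weights = NULL, rate = NULL,
                                  accrual = c("start", "end")) {
  stopifnot(inherits(trace, "lc_trace"))
  if (is.null(weights)) weights <- trace$weights
  if (is.null(rate)) rate <- trace$outcome_discount
  stopifnot(rate >= 0)
  sum(.lfy_increments(trace$occupancy, weights, rate, match.arg(accrual)))
}
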