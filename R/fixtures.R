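## Synthetic parameter-set generation for property-based testing.  The
## generator's RNG is isolated from the global stream so fixture creation
## never perturbs analysis reproducibility.

.with_isolated_rng <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

#' Generate a random, structurally valid parameter set
#'
#' Draws a parameter set with the same structure as the packaged baseline
#' but randomised values: costs log-uniform within `cost_range`, incidences
#' and mortality uniform within `prob_range`, relative risks uniform within
#' `rr_range`, and transition rows drawn so each row sum stays admissible.
#' With `invalid_mode` set, exactly one named invariant is broken instead,
#' so generator output and [validate_params()] can be tested against each
#' other.
#'
#' @param seed integer seed (RNG isolated from the caller's stream)
#' @param cost_range,prob_range,rr_range admissible sampling ranges per
#'   parameter family
#' @param force_identity_transitions zero all loneliness transitions in
#'   both arms (states frozen apart from death)
#' @param zero_mortality set the annual death probability to zero
#' @param frozen_control zero the control-arm transitions only (the
#'   "no change without intervention" variant)
#' @param invalid_mode `NULL`, or one of `"row_sum"`, `"initial_mix"`,
#'   `"negative_cost"`, `"rr_nonpositive"`, `"prob_range"`: break that one
#'   invariant
#' @return an `lc_params`
#' @export
random_parameter_set <- function(seed = NULL,
                                 cost_range = c(10, 20000),
                                 prob_range = c(0.001, 0.05),
                                 rr_range = c(1, 5),
                                 force_identity_transitions = FALSE,
                                 zero_mortality = FALSE,
                                 frozen_control = FALSE,
                                 invalid_mode = NULL) {
  stopifnot(cost_range[1] >= 0, prob_range[1] >= 0, prob_range[2] <= 1,
            rr_range[1] > 0)
  if (!is.null(invalid_mode))
    invalid_mode <- match.arg(invalid_mode,
                              c("row_sum", "initial_mix", "negative_cost",
                                "rr_nonpositive", "prob_range"))
  .with_isolated_rng(seed, {
    p <- loneliness_params(calibrate = FALSE)
    tab <- p$table
    grp <- sub("\\..*$", "", tab$id)

    k <- grp == "costs"
    tab$mean[k] <- exp(stats::runif(sum(k), log(cost_range[1] + 1),
                                    log(cost_range[2])))
    k <- grp == "incidence" & tab$id != "incidence.other_hospital_contact"
    tab$mean[k] <- stats::runif(sum(k), prob_range[1], prob_range[2])
    tab$mean[tab$id == "incidence.other_hospital_contact"] <-
      stats::runif(1, prob_range[1], 1)
    k <- grp == "rr"
    tab$mean[k] <- stats::runif(sum(k), rr_range[1], rr_range[2])
    tab$mean[tab$id == "rr.other_hospital_contact"] <-
      stats::runif(1, rr_range[1], rr_range[2])
    ## keep mortality composable with the death relative risk
    tab$mean[tab$id == "rr.death"] <- stats::runif(1, 1, 3)
    tab$mean[tab$id == "misc.p_death"] <- stats::runif(1, 0, 0.1)

    row_draw <- function() {           # two flows with admissible sum
      repeat {
        x <- stats::runif(2, 0, 0.9)
        if (sum(x) <= 0.98) return(x)
      }
    }
    for (arm in c("intervention", "control"))
      for (rw in list(c("severe_to_moderate", "severe_to_not"),
                      c("moderate_to_severe", "moderate_to_not"),
                      c("not_to_severe", "not_to_moderate"))) {
        ids <- sprintf("transitions.%s.%s", arm, rw)
        tab$mean[match(ids, tab$id)] <- row_draw()
      }
    sev <- stats::runif(1, 0.05, 0.95)
    tab$mean[tab$id == "misc.initial_severe"] <- sev
    tab$mean[tab$id == "misc.initial_moderate"] <- 1 - sev
    tab$mean[tab$id == "misc.sustained_participation"] <- stats::runif(1, 0.5, 1)
    tab$mean[tab$id == "misc.p_not_lonely_after_intervention"] <-
      stats::runif(1, 0.05, 0.5)
    tab$mean[tab$id == "misc.gp_contacts_per_year"] <- stats::runif(1, 1, 15)
    ## zero-mean rows cannot remain beta
    tab$family[tab$mean == 0 & tab$family == "beta"] <- "fixed"

    zero_ids <- character()
    if (force_identity_transitions)
      zero_ids <- grep("^transitions\\.", tab$id, value = TRUE)
    else if (frozen_control)
      zero_ids <- grep("^transitions\\.control\\.", tab$id, value = TRUE)
    if (length(zero_ids)) {
      k <- match(zero_ids, tab$id)
      tab$mean[k] <- 0
      tab$family[k] <- "fixed"
    }
    if (zero_mortality) {
      k <- tab$id == "misc.p_death"
      tab$mean[k] <- 0
      tab$family[k] <- "fixed"
    }

    if (!is.null(invalid_mode)) {
      brk <- switch(invalid_mode,
        row_sum = {
          ids <- sprintf("transitions.intervention.%s",
                         c("moderate_to_severe", "moderate_to_not"))
          tab$mean[match(ids, tab$id)] <- c(0.7, 0.5)
        },
        initial_mix = tab$mean[tab$id == "misc.initial_moderate"] <-
          max(0, tab$mean[tab$id == "misc.initial_severe"] - 0.06),
        negative_cost = tab$mean[tab$id == "costs.gp_contact"] <- -5,
        rr_nonpositive = tab$mean[tab$id == "rr.stroke"] <- -0.5,
        prob_range = tab$mean[tab$id == "incidence.dementia"] <- 1.4)
      brk
    }
    p$table <- tab
    p
  })
}

#' Frozen-control variant of a parameter set
#'
#' Zeroes the control arm's loneliness transitions so that, without the
#' intervention, loneliness states never change (mortality still applies).
#' With no mortality and no outcome discounting the control arm's
#' loneliness-free years then have the closed form
#' initial_moderate x 0.5 x n_cycles.
#'
#' @param params an `lc_params` object
#' @return the modified `lc_params`; the intervention arm is untouched
#' @export
frozen_control_variant <- function(params) {
  stopifnot(inherits(params, "lc_params"))
  ids <- grep("^transitions\\.control\\.", params$table$id, value = TRUE)
  k <- match(ids, params$table$id)
  params$table$mean[k] <- 0
  params$table$family[k] <- "fixed"
  params
}
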