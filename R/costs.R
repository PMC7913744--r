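## Cost accrual.  Event-cost rules translate state occupancy into expected
## per-person-year spending: baseline annual rate x unit cost, with the
## severe-loneliness relative risk applied to the severely lonely (and to
## the moderately lonely only for self-harm).  The dead accrue nothing.

.cost_rules <- function(m, perspective = c("health_social_care", "broader")) {
  perspective <- match.arg(perspective)
  cat_ <- c("gp_visits", "depression", "self_harm", "chd", "stroke",
            "dementia", "residential_care", "other_hospital_contacts")
  rate <- unname(m[c("misc.gp_contacts_per_year", "incidence.depression",
                     "incidence.self_harm", "incidence.chd", "incidence.stroke",
                     "incidence.dementia", "incidence.residential_care",
                     "incidence.other_hospital_contact")])
  unit <- unname(m[c("costs.gp_contact", "costs.depression_annual",
                     "costs.self_harm_presentation", "costs.chd_annual",
                     "costs.stroke_hsc_annual", "costs.dementia_hsc_annual",
                     "costs.residential_care_weekly", "costs.hospital_admission")])
  unit[7] <- unit[7] * m[["misc.weeks_per_admission"]]
  rr <- unname(m[c("rr.gp_contact", "rr.depression", "rr.self_harm", "rr.chd",
                   "rr.stroke", "rr.dementia", "rr.residential_care",
                   "rr.other_hospital_contact")])
  moderate <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  tag <- rep("health_social_care", 8L)
  if (perspective == "broader") {
    cat_ <- c(cat_, "informal_care_stroke", "informal_care_dementia")
    rate <- c(rate, m[["incidence.stroke"]], m[["incidence.dementia"]])
    unit <- c(unit, m[["costs.stroke_informal_annual"]],
              m[["costs.dementia_informal_annual"]])
    rr <- c(rr, m[["rr.stroke"]], m[["rr.dementia"]])
    moderate <- c(moderate, FALSE, FALSE)
    tag <- c(tag, "broader_only", "broader_only")
  }
  rules <- data.frame(category = cat_, rate = rate, unit_cost = unit, rr = rr,
                      applies_to_moderate = moderate, perspective = tag,
                      stringsAsFactors = FALSE)
  ## drop the calibratable category when its drivers are unset
  rules[!is.na(rules$rate) & !is.na(rules$rr), , drop = FALSE]
}

#' Expected annual cost of one event category
#'
#' @param rule a list or one-row data frame with elements `rate` (events or
#'   probability per person-year), `unit_cost` (GBP), `rr` (severe-loneliness
#'   relative risk) and `applies_to_moderate` (logical; `TRUE` only for
#'   self-harm, whose elevated risk covers moderate loneliness as well)
#' @param occupancy named state-fraction vector over the four states
#' @return expected GBP per person-year; the dead contribute nothing
#' @export
expected_annual_cost <- function(rule, occupancy) {
  stopifnot(all(c("rate", "unit_cost", "rr") %in% names(rule)))
  mod_rr <- if (isTRUE(rule$applies_to_moderate[[1]])) rule$rr[[1]] else 1
  w <- occupancy[["not_lonely"]] +
    occupancy[["moderately_lonely"]] * mod_rr +
    occupancy[["severely_lonely"]] * rule$rr[[1]]
  rule$rate[[1]] * rule$unit_cost[[1]] * w
}

## discounted category totals; event costs are charged from `from_cycle`
## onward (default 2: elevated event risks take a model year to manifest),
## using cycle-start occupancy and discount exponent k - 1.
.category_totals <- function(rules, occ, disc, from_cycle = 2L) {
  n <- nrow(occ) - 1L
  cycles <- seq.int(from_cycle, n)
  weights <- vapply(cycles, function(k) {
    v <- occ[k, ]
    base <- v[["not_lonely"]]
    c(base + v[["moderately_lonely"]], v[["severely_lonely"]],
      v[["moderately_lonely"]])
  }, numeric(3))
  df <- (1 + disc)^-(cycles - 1L)
  ## split occupancy into (not+mod, sev, mod): category weight is
  ## (not+mod) + rr*sev, plus (rr-1)*mod when the rr covers moderate
  base <- drop(weights[1, ] %*% df)
  sev <- drop(weights[2, ] %*% df)
  mod <- drop(weights[3, ] %*% df)
  vapply(seq_len(nrow(rules)), function(i) {
    extra_mod <- if (rules$applies_to_moderate[i]) (rules$rr[i] - 1) * mod else 0
    rules$rate[i] * rules$unit_cost[i] * (base + rules$rr[i] * sev + extra_mod)
  }, numeric(1))
}

.volunteer_offset <- function(m, engaged, disc, from_cycle = 2L) {
  n <- length(engaged) - 1L
  cycles <- seq.int(from_cycle, n)
  annual <- m[["misc.volunteer_prob"]] * m[["misc.volunteer_hours_week"]] *
    52 * m[["misc.volunteer_wage_hour"]]
  -annual * sum(engaged[cycles] / (1 + disc)^(cycles - 1L))
}

#' One-off intervention cost
#'
#' The per-client service cost is incurred in year one only, for the share
#' of clients who sustain participation, and carries no discounting (first
#' -year flows have discount exponent zero). The control arm costs nothing.
#'
#' @param params an `lc_params` object
#' @param arm `"intervention"` or `"control"`
#' @return GBP per model participant
#' @export
intervention_cost <- function(params, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  if (arm == "control") return(0)
  m <- param_values(params)
  m[["costs.intervention_per_client"]] * m[["misc.sustained_participation"]]
}

.arm_costs_core <- function(m, occ, engaged, arm, perspective) {
  disc <- m[["misc.cost_discount"]]
  rules <- .cost_rules(m, perspective)
  totals <- .category_totals(rules, occ, disc)
  names(totals) <- rules$category
  iv <- if (arm == "intervention")
    m[["costs.intervention_per_client"]] * m[["misc.sustained_participation"]] else 0
  out <- c(intervention = iv, totals)
  if (perspective == "broader")
    out <- c(out, volunteering_offset =
               if (arm == "intervention") .volunteer_offset(m, engaged, disc) else 0)
  out
}

#' Discounted per-category costs for one arm
#'
#' Sums expected annual event costs over the model horizon at the cost
#' discount rate (exponent k - 1), charging event categories from the
#' second cycle onward, plus the one-off year-one intervention cost. Under
#' the broader perspective, informal-care costs for stroke and dementia are
#' added (same incidence-times-relative-risk structure) and the value of
#' participants' own volunteering is subtracted while they remain engaged.
#'
#' @param trace an `lc_trace` from [run_cohort()]
#' @param params the `lc_params` the trace was produced under
#' @param perspective `"health_social_care"` (primary) or `"broader"`
#' @return an `lc_costs` named vector of per-category discounted GBP totals
#'   with a `total` attribute; `volunteering_offset` is the only
#'   non-positive category
#' @export
arm_costs <- function(trace, params,
                      perspective = c("health_social_care", "broader")) {
  stopifnot(inherits(trace, "lc_trace"))
  perspective <- match.arg(perspective)
  m <- param_values(params)
  out <- .arm_costs_core(m, trace$occupancy, trace$engaged, trace$arm, perspective)
  structure(out, total = sum(out), arm = trace$arm, perspective = perspective,
            class = "lc_costs")
}

#' @export
print.lc_costs <- function(x, ...) {
  cat(sprintf("<lc_costs> %s arm, %s perspective\n",
              attr(x, "arm"), attr(x, "perspective")))
  for (nm in names(x)) cat(sprintf("  %-24s %9.0f\n", nm, x[[nm]]))
  cat(sprintf("  %-24s %9.0f\n", "total", attr(x, "total")))
  invisible(x)
}

#' Calibrate the pooled "other hospital contacts" category
#'
#' The published table prices accident-and-emergency visits, ambulance
#' call-outs and hospital admissions but gives the pooled category no rate
#' or relative-risk driver, while the results table reports one per-arm
#' cost cell for it. This solves for the annual contact rate and the
#' severe-loneliness relative risk such that the category's discounted
#' totals reproduce both cells, using the hospital admission cost as the
#' unit price (rate and unit price enter only as a product, so the unit
#' choice is a labelling convention). The two totals are linear in the
#' rate and, given the two arms' occupancy traces, monotone in the relative
#' risk, so the pair is identified; the relative risk is found by root
#' finding on the ratio of the two cells.
#'
#' @param params an `lc_params` object (its other-contact drivers are
#'   overwritten)
#' @param targets named numeric `c(intervention=, control=)`: the two
#'   discounted five-year category totals (GBP)
#' @param rr optional fixed relative risk; when supplied, only the rate is
#'   fitted and calibration fails unless both cells are met within
#'   `tolerance`
#' @param tolerance maximum admissible relative error on each reproduced
#'   cell (default 0.005)
#' @return the updated `lc_params`, with a `calibration` record
#' @export
calibrate_other_contacts <- function(params,
                                     targets = c(intervention = 799,
                                                 control = 818),
                                     rr = NULL, tolerance = 0.005) {
  stopifnot(inherits(params, "lc_params"), length(targets) == 2L)
  if (is.null(names(targets))) names(targets) <- c("intervention", "control")
  ti <- targets[["intervention"]]; tc <- targets[["control"]]
  if (ti < 0 || tc < 0) stop("calibration targets must be non-negative")
  m <- param_values(params)
  unit <- m[["costs.hospital_admission"]]
  disc <- m[["misc.cost_discount"]]
  n <- as.integer(m[["misc.n_cycles"]])
  cycles <- seq.int(2L, n)
  df <- (1 + disc)^-(cycles - 1L)
  comp <- function(arm) {
    occ <- .run_cohort_core(m, arm)$occupancy
    c(base = sum((occ[cycles, "not_lonely"] +
                  occ[cycles, "moderately_lonely"]) * df),
      sev = sum(occ[cycles, "severely_lonely"] * df))
  }
  si <- comp("intervention"); sc <- comp("control")
  record <- function(rate, rr) {
    cells <- c(intervention = rate * unit * (si[["base"]] + rr * si[["sev"]]),
               control = rate * unit * (sc[["base"]] + rr * sc[["sev"]]))
    err <- abs(cells - targets) / pmax(targets, 1e-12)
    if (any(err[targets > 0] > tolerance))
      stop(sprintf(paste0("other-contact calibration failed: fitted cells ",
                          "(%.2f, %.2f) miss targets (%.2f, %.2f)"),
                   cells[1], cells[2], ti, tc))
    p <- update_params(params,
                       incidence.other_hospital_contact = rate,
                       rr.other_hospital_contact = rr)
    p$calibration <- list(targets = targets, rate = rate, rr = rr,
                          fitted_cells = cells, unit_cost = unit)
    p
  }
  if (ti == 0 && tc == 0) return(record(0, if (is.null(rr)) 1 else rr))
  if (ti == 0 || tc == 0)
    stop("other-contact calibration failed: one target is zero, the other is not")
  if (!is.null(rr)) {
    stopifnot(rr > 0)
    rate <- ti / (unit * (si[["base"]] + rr * si[["sev"]]))
    return(record(rate, rr))
  }
  g <- function(r) ti * (sc[["base"]] + r * sc[["sev"]]) -
                   tc * (si[["base"]] + r * si[["sev"]])
  lo <- 1e-9; hi <- 1e4
  if (g(lo) * g(hi) > 0)
    stop(sprintf(paste0("other-contact calibration failed: no admissible ",
                        "relative risk in (%g, %g) reproduces the target ",
                        "ratio %.4f"), lo, hi, tc / ti))
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  rate <- ti / (unit * (si[["base"]] + r * si[["sev"]]))
  if (rate < 0) stop("other-contact calibration failed: negative rate")
  record(rate, r)
}
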