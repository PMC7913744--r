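## Main model interface: lonely_cea() runs the full deterministic pipeline
## for both arms and returns a classed fit object.

.eval_core <- function(m, perspective) {
  ctl <- .run_cohort_core(m, "control")
  itv <- .run_cohort_core(m, "intervention")
  w <- .state_weights(m)
  orate <- m[["misc.outcome_discount"]]
  lfy <- c(intervention = sum(.lfy_increments(itv$occupancy, w, orate)),
           control = sum(.lfy_increments(ctl$occupancy, w, orate)))
  ci <- .arm_costs_core(m, itv$occupancy, itv$engaged, "intervention", perspective)
  cc <- .arm_costs_core(m, ctl$occupancy, ctl$engaged, "control", perspective)
  list(lfy = lfy, cost = c(intervention = sum(ci), control = sum(cc)),
       cost_breakdown = list(intervention = ci, control = cc),
       cores = list(intervention = itv, control = ctl))
}

#' Evaluate the loneliness-alleviation decision model
#'
#' Runs the five-cycle, four-state cohort model for the intervention and
#' no-intervention arms under one parameter set, accrues discounted
#' loneliness-free years (outcome discount rate) and discounted
#' per-category costs (cost discount rate), and computes the incremental
#' cost-effectiveness ratio.
#'
#' @param params an `lc_params` object; defaults to the packaged baseline
#' @param perspective `"health_social_care"` (primary analysis) or
#'   `"broader"` (adds stroke and dementia informal care and the
#'   volunteering offset)
#' @return an object of class `lonely_cea` with components `params`,
#'   `perspective`, `traces` (per-arm `lc_trace`), `costs` (per-arm
#'   `lc_costs`), `lfy`, and `result` (an `lc_ce`)
#' @examples
#' fit <- lonely_cea()
#' fit
#' coef(fit)
#' @export
lonely_cea <- function(params = loneliness_params(),
                       perspective = c("health_social_care", "broader")) {
  perspective <- match.arg(perspective)
  assert_valid_params(params)
  m <- param_values(params)
  ev <- .eval_core(m, perspective)
  traces <- lapply(c(intervention = "intervention", control = "control"),
                   function(a) run_cohort(params, a))
  costs <- lapply(traces, arm_costs, params = params, perspective = perspective)
  structure(list(params = params,
                 perspective = perspective,
                 traces = traces,
                 costs = costs,
                 lfy = ev$lfy,
                 result = icer(ev$cost[["intervention"]], ev$cost[["control"]],
                               ev$lfy[["intervention"]], ev$lfy[["control"]])),
            class = "lonely_cea")
}

#' @export
print.lonely_cea <- function(x, ...) {
  r <- x$result
  cat(sprintf("Loneliness-alleviation cohort model (%s perspective, %d cycles)\n",
              x$perspective, x$traces$control$n_cycles))
  cat(sprintf("  total cost:    %7.0f vs %7.0f GBP (delta %+.0f)\n",
              r$cost[1], r$cost[2], r$dcost))
  cat(sprintf("  LFY:           %7.2f vs %7.2f     (delta %+.2f)\n",
              r$effect[1], r$effect[2], r$deffect))
  if (r$dominance %in% c("icer", "southwest"))
    cat(sprintf("  ICER:          %7.0f GBP per loneliness-free year\n", r$icer))
  else cat(sprintf("  dominance:     %s\n", r$dominance))
  invisible(x)
}

#' @export
summary.lonely_cea <- function(object, ...) {
  structure(list(table = cea_table(object), result = object$result,
                 perspective = object$perspective),
            class = "summary.lonely_cea")
}

#' @export
print.summary.lonely_cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness summary (%s perspective)\n", x$perspective))
  tab <- x$table
  fmt <- function(v) sprintf(ifelse(tab$category == "lfy", "%.2f", "%.0f"), v)
  tab$intervention <- fmt(tab$intervention)   # whole GBP at the printing layer
  tab$control <- fmt(tab$control)
  print(tab, row.names = FALSE)
  r <- x$result
  if (r$dominance %in% c("icer", "southwest"))
    cat(sprintf("ICER: %.0f GBP per loneliness-free year\n", r$icer))
  else cat(sprintf("dominance: %s\n", r$dominance))
  invisible(x)
}

#' @export
coef.lonely_cea <- function(object, ...) {
  r <- object$result
  c(cost_intervention = unname(r$cost[1]), cost_control = unname(r$cost[2]),
    lfy_intervention = unname(r$effect[1]), lfy_control = unname(r$effect[2]),
    dcost = r$dcost, dlfy = r$deffect, icer = r$icer)
}

#' Plot a fitted model: cohort state occupancy by arm
#'
#' @param x a `lonely_cea` object
#' @param ... passed to [graphics::matplot()]
#' @export
plot.lonely_cea <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  cols <- c("#2c7fb8", "#fdae61", "#d7191c", "grey40")
  for (arm in c("intervention", "control")) {
    occ <- x$traces[[arm]]$occupancy
    graphics::matplot(as.integer(rownames(occ)), occ, type = "b", pch = 16,
                      lty = 1, col = cols, ylim = c(0, 1),
                      xlab = "cycle (years)", ylab = "state occupancy",
                      main = arm, ...)
  }
  graphics::legend("topright", legend = colnames(x$traces$control$occupancy),
                   col = cols, lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate parameter uncertainty for a fitted model
#'
#' Convenience wrapper: reruns the fitted model `nsim` times with parameters
#' drawn from their assigned distributions (see [run_psa()]).
#'
#' @param object a `lonely_cea` object
#' @param nsim number of Monte Carlo replications
#' @param seed master seed for the replication streams
#' @param ... passed to [run_psa()]
#' @export
simulate.lonely_cea <- function(object, nsim = 1000, seed = 1L, ...) {
  run_psa(object$params, n = nsim, seed = seed,
          perspective = object$perspective, ...)
}
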