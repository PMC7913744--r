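## Incremental cost-effectiveness metrics on the cost-effectiveness plane
## (x = incremental effect in loneliness-free years, y = incremental cost).

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param cost_i,cost_c discounted total cost per arm (GBP)
#' @param eff_i,eff_c discounted effect per arm (loneliness-free years)
#' @return an `lc_ce` object: per-arm totals, increments, the ICER value
#'   when defined, and a dominance label: `"icer"` (north-east),
#'   `"dominant"` (cheaper, no worse), `"dominated"` (costlier, worse),
#'   `"southwest"` (cheaper and worse; ratio reported),
#'   `"dominated_by_convention"` (costlier with exactly zero effect gain)
#' @examples
#' icer(100, 50, 2, 1)   # 50 GBP per loneliness-free year
#' icer(50, 100, 2, 1)   # dominant
#' @export
icer <- function(cost_i, cost_c, eff_i, eff_c) {
  stopifnot(is.finite(cost_i), is.finite(cost_c),
            is.finite(eff_i), is.finite(eff_c))
  dc <- cost_i - cost_c
  de <- eff_i - eff_c
  if (de > 0 && dc > 0) {
    label <- "icer"; value <- dc / de
  } else if (de > 0) {
    label <- "dominant"; value <- NA_real_
  } else if (de < 0 && dc > 0) {
    label <- "dominated"; value <- NA_real_
  } else if (de < 0 && dc < 0) {
    label <- "southwest"; value <- dc / de
  } else if (de == 0 && dc > 0) {
    label <- "dominated_by_convention"; value <- NA_real_
  } else {  # de == 0, dc <= 0
    label <- if (dc < 0) "dominant" else "indifferent"
    value <- NA_real_
  }
  structure(list(cost = c(intervention = cost_i, control = cost_c),
                 effect = c(intervention = eff_i, control = eff_c),
                 dcost = dc, deffect = de, icer = value, dominance = label),
            class = "lc_ce")
}

#' @export
print.lc_ce <- function(x, ...) {
  cat("<lc_ce>\n")
  cat(sprintf("  cost:   intervention %9.0f  control %9.0f  (delta %+.0f)\n",
              x$cost[1], x$cost[2], x$dcost))
  cat(sprintf("  effect: intervention %9.3f  control %9.3f  (delta %+.3f)\n",
              x$effect[1], x$effect[2], x$deffect))
  if (x$dominance %in% c("icer", "southwest"))
    cat(sprintf("  ICER: %.0f GBP per loneliness-free year (%s)\n",
                x$icer, x$dominance))
  else cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * deffect - dcost`; positive exactly when the intervention is
#' cost-effective at willingness-to-pay `wtp`.
#'
#' @param dcost,deffect incremental cost (GBP) and effect (loneliness-free
#'   years); vectors recycle
#' @param wtp willingness to pay per loneliness-free year (GBP)
#' @export
nmb <- function(dcost, deffect, wtp) wtp * deffect - dcost

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective: the fraction of replications with strictly positive
#' net monetary benefit (ties count as not cost-effective).
#'
#' @param dcost,deffect per-replication incremental cost and effect
#' @param wtp ascending grid of willingness-to-pay values (GBP per
#'   loneliness-free year); the default spans zero to three times the
#'   baseline per-client intervention cost in unit steps
#' @return a data frame with columns `wtp` and `prob`
#' @export
ceac <- function(dcost, deffect, wtp = 0:2256) {
  stopifnot(length(dcost) == length(deffect), length(dcost) > 0,
            !is.unsorted(wtp))
  prob <- vapply(wtp, function(l) mean(l * deffect - dcost > 0), numeric(1))
  data.frame(wtp = wtp, prob = prob)
}

#' Break-even willingness to pay
#'
#' The smallest willingness-to-pay at which the intervention is more likely
#' cost-effective than not (acceptability above 0.5), linearly interpolated
#' between the bracketing grid points.
#'
#' @param points a data frame from [ceac()]
#' @return GBP per loneliness-free year, or `NA` if the curve never crosses
#'   0.5 on the grid
#' @export
break_even_wtp <- function(points) {
  stopifnot(all(c("wtp", "prob") %in% names(points)))
  above <- which(points$prob > 0.5)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(points$wtp[1])
  p0 <- points$prob[i - 1L]; p1 <- points$prob[i]
  w0 <- points$wtp[i - 1L]; w1 <- points$wtp[i]
  w0 + (0.5 - p0) / (p1 - p0) * (w1 - w0)
}

#' Cost-effectiveness plane summary
#'
#' Quadrant shares of the replication cloud and a 95% bivariate-normal
#' ellipse fitted by moments. Quadrants follow the usual plane convention
#' (effect on x, cost on y): NE more effective and more costly, SE more
#' effective and cheaper (dominant), NW less effective and more costly
#' (dominated), SW less effective and cheaper.
#'
#' @param dcost,deffect per-replication incremental cost and effect
#'   (at least two replications)
#' @param level ellipse coverage probability
#' @return a list with `quadrants` (named shares summing to 1, boundary
#'   points grouped with the weakly-dominant side) and `ellipse` (centre,
#'   covariance, semi-axes and orientation), or `ellipse = NULL` with
#'   `degenerate = TRUE` when the cloud has no variance
#' @export
plane_summary <- function(dcost, deffect, level = 0.95) {
  stopifnot(length(dcost) == length(deffect), length(dcost) >= 2)
  ne <- deffect > 0 & dcost > 0
  se <- deffect > 0 & dcost <= 0
  nw <- deffect <= 0 & dcost > 0
  sw <- !(ne | se | nw)
  quad <- c(NE = mean(ne), SE = mean(se), NW = mean(nw), SW = mean(sw))
  S <- stats::cov(cbind(deffect, dcost))
  degenerate <- any(diag(S) < .Machine$double.eps)
  ell <- NULL
  if (!degenerate) {
    eg <- eigen(S, symmetric = TRUE)
    r <- sqrt(stats::qchisq(level, df = 2))
    ell <- list(center = c(deffect = mean(deffect), dcost = mean(dcost)),
                cov = S,
                semi_axes = r * sqrt(pmax(eg$values, 0)),
                angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                level = level)
  }
  list(quadrants = quad, ellipse = ell, degenerate = degenerate)
}
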