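## One-way (tornado) and probabilistic sensitivity analysis.

#' Scale the intervention's effectiveness
#'
#' The intervention arm's annual transitions have a mixture structure: with
#' probability e (about 0.19, the "probability of becoming not lonely after
#' the intervention") a participant exits loneliness, and with probability
#' 1 - e follows the no-intervention dynamics (each published
#' lonely-to-lonely intervention flow equals the control flow times 1 - e).
#' Effectiveness is therefore the achieved reduction 1 - e in the relative
#' risk of remaining lonely, and scaling it by `factor` multiplies that
#' relative risk rho = 1 - e by (2 - factor): 10% less effective
#' (`factor = 0.9`) raises rho by 10%, pushing every flow toward the
#' control dynamics; at `factor` slightly below 0.8 the intervention's
#' transitions coincide with control and the effect vanishes.
#'
#' Concretely, the exit flows (severe to not, moderate to not) are scaled
#' by e'/e and the four lonely-to-lonely flows by (1 - e')/(1 - e), where
#' e' = 1 - (1 - e) (2 - factor). Control transitions are untouched and
#' `factor = 1` is the identity.
#'
#' @param params an `lc_params` object
#' @param factor positive effectiveness multiplier; values making any
#'   transition probability inadmissible raise an error
#' @return the scaled `lc_params`
#' @export
scale_effectiveness <- function(params, factor) {
  stopifnot(inherits(params, "lc_params"), is.numeric(factor),
            length(factor) == 1L, factor > 0)
  if (factor == 1) return(params)
  e0 <- param_value(params, "misc.p_not_lonely_after_intervention")
  rho <- (1 - e0) * (2 - factor)
  e <- 1 - rho
  if (e < 0 || e > 1 || rho < 0)
    stop(sprintf(paste0("effectiveness factor %.3f is inadmissible: implied ",
                        "exit probability %.4f outside [0, 1]"), factor, e))
  ids_exit <- c("transitions.intervention.severe_to_not",
                "transitions.intervention.moderate_to_not")
  ids_lonely <- c("transitions.intervention.severe_to_moderate",
                  "transitions.intervention.moderate_to_severe",
                  "transitions.intervention.not_to_severe",
                  "transitions.intervention.not_to_moderate")
  v <- c(param_value(params, ids_exit) * e / e0,
         param_value(params, ids_lonely) * (2 - factor))
  p <- update_params(params, stats::setNames(c(v, e), c(ids_exit, ids_lonely,
        "misc.p_not_lonely_after_intervention")))
  bad <- validate_params(p)
  bad <- grep("transitions", bad, value = TRUE)
  if (length(bad))
    stop("effectiveness factor ", factor, " makes transitions inadmissible:\n  ",
         paste(bad, collapse = "\n  "))
  p
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full deterministic pipeline varying one parameter at a time
#' by the given multipliers, holding everything else at base case. The id
#' `"effectiveness"` is special-cased through [scale_effectiveness()];
#' every other id multiplies that parameter's mean. Perturbed sets that
#' violate an invariant are flagged (ICER `NA` and the violation recorded),
#' never silently dropped; the input parameter set is returned untouched.
#'
#' @param params an `lc_params` object
#' @param ids parameter ids to vary; default covers the influential levers
#' @param multipliers multipliers applied to each parameter; the extreme
#'   pair defines each entry's low/high columns
#' @param perspective costing perspective for the reruns
#' @return a data frame (class `lc_tornado`) with one row per parameter:
#'   `parameter`, `mult_low`, `icer_low`, `mult_high`, `icer_high`,
#'   `spread`, `note`, sorted by decreasing spread (stable); the full
#'   multiplier grid is in `attr(, "grid")`
#' @export
tornado <- function(params,
                    ids = c("effectiveness",
                            "costs.intervention_per_client",
                            "rr.residential_care",
                            "costs.residential_care_weekly",
                            "rr.gp_contact",
                            "misc.sustained_participation",
                            "incidence.residential_care",
                            "misc.gp_contacts_per_year"),
                    multipliers = c(0.8, 1.2),
                    perspective = c("health_social_care", "broader")) {
  perspective <- match.arg(perspective)
  assert_valid_params(params)
  stopifnot(length(multipliers) >= 2)
  known <- c("effectiveness", params$table$id)
  if (length(bad <- setdiff(ids, known)))
    stop("unknown parameter id: ", paste(bad, collapse = ", "))
  base_icer <- lonely_cea(params, perspective)$result$icer

  one <- function(id, mult) {
    p <- try(if (id == "effectiveness") scale_effectiveness(params, mult)
             else update_params(params, stats::setNames(
                    param_value(params, id) * mult, id)),
             silent = TRUE)
    if (inherits(p, "try-error"))
      return(list(icer = NA_real_, note = conditionMessage(attr(p, "condition"))))
    viol <- validate_params(p)
    if (length(viol)) return(list(icer = NA_real_, note = viol[1]))
    r <- lonely_cea(p, perspective)$result
    list(icer = if (is.na(r$icer)) NA_real_ else r$icer,
         note = if (r$dominance %in% c("icer", "southwest")) "" else r$dominance)
  }

  grid <- do.call(rbind, lapply(ids, function(id)
    do.call(rbind, lapply(multipliers, function(mu) {
      r <- one(id, mu)
      data.frame(parameter = id, multiplier = mu, icer = r$icer,
                 note = r$note, stringsAsFactors = FALSE)
    }))))
  lo <- min(multipliers); hi <- max(multipliers)
  ent <- do.call(rbind, lapply(ids, function(id) {
    gl <- grid[grid$parameter == id & grid$multiplier == lo, ]
    gh <- grid[grid$parameter == id & grid$multiplier == hi, ]
    data.frame(parameter = id, mult_low = lo, icer_low = gl$icer,
               mult_high = hi, icer_high = gh$icer,
               spread = abs(gh$icer - gl$icer),
               note = trimws(paste(gl$note, gh$note)),
               stringsAsFactors = FALSE)
  }))
  ent <- ent[order(-ent$spread, na.last = TRUE), , drop = FALSE]
  rownames(ent) <- NULL
  structure(ent, grid = grid, base_icer = base_icer, class = c("lc_tornado",
            "data.frame"))
}

#' Outcome discount-rate variant
#'
#' Reruns the deterministic base case with the outcome discount rate
#' overridden (costs keep their own rate).
#'
#' @param params an `lc_params` object
#' @param outcome_rate annual outcome discount rate
#' @param perspective costing perspective
#' @return an `lc_ce` for the rerun
#' @export
discount_rate_variant <- function(params, outcome_rate = 0.035,
                                  perspective = c("health_social_care",
                                                  "broader")) {
  stopifnot(outcome_rate >= 0)
  lonely_cea(update_params(params, misc.outcome_discount = outcome_rate),
             match.arg(perspective))$result
}

## Vectorised draw of all parameter means from the current RNG state.
## Returns the named mean vector plus clip / redraw counters.
.sample_means <- function(tab, cv_default) {
  mu <- tab$mean
  sdv <- ifelse(!is.na(tab$se), tab$se,
                ifelse(!is.na(tab$cv), tab$cv, cv_default) * mu)
  draw_rows <- function(rows) {
    m <- mu[rows]; s <- sdv[rows]; fam <- tab$family[rows]
    out <- m
    ok <- !is.na(m) & !is.na(s) & s > 0
    b <- fam == "beta" & ok & m > 0 & m < 1   # boundary means stay put
    if (any(b)) {
      ## method of moments; dispersion capped below the beta support limit
      smax <- 0.95 * sqrt(m[b] * (1 - m[b]))
      sb <- pmin(s[b], smax)
      nu <- m[b] * (1 - m[b]) / sb^2 - 1
      out[b] <- stats::rbeta(sum(b), m[b] * nu, (1 - m[b]) * nu)
    }
    g <- fam == "gamma" & ok
    if (any(g))
      out[g] <- stats::rgamma(sum(g), shape = (m[g] / s[g])^2,
                              scale = s[g]^2 / m[g])
    l <- fam == "lognormal" & ok
    if (any(l)) {
      ## arithmetic mean pinned to the tabled value
      sdl2 <- log(1 + (s[l] / m[l])^2)
      out[l] <- stats::rlnorm(sum(l), log(m[l]) - sdl2 / 2, sqrt(sdl2))
    }
    out
  }
  v <- draw_rows(seq_len(nrow(tab)))
  ## admissible bounds
  lo <- ifelse(is.na(tab$low), -Inf, tab$low)
  hi <- ifelse(is.na(tab$high), Inf, tab$high)
  clipped <- sum(v < lo | v > hi, na.rm = TRUE)
  v <- pmin(pmax(v, lo), hi)
  names(v) <- tab$id
  ## structural ties and constraints
  v[["misc.initial_moderate"]] <- 1 - v[["misc.initial_severe"]]
  redraws <- 0L
  rows <- list(c("severe_to_moderate", "severe_to_not"),
               c("moderate_to_severe", "moderate_to_not"),
               c("not_to_severe", "not_to_moderate"))
  for (arm in c("intervention", "control"))
    for (rw in rows) {
      ids <- sprintf("transitions.%s.%s", arm, rw)
      k <- match(ids, tab$id)
      tries <- 0L
      while (sum(v[ids]) > 1 && tries < 100L) {
        v[ids] <- pmin(pmax(draw_rows(k), lo[k]), hi[k])
        tries <- tries + 1L
      }
      if (sum(v[ids]) > 1) v[ids] <- v[ids] / (sum(v[ids]) + 1e-9)
      redraws <- redraws + tries
    }
  while (v[["misc.p_death"]] * v[["rr.death"]] > 1) {
    v[["rr.death"]] <- draw_rows(match("rr.death", tab$id))
    redraws <- redraws + 1L
  }
  attr(v, "clipped") <- clipped
  attr(v, "redraws") <- redraws
  v
}

#' Draw one parameter set from the assigned distributions
#'
#' Samples every non-fixed parameter from its distribution family using the
#' current RNG state: beta by method of moments from (mean, sd), gamma by
#' shape/scale from (mean, sd), lognormal with the arithmetic mean pinned
#' to the tabled mean and sd from the dispersion. The dispersion is the
#' parameter's `se` if set, else its `cv` (or the set-wide default) times
#' the mean. Draws are clipped to declared bounds, the initial moderate
#' share is tied to 1 minus the severe share, and transition rows breaching
#' the row-sum constraint are redrawn; clip and redraw counts are attached
#' as attributes.
#'
#' @param params an `lc_params` object
#' @return an `lc_params` whose means are one random draw, with attributes
#'   `clipped` and `redraws`
#' @export
sample_parameters <- function(params) {
  stopifnot(inherits(params, "lc_params"))
  bad <- params$table$family == "beta" &
    (params$table$mean < 0 | params$table$mean > 1)
  if (any(bad, na.rm = TRUE))
    stop("beta distribution requires mean in (0, 1): ",
         paste(params$table$id[which(bad)], collapse = ", "))
  v <- .sample_means(params$table, params$cv_default)
  p <- params
  p$table$mean <- unname(v)
  attr(p, "clipped") <- attr(v, "clipped")
  attr(p, "redraws") <- attr(v, "redraws")
  p
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: `n` independent
#' parameter draws (see [sample_parameters()]), each run through both
#' arms' full deterministic pipeline. Each replication consumes its own
#' L'Ecuyer-CMRG RNG substream derived from the master seed, so results
#' are reproducible and independent of evaluation order; the caller's RNG
#' state is restored on exit.
#'
#' @param params an `lc_params` object
#' @param n number of replications
#' @param seed master integer seed
#' @param perspective costing perspective
#' @param wtp willingness-to-pay grid for the acceptability curve; default
#'   zero to three times the per-client intervention cost, unit steps
#' @return an `lc_psa`: per-replication increments, acceptability curve,
#'   plane quadrant shares and ellipse, summary quantiles, clip/redraw
#'   counts
#' @export
run_psa <- function(params, n = 10000, seed = 1L,
                    perspective = c("health_social_care", "broader"),
                    wtp = NULL) {
  perspective <- match.arg(perspective)
  assert_valid_params(params)
  stopifnot(n >= 1)
  if (is.null(wtp))
    wtp <- seq(0, round(3 * param_value(params, "costs.intervention_per_client")))

  ## isolate the PSA RNG from the caller's stream
  had_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had_seed) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())

  tab <- params$table
  cvd <- params$cv_default
  dcost <- numeric(n); dlfy <- numeric(n)
  clipped <- 0L; redraws <- 0L
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, globalenv())
    v <- .sample_means(tab, cvd)
    clipped <- clipped + attr(v, "clipped")
    redraws <- redraws + attr(v, "redraws")
    ev <- .eval_core(v, perspective)
    dcost[i] <- ev$cost[[1L]] - ev$cost[[2L]]
    dlfy[i] <- ev$lfy[[1L]] - ev$lfy[[2L]]
  }
  curve <- ceac(dcost, dlfy, wtp)
  plane <- if (n >= 2) plane_summary(dcost, dlfy) else NULL
  qs <- function(x) c(mean = mean(x), stats::quantile(x, c(0.025, 0.5, 0.975)))
  structure(list(seed = seed, n = n, perspective = perspective,
                 draws = data.frame(dcost = dcost, dlfy = dlfy),
                 ceac = curve,
                 break_even = break_even_wtp(curve),
                 quadrants = plane$quadrants,
                 ellipse = plane$ellipse,
                 summary = rbind(dcost = qs(dcost), dlfy = qs(dlfy)),
                 clipped = clipped, redraws = redraws),
            class = "lc_psa")
}

#' @export
print.lc_psa <- function(x, ...) {
  cat(sprintf("<lc_psa> %d replications (seed %d, %s perspective)\n",
              x$n, x$seed, x$perspective))
  cat(sprintf("  mean dcost %.0f GBP, mean dLFY %.3f\n",
              mean(x$draws$dcost), mean(x$draws$dlfy)))
  if (!is.null(x$quadrants)) {
    q <- x$quadrants
    cat(sprintf("  quadrants: NE %.1f%%  SE (dominant) %.1f%%  NW %.1f%%  SW %.1f%%\n",
                100 * q[["NE"]], 100 * q[["SE"]], 100 * q[["NW"]], 100 * q[["SW"]]))
  }
  if (!is.na(x$break_even))
    cat(sprintf("  break-even willingness to pay: %.0f GBP per LFY\n", x$break_even))
  invisible(x)
}

#' Plot a probabilistic sensitivity analysis
#'
#' Left panel: the cost-effectiveness plane with the 95% moment ellipse;
#' right panel: the cost-effectiveness acceptability curve.
#'
#' @param x an `lc_psa` object
#' @param ... passed to [graphics::plot()]
#' @export
plot.lc_psa <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.2, 4.2, 2.5, 1))
  on.exit(graphics::par(op))
  d <- x$draws
  graphics::plot(d$dlfy, d$dcost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("#2c7fb8", 0.35),
                 xlab = "incremental loneliness-free years",
                 ylab = "incremental cost (GBP)",
                 main = "cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  if (!is.null(x$ellipse)) {
    e <- x$ellipse
    t <- seq(0, 2 * pi, length.out = 181)
    R <- cbind(c(cos(e$angle), sin(e$angle)), c(-sin(e$angle), cos(e$angle)))
    pts <- t(R %*% rbind(e$semi_axes[1] * cos(t), e$semi_axes[2] * sin(t)))
    graphics::lines(e$center[1] + pts[, 1], e$center[2] + pts[, 2],
                    col = "#d7191c", lwd = 2)
  }
  graphics::plot(x$ceac$wtp, x$ceac$prob, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "willingness to pay (GBP per LFY)",
                 ylab = "probability cost-effective",
                 main = "acceptability curve")
  graphics::abline(h = 0.5, col = "grey60", lty = 2)
  if (!is.na(x$break_even)) graphics::abline(v = x$break_even, col = "#d7191c",
                                             lty = 2)
  invisible(x)
}
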