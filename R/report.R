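## Reporting surfaces: summary cost table, CSV/JSON exports and run
## manifests.  Internal arithmetic is never rounded; currency rounding
## happens only when printing.

#' Cost-effectiveness summary table
#'
#' Per-category discounted costs for both arms plus the loneliness-free
#' years, shaped like the published summary tables (one row per category,
#' one column per arm). Values are unrounded.
#'
#' @param fit a `lonely_cea` object
#' @return a data frame with columns `category`, `intervention`, `control`
#' @export
cea_table <- function(fit) {
  stopifnot(inherits(fit, "lonely_cea"))
  ci <- fit$costs$intervention
  cc <- fit$costs$control
  data.frame(category = c(names(ci), "total_cost", "lfy"),
             intervention = c(as.numeric(ci), attr(ci, "total"),
                              fit$lfy[["intervention"]]),
             control = c(as.numeric(cc), attr(cc, "total"),
                         fit$lfy[["control"]]),
             stringsAsFactors = FALSE)
}

## 64-bit-ish FNV-1a over the serialized parameter means; changes iff any
## parameter (mean, family, dispersion or bound) changes.
.config_hash <- function(params) {
  bytes <- as.integer(serialize(list(params$table, params$cv_default), NULL,
                                version = 2))
  h1 <- 17; h2 <- 59
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 16777213   # two independent 24-bit rolling hashes
    h2 <- (h2 * 37 + b) %% 16777199
  }
  sprintf("%06x%06x", as.integer(h1), as.integer(h2))
}

.manifest <- function(params, seed = NA, perspective = NA, outputs = character()) {
  list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("lonelycea")),
       config_hash = .config_hash(params),
       seed = seed,
       perspective = perspective,
       outputs = as.list(outputs))
}

#' Export a deterministic model run
#'
#' Writes the per-category cost table, one cohort-trace CSV per arm
#' (columns cycle, state, occupancy, discounted_lfy_increment) and a JSON
#' run manifest (timestamp, package version, parameter-configuration hash,
#' perspective, output paths).
#'
#' @param fit a `lonely_cea` object
#' @param dir output directory (created if missing)
#' @return invisibly, the manifest path
#' @export
export_cea <- function(fit, dir) {
  stopifnot(inherits(fit, "lonely_cea"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(costs = file.path(dir, "costs.csv"),
             intervention = file.path(dir, "trace_intervention.csv"),
             control = file.path(dir, "trace_control.csv"))
  utils::write.csv(cea_table(fit), paths[["costs"]], row.names = FALSE)
  for (arm in c("intervention", "control"))
    utils::write.csv(as.data.frame(fit$traces[[arm]]), paths[[arm]],
                     row.names = FALSE)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(.manifest(fit$params, perspective = fit$perspective,
                                 outputs = unname(paths)),
                       mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mpath)
}

#' Export a probabilistic sensitivity analysis
#'
#' Writes the per-replication increments as CSV, the acceptability curve as
#' CSV, and a JSON summary (seed, replication count, clip and redraw
#' counts, quadrant shares, break-even willingness to pay) plus a run
#' manifest.
#'
#' @param psa an `lc_psa` object
#' @param params the `lc_params` the analysis was run under (for the
#'   manifest's configuration hash)
#' @param dir output directory (created if missing)
#' @return invisibly, the manifest path
#' @export
export_psa <- function(psa, params, dir) {
  stopifnot(inherits(psa, "lc_psa"), inherits(params, "lc_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(draws = file.path(dir, "psa_draws.csv"),
             ceac = file.path(dir, "ceac.csv"),
             summary = file.path(dir, "psa_summary.json"))
  utils::write.csv(psa$draws, paths[["draws"]], row.names = FALSE)
  utils::write.csv(psa$ceac, paths[["ceac"]], row.names = FALSE)
  jsonlite::write_json(list(seed = psa$seed, n = psa$n,
                            perspective = psa$perspective,
                            clipped = psa$clipped, redraws = psa$redraws,
                            quadrants = as.list(psa$quadrants),
                            break_even_wtp = psa$break_even),
                       paths[["summary"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(.manifest(params, seed = psa$seed,
                                 perspective = psa$perspective,
                                 outputs = unname(paths)),
                       mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mpath)
}
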