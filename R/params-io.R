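## Structured configuration IO.  A config is either a JSON/YAML document
##   schema_version: "1.0"
##   cv_default: 0.2            (optional)
##   parameters:
##     <id>: {mean:, family:, cv:, se:, low:, high:}   (family etc. optional)
## or a CSV table with columns (id, mean, family, cv, se, low, high) and a
## leading comment line "# schema_version: 1.0".  A config may list any
## subset of ids; missing entries keep their values from `base`.

.param_fields <- c("mean", "family", "cv", "se", "low", "high")

#' Read and write parameter configurations
#'
#' `write_params()` serialises a parameter set to JSON, YAML or CSV
#' (chosen from the file extension); `read_params()` loads one back. A file
#' holding the full set round-trips exactly; a file holding a subset of ids
#' acts as an override layer on top of `base`. Unknown ids or fields are
#' rejected by name, and the loaded set must pass [validate_params()].
#'
#' @param params an `lc_params` object
#' @param path file path ending in `.json`, `.yaml`/`.yml` or `.csv`
#' @param base parameter set the file's entries are merged into; defaults to
#'   the packaged baseline
#' @return `read_params`: an `lc_params` object
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "lc_params"))
  fmt <- .config_format(path)
  tab <- params$table
  if (fmt == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# schema_version: %s", params$schema_version), con)
    writeLines(sprintf("# cv_default: %s", format(params$cv_default, digits = 17)), con)
    out <- tab
    for (f in c("mean", "cv", "se", "low", "high"))   # full double precision
      out[[f]] <- ifelse(is.na(tab[[f]]), "", sprintf("%.17g", tab[[f]]))
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else {
    entries <- lapply(seq_len(nrow(tab)), function(k) {
      e <- list(mean = tab$mean[k], family = tab$family[k])
      for (f in c("cv", "se", "low", "high"))
        if (!is.na(tab[[f]][k])) e[[f]] <- tab[[f]][k]
      e
    })
    names(entries) <- tab$id
    doc <- list(schema_version = params$schema_version,
                cv_default = params$cv_default,
                parameters = entries)
    if (fmt == "json") {
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, na = "null")
    } else {
      yaml::write_yaml(doc, path, precision = 17)
    }
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, base = loneliness_params()) {
  stopifnot(inherits(base, "lc_params"))
  fmt <- .config_format(path)
  if (fmt == "csv") {
    head <- readLines(path, n = 10L)
    vline <- grep("^#\\s*schema_version:", head, value = TRUE)
    if (!length(vline)) stop("config is missing the schema_version header")
    version <- trimws(sub("^#\\s*schema_version:", "", vline[1]))
    cvline <- grep("^#\\s*cv_default:", head, value = TRUE)
    cv_default <- if (length(cvline))
      as.numeric(trimws(sub("^#\\s*cv_default:", "", cvline[1]))) else base$cv_default
    raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
    extra <- setdiff(names(raw), c("id", .param_fields))
    if (length(extra)) stop("unknown column in parameter CSV: ",
                            paste(extra, collapse = ", "))
    if (!"id" %in% names(raw) || !"mean" %in% names(raw))
      stop("parameter CSV needs at least columns 'id' and 'mean'")
    entries <- lapply(seq_len(nrow(raw)), function(k) {
      e <- as.list(raw[k, setdiff(names(raw), "id"), drop = FALSE])
      e[!vapply(e, function(v) is.na(v) || identical(v, ""), TRUE)]
    })
    names(entries) <- raw$id
  } else {
    doc <- if (fmt == "json") jsonlite::read_json(path, simplifyVector = FALSE)
           else yaml::read_yaml(path)
    extra <- setdiff(names(doc), c("schema_version", "cv_default", "parameters"))
    if (length(extra)) stop("unknown top-level key in config: ",
                            paste(extra, collapse = ", "))
    if (is.null(doc$schema_version)) stop("config is missing schema_version")
    version <- as.character(doc$schema_version)
    cv_default <- if (!is.null(doc$cv_default)) as.numeric(doc$cv_default)
                  else base$cv_default
    entries <- doc$parameters
    if (is.null(entries)) stop("config is missing the 'parameters' block")
  }
  if (version != PARAM_SCHEMA_VERSION)
    stop(sprintf("unsupported schema_version '%s' (expected '%s')",
                 version, PARAM_SCHEMA_VERSION))

  p <- base
  p$cv_default <- cv_default
  unknown <- setdiff(names(entries), p$table$id)
  if (length(unknown))
    stop("unknown parameter key in config: ", paste(unknown, collapse = ", "))
  for (id in names(entries)) {
    e <- entries[[id]]
    if (!is.list(e)) e <- list(mean = e)
    extra <- setdiff(names(e), .param_fields)
    if (length(extra))
      stop(sprintf("unknown field '%s' for parameter '%s'", extra[1], id))
    k <- match(id, p$table$id)
    for (f in names(e)) {
      v <- e[[f]]
      p$table[[f]][k] <- if (f == "family") as.character(v)
                         else if (is.null(v)) NA_real_ else as.numeric(v)
    }
  }
  assert_valid_params(p)
  p
}

.config_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         json = "json", yaml = "yaml", yml = "yaml", csv = "csv",
         stop("unsupported config extension: .", ext,
              " (use .json, .yaml, .yml or .csv)"))
}
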