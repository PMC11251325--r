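#' Read a scenario table
#'
#' Reads a CSV of design scenarios, one row per scenario, with columns
#' `ve`, `coverage`, and either `lambda_i`, `lambda_n`, `tau` or `pi`
#' (mutually exclusive per row); optional columns `id`, `theta0`, `alpha`,
#' `power` (defaults 1, 0.025, 0.8). Every row is validated through
#' [tnd_design()]; errors name the offending row.
#'
#' @param path Path to the CSV file.
#' @return A named list of `tnd_design` objects (names are scenario ids,
#'   defaulting to the row number).
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ve", "coverage")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_invalid("scenario file is missing column(s): ",
                 paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(structure(list(), class = "tnd_scenarios"))
  ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(nrow(df)))
  if (anyDuplicated(ids)) stop_invalid("scenario ids must be unique")
  get <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]][row]
    if (is.na(v)) NULL else v
  }
  out <- lapply(seq_len(nrow(df)), function(r) {
    tryCatch(
      tnd_design(
        ve = df$ve[r], coverage = df$coverage[r],
        lambda_i = get(r, "lambda_i"), lambda_n = get(r, "lambda_n"),
        tau = get(r, "tau"), pi = get(r, "pi"),
        theta0 = if (is.null(get(r, "theta0"))) 1 else get(r, "theta0"),
        alpha = if (is.null(get(r, "alpha"))) 0.025 else get(r, "alpha"),
        power = if (is.null(get(r, "power"))) 0.8 else get(r, "power")),
      tnd_invalid_parameter = function(e) {
        stop_invalid("scenario '", ids[r], "' (row ", r, "): ",
                     conditionMessage(e))
      })
  })
  names(out) <- ids
  structure(out, class = "tnd_scenarios")
}

#' Write results with run metadata
#'
#' Writes a homogeneous list of result records to CSV or JSON. A metadata
#' block (seed, replicate count, package version and any other fields
#' passed in `meta`) accompanies the records: as `#`-prefixed comment
#' lines at the top of a CSV, or as a `meta` object in JSON. Numeric
#' fields are written at full precision so files round-trip.
#'
#' @param records A data.frame, or a list of records coercible to one.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param meta Named list of run metadata (e.g. `seed`, `reps`).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json"),
                          meta = list()) {
  format <- match.arg(format)
  if (!is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(records)) records <- data.frame()
  meta <- c(meta, list(package_version = as.character(utils::packageVersion("tnddesign"))))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
      writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
    utils::write.csv(format(records, digits = 17, trim = TRUE), con,
                     row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(meta = meta, records = records), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path to a CSV or JSON results file.
#' @return A list with `meta` (named list) and `records` (data.frame).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(list(meta = x$meta, records = as.data.frame(x$records)))
  }
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]+: ", "", kv)
  }
  body <- lines[!startsWith(lines, "# ")]
  records <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n")),
    error = function(e) data.frame())
  list(meta = meta, records = records)
}
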