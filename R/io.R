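#' Shasta reservoir February capacity fixture
#'
#' The 20 February monthly water-capacity proportions of the Shasta
#' reservoir (California, USA) for 1991-2010, the real-data application
#' dataset packaged with the library.
#'
#' @return numeric vector of length 20, first value 0.338936.
#' @examples
#' shasta_capacity()
#' @export
shasta_capacity <- function() {
  path <- system.file("extdata", "shasta_feb_1991_2010.csv",
                      package = "kumacens", mustWork = TRUE)
  read_sample(path)
}

#' Read a sample of unit-interval observations from CSV
#'
#' One observation per line; an optional single header line is skipped.
#' Parsing is locale-independent (dot decimal separator).  Values outside
#' (0, 1) raise an error naming the offending line.
#'
#' @param path CSV file path.
#' @param scheme optional [censoring_scheme()]; when supplied, the values
#'   are validated into a [pcs2_sample()].
#' @return numeric vector, or a `pcs2_sample` when `scheme` is given.
#' @export
read_sample <- function(path, scheme = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sample file: ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(lines[1]))
  header <- is.na(first)
  body <- if (header) lines[-1] else lines
  if (!length(body)) stop("no data rows in: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(body))
  lineno <- seq_along(body) + as.integer(header)
  bad <- which(is.na(vals) | vals <= 0 | vals >= 1)
  if (length(bad))
    stop(sprintf("value '%s' on line %d of %s is not in (0, 1)",
                 body[bad[1]], lineno[bad[1]], path), call. = FALSE)
  if (is.null(scheme)) vals else pcs2_sample(vals, scheme)
}

#' Read a censoring scheme from JSON or YAML
#'
#' The file must provide keys `n`, `m` and `removals`; `removals` may be a
#' vector or the run-length shorthand string (e.g. `"20,0*19"`).  The format
#' is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return a [censoring_scheme()].
#' @export
read_scheme <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported scheme file extension: .", ext, call. = FALSE))
  # YAML 1.1 reads a bare 'n' key as boolean FALSE; map it back
  if (is.null(raw$n) && !is.null(raw[["FALSE"]])) raw$n <- raw[["FALSE"]]
  for (k in c("n", "m", "removals"))
    if (is.null(raw[[k]])) stop("scheme file missing key '", k, "'",
                                call. = FALSE)
  censoring_scheme(raw$n, raw$m, raw$removals)
}

#' Write analysis results to JSON or CSV
#'
#' JSON output wraps the payload with provenance (seed, package version,
#' timestamp); numeric values round-trip at full double precision.  CSV
#' expects a data.frame.
#'
#' @param results a list or data.frame of results.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @param seed optional seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         seed = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(results = results,
                    seed = seed,
                    package = "kumacens",
                    version = as.character(packageVersion("kumacens")))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    if (!is.data.frame(results))
      stop("CSV output requires a data.frame", call. = FALSE)
    write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path file written by [write_report()].
#' @return the parsed list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}
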