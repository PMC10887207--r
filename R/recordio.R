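#' Write a pulse recording as annotated CSV
#'
#' On-disk format: `#key=value` comment header lines carrying all metadata
#' (format tag, version, `fs`, `distance`, `start_time`, channel names,
#' declared sample count `n`, optional single-line JSON `provenance`),
#' followed by a `time,prox,dist` header row and one data row per sample.
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every sample to <= 1e-12 relative error. All units are SI
#' (seconds, Hz, meters). The time column is stored explicitly so grid
#' uniformity can be verified on read.
#'
#' @param path Output file path.
#' @param rec A [pulse_recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(path, rec) {
  stopifnot(inherits(rec, "pwv_recording"))
  n <- length(rec$prox$samples)
  header <- c(
    "#format=pwvrecon-recording",
    "#version=1",
    sprintf("#fs=%.17g", rec$prox$fs),
    sprintf("#distance=%.17g", rec$distance),
    sprintf("#start_time=%.17g", rec$prox$start_time),
    "#channels=prox,dist",
    sprintf("#n=%d", n)
  )
  prov_json <- tryCatch(
    as.character(jsonlite::toJSON(unclass_deep(rec$provenance), auto_unbox = TRUE, digits = NA)),
    error = function(e) NULL
  )
  if (!is.null(prov_json) && !identical(prov_json, "[]")) {
    header <- c(header, paste0("#provenance=", prov_json))
  }
  times <- ts_times(rec$prox)
  rows <- sprintf("%.17g,%.17g,%.17g", times, rec$prox$samples, rec$dist$samples)
  con <- tryCatch(file(path, "w"), error = function(e) {
    pwv_abort("io_error", sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, "time,prox,dist", rows), con)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}

#' Read a pulse recording from annotated CSV
#'
#' Parses the format written by [write_recording()], with validation: the
#' required header keys must be present, the data block must contain exactly
#' the `time,prox,dist` columns with finite values, the time grid must be
#' uniform, and the declared `fs` must agree with the time column to within
#' 1e-6 relative error.
#'
#' @param path Input file path.
#' @return A validated [pulse_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    pwv_abort("io_error", sprintf("file '%s' does not exist", path))
  }
  lines_head <- readLines(path, n = 64L)
  n_header <- 0L
  meta <- list()
  for (ln in lines_head) {
    if (!startsWith(ln, "#")) break
    n_header <- n_header + 1L
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
    }
  }
  for (key in c("fs", "distance")) {
    if (is.null(meta[[key]])) {
      pwv_abort("schema_error", sprintf("header is missing required key '%s'", key))
    }
  }
  fs <- as.numeric(meta$fs)
  distance <- as.numeric(meta$distance)
  start_time <- if (!is.null(meta$start_time)) as.numeric(meta$start_time) else 0
  if (!is.finite(fs) || fs <= 0) pwv_abort("schema_error", "header 'fs' is not a positive number")

  dat <- tryCatch(
    data.table::fread(path, skip = n_header, header = TRUE, data.table = FALSE),
    error = function(e) {
      pwv_abort("parse_error", sprintf("malformed data block in '%s': %s", path, conditionMessage(e)))
    }
  )
  if (!identical(names(dat), c("time", "prox", "dist"))) {
    pwv_abort(c("unsupported_channel_count", "parse_error"),
              sprintf("expected columns time,prox,dist; found: %s", paste(names(dat), collapse = ",")))
  }
  if (nrow(dat) < 2L) pwv_abort("parse_error", "recording must contain at least 2 samples")
  bad <- which(!stats::complete.cases(dat) | !is.finite(dat$time) | !is.finite(dat$prox) | !is.finite(dat$dist))
  if (length(bad)) {
    pwv_abort("parse_error",
              sprintf("non-finite value at data row %d (file line %d)",
                      bad[1L], bad[1L] + n_header + 1L))
  }
  dt <- diff(dat$time)
  step <- 1 / fs
  off <- which(abs(dt - step) > 1e-6 * step)
  if (length(off)) {
    pwv_abort(c("non_uniform_grid", "parse_error"),
              sprintf("non-uniform time grid at data row %d (file line %d): step %.9g, expected %.9g",
                      off[1L] + 1L, off[1L] + n_header + 2L, dt[off[1L]], step))
  }
  fs_implied <- 1 / mean(dt)
  if (abs(fs_implied - fs) > 1e-6 * fs) {
    pwv_abort("schema_error",
              sprintf("declared fs=%.9g disagrees with time column (implied %.9g)", fs, fs_implied))
  }
  if (!is.null(meta$n) && as.integer(meta$n) != nrow(dat)) {
    pwv_abort("schema_error",
              sprintf("declared n=%s but found %d data rows", meta$n, nrow(dat)))
  }
  provenance <- if (!is.null(meta$provenance)) {
    tryCatch(jsonlite::fromJSON(meta$provenance, simplifyVector = TRUE),
             error = function(e) list(raw = meta$provenance))
  } else list()
  pulse_recording(
    time_series(dat$prox, fs = fs, start_time = start_time),
    time_series(dat$dist, fs = fs, start_time = start_time),
    distance = distance,
    provenance = provenance
  )
}

#' Write an analysis report as JSON
#'
#' Serializes a `pwv_result` (or any list) to pretty-printed JSON with a
#' schema tag, suitable for downstream tooling.
#'
#' @param result A `pwv_result` or plain list.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_report <- function(result, path = NULL) {
  body <- if (inherits(result, "pwv_result")) unclass(result) else result
  doc <- c(list(schema = "pwvrecon-report/1"), body)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null", dataframe = "columns")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}
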