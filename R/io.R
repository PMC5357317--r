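# File formats. All three input tables are plain CSV with a header row and
# ISO 8601 timestamps carrying a UTC offset. Readers validate every row,
# collect row-numbered diagnostics, drop offending rows, and raise a single
# summary error if anything was rejected; write_*/read_* round-trip exactly
# at 6+ significant digits.

check_columns <- function(dt, required, path) {
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop(sprintf("format error in %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

read_validated <- function(path, required, validate_row) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = required[1]))
  if (nrow(dt) == 0) stop("empty input file: ", path, call. = FALSE)
  check_columns(dt, required, path)
  problems <- validate_row(dt)
  if (length(problems)) {
    keep <- !(seq_len(nrow(dt)) %in% vapply(problems, `[[`, 0L, "row"))
    msgs <- vapply(problems, function(p)
      sprintf("row %d: %s", p$row + 1L, p$msg), "")  # +1 for the header line
    stop(sprintf("%d invalid row(s) in %s:\n  %s", length(problems), path,
                 paste(utils::head(msgs, 10), collapse = "\n  ")),
         call. = FALSE)
  }
  dt
}

row_problems <- function(bad, msg) {
  lapply(which(bad), function(r) list(row = r, msg = msg))
}

#' Read pipeline input tables
#'
#' `read_gps()` expects columns `participant,timestamp,lat,lon`;
#' `read_ema()` expects `participant,timestamp,pa,na`; `read_traits()`
#' expects `participant,sias,dass_dep`. Timestamps must be ISO 8601 with a
#' UTC offset. Rows violating the domain invariants (coordinates outside
#' WGS84 bounds, affect outside 0-100, trait totals outside instrument
#' ranges, unparseable timestamps) abort with row-numbered diagnostics.
#' Output is sorted by participant then time.
#'
#' @param path CSV file path.
#' @return A `data.table`; timestamps are POSIXct (UTC).
#' @export
read_gps <- function(path) {
  dt <- read_validated(path, c("participant", "timestamp", "lat", "lon"),
    function(d) {
      t <- parse_iso8601(d$timestamp)
      c(row_problems(is.na(t), "unparseable timestamp"),
        row_problems(!is.na(d$lat) & (d$lat < -90 | d$lat > 90),
                     "lat outside [-90, 90]"),
        row_problems(!is.na(d$lon) & (d$lon < -180 | d$lon > 180),
                     "lon outside [-180, 180]"),
        row_problems(is.na(d$lat) | is.na(d$lon), "missing coordinate"))
    })
  dt[, time := parse_iso8601(timestamp)][, timestamp := NULL]
  setorder(dt, participant, time)
  dt[, .(participant, time, lat, lon)]
}

#' @rdname read_gps
#' @export
read_ema <- function(path) {
  dt <- read_validated(path, c("participant", "timestamp", "pa", "na"),
    function(d) {
      t <- parse_iso8601(d$timestamp)
      c(row_problems(is.na(t), "unparseable timestamp"),
        row_problems(!is.na(d$pa) & (d$pa < 0 | d$pa > 100),
                     "pa outside [0, 100]"),
        row_problems(!is.na(d$na) & (d$na < 0 | d$na > 100),
                     "na outside [0, 100]"),
        row_problems(is.na(d$pa) | is.na(d$na), "missing affect value"))
    })
  dt[, time := parse_iso8601(timestamp)][, timestamp := NULL]
  setorder(dt, participant, time)
  dt[, .(participant, time, pa, na)]
}

#' @rdname read_gps
#' @export
read_traits <- function(path) {
  dt <- read_validated(path, c("participant", "sias", "dass_dep"),
    function(d) {
      c(row_problems(!is.na(d$sias) & (d$sias < 0 | d$sias > 80),
                     "sias outside [0, 80]"),
        row_problems(!is.na(d$dass_dep) & (d$dass_dep < 0 | d$dass_dep > 21),
                     "dass_dep outside [0, 21]"),
        row_problems(is.na(d$sias) | is.na(d$dass_dep),
                     "missing trait score"))
    })
  setorder(dt, participant)
  dt[, .(participant, sias, dass_dep)]
}

num_fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' Write pipeline tables as CSV
#'
#' Inverse of the corresponding readers: numeric columns are printed with 10
#' significant digits and timestamps as ISO 8601 UTC, so write-then-read is
#' an identity on valid records.
#'
#' @param dt Table with the reader's columns (`time` as POSIXct).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gps <- function(dt, path) {
  out <- data.table(participant = dt$participant,
                    timestamp = format_iso8601(dt$time),
                    lat = num_fmt(dt$lat), lon = num_fmt(dt$lon))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_gps
#' @export
write_ema <- function(dt, path) {
  out <- data.table(participant = dt$participant,
                    timestamp = format_iso8601(dt$time),
                    pa = num_fmt(dt$pa), na = num_fmt(dt$na))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_gps
#' @export
write_traits <- function(dt, path) {
  out <- data.table(participant = dt$participant,
                    sias = num_fmt(dt$sias), dass_dep = num_fmt(dt$dass_dep))
  data.table::fwrite(out, path)
  invisible(path)
}

write_run_meta <- function(config, path) {
  meta <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("homestay")),
    r_version = as.character(getRversion()),
    created = format_iso8601(Sys.time())
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
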