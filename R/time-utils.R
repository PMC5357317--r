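# Time helpers. All timestamps are POSIXct; window logic (nighttime, workday,
# prompt windows) operates in the study's civil timezone, carried in `tz`.
# Intervals are half-open [start, end) throughout: an instant at 18:00:00
# belongs to the next window.

local_hour <- function(time, tz) {
  lt <- as.POSIXlt(time, tz = tz)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

local_date <- function(time, tz) {
  as.Date(format(time, tz = tz, format = "%Y-%m-%d"))
}

# POSIXct instant for local `date` at fractional `hour` in `tz`
local_time <- function(date, hour, tz) {
  h <- floor(hour)
  m <- floor((hour - h) * 60)
  s <- round(((hour - h) * 60 - m) * 60)
  as.POSIXct(sprintf("%s %02d:%02d:%02d", format(date), h, m, s), tz = tz)
}

# Overlap in seconds between [a1,a2) and [b1,b2)
interval_overlap_s <- function(a1, a2, b1, b2) {
  pmax(0, as.numeric(pmin(a2, b2)) - as.numeric(pmax(a1, b1)))
}

format_iso8601 <- function(time) {
  format(time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S+0000")
}

parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S%z")
  # fall back for offsets written with a colon (+00:00)
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    fixed <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x[miss])
    out[miss] <- as.POSIXct(fixed, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S%z")
  }
  out
}
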