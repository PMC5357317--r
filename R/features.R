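# Analysis windows and homestay/affect variables.
#
# Two window kinds mirror the four temporal framings of the analysis:
#   prompt_pair - consecutive same-day prompts at most 4 h apart; affect
#                 enters as a change score (end minus start), homestay over
#                 the window itself (framing "change_4h").
#   daily       - the workday window 10:00 AM-6:00 PM; affect enters as the
#                 day's mean over answered prompts, aligned to the same
#                 (lag 0), following (lag +1) or previous (lag -1) day's
#                 homestay window.
# The continuous outcome is the window home fraction divided by the
# participant's study-wide average workday home fraction (self-normalising
# within person), log-transformed with a small epsilon because the ratio can
# be exactly 0; the binary outcome is "spent any time at home in the window".

# seconds of overlap between timeline segments in `states` and [s, e).
# Base-vector arithmetic: this sits in the inner loop over analysis windows.
timeline_time <- function(timeline, s, e, states, home_cluster = NULL) {
  sel <- timeline$state %in% states
  if (!is.null(home_cluster)) {
    sel <- sel & !is.na(timeline$cluster) & timeline$cluster %in% home_cluster
  }
  if (!any(sel)) return(0)
  sum(pmax(0, pmin(timeline$end[sel], e) - pmax(timeline$start[sel], s)))
}

#' Homestay measures for one time window
#'
#' @param timeline Imputed timeline for one participant (`start`, `end`
#'   numeric epoch, `state`, `cluster`).
#' @param home_cluster Home cluster id from [infer_home()].
#' @param start,end Window bounds (POSIXct or epoch seconds).
#' @param personal_avg The participant's study-wide average workday home
#'   fraction (must be > 0).
#' @param config A [hs_config()] object (`log_eps`).
#' @return A one-row `data.table` (`frac`, `ratio`, `log_ratio`, `any_home`)
#'   or `NULL` if the window contains no observed (non-gap) time.
#' @export
homestay_for_window <- function(timeline, home_cluster, start, end,
                                personal_avg, config = hs_config()) {
  stopifnot(personal_avg > 0)
  s <- as.numeric(start); e <- as.numeric(end)
  denom <- timeline_time(timeline, s, e, c("stay", "away"))
  if (denom <= 0) return(NULL)
  home_s <- timeline_time(timeline, s, e, "stay", home_cluster)
  frac <- home_s / denom
  ratio <- frac / personal_avg
  data.table(frac = frac, ratio = ratio,
             log_ratio = log(ratio + config$log_eps),
             any_home = as.integer(frac > 0))
}

#' Study-wide average workday home fraction for one participant
#'
#' Mean over study days of the 10:00 AM-6:00 PM home fraction; days with no
#' observed workday time are skipped.
#'
#' @inheritParams homestay_for_window
#' @param config A [hs_config()] object (`day_start`, `day_end`, `tz`).
#' @return Fraction in \[0, 1\], or `NA` if no day has usable data.
#' @export
personal_average <- function(timeline, home_cluster, config = hs_config()) {
  if (!nrow(timeline)) return(NA_real_)
  tz <- config$tz
  d0 <- local_date(as.POSIXct(min(timeline$start), origin = "1970-01-01", tz = "UTC"), tz)
  d1 <- local_date(as.POSIXct(max(timeline$end), origin = "1970-01-01", tz = "UTC"), tz)
  days <- seq(d0, d1, by = "day")
  s_all <- as.numeric(local_time(days, config$day_start, tz))
  e_all <- as.numeric(local_time(days, config$day_end, tz))
  fr <- numeric(0)
  for (k in seq_along(days)) {
    denom <- timeline_time(timeline, s_all[k], e_all[k], c("stay", "away"))
    if (denom > 0) {
      fr <- c(fr, timeline_time(timeline, s_all[k], e_all[k], "stay",
                                home_cluster) / denom)
    }
  }
  if (!length(fr)) return(NA_real_)
  mean(fr)
}

#' Build prompt-pair windows with affect change scores
#'
#' Each pair of consecutive same-day prompts at most `max_window_s` apart
#' (default 4 h, the scheduler's maximum spacing of adjacent random prompts)
#' yields one window; affect enters as end-minus-start change. Pairs farther
#' apart are unanalysable and counted in attribute `discarded`.
#'
#' @param ema EMA table (`participant`, `time`, `pa`, `na`), sorted.
#' @param config A [hs_config()] object.
#' @return `data.table` (`participant`, `kind` = "prompt_pair", `lag` = NA,
#'   `start`, `end`, `length_s`, `na_value`, `pa_value`); attribute
#'   `discarded` counts rejected pairs.
#' @export
build_prompt_windows <- function(ema, config = hs_config()) {
  e <- as.data.table(ema)
  e[, day := local_date(time, config$tz)]
  setorder(e, participant, time)
  e[, `:=`(t2 = shift(time, -1), pa2 = shift(pa, -1), na2 = shift(na, -1),
           day2 = shift(day, -1)), by = participant]
  pairs <- e[!is.na(t2) & day == day2]
  span <- as.numeric(pairs$t2) - as.numeric(pairs$time)
  keep <- span <= config$max_window_s & span > 0
  out <- pairs[keep, .(participant, kind = "prompt_pair", lag = NA_integer_,
                       start = as.numeric(time), end = as.numeric(t2),
                       length_s = as.numeric(t2) - as.numeric(time),
                       na_value = na2 - na, pa_value = pa2 - pa)]
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Build daily windows pairing mean affect with lagged homestay days
#'
#' Affect is the mean of a calendar day's answered prompts; each affect day
#' produces up to three rows aligning it with the same day's (lag 0), the
#' following day's (lag +1) and the previous day's (lag -1) workday homestay
#' window. Edge days produce only the feasible lags.
#'
#' @inheritParams build_prompt_windows
#' @return `data.table` with the same columns as [build_prompt_windows()],
#'   `kind` = "daily", `lag` in -1/0/+1.
#' @export
build_daily_windows <- function(ema, config = hs_config()) {
  e <- as.data.table(ema)
  e[, day := local_date(time, config$tz)]
  daily <- e[, .(na_value = mean(na), pa_value = mean(pa)), by = .(participant, day)]
  out <- list()
  for (id in unique(daily$participant)) {
    dd <- daily[participant == id]
    d_min <- min(dd$day); d_max <- max(dd$day)
    for (lg in c(0L, 1L, -1L)) {
      hd <- dd$day + lg
      ok <- hd >= d_min & hd <= d_max
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.table(
        participant = id, kind = "daily", lag = lg,
        start = as.numeric(local_time(hd[ok], config$day_start, config$tz)),
        end = as.numeric(local_time(hd[ok], config$day_end, config$tz)),
        length_s = (config$day_end - config$day_start) * 3600,
        na_value = dd$na_value[ok], pa_value = dd$pa_value[ok])
    }
  }
  rbindlist(out)
}

#' Assemble the full analysis feature table
#'
#' Joins windows ([build_prompt_windows()], [build_daily_windows()]) with
#' homestay measures computed from the imputed timelines. Participants whose
#' study-wide home fraction is zero or undefined are excluded with a warning;
#' windows with no observed time are dropped and counted.
#'
#' @param gps_pre A `homestay_gps` result from [preprocess_gps()], or any
#'   list with `timelines` (imputed, all participants) and `homes` tables
#'   (e.g. read back from the preprocess stage's CSV outputs).
#' @param ema EMA table.
#' @param config A [hs_config()] object.
#' @return `data.table`: `participant`, `kind`, `lag`, `start`, `end`,
#'   `length_s`, `frac`, `ratio`, `log_ratio`, `any_home`, `na_value`,
#'   `pa_value`. Attributes: `discarded_pairs`, `dropped_windows`,
#'   `excluded_participants`, `personal_avgs`.
#' @export
build_features <- function(gps_pre, ema, config = hs_config()) {
  wins <- rbind(build_prompt_windows(ema, config),
                build_daily_windows(ema, config))
  discarded <- attr(wins, "discarded")
  out <- list(); dropped <- 0L; excluded <- character()
  pavgs <- list()
  for (id in gps_pre$homes$participant) {
    tl <- gps_pre$timelines[participant == id]
    home_cl <- gps_pre$homes[participant == id]$cluster
    pa_avg <- personal_average(tl, home_cl, config)
    if (is.na(pa_avg) || pa_avg <= 0) {
      warning("participant ", id,
              " excluded: zero or undefined study-wide homestay")
      excluded <- c(excluded, id)
      next
    }
    pavgs[[id]] <- pa_avg
    pw <- wins[participant == id]
    if (!nrow(pw)) next
    hm <- vector("list", nrow(pw))
    for (k in seq_len(nrow(pw))) {
      hm[[k]] <- homestay_for_window(tl, home_cl, pw$start[k], pw$end[k],
                                     pa_avg, config)
    }
    ok <- !vapply(hm, is.null, NA)
    dropped <- dropped + sum(!ok)
    if (any(ok)) out[[id]] <- cbind(pw[ok], rbindlist(hm[ok]))
  }
  feats <- rbindlist(out)
  attr(feats, "discarded_pairs") <- discarded
  attr(feats, "dropped_windows") <- dropped
  attr(feats, "excluded_participants") <- excluded
  attr(feats, "personal_avgs") <- unlist(pavgs)
  feats
}

#' Write / read the feature table
#'
#' @param feats Feature table from [build_features()].
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_features <- function(feats, path) {
  out <- copy(feats)
  out[, `:=`(start = format_iso8601(as.POSIXct(start, origin = "1970-01-01", tz = "UTC")),
             end = format_iso8601(as.POSIXct(end, origin = "1970-01-01", tz = "UTC")))]
  for (cl in c("length_s", "frac", "ratio", "log_ratio", "na_value", "pa_value")) {
    out[[cl]] <- num_fmt(out[[cl]])
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "participant"))
  check_columns(dt, c("participant", "kind", "lag", "start", "end", "length_s",
                      "frac", "ratio", "log_ratio", "any_home",
                      "na_value", "pa_value"), path)
  dt[, `:=`(start = as.numeric(parse_iso8601(start)),
            end = as.numeric(parse_iso8601(end)))]
  dt
}
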