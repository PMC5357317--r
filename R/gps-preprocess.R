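# Stay-point detection and homestay substrate.
#
# Raw fixes are grouped by a sequential scan: a fix joins the current group
# while it lies within `spatial_m` of the group's running centroid (and the
# time gap to the previous fix does not exceed `merge_gap_s`). Groups
# spanning at least `min_dwell_s` become visits; shorter groups are travel
# and are dropped. Consecutive visits at the same locality separated by at
# most `merge_gap_s` merge into one visit (this is how the 30-minute temporal
# threshold and the 5-minute removal rule coexist: 5 min is the minimum dwell
# to count as a stay, 30 min the maximum gap when stitching a stay back
# together around a brief excursion or data dropout). Visits are then
# agglomerated across the study into stay clusters by centroid proximity.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a sphere of radius 6,371,000 m. Vectorised and
#' recycled like arithmetic.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @export
#' @examples
#' haversine_m(38, -78.5, 38.001, -78.5)  # ~111 m
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# sequential scan into spatially coherent runs; returns integer run id per fix
scan_runs <- function(t, lat, lon, spatial_m, max_gap_s) {
  n <- length(t)
  run <- integer(n)
  if (n == 0) return(run)
  run[1] <- 1L
  c_lat <- lat[1]; c_lon <- lon[1]; c_n <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- t[i] - t[i - 1]
    d <- haversine_m(lat[i], lon[i], c_lat, c_lon)
    if (gap <= max_gap_s && d <= spatial_m) {
      run[i] <- run[i - 1]
      c_n <- c_n + 1L
      c_lat <- c_lat + (lat[i] - c_lat) / c_n
      c_lon <- c_lon + (lon[i] - c_lon) / c_n
    } else {
      run[i] <- run[i - 1] + 1L
      c_lat <- lat[i]; c_lon <- lon[i]; c_n <- 1L
    }
  }
  run
}

#' Detect stay visits and clusters in one participant's fix stream
#'
#' @param fixes `data.table` of one participant's fixes (`participant`,
#'   `time`, `lat`, `lon`), sorted by time.
#' @param config A [hs_config()] object supplying `spatial_m` (30 m),
#'   `min_dwell_s` (300 s), `merge_gap_s` (1800 s) and `gap_threshold_s`.
#' @return A list of class `homestay_stays`:
#'   \item{clusters}{one row per stay cluster: `cluster`, `lat`, `lon`
#'     (dwell-weighted centroid), `total_dwell_s`, `n_visits`,
#'     `night_fixes`.}
#'   \item{visits}{one row per visit: `cluster`, `start`, `end`, `dwell_s`.}
#'   \item{timeline}{labelled segments tiling the observation span: `start`,
#'     `end`, `state` in stay/away/gap, `cluster` (NA unless stay).}
#'   \item{fix_cluster}{per input fix, the cluster id or NA (travel).}
#' An empty fix list yields empty components, not an error.
#' @export
detect_stays <- function(fixes, config = hs_config()) {
  empty <- function() {
    structure(list(
      clusters = data.table(cluster = integer(), lat = numeric(),
                            lon = numeric(), total_dwell_s = numeric(),
                            n_visits = integer(), night_fixes = integer()),
      visits = data.table(cluster = integer(), start = numeric(),
                          end = numeric(), dwell_s = numeric()),
      timeline = data.table(start = numeric(), end = numeric(),
                            state = character(), cluster = integer()),
      fix_cluster = integer(0), participant = NA_character_,
      fix_time = numeric(0)), class = "homestay_stays")
  }
  if (nrow(fixes) < 2) return(empty())
  stopifnot(length(unique(fixes$participant)) == 1L)
  t <- as.numeric(fixes$time)
  if (is.unsorted(t)) stop("fixes must be sorted by time")
  lat <- fixes$lat; lon <- fixes$lon
  run <- scan_runs(t, lat, lon, config$spatial_m, config$merge_gap_s)

  # candidate visits = runs with enough dwell
  rs <- data.table(run = run, t = t, lat = lat, lon = lon)
  cand <- rs[, .(start = t[1], end = t[.N], n = .N,
                 clat = mean(lat), clon = mean(lon)), by = run]
  cand <- cand[end - start >= config$min_dwell_s]
  if (nrow(cand) == 0) {
    out <- empty()
    out$participant <- fixes$participant[1]
    out$fix_cluster <- rep(NA_integer_, nrow(fixes))
    out$fix_time <- t
    out$timeline <- base_timeline(t, config$gap_threshold_s, NULL)
    return(out)
  }

  # merge consecutive visits at the same locality across short interruptions
  m <- 1L
  grp <- integer(nrow(cand)); grp[1] <- 1L
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      gap <- cand$start[i] - cand$end[i - 1]
      d <- haversine_m(cand$clat[i], cand$clon[i],
                       cand$clat[i - 1], cand$clon[i - 1])
      if (gap <= config$merge_gap_s && d <= config$spatial_m) {
        grp[i] <- grp[i - 1]
      } else {
        m <- m + 1L
        grp[i] <- m
      }
    }
  }
  cand[, grp := grp]
  visits <- cand[, .(start = start[1], end = end[.N],
                     clat = sum(clat * n) / sum(n),
                     clon = sum(clon * n) / sum(n),
                     n = sum(n), runs = list(run)), by = grp]
  visits[, dwell_s := end - start]

  # agglomerate visits into study-level clusters by centroid proximity
  nv <- nrow(visits)
  cl_id <- integer(nv)
  cl_lat <- numeric(0); cl_lon <- numeric(0); cl_w <- numeric(0)
  for (i in seq_len(nv)) {
    if (length(cl_lat)) {
      d <- haversine_m(visits$clat[i], visits$clon[i], cl_lat, cl_lon)
      j <- which.min(d)
    } else j <- NA_integer_
    if (!is.na(j) && d[j] <= config$spatial_m) {
      cl_id[i] <- j
      w <- visits$dwell_s[i]
      cl_lat[j] <- (cl_lat[j] * cl_w[j] + visits$clat[i] * w) / (cl_w[j] + w)
      cl_lon[j] <- (cl_lon[j] * cl_w[j] + visits$clon[i] * w) / (cl_w[j] + w)
      cl_w[j] <- cl_w[j] + w
    } else {
      cl_lat <- c(cl_lat, visits$clat[i])
      cl_lon <- c(cl_lon, visits$clon[i])
      cl_w <- c(cl_w, visits$dwell_s[i])
      cl_id[i] <- length(cl_lat)
    }
  }
  visits[, cluster := cl_id]

  fix_cluster <- rep(NA_integer_, length(t))
  for (i in seq_len(nv)) {
    fix_cluster[run %in% visits$runs[[i]]] <- visits$cluster[i]
  }

  clusters <- visits[, .(lat = sum(clat * dwell_s) / sum(dwell_s),
                         lon = sum(clon * dwell_s) / sum(dwell_s),
                         total_dwell_s = sum(dwell_s), n_visits = .N),
                     by = cluster][order(cluster)]

  vis_out <- visits[, .(cluster, start, end, dwell_s)][order(start)]
  timeline <- base_timeline(t, config$gap_threshold_s, vis_out)

  structure(list(clusters = clusters, visits = vis_out, timeline = timeline,
                 fix_cluster = fix_cluster,
                 participant = fixes$participant[1], fix_time = t),
            class = "homestay_stays")
}

# Tile the observation span [first fix, last fix] with stay / away / gap
# segments. Gap = a silent stretch between consecutive fixes longer than
# gap_threshold_s that is not inside a visit (silences inside a visit are
# absorbed by the stay itself). Everything else outside visits is away
# (observed travel or sub-dwell stops).
base_timeline <- function(t, gap_threshold_s, visits) {
  span <- c(t[1], t[length(t)])
  dt_gap <- which(diff(t) > gap_threshold_s)
  gaps <- if (length(dt_gap)) cbind(t[dt_gap], t[dt_gap + 1]) else
    matrix(numeric(0), ncol = 2)
  vmat <- if (!is.null(visits) && nrow(visits)) {
    cbind(visits$start, visits$end)
  } else matrix(numeric(0), ncol = 2)
  bp <- sort(unique(c(span, vmat, gaps)))
  bp <- bp[bp >= span[1] & bp <= span[2]]
  if (length(bp) < 2) {
    return(data.table(start = numeric(), end = numeric(),
                      state = character(), cluster = integer()))
  }
  s <- bp[-length(bp)]; e <- bp[-1]
  mid <- (s + e) / 2
  state <- rep("away", length(mid))
  cluster <- rep(NA_integer_, length(mid))
  if (nrow(gaps)) {
    in_gap <- vapply(mid, function(x) any(x > gaps[, 1] & x < gaps[, 2]), NA)
    state[in_gap] <- "gap"
  }
  if (nrow(vmat)) {
    for (k in seq_len(nrow(vmat))) {
      inside <- mid > vmat[k, 1] & mid < vmat[k, 2]
      state[inside] <- "stay"
      cluster[inside] <- visits$cluster[k]
    }
  }
  tl <- data.table(start = s, end = e, state = state, cluster = cluster)
  merge_segments(tl[end > start])
}

merge_segments <- function(tl) {
  if (nrow(tl) < 2) return(tl)
  key <- paste(tl$state, tl$cluster)
  new_seg <- c(TRUE, key[-1] != key[-nrow(tl)] |
                 tl$start[-1] != tl$end[-nrow(tl)])
  grp <- cumsum(new_seg)
  tl[, .(start = start[1], end = end[.N],
         state = state[1], cluster = cluster[1]), by = grp][, grp := NULL][]
}

#' Infer the home cluster from nighttime occupancy
#'
#' Home is the stay cluster containing the largest number of fixes whose
#' local time falls in the nighttime window (default 12:00 AM-6:00 AM),
#' counted across all study days. Ties break deterministically: larger total
#' dwell, then smaller cluster id.
#'
#' @param stays A `homestay_stays` result.
#' @param config A [hs_config()] object (`night_start`, `night_end`, `tz`).
#' @return A list (`participant`, `cluster`, `lat`, `lon`,
#'   `night_fix_count`).
#' @export
infer_home <- function(stays, config = hs_config()) {
  ft <- as.POSIXct(stays$fix_time, origin = "1970-01-01", tz = "UTC")
  hr <- local_hour(ft, config$tz)
  night <- hr >= config$night_start & hr < config$night_end
  cl <- stays$fix_cluster
  ok <- night & !is.na(cl)
  if (!any(ok)) {
    stop(sprintf("home undetermined for participant %s: no nighttime fixes in any stay cluster",
                 stays$participant), call. = FALSE)
  }
  counts <- table(cl[ok])
  cand <- data.table(cluster = as.integer(names(counts)),
                     n_night = as.integer(counts))
  cand <- merge(cand, stays$clusters, by = "cluster")
  setorder(cand, -n_night, -total_dwell_s, cluster)
  list(participant = stays$participant,
       cluster = cand$cluster[1],
       lat = cand$lat[1], lon = cand$lon[1],
       night_fix_count = cand$n_night[1])
}

#' Impute timeline gaps by last observation carried forward
#'
#' Every gap segment inherits the label of the segment immediately before it;
#' a leading gap (nothing observed yet) stays a gap and is excluded from all
#' homestay denominators downstream. Idempotent.
#'
#' @param timeline Timeline `data.table` (`start`, `end`, `state`,
#'   `cluster`).
#' @return Imputed timeline, adjacent same-label segments merged; the number
#'   of imputed seconds is attached as attribute `imputed_s`.
#' @export
locf_impute <- function(timeline) {
  tl <- copy(timeline)
  imputed <- 0
  if (nrow(tl) > 1) {
    for (i in 2:nrow(tl)) {
      if (tl$state[i] == "gap" && tl$state[i - 1] != "gap") {
        imputed <- imputed + (tl$end[i] - tl$start[i])
        tl[i, `:=`(state = tl$state[i - 1], cluster = tl$cluster[i - 1])]
      }
    }
  }
  out <- merge_segments(tl)
  prev <- attr(timeline, "imputed_s")
  attr(out, "imputed_s") <- imputed + if (is.null(prev)) 0 else prev
  out
}

#' GPS completeness over a time window
#'
#' Observed fixes in `[start, end)` divided by the number possible at the
#' sampling interval, capped at 1. With the 150-second interval the
#' 10:00 AM-6:00 PM workday window has 192 possible fixes.
#'
#' @param fix_times POSIXct (or numeric epoch) fix times.
#' @param start,end Window bounds (POSIXct or numeric).
#' @param gps_interval Sampling interval in seconds.
#' @return Fraction in \[0, 1\].
#' @export
completeness <- function(fix_times, start, end, gps_interval = 150) {
  t <- as.numeric(fix_times)
  s <- as.numeric(start); e <- as.numeric(end)
  stopifnot(e > s)
  possible <- (e - s) / gps_interval
  min(1, sum(t >= s & t < e) / possible)
}

#' Preprocess a multi-participant GPS table
#'
#' Runs [detect_stays()], [infer_home()] and [locf_impute()] per participant
#' and audits workday completeness per day.
#'
#' @param gps GPS table as returned by [read_gps()] or [simulate_cohort()].
#' @param config A [hs_config()] object.
#' @return List of class `homestay_gps`: `stays` (named per-participant
#'   `homestay_stays`), `homes` (table), `timelines` (imputed, per
#'   participant), `completeness` (participant x day workday fraction).
#' @export
preprocess_gps <- function(gps, config = hs_config()) {
  ids <- unique(gps$participant)
  stays_l <- list(); homes_l <- list(); tl_l <- list(); comp_l <- list()
  for (id in ids) {
    fx <- gps[participant == id]
    st <- detect_stays(fx, config)
    if (!nrow(st$clusters)) {
      warning("no stay clusters for participant ", id, "; skipped")
      next
    }
    home <- infer_home(st, config)
    tl <- locf_impute(st$timeline)
    stays_l[[id]] <- st
    homes_l[[id]] <- as.data.table(home)
    tl_l[[id]] <- cbind(data.table(participant = id), tl)
    days <- unique(local_date(fx$time, config$tz))
    comp_l[[id]] <- data.table(
      participant = id, date = days,
      completeness = vapply(days, function(d) {
        completeness(fx$time,
                     local_time(d, config$day_start, config$tz),
                     local_time(d, config$day_end, config$tz),
                     config$gps_interval)
      }, 0))
  }
  structure(list(stays = stays_l, homes = rbindlist(homes_l),
                 timelines = rbindlist(tl_l),
                 completeness = rbindlist(comp_l), config = config),
            class = "homestay_gps")
}
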