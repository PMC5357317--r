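#' @import data.table
#' @importFrom stats rnorm runif rgeom qnorm pnorm plogis optim rbinom sd var
#'   coef setNames complete.cases aggregate dbinom pbinom binomial as.formula
#'   qlogis
NULL

# Per-participant, per-purpose RNG substreams: a single global seed drives
# deterministic sub-seeds so participant i's data are identical whatever the
# cohort size (cohorts are extensible without reshuffling). Streams:
# 1 = traits, 2 = other latents (home, propensities), 3 = schedule,
# 4 = gps, 5 = ema. All sub-seeds stay below 2^31.
participant_seed <- function(seed, i, stream) {
  as.integer((as.numeric(seed) + i * 100003 + stream * 523) %% 2147483647)
}

# ---------------------------------------------------------------------------
# Traits: truncated-normal scores with *sample* moments matching the target.
# Truncating a N(mu, sigma) to the instrument range shifts its moments (for a
# DASS-depression mean of 3.3 with SD 2.4 the floor at 0 is only 1.4 SD away,
# which would inflate the mean by ~0.4 points), so the parent parameters are
# solved such that the truncated distribution itself has the configured
# mean and SD.

trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

trunc_norm_params <- function(target_mean, target_sd, lo, hi) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(par) {
    mo <- trunc_norm_moments(par[1], exp(par[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# inverse-CDF draw from N(mu, sigma) truncated to [lo, hi]
rtrunc_norm <- function(n, mu, sigma, lo, hi) {
  if (sigma == 0) return(rep(mu, n))
  u <- runif(n, pnorm(lo, mu, sigma), pnorm(hi, mu, sigma))
  pmin(pmax(qnorm(u, mu, sigma), lo), hi)
}

#' Generate baseline trait scores for a synthetic cohort
#'
#' Draws one SIAS (0-80) and one DASS-21 depression (0-21) total per
#' participant from truncated normal distributions whose post-truncation mean
#' and SD equal the configured targets (`sias_mean`/`sias_sd`,
#' `dass_mean`/`dass_sd`). Draws use per-participant RNG substreams keyed on
#' `config$seed`, so a participant's scores do not depend on cohort size.
#'
#' @param config A [hs_config()] object.
#' @return `data.table` with columns `participant`, `sias`, `dass_dep`.
#' @export
#' @examples
#' tr <- generate_traits(hs_config(n_participants = 5, seed = 1))
#' stopifnot(all(tr$sias >= 0 & tr$sias <= 80))
generate_traits <- function(config) {
  validate_config(config)
  ps <- trunc_norm_params(config$sias_mean, config$sias_sd, 0, 80)
  pd <- trunc_norm_params(config$dass_mean, config$dass_sd, 0, 21)
  n <- config$n_participants
  sias <- numeric(n); dass <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(participant_seed(config$seed, i, 1L))
    sias[i] <- rtrunc_norm(1, ps["mu"], ps["sigma"], 0, 80)
    dass[i] <- rtrunc_norm(1, pd["mu"], pd["sigma"], 0, 21)
  }
  data.table(participant = sprintf("P%03d", seq_len(n)),
             sias = sias, dass_dep = dass)
}

# ---------------------------------------------------------------------------
# Latent participants: home and away anchor places plus affect latents.
# Homes are scattered over a ~4 km campus neighbourhood; away places sit
# 300-2000 m from home, far beyond 2x the 30 m spatial threshold, so home
# inference has an unambiguous ground truth.

CAMPUS <- c(lat = 38.035, lon = -78.505)
M_PER_DEG_LAT <- 111320

offset_latlon <- function(lat, lon, north_m, east_m) {
  lat <- unname(lat); lon <- unname(lon)
  c(lat = lat + north_m / M_PER_DEG_LAT,
    lon = lon + east_m / (M_PER_DEG_LAT * cos(lat * pi / 180)))
}

simulate_latent_participant <- function(i, config) {
  traits <- generate_traits_one(i, config)
  set.seed(participant_seed(config$seed, i, 2L))
  home <- offset_latlon(CAMPUS["lat"], CAMPUS["lon"],
                        runif(1, -2000, 2000), runif(1, -2000, 2000))
  n_away <- 3L
  away <- lapply(seq_len(n_away), function(k) {
    d <- runif(1, 300, 2000)
    th <- runif(1, 0, 2 * pi)
    offset_latlon(home["lat"], home["lon"], d * cos(th), d * sin(th))
  })
  z_sias <- if (config$sias_sd > 0)
    (traits$sias - config$sias_mean) / config$sias_sd else 0
  b_logit <- rnorm(1, config$propensity_logit_mean +
                     config$propensity_sias_slope * z_sias,
                   config$propensity_sd_between)
  day_logits <- rnorm(config$n_days, b_logit, config$propensity_sd_within)
  list(
    id = sprintf("P%03d", i),
    home = home,
    away_places = away,
    sias_true = traits$sias,
    dass_true = traits$dass_dep,
    baseline_na = config$baseline_na,
    baseline_pa = config$baseline_pa,
    random_intercept_na = rnorm(1, 0, config$intercept_sd_na),
    random_intercept_pa = rnorm(1, 0, config$intercept_sd_pa),
    propensity_logit = b_logit,
    day_propensity = plogis(day_logits)
  )
}

# trait pair for one participant, same substream as generate_traits()
generate_traits_one <- function(i, config) {
  ps <- trunc_norm_params(config$sias_mean, config$sias_sd, 0, 80)
  pd <- trunc_norm_params(config$dass_mean, config$dass_sd, 0, 21)
  set.seed(participant_seed(config$seed, i, 1L))
  list(sias = rtrunc_norm(1, ps["mu"], ps["sigma"], 0, 80),
       dass_dep = rtrunc_norm(1, pd["mu"], pd["sigma"], 0, 21))
}

# ---------------------------------------------------------------------------
# Daily schedule: piecewise-constant place occupancy. Nighttime (00:00-06:00)
# is forced at home (unless relaxed), the rest of the day is tiled with
# fixed-length blocks that are independently at home with the day's latent
# propensity; contiguous same-state blocks merge into one episode and each
# away run picks one anchor place. Episode-based mobility keeps ground-truth
# homestay exact: the expected home fraction of any daytime window equals the
# propensity.

#' Simulate one day's place-occupancy episodes
#'
#' @param participant A latent participant as built by the cohort simulator
#'   (list with `id`, `home`, `away_places`).
#' @param date A `Date`, the local calendar day.
#' @param propensity Probability in \[0,1\] that any daytime block is spent at
#'   home; the affect generator reads the same latent value.
#' @param config A [hs_config()] object.
#' @return `data.table` of episodes (`participant`, `start`, `end`, `lat`,
#'   `lon`, `at_home`) tiling local 00:00-24:00, alternating home/away.
#' @export
generate_day_schedule <- function(participant, date, propensity, config) {
  stopifnot(propensity >= 0, propensity <= 1)
  tz <- config$tz
  day0 <- local_time(date, 0, tz)
  day_end <- day0 + 86400
  blk <- config$home_block_minutes * 60
  night_end_t <- if (config$force_night_home) day0 + config$night_end * 3600 else day0
  starts <- seq(from = as.numeric(night_end_t), to = as.numeric(day_end) - 1, by = blk)
  ends <- pmin(starts + blk, as.numeric(day_end))
  at_home <- runif(length(starts)) < propensity
  if (config$force_night_home) {
    starts <- c(as.numeric(day0), starts)
    ends <- c(as.numeric(night_end_t), ends)
    at_home <- c(TRUE, at_home)
  }
  # merge contiguous same-state blocks into alternating episodes
  r <- rle(at_home)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  ep_start <- starts[idx_start]
  ep_end <- ends[idx_end]
  ep_home <- r$values
  lat <- lon <- numeric(length(ep_home))
  for (k in seq_along(ep_home)) {
    if (ep_home[k]) {
      lat[k] <- participant$home["lat"]; lon[k] <- participant$home["lon"]
    } else {
      p <- participant$away_places[[sample.int(length(participant$away_places), 1)]]
      lat[k] <- p["lat"]; lon[k] <- p["lon"]
    }
  }
  data.table(
    participant = participant$id,
    start = as.POSIXct(ep_start, origin = "1970-01-01", tz = tz),
    end = as.POSIXct(ep_end, origin = "1970-01-01", tz = tz),
    lat = lat, lon = lon, at_home = ep_home
  )
}

# ---------------------------------------------------------------------------
# GPS: fixes every gps_interval seconds at the occupied place plus isotropic
# Gaussian jitter. Missingness is generated as gap *runs* (a two-state Markov
# chain with geometric run lengths), not independent drops, because LOCF
# imputation behaves differently on contiguous gaps.

#' Simulate GPS fixes for a set of episodes
#'
#' @param episodes Episode table from [generate_day_schedule()] (one or more
#'   days, one participant).
#' @param config A [hs_config()] object.
#' @return `data.table` (`participant`, `time`, `lat`, `lon`) of retained
#'   fixes, sorted by time.
#' @export
generate_gps <- function(episodes, config) {
  stopifnot(nrow(episodes) > 0)
  span0 <- as.numeric(min(episodes$start))
  span1 <- as.numeric(max(episodes$end))
  n_fix <- ceiling((span1 - span0) / config$gps_interval - 1e-9)
  times <- span0 + config$gps_interval * (seq_len(n_fix) - 1)
  ep_idx <- findInterval(times, as.numeric(episodes$start))
  lat0 <- episodes$lat[ep_idx]
  lon0 <- episodes$lon[ep_idx]
  n <- length(times)
  jn <- rnorm(n, 0, config$gps_noise_sd)
  je <- rnorm(n, 0, config$gps_noise_sd)
  lat <- lat0 + jn / M_PER_DEG_LAT
  lon <- lon0 + je / (M_PER_DEG_LAT * cos(lat0 * pi / 180))
  keep <- !missing_run_mask(n, config$missing_rate, config$gap_run_fixes)
  data.table(
    participant = episodes$participant[1],
    time = as.POSIXct(times[keep], origin = "1970-01-01", tz = config$tz),
    lat = lat[keep], lon = lon[keep]
  )
}

# TRUE = fix lost. Stationary missing fraction = rate; missing runs are
# geometric with mean run_len fixes.
missing_run_mask <- function(n, rate, run_len) {
  if (rate <= 0) return(logical(n))
  if (rate >= 1) return(rep(TRUE, n))
  p_enter <- min(1, rate / ((1 - rate) * run_len))
  p_exit <- 1 / run_len
  mask <- logical(n)
  state <- runif(1) < rate
  i <- 1L
  while (i <= n) {
    len <- if (state) rgeom(1, p_exit) + 1L else rgeom(1, p_enter) + 1L
    len <- min(len, n - i + 1L)
    mask[i:(i + len - 1L)] <- state
    i <- i + len
    state <- !state
  }
  mask
}

# ---------------------------------------------------------------------------
# EMA: up to one prompt per 2-hour window (9 AM-9 PM), answered with
# probability compliance_rate, timed uniformly within the window. Affect is
# baseline + person intercept + (coupling + moderation x z(SIAS)) x centred
# homestay propensity + Gaussian noise, clipped to the VAS range. The
# propensity passed in may belong to a lagged day (coupling_lag), so
# "affect precedes next-day homestay" worlds are configurable.

#' Simulate one day of answered EMA prompts
#'
#' @param participant Latent participant (needs affect latents and
#'   `sias_true`).
#' @param date Local calendar day.
#' @param propensity The homestay propensity the affect should couple to
#'   (possibly a lagged day's value).
#' @param config A [hs_config()] object.
#' @return `data.table` (`participant`, `time`, `pa`, `na`), possibly empty.
#' @export
generate_ema <- function(participant, date, propensity, config) {
  tz <- config$tz
  win_starts <- seq(config$prompt_start, config$prompt_end - 2, by = 2)
  win_starts <- win_starts[seq_len(min(length(win_starts),
                                       config$prompts_per_day_max))]
  answered <- runif(length(win_starts)) < config$compliance_rate
  hours <- win_starts + runif(length(win_starts)) * 2
  hours <- hours[answered]
  if (!length(hours)) {
    return(data.table(participant = character(), time = as.POSIXct(character(), tz = tz),
                      pa = numeric(), na = numeric()))
  }
  z_sias <- if (config$sias_sd > 0)
    (participant$sias_true - config$sias_mean) / config$sias_sd else 0
  pc <- propensity - 0.5
  k <- length(hours)
  na_mu <- participant$baseline_na + participant$random_intercept_na +
    (config$coupling_na + config$moderation_na_sias * z_sias) * pc
  pa_mu <- participant$baseline_pa + participant$random_intercept_pa +
    (config$coupling_pa + config$moderation_pa_sias * z_sias) * pc
  na_v <- pmin(100, pmax(0, na_mu + rnorm(k, 0, config$ema_noise_sd)))
  pa_v <- pmin(100, pmax(0, pa_mu + rnorm(k, 0, config$ema_noise_sd)))
  data.table(
    participant = participant$id,
    time = local_time(date, 0, tz) + round(hours * 3600),
    pa = pa_v, na = na_v
  )
}

# ---------------------------------------------------------------------------

#' Simulate a full synthetic cohort
#'
#' Runs the whole generative model: latent participants (home and away
#' anchors, traits, affect baselines), per-day homestay propensities,
#' episode schedules, GPS fixes with jittered positions and gap-run
#' missingness, and EMA affect ratings coupled to the (optionally lagged)
#' homestay propensity. Ground-truth latents are returned as a sidecar for
#' parameter-recovery tests.
#'
#' @param config A [hs_config()] object.
#' @return A list of class `homestay_cohort`: `gps`, `ema`, `traits`
#'   (the three pipeline input tables), `truth_participants`, `truth_days`
#'   (ground-truth sidecars), and `config`.
#' @export
#' @examples
#' co <- simulate_cohort(hs_config(n_participants = 2, n_days = 2, seed = 7))
#' names(co)
simulate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_participants
  dates <- as.Date(config$start_date) + seq_len(config$n_days) - 1L
  gps_l <- vector("list", n); ema_l <- vector("list", n)
  tp_l <- vector("list", n); td_l <- vector("list", n)
  for (i in seq_len(n)) {
    lp <- simulate_latent_participant(i, config)
    set.seed(participant_seed(config$seed, i, 3L))
    eps <- rbindlist(lapply(seq_along(dates), function(d) {
      generate_day_schedule(lp, dates[d], lp$day_propensity[d], config)
    }))
    set.seed(participant_seed(config$seed, i, 4L))
    gps_l[[i]] <- generate_gps(eps, config)
    set.seed(participant_seed(config$seed, i, 5L))
    ema_l[[i]] <- rbindlist(lapply(seq_along(dates), function(d) {
      da <- min(max(d + config$coupling_lag, 1L), length(dates))
      generate_ema(lp, dates[d], lp$day_propensity[da], config)
    }))
    tp_l[[i]] <- data.table(
      participant = lp$id,
      home_lat = lp$home["lat"], home_lon = lp$home["lon"],
      sias = lp$sias_true, dass_dep = lp$dass_true,
      baseline_na = lp$baseline_na, baseline_pa = lp$baseline_pa,
      intercept_na = lp$random_intercept_na,
      intercept_pa = lp$random_intercept_pa,
      propensity_logit = lp$propensity_logit
    )
    td_l[[i]] <- data.table(participant = lp$id, date = dates,
                            propensity = lp$day_propensity)
  }
  traits <- rbindlist(lapply(tp_l, function(x)
    x[, c("participant", "sias", "dass_dep")]))
  out <- list(gps = rbindlist(gps_l), ema = rbindlist(ema_l),
              traits = traits,
              truth_participants = rbindlist(tp_l),
              truth_days = rbindlist(td_l),
              config = config)
  class(out) <- "homestay_cohort"
  out
}

#' @export
print.homestay_cohort <- function(x, ...) {
  cat(sprintf("<homestay_cohort> %d participants, %s gps fixes, %d ema ratings\n",
              x$config$n_participants, format(nrow(x$gps), big.mark = ","),
              nrow(x$ema)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Emits the three pipeline input files (`gps.csv`, `ema.csv`, `traits.csv`),
#' ground-truth sidecars (`truth_participants.csv`, `truth_days.csv`) and a
#' machine-readable `run_meta.json` echoing the configuration and versions.
#'
#' @param cohort A `homestay_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "homestay_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gps(cohort$gps, file.path(dir, "gps.csv"))
  write_ema(cohort$ema, file.path(dir, "ema.csv"))
  write_traits(cohort$traits, file.path(dir, "traits.csv"))
  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  tp <- copy(cohort$truth_participants)
  for (cl in setdiff(names(tp), "participant")) tp[[cl]] <- fmt(tp[[cl]])
  data.table::fwrite(tp, file.path(dir, "truth_participants.csv"))
  td <- copy(cohort$truth_days)
  td$propensity <- fmt(td$propensity)
  data.table::fwrite(td, file.path(dir, "truth_days.csv"))
  write_run_meta(cohort$config, file.path(dir, "run_meta.json"))
  invisible(dir)
}
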