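# Shared fixtures, all built in code.

local_time_utc <- function(date, hour) {
  homestay:::local_time(as.Date(date), hour, "UTC")
}

# small, fast cohort configuration for pipeline tests
tiny_config <- function(...) {
  hs_config(n_participants = 4L, n_days = 4L, gps_interval = 600,
            seed = 101L, ...)
}

# a latent participant without going through the cohort RNG streams
toy_participant <- function(sias = 30) {
  home <- c(lat = 38.03, lon = -78.5)
  list(id = "T001", home = home,
       away_places = list(c(lat = 38.04, lon = -78.5),
                          c(lat = 38.03, lon = -78.48)),
       sias_true = sias, dass_true = 3,
       baseline_na = 35, baseline_pa = 55,
       random_intercept_na = 0, random_intercept_pa = 0)
}

# fix stream at `point` (+offsets in metres), regular spacing
make_fixes <- function(n, t0 = 0, dt = 150, lat = 38.03, lon = -78.5,
                       north_m = 0, east_m = 0, id = "X") {
  data.table::data.table(
    participant = id,
    time = as.POSIXct(t0 + dt * (seq_len(n) - 1), origin = "1970-01-01", tz = "UTC"),
    lat = lat + north_m / 111320,
    lon = lon + east_m / (111320 * cos(lat * pi / 180)))
}

# data simulated straight from the displayed mixed-model equation
# T = b0 + b1*NA + b2*Dep + b3*NA*Dep + S_0s + e, crossed with a day intercept
equation_table <- function(n_subj, n_day, b = c(0, 0.5, 0.2, 0.1),
                           tau2_subj = 1, tau2_day = 0, sigma2 = 1) {
  subj <- rep(seq_len(n_subj), each = n_day)
  day <- rep(seq_len(n_day), times = n_subj)
  S <- rnorm(n_subj, 0, sqrt(tau2_subj))[subj]
  D <- rnorm(n_day, 0, sqrt(tau2_day))[day]
  na <- rnorm(n_subj * n_day)
  dep <- rnorm(n_subj, 0, 1)[subj]
  y <- b[1] + b[2] * na + b[3] * dep + b[4] * na * dep + S + D +
    rnorm(n_subj * n_day, 0, sqrt(sigma2))
  data.table::data.table(
    y = y, affect = na, sias_z = rnorm(n_subj, 0, 1)[subj], dass_z = dep,
    wlen_z = 0, participant = sprintf("S%03d", subj),
    day = as.Date("2024-01-01") + day)
}

# logistic analogue
equation_table_binary <- function(n_subj, n_day, b = c(0, 1, 0, 0),
                                  tau2_subj = 1) {
  tab <- equation_table(n_subj, n_day, b = c(0, 0, 0, 0),
                        tau2_subj = 0, sigma2 = 1)
  S <- rnorm(n_subj, 0, sqrt(tau2_subj))[rep(seq_len(n_subj), each = n_day)]
  eta <- b[1] + b[2] * tab$affect + b[3] * tab$dass_z +
    b[4] * tab$affect * tab$dass_z + S
  tab$y <- rbinom(nrow(tab), 1, plogis(eta))
  tab
}

# random trajectory for stay-detection oracle tests: a few anchor places,
# dwell runs with jitter, travel bursts, and occasional long silences
random_trajectory <- function(n_max = 100) {
  n <- sample(5:n_max, 1)
  anchors <- cbind(lat = 38 + runif(3, -0.01, 0.01),
                   lon = -78.5 + runif(3, -0.01, 0.01))
  t <- cumsum(sample(c(150, 150, 150, 450, 2500), n, replace = TRUE,
                     prob = c(.6, .15, .1, .1, .05)))
  lat <- numeric(n); lon <- numeric(n)
  i <- 1
  while (i <= n) {
    len <- min(sample(1:25, 1), n - i + 1)
    if (runif(1) < 0.75) {           # dwell at an anchor with ~8 m jitter
      a <- anchors[sample(3, 1), ]
      lat[i:(i + len - 1)] <- a["lat"] + rnorm(len, 0, 8) / 111320
      lon[i:(i + len - 1)] <- a["lon"] + rnorm(len, 0, 8) / 87000
    } else {                          # travel: big jumps
      lat[i:(i + len - 1)] <- 38 + runif(len, -0.02, 0.02)
      lon[i:(i + len - 1)] <- -78.5 + runif(len, -0.02, 0.02)
    }
    i <- i + len
  }
  data.table::data.table(participant = "R",
                         time = as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                         lat = lat, lon = lon)
}
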