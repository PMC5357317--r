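test_that("haversine matches closed-form arcs and is symmetric", {
  expect_equal(haversine_m(38, -78.5, 38, -78.5), 0)
  # 0.001 degrees of latitude at the equator: meridian arc R * dtheta
  expect_equal(haversine_m(0, 0, 0.001, 0), 6371000 * 0.001 * pi / 180,
               tolerance = 1e-6)
  expect_equal(haversine_m(38.03, -78.5, 38.05, -78.47),
               haversine_m(38.05, -78.47, 38.03, -78.5))
})

test_that("stay detection handles canonical micro-cases", {
  cfg <- hs_config()
  # 20 fixes at one point over 50 min -> one cluster, one visit
  fx <- make_fixes(20, dt = 50 * 60 / 19)
  st <- detect_stays(fx, cfg)
  expect_equal(nrow(st$clusters), 1L)
  expect_equal(nrow(st$visits), 1L)
  expect_equal(st$visits$dwell_s, 50 * 60, tolerance = 0.01)

  # constant 50 m movement every 150 s -> everything is travel
  mv <- make_fixes(40)
  mv$lat <- mv$lat + (seq_len(40) - 1) * 50 / 111320
  st2 <- detect_stays(mv, cfg)
  expect_equal(nrow(st2$clusters), 0L)
  expect_true(all(is.na(st2$fix_cluster)))

  # empty and single-fix inputs are empty results, not errors
  expect_equal(nrow(detect_stays(make_fixes(0), cfg)$visits), 0L)
  expect_equal(nrow(detect_stays(make_fixes(1), cfg)$visits), 0L)
})

test_that("same-locality visits merge across short excursions only", {
  cfg <- hs_config()
  # sub-dwell excursion (2.5 min at 500 m) is travel: home visits 20 min
  # apart merge into one; the far point never becomes a cluster
  home1 <- make_fixes(17, t0 = 0)                         # 0..40 min
  blip <- make_fixes(2, t0 = 45 * 60, north_m = 500)      # dropped (<5 min)
  home2 <- make_fixes(17, t0 = 60 * 60)                   # 60..100 min
  fx <- data.table::rbindlist(list(home1, blip, home2))
  st <- detect_stays(fx, cfg)
  expect_equal(nrow(st$clusters), 1L)
  expect_equal(nrow(st$visits), 1L)
  expect_equal(st$visits$dwell_s, 100 * 60, tolerance = 0.01)

  # a real far visit (20 min dwell) is kept and keeps the home visits apart
  far <- make_fixes(9, t0 = 45 * 60, north_m = 500)       # 45..65 min
  home3 <- make_fixes(17, t0 = 70 * 60)
  fx2 <- data.table::rbindlist(list(home1, far, home3))
  st2 <- detect_stays(fx2, cfg)
  expect_equal(nrow(st2$clusters), 2L)
  home_cl2 <- st2$clusters[which.max(total_dwell_s)]$cluster
  expect_equal(sum(st2$visits$cluster == home_cl2), 2L)

  # but with a > 30-min silent hole between them they stay separate even at
  # the same place
  home_late <- make_fixes(17, t0 = 75 * 60)               # 35-min gap
  st3 <- detect_stays(data.table::rbindlist(list(home1, home_late)), cfg)
  expect_equal(nrow(st3$visits), 2L)
  expect_equal(nrow(st3$clusters), 1L)
})

test_that("stay detection agrees with the brute-force oracle on random instances", {
  cfg <- hs_config()
  set.seed(77)
  for (rep in 1:200) {
    fx <- random_trajectory(100)
    st <- detect_stays(fx, cfg)
    or <- oracle_detect_stays(fx, cfg)
    expect_equal(nrow(st$visits), nrow(or$visits), info = paste("rep", rep))
    expect_equal(st$visits$start, or$visits$start, info = paste("rep", rep))
    expect_equal(st$visits$end, or$visits$end, info = paste("rep", rep))
    expect_equal(st$fix_cluster, or$fix_cluster, info = paste("rep", rep))
  }
})

test_that("timeline conserves the observation span", {
  cfg <- hs_config()
  set.seed(99)
  for (rep in 1:40) {
    fx <- random_trajectory(100)
    st <- detect_stays(fx, cfg)
    tl <- st$timeline
    if (!nrow(tl)) next
    # segments tile [first fix, last fix] with no holes or zero lengths
    expect_equal(tl$start[1], as.numeric(fx$time[1]))
    expect_equal(tl$end[nrow(tl)], as.numeric(fx$time[nrow(fx)]))
    expect_true(all(tl$end > tl$start))
    if (nrow(tl) > 1) expect_equal(tl$start[-1], tl$end[-nrow(tl)])
    # visit dwell + travel + gap = span
    span <- as.numeric(fx$time[nrow(fx)]) - as.numeric(fx$time[1])
    expect_equal(sum(tl$end - tl$start), span)
  }
})

test_that("home inference counts nighttime fixes with deterministic tie-breaks", {
  cfg <- hs_config()
  mk_stays <- function(night_counts, dwells) {
    k <- length(night_counts)
    # fabricate fix streams: cluster i gets night_counts[i] fixes at 01:00
    ft <- c(); fc <- c()
    for (i in seq_len(k)) {
      # cluster i's fixes on day i, 01:00-02:30 local (inside the night window)
      ft <- c(ft, as.numeric(local_time_utc("2024-01-02", 1)) +
                seq_len(night_counts[i]) * 10 + i * 86400)
      fc <- c(fc, rep(i, night_counts[i]))
    }
    structure(list(
      clusters = data.table::data.table(cluster = seq_len(k), lat = 38 + seq_len(k),
                                        lon = -78.5, total_dwell_s = dwells,
                                        n_visits = 1L),
      fix_cluster = fc, fix_time = ft, participant = "P1"),
      class = "homestay_stays")
  }
  # majority: 500 vs 100 night fixes
  h <- infer_home(mk_stays(c(500, 100), c(1000, 1000)), cfg)
  expect_equal(h$cluster, 1L)
  expect_equal(h$night_fix_count, 500L)
  # exact tie in night fixes: greater dwell wins
  h2 <- infer_home(mk_stays(c(100, 100), c(1000, 5000)), cfg)
  expect_equal(h2$cluster, 2L)
  # tie on both: smaller id wins
  h3 <- infer_home(mk_stays(c(100, 100), c(1000, 1000)), cfg)
  expect_equal(h3$cluster, 1L)
  # no nighttime clustered fixes -> error naming the participant
  st <- mk_stays(c(1), c(10))
  st$fix_time <- as.numeric(local_time_utc("2024-01-02", 12))
  st$fix_cluster <- 1L
  expect_error(infer_home(st, cfg), "P1")
})

test_that("home inference recovers ground truth on a synthetic cohort", {
  cfg <- tiny_config(gps_noise_sd = 10, n_participants = 6)
  co <- simulate_cohort(cfg)
  pre <- preprocess_gps(co$gps, cfg)
  expect_equal(nrow(pre$homes), 6L)
  for (i in seq_len(6)) {
    truth <- co$truth_participants[i]
    est <- pre$homes[participant == truth$participant]
    expect_lt(haversine_m(est$lat, est$lon, truth$home_lat, truth$home_lon), 15)
  }
})

test_that("LOCF relabels gaps from the left and is idempotent", {
  tl <- data.table::data.table(
    start = c(0, 100, 200, 300), end = c(100, 200, 300, 400),
    state = c("stay", "gap", "away", "gap"),
    cluster = c(1L, NA, NA, NA))
  out <- locf_impute(tl)
  # gaps inherit the left label, then adjacent same-label segments merge
  expect_equal(out$state, c("stay", "away"))
  expect_equal(out$end, c(200, 400))
  expect_equal(out$cluster, c(1L, NA))
  expect_equal(attr(out, "imputed_s"), 200)
  # leading gap is preserved (no prior observation)
  tl2 <- data.table::data.table(start = c(0, 100), end = c(100, 200),
                                state = c("gap", "stay"), cluster = c(NA, 2L))
  out2 <- locf_impute(tl2)
  expect_equal(out2$state, c("gap", "stay"))
  # idempotence and gapless identity
  expect_equal(locf_impute(out)$state, out$state)
  expect_equal(locf_impute(out)$end, out$end)
  gapless <- data.table::data.table(start = 0, end = 50, state = "stay",
                                    cluster = 1L)
  expect_equal(locf_impute(gapless)$state, "stay")
})

test_that("completeness is observed over possible, capped at one", {
  s <- local_time_utc("2024-01-01", 10)
  e <- local_time_utc("2024-01-01", 18)
  full <- as.numeric(s) + 150 * (0:191)
  expect_equal((as.numeric(e) - as.numeric(s)) / 150, 192)
  expect_equal(completeness(full, s, e, 150), 1)
  expect_equal(completeness(full[1:96], s, e, 150), 0.5)
  expect_equal(completeness(numeric(0), s, e, 150), 0)
  # a fix at exactly 18:00:00 belongs to the next window
  expect_equal(completeness(c(full, as.numeric(e)), s, e, 150), 1)
})
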