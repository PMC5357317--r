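#' Pipeline and simulation configuration
#'
#' Builds the single configuration object used by every stage of the pipeline:
#' the synthetic-cohort generator, GPS preprocessing, feature construction,
#' model fitting, and reporting. Every threshold of the analysis design is a
#' named key with the study-design value as its default, so a config file can
#' override any of them.
#'
#' Key groups (defaults in parentheses):
#' \describe{
#'   \item{cohort}{\code{n_participants} (63), \code{n_days} (14),
#'     \code{start_date} ("2024-01-08"), \code{tz} ("UTC").}
#'   \item{GPS sampling}{\code{gps_interval} seconds between fixes (150),
#'     \code{gps_noise_sd} metres of isotropic jitter (5),
#'     \code{missing_rate} stationary fraction of fixes lost to gap runs
#'     (0.08), \code{gap_run_fixes} mean gap-run length in fixes (10).}
#'   \item{EMA design}{\code{prompts_per_day_max} (6) two-hour prompt windows
#'     between \code{prompt_start} (9) and \code{prompt_end} (21) local hours;
#'     \code{compliance_rate} probability a prompt is answered (0.42, which
#'     reproduces the observed ~2.5 answered prompts/day).}
#'   \item{traits}{\code{sias_mean}/\code{sias_sd} (29.9/9.6) and
#'     \code{dass_mean}/\code{dass_sd} (3.3/2.4): target sample moments of the
#'     truncated-normal trait generator, on the SIAS 0-80 and DASS-21
#'     depression 0-21 ranges.}
#'   \item{affect model}{\code{baseline_na}/\code{baseline_pa} cohort VAS
#'     baselines (35/55), \code{intercept_sd_na}/\code{intercept_sd_pa}
#'     between-person SD (8), \code{ema_noise_sd} momentary noise SD (10),
#'     couplings \code{coupling_na}, \code{coupling_pa} (VAS units per unit of
#'     centred homestay propensity; 0 = null world),
#'     \code{moderation_na_sias}, \code{moderation_pa_sias} (extra coupling
#'     per SD of SIAS; 0), and \code{coupling_lag} in days (0): which day's
#'     homestay propensity the affect generator reads.}
#'   \item{mobility}{\code{home_block_minutes} occupancy block length (120),
#'     \code{propensity_logit_mean} (0), \code{propensity_sd_between} (1.0),
#'     \code{propensity_sd_within} (1.5) on the logit scale,
#'     \code{propensity_sias_slope} between-subjects trait coupling in logit
#'     units per SD of SIAS (0), \code{force_night_home} (TRUE).}
#'   \item{preprocessing}{\code{spatial_m} stay radius (30),
#'     \code{min_dwell_s} minimum stay dwell (300), \code{merge_gap_s}
#'     temporal merge threshold (1800), \code{gap_threshold_s} silence needed
#'     to declare a data gap (600).}
#'   \item{windows}{\code{night_start}/\code{night_end} (0/6),
#'     \code{day_start}/\code{day_end} (10/18) local hours,
#'     \code{max_window_s} prompt-pair span cap (14400 = 4 h).}
#'   \item{analysis}{\code{log_eps} added inside the log-ratio transform
#'     (0.01), \code{alpha} significance level (0.05),
#'     \code{standardize_outcome} (TRUE), \code{daily_affect_all_prompts}
#'     (TRUE: daily affect means use all answered prompts, not just those in
#'     the workday window).}
#'   \item{misc}{\code{seed} (1).}
#' }
#'
#' @param ... name = value overrides of any default key.
#' @return A named list of class \code{"homestay_config"}.
#' @export
#' @examples
#' cfg <- hs_config(n_participants = 10, n_days = 7, seed = 42)
#' cfg$gps_interval
hs_config <- function(...) {
  cfg <- list(
    n_participants = 63L,
    n_days = 14L,
    start_date = "2024-01-08",
    tz = "UTC",
    gps_interval = 150,
    gps_noise_sd = 5,
    missing_rate = 0.08,
    gap_run_fixes = 10,
    prompts_per_day_max = 6L,
    compliance_rate = 0.42,
    sias_mean = 29.9, sias_sd = 9.6,
    dass_mean = 3.3, dass_sd = 2.4,
    baseline_na = 35, baseline_pa = 55,
    intercept_sd_na = 8, intercept_sd_pa = 8,
    ema_noise_sd = 10,
    coupling_na = 0, coupling_pa = 0,
    moderation_na_sias = 0, moderation_pa_sias = 0,
    coupling_lag = 0L,
    home_block_minutes = 120,
    propensity_logit_mean = 0,
    propensity_sias_slope = 0,
    propensity_sd_between = 1.0,
    propensity_sd_within = 1.5,
    force_night_home = TRUE,
    spatial_m = 30,
    min_dwell_s = 300,
    merge_gap_s = 1800,
    gap_threshold_s = 600,
    night_start = 0, night_end = 6,
    day_start = 10, day_end = 18,
    prompt_start = 9, prompt_end = 21,
    max_window_s = 14400,
    log_eps = 0.01,
    alpha = 0.05,
    standardize_outcome = TRUE,
    daily_affect_all_prompts = TRUE,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "homestay_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1, cfg$n_days >= 1,
    cfg$gps_interval > 0,
    cfg$missing_rate >= 0, cfg$missing_rate <= 1,
    cfg$compliance_rate >= 0, cfg$compliance_rate <= 1,
    cfg$prompts_per_day_max >= 1,
    cfg$gps_noise_sd >= 0,
    cfg$sias_sd >= 0, cfg$dass_sd >= 0,
    cfg$spatial_m > 0, cfg$min_dwell_s > 0, cfg$merge_gap_s >= 0,
    cfg$log_eps > 0, cfg$alpha > 0, cfg$alpha < 1
  )
  invisible(cfg)
}

#' Read or write a flat key-value config file
#'
#' The on-disk format is one `key = value` pair per line; `#` starts a
#' comment. Values are parsed as numbers when possible, `TRUE`/`FALSE` as
#' logicals, anything else as a string. Unknown keys are an error, so typos
#' in config files fail loudly.
#'
#' @param path File path.
#' @param cfg A `homestay_config` (for writing).
#' @return `read_config()` returns a `homestay_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(hs_config())
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- trimws(vapply(parts, `[`, "", 2L))
  parse_val <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  ovr <- stats::setNames(lapply(vals, parse_val), keys)
  do.call(hs_config, ovr)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "homestay_config"))
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, format(v, scientific = FALSE))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' @export
print.homestay_config <- function(x, ...) {
  cat("<homestay_config>\n")
  cat(sprintf("  cohort: %d participants x %d days, tz %s\n",
              x$n_participants, x$n_days, x$tz))
  cat(sprintf("  gps: every %gs, noise %gm, missing %.0f%%\n",
              x$gps_interval, x$gps_noise_sd, 100 * x$missing_rate))
  cat(sprintf("  ema: up to %d prompts/day, compliance %.0f%%\n",
              x$prompts_per_day_max, 100 * x$compliance_rate))
  cat(sprintf("  couplings: NA %g, PA %g, NAxSIAS %g, PAxSIAS %g, lag %d\n",
              x$coupling_na, x$coupling_pa, x$moderation_na_sias,
              x$moderation_pa_sias, x$coupling_lag))
  invisible(x)
}
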