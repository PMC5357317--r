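# Mixed-effects model grid.
#
# Eight model cells (2 outcomes x 4 temporal framings), each fitted once per
# affect variable (NA, PA) with both trait moderators entered jointly:
#
#   outcome ~ affect + SIAS + DASS + affect:SIAS + affect:DASS
#             + (1 | subject) + (1 | day) [+ (0 + window length | subject)]
#
# Continuous outcome: the log-transformed personal-average homestay ratio,
# z-scored together with all predictors (standardized betas). Binary
# outcome: any time at home in the window, logistic link, affect on its raw
# scale (unstandardized betas) with moderators z-scored before forming
# interactions. Subject and calendar day are crossed random intercepts; the
# window-length random slope applies only to the 4-hour change framing,
# grouped by subject. Each fit contributes 3 of the 48 reported effects
# (affect main effect and its two trait interactions).
#
# Estimation is delegated to lme4 (REML for the Gaussian models, Laplace for
# the logistic ones); the test suite checks the Gaussian fits against an
# independent dense profiled-likelihood optimizer.

FRAMINGS <- c("change_4h", "same_day", "prev_day", "next_day")
OUTCOMES <- c("continuous", "binary")
AFFECTS <- c("na", "pa")

framing_rows <- function(features, framing) {
  switch(framing,
    change_4h = features[kind == "prompt_pair"],
    same_day = features[kind == "daily" & lag == 0L],
    next_day = features[kind == "daily" & lag == 1L],
    prev_day = features[kind == "daily" & lag == -1L],
    stop("unknown framing: ", framing))
}

zscore <- function(x, name) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance variable: ", name, call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Build the standardized analysis table for one model cell
#'
#' Selects the rows of one temporal framing, merges trait scores, and applies
#' the standardization contract: for the continuous outcome, affect,
#' moderators and (by default) the outcome are z-scored over the analysis
#' rows; for the binary outcome, affect stays on its raw scale and only the
#' moderators are z-scored (so interaction betas are per raw affect unit and
#' per moderator SD). `day` is the local calendar date of the homestay
#' window, the crossed random grouping alongside subject.
#'
#' @param features Feature table from [build_features()].
#' @param traits Trait table (`participant`, `sias`, `dass_dep`).
#' @param outcome "continuous" or "binary".
#' @param framing One of "change_4h", "same_day", "prev_day", "next_day".
#' @param affect "na" or "pa".
#' @param config A [hs_config()] object.
#' @return `data.table` with columns `y`, `affect`, `sias_z`, `dass_z`,
#'   `wlen_z`, `participant`, `day`.
#' @export
standardize_table <- function(features, traits, outcome, framing, affect,
                              config = hs_config()) {
  rows <- framing_rows(as.data.table(features), framing)
  if (!nrow(rows)) stop("no analysis rows for framing ", framing)
  tab <- merge(rows, as.data.table(traits), by = "participant")
  aff_raw <- if (affect == "na") tab$na_value else tab$pa_value
  out <- data.table(
    participant = tab$participant,
    day = local_date(as.POSIXct(tab$start, origin = "1970-01-01", tz = "UTC"),
                     config$tz),
    sias_z = zscore(tab$sias, "sias"),
    dass_z = zscore(tab$dass_dep, "dass_dep"),
    wlen_z = if (sd(tab$length_s) > 0) zscore(tab$length_s, "length_s") else 0
  )
  if (outcome == "continuous") {
    out[, y := if (config$standardize_outcome) zscore(tab$log_ratio, "log_ratio")
        else tab$log_ratio]
    out[, affect := zscore(aff_raw, affect)]
  } else {
    out[, y := tab$any_home]
    if (sd(aff_raw) == 0) stop("zero-variance variable: ", affect, call. = FALSE)
    out[, affect := aff_raw]
  }
  out[]
}

check_grouping <- function(tab) {
  ns <- length(unique(tab$participant))
  nd <- length(unique(tab$day))
  if (ns < 2 || nd < 2) {
    stop(sprintf("need at least 2 subjects and 2 days (got %d, %d)", ns, nd),
         call. = FALSE)
  }
  if (ns < 10) warning("fewer than 10 subjects; estimates will be unstable")
  c(ns, nd)
}

fit_terms <- function(fit_obj) {
  sm <- summary(fit_obj)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  z <- est / se
  list(betas = est, ses = se,
       p_values = 2 * pnorm(-abs(z)),
       f_stats = z^2)
}

extract_varcomp <- function(fit_obj) {
  vc <- lme4::VarCorr(fit_obj)
  get1 <- function(grp, var) {
    for (i in seq_along(vc)) {
      if (names(vc)[i] == grp && var %in% rownames(vc[[i]])) {
        return(vc[[i]][var, var])
      }
    }
    0
  }
  list(var_subject = get1("participant", "(Intercept)"),
       var_day = get1("day", "(Intercept)"),
       var_slope = get1("participant.1", "wlen_z") + get1("participant", "wlen_z"))
}

build_formula <- function(outcome, framing) {
  rhs <- "affect + sias_z + dass_z + affect:sias_z + affect:dass_z + (1 | participant) + (1 | day)"
  if (framing == "change_4h") {
    rhs <- paste(rhs, "+ (0 + wlen_z | participant)")
  }
  as.formula(paste("y ~", rhs))
}

#' Fit one Gaussian mixed model cell
#'
#' REML estimation (via lme4) of the continuous-outcome model with crossed
#' subject/day random intercepts (plus the window-length random slope for the
#' 4-hour change framing). Coefficient tests are Wald z; the single-df F
#' statistic is reported as the squared z. A singular fit (a variance
#' component estimated at 0) sets the `singular` flag rather than failing.
#'
#' @param tab Analysis table from [standardize_table()].
#' @param framing Temporal framing label (controls the random slope).
#' @param affect Affect label, recorded in the result.
#' @return Object of class `homestay_fit`: `betas`, `ses`, `p_values`,
#'   `f_stats`, `df`, variance components, `r2_fixed`, `n_obs`,
#'   `n_subjects`, `n_days`, `singular`.
#' @export
fit_lmm <- function(tab, framing = "same_day", affect = "na") {
  nn <- check_grouping(tab)
  form <- build_formula("continuous", framing)
  fit_obj <- tryCatch(
    suppressMessages(lme4::lmer(
      form, data = tab, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) stop(sprintf("LMM (continuous, %s, %s) failed: %s",
                                     framing, affect, conditionMessage(e)),
                             call. = FALSE))
  tt <- fit_terms(fit_obj)
  vcs <- extract_varcomp(fit_obj)
  res <- structure(c(list(
    outcome = "continuous", framing = framing, affect = affect,
    var_resid = stats::sigma(fit_obj)^2,
    fixed_pred = as.numeric(stats::model.matrix(fit_obj) %*% lme4::fixef(fit_obj)),
    slope_msq = if (framing == "change_4h") mean(tab$wlen_z^2) else 0,
    df = nrow(tab) - length(tt$betas),
    n_obs = nrow(tab), n_subjects = nn[1], n_days = nn[2],
    singular = lme4::isSingular(fit_obj, tol = 1e-5)),
    tt, vcs), class = "homestay_fit")
  res$r2_fixed <- marginal_r2(res)
  res
}

#' Fit one logistic mixed model cell
#'
#' Laplace-approximate ML (lme4::glmer) for the binary any-home outcome with
#' the same random structure as [fit_lmm()]. Unstandardized betas. Errors if
#' the outcome has a single class; flags apparent complete separation
#' (|beta| > 15 on the logit scale) on the offending term.
#'
#' @inheritParams fit_lmm
#' @return A `homestay_fit` (no residual variance; `r2_fixed` is `NA`).
#' @export
fit_glmm_binary <- function(tab, framing = "same_day", affect = "na") {
  nn <- check_grouping(tab)
  if (length(unique(tab$y)) < 2) {
    stop(sprintf("binary outcome has a single class (%s, %s)", framing, affect),
         call. = FALSE)
  }
  form <- build_formula("binary", framing)
  fit_obj <- tryCatch(
    suppressMessages(suppressWarnings(lme4::glmer(
      form, data = tab, family = binomial(),
      control = lme4::glmerControl(check.conv.singular = "ignore",
                                   calc.derivs = FALSE)))),
    error = function(e) stop(sprintf("GLMM (binary, %s, %s) failed: %s",
                                     framing, affect, conditionMessage(e)),
                             call. = FALSE))
  tt <- fit_terms(fit_obj)
  sep <- names(tt$betas)[abs(tt$betas) > 15]
  if (length(sep)) {
    stop("apparent complete separation on term(s): ",
         paste(sep, collapse = ", "), call. = FALSE)
  }
  vcs <- extract_varcomp(fit_obj)
  structure(c(list(
    outcome = "binary", framing = framing, affect = affect,
    var_resid = NA_real_, r2_fixed = NA_real_,
    df = nrow(tab) - length(tt$betas),
    n_obs = nrow(tab), n_subjects = nn[1], n_days = nn[2],
    singular = lme4::isSingular(fit_obj, tol = 1e-5)),
    tt, vcs), class = "homestay_fit")
}

#' Marginal (fixed-effects) R-squared
#'
#' Variance of the fixed-effects linear predictor divided by the total
#' outcome variance decomposition: fixed + subject + day (+ random-slope
#' contribution) + residual. Defined for Gaussian fits.
#'
#' @param fit A `homestay_fit` from [fit_lmm()].
#' @return Fraction in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "homestay_fit"))
  if (fit$outcome != "continuous") return(NA_real_)
  vf <- var(fit$fixed_pred)
  slope_v <- fit$var_slope * fit$slope_msq
  vf / (vf + fit$var_subject + fit$var_day + slope_v + fit$var_resid)
}

#' @export
print.homestay_fit <- function(x, ...) {
  cat(sprintf("<homestay_fit> %s outcome, %s framing, affect %s\n",
              x$outcome, x$framing, toupper(x$affect)))
  tab <- data.frame(beta = x$betas, se = x$ses, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("var: subject %.3g, day %.3g, resid %.3g; R2(fixed) %.3g; n=%d\n",
              x$var_subject, x$var_day, x$var_resid,
              if (is.na(x$r2_fixed)) NA else x$r2_fixed, x$n_obs))
  invisible(x)
}

#' Fit the full 48-effect model grid
#'
#' Runs every combination of outcome (continuous ratio, binary any-home),
#' temporal framing (4-hour change, same/previous/next day) and affect
#' variable (NA, PA): 16 fits, each reporting the affect main effect and its
#' SIAS and DASS interactions - 48 effects in all.
#'
#' @param features Feature table from [build_features()].
#' @param traits Trait table.
#' @param config A [hs_config()] object.
#' @return List of class `homestay_grid` with one `homestay_fit` per
#'   `<outcome>.<framing>.<affect>` name.
#' @export
fit_model_grid <- function(features, traits, config = hs_config()) {
  fits <- list()
  for (oc in OUTCOMES) {
    for (fr in FRAMINGS) {
      for (af in AFFECTS) {
        tab <- standardize_table(features, traits, oc, fr, af, config)
        fit <- if (oc == "continuous") fit_lmm(tab, fr, af)
               else fit_glmm_binary(tab, fr, af)
        fits[[paste(oc, fr, af, sep = ".")]] <- fit
      }
    }
  }
  structure(fits, class = "homestay_grid")
}

#' Between-subjects trait models
#'
#' Four models of raw (not personally averaged) homestay on the two traits
#' entered jointly: {4-hour windows, workday windows} x {continuous
#' log(home fraction + eps), binary any-home}, each with crossed subject/day
#' random intercepts. The continuous outcome and both traits are z-scored
#' (standardized betas); binary fits report unstandardized betas for
#' z-scored traits.
#'
#' @inheritParams fit_model_grid
#' @return Named list of 4 `homestay_fit` objects
#'   (`<window>.<outcome>`).
#' @export
fit_trait_models <- function(features, traits, config = hs_config()) {
  feats <- as.data.table(features)
  fits <- list()
  for (win in c("window_4h", "workday")) {
    rows <- if (win == "window_4h") feats[kind == "prompt_pair"]
            else feats[kind == "daily" & lag == 0L]
    tab0 <- merge(rows, as.data.table(traits), by = "participant")
    base <- data.table(
      participant = tab0$participant,
      day = local_date(as.POSIXct(tab0$start, origin = "1970-01-01", tz = "UTC"),
                       config$tz),
      sias_z = zscore(tab0$sias, "sias"),
      dass_z = zscore(tab0$dass_dep, "dass_dep"))
    for (oc in OUTCOMES) {
      tab <- copy(base)
      if (oc == "continuous") {
        tab[, y := zscore(log(tab0$frac + config$log_eps), "log(frac)")]
      } else {
        tab[, y := tab0$any_home]
      }
      nn <- check_grouping(tab)
      form <- y ~ sias_z + dass_z + (1 | participant) + (1 | day)
      fit_obj <- if (oc == "continuous") {
        suppressMessages(lme4::lmer(form, data = tab, REML = TRUE,
          control = lme4::lmerControl(check.conv.singular = "ignore",
                                      calc.derivs = FALSE)))
      } else {
        if (length(unique(tab$y)) < 2) stop("binary outcome has a single class")
        suppressMessages(suppressWarnings(lme4::glmer(form, data = tab,
          family = binomial(),
          control = lme4::glmerControl(check.conv.singular = "ignore",
                                       calc.derivs = FALSE))))
      }
      tt <- fit_terms(fit_obj)
      vcs <- extract_varcomp(fit_obj)
      fits[[paste(win, oc, sep = ".")]] <- structure(c(list(
        outcome = oc, framing = win, affect = NA_character_,
        var_resid = if (oc == "continuous") stats::sigma(fit_obj)^2 else NA_real_,
        fixed_pred = as.numeric(stats::model.matrix(fit_obj) %*% lme4::fixef(fit_obj)),
        slope_msq = 0, df = nrow(tab) - length(tt$betas),
        n_obs = nrow(tab), n_subjects = nn[1], n_days = nn[2],
        singular = lme4::isSingular(fit_obj, tol = 1e-5), r2_fixed = NA_real_),
        tt, vcs), class = "homestay_fit")
    }
  }
  fits
}

#' Serialize / load a model grid
#'
#' Writes one flat JSON record per fit (coefficients, standard errors,
#' p-values, variance components, marginal R-squared, sample sizes), readable
#' by the report stage.
#'
#' @param grid A `homestay_grid`.
#' @param path JSON file path.
#' @return `path` / a `homestay_grid`-shaped list.
#' @export
write_fits <- function(grid, path) {
  recs <- lapply(grid, function(f) {
    list(outcome = f$outcome, framing = f$framing, affect = f$affect,
         terms = names(f$betas), betas = unname(f$betas),
         ses = unname(f$ses), p_values = unname(f$p_values),
         var_subject = f$var_subject, var_day = f$var_day,
         var_slope = f$var_slope, var_resid = f$var_resid,
         r2_fixed = f$r2_fixed, n_obs = f$n_obs,
         n_subjects = f$n_subjects, n_days = f$n_days,
         singular = f$singular)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fits <- lapply(recs, function(r) {
    structure(list(
      outcome = r$outcome, framing = r$framing, affect = r$affect,
      betas = setNames(unlist(r$betas), unlist(r$terms)),
      ses = setNames(unlist(r$ses), unlist(r$terms)),
      p_values = setNames(unlist(r$p_values), unlist(r$terms)),
      var_subject = r$var_subject, var_day = r$var_day,
      var_slope = r$var_slope, var_resid = r$var_resid,
      r2_fixed = r$r2_fixed, n_obs = r$n_obs,
      n_subjects = r$n_subjects, n_days = r$n_days,
      singular = r$singular), class = "homestay_fit")
  })
  names(fits) <- vapply(fits, function(f)
    paste(f$outcome, f$framing, f$affect, sep = "."), "")
  structure(fits, class = "homestay_grid")
}
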