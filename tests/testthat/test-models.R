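make_pipeline_features <- function(cfg) {
  co <- simulate_cohort(cfg)
  pre <- preprocess_gps(co$gps, cfg)
  list(features = build_features(pre, co$ema, cfg), traits = co$traits)
}

test_that("standardization contract: z-scores, raw binary affect, named errors", {
  cfg <- tiny_config(n_participants = 5, n_days = 5)
  pf <- make_pipeline_features(cfg)
  tab <- standardize_table(pf$features, pf$traits, "continuous", "same_day",
                           "na", cfg)
  for (v in c("y", "affect", "sias_z", "dass_z")) {
    expect_equal(mean(tab[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(tab[[v]]), 1, tolerance = 1e-10)
  }
  # standardizing an already-standard column is a no-op
  expect_equal(homestay:::zscore(tab$affect, "x"), tab$affect, tolerance = 1e-10)

  # binary outcome: affect on raw scale, moderators z-scored
  tb <- standardize_table(pf$features, pf$traits, "binary", "same_day", "na", cfg)
  raw <- merge(pf$features[kind == "daily" & lag == 0L], pf$traits,
               by = "participant")
  expect_equal(sort(tb$affect), sort(raw$na_value))
  expect_true(all(tb$y %in% 0:1))
  expect_equal(sd(tb$sias_z), 1, tolerance = 1e-10)

  # constant column is a named error
  tr0 <- data.table::copy(pf$traits)[, sias := 30]
  expect_error(standardize_table(pf$features, tr0, "continuous", "same_day",
                                 "na", cfg), "sias")
})

test_that("LMM recovers the generating equation's coefficients", {
  set.seed(2024)
  tab <- equation_table(60, 14, b = c(0, 0.5, 0.2, 0.1),
                        tau2_subj = 1, tau2_day = 0, sigma2 = 1)
  fit <- suppressWarnings(fit_lmm(tab, "same_day", "na"))
  expect_lt(abs(fit$betas[["affect"]] - 0.5), 0.1)
  expect_lt(abs(fit$var_subject - 1), 0.4)
  expect_lt(abs(fit$var_resid - 1), 0.15)
  expect_equal(fit$n_subjects, 60)
  # F for a single-df effect is the squared Wald statistic
  expect_equal(fit$f_stats[["affect"]],
               (fit$betas[["affect"]] / fit$ses[["affect"]])^2)
})

test_that("zero subject variance degenerates to OLS", {
  set.seed(7)
  tab <- equation_table(50, 10, b = c(0, 0.4, 0, 0), tau2_subj = 0,
                        tau2_day = 0, sigma2 = 1)
  fit <- suppressWarnings(fit_lmm(tab, "same_day", "na"))
  expect_lt(fit$var_subject, 0.08)  # positive-part REML noise at finite n
  expect_true(fit$singular)
  ols <- lm(y ~ affect + sias_z + dass_z + affect:sias_z + affect:dass_z,
            data = tab)
  expect_lt(max(abs(unname(fit$betas) - unname(coef(ols)))), 0.03)
})

test_that("LMM matches the dense profiled-REML oracle to 3 significant digits", {
  set.seed(31)
  tab <- equation_table(25, 8, b = c(0.3, 0.5, -0.2, 0.1),
                        tau2_subj = 0.8, tau2_day = 0.4, sigma2 = 1)
  fit <- fit_lmm(tab, "same_day", "na")
  X <- model.matrix(~ affect + sias_z + dass_z + affect:sias_z + affect:dass_z,
                    data = tab)
  orc <- oracle_reml(tab$y, X, list(tab$participant, tab$day))
  expect_equal(unname(fit$betas), orc$beta, tolerance = 1e-3)
  expect_equal(unname(c(fit$var_subject, fit$var_day, fit$var_resid)),
               unname(orc$variances), tolerance = 1e-2)
})

test_that("Wald type-I error is near nominal under the null", {
  set.seed(555)
  pvals <- replicate(500, {
    tab <- equation_table(30, 8, b = c(0, 0, 0, 0), tau2_subj = 1,
                          tau2_day = 0.3, sigma2 = 1)
    fit <- suppressWarnings(fit_lmm(tab, "same_day", "na"))
    fit$p_values[["affect"]]
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.085)
})

test_that("logistic GLMM recovers a known slope and the null", {
  set.seed(91)
  tab <- equation_table_binary(60, 14, b = c(0, 1, 0, 0), tau2_subj = 1)
  fit <- fit_glmm_binary(tab, "same_day", "na")
  expect_lt(abs(fit$betas[["affect"]] - 1), 0.25)
  expect_true(is.na(fit$r2_fixed))

  # intercept-only at 50%: logit(0.5) = 0
  set.seed(17)
  tab0 <- equation_table_binary(40, 10, b = c(0, 0, 0, 0), tau2_subj = 0.01)
  fit0 <- suppressWarnings(fit_glmm_binary(tab0, "same_day", "na"))
  expect_lt(abs(fit0$betas[["(Intercept)"]]), 0.2)

  # null slope: mean estimate near zero over replicates
  set.seed(404)
  ests <- replicate(200, {
    tb <- equation_table_binary(20, 6, b = c(0, 0, 0, 0), tau2_subj = 0.5)
    suppressWarnings(fit_glmm_binary(tb, "same_day", "na"))$betas[["affect"]]
  })
  expect_lt(abs(mean(ests)), 0.15)

  # one-class outcome errors
  tab1 <- data.table::copy(tab0)[, y := 1L]
  expect_error(fit_glmm_binary(tab1, "same_day", "na"), "single class")
})

test_that("marginal R2 follows the variance-partition definition", {
  # null fixed effects: R2 ~ 0 (chance trait-intercept correlation at
  # finite n leaves a small residue)
  set.seed(5)
  tabn <- equation_table(60, 8, b = c(0, 0, 0, 0), tau2_subj = 1,
                         tau2_day = 0.3, sigma2 = 1)
  fitn <- suppressWarnings(fit_lmm(tabn, "same_day", "na"))
  expect_lt(marginal_r2(fitn), 0.06)

  # known components: R2 = b1^2 / (b1^2 + tau + sigma2) for x ~ N(0,1)
  set.seed(6)
  tabk <- equation_table(60, 14, b = c(0, 0.8, 0, 0), tau2_subj = 0.5,
                         tau2_day = 0, sigma2 = 1)
  fitk <- suppressWarnings(fit_lmm(tabk, "same_day", "na"))
  r2_true <- 0.64 / (0.64 + 0.5 + 1)
  expect_equal(marginal_r2(fitk), r2_true, tolerance = 0.06)

  # degenerate limit: no random or residual variance -> 1
  fit1 <- structure(list(outcome = "continuous", fixed_pred = rnorm(50),
                         var_subject = 0, var_day = 0, var_slope = 0,
                         slope_msq = 0, var_resid = 0),
                    class = "homestay_fit")
  expect_equal(marginal_r2(fit1), 1)
})

test_that("continuous fits are invariant to affine rescaling of raw predictors", {
  cfg <- tiny_config(n_participants = 8, n_days = 6)
  pf <- make_pipeline_features(cfg)
  f2 <- data.table::copy(pf$features)[, na_value := 1000 * na_value + 5]
  t1 <- standardize_table(pf$features, pf$traits, "continuous", "same_day", "na", cfg)
  t2 <- standardize_table(f2, pf$traits, "continuous", "same_day", "na", cfg)
  fit1 <- suppressWarnings(fit_lmm(t1, "same_day", "na"))
  fit2 <- suppressWarnings(fit_lmm(t2, "same_day", "na"))
  expect_equal(fit1$betas, fit2$betas, tolerance = 1e-8)
})

test_that("estimates tighten as the subject count quadruples", {
  set.seed(808)
  rmse <- function(n_subj, reps) {
    errs <- replicate(reps, {
      tab <- equation_table(n_subj, 6, b = c(0, 0.5, 0, 0), tau2_subj = 1,
                            tau2_day = 0, sigma2 = 1)
      suppressWarnings(fit_lmm(tab, "same_day", "na"))$betas[["affect"]] - 0.5
    })
    sqrt(mean(errs^2))
  }
  expect_gt(rmse(10, 30) / rmse(40, 30), 1.3)
})

test_that("random slope enters only the 4-hour-change framing", {
  cfg <- tiny_config(n_participants = 10, n_days = 6)
  pf <- make_pipeline_features(cfg)
  tab <- standardize_table(pf$features, pf$traits, "continuous", "change_4h",
                           "na", cfg)
  fit <- suppressWarnings(fit_lmm(tab, "change_4h", "na"))
  expect_gte(fit$var_slope, 0)
  expect_gt(fit$slope_msq, 0)
  tabd <- standardize_table(pf$features, pf$traits, "continuous", "same_day",
                            "na", cfg)
  fitd <- suppressWarnings(fit_lmm(tabd, "same_day", "na"))
  expect_equal(fitd$var_slope, 0)
})

test_that("trait models recover between-subjects coupling and the null", {
  # high-SIAS participants configured to stay home more
  cfg <- hs_config(n_participants = 30, n_days = 8, gps_interval = 600,
                   seed = 61, propensity_sias_slope = 1.0)
  pf <- suppressWarnings(make_pipeline_features(cfg))  # rare all-away exclusion
  tf <- fit_trait_models(pf$features, pf$traits, cfg)
  expect_named(tf, c("window_4h.continuous", "window_4h.binary",
                     "workday.continuous", "workday.binary"))
  fit <- tf[["workday.continuous"]]
  expect_gt(fit$betas[["sias_z"]], 0)
  expect_lt(fit$p_values[["sias_z"]], 0.05)

  # independent traits: both trait betas small
  cfg0 <- hs_config(n_participants = 30, n_days = 8, gps_interval = 600,
                    seed = 62)
  pf0 <- make_pipeline_features(cfg0)
  tf0 <- fit_trait_models(pf0$features, pf0$traits, cfg0)
  b0 <- tf0[["workday.continuous"]]$betas
  expect_lt(abs(b0[["sias_z"]]), 0.35)
  expect_lt(abs(b0[["dass_z"]]), 0.35)

  # constant trait surfaces the standardization error
  tr0 <- data.table::copy(pf$traits)[, dass_dep := 3]
  expect_error(fit_trait_models(pf$features, tr0, cfg), "dass_dep")
})

test_that("fits serialize to JSON and back", {
  cfg <- tiny_config(n_participants = 12, n_days = 6, compliance_rate = 0.7)
  pf <- make_pipeline_features(cfg)
  grid <- suppressWarnings(fit_model_grid(pf$features, pf$traits, cfg))
  expect_length(grid, 16)
  d <- withr::local_tempdir()
  write_fits(grid, file.path(d, "fits.json"))
  g2 <- read_fits(file.path(d, "fits.json"))
  expect_equal(names(g2), names(grid))
  f <- grid[["continuous.same_day.na"]]; f2 <- g2[["continuous.same_day.na"]]
  expect_equal(f2$betas, f$betas)
  expect_equal(f2$p_values, f$p_values)
  expect_equal(f2$var_subject, f$var_subject)
  expect_equal(f2$r2_fixed, f$r2_fixed)
})
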