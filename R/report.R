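# Effect-grid assembly and the significance-count binomial argument.
#
# The full analysis produces 48 effects: 2 outcome panels x 4 temporal
# framings x 6 terms (NA, NA x SIAS, NA x DASS, PA, PA x SIAS, PA x DASS).
# Rather than a Bonferroni-style correction, the count of significant
# effects is compared against chance with an exact binomial upper tail:
# under 48 independent tests at alpha = 0.05 one expects 2.4 significant
# results; P(X >= k) for X ~ Binomial(48, 0.05) quantifies surprise.

EFFECT_TERMS <- c("NA", "NA x SIAS", "NA x DASS", "PA", "PA x SIAS", "PA x DASS")

#' Assemble the 48-effect table from a fitted model grid
#'
#' Extracts the affect main effect and both trait interactions from each of
#' the 16 fits and orders them as outcome panel x framing x term. A missing
#' or duplicated cell is a hard error listing the offending cells.
#'
#' @param fits A `homestay_grid` from [fit_model_grid()] or [read_fits()].
#' @param alpha Per-test significance level for the `significant` flag.
#' @return `data.table` of class `homestay_effects` with columns `outcome`,
#'   `framing`, `term`, `beta`, `p`, `significant`; attribute `alpha`.
#' @export
assemble_effect_table <- function(fits, alpha = 0.05) {
  recs <- list()
  for (f in fits) {
    if (is.na(f$affect)) next  # trait models are reported separately
    lab <- toupper(f$affect)
    wanted <- c(affect = lab,
                `affect:sias_z` = paste(lab, "x SIAS"),
                `affect:dass_z` = paste(lab, "x DASS"))
    for (tm in names(wanted)) {
      if (!tm %in% names(f$betas)) {
        stop(sprintf("fit (%s, %s, %s) lacks term %s",
                     f$outcome, f$framing, f$affect, tm), call. = FALSE)
      }
      recs[[length(recs) + 1L]] <- data.table(
        outcome = f$outcome, framing = f$framing, term = wanted[[tm]],
        beta = unname(f$betas[tm]), p = unname(f$p_values[tm]))
    }
  }
  tab <- rbindlist(recs)
  full <- data.table(expand.grid(term = EFFECT_TERMS, framing = FRAMINGS,
                                 outcome = OUTCOMES,
                                 stringsAsFactors = FALSE))
  key <- function(d) paste(d$outcome, d$framing, d$term)
  missing <- setdiff(key(full), key(tab))
  if (length(missing)) {
    stop("missing effect cell(s): ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  if (anyDuplicated(key(tab))) {
    stop("duplicate effect cell(s): ",
         paste(unique(key(tab)[duplicated(key(tab))]), collapse = "; "),
         call. = FALSE)
  }
  tab <- tab[match(key(full), key(tab))]
  tab[, significant := as.integer(p < alpha)]
  setattr(tab, "alpha", alpha)
  setattr(tab, "class", c("homestay_effects", class(tab)))
  tab[]
}

#' Exact binomial upper tail P(X >= k)
#'
#' Direct summation of Binomial(n, p0) probabilities from k to n using the
#' stable term recurrence t_{j+1} = t_j (n-j)/(j+1) p/(1-p), seeded at the
#' smallest term in the summed range. No normal approximation: the relevant
#' counts sit in the far tail where approximations distort.
#'
#' @param n Number of trials.
#' @param k Threshold count.
#' @param p0 Per-trial success probability, in (0, 1).
#' @return P(X >= k).
#' @export
#' @examples
#' binomial_tail(48, 8, 0.05)  # ~0.00246
binomial_tail <- function(n, k, p0) {
  stopifnot(length(n) == 1, length(k) == 1, n >= 0, k >= 0, k <= n,
            p0 > 0, p0 < 1)
  if (k == 0) return(1)
  r <- p0 / (1 - p0)
  # log of P(X = k), then accumulate upward
  log_t <- lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)
  t <- exp(log_t)
  total <- t
  if (k < n) {
    for (j in k:(n - 1)) {
      t <- t * (n - j) / (j + 1) * r
      total <- total + t
    }
  }
  min(1, total)
}

#' Significance-count summary of an effect table
#'
#' @param table A `homestay_effects` table.
#' @param p0 Per-test type-I error rate.
#' @return List (`n`, `k`, `p0`, `tail_prob`) of class `homestay_binomial`.
#' @export
binomial_summary <- function(table, p0 = attr(table, "alpha")) {
  if (is.null(p0)) p0 <- 0.05
  n <- nrow(table)
  k <- sum(table$significant)
  structure(list(n = n, k = k, p0 = p0,
                 tail_prob = binomial_tail(n, k, p0)),
            class = "homestay_binomial")
}

#' @export
print.homestay_binomial <- function(x, ...) {
  cat(sprintf("%d of %d effects significant at alpha = %g; P(X >= %d) = %s\n",
              x$k, x$n, x$p0, x$k, format(x$tail_prob, digits = 6)))
  invisible(x)
}

#' Read / write an effect table as CSV
#'
#' `effects.csv` columns: `outcome,framing,term,beta,p,significant`. The
#' round trip is an identity (betas and p-values printed at full precision).
#'
#' @param table A `homestay_effects` table.
#' @param path CSV path.
#' @param alpha Significance level re-applied on read.
#' @return `path` / the table.
#' @export
write_effects <- function(table, path) {
  out <- copy(table)
  out$beta <- format(out$beta, digits = 17, scientific = FALSE, trim = TRUE)
  out$p <- format(out$p, digits = 17, scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path, alpha = 0.05) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = NULL)  # "NA" is a real term label
  check_columns(dt, c("outcome", "framing", "term", "beta", "p"), path)
  dt[, significant := as.integer(p < alpha)]
  setattr(dt, "alpha", alpha)
  setattr(dt, "class", c("homestay_effects", class(dt)))
  dt[]
}

#' Parse a published effect table with censored p-values
#'
#' Reads a Table-1-shaped CSV in which p-values may be printed as upper
#' bounds (e.g. `<.01`). A censored p counts as significant when its bound is
#' at or below alpha. The package ships the reference study's printed
#' 48-effect panel as `published_effects.csv` in `extdata`.
#'
#' @param path CSV with columns `outcome,framing,term,beta,p` (`p` possibly
#'   censored strings).
#' @param alpha Significance level.
#' @return `data.table` with numeric `p_bound`, logical `p_censored`, and
#'   `significant` flags.
#' @export
#' @examples
#' tab <- parse_published_table(
#'   system.file("extdata", "published_effects.csv", package = "homestay"))
#' sum(tab$significant)  # 8
parse_published_table <- function(path, alpha = 0.05) {
  dt <- data.table::fread(path, colClasses = list(character = "p"),
                          na.strings = NULL)
  check_columns(dt, c("outcome", "framing", "term", "beta", "p"), path)
  p_raw <- trimws(dt$p)
  censored <- startsWith(p_raw, "<")
  bound <- as.numeric(sub("^<", "", p_raw))
  if (anyNA(bound)) {
    stop("unparseable p-value(s): ",
         paste(p_raw[is.na(bound)], collapse = ", "), call. = FALSE)
  }
  dt[, `:=`(p_bound = bound, p_censored = censored,
            significant = as.integer(ifelse(censored, bound <= alpha,
                                            bound < alpha)))]
  dt[, p := NULL]
  dt[]
}

#' Render report files
#'
#' Writes `effects.csv`, `binomial.txt` (counts and the exact tail
#' probability at full precision), and - when the binary next-day fits are
#' supplied - `interaction_next_day.pdf`, the predicted next-day home
#' probability against affect at +/-1 SD of SIAS (the moderator is entered
#' continuously in the model; high/low curves are for display only).
#'
#' @param table A `homestay_effects` table.
#' @param summary A `homestay_binomial` summary.
#' @param out_dir Output directory (created if needed).
#' @param fits Optional `homestay_grid` for the interaction plot.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(table, summary, out_dir, fits = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  f1 <- file.path(out_dir, "effects.csv")
  write_effects(table, f1)
  files <- c(files, f1)
  f2 <- file.path(out_dir, "binomial.txt")
  writeLines(c(
    sprintf("n = %d", summary$n),
    sprintf("k = %d", summary$k),
    sprintf("p0 = %s", format(summary$p0, digits = 17)),
    sprintf("tail_prob = %s", format(summary$tail_prob, digits = 17))), f2)
  files <- c(files, f2)
  if (!is.null(fits)) {
    f3 <- file.path(out_dir, "interaction_next_day.pdf")
    grDevices::pdf(f3, width = 9, height = 4.5)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (af in c("na", "pa")) {
      fit <- fits[[paste("binary", "next_day", af, sep = ".")]]
      if (is.null(fit)) next
      b <- fit$betas
      aff <- seq(0, 100, length.out = 101)
      pred <- function(s) {
        plogis(b[["(Intercept)"]] + b[["affect"]] * aff + b[["sias_z"]] * s +
                 b[["affect:sias_z"]] * aff * s)
      }
      graphics::plot(aff, pred(1), type = "l", col = "red3", ylim = c(0, 1),
                     xlab = sprintf("mean %s affect (VAS)",
                                    if (af == "na") "negative" else "positive"),
                     ylab = "P(at home next day)",
                     main = sprintf("%s x social anxiety", toupper(af)))
      graphics::lines(aff, pred(-1), col = "blue3")
      graphics::legend("topright", c("SIAS +1 SD", "SIAS -1 SD"),
                       col = c("red3", "blue3"), lty = 1, bty = "n")
    }
    grDevices::dev.off()
    files <- c(files, f3)
  }
  invisible(files)
}
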