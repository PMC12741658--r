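# Cross-modal agreement statistics: per-participant aggregation, Bland-Altman
# bias and 95% limits of agreement, paired t tests, Pearson correlation with
# Fisher-z intervals, Shapiro-Wilk normality reporting and Mukaka magnitude
# classification.
#
# Sign convention: a pair "A vs B" is always A - B, so a positive onset bias
# means modality A detects sleep later than B.

#' Aggregate daily records to one summary per participant-modality
#'
#' Arithmetic means on the window-relative minute scale (wrap-safe: 23:00 and
#' 01:00 average to midnight, not noon) plus mean TST and the number of
#' contributing days.
#'
#' @param records daily records from [build_daily_records()].
#' @return data.frame: `participant`, `modality`, `mean_onset_rel`,
#'   `mean_offset_rel`, `mean_tst_min`, `n_days`, and presentation-only
#'   `onset_clock`/`offset_clock` strings.
#' @export
summarize_participants <- function(records) {
  if (!nrow(records)) {
    return(data.frame(participant = character(), modality = character(),
                      mean_onset_rel = numeric(), mean_offset_rel = numeric(),
                      mean_tst_min = numeric(), n_days = integer(),
                      onset_clock = character(), offset_clock = character()))
  }
  # \036 (record separator) cannot occur in ids, unlike "."
  key <- factor(paste(records$participant, records$modality, sep = "\036"))
  agg <- function(x) tapply(x, key, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  # tapply returns in level order of `key`; rebuild ids from the levels
  parts <- strsplit(levels(key), "\036", fixed = TRUE)
  out <- data.frame(
    participant = vapply(parts, `[`, character(1), 1),
    modality = vapply(parts, `[`, character(1), 2),
    mean_onset_rel = as.numeric(agg(records$onset_rel)),
    mean_offset_rel = as.numeric(agg(records$offset_rel)),
    mean_tst_min = as.numeric(agg(records$tst_min)),
    n_days = as.integer(tapply(rep(1L, nrow(records)), key, sum)),
    stringsAsFactors = FALSE
  )
  out$onset_clock <- ifelse(is.na(out$mean_onset_rel), NA_character_,
                            rel_min_to_clock(out$mean_onset_rel))
  out$offset_clock <- ifelse(is.na(out$mean_offset_rel), NA_character_,
                             rel_min_to_clock(out$mean_offset_rel))
  rownames(out) <- NULL
  out
}

#' Paired t test on a vector of differences
#'
#' @param d numeric differences (n >= 2, non-degenerate SD).
#' @return list `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired t test needs at least 2 differences", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("degenerate differences: zero standard deviation",
                   call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param conf confidence level (default 0.95).
#' @return list `r`, `ci` (length 2), `p` (two-sided).
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("Pearson correlation needs at least 3 pairs",
                        call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        conf.level = conf)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value)
}

#' Classify a correlation magnitude by the Mukaka bands
#'
#' `|r|` in \[0.70, 1\] is "high", \[0.50, 0.70) "moderate", \[0.30, 0.50)
#' "low", below 0.30 "negligible"; a boundary value takes the higher band.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return character vector of labels.
#' @export
classify_correlation <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  a <- abs(r)
  out <- ifelse(a >= 0.7, "high",
                ifelse(a >= 0.5, "moderate",
                       ifelse(a >= 0.3, "low", "negligible")))
  out[is.na(r)] <- NA_character_
  out
}

#' Shapiro-Wilk normality check
#'
#' Reported alongside correlations; a non-normal result never blocks the
#' analysis, it is informational.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list `W`, `p`.
#' @export
shapiro_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires 3 to 5000 observations", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are `a - b`. Mean bias, sample SD of the differences, 95%
#' limits of agreement `bias +/- 1.96 * SD`, a t-based CI for the bias, the
#' paired t test, Pearson r with Fisher-z CI and Mukaka class, and the
#' Shapiro-Wilk statistic of the differences. When all differences are equal
#' (SD 0) the limits collapse onto the bias and the t test is flagged
#' degenerate rather than computed.
#'
#' @param a,b paired numeric vectors (same participants, same order).
#' @param metric label such as "onset" (stored for reporting).
#' @param pair character 2-vector naming the modalities, `a` first.
#' @param conf confidence level for the bias CI.
#' @return object of class `bland_altman`; see Details. Component `points`
#'   holds `(mean, diff)` pairs for plotting.
#' @export
bland_altman <- function(a, b, metric = "value",
                         pair = c("A", "B"), conf = 0.95) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least 2 complete pairs",
                  call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 1)
  res <- list(
    metric = metric, pair = pair, n = n,
    mean_bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    bias_ci = bias + c(-1, 1) * tcrit * s / sqrt(n),
    degenerate = degenerate,
    points = data.frame(mean = (a + b) / 2, diff = d)
  )
  if (degenerate) {
    res[c("t", "df", "p")] <- list(NA_real_, n - 1, NA_real_)
  } else {
    res[c("t", "df", "p")] <- paired_t(d)
  }
  if (n >= 3 && !degenerate && stats::sd(a) > 0 && stats::sd(b) > 0) {
    pc <- pearson_ci(a, b, conf)
    res$r <- pc$r; res$r_ci <- pc$ci; res$r_p <- pc$p
    res$r_class <- classify_correlation(pc$r)
    sw <- tryCatch(shapiro_check(d), error = function(e) NULL)
    res$shapiro_W <- sw$W %||% NA_real_
    res$shapiro_p <- sw$p %||% NA_real_
  } else {
    res[c("r", "r_p", "shapiro_W", "shapiro_p")] <-
      list(NA_real_, NA_real_, NA_real_, NA_real_)
    res$r_ci <- c(NA_real_, NA_real_)
    res$r_class <- NA_character_
  }
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement: %s, %s vs %s (n = %d)\n",
              x$metric, x$pair[1], x$pair[2], x$n))
  cat(sprintf("  bias %.2f (SD %.2f), 95%% CI [%.2f, %.2f]\n",
              x$mean_bias, x$sd_diff, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  95%% LoA [%.2f, %.2f]\n", x$loa_low, x$loa_high))
  if (x$degenerate) {
    cat("  all differences identical; t test degenerate\n")
  } else {
    cat(sprintf("  paired t = %.2f (df %d), p = %.3g\n", x$t, x$df, x$p))
  }
  if (!is.na(x$r)) {
    cat(sprintf("  Pearson r = %.2f [%.2f, %.2f] (%s), p = %.3g\n",
                x$r, x$r_ci[1], x$r_ci[2], x$r_class, x$r_p))
  }
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = sprintf("Mean of %s and %s", x$pair[1], x$pair[2]),
                 ylab = sprintf("%s - %s", x$pair[1], x$pair[2]),
                 main = sprintf("Bland-Altman: %s", x$metric), ...)
  graphics::abline(h = x$mean_bias, col = "red", lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "darkgreen", lty = 2)
  invisible(x)
}

ba_row <- function(x, group) {
  data.frame(
    metric = x$metric, pair = paste(x$pair, collapse = " vs "),
    group = group, n = x$n, mean_bias = x$mean_bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    bias_ci_low = x$bias_ci[1], bias_ci_high = x$bias_ci[2],
    t = x$t, df = x$df, p = x$p,
    r = x$r, r_ci_low = x$r_ci[1], r_ci_high = x$r_ci[2], r_p = x$r_p,
    r_class = x$r_class %||% NA_character_,
    shapiro_W = x$shapiro_W, shapiro_p = x$shapiro_p,
    stringsAsFactors = FALSE
  )
}

AGREEMENT_PAIRS <- list(
  onset = list(c("actigraph", "bed"), c("smartphone", "bed"),
               c("actigraph", "smartphone")),
  offset = list(c("actigraph", "bed"), c("smartphone", "bed"),
                c("actigraph", "smartphone")),
  tst = list(c("actigraph", "bed"), c("actigraph", "smartphone"),
             c("actigraph", "ema"), c("ema", "bed"), c("ema", "smartphone"),
             c("smartphone", "bed"))
)

metric_column <- c(onset = "mean_onset_rel", offset = "mean_offset_rel",
                   tst = "mean_tst_min")
metric_column_day <- c(onset = "onset_rel", offset = "offset_rel",
                       tst = "tst_min")

#' Full grid of pairwise agreement statistics, overall and by group
#'
#' Computes one [bland_altman()] per metric (onset, offset, TST) x modality
#' pair x group (`all`, `control`, `patients`), on participant-level averages
#' by default (pairwise-complete: a participant enters a comparison only with
#' both modalities present). EMA enters the TST comparisons only. Groups or
#' pairs with fewer than 2 complete participants are skipped with a warning.
#'
#' @param records daily records from [build_daily_records()].
#' @param demographics data.frame with `participant` and `group`
#'   (`control`/`MDD`/`BD`/`BPD`).
#' @param level `"participant"` (default, aggregate first) or `"day"`
#'   (pair day-level rows on participant + study day).
#' @return list: `table` (one row per comparison) and `objects` (the named
#'   `bland_altman` objects, for plotting).
#' @export
agreement_by_group <- function(records, demographics,
                               level = c("participant", "day")) {
  level <- match.arg(level)
  grp <- stats::setNames(demographics$group, demographics$participant)
  groups <- list(all = unique(demographics$participant),
                 control = demographics$participant[grp == "control"],
                 patients = demographics$participant[grp != "control"])
  base <- if (level == "participant") summarize_participants(records)
  else records
  cols <- if (level == "participant") metric_column else metric_column_day
  rows <- list(); objects <- list()
  for (metric in names(AGREEMENT_PAIRS)) {
    for (pair in AGREEMENT_PAIRS[[metric]]) {
      da <- base[base$modality == pair[1], , drop = FALSE]
      db <- base[base$modality == pair[2], , drop = FALSE]
      join_cols <- if (level == "participant") "participant"
      else c("participant", "study_day")
      m <- merge(da, db, by = join_cols, suffixes = c(".a", ".b"))
      for (gname in names(groups)) {
        gm <- m[m$participant %in% groups[[gname]], , drop = FALSE]
        va <- gm[[paste0(cols[[metric]], ".a")]]
        vb <- gm[[paste0(cols[[metric]], ".b")]]
        ok <- stats::complete.cases(va, vb)
        if (sum(ok) < 2) {
          warning("skipping ", metric, " ", paste(pair, collapse = " vs "),
                  " for group '", gname, "': fewer than 2 complete pairs",
                  call. = FALSE)
          next
        }
        ba <- bland_altman(va[ok], vb[ok], metric = metric, pair = pair)
        key <- paste(metric, paste(pair, collapse = "_"), gname, sep = ".")
        objects[[key]] <- ba
        rows[[key]] <- ba_row(ba, gname)
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       objects = objects)
}
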