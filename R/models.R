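# Mixed-effects analysis of day-level alignment: the absolute between-modality
# difference (in hours) is modelled with a participant random intercept and
# age, sex, chronotype (MEQ), diagnostic group and seasonal day-length fixed
# effects. Variance components give the ICC; marginal and conditional R2
# follow the Nakagawa variance-partition definitions.

#' Build the day-level model table for one metric and modality pair
#'
#' Inner-joins the two modalities' daily records on participant and study
#' day (a day present in only one modality is excluded), takes the absolute
#' difference of the metric in hours, and attaches demographics plus the
#' day length of the wake-up morning (study day + 1).
#'
#' @param records daily records from [build_daily_records()].
#' @param demographics data.frame: `participant`, `age`, `sex`, `meq`,
#'   `group`.
#' @param metric `"onset"`, `"offset"` or `"tst"`.
#' @param pair character 2-vector of modalities (EMA allowed for `tst`).
#' @param latitude,longitude location for the daylight covariate.
#' @param daylight_scale `"h"` (default; per-hour day length, the scale on
#'   which the printed coefficient magnitudes are physically plausible) or
#'   `"min"`.
#' @return data.frame: `participant`, `study_day`, `abs_diff` (hours),
#'   `age`, `sex`, `meq`, `daylight`, `group` (factor, control reference).
#' @export
build_model_table <- function(records, demographics, metric, pair,
                              latitude = 60.17, longitude = 24.94,
                              daylight_scale = c("h", "min")) {
  daylight_scale <- match.arg(daylight_scale)
  col <- metric_column_day[[match.arg(metric, names(metric_column_day))]]
  a <- records[records$modality == pair[1], c("participant", "study_day", col)]
  b <- records[records$modality == pair[2], c("participant", "study_day", col)]
  m <- merge(a, b, by = c("participant", "study_day"),
             suffixes = c(".a", ".b"))
  out <- data.frame(
    participant = m$participant, study_day = m$study_day,
    abs_diff = abs(m[[paste0(col, ".a")]] - m[[paste0(col, ".b")]]) / 60,
    stringsAsFactors = FALSE
  )
  dl <- day_length(out$study_day + 1L, latitude, longitude)
  out$daylight <- if (daylight_scale == "h") dl / 60 else dl
  dem <- demographics[c("participant", "age", "sex", "meq", "group")]
  out <- merge(out, dem, by = "participant")
  out$sex <- factor(out$sex, levels = c("male", "female"))
  out$group <- factor(out$group,
                      levels = c("control",
                                 intersect(c("MDD", "BD", "BPD"),
                                           unique(out$group))))
  out[order(out$participant, out$study_day), , drop = FALSE]
}

#' Fit the random-intercept alignment model
#'
#' REML fit of `abs_diff ~ age + sex + meq + daylight + group +
#' (1 | participant)` via \pkg{lme4} (terms present in `data` only). Wald
#' normal 95% CIs and p-values are reported for the fixed effects -- simple
#' and deterministic, matching an "estimate (95% CI)" presentation.
#' A singular fit (participant variance estimated at zero) is returned with
#' `singular = TRUE`, not an error.
#'
#' @param data model table from [build_model_table()] (or any data.frame with
#'   `abs_diff`, `participant` and the predictors).
#' @param formula fixed-effects formula; the participant random intercept is
#'   added automatically.
#' @param conf confidence level for the Wald intervals.
#' @return object of class `alignment_model`: `coefficients` (estimate, se,
#'   ci_low, ci_high, p per term), `sigma2`, `tau00`, `icc`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_participants`, `singular`, and the
#'   underlying `fit`.
#' @export
fit_alignment_model <- function(data,
                                formula = abs_diff ~ age + sex + meq +
                                  daylight + group,
                                conf = 0.95) {
  if (length(unique(data$participant)) < 2) {
    stop("mixed model needs at least 2 participants", call. = FALSE)
  }
  full <- stats::update(formula, . ~ . + (1 | participant))
  # singularity is reported through the `singular` flag, not a warning
  fit <- withCallingHandlers(
    lme4::lmer(full, data = data, REML = TRUE),
    warning = function(w) {
      if (grepl("singular|boundary", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) {
      if (grepl("singular|boundary", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    })
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    ci_low = unname(beta - z * se), ci_high = unname(beta + z * se),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE
  )
  vc <- lme4::VarCorr(fit)
  tau00 <- as.numeric(vc$participant)
  sigma2 <- stats::sigma(fit)^2
  r2 <- r2_nakagawa(fit)
  res <- list(
    coefficients = coefs, sigma2 = sigma2, tau00 = tau00,
    icc = icc(sigma2, tau00),
    r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
    n_obs = stats::nobs(fit),
    n_participants = lme4::ngrps(fit)[["participant"]],
    singular = lme4::isSingular(fit),
    formula = full, fit = fit
  )
  class(res) <- "alignment_model"
  res
}

#' Intraclass correlation from variance components
#'
#' Share of outcome variance attributable to stable between-participant
#' differences in a random-intercept model: `tau00 / (tau00 + sigma2)`.
#'
#' @param sigma2 residual variance (> 0).
#' @param tau00 participant intercept variance (>= 0).
#' @return numeric in \[0, 1\].
#' @export
icc <- function(sigma2, tau00) {
  stopifnot(all(sigma2 > 0), all(tau00 >= 0))
  tau00 / (tau00 + sigma2)
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a Gaussian random-intercept model: with `var_f` the variance of the
#' fixed-effect predictions, marginal R2 is
#' `var_f / (var_f + tau00 + sigma2)` and conditional R2 is
#' `(var_f + tau00) / (var_f + tau00 + sigma2)`.
#'
#' @param fit an `lmerMod` or an `alignment_model`.
#' @return named numeric: `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "alignment_model")) fit <- fit$fit
  var_f <- stats::var(as.vector(stats::model.matrix(fit) %*%
                                  lme4::fixef(fit)))
  tau00 <- as.numeric(lme4::VarCorr(fit)$participant)
  sigma2 <- stats::sigma(fit)^2
  tot <- var_f + tau00 + sigma2
  c(marginal = var_f / tot, conditional = (var_f + tau00) / tot)
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("Alignment mixed model (%d obs, %d participants%s)\n",
              x$n_obs, x$n_participants,
              if (x$singular) "; singular fit" else ""))
  cf <- x$coefficients
  cat(sprintf("  %-14s %9s [%7s, %7s] %8s\n",
              "term", "estimate", "lo", "hi", "p"))
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-14s %9.3f [%7.3f, %7.3f] %8.3g\n", cf$term[i],
                cf$estimate[i], cf$ci_low[i], cf$ci_high[i], cf$p[i]))
  }
  cat(sprintf("  sigma2 %.3f  tau00 %.3f  ICC %.2f  R2 %.3f/%.3f\n",
              x$sigma2, x$tau00, x$icc, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.alignment_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.alignment_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Fit the full grid of alignment models
#'
#' One model per metric x sensor pair (onset, offset, TST x
#' actigraph-bed, smartphone-bed, actigraph-smartphone), nine in total.
#' Pairs whose joined table has fewer than 2 participants with repeated days
#' are skipped with a warning.
#'
#' @inheritParams build_model_table
#' @return named list of `alignment_model` objects
#'   (`"<metric>.<modA>_<modB>"`).
#' @export
fit_all_alignment_models <- function(records, demographics,
                                     latitude = 60.17, longitude = 24.94,
                                     daylight_scale = "h") {
  pairs <- list(c("actigraph", "bed"), c("smartphone", "bed"),
                c("actigraph", "smartphone"))
  out <- list()
  for (metric in c("tst", "offset", "onset")) {
    for (pair in pairs) {
      tab <- build_model_table(records, demographics, metric, pair,
                               latitude, longitude, daylight_scale)
      key <- paste0(metric, ".", paste(pair, collapse = "_"))
      if (length(unique(tab$participant)) < 2 || nrow(tab) < 10) {
        warning("skipping model ", key, ": insufficient data", call. = FALSE)
        next
      }
      out[[key]] <- fit_alignment_model(tab)
    }
  }
  out
}
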