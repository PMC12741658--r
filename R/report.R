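# Orchestration and reporting: run simulate -> ingest -> derive -> agree ->
# model end to end, export the publication-shaped tables, and account for
# every removed row in a run manifest.

#' Round half away from zero to a fixed number of decimals
#'
#' Display-only rounding (0.3396 renders as "0.34", -0.005 as "-0.01");
#' CSV outputs keep full precision.
#'
#' @param x numeric.
#' @param digits decimals (default 2).
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Descriptive table of mean sleep parameters by modality and group
#'
#' Participant-level means aggregated to group level: mean and SD of onset
#' and offset (clock-rendered from window-relative minutes) and of TST, per
#' modality and group (controls vs pooled patients).
#'
#' @param records daily records from [build_daily_records()].
#' @param demographics demographics table with `participant`, `group`.
#' @return data.frame, one row per parameter x group x modality.
#' @export
descriptive_table <- function(records, demographics) {
  ps <- summarize_participants(records)
  grp <- stats::setNames(demographics$group, demographics$participant)
  ps$group <- ifelse(grp[ps$participant] == "control", "control", "patients")
  rows <- list()
  specs <- list(onset = "mean_onset_rel", offset = "mean_offset_rel",
                tst = "mean_tst_min")
  for (param in names(specs)) {
    for (g in c("control", "patients")) {
      for (m in c("bed", "actigraph", "smartphone", "ema")) {
        v <- ps[ps$group == g & ps$modality == m, specs[[param]]]
        v <- v[!is.na(v)]
        if (!length(v)) next
        if (param == "tst") {
          mm <- mean(v)
          val <- sprintf("%d h %d min", floor(mm / 60), round(mm %% 60))
        } else {
          val <- rel_min_to_clock(mean(v))
        }
        rows[[length(rows) + 1]] <- data.frame(
          parameter = param, group = g, modality = m, n = length(v),
          mean = val, sd_min = round_half_up(stats::sd(v), 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export publication-shaped result tables
#'
#' Writes `descriptives.csv` (modality x group means), `agreement.csv` (one
#' row per metric x pair x group with all Bland-Altman fields),
#' `bland_altman_points.csv`, `models.csv` (one row per model x term) and
#' `model_variance.csv` (sigma2, tau00, ICC, marginal/conditional R2).
#' Display rounding is half-up to 2 decimals only in the `*_2dp` columns;
#' raw precision is preserved elsewhere.
#'
#' @param results result list from [run_full_analysis()] (components
#'   `records`, `demographics`, `agreement`, `models`).
#' @param out_dir output directory.
#' @return invisibly, the files written.
#' @export
export_paper_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path)
    files <<- c(files, path)
  }
  w(descriptive_table(results$records, results$demographics),
    "descriptives.csv")
  agr <- results$agreement$table
  agr$mean_bias_2dp <- fmt2(agr$mean_bias)
  agr$r_2dp <- ifelse(is.na(agr$r), NA, fmt2(agr$r))
  w(agr, "agreement.csv")
  pts <- do.call(rbind, lapply(names(results$agreement$objects), function(k) {
    o <- results$agreement$objects[[k]]
    cbind(comparison = k, o$points)
  }))
  w(pts, "bland_altman_points.csv")
  if (length(results$models)) {
    coefs <- do.call(rbind, lapply(names(results$models), function(k) {
      cf <- results$models[[k]]$coefficients
      cbind(model = k, cf,
            estimate_2dp = fmt2(cf$estimate),
            ci_2dp = sprintf("%s to %s", fmt2(cf$ci_low), fmt2(cf$ci_high)))
    }))
    w(coefs, "models.csv")
    vars <- do.call(rbind, lapply(names(results$models), function(k) {
      m <- results$models[[k]]
      data.frame(model = k, sigma2 = m$sigma2, tau00 = m$tau00,
                 icc = m$icc, icc_2dp = fmt2(m$icc),
                 r2_marginal = m$r2_marginal,
                 r2_conditional = m$r2_conditional,
                 n_obs = m$n_obs, n_participants = m$n_participants,
                 singular = m$singular)
    }))
    w(vars, "model_variance.csv")
  }
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Either simulates a cohort (when `config` is given) or reads raw streams
#' from `input_dir`, then ingests, derives daily records, computes the
#' agreement grid and fits the nine alignment models, writes all stage
#' outputs and a run manifest accounting for every removed row.
#'
#' @param config a [cohort_config()]; when supplied the cohort is simulated
#'   and its streams are round-tripped through CSV and [read_stream_dir()]
#'   so the run exercises the same path as real exports.
#' @param input_dir directory of raw stream CSVs (used when `config` is
#'   `NULL`).
#' @param out_dir output directory.
#' @param gap_threshold_min,tst_range_h,outlier_k derivation parameters, see
#'   [build_daily_records()].
#' @param daylight_scale `"h"` or `"min"`, see [build_model_table()].
#' @param fit_models set `FALSE` to skip the mixed models.
#' @return invisibly, a list: `manifest`, `records`, `demographics`,
#'   `agreement`, `models`, `files`.
#' @export
run_full_analysis <- function(config = NULL, input_dir = NULL,
                              out_dir = tempfile("somnalign_run"),
                              gap_threshold_min = 5, tst_range_h = c(3, 13),
                              outlier_k = 2, daylight_scale = "h",
                              fit_models = TRUE) {
  if (is.null(config) && is.null(input_dir)) {
    stop("supply either a cohort config (simulate) or an input directory",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config)) {
    sim <- simulate_cohort(config)
    raw_dir <- file.path(out_dir, "raw")
    write_cohort_csv(sim, raw_dir)
    input_dir <- raw_dir
  }
  ing <- read_stream_dir(input_dir)
  if (is.null(ing$demographics)) {
    stop("demographics.csv is required for agreement and models",
         call. = FALSE)
  }
  raw_counts <- vapply(ing$streams, nrow, integer(1))
  records <- build_daily_records(ing$streams,
                                 gap_threshold_min = gap_threshold_min,
                                 tst_range_h = tst_range_h,
                                 outlier_k = outlier_k)
  daily_out <- records
  daily_out$onset <- format_instants(daily_out$onset)
  daily_out$offset <- format_instants(daily_out$offset)
  data.table::fwrite(daily_out, file.path(out_dir, "daily_sleep.csv"))
  agreement <- agreement_by_group(records, ing$demographics)
  models <- if (fit_models) {
    fit_all_alignment_models(records, ing$demographics,
                             daylight_scale = daylight_scale)
  } else list()
  results <- list(records = records, demographics = ing$demographics,
                  agreement = agreement, models = models)
  files <- export_paper_tables(results, out_dir)
  attrition <- attr(records, "attrition")
  cfg_json <- jsonlite::toJSON(
    if (is.null(config)) list(input_dir = input_dir)
    else config[setdiff(names(config), "params")],
    auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    tool_version = as.character(utils::packageVersion("somnalign")),
    config_hash = unname(tools::md5sum(tf)),
    seed = if (!is.null(config)) config$seed else NA,
    rows_in = as.list(raw_counts),
    rows_dropped_incomplete = as.list(ing$dropped),
    attrition = attrition,
    daily_records = nrow(records),
    files = c(file.path(out_dir, "daily_sleep.csv"), files)
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(list(manifest = manifest, files = manifest$files), results))
}
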