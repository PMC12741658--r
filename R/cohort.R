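# Synthetic cohort generator: participants with group-dependent sleep timing,
# nightly ground-truth sleep intervals, and renderers that turn each truth
# into the four raw device streams (actigraph epoch labels, 1 Hz bed status,
# screen events, categorical morning reports) with device-specific systematic
# biases, night-level noise and Bernoulli missingness.
#
# Defaults live in inst/extdata/cohort_defaults.json and mirror the magnitudes
# of the published descriptive tables: controls fall asleep around 23:55 and
# sleep ~7.6 h, patient groups ~35-45 min later with larger night-to-night
# spread; the actigraph wakes ~30 min late and the smartphone ~38 min early
# relative to the bed sensor, with near-zero onset biases.

MODALITIES <- c("actigraph", "bed", "smartphone", "ema")
PATIENT_GROUPS <- c("MDD", "BD", "BPD")

#' Default synthetic-cohort parameters
#'
#' Reads the parameter file shipped with the package. Any element can be
#' overridden by modifying the returned list before passing it to
#' [cohort_config()].
#' @return nested list of generator parameters.
#' @export
cohort_defaults <- function() {
  path <- system.file("extdata", "cohort_defaults.json", package = "somnalign")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Configuration for a synthetic cohort
#'
#' @param n_controls number of healthy controls (default 50, the published
#'   cohort's control count).
#' @param n_patients_by_group named counts for the `MDD`, `BD` and `BPD`
#'   diagnostic groups (defaults 78/21/20).
#' @param study_start_date first study day (date of the first 15:00 window
#'   start).
#' @param n_days nights per participant (default 14, the active phase length).
#' @param latitude,longitude coordinates for the daylight term (default
#'   Helsinki).
#' @param seed integer RNG seed; a fixed seed makes [generate_cohort()] and
#'   the renderers byte-identical across runs.
#' @param params parameter list as from [cohort_defaults()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 50,
                          n_patients_by_group = c(MDD = 78, BD = 21, BPD = 20),
                          study_start_date = as.Date("2019-01-07"),
                          n_days = 14,
                          latitude = 60.17, longitude = 24.94,
                          seed = 1L,
                          params = cohort_defaults()) {
  n_patients_by_group <- n_patients_by_group[PATIENT_GROUPS]
  names(n_patients_by_group) <- PATIENT_GROUPS
  n_patients_by_group[is.na(n_patients_by_group)] <- 0
  stopifnot(n_controls >= 0, all(n_patients_by_group >= 0), n_days >= 1)
  structure(list(
    n_controls = as.integer(n_controls),
    n_patients_by_group = as.integer(n_patients_by_group) |>
      stats::setNames(PATIENT_GROUPS),
    study_start_date = as.Date(study_start_date),
    n_days = as.integer(n_days),
    latitude = latitude, longitude = longitude,
    seed = as.integer(seed),
    params = params
  ), class = "cohort_config")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate participant profiles and nightly ground truth
#'
#' Draws one profile per participant (group, age, sex, MEQ chronotype score,
#' personal mean onset/TST and night-to-night SDs) and one ground-truth night
#' per participant-day. Nightly onset and duration are Gaussian around the
#' participant's means; the true offset is additionally shifted by a seasonal
#' daylight term, `coef * (day length in hours - 12)`, so long summer days
#' pull wake-up earlier under the default negative coefficient. Onset and
#' offset are snapped to the 30-second actigraph grid so that a zero-noise
#' round trip through rendering and derivation is exact. Each night also
#' carries realized per-device onset/offset shifts (systematic bias plus
#' night-level Gaussian noise) and Bernoulli missingness flags per modality.
#'
#' @param config a [cohort_config()].
#' @return list with `profiles` (one row per participant) and `truths` (one
#'   row per participant-night: `onset`, `offset`, `tst_min`, per-device
#'   `*_onset_shift`/`*_offset_shift` in minutes, `missing_*` flags).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  p <- config$params
  groups <- c(rep("control", config$n_controls),
              rep(PATIENT_GROUPS, config$n_patients_by_group))
  n <- length(groups)
  if (n == 0) {
    return(list(profiles = data.frame(participant = character(),
                                      group = character(), age = numeric(),
                                      sex = character(), meq = numeric()),
                truths = data.frame()))
  }
  dem <- p$demographics
  profiles <- data.frame(
    participant = sprintf("P%03d", seq_len(n)),
    group = groups,
    age = round(clamp(stats::rnorm(n, dem$age_mean, dem$age_sd),
                      dem$age_min, dem$age_max)),
    sex = ifelse(stats::runif(n) < dem$prop_female, "female", "male"),
    meq = round(clamp(stats::rnorm(n, dem$meq_mean, dem$meq_sd), 16, 86)),
    stringsAsFactors = FALSE
  )
  gt <- p$group_timing
  profiles$mean_onset_min <- NA_real_
  profiles$sd_onset_min <- NA_real_
  profiles$mean_tst_min <- NA_real_
  profiles$sd_tst_min <- NA_real_
  for (g in names(gt)) {
    idx <- profiles$group == g
    ng <- sum(idx)
    if (!ng) next
    profiles$mean_onset_min[idx] <-
      stats::rnorm(ng, gt[[g]]$onset_mean_min, gt[[g]]$onset_between_sd)
    profiles$sd_onset_min[idx] <- gt[[g]]$onset_within_sd
    profiles$mean_tst_min[idx] <-
      clamp(stats::rnorm(ng, gt[[g]]$tst_mean_min, gt[[g]]$tst_between_sd),
            240, 720)
    profiles$sd_tst_min[idx] <- gt[[g]]$tst_within_sd
  }

  days <- config$study_start_date + seq_len(config$n_days) - 1L
  truths <- data.frame(
    participant = rep(profiles$participant, each = config$n_days),
    group = rep(profiles$group, each = config$n_days),
    study_day = rep(days, times = n)
  )
  i <- match(truths$participant, profiles$participant)
  nt <- nrow(truths)
  onset_rel <- clamp(stats::rnorm(nt, profiles$mean_onset_min[i],
                                  profiles$sd_onset_min[i]), 60, 1320)
  tst <- clamp(stats::rnorm(nt, profiles$mean_tst_min[i],
                            profiles$sd_tst_min[i]), 60, 840)
  dl_h <- day_length(truths$study_day + 1L, config$latitude,
                     config$longitude) / 60
  offset_rel <- clamp(onset_rel + tst +
                        p$daylight_offset_coef_min_per_h * (dl_h - 12),
                      onset_rel + 30, 1435)
  # snap to the 30-s actigraph grid
  onset_rel <- round(onset_rel * 2) / 2
  offset_rel <- round(offset_rel * 2) / 2
  ws <- study_day_start(truths$study_day)
  truths$onset <- ws + onset_rel * 60
  truths$offset <- ws + offset_rel * 60
  truths$tst_min <- offset_rel - onset_rel

  for (dev in c("actigraph", "bed", "smartphone")) {
    b <- p$device_bias[[dev]]
    truths[[paste0(dev, "_onset_shift")]] <-
      b$onset_min + stats::rnorm(nt, 0, b$night_sd_min)
    truths[[paste0(dev, "_offset_shift")]] <-
      b$offset_min + stats::rnorm(nt, 0, b$night_sd_min)
  }
  for (m in MODALITIES) {
    truths[[paste0("missing_", m)]] <-
      stats::runif(nt) < p$missing_prob[[m]]
  }
  list(profiles = profiles, truths = truths)
}

biased_interval <- function(truths, device) {
  on <- truths$onset + truths[[paste0(device, "_onset_shift")]] * 60
  off <- truths$offset + truths[[paste0(device, "_offset_shift")]] * 60
  off <- pmax(off, on + 60)  # degenerate shifts: keep at least one minute
  list(on = on, off = off)
}

#' Render actigraph epoch labels for ground-truth nights
#'
#' Produces a 30-second epoch grid covering each night's full 3 PM-to-3 PM
#' window. Epochs whose start falls inside the device-biased sleep interval
#' (half-open) are labelled `REST-S`; other epochs are drawn from
#' `ACTIVE`/`REST`. Optional mid-sleep interruptions of configurable length
#' are relabelled `ACTIVE`, which exercises the downstream 5-minute gap rule.
#' Nights flagged missing for the actigraph are skipped.
#'
#' @param truths ground-truth rows from [generate_cohort()] (or a compatible
#'   data frame); columns `actigraph_onset_shift`/`_offset_shift` default to 0
#'   when absent.
#' @param noise_params list: `p_rest` probability a non-sleep epoch reads
#'   `REST`; `interruption_rate` expected interruptions per night (Poisson);
#'   `interruption_min` interruption length in minutes.
#' @return data.frame `participant`, `timestamp` (POSIXct), `label`.
#' @export
render_actigraph <- function(truths,
                             noise_params = list(p_rest = 0.25,
                                                 interruption_rate = 0,
                                                 interruption_min = 4)) {
  truths <- fill_shift_cols(truths, "actigraph")
  keep <- !isTRUE_col(truths, "missing_actigraph")
  truths <- truths[keep, , drop = FALSE]
  if (!nrow(truths)) return(empty_stream("label"))
  iv <- biased_interval(truths, "actigraph")
  ws <- study_day_start(truths$study_day)
  per_night <- lapply(seq_len(nrow(truths)), function(k) {
    tt <- as.numeric(ws[k]) + seq(0, 86400 - 30, by = 30)
    asleep <- tt >= as.numeric(iv$on[k]) & tt < as.numeric(iv$off[k])
    lab <- ifelse(asleep, "REST-S",
                  ifelse(stats::runif(length(tt)) < noise_params$p_rest,
                         "REST", "ACTIVE"))
    n_int <- if (noise_params$interruption_rate > 0)
      stats::rpois(1, noise_params$interruption_rate) else 0L
    if (n_int > 0 && any(asleep)) {
      sl <- range(which(asleep))
      for (j in seq_len(n_int)) {
        st <- sample(sl[1]:sl[2], 1)
        en <- min(sl[2], st + noise_params$interruption_min * 2 - 1)
        lab[st:en] <- "ACTIVE"
      }
    }
    data.table::data.table(participant = truths$participant[k],
                           timestamp = tt, label = lab)
  })
  out <- as.data.frame(data.table::rbindlist(per_night))
  out$timestamp <- .POSIXct(out$timestamp, tz = HELSINKI_TZ)
  out
}

#' Render 1 Hz bed-sensor status for ground-truth nights
#'
#' Emits one status sample per second over a coverage window spanning the
#' device-biased sleep interval plus a margin (the sensor reports nothing
#' useful while the bed is empty, and a full 24 h at 1 Hz would be needlessly
#' heavy). Status is `1` (asleep) inside the biased interval, `2` (awake in
#' bed) during in-bed margins directly before and after, `0` elsewhere, with
#' optional mid-sleep `3` (signal overload) bursts.
#'
#' @param truths as for [render_actigraph()].
#' @param noise_params list: `margin_min` coverage margin around the biased
#'   interval; `in_bed_min` minutes of status `2` before onset and after
#'   offset; `overload_rate` expected overload bursts per night;
#'   `overload_min` burst length.
#' @return data.frame `participant`, `timestamp`, `status` (integer).
#' @export
render_bed <- function(truths,
                       noise_params = list(margin_min = 45, in_bed_min = 10,
                                           overload_rate = 0,
                                           overload_min = 3)) {
  truths <- fill_shift_cols(truths, "bed")
  keep <- !isTRUE_col(truths, "missing_bed")
  truths <- truths[keep, , drop = FALSE]
  if (!nrow(truths)) return(empty_stream("status"))
  iv <- biased_interval(truths, "bed")
  per_night <- lapply(seq_len(nrow(truths)), function(k) {
    on <- as.numeric(iv$on[k]); off <- as.numeric(iv$off[k])
    t0 <- floor(on - noise_params$margin_min * 60)
    t1 <- ceiling(off + noise_params$margin_min * 60)
    tt <- seq(t0, t1 - 1)
    st <- integer(length(tt))
    st[tt >= on - noise_params$in_bed_min * 60 & tt < on] <- 2L
    st[tt >= off & tt < off + noise_params$in_bed_min * 60] <- 2L
    st[tt >= on & tt < off] <- 1L
    n_ov <- if (noise_params$overload_rate > 0)
      stats::rpois(1, noise_params$overload_rate) else 0L
    if (n_ov > 0) {
      sl <- which(st == 1L)
      for (j in seq_len(n_ov)) {
        a <- sample(sl, 1)
        b <- min(max(sl), a + noise_params$overload_min * 60 - 1)
        st[a:b] <- 3L
      }
    }
    data.table::data.table(participant = truths$participant[k],
                           timestamp = tt, status = st)
  })
  out <- as.data.frame(data.table::rbindlist(per_night))
  out$timestamp <- .POSIXct(out$timestamp, tz = HELSINKI_TZ)
  out
}

#' Render smartphone screen events for ground-truth nights
#'
#' The phone locks at the device-biased onset and unlocks at the biased
#' offset. Daytime use is simulated as unlock-lock bouts with exponential
#' inter-bout gaps before onset and after offset within the night's window;
#' the final evening bout ends exactly at the biased onset (the user checks
#' the phone, then puts it away for the night).
#'
#' @param truths as for [render_actigraph()].
#' @param usage_params list: `bout_gap_min` mean minutes between daytime
#'   bouts (exponential; `Inf` disables daytime use), `bout_dur_min` mean
#'   bout duration (exponential, floored at 6 min -- daytime sessions must
#'   typically exceed the downstream 5-minute gap-merge threshold, otherwise
#'   the whole evening chains into one inactivity interval).
#' @return data.frame `participant`, `timestamp`, `event` in
#'   `on/off/lock/unlock`, strictly time-ordered within participant.
#' @export
render_screen <- function(truths,
                          usage_params = list(bout_gap_min = 45,
                                              bout_dur_min = 12)) {
  truths <- fill_shift_cols(truths, "smartphone")
  keep <- !isTRUE_col(truths, "missing_smartphone")
  truths <- truths[keep, , drop = FALSE]
  if (!nrow(truths)) return(empty_stream("event"))
  iv <- biased_interval(truths, "smartphone")
  ws <- study_day_start(truths$study_day)
  bouts_between <- function(t0, t1) {
    if (!is.finite(usage_params$bout_gap_min) || t1 <= t0) {
      return(data.frame(t = numeric(), e = character()))
    }
    t <- t0; out_t <- numeric(); out_e <- character()
    repeat {
      t <- t + stats::rexp(1, 1 / (usage_params$bout_gap_min * 60))
      if (t >= t1) break
      dur <- max(360, stats::rexp(1, 1 / (usage_params$bout_dur_min * 60)))
      out_t <- c(out_t, t, min(t + dur, t1 - 1))
      out_e <- c(out_e, "unlock", "lock")
      t <- t + dur
    }
    data.frame(t = out_t, e = out_e)
  }
  per_night <- lapply(seq_len(nrow(truths)), function(k) {
    on <- as.numeric(iv$on[k]); off <- as.numeric(iv$off[k])
    w0 <- as.numeric(ws[k]); w1 <- w0 + 86400
    # the last evening check must outlast the downstream 5-min merge rule or
    # evening idle time would chain into the night interval
    presleep <- if (is.finite(usage_params$bout_gap_min)) {
      data.frame(t = c(on - 600, on), e = c("unlock", "lock"))
    } else {
      data.frame(t = on, e = "lock")
    }
    ev <- rbind(
      bouts_between(w0, on - 660),
      presleep,
      data.frame(t = off, e = "unlock"),
      bouts_between(off + 60, w1)
    )
    ev <- ev[order(ev$t), ]
    data.table::data.table(participant = truths$participant[k],
                           timestamp = ev$t, event = ev$e)
  })
  out <- as.data.frame(data.table::rbindlist(per_night))
  out$timestamp <- .POSIXct(round(out$timestamp), tz = HELSINKI_TZ)
  out
}

#' Render categorical morning sleep reports
#'
#' Perceived total sleep time is the true duration plus Gaussian
#' misperception noise, then binned into the seven response categories
#' ("under 5 hours", "5-6 hours", ..., "over 10 hours"; bins half-open on the
#' right, so exactly 6 h reads "6-7 hours").
#'
#' @param truths as for [render_actigraph()].
#' @param misperception_sd Gaussian SD of the misperception, minutes.
#' @return data.frame `participant`, `date` (study day of the night) and
#'   `category`.
#' @export
render_ema <- function(truths, misperception_sd = 40) {
  truths <- fill_shift_cols(truths, "bed")
  keep <- !isTRUE_col(truths, "missing_ema")
  truths <- truths[keep, , drop = FALSE]
  if (!nrow(truths)) {
    return(data.frame(participant = character(), date = as.Date(character()),
                      category = character()))
  }
  perceived_h <- (truths$tst_min +
                    stats::rnorm(nrow(truths), 0, misperception_sd)) / 60
  data.frame(participant = truths$participant,
             date = truths$study_day,
             category = bin_tst_hours(perceived_h),
             stringsAsFactors = FALSE)
}

#' Bin perceived sleep duration into the seven report categories
#' @param hours numeric vector of perceived total sleep time in hours.
#' @return character vector of categories.
#' @export
bin_tst_hours <- function(hours) {
  as.character(cut(hours, breaks = c(-Inf, 5:10, Inf),
                   labels = EMA_CATEGORIES, right = FALSE))
}

fill_shift_cols <- function(truths, device) {
  for (col in paste0(device, c("_onset_shift", "_offset_shift"))) {
    if (is.null(truths[[col]])) truths[[col]] <- 0
  }
  if (is.null(truths$study_day)) {
    truths$study_day <- assign_day_window(truths$onset)
  }
  if (is.null(truths$tst_min)) {
    truths$tst_min <- as.numeric(difftime(truths$offset, truths$onset,
                                          units = "mins"))
  }
  truths
}

isTRUE_col <- function(df, col) {
  if (is.null(df[[col]])) rep(FALSE, nrow(df)) else isTRUE_vec(df[[col]])
}
isTRUE_vec <- function(x) !is.na(x) & x

empty_stream <- function(value_col) {
  out <- data.frame(participant = character(),
                    timestamp = .POSIXct(numeric(), tz = HELSINKI_TZ))
  out[[value_col]] <- if (value_col == "status") integer() else character()
  out
}

#' Simulate a full multimodal cohort
#'
#' Runs [generate_cohort()] and all four renderers under the config's seed,
#' returning streams in the same shape [read_stream()] produces.
#'
#' @param config a [cohort_config()].
#' @param noise_actigraph,noise_bed,usage_screen,misperception_sd renderer
#'   parameters; defaults as in the individual renderers (misperception from
#'   the config parameter file).
#' @return list: `profiles`, `truths`, `streams` (named list
#'   actigraph/bed/screen/ema).
#' @export
simulate_cohort <- function(config,
                            noise_actigraph = NULL, noise_bed = NULL,
                            usage_screen = NULL, misperception_sd = NULL) {
  cohort <- generate_cohort(config)
  if (!nrow(cohort$profiles)) {
    return(c(cohort, list(streams = list())))
  }
  args <- function(user, f) {
    def <- eval(formals(f)[[2]])
    if (is.null(user)) def else utils::modifyList(def, user)
  }
  streams <- list(
    actigraph = render_actigraph(cohort$truths,
                                 args(noise_actigraph, render_actigraph)),
    bed = render_bed(cohort$truths, args(noise_bed, render_bed)),
    screen = render_screen(cohort$truths, args(usage_screen, render_screen)),
    ema = render_ema(cohort$truths,
                     misperception_sd %||%
                       config$params$ema_misperception_sd_min)
  )
  c(cohort, list(streams = streams))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulated streams and demographics as CSV files
#'
#' Emits the same delimited schemas [read_stream()] consumes:
#' `actigraph.csv`, `bed.csv`, `screen.csv`, `ema.csv`, `demographics.csv`
#' and a `ground_truth.csv` with the generating truth.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, time_col = "timestamp") {
    if (!is.null(df[[time_col]]) && inherits(df[[time_col]], "POSIXct")) {
      df[[time_col]] <- format_instants(df[[time_col]])
    }
    path <- file.path(dir, name)
    data.table::fwrite(df, path)
    path
  }
  files <- c(
    w(sim$streams$actigraph, "actigraph.csv"),
    w(sim$streams$bed, "bed.csv"),
    w(sim$streams$screen, "screen.csv"),
    w(sim$streams$ema, "ema.csv"),
    w(sim$profiles[c("participant", "age", "sex", "meq", "group")],
      "demographics.csv"),
    w(within(sim$truths, {
      onset <- format_instants(onset); offset <- format_instants(offset)
    }), "ground_truth.csv")
  )
  invisible(files)
}
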