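# Fixture builders and independent oracles used across the suite.

hel <- function(s) as.POSIXct(s, tz = "Europe/Helsinki")

# Actigraph stream with 30-s epochs starting at `start`, given labels.
mk_actigraph <- function(labels, start, participant = "P1") {
  data.frame(participant = participant,
             timestamp = hel(start) + 30 * (seq_along(labels) - 1),
             label = labels, stringsAsFactors = FALSE)
}

# Bed stream with 1 Hz samples starting at `start`.
mk_bed <- function(status, start, participant = "P1") {
  data.frame(participant = participant,
             timestamp = hel(start) + seq_along(status) - 1,
             status = as.integer(status), stringsAsFactors = FALSE)
}

mk_screen <- function(times, events, participant = "P1") {
  data.frame(participant = participant, timestamp = times, event = events,
             stringsAsFactors = FALSE)
}

# A single ground-truth night on the 30-s grid with zero device shifts.
mk_truth <- function(onset = "2019-01-07 23:55:00",
                     offset = "2019-01-08 06:51:00",
                     participant = "P1") {
  on <- hel(onset); off <- hel(offset)
  data.frame(participant = participant,
             study_day = assign_day_window(on),
             onset = on, offset = off,
             tst_min = as.numeric(difftime(off, on, units = "mins")),
             stringsAsFactors = FALSE)
}

# --- independent oracles -----------------------------------------------------

# Brute-force per-second scanner: mark seconds covered by sleep samples, close
# interior non-sleep gaps of at most gap_min minutes, report maximal runs.
oracle_episodes <- function(t_sec, epoch_s, gap_min = 5) {
  if (!length(t_sec)) return(data.frame(onset = numeric(), offset = numeric()))
  t_sec <- sort(unique(t_sec))
  t0 <- min(t_sec)
  covered <- rep(FALSE, max(t_sec) + epoch_s - t0)
  for (t in t_sec) covered[(t - t0) + seq_len(epoch_s)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1 && i < length(r$values) &&
        r$lengths[i] <= gap_min * 60) {
      covered[(ends[i] - r$lengths[i] + 1):ends[i]] <- TRUE
    }
  }
  r2 <- rle(covered)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1
  data.frame(onset = t0 + s2[r2$values] - 1, offset = t0 + e2[r2$values])
}

# Per-second state replay for the screen state machine. Events at integer
# seconds, strictly increasing. Inactive runs that reach the end of the
# observed horizon are unterminated and dropped; active gaps of at most
# gap_min minutes between inactive runs are merged.
oracle_inactivity <- function(t_sec, events, gap_min = 5) {
  stopifnot(!is.unsorted(t_sec, strictly = TRUE))
  horizon <- max(t_sec)
  state <- NA  # unknown until first event
  runs <- data.frame(onset = numeric(), offset = numeric())
  open_at <- NA_real_
  for (i in seq_along(t_sec)) {
    new_state <- if (events[i] %in% c("lock", "off")) "inactive" else "active"
    if (identical(state, new_state)) next
    if (identical(new_state, "inactive")) {
      open_at <- t_sec[i]
    } else if (identical(state, "inactive")) {
      if (t_sec[i] > open_at) {
        runs <- rbind(runs, data.frame(onset = open_at, offset = t_sec[i]))
      }
      open_at <- NA_real_
    }
    state <- new_state
  }
  if (!nrow(runs)) return(runs)
  # merge short active gaps
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$onset[i] - merged$offset[nrow(merged)] <= gap_min * 60) {
      merged$offset[nrow(merged)] <- runs$offset[i]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  merged
}

# Independent solar ephemeris (Michalsky-style Astronomical Almanac series)
# for the day-length cross-check.
oracle_day_length <- function(date, lat) {
  n <- as.numeric(as.Date(date)) + 2440587.5 + 0.5 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  eps <- 23.439 - 0.0000004 * n
  d <- asin(sin(eps * pi / 180) * sin(lam * pi / 180))
  phi <- lat * pi / 180
  ch <- (cos(90.833 * pi / 180) - sin(phi) * sin(d)) / (cos(phi) * cos(d))
  8 * acos(pmin(1, pmax(-1, ch))) * 180 / pi
}

# Random label stream on a 30-s (or 1-s) grid for oracle equivalence checks.
random_label_stream <- function(n_epochs, epoch_s, p_sleep, marker,
                                other = c("ACTIVE", "REST"),
                                start = hel("2019-03-01 15:00:00")) {
  run_len <- pmax(1, stats::rpois(n_epochs, 8))
  states <- stats::runif(length(run_len)) < p_sleep
  lab <- rep(ifelse(states, "S", "W"), run_len)[1:n_epochs]
  lab[is.na(lab)] <- "W"
  vals <- ifelse(lab == "S", marker, sample(other, n_epochs, replace = TRUE))
  # random dropouts so gaps in the grid are exercised too
  keep <- stats::runif(n_epochs) > 0.05
  data.frame(participant = "P1",
             timestamp = start + epoch_s * (which(keep) - 1),
             value = vals[keep], stringsAsFactors = FALSE)
}

# Fabricated daily records (skips the stream layer; for stats-level tests).
mk_records <- function(participant, modality, study_day, onset_rel,
                       offset_rel = onset_rel + tst_min, tst_min = 450) {
  ws <- study_day_start(as.Date(study_day))
  data.frame(participant = participant, study_day = as.Date(study_day),
             modality = modality,
             onset = ws + onset_rel * 60, offset = ws + offset_rel * 60,
             tst_min = offset_rel - onset_rel,
             onset_rel = onset_rel, offset_rel = offset_rel,
             stringsAsFactors = FALSE)
}

# Synthetic day-level model table with known coefficients, for mixed-model
# parameter recovery: abs_diff = b0 + b_age * age + u_participant + eps.
mk_model_table <- function(n_participants = 150, n_days = 14,
                           beta_age = -0.02, b0 = 1.5,
                           tau = 0.5, sigma = 1) {
  age <- round(stats::runif(n_participants, 18, 70))
  u <- stats::rnorm(n_participants, 0, tau)
  id <- sprintf("P%03d", seq_len(n_participants))
  df <- data.frame(
    participant = rep(id, each = n_days),
    study_day = rep(as.Date("2019-01-07") + seq_len(n_days) - 1,
                    n_participants),
    age = rep(age, each = n_days)
  )
  df$abs_diff <- b0 + beta_age * df$age + rep(u, each = n_days) +
    stats::rnorm(nrow(df), 0, sigma)
  df
}
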