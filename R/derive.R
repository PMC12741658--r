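# Sleep derivation: raw streams -> one nightly onset/offset/TST record per
# participant-day-modality.
#
# Pipeline order (fixed and tested): completeness filter and timezone
# standardization happen at ingest; here episodes are extracted with 5-minute
# gap merging, assigned to the 3 PM-to-3 PM window containing their onset,
# the longest candidate per window is selected (ties: earliest onset), the
# 3-13 h plausibility filter is applied to the selected episode (a failing
# main episode yields no record, not the runner-up), and finally the k
# largest onset/offset outliers per modality are removed.

# Merge sorted sample intervals [t, t+epoch_s) into maximal episodes, closing
# non-sleep gaps of at most gap_min minutes (inclusive). Returns one row per
# episode with numeric-second onset/offset.
merge_marked_intervals <- function(t_sec, epoch_s, gap_min) {
  if (!length(t_sec)) {
    return(data.frame(onset = numeric(), offset = numeric()))
  }
  t_sec <- sort(t_sec)
  ends <- t_sec + epoch_s
  n <- length(t_sec)
  new_run <- c(TRUE, t_sec[-1] - ends[-n] > gap_min * 60)
  id <- cumsum(new_run)
  data.frame(onset = tapply(t_sec, id, min),
             offset = tapply(ends, id, max),
             row.names = NULL)
}

#' Extract sleep episodes from a labelled epoch or status stream
#'
#' Groups maximal runs of sleep-marked samples (`REST-S` epochs for the
#' actigraph, status `1` seconds for the bed sensor) into episodes, merging
#' two runs whenever the non-sleep gap between them is at most
#' `gap_threshold_min` minutes (inclusive; the gap counts toward the episode
#' span). Episode onset is the first marked sample's start; offset is the end
#' of the last marked sample.
#'
#' @param stream actigraph or bed stream (sorted, from [read_stream()] or a
#'   renderer).
#' @param sleep_marker value marking sleep: `"REST-S"` or `1`.
#' @param gap_threshold_min maximum mergeable gap, minutes (default 5).
#' @param epoch_s sample coverage in seconds: 30 for actigraph epochs, 1 for
#'   bed samples. Defaults by marker.
#' @return data.frame: `participant`, `onset`, `offset` (POSIXct),
#'   `duration_min`, `study_day` (window of the onset).
#' @export
extract_label_episodes <- function(stream, sleep_marker,
                                   gap_threshold_min = 5,
                                   epoch_s = if (identical(sleep_marker,
                                                           "REST-S")) 30 else 1) {
  value_col <- intersect(c("label", "status"), names(stream))[1]
  marked <- stream[!is.na(stream[[value_col]]) &
                     stream[[value_col]] == sleep_marker, , drop = FALSE]
  episodes_from_marks(marked$participant, as.numeric(marked$timestamp),
                      epoch_s, gap_threshold_min)
}

episodes_from_marks <- function(participant, t_sec, epoch_s, gap_min) {
  if (!length(t_sec)) return(empty_episodes())
  parts <- split(t_sec, participant)
  out <- lapply(names(parts), function(p) {
    ep <- merge_marked_intervals(parts[[p]], epoch_s, gap_min)
    ep$participant <- p
    ep
  })
  out <- do.call(rbind, out)
  finish_episodes(out)
}

finish_episodes <- function(out) {
  onset <- .POSIXct(out$onset, tz = HELSINKI_TZ)
  offset <- .POSIXct(out$offset, tz = HELSINKI_TZ)
  data.frame(participant = out$participant, onset = onset, offset = offset,
             duration_min = (out$offset - out$onset) / 60,
             study_day = assign_day_window(onset),
             stringsAsFactors = FALSE)
}

empty_episodes <- function() {
  data.frame(participant = character(),
             onset = .POSIXct(numeric(), tz = HELSINKI_TZ),
             offset = .POSIXct(numeric(), tz = HELSINKI_TZ),
             duration_min = numeric(), study_day = as.Date(character()))
}

#' Infer inactivity intervals from a screen event log
#'
#' A two-state machine over the event sequence: `lock` and `off` switch the
#' phone to inactive, `unlock` and `on` to active. Maximal inactive intervals
#' are emitted; redundant repeated events are ignored (state does not
#' change), so duplicate consecutive locks are tolerated. The first interval
#' opens at the first observed transition -- no state is extrapolated before
#' the first event -- and a trailing interval left open at the end of the log
#' is discarded because its end is unobserved. As with the label streams,
#' inactive intervals separated by at most `gap_threshold_min` minutes of
#' activity (a brief nocturnal phone check) are merged; zero-length intervals
#' are dropped with a warning.
#'
#' @param log screen event stream (sorted).
#' @param gap_threshold_min maximum mergeable active gap, minutes.
#' @return data.frame as [extract_label_episodes()].
#' @export
infer_screen_inactivity <- function(log, gap_threshold_min = 5) {
  if (!nrow(log)) return(empty_episodes())
  inactive_evt <- log$event %in% c("lock", "off")
  parts <- split(seq_len(nrow(log)), log$participant)
  res <- lapply(names(parts), function(p) {
    idx <- parts[[p]]
    t <- as.numeric(log$timestamp[idx])
    inact <- inactive_evt[idx]
    keep <- c(TRUE, inact[-1] != inact[-length(inact)])  # state transitions
    t <- t[keep]; inact <- inact[keep]
    if (!any(inact)) return(NULL)
    starts <- which(inact)
    on <- t[starts]
    off <- ifelse(starts + 1 <= length(t), t[starts + 1], NA_real_)
    ok <- !is.na(off)
    if (!any(ok)) return(NULL)
    iv <- data.frame(onset = on[ok], offset = off[ok])
    zero <- iv$offset <= iv$onset
    if (any(zero)) {
      warning(sum(zero), " zero-length inactivity interval(s) dropped for ",
              p, call. = FALSE)
      iv <- iv[!zero, , drop = FALSE]
    }
    if (!nrow(iv)) return(NULL)
    # merge across brief active gaps, same rule as the label streams
    nr <- nrow(iv)
    new_run <- c(TRUE, iv$onset[-1] - iv$offset[-nr] > gap_threshold_min * 60)
    id <- cumsum(new_run)
    merged <- data.frame(onset = tapply(iv$onset, id, min),
                         offset = tapply(iv$offset, id, max),
                         row.names = NULL)
    merged$participant <- p
    merged
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(empty_episodes())
  finish_episodes(res)
}

#' Select the main (nocturnal) sleep episode per participant-day
#'
#' Within each 3 PM-to-3 PM window the longest candidate is classified as
#' nocturnal sleep; ties are broken by earliest onset. Windows with no
#' candidate simply yield no record.
#'
#' @param episodes data.frame from [extract_label_episodes()] or
#'   [infer_screen_inactivity()].
#' @return one row per participant-study_day.
#' @export
select_main_sleep <- function(episodes) {
  if (!nrow(episodes)) return(episodes)
  o <- order(episodes$participant, episodes$study_day,
             -episodes$duration_min, episodes$onset)
  ep <- episodes[o, , drop = FALSE]
  keep <- !duplicated(ep[c("participant", "study_day")])
  out <- ep[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plausibility filter on total sleep time
#'
#' Keeps records whose TST lies in the inclusive 3-13 h range; values outside
#' indicate naps, device errors or atypical patterns.
#'
#' @param records data.frame with a `tst_min` (or `duration_min`) column.
#' @param min_h,max_h bounds in hours (defaults 3 and 13).
#' @return the surviving rows; attribute `n_filtered` counts removals.
#' @export
apply_tst_filter <- function(records, min_h = 3, max_h = 13) {
  col <- intersect(c("tst_min", "duration_min"), names(records))[1]
  keep <- records[[col]] >= min_h * 60 & records[[col]] <= max_h * 60
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Convert a categorical sleep-duration response to hours
#'
#' Interval midpoints: "6-7 hours" is 6.5 h. The open-ended categories take
#' half an hour beyond their bound, consistent with the one-hour inner bins:
#' "under 5 hours" is 4.5 h and "over 10 hours" is 10.5 h.
#'
#' @param category character vector of responses.
#' @return numeric hours.
#' @export
ema_to_hours <- function(category) {
  map <- stats::setNames(c(4.5, 5.5, 6.5, 7.5, 8.5, 9.5, 10.5),
                         EMA_CATEGORIES)
  unknown <- !(category %in% names(map))
  if (any(unknown)) {
    stop("unknown sleep duration category: '", category[unknown][1], "'",
         call. = FALSE)
  }
  unname(map[category])
}

#' Remove the k largest onset/offset outliers from a daily table
#'
#' Within one modality's daily records, onset and offset are expressed as
#' window-relative minutes (avoiding the midnight wrap) and, per column, the
#' `k` rows deviating most (absolutely) from the column mean are flagged; the
#' union of flagged rows is removed, so a row extreme in both columns is
#' removed once. Ties are broken by first occurrence. Tables with at most `k`
#' rows are returned untouched with a warning.
#'
#' @param daily daily records of one sensor modality with `onset_rel` and
#'   `offset_rel` columns (see [build_daily_records()]).
#' @param k outliers flagged per column (default 2).
#' @return list: `kept` and `removed` (removed rows carry a
#'   `flagged_by` column).
#' @export
remove_outliers <- function(daily, k = 2) {
  if (nrow(daily) <= k) {
    if (nrow(daily)) {
      warning("table has <= k rows; no outliers removed", call. = FALSE)
    }
    return(list(kept = daily, removed = daily[0, , drop = FALSE]))
  }
  flag_col <- function(x) {
    dev <- abs(x - mean(x))
    order(-dev, seq_along(dev))[seq_len(k)]
  }
  on_idx <- flag_col(daily$onset_rel)
  off_idx <- flag_col(daily$offset_rel)
  rem <- sort(union(on_idx, off_idx))
  removed <- daily[rem, , drop = FALSE]
  removed$flagged_by <- vapply(rem, function(i) {
    paste(c("onset", "offset")[c(i %in% on_idx, i %in% off_idx)],
          collapse = "+")
  }, character(1))
  kept <- daily[-rem, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Build the daily sleep record table from raw streams
#'
#' Composes the full derivation for every available modality: episode
#' extraction (label streams) or inactivity inference (screen log) with gap
#' merging, main-sleep selection per window, the 3-13 h TST filter, and
#' per-modality outlier trimming. EMA responses contribute TST-only rows (the
#' categorical response converted to hours); their `date` is the study day of
#' the reported night.
#'
#' @param streams named list with any of `actigraph`, `bed`, `screen`, `ema`.
#' @param gap_threshold_min gap-merge threshold, minutes.
#' @param tst_range_h inclusive plausibility bounds, hours.
#' @param outlier_k outliers flagged per column and modality; `0` disables.
#' @return long data.frame, one row per surviving participant-day-modality:
#'   `participant`, `study_day`, `modality`, `onset`, `offset`, `tst_min`,
#'   `onset_rel`, `offset_rel` (window-relative minutes; `NA` for ema).
#'   Attribute `attrition` holds per-modality counts at each stage.
#' @export
build_daily_records <- function(streams, gap_threshold_min = 5,
                                tst_range_h = c(3, 13), outlier_k = 2) {
  records <- list()
  attrition <- list()
  sensor_defs <- list(
    actigraph = function(s) extract_label_episodes(s, "REST-S",
                                                   gap_threshold_min),
    bed = function(s) extract_label_episodes(s, 1L, gap_threshold_min),
    smartphone = function(s) infer_screen_inactivity(s, gap_threshold_min)
  )
  stream_names <- c(actigraph = "actigraph", bed = "bed",
                    smartphone = "screen")
  for (m in names(sensor_defs)) {
    st <- streams[[stream_names[[m]]]]
    if (is.null(st)) next
    eps <- sensor_defs[[m]](st)
    main <- select_main_sleep(eps)
    filt <- apply_tst_filter(main, tst_range_h[1], tst_range_h[2])
    if (nrow(filt)) {
      filt$onset_rel <- window_rel_min(filt$onset)
      filt$offset_rel <- window_rel_min(filt$offset, anchor = filt$onset)
    } else {
      filt$onset_rel <- numeric(); filt$offset_rel <- numeric()
    }
    trimmed <- if (outlier_k > 0 && nrow(filt) > outlier_k) {
      remove_outliers(filt, k = outlier_k)
    } else list(kept = filt, removed = filt[0, , drop = FALSE])
    rec <- trimmed$kept
    attrition[[m]] <- c(episodes = nrow(eps), selected = nrow(main),
                        tst_filtered = attr(filt, "n_filtered") %||% 0L,
                        outliers_removed = nrow(trimmed$removed),
                        kept = nrow(rec))
    if (nrow(rec)) {
      records[[m]] <- data.frame(
        participant = rec$participant, study_day = rec$study_day,
        modality = m, onset = rec$onset, offset = rec$offset,
        tst_min = rec$duration_min,
        onset_rel = rec$onset_rel, offset_rel = rec$offset_rel,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(streams$ema) && nrow(streams$ema)) {
    ema <- streams$ema
    records$ema <- data.frame(
      participant = ema$participant, study_day = as.Date(ema$date),
      modality = "ema",
      onset = .POSIXct(NA_real_, tz = HELSINKI_TZ),
      offset = .POSIXct(NA_real_, tz = HELSINKI_TZ),
      tst_min = ema_to_hours(ema$category) * 60,
      onset_rel = NA_real_, offset_rel = NA_real_,
      stringsAsFactors = FALSE
    )
    attrition$ema <- c(episodes = nrow(ema), selected = nrow(ema),
                       tst_filtered = 0L, outliers_removed = 0L,
                       kept = nrow(ema))
  }
  out <- if (length(records)) {
    do.call(rbind, c(records, list(make.row.names = FALSE)))
  } else {
    data.frame(participant = character(), study_day = as.Date(character()),
               modality = character(),
               onset = .POSIXct(numeric(), tz = HELSINKI_TZ),
               offset = .POSIXct(numeric(), tz = HELSINKI_TZ),
               tst_min = numeric(), onset_rel = numeric(),
               offset_rel = numeric())
  }
  attr(out, "attrition") <- attrition
  out
}
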