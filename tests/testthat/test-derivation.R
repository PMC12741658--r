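test_that("a single REST-S run yields one episode with exact bounds", {
  # epochs 23:55:00 .. 06:50:30 cover [23:55, 06:51)
  n_sleep <- as.integer((7 * 60 - 4) * 2)  # 6 h 56 min of epochs
  labels <- c("ACTIVE", rep("REST-S", n_sleep), "REST", "ACTIVE")
  st <- mk_actigraph(labels, "2019-01-07 23:54:30")
  ep <- extract_label_episodes(st, "REST-S")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset, hel("2019-01-07 23:55:00"))
  expect_equal(ep$offset, hel("2019-01-08 06:51:00"))
  expect_equal(ep$duration_min, 416)
  expect_equal(ep$study_day, as.Date("2019-01-07"))
})

test_that("gap merging is inclusive at the 5-minute threshold", {
  run <- function(gap_epochs) {
    labels <- c(rep("REST-S", 20), rep("ACTIVE", gap_epochs),
                rep("REST-S", 20))
    extract_label_episodes(mk_actigraph(labels, "2019-01-07 23:00:00"),
                           "REST-S")
  }
  expect_equal(nrow(run(8)), 1)    # 4-min interruption merges
  expect_equal(nrow(run(10)), 1)   # exactly 5 min still merges ("up to")
  expect_equal(nrow(run(12)), 2)   # 6 min splits
  merged <- run(10)
  expect_equal(merged$duration_min, 25)  # gap counts toward the span
})

test_that("bed status-1 runs merge across short interruptions", {
  status <- c(rep(0L, 60), rep(1L, 1200), rep(3L, 240), rep(1L, 1200),
              rep(2L, 30))
  st <- mk_bed(status, "2019-01-07 23:00:00")
  ep <- extract_label_episodes(st, 1L)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_min, 44)  # 1200 + 240 + 1200 seconds
  long_gap <- mk_bed(c(rep(1L, 600), rep(0L, 360), rep(1L, 600)),
                     "2019-01-07 23:00:00")
  expect_equal(nrow(extract_label_episodes(long_gap, 1L)), 2)
})

test_that("episode extraction matches the brute-force scanner on random streams", {
  set.seed(101)
  for (rep in 1:60) {
    epoch_s <- sample(c(30, 1), 1)
    marker <- if (epoch_s == 30) "REST-S" else 1L
    st <- random_label_stream(500, epoch_s, p_sleep = 0.4,
                              marker = as.character(marker),
                              other = if (epoch_s == 30) c("ACTIVE", "REST")
                              else c("0", "2", "3"))
    names(st)[3] <- if (epoch_s == 30) "label" else "status"
    if (epoch_s == 1) st$status <- as.integer(st$status)
    got <- extract_label_episodes(st, marker)
    marked <- as.numeric(st$timestamp[st[[3]] == marker])
    want <- oracle_episodes(marked, epoch_s)
    expect_equal(as.numeric(got$onset), want$onset)
    expect_equal(as.numeric(got$offset), want$offset)
  }
})

test_that("screen inactivity follows the two-state machine", {
  lg <- mk_screen(hel(c("2019-01-07 23:00:00", "2019-01-08 07:00:00")),
                  c("lock", "unlock"))
  iv <- infer_screen_inactivity(lg)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$onset, hel("2019-01-07 23:00:00"))
  expect_equal(iv$offset, hel("2019-01-08 07:00:00"))
  expect_equal(iv$duration_min, 480)
  # duplicate locks: interval opens at the first
  lg2 <- mk_screen(hel(c("2019-01-07 23:00:00", "2019-01-07 23:30:00",
                         "2019-01-08 07:00:00")),
                   c("lock", "lock", "unlock"))
  iv2 <- infer_screen_inactivity(lg2)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$onset, hel("2019-01-07 23:00:00"))
  # off/on behave like lock/unlock
  lg3 <- mk_screen(hel(c("2019-01-07 23:00:00", "2019-01-08 07:00:00")),
                   c("off", "on"))
  expect_equal(infer_screen_inactivity(lg3)$duration_min, 480)
  # log starting mid-state: no extrapolation before the first event
  lg4 <- mk_screen(hel(c("2019-01-07 23:00:00", "2019-01-08 07:00:00")),
                   c("unlock", "lock"))
  expect_equal(nrow(infer_screen_inactivity(lg4)), 0)  # trailing open dropped
})

test_that("screen inference matches the state-replay oracle on random logs", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(10:60, 1)
    t0 <- as.numeric(hel("2019-02-01 15:00:00"))
    t <- t0 + sort(sample.int(86400, n))
    ev <- sample(c("lock", "unlock", "on", "off"), n, replace = TRUE)
    lg <- mk_screen(.POSIXct(t, tz = "Europe/Helsinki"), ev)
    got <- suppressWarnings(infer_screen_inactivity(lg))
    want <- oracle_inactivity(t, ev)
    expect_equal(as.numeric(got$onset), want$onset)
    expect_equal(as.numeric(got$offset), want$offset)
  }
})

test_that("study-day windows partition the timeline, including DST weeks", {
  expect_equal(assign_day_window(hel("2019-01-02 02:00:00")),
               as.Date("2019-01-01"))
  expect_equal(assign_day_window(hel("2019-01-02 15:00:00")),
               as.Date("2019-01-02"))  # half-open: 15:00 starts the new day
  expect_equal(assign_day_window(hel("2019-01-02 14:59:59")),
               as.Date("2019-01-01"))
  # exhaustive minute scan over both 2019 transition weeks
  for (start in c("2019-03-28 00:00:00", "2019-10-24 00:00:00")) {
    t <- hel(start) + 60 * (0:(7 * 1440))
    day <- assign_day_window(t)
    expect_false(anyNA(day))
    ws <- study_day_start(day)
    next_ws <- study_day_start(day + 1)
    expect_true(all(as.numeric(t) >= as.numeric(ws)))
    expect_true(all(as.numeric(t) < as.numeric(next_ws)))
  }
})

test_that("main-sleep selection takes the longest, ties to earliest onset", {
  eps <- mk_records("P1", "actigraph", "2019-01-07",
                    onset_rel = c(500, 1200), tst_min = c(420, 35))
  eps$duration_min <- eps$tst_min
  sel <- select_main_sleep(eps)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$onset_rel, 500)
  tie <- mk_records("P1", "actigraph", "2019-01-07",
                    onset_rel = c(600, 480), tst_min = c(400, 400))
  tie$duration_min <- tie$tst_min
  expect_equal(select_main_sleep(tie)$onset_rel, 480)
})

test_that("main-sleep selection equals the argmax oracle on random sets", {
  set.seed(303)
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    onset <- sample(seq(300, 900, by = 15), k)
    dur <- sample(seq(30, 600, by = 30), k, replace = TRUE)
    eps <- mk_records("P1", "actigraph", "2019-01-07",
                      onset_rel = onset, tst_min = dur)
    eps$duration_min <- dur
    sel <- select_main_sleep(eps)
    ord <- order(-dur, onset)
    expect_equal(sel$onset_rel, onset[ord[1]])
    expect_equal(sel$duration_min, dur[ord[1]])
  }
})

test_that("TST plausibility filter is inclusive at 3 and 13 hours", {
  rec <- mk_records("P1", "actigraph",
                    rep("2019-01-07", 4) , onset_rel = rep(500, 4),
                    tst_min = c(179, 180, 780, 781))
  out <- apply_tst_filter(rec)
  expect_equal(out$tst_min, c(180, 780))
  expect_equal(attr(out, "n_filtered"), 2)
})

test_that("categorical TST converts to interval midpoints", {
  expect_equal(ema_to_hours("6-7 hours"), 6.5)
  expect_equal(ema_to_hours("8-9 hours"), 8.5)
  expect_equal(ema_to_hours(c("under 5 hours", "over 10 hours")),
               c(4.5, 10.5))
  expect_error(ema_to_hours("11-12 hours"), "unknown")
})

test_that("outlier trimming flags the k largest deviations per column", {
  daily <- mk_records("P1", "bed", rep("2019-01-07", 5),
                      onset_rel = c(0, 1, 2, 240, -300),
                      offset_rel = c(450, 451, 452, 690, 150))
  res <- remove_outliers(daily, k = 2)
  # oracle: rank |x - mean|
  dev <- abs(daily$onset_rel - mean(daily$onset_rel))
  want <- sort(daily$onset_rel[order(-dev)[1:2]])
  expect_equal(sort(res$removed$onset_rel), want)
  expect_equal(sort(res$removed$onset_rel), c(-300, 240))
  # rows extreme in both columns are removed once (union semantics)
  expect_equal(nrow(res$removed), 2)
  expect_equal(res$removed$flagged_by, c("onset+offset", "onset+offset"))
  expect_equal(nrow(res$kept), 3)
})

test_that("outlier trimming is deterministic under ties and small tables", {
  same <- mk_records("P1", "bed", rep("2019-01-07", 4),
                     onset_rel = c(500, 500, 500, 500))
  res <- remove_outliers(same, k = 2)
  expect_equal(nrow(res$removed), 2)  # first occurrences flagged
  expect_identical(res$removed$study_day, same$study_day[1:2])
  tiny <- same[1:2, ]
  expect_warning(res2 <- remove_outliers(tiny, k = 2), "no outliers")
  expect_equal(nrow(res2$kept), 2)
})

test_that("daily record building recovers a zero-noise synthetic night", {
  truth <- mk_truth("2019-01-07 23:55:00", "2019-01-08 06:51:00")
  streams <- list(
    actigraph = render_actigraph(truth),
    bed = render_bed(truth),
    screen = render_screen(truth, usage_params = list(bout_gap_min = Inf,
                                                      bout_dur_min = 12)),
    ema = render_ema(truth, misperception_sd = 0)
  )
  rec <- build_daily_records(streams, outlier_k = 0)
  expect_setequal(rec$modality, c("actigraph", "bed", "smartphone", "ema"))
  expect_equal(nrow(rec), 4)
  true_tst <- truth$tst_min
  sens <- rec[rec$modality != "ema", ]
  expect_true(all(abs(sens$tst_min - true_tst) <= 0.5))
  expect_equal(rec$tst_min[rec$modality == "ema"], 6.5 * 60)
  # output TST equals offset - onset for sensor rows
  expect_equal(sens$tst_min,
               as.numeric(difftime(sens$offset, sens$onset, units = "mins")))
})

test_that("an implausibly short main episode yields no record, not the runner-up", {
  # 2-h main episode plus a 1-h nap: selection happens before the filter
  labels <- c(rep("REST-S", 240), rep("ACTIVE", 120), rep("REST-S", 120))
  st <- mk_actigraph(labels, "2019-01-08 01:00:00")
  rec <- build_daily_records(list(actigraph = st), outlier_k = 0)
  expect_equal(nrow(rec), 0)
  att <- attr(rec, "attrition")
  expect_equal(unname(att$actigraph["tst_filtered"]), 1)
})

test_that("filter order is stable: selection over unfiltered candidates", {
  # candidates: 14 h (implausible) and 6 h; selecting first then filtering
  # drops the day entirely, filtering first would keep the 6-h episode
  labels <- c(rep("REST-S", 14 * 120), rep("ACTIVE", 20),
              rep("REST-S", 6 * 120))
  st <- mk_actigraph(labels, "2019-01-07 15:30:00")
  rec <- build_daily_records(list(actigraph = st), outlier_k = 0)
  expect_equal(nrow(rec), 0)
  pre_filtered <- apply_tst_filter(
    select_main_sleep(extract_label_episodes(st, "REST-S")))
  expect_equal(nrow(pre_filtered), 0)
})
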