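test_that("day length behaves physically and matches an independent ephemeris", {
  # equator: close to 12 h all year
  eq <- day_length(seq(as.Date("2019-01-01"), by = "month", length.out = 12),
                   latitude = 0)
  expect_true(all(abs(eq - 720) < 15))
  # Helsinki: midsummer > equinox > midwinter
  hki <- day_length(as.Date(c("2019-06-21", "2019-03-20", "2019-12-21")))
  expect_true(all(diff(hki) < 0))
  expect_gt(hki[1], 18 * 60)
  expect_lt(hki[3], 7 * 60)
  # polar clamps
  expect_equal(day_length(as.Date("2019-06-21"), latitude = 80), 1440)
  expect_equal(day_length(as.Date("2019-12-21"), latitude = 80), 0)
  # cross-check against the almanac-series oracle over three sampled years
  dates <- seq(as.Date("2018-01-01"), as.Date("2020-12-31"), by = "3 days")
  expect_lt(max(abs(day_length(dates) - oracle_day_length(dates, 60.17))), 2)
})

mk_dem <- function(ids, group = "control") {
  data.frame(participant = ids, age = 35, sex = "female", meq = 39,
             group = group, stringsAsFactors = FALSE)
}

test_that("model tables inner-join the two modalities by participant-day", {
  rec <- rbind(
    mk_records("P1", "actigraph", c("2019-01-07", "2019-01-08", "2019-01-09"),
               onset_rel = c(500, 520, 540), tst_min = 450),
    mk_records("P1", "bed", c("2019-01-07", "2019-01-09"),
               onset_rel = c(490, 530), tst_min = 460),
    mk_records("P2", "actigraph", "2019-01-07", onset_rel = 510,
               tst_min = 440))
  tab <- build_model_table(rec, mk_dem(c("P1", "P2")), "onset",
                           c("actigraph", "bed"))
  # oracle: set intersection of (participant, day) keys
  ka <- paste("P1", c("2019-01-07", "2019-01-08", "2019-01-09"))
  kb <- paste("P1", c("2019-01-07", "2019-01-09"))
  expect_equal(nrow(tab), length(intersect(ka, kb)))
  expect_equal(tab$abs_diff, c(10, 10) / 60)
  expect_true(all(tab$daylight >= 0 & tab$daylight <= 24))
  # identical records give zero difference
  tab0 <- build_model_table(rbind(
    mk_records("P1", "actigraph", "2019-01-07", onset_rel = 500),
    mk_records("P1", "bed", "2019-01-07", onset_rel = 500),
    mk_records("P2", "actigraph", "2019-01-07", onset_rel = 520),
    mk_records("P2", "bed", "2019-01-07", onset_rel = 520)),
    mk_dem(c("P1", "P2")), "onset", c("actigraph", "bed"))
  expect_equal(tab0$abs_diff, c(0, 0))
})

test_that("the mixed model recovers a known age effect", {
  set.seed(71)
  tab <- mk_model_table(n_participants = 150, n_days = 14, beta_age = -0.02)
  fit <- fit_alignment_model(tab, formula = abs_diff ~ age)
  cf <- fit$coefficients
  age_row <- cf[cf$term == "age", ]
  expect_lt(age_row$ci_low, -0.02)
  expect_gt(age_row$ci_high, -0.02)
  expect_equal(age_row$estimate, -0.02, tolerance = 0.35)
  expect_equal(fit$n_obs, 150 * 14)
  expect_equal(fit$n_participants, 150)
  # variance components near their generating values (tau 0.25, sigma2 1)
  expect_equal(fit$sigma2, 1, tolerance = 0.1)
  expect_equal(fit$tau00, 0.25, tolerance = 0.35)
})

test_that("ICC identities hold, including the printed worked examples", {
  expect_equal(round_half_up(icc(2.47, 1.27), 2), 0.34)
  expect_equal(round_half_up(icc(2.97, 2.12), 2), 0.42)
  expect_equal(icc(2.47, 0), 0)
  expect_error(icc(0, 1))
  set.seed(81)
  tab <- mk_model_table(n_participants = 40, n_days = 8)
  fit <- fit_alignment_model(tab, formula = abs_diff ~ age)
  expect_identical(fit$icc, icc(fit$sigma2, fit$tau00))
})

test_that("participant-constant outcomes drive the ICC toward 1", {
  set.seed(91)
  ids <- sprintf("P%02d", 1:30)
  tab <- data.frame(
    participant = rep(ids, each = 6),
    abs_diff = rep(rnorm(30, 2, 1), each = 6) + rnorm(180, 0, 0.01)
  )
  fit <- fit_alignment_model(tab, formula = abs_diff ~ 1)
  expect_gt(fit$icc, 0.99)
})

test_that("Nakagawa R2 identities: no fixed effects and no random variance", {
  set.seed(92)
  ids <- sprintf("P%02d", 1:30)
  tab <- data.frame(participant = rep(ids, each = 6),
                    abs_diff = rep(rnorm(30, 2, 0.8), each = 6) +
                      rnorm(180, 0, 0.5))
  fit <- fit_alignment_model(tab, formula = abs_diff ~ 1)
  # intercept-only: var of fixed predictions is 0 exactly
  expect_equal(fit$r2_marginal, 0)
  expect_equal(fit$r2_conditional, fit$icc)
  # no between-participant variance: singular fit, conditional == marginal
  tab2 <- data.frame(participant = rep(ids, each = 6),
                     x = rnorm(180),
                     abs_diff = NA)
  tab2$abs_diff <- 1 + 0.5 * tab2$x + rnorm(180, 0, 1)
  fit2 <- fit_alignment_model(tab2, formula = abs_diff ~ x)
  expect_true(fit2$singular)
  expect_equal(fit2$tau00, 0)
  expect_equal(fit2$r2_conditional, fit2$r2_marginal)
})

test_that("R2 recovers a known variance budget", {
  set.seed(93)
  # var_f = 1 (x ~ N(0,1), beta 1), tau = 0.5, sigma2 = 0.5
  n <- 400; ids <- sprintf("P%03d", 1:n)
  tab <- data.frame(participant = rep(ids, each = 6),
                    x = rnorm(6 * n))
  u <- rnorm(n, 0, sqrt(0.5))
  tab$abs_diff <- 1 * tab$x + rep(u, each = 6) + rnorm(6 * n, 0, sqrt(0.5))
  fit <- fit_alignment_model(tab, formula = abs_diff ~ x)
  expect_equal(fit$r2_marginal, 1 / 2, tolerance = 0.05)
  expect_equal(fit$r2_conditional, 1.5 / 2, tolerance = 0.05)
})

test_that("adding an irrelevant predictor cannot shrink conditional R2 much", {
  set.seed(94)
  tab <- mk_model_table(n_participants = 50, n_days = 8)
  tab$junk <- rnorm(nrow(tab))
  f1 <- fit_alignment_model(tab, formula = abs_diff ~ age)
  f2 <- fit_alignment_model(tab, formula = abs_diff ~ age + junk)
  expect_gt(f2$r2_conditional, f1$r2_conditional - 0.01)
})

test_that("rescaling daylight from minutes to hours rescales beta by 60", {
  cfg <- cohort_config(n_controls = 8, n_patients_by_group = c(MDD = 8),
                       n_days = 6, seed = 13)
  sim <- simulate_cohort(cfg)
  # rendered screen logs can round a bout to zero length; that warning is
  # exercised elsewhere
  rec <- suppressWarnings(build_daily_records(sim$streams))
  dem <- sim$profiles[c("participant", "age", "sex", "meq", "group")]
  th <- build_model_table(rec, dem, "offset", c("actigraph", "bed"),
                          daylight_scale = "h")
  tm <- build_model_table(rec, dem, "offset", c("actigraph", "bed"),
                          daylight_scale = "min")
  # small fixture; lme4 may grumble about convergence on the minute scale
  fh <- suppressWarnings(fit_alignment_model(th,
                                             formula = abs_diff ~ age + daylight))
  fm <- suppressWarnings(fit_alignment_model(tm,
                                             formula = abs_diff ~ age + daylight))
  bh <- fh$coefficients[fh$coefficients$term == "daylight", ]
  bm <- fm$coefficients[fm$coefficients$term == "daylight", ]
  expect_equal(bh$estimate, 60 * bm$estimate, tolerance = 1e-4)
  expect_equal(bh$p, bm$p, tolerance = 1e-4)
})

test_that("the full model grid fits on a simulated cohort", {
  cfg <- cohort_config(n_controls = 8, n_patients_by_group = c(MDD = 8),
                       n_days = 6, seed = 17)
  sim <- simulate_cohort(cfg)
  rec <- build_daily_records(sim$streams)
  dem <- sim$profiles[c("participant", "age", "sex", "meq", "group")]
  models <- fit_all_alignment_models(rec, dem)
  expect_length(models, 9)
  m <- models[["tst.actigraph_bed"]]
  expect_s3_class(m, "alignment_model")
  expect_true(all(c("(Intercept)", "age", "sexfemale", "meq", "daylight",
                    "groupMDD") %in% m$coefficients$term))
  expect_true(m$sigma2 > 0 && m$tau00 >= 0)
  expect_true(m$r2_marginal <= m$r2_conditional)
  expect_true(m$icc >= 0 && m$icc <= 1)
})
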