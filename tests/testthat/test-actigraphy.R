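# SPT-window detector primitives and derived sleep metrics.

test_that("rolling median of absolute angle change matches its definition", {
  eps <- 5
  # constant angle -> all zeros
  expect_equal(rolling_median_abs_change(rep(30, 100), 5, eps),
               rep(0, 100))
  # alternating 0/10 degrees, 3-epoch window -> constant 10
  z <- rep(c(0, 10), 30)
  expect_equal(rolling_median_abs_change(z, 3 * eps / 60, eps),
               rep(10, 60))
  # one-epoch window degenerates to |diff| with the leading value repeated
  z <- c(3, 7, 7, 1)
  expect_equal(rolling_median_abs_change(z, eps / 60, eps),
               c(4, 4, 0, 6))
  # random series vs brute-force windowed-median oracle
  for (seed in 1:5) {
    set.seed(seed)
    z <- runif(200, -90, 90)
    w <- sample(c(3, 7, 15, 61), 1)
    expect_equal(rolling_median_abs_change(z, w * eps / 60, eps),
                 oracle_rolling_median(z, w))
  }
  expect_error(rolling_median_abs_change(c(1, 2), 0.01, 5), "one epoch")
  expect_error(rolling_median_abs_change(numeric(1)), "two epochs")
})

test_that("movement threshold is the linear-interpolation quantile", {
  expect_equal(movement_threshold(rep(0, 50)), 0)
  expect_equal(movement_threshold(rep(2.5, 50)), 2.5)
  expect_equal(movement_threshold(1:100, 0.1), oracle_quantile(1:100, 0.1))
  set.seed(1)
  x <- rexp(333)
  for (p in c(0.05, 0.1, 0.5, 0.9)) {
    expect_equal(movement_threshold(x, p), oracle_quantile(x, p))
  }
  expect_equal(movement_threshold(1:10, 0.1, multiplier = 15),
               15 * oracle_quantile(1:10, 0.1))
  expect_error(movement_threshold(numeric(0)), "nonempty")
})

test_that("inactivity bouts are maximal runs above the strict minimum", {
  eps <- 5
  # 2 h contiguous -> one 120-min bout
  mask <- rep(c(FALSE, TRUE, FALSE), c(10, 1440, 10))
  b <- detect_inactivity_bouts(mask, 30, eps)
  expect_equal(b, data.frame(start = 11L, end = 1451L))
  expect_equal((b$end - b$start) * eps / 60, 120)
  # 29-min run -> nothing (strict minimum)
  mask <- rep(c(FALSE, TRUE, FALSE), c(5, 29 * 12, 5))
  expect_equal(nrow(detect_inactivity_bouts(mask, 30, eps)), 0L)
  # exactly 30 min passes
  mask <- rep(c(FALSE, TRUE, FALSE), c(5, 30 * 12, 5))
  expect_equal(nrow(detect_inactivity_bouts(mask, 30, eps)), 1L)
  # random masks vs exhaustive run-length scan
  for (seed in 1:10) {
    set.seed(seed)
    mask <- runif(500) < 0.7
    expect_equal(detect_inactivity_bouts(mask, 1, 60),
                 oracle_runs(mask, min_len = 1L))
    expect_equal(detect_inactivity_bouts(mask, 0.5, 5),
                 oracle_runs(mask, min_len = 6L))
  }
})

test_that("bout merging bridges gaps strictly below the maximum", {
  eps <- 5
  two <- function(gap_min) {
    data.frame(start = c(1L, 1L + 360L + gap_min * 12L),
               end = c(361L, 361L + gap_min * 12L + 360L))
  }
  expect_equal(nrow(merge_bouts_to_blocks(two(59), 60, eps)), 1L)
  expect_equal(nrow(merge_bouts_to_blocks(two(60), 60, eps)), 2L)
  # three bouts chained by 30-min gaps collapse into one spanning block
  b <- data.frame(start = c(1L, 721L, 1441L), end = c(361L, 1081L, 1801L))
  m <- merge_bouts_to_blocks(b, 60, eps)
  expect_equal(m, data.frame(start = 1L, end = 1801L))
  expect_equal(m, oracle_merge(b, 60 * 12))
  # random sorted disjoint bouts vs transitive-closure oracle
  for (seed in 1:10) {
    set.seed(seed)
    pos <- 0L
    b <- do.call(rbind, lapply(1:8, function(i) {
      s <- pos + sample(5:400, 1)
      e <- s + sample(1:150, 1)
      pos <<- e
      data.frame(start = s, end = e)
    }))
    gap_min <- sample(c(2, 10, 30), 1)
    expect_equal(merge_bouts_to_blocks(b, gap_min, eps),
                 oracle_merge(b, gap_min * 12))
  }
  expect_error(merge_bouts_to_blocks(
    data.frame(start = c(10L, 1L), end = c(20L, 5L))), "sorted")
})

test_that("SPT window is the longest block with earliest-onset tie-break", {
  blocks <- data.frame(start = c(100L, 3000L), end = c(100L + 2160L,
                                                       3000L + 5040L))
  expect_equal(detect_spt_window(blocks),
               data.frame(onset = 3000L, wake = 8040L))
  one <- data.frame(start = 5L, end = 50L)
  expect_equal(detect_spt_window(one), data.frame(onset = 5L, wake = 50L))
  ties <- data.frame(start = c(10L, 500L), end = c(110L, 600L))
  expect_equal(detect_spt_window(ties)$onset, 10L)
  expect_null(detect_spt_window(blocks[0, ]))
})

test_that("sleep episodes are stable runs of at least 5 min inside the SPT", {
  eps <- 5
  n <- 4000L
  spt <- data.frame(onset = 501L, wake = 3501L)
  # constant angle through the SPT -> one episode spanning (almost) all of it
  z <- runif(n, -80, 80)
  z[501:3500] <- 20
  ep <- detect_sleep_episodes(z, spt, epoch_seconds = eps)
  expect_equal(nrow(ep), 1L)
  expect_gte(ep$start, spt$onset)
  expect_lte(ep$end, spt$wake)
  expect_gte((ep$end - ep$start) * eps / 60, 249)  # ~250 min SPT
  # stable runs of 4 min separated by big posture changes -> no episodes
  z4 <- rep(rep(c(0, 30, 60, 30), length.out = 64), each = 47)[1:3000]
  z <- runif(n, -80, 80)
  z[501:3500] <- z4
  expect_equal(nrow(detect_sleep_episodes(z, spt, window_min = eps / 60,
                                          epoch_seconds = eps)), 0L)
  # planted posture changes at known epochs vs run-length oracle
  # (1-epoch rolling window so the stable mask equals the raw |diff| rule)
  z <- runif(n, -80, 80)
  z[501:3500] <- rep(c(10, 40, -20), c(1200, 900, 900))
  ep <- detect_sleep_episodes(z, spt, window_min = eps / 60,
                              epoch_seconds = eps)
  rolled <- rolling_median_abs_change(z, eps / 60, eps)
  mask <- rolled < 5
  mask[seq_len(n) < 501 | seq_len(n) >= 3501] <- FALSE
  expect_equal(ep, oracle_runs(mask, min_len = 60L))
  expect_equal(nrow(ep), 3L)
  expect_error(detect_sleep_episodes(z, data.frame(onset = 1L,
                                                   wake = n + 5L)),
               "outside")
})

test_that("day metrics follow their closed-form definitions", {
  eps <- 5
  epd <- 86400 / eps
  spt <- data.frame(onset = 7921L, wake = 7921L + 5760L)  # 480 min
  bouts <- data.frame(start = spt$onset, end = spt$wake)
  full <- data.frame(start = spt$onset, end = spt$wake)
  part <- data.frame(start = spt$onset, end = spt$onset + 4320L) # 360 min
  act <- rep(100, epd)
  m <- compute_day_metrics(act, spt, full, bouts, eps)
  expect_equal(m$sleep_efficiency, 1.0)
  expect_equal(m$spt_duration_min, 480)
  m <- compute_day_metrics(act, spt, part, bouts, eps)
  expect_equal(m$sleep_efficiency, 0.75)
  expect_equal(m$sleep_duration_min, 360)
  expect_equal(m$n_sleep_bouts, 1)
  expect_equal(m$sleep_midpoint_min, (7920 + 7920 + 5760) / 2 * eps / 60)
  expect_equal(m$diurnal_inactivity_min, 0)
  # planted activity trough 02:00-07:00 -> L5 midpoint 4.5 h after midnight
  act <- rep(100, epd)
  trough <- (14 * 3600 / eps + 1):(19 * 3600 / eps)  # 02:00-07:00
  act[trough] <- 1
  m <- compute_day_metrics(act, spt, part, bouts, eps)
  expect_equal(m$l5_timing_h, 4.5)
  # planted activity peak 13:00-23:00 -> M10 midpoint 6 h after midday
  act <- rep(10, epd)
  act[(3600 / eps + 1):(11 * 3600 / eps)] <- 200
  m <- compute_day_metrics(act, spt, part, bouts, eps)
  expect_equal(m$m10_timing_h, 6)
  # bout wholly outside the SPT counts as diurnal inactivity
  bouts2 <- rbind(bouts, data.frame(start = 1000L, end = 1480L))
  m <- compute_day_metrics(act, spt, part, bouts2[order(bouts2$start), ],
                           eps)
  expect_equal(m$diurnal_inactivity_min, 40)
  expect_error(compute_day_metrics(act, data.frame(onset = 5L, wake = 5L),
                                   part, bouts, eps), "positive duration")
})

test_that("L5/M10 moving-average search equals exhaustive window scan", {
  eps <- 60
  for (seed in 1:5) {
    set.seed(seed)
    act <- rexp(1440, 1 / 50)  # one day at 60-s epochs
    i5 <- oracle_extreme_window(act, 5 * 60, "min")
    i10 <- oracle_extreme_window(act, 10 * 60, "max")
    spt <- data.frame(onset = 1L, wake = 100L)
    ep <- data.frame(start = 1L, end = 100L)
    m <- compute_day_metrics(act, spt, ep, ep, eps)
    expect_equal(m$l5_timing_h, (((i5 - 1) + 150) * 60 / 3600 - 12) %% 24)
    expect_equal(m$m10_timing_h, (((i10 - 1) + 300) * 60 / 3600) %% 24)
  }
})

test_that("person summary uses the sample SD and flags single days", {
  days <- data.frame(spt_duration_min = rep(500, 3),
                     sleep_duration_min = c(400, 420, 440),
                     sleep_efficiency = c(0.8, 0.84, 0.88),
                     n_sleep_bouts = c(10, 12, 14),
                     sleep_midpoint_min = c(900, 910, 920),
                     l5_timing_h = c(3, 4, 5),
                     m10_timing_h = c(5, 6, 7),
                     diurnal_inactivity_min = c(0, 30, 60))
  s <- summarize_person(days)
  expect_equal(s$sleep_duration_mean_min, 420)
  expect_equal(s$sleep_duration_sd_min, 20)
  expect_equal(s$sleep_efficiency_mean, 0.84)
  # identical days -> zero SD
  s0 <- summarize_person(days[c(1, 1, 1), ])
  expect_equal(s0$sleep_duration_sd_min, 0)
  # single day -> SD missing
  expect_true(is.na(summarize_person(days[1, ])$sleep_duration_sd_min))
  # days without an SPT are excluded
  days2 <- rbind(days, NA)
  expect_equal(summarize_person(days2)$n_days, 3)
  expect_error(summarize_person(days[0, ]), "no days")
})

test_that("detector is invariant to adding a constant to all z-angles", {
  cfg <- accel_sim_config(n_days = 1, seed = 11, sleep_onset_min = 630,
                          sleep_wake_min = 1155)
  sim <- gen_accel_trace(cfg)
  # halve angles so a +15 degree offset cannot clip at the sensor range
  tr <- sim$trace
  tr$z_angle <- tr$z_angle / 2
  res_a <- run_actigraphy(tr)
  tr$z_angle <- tr$z_angle + 15
  res_b <- run_actigraphy(tr)
  expect_equal(res_a$days[, c("onset", "wake", "sleep_duration_min",
                              "n_sleep_bouts")],
               res_b$days[, c("onset", "wake", "sleep_duration_min",
                              "n_sleep_bouts")])
})

test_that("noiseless planted windows are recovered to the epoch grid", {
  cfg <- accel_sim_config(n_days = 3, angle_noise_sd = 0,
                          n_posture_changes_in_sleep = 0, seed = 5)
  sim <- gen_accel_trace(cfg)
  res <- run_actigraphy(sim$trace)
  day_onset <- sim$truth$onset_epoch - (sim$truth$day - 1) * 17280
  day_wake <- sim$truth$wake_epoch - (sim$truth$day - 1) * 17280
  # the entry transition occupies the window's first epoch, so a
  # change-based detector certifies stability from the second epoch on
  expect_equal(res$days$onset, day_onset + 1L)
  expect_equal(res$days$wake, day_wake)
  expect_equal(res$days$sleep_efficiency, rep(1, 3))
  # planted nap creates diurnal inactivity but never displaces the SPT
  cfgn <- accel_sim_config(n_days = 1, angle_noise_sd = 0,
                           n_posture_changes_in_sleep = 0,
                           daytime_nap = c(120, 210), seed = 5)
  simn <- gen_accel_trace(cfgn)
  resn <- run_actigraphy(simn$trace)
  expect_equal(resn$days$onset, day_onset[1] + 1L)
  expect_gte(resn$days$diurnal_inactivity_min, 85)
})

test_that("accelerometer CSV round-trips through read/write", {
  cfg <- accel_sim_config(n_days = 1, seed = 2)
  sim <- gen_accel_trace(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(sim$trace, path)
  back <- read_accel_csv(path)
  expect_equal(back$epoch_seconds, 5)
  expect_equal(back$z_angle, sim$trace$z_angle, tolerance = 1e-6)
  expect_equal(run_actigraphy(back)$days$onset,
               run_actigraphy(sim$trace)$days$onset)
})
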