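# Activity classification, bout segmentation and locomotor summaries.

test_that("speed is displacement over time (Pythagoras oracle)", {
  traj <- data.frame(fly_id = "f", t_s = c(0, 0.2), x_mm = c(0, 3),
                     y_mm = c(0, 4))
  expect_equal(compute_speed(traj), 25)
  # stationary fly
  still <- data.frame(fly_id = "f", t_s = (0:10) * 0.2, x_mm = 0, y_mm = 0)
  expect_equal(compute_speed(still), rep(0, 10))
  # straight walk at 6.2 mm/s
  expect_equal(unique(round(compute_speed(straight_trajectory(6.2)), 9)), 6.2)
})

test_that("speed requires a uniform time grid", {
  bad <- data.frame(fly_id = "f", t_s = c(0, 0.2, 0.6), x_mm = 0:2, y_mm = 0)
  expect_error(compute_speed(bad), "non-uniform")
})

test_that("activity classification obeys the threshold and edge rule", {
  sp <- c(0.5, 2, 2, 0.1)
  expect_equal(classify_activity(sp, 0), rep(TRUE, 5))        # threshold 0
  expect_equal(classify_activity(sp, 10), rep(FALSE, 5))      # all below
  r <- classify_activity(sp, 1)
  expect_equal(r, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(r[1], r[2])  # first sample inherits the second's class
})

test_that("percent active is non-increasing in the threshold", {
  sess <- small_session(n_flies = 2, duration_s = 300, seed = 9)
  tr <- sess$trajectories[sess$trajectories$fly_id == "fly001", ]
  sp <- compute_speed(tr)
  pa <- vapply(c(0, 0.5, 1, 2, 4, 8, 16),
               function(th) mean(classify_activity(sp, th)), numeric(1))
  expect_true(all(diff(pa) <= 0))
})

test_that("segmentation equals run-length encoding when no merging occurs", {
  set.seed(33)
  # random raster built of runs all >= 2 samples
  runs <- pmax(2, rpois(40, 5))
  vals <- rep(c(TRUE, FALSE), 20)
  raster <- rep(vals, runs)
  seg <- segment_bouts(raster, dt = 0.2, min_bout_s = 0.4, min_ibi_s = 0.4)
  r <- rle(raster)
  expect_equal(nrow(seg), length(r$lengths))
  expect_equal(seg$end_s - seg$start_s, r$lengths * 0.2)
  expect_equal(seg$kind == "walk", r$values)
  expect_equal(seg$censored_start, seq_len(nrow(seg)) == 1)
  expect_equal(seg$censored_end, seq_len(nrow(seg)) == nrow(seg))
})

test_that("sub-minimum runs are merged into the flanking state", {
  # pattern: 10 walk, 1 pause, 10 walk -> one 21-sample walk bout
  raster <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10))
  seg <- segment_bouts(raster, dt = 0.2, min_bout_s = 0.4, min_ibi_s = 0.4)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$kind, "walk")
  expect_equal(seg$end_s - seg$start_s, 21 * 0.2)
})

test_that("segmentation tiles the session for arbitrary rasters", {
  set.seed(44)
  for (i in 1:10) {
    raster <- runif(200) > runif(1, 0.2, 0.8)
    seg <- segment_bouts(raster, dt = 0.2, min_bout_s = 0.4, min_ibi_s = 0.4)
    expect_equal(sum(seg$end_s - seg$start_s), 200 * 0.2, tolerance = 1e-9)
    if (nrow(seg) > 1)
      expect_true(all(seg$kind[-1] != seg$kind[-nrow(seg)]))
  }
})

test_that("strict alternation yields the constructed bout statistics", {
  # 2 s walk / 3 s pause over 60 min: 720 cycles
  traj <- blocky_trajectory(walk_s = 2, pause_s = 3, duration_s = 3600)
  s <- summarize_session(traj)
  expect_equal(s$n_bouts, 720)
  expect_equal(s$mean_bout_s, 2)
  expect_equal(s$mean_ibi_s, 3)
  expect_equal(s$percent_active, 100 * 2 / 5)
  # initiation rate: one onset per 3-s pause (first walk bout censored)
  expect_equal(s$initiation_rate_per_s, 719 / (720 * 3), tolerance = 1e-6)
})

test_that("a fully active session gives one doubly censored bout and no IBIs", {
  traj <- straight_trajectory(6, n_steps = 100)
  s <- summarize_session(traj)
  expect_equal(s$n_bouts, 1)
  expect_equal(s$percent_active, 100)
  expect_true(is.na(s$mean_ibi_s))
  expect_true(is.na(s$initiation_rate_per_s))  # no pause time
})

test_that("a fully paused session reports zero activity and zero initiations", {
  traj <- data.frame(fly_id = "f", t_s = (0:100) * 0.2, x_mm = 0, y_mm = 0)
  s <- summarize_session(traj)
  expect_equal(s$percent_active, 0)
  expect_equal(s$initiation_rate_per_s, 0)
})

test_that("preset cohorts recover the published locomotor metrics", {
  # per-fly metrics within 10% of the generating parameters at modest n
  cases <- list(
    wt25 = c(act = 34, speed = 6.2, init = 1 / 3.2, bout = 1.6, ibi = 3.2),
    wt31 = c(act = 77, speed = 10.4, init = 1 / 0.9, bout = 3.2, ibi = 0.9)
  )
  for (cn in names(cases)) {
    sess <- generate_locomotor_session(
      preset_config(cn, n_flies = 40, duration_s = 1800, seed = 17))
    s <- summarize_cohort(sess$trajectories)
    tgt <- cases[[cn]]
    expect_equal(mean(s$percent_active), tgt[["act"]], tolerance = 0.10)
    expect_equal(mean(s$mean_speed_active_mm_s), tgt[["speed"]], tolerance = 0.10)
    expect_equal(mean(s$initiation_rate_per_s), tgt[["init"]], tolerance = 0.10)
    expect_equal(mean(s$mean_bout_s), tgt[["bout"]], tolerance = 0.10)
    expect_equal(mean(s$mean_ibi_s), tgt[["ibi"]], tolerance = 0.10)
  }
})

test_that("startle response recovers the generator speed shift", {
  for (delta in c(2.4, -1.2)) {
    sess <- generate_locomotor_session(session_config(
      n_flies = 25, duration_s = 1200, startle_delta_mm_s = delta,
      bout_mean_s = 3.2, pause_mean_s = 0.9, seed = 23))
    st <- vapply(split(sess$trajectories, sess$trajectories$fly_id),
                 function(tr) {
                   attr(tr, "stimulus") <- attr(sess$trajectories, "stimulus")
                   startle_response(tr)$delta_speed_mm_s
                 }, numeric(1))
    expect_equal(mean(st, na.rm = TRUE), delta, tolerance = 0.25)
    if (delta < 0) expect_lt(mean(st, na.rm = TRUE), 0)
  }
})

test_that("no speed change across the stimulus gives a zero startle delta", {
  traj <- straight_trajectory(6, n_steps = 1500)  # 300 s constant walking
  attr(traj, "stimulus") <- stimulus_event(onset_s = 150)
  expect_equal(startle_response(traj, window_s = 60)$delta_speed_mm_s, 0)
})

test_that("startle errors without a stimulus or with an oversized window", {
  traj <- straight_trajectory(6, n_steps = 1500)
  expect_error(startle_response(traj), "no stimulus")
  attr(traj, "stimulus") <- stimulus_event(onset_s = 20)
  expect_error(startle_response(traj, window_s = 60), "window")
})

test_that("raster matrix stacks flies and averages columns", {
  # one all-active fly: a row of ones
  traj <- straight_trajectory(6, n_steps = 20)
  rm1 <- raster_matrix(traj)
  expect_true(all(rm1$matrix == 1))
  # two complementary flies -> column mean 0.5
  n <- 20
  a <- blocky_trajectory(2, 2, duration_s = n * 0.2)
  b <- blocky_trajectory(2, 2, duration_s = n * 0.2)
  b$x_mm <- c(b$x_mm[-1], b$x_mm[length(b$x_mm) - 1])  # shifted by one step
  a$fly_id <- "a"; b$fly_id <- "b"
  # mismatched grids must error
  bad <- b; bad$t_s <- bad$t_s + 0.1
  expect_error(raster_matrix(rbind(a, bad)), "shared time grid")
})

test_that("warmer cohort activity curve dominates the cooler one", {
  s25 <- generate_locomotor_session(
    preset_config("wt25", n_flies = 20, duration_s = 900, seed = 31))
  s31 <- generate_locomotor_session(
    preset_config("wt31", n_flies = 20, duration_s = 900, seed = 32))
  c25 <- raster_matrix(s25$trajectories)$activity_curve
  c31 <- raster_matrix(s31$trajectories)$activity_curve
  expect_gte(mean(c31 > c25), 0.95)
})
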