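# Locomotor session generator: determinism, confinement, tiling, renewal
# consistency.

test_that("identical seeds give bit-identical sessions, different seeds differ", {
  a <- small_session(seed = 42)
  b <- small_session(seed = 42)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth$intervals, b$truth$intervals)
  c <- small_session(seed = 43)
  expect_false(identical(a$trajectories$x_mm, c$trajectories$x_mm))
})

test_that("all positions stay within the arena radius", {
  for (cn in c("wt25", "wt31")) {
    sess <- generate_locomotor_session(
      preset_config(cn, n_flies = 3, duration_s = 300, seed = 7))
    r <- sqrt(sess$trajectories$x_mm^2 + sess$trajectories$y_mm^2)
    expect_lte(max(r), 17.5)
  }
})

test_that("walk and pause intervals alternate and tile the session exactly", {
  sess <- small_session(n_flies = 4, duration_s = 600, seed = 3)
  for (iv in split(sess$truth$intervals, sess$truth$intervals$fly_id)) {
    expect_equal(sum(iv$end_s - iv$start_s), 600, tolerance = 1e-9)
    expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)], tolerance = 1e-9)
    expect_true(all(iv$kind[-1] != iv$kind[-nrow(iv)]))
  }
})

test_that("generated durations honour the configured means", {
  cfg <- session_config(n_flies = 30, duration_s = 1800, bout_mean_s = 3.2,
                        pause_mean_s = 0.9, pause_shape_k = 0.45, seed = 5)
  sess <- generate_locomotor_session(cfg)
  iv <- sess$truth$intervals
  uncens <- !iv$censored_start & !iv$censored_end
  expect_equal(mean(iv$end_s[uncens & iv$kind == "walk"] -
                      iv$start_s[uncens & iv$kind == "walk"]),
               3.2, tolerance = 0.1)
  expect_equal(mean(iv$end_s[uncens & iv$kind == "pause"] -
                      iv$start_s[uncens & iv$kind == "pause"]),
               0.9, tolerance = 0.1)
})

test_that("fraction of time walking matches the renewal occupancy", {
  # bout_mean / (bout_mean + pause_mean): generated ground truth across a
  # cohort must sit within 3 percentage points
  cfg <- session_config(n_flies = 100, duration_s = 3600, bout_mean_s = 3.2,
                        pause_mean_s = 0.9, pause_shape_k = 0.45, seed = 11)
  sess <- generate_locomotor_session(cfg)
  iv <- sess$truth$intervals
  frac <- sum(iv$end_s[iv$kind == "walk"] - iv$start_s[iv$kind == "walk"]) /
    sum(iv$end_s - iv$start_s)
  expect_equal(frac, 3.2 / (3.2 + 0.9), tolerance = 0.03 / frac)
})

test_that("an always-active configuration yields a single walk interval", {
  sess <- generate_locomotor_session(
    session_config(n_flies = 1, duration_s = 60, pause_mean_s = 0, seed = 1))
  iv <- sess$truth$intervals
  expect_equal(nrow(iv), 1)
  expect_equal(iv$kind, "walk")
})

test_that("invalid session configurations are rejected", {
  expect_error(session_config(duration_s = 0), "duration_s")
  expect_error(session_config(sample_dt_s = -1), "sample_dt_s")
  expect_error(session_config(pause_shape_k = 0), "pause_shape_k")
  expect_error(session_config(bout_mean_s = -2), "bout_mean_s")
  expect_error(session_config(arena_diameter_mm = 0), "arena_diameter_mm")
})

test_that("presets carry the published per-condition parameters", {
  p <- preset_config("wt25")
  expect_equal(p$bout_mean_s, 1.6)
  expect_equal(p$pause_mean_s, 3.2)
  expect_equal(p$pause_shape_k, 0.27)
  expect_equal(p$speed_mean_mm_s, 6.2)
  expect_equal(p$startle_delta_mm_s, 2.4)
  p <- preset_config("c105-shi31")
  expect_equal(p$bout_mean_s, 1.3)
  expect_equal(p$pause_mean_s, 0.9)
  expect_equal(p$pause_shape_k, 0.27)
  expect_equal(p$speed_mean_mm_s, 6.8)
  expect_equal(preset_config("R59B10-shi31")$startle_delta_mm_s, -1.2)
  expect_error(preset_config("nonsense"), "unknown condition")
})

# --- imaging generators ---------------------------------------------------

test_that("noiseless zero-amplitude movie is constant and ramp spans 20-35 C", {
  cfg <- calcium_movie_config(n_cells = 1, transient_amplitude_rel = 0,
                              noise_sd = 0)
  mv <- generate_calcium_movie(cfg)
  expect_equal(min(mv$ramp$temp_c), 20)
  expect_equal(max(mv$ramp$temp_c), 35)
  expect_true(all(mv$stack == as.vector(mv$stack[, , 1])))
})

test_that("movie generator rejects negative noise and embeds exact amplitudes", {
  expect_error(calcium_movie_config(noise_sd = -1), "noise_sd")
  mv <- generate_calcium_movie(
    calcium_movie_config(n_cells = 1, transient_amplitude_rel = 0.49,
                         onset_temp_c = 27, noise_sd = 0))
  tr <- extract_roi_traces(mv$stack, mv$masks)
  d <- compute_dff(tr$intensity, mv$frame_times)
  expect_equal(max(d$dff), 0.49, tolerance = 1e-12)
})

test_that("campari stacks reproduce the configured ratio and reject bad dims", {
  st <- generate_campari_stacks(campari_config(red_green_ratio_true = 0.16,
                                               noise_sd = 0))
  expect_equal(campari_ratio(st$green, st$red, st$mask)$ratio_pct, 16,
               tolerance = 1e-9)
  expect_error(campari_config(n_slices = 0), "dimensions")
  expect_error(campari_config(green_level = 0), "green_level")
})

# --- voltage trace generator ----------------------------------------------

test_that("zero-current trace is flat at the resting potential", {
  vt <- generate_voltage_traces(
    voltage_trace_config(current_steps_pa = 0, noise_sd_mv = 0))
  expect_equal(unique(vt$traces[[1]]$vm_mv), -52.9)
})

test_that("a step at the rate ceiling carries the expected spike count", {
  vt <- generate_voltage_traces(
    voltage_trace_config(current_steps_pa = 40, gain_hz_per_pa = 2,
                         max_rate_hz = 80, step_s = 1))
  expect_equal(vt$truth$per_step$n_spikes, 80)
})

test_that("hyperpolarizing steady state follows Ohm's law", {
  vt <- generate_voltage_traces(
    voltage_trace_config(current_steps_pa = -10, rin_mohm = 1185,
                         noise_sd_mv = 0, tau_ms = 20))
  tr <- vt$traces[[1]]
  steady <- tr$t_s >= tr$step_onset_s + 0.8 * tr$step_dur_s &
    tr$t_s < tr$step_onset_s + tr$step_dur_s
  expect_equal(mean(tr$vm_mv[steady]) - (-52.9), -11.85, tolerance = 1e-3)
})

test_that("empty current-step list is rejected", {
  expect_error(voltage_trace_config(current_steps_pa = numeric(0)), "empty")
})
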