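#' Mechanical startle stimulus description
#'
#' The open-field protocol delivers a short train of arena vibrations half-way
#' through the recording to probe arousal: five 200-ms pulses separated by
#' 800-ms gaps, 30 min after recording onset.  The stimulus span (from first
#' pulse onset to last pulse offset) is therefore 4.2 s by default.
#'
#' @param onset_s Stimulus onset, seconds from recording start.
#' @param n_pulses Number of vibration pulses.
#' @param pulse_ms Pulse duration, milliseconds.
#' @param gap_ms Gap between consecutive pulses, milliseconds.
#' @return An object of class `stimulus_event` with fields `onset_s`,
#'   `n_pulses`, `pulse_ms`, `gap_ms` and the derived `end_s`.
#' @examples
#' stim <- stimulus_event()
#' stim$end_s - stim$onset_s  # 4.2 s span
#' @export
stimulus_event <- function(onset_s = 1800, n_pulses = 5, pulse_ms = 200,
                           gap_ms = 800) {
  stopifnot(onset_s >= 0, n_pulses >= 0, pulse_ms >= 0, gap_ms >= 0)
  span_s <- if (n_pulses > 0) {
    (n_pulses * pulse_ms + (n_pulses - 1) * gap_ms) / 1000
  } else 0
  structure(
    list(onset_s = onset_s, n_pulses = n_pulses, pulse_ms = pulse_ms,
         gap_ms = gap_ms, end_s = onset_s + span_s),
    class = "stimulus_event"
  )
}

#' @export
print.stimulus_event <- function(x, ...) {
  cat(sprintf("<stimulus_event> %d pulse(s) of %g ms / %g ms gap, onset %g s (span %g s)\n",
              x$n_pulses, x$pulse_ms, x$gap_ms, x$onset_s, x$end_s - x$onset_s))
  invisible(x)
}

#' Configuration of a simulated open-field session
#'
#' Describes one cohort of flies walking in circular arenas, recorded as
#' position samples on a uniform grid.  Locomotion follows a two-state
#' renewal process: walking bouts (exponential or gamma durations) alternate
#' with pauses whose durations follow a Weibull law with shape
#' `pause_shape_k`.  Durations are resolved on the sampling grid (see
#' [generate_locomotor_session()]); `bout_mean_s` and `pause_mean_s` are the
#' means of the generated, grid-resolved durations.
#'
#' @param n_flies Number of flies in the cohort.
#' @param duration_s Session length, seconds.
#' @param sample_dt_s Sampling interval of the position track, seconds.
#' @param arena_diameter_mm Arena diameter, millimetres.
#' @param bout_mean_s Mean walking-bout duration, seconds.
#' @param bout_family Family of the bout-duration law, `"exponential"`
#'   (default) or `"gamma"`.
#' @param bout_gamma_shape Shape of the gamma bout law when
#'   `bout_family = "gamma"`.
#' @param pause_shape_k Weibull shape of the pause (inter-bout interval)
#'   duration law; values below 1 produce bursty, heavy-tailed pausing.
#' @param pause_mean_s Mean pause duration, seconds.
#' @param speed_mean_mm_s,speed_sd_mm_s Mean and SD of the per-bout walking
#'   speed, mm/s.
#' @param startle_delta_mm_s Shift of walking speed during the post-stimulus
#'   startle window, mm/s (negative values allowed).
#' @param startle_window_s Length of the post-stimulus window over which the
#'   speed shift applies, seconds.
#' @param stimulus A [stimulus_event()], or `NULL` for no stimulus.  When
#'   not supplied, the stimulus is placed at the session midpoint (30 min
#'   into the standard 60-min recording).
#' @param condition Condition label carried into the trajectory table.
#' @param seed Integer seed; identical configurations yield bit-identical
#'   output.
#' @return An object of class `session_config`.
#' @seealso [preset_config()] for the published per-condition parameter sets.
#' @export
session_config <- function(n_flies = 138,
                           duration_s = 3600,
                           sample_dt_s = 0.2,
                           arena_diameter_mm = 35,
                           bout_mean_s = 3.2,
                           bout_family = c("exponential", "gamma"),
                           bout_gamma_shape = 2,
                           pause_shape_k = 0.45,
                           pause_mean_s = 0.9,
                           speed_mean_mm_s = 10.4,
                           speed_sd_mm_s = 1.5,
                           startle_delta_mm_s = 1.7,
                           startle_window_s = 60,
                           stimulus = stimulus_event(onset_s = duration_s / 2),
                           condition = "unspecified",
                           seed = 1L) {
  bout_family <- match.arg(bout_family)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (sample_dt_s <= 0) stop("`sample_dt_s` must be positive", call. = FALSE)
  if (arena_diameter_mm <= 0) stop("`arena_diameter_mm` must be positive", call. = FALSE)
  if (bout_mean_s <= 0) stop("`bout_mean_s` must be positive", call. = FALSE)
  if (pause_shape_k <= 0) stop("`pause_shape_k` must be positive", call. = FALSE)
  if (pause_mean_s < 0) stop("`pause_mean_s` must be non-negative", call. = FALSE)
  if (n_flies < 1) stop("`n_flies` must be at least 1", call. = FALSE)
  if (speed_mean_mm_s <= 0) stop("`speed_mean_mm_s` must be positive", call. = FALSE)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_event"))
    if (stimulus$onset_s >= duration_s)
      stop("stimulus onset lies outside the session", call. = FALSE)
  }
  structure(
    list(n_flies = as.integer(n_flies), duration_s = duration_s,
         sample_dt_s = sample_dt_s, arena_diameter_mm = arena_diameter_mm,
         bout_mean_s = bout_mean_s, bout_family = bout_family,
         bout_gamma_shape = bout_gamma_shape,
         pause_shape_k = pause_shape_k, pause_mean_s = pause_mean_s,
         speed_mean_mm_s = speed_mean_mm_s, speed_sd_mm_s = speed_sd_mm_s,
         startle_delta_mm_s = startle_delta_mm_s,
         startle_window_s = startle_window_s,
         stimulus = stimulus, condition = condition, seed = as.integer(seed)),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> '%s': %d flies x %g s @ %g s, arena %g mm\n",
              x$condition, x$n_flies, x$duration_s, x$sample_dt_s,
              x$arena_diameter_mm))
  cat(sprintf("  bouts %s(mean %g s), pauses Weibull(k = %g, mean %g s)\n",
              x$bout_family, x$bout_mean_s, x$pause_shape_k, x$pause_mean_s))
  cat(sprintf("  speed %g +/- %g mm/s, startle delta %g mm/s, seed %d\n",
              x$speed_mean_mm_s, x$speed_sd_mm_s, x$startle_delta_mm_s, x$seed))
  invisible(x)
}

# Published per-condition locomotor parameters.  Speeds, bout and pause
# (inter-bout interval) means, Weibull shape and startle speed shift are the
# values reported per genotype/temperature; where a study condition does not
# report a parameter (marked in the roxygen of preset_config) the 31 degree
# wild-type value is used.
.preset_table <- list(
  wt25 = list(bout_mean_s = 1.6, pause_mean_s = 3.2, pause_shape_k = 0.27,
              speed_mean_mm_s = 6.2, startle_delta_mm_s = 2.4),
  wt31 = list(bout_mean_s = 3.2, pause_mean_s = 0.9, pause_shape_k = 0.45,
              speed_mean_mm_s = 10.4, startle_delta_mm_s = 1.7),
  `EB1-shi31` = list(bout_mean_s = 1.8, pause_mean_s = 2.1, pause_shape_k = 0.22,
                     speed_mean_mm_s = 8.0, startle_delta_mm_s = 1.9),
  `c232-shi31` = list(bout_mean_s = 3.2, pause_mean_s = 0.9, pause_shape_k = 0.26,
                      speed_mean_mm_s = 8.7, startle_delta_mm_s = 1.7),
  `c105-shi31` = list(bout_mean_s = 1.3, pause_mean_s = 0.9, pause_shape_k = 0.27,
                      speed_mean_mm_s = 6.8, startle_delta_mm_s = 2.4),
  `R59B10-shi31` = list(bout_mean_s = 1.7, pause_mean_s = 0.8, pause_shape_k = 0.37,
                        speed_mean_mm_s = 9.0, startle_delta_mm_s = -1.2),
  `R78B06-shi31` = list(bout_mean_s = 1.2, pause_mean_s = 0.9, pause_shape_k = 0.45,
                        speed_mean_mm_s = 5.4, startle_delta_mm_s = 0.8)
)

#' Session configuration for a published study condition
#'
#' Returns a [session_config()] populated with the per-condition locomotor
#' parameters reported for wild-type flies at 25 and 31 degrees C and for the
#' ring-neuron silencing genotypes recorded at 31 degrees C
#' (`shibire^TS` driven by `EB1`, `c232`, `c105`, `R59B10` or `R78B06`).
#'
#' Not every condition reports every parameter: the `c232-shi31` condition
#' reports only walking speed and shape factor, and `R78B06-shi31` reports
#' speed, bout length and startle shift; the remaining fields of those
#' presets fall back to the 31 degree wild-type values.
#'
#' @param condition_name One of `"wt25"`, `"wt31"`, `"EB1-shi31"`,
#'   `"c232-shi31"`, `"c105-shi31"`, `"R59B10-shi31"`, `"R78B06-shi31"`.
#' @param ... Overrides passed on to [session_config()] (e.g. `n_flies`,
#'   `seed`).
#' @return A `session_config`.
#' @examples
#' preset_config("wt25", n_flies = 10, seed = 42)
#' @export
preset_config <- function(condition_name, ...) {
  if (!condition_name %in% names(.preset_table)) {
    stop(sprintf("unknown condition '%s'; available: %s", condition_name,
                 paste(names(.preset_table), collapse = ", ")), call. = FALSE)
  }
  p <- .preset_table[[condition_name]]
  args <- c(p, list(condition = condition_name), list(...))
  do.call(session_config, args)
}
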