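# Locomotor metric extraction from position time series.

.check_single_fly <- function(traj) {
  if (length(unique(traj$fly_id)) != 1)
    stop("expected a single fly; split the cohort by `fly_id` first",
         call. = FALSE)
}

.traj_dt <- function(traj, tol = 1e-6) {
  dts <- diff(traj$t_s)
  if (length(dts) == 0) stop("trajectory needs at least 2 samples", call. = FALSE)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * max(1, dt)))
    stop("non-uniform timestamps in trajectory", call. = FALSE)
  dt
}

#' Instantaneous speed from a position track
#'
#' Finite-difference displacement between consecutive samples divided by the
#' sampling interval.  The series has one element fewer than the track;
#' element `i` is the speed over the step from sample `i` to sample `i + 1`.
#'
#' @param traj Single-fly trajectory data frame with columns `t_s`, `x_mm`,
#'   `y_mm` (uniform time grid).
#' @return Numeric vector of speeds, mm/s, length `nrow(traj) - 1`.
#' @examples
#' traj <- data.frame(fly_id = "f", t_s = c(0, 0.2), x_mm = c(0, 3),
#'                    y_mm = c(0, 4))
#' compute_speed(traj)  # 25 mm/s: 3-4-5 triangle over 0.2 s
#' @export
compute_speed <- function(traj) {
  .check_single_fly(traj)
  dt <- .traj_dt(traj)
  sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) / dt
}

#' Classify samples as active or inactive
#'
#' A sample is active when the speed of the step leading into it reaches
#' `threshold_mm_s`.  The first sample, which has no incoming step, inherits
#' the class of the second.
#'
#' @param speed Speed series from [compute_speed()].
#' @param threshold_mm_s Activity threshold, mm/s.  The default of 1 mm/s
#'   separates walking from positional jitter at 0.2-s sampling.
#' @return Logical vector of length `length(speed) + 1`.
#' @export
classify_activity <- function(speed, threshold_mm_s = 1.0) {
  if (threshold_mm_s < 0) stop("`threshold_mm_s` must be >= 0", call. = FALSE)
  if (length(speed) == 0) stop("empty speed series", call. = FALSE)
  active <- speed >= threshold_mm_s
  c(active[1], active)
}

#' Segment an activity raster into walk bouts and inter-bout intervals
#'
#' Run-length encodes the raster, then iteratively reassigns runs shorter
#' than the minimum durations to the flanking state (shortest run first;
#' when a walk and a pause run tie in length the walk run is reassigned
#' first).  The first and last intervals touch the recording edges and are
#' flagged as censored.
#'
#' @param raster Logical activity vector from [classify_activity()].
#' @param dt Sampling interval, seconds.
#' @param min_bout_s,min_ibi_s Minimum accepted walk-bout / pause durations,
#'   seconds.  The default of one sample (0.2 s) keeps every resolvable
#'   interval; raise to suppress classification flicker in noisy tracks.
#' @return Data frame with columns `start_s`, `end_s`, `kind`
#'   (`"walk"`/`"pause"`), `censored_start`, `censored_end`.  Intervals
#'   alternate and tile `[0, length(raster) * dt]`.
#' @export
segment_bouts <- function(raster, dt = 0.2, min_bout_s = 0.2, min_ibi_s = 0.2) {
  if (length(raster) == 0) stop("empty raster", call. = FALSE)
  r <- rle(as.logical(raster))
  repeat {
    if (length(r$lengths) <= 1) break
    len_s <- r$lengths * dt
    min_s <- ifelse(r$values, min_bout_s, min_ibi_s)
    bad <- which(len_s < min_s - 1e-9)
    if (length(bad) == 0) break
    # shortest first; walk runs take priority on ties
    ord <- order(len_s[bad], !r$values[bad])
    i <- bad[ord[1]]
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  n <- length(r$lengths)
  end_idx <- cumsum(r$lengths)
  start_idx <- end_idx - r$lengths
  data.frame(
    start_s = start_idx * dt,
    end_s = end_idx * dt,
    kind = ifelse(r$values, "walk", "pause"),
    censored_start = seq_len(n) == 1,
    censored_end = seq_len(n) == n,
    stringsAsFactors = FALSE
  )
}

#' Locomotor summary metrics for one fly
#'
#' Computes the percentage of time active, mean walking speed over active
#' samples, the action-initiation rate (uncensored walk-bout onsets per
#' second of total pause time), and mean bout / inter-bout-interval
#' durations with edge-censored intervals excluded.
#'
#' @param traj Single-fly trajectory.
#' @param segmentation Optional segmentation from [segment_bouts()];
#'   computed from `traj` with the parameters below when missing.
#' @param threshold_mm_s,min_bout_s,min_ibi_s Classification parameters, see
#'   [classify_activity()] and [segment_bouts()].
#' @return One-row data frame with `fly_id`, `percent_active`,
#'   `mean_speed_active_mm_s`, `initiation_rate_per_s`, `mean_bout_s`,
#'   `mean_ibi_s`, `n_bouts`.  The initiation rate is `NA` when there is no
#'   pause time and 0 for a fully paused session; duration means are `NA`
#'   when no uncensored interval of that kind exists.
#' @export
summarize_session <- function(traj, segmentation = NULL, threshold_mm_s = 1.0,
                              min_bout_s = 0.2, min_ibi_s = 0.2) {
  .check_single_fly(traj)
  dt <- .traj_dt(traj)
  speed <- compute_speed(traj)
  raster <- classify_activity(speed, threshold_mm_s)
  if (is.null(segmentation)) {
    segmentation <- segment_bouts(raster[-1], dt, min_bout_s, min_ibi_s)
  }
  seg <- segmentation
  dur <- seg$end_s - seg$start_s
  total <- sum(dur)
  walk <- seg$kind == "walk"
  percent_active <- 100 * sum(dur[walk]) / total
  # active samples consistent with the (possibly merged) segmentation
  step_active <- rep.int(walk, round(dur / dt))
  mean_speed_active <- if (any(step_active)) mean(speed[step_active]) else NA_real_
  pause_time <- sum(dur[!walk])
  onsets <- sum(walk & !seg$censored_start)
  initiation_rate <- if (pause_time > 0) {
    onsets / pause_time
  } else if (any(walk)) NA_real_ else 0
  uncens <- !seg$censored_start & !seg$censored_end
  mean_bout <- if (any(walk & uncens)) mean(dur[walk & uncens]) else NA_real_
  mean_ibi <- if (any(!walk & uncens)) mean(dur[!walk & uncens]) else NA_real_
  data.frame(
    fly_id = traj$fly_id[1],
    percent_active = percent_active,
    mean_speed_active_mm_s = mean_speed_active,
    initiation_rate_per_s = initiation_rate,
    mean_bout_s = mean_bout,
    mean_ibi_s = mean_ibi,
    n_bouts = sum(walk),
    stringsAsFactors = FALSE
  )
}

#' Startle response to the mechanical stimulus
#'
#' Change of walking speed across the stimulus: mean speed in the window
#' after stimulus offset minus mean speed in the window before stimulus
#' onset.  The stimulus span itself is excluded.  By default only active
#' samples enter the means, quantifying the change in walking speed rather
#' than in activity; set `active_only = FALSE` to average over all samples.
#'
#' @param traj Single-fly trajectory whose `stimulus` attribute is a
#'   [stimulus_event()] (or pass one via `stimulus`).
#' @param window_s Pre/post window length, seconds.
#' @param stimulus Optional stimulus overriding the trajectory attribute.
#' @param threshold_mm_s Activity threshold used when `active_only = TRUE`.
#' @param active_only Average over active samples only (default).
#' @return One-row data frame with `fly_id`, `delta_speed_mm_s`,
#'   `pre_mean_mm_s`, `post_mean_mm_s`, `window_s`.
#' @export
startle_response <- function(traj, window_s = 60, stimulus = NULL,
                             threshold_mm_s = 1.0, active_only = TRUE) {
  .check_single_fly(traj)
  if (is.null(stimulus)) stimulus <- attr(traj, "stimulus")
  if (is.null(stimulus)) stop("trajectory has no stimulus", call. = FALSE)
  dt <- .traj_dt(traj)
  t_end <- max(traj$t_s)
  if (stimulus$onset_s - window_s < 0 || stimulus$end_s + window_s > t_end)
    stop("startle window does not fit in the session", call. = FALSE)
  speed <- compute_speed(traj)
  t_mid <- traj$t_s[-1] - dt / 2  # time of each speed step (midpoint)
  pre <- t_mid >= stimulus$onset_s - window_s & t_mid < stimulus$onset_s
  post <- t_mid > stimulus$end_s & t_mid <= stimulus$end_s + window_s
  if (active_only) {
    act <- speed >= threshold_mm_s
    pre <- pre & act
    post <- post & act
  }
  pre_mean <- if (any(pre)) mean(speed[pre]) else NA_real_
  post_mean <- if (any(post)) mean(speed[post]) else NA_real_
  data.frame(
    fly_id = traj$fly_id[1],
    delta_speed_mm_s = post_mean - pre_mean,
    pre_mean_mm_s = pre_mean, post_mean_mm_s = post_mean,
    window_s = window_s, stringsAsFactors = FALSE
  )
}

#' Cohort activity raster matrix
#'
#' Stacks the per-fly activity rasters of a cohort into a flies-by-time
#' logical matrix and the population activity curve (column means).
#'
#' @param cohort Trajectory data frame covering several flies on a shared
#'   time grid (as produced by [generate_locomotor_session()]).
#' @param threshold_mm_s Activity threshold, mm/s.
#' @return List with `matrix` (rows = flies, columns = samples) and
#'   `activity_curve` (fraction of flies active per sample), plus `t_s`.
#' @export
raster_matrix <- function(cohort, threshold_mm_s = 1.0) {
  ids <- unique(cohort$fly_id)
  grids <- split(cohort$t_s, cohort$fly_id)
  ref <- grids[[ids[1]]]
  for (id in ids) {
    g <- grids[[id]]
    if (length(g) != length(ref) || any(abs(g - ref) > 1e-9))
      stop("flies are not on a shared time grid", call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    tr <- cohort[cohort$fly_id == id, , drop = FALSE]
    classify_activity(compute_speed(tr), threshold_mm_s)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  list(matrix = m, activity_curve = colMeans(m), t_s = ref)
}

#' Per-fly locomotor summaries for a whole cohort
#'
#' Convenience wrapper applying [summarize_session()] (and optionally
#' [startle_response()]) to every fly of a cohort.
#'
#' @inheritParams summarize_session
#' @param cohort Multi-fly trajectory data frame.
#' @param startle Also compute the startle response when the cohort carries
#'   a stimulus.
#' @param window_s Startle window, seconds.
#' @return Data frame with one row per fly.
#' @export
summarize_cohort <- function(cohort, threshold_mm_s = 1.0, min_bout_s = 0.2,
                             min_ibi_s = 0.2, startle = FALSE, window_s = 60) {
  stim <- attr(cohort, "stimulus")
  res <- lapply(split(seq_len(nrow(cohort)), cohort$fly_id), function(i) {
    tr <- cohort[i, , drop = FALSE]
    attr(tr, "stimulus") <- stim
    s <- summarize_session(tr, threshold_mm_s = threshold_mm_s,
                           min_bout_s = min_bout_s, min_ibi_s = min_ibi_s)
    if (startle && !is.null(stim)) {
      s$startle_delta_mm_s <- startle_response(
        tr, window_s = window_s, threshold_mm_s = threshold_mm_s
      )$delta_speed_mm_s
    }
    s
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled cohort action-initiation rate
#'
#' Total uncensored walk-bout onsets divided by total pause time, pooled
#' over all flies of a cohort.  The pooled ratio-of-sums is preferred over
#' averaging per-fly rates for this metric: per-fly rates are ratios with a
#' heavy-tailed random denominator (pause time), whose mean is biased
#' upward; pooling removes that bias (see the package vignette).
#'
#' @inheritParams summarize_cohort
#' @return Initiation rate, onsets per second of pause time (`NA` when the
#'   cohort has no pause time).
#' @export
cohort_initiation_rate <- function(cohort, threshold_mm_s = 1.0,
                                   min_bout_s = 0.2, min_ibi_s = 0.2) {
  parts <- lapply(split(seq_len(nrow(cohort)), cohort$fly_id), function(i) {
    tr <- cohort[i, , drop = FALSE]
    dt <- .traj_dt(tr)
    seg <- segment_bouts(classify_activity(compute_speed(tr), threshold_mm_s)[-1],
                         dt, min_bout_s, min_ibi_s)
    dur <- seg$end_s - seg$start_s
    c(onsets = sum(seg$kind == "walk" & !seg$censored_start),
      pause_s = sum(dur[seg$kind == "pause"]))
  })
  m <- do.call(rbind, parts)
  if (sum(m[, "pause_s"]) <= 0) return(NA_real_)
  sum(m[, "onsets"]) / sum(m[, "pause_s"])
}

#' Pooled inter-bout intervals of a cohort
#'
#' Segments every fly and pools the uncensored pause durations, the input
#' to the Weibull burstiness fit.
#'
#' @inheritParams summarize_cohort
#' @return Numeric vector of pause durations, seconds.
#' @export
cohort_ibis <- function(cohort, threshold_mm_s = 1.0, min_bout_s = 0.2,
                        min_ibi_s = 0.2) {
  unlist(lapply(split(seq_len(nrow(cohort)), cohort$fly_id), function(i) {
    tr <- cohort[i, , drop = FALSE]
    dt <- .traj_dt(tr)
    seg <- segment_bouts(classify_activity(compute_speed(tr), threshold_mm_s)[-1],
                         dt, min_bout_s, min_ibi_s)
    keep <- seg$kind == "pause" & !seg$censored_start & !seg$censored_end
    seg$end_s[keep] - seg$start_s[keep]
  }), use.names = FALSE)
}
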