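# Two-state renewal simulation of open-field walking.
#
# Durations are resolved on the sampling grid: a recording sampled every
# sample_dt_s cannot distinguish a pause shorter than one sample from
# continuous walking, so the generator draws continuous durations from the
# configured law and rounds them to the nearest grid multiple (minimum one
# sample).  The continuous scale parameter is calibrated numerically so the
# grid-resolved durations have exactly the requested mean; this keeps the
# renewal identity  fraction active = bout_mean / (bout_mean + pause_mean)
# exact for the generated ground truth.

# survival function S(x) of the configured duration law with scale `sc`
.duration_survival <- function(family, shape, sc) {
  switch(family,
    weibull = function(x) exp(-(x / sc)^shape),
    exponential = function(x) exp(-x / sc),
    gamma = function(x) stats::pgamma(x, shape = shape, scale = sc,
                                      lower.tail = FALSE)
  )
}

# mean of dt * max(1, round(X / dt)) for X with survival S:
# E = dt * (1 + sum_{m>=1} S((m + 0.5) dt))
.quantized_mean <- function(surv, dt, tol = 1e-10, block = 4096L) {
  total <- 0
  m0 <- 0L
  repeat {
    m <- (m0 + 1L):(m0 + block)
    s <- surv((m + 0.5) * dt)
    total <- total + sum(s)
    if (s[block] < tol || m0 > 5e6) break
    m0 <- m0 + block
  }
  dt * (1 + total)
}

# scale such that the grid-resolved mean equals `mean_target`
.calibrate_scale <- function(family, shape, mean_target, dt) {
  f <- function(sc) .quantized_mean(.duration_survival(family, shape, sc), dt) - mean_target
  lo <- mean_target * 1e-7
  hi <- mean_target * 4 + 4 * dt
  # the quantized mean is bounded below by dt; an unreachable target means
  # the requested mean is below the grid resolution
  if (mean_target < dt) {
    stop(sprintf("mean duration %g s is below the sampling resolution %g s",
                 mean_target, dt), call. = FALSE)
  }
  if (f(lo) > 0) return(lo)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

.draw_durations <- function(n, family, shape, sc) {
  switch(family,
    weibull = stats::rweibull(n, shape = shape, scale = sc),
    exponential = stats::rexp(n, rate = 1 / sc),
    gamma = stats::rgamma(n, shape = shape, scale = sc)
  )
}

# grid-resolved residual-length sampler for the equilibrium (stationary)
# start: the recording window opens on an ongoing process, so the first
# interval is the residual of a length-biased draw.  For a discrete
# alternating renewal process the residual length r (in samples) of the
# interval covering time 0 has P(r) proportional to P(L >= r).
.residual_weights <- function(surv, dt, tol = 1e-10, max_m = 5e6) {
  m <- 1L
  block <- 65536L
  out <- numeric(0)
  repeat {
    idx <- m:(m + block - 1L)
    s <- pmin(1, surv((idx - 0.5) * dt))
    s[idx == 1L] <- 1
    out <- c(out, s)
    if (s[block] < tol || length(out) >= max_m) break
    m <- m + block
  }
  out
}

# alternating walk/pause intervals tiling [0, duration_s] exactly; the
# session opens in the equilibrium state of the renewal process (state
# chosen by stationary occupancy, first interval from the residual-length
# law), so long-run time-in-state fractions are unbiased even over finite
# recordings
.simulate_intervals <- function(config, bout_scale, pause_scale, eq) {
  dur <- config$duration_s
  dt <- config$sample_dt_s
  p_walk <- config$bout_mean_s / (config$bout_mean_s + config$pause_mean_s)
  walk_first <- stats::runif(1) < p_walk
  w <- if (walk_first) eq$walk else eq$pause
  u <- stats::runif(1) * w$total
  first_len <- dt * findInterval(u, w$cum) + dt  # first index with cum >= u
  bf <- config$bout_family
  bshape <- if (bf == "gamma") config$bout_gamma_shape else 1
  kinds <- if (walk_first) "walk" else "pause"
  lens <- first_len
  repeat {
    covered <- sum(lens)
    if (covered >= dur) break
    n_pairs <- max(8L, ceiling(1.4 * (dur - covered) /
                                 (config$bout_mean_s + config$pause_mean_s)) + 8L)
    b <- dt * pmax(1, round(.draw_durations(n_pairs, bf, bshape, bout_scale) / dt))
    p <- dt * pmax(1, round(.draw_durations(n_pairs, "weibull",
                                            config$pause_shape_k, pause_scale) / dt))
    chunk <- if (xor(walk_first, length(kinds) %% 2 == 1)) {
      list(len = as.vector(rbind(b, p)), kind = rep(c("walk", "pause"), n_pairs))
    } else {
      list(len = as.vector(rbind(p, b)), kind = rep(c("pause", "walk"), n_pairs))
    }
    kinds <- c(kinds, chunk$kind)
    lens <- c(lens, chunk$len)
  }
  # truncate the last interval at the session end (right-censored)
  ends <- cumsum(lens)
  keep <- which(ends - lens < dur - 1e-9)
  kinds <- kinds[keep]
  lens <- lens[keep]
  ends <- ends[keep]
  lens[length(lens)] <- dur - (ends[length(ends)] - lens[length(lens)])
  data.frame(
    start_s = cumsum(lens) - lens,
    end_s = cumsum(lens),
    kind = kinds,
    stringsAsFactors = FALSE
  )
}

# positions for one fly from its interval table; persistent random walk with
# wrapped-gaussian turning during bouts, specular reflection at the wall,
# sub-threshold jitter around an anchor point during pauses
.simulate_positions <- function(intervals, speeds, config) {
  dt <- config$sample_dt_s
  n_steps <- round(config$duration_s / dt)
  radius <- config$arena_diameter_mm / 2
  # per-step state and speed from the interval table (steps are grid-aligned)
  step_kind <- character(n_steps)
  step_speed <- numeric(n_steps)
  idx <- rep.int(seq_len(nrow(intervals)),
                 times = round((intervals$end_s - intervals$start_s) / dt))
  idx <- idx[seq_len(n_steps)]
  step_kind <- intervals$kind[idx]
  step_speed <- ifelse(step_kind == "walk", speeds[idx], 0)
  # startle window: walking speed shifted after stimulus end
  t_mid <- (seq_len(n_steps) - 0.5) * dt
  if (!is.null(config$stimulus)) {
    w <- t_mid > config$stimulus$end_s &
      t_mid <= config$stimulus$end_s + config$startle_window_s
    step_speed[w & step_kind == "walk"] <-
      pmax(0, step_speed[w & step_kind == "walk"] + config$startle_delta_mm_s)
  }
  turn <- stats::rnorm(n_steps, 0, 30 * pi / 180)
  jit_r <- stats::runif(n_steps, 0, 0.045)
  jit_a <- stats::runif(n_steps, 0, 2 * pi)
  x <- numeric(n_steps + 1)
  y <- numeric(n_steps + 1)
  # random start inside the arena (uniform over the disc, away from the wall)
  r0 <- 0.9 * radius * sqrt(stats::runif(1))
  a0 <- stats::runif(1, 0, 2 * pi)
  x[1] <- r0 * cos(a0)
  y[1] <- r0 * sin(a0)
  heading <- stats::runif(1, 0, 2 * pi)
  ax <- x[1]; ay <- y[1]  # pause anchor
  walking_prev <- FALSE
  for (i in seq_len(n_steps)) {
    if (step_kind[i] == "walk") {
      heading <- heading + turn[i]
      nx <- x[i] + step_speed[i] * dt * cos(heading)
      ny <- y[i] + step_speed[i] * dt * sin(heading)
      r2 <- nx * nx + ny * ny
      if (r2 > radius * radius) {
        # specular reflection about the tangent at the boundary point
        r <- sqrt(r2)
        nxn <- nx / r; nyn <- ny / r
        # reflect the overshoot and the heading
        over <- r - radius
        nx <- nx - 2 * over * nxn
        ny <- ny - 2 * over * nyn
        dot <- cos(heading) * nxn + sin(heading) * nyn
        hx <- cos(heading) - 2 * dot * nxn
        hy <- sin(heading) - 2 * dot * nyn
        heading <- atan2(hy, hx)
        r2 <- nx * nx + ny * ny
        if (r2 > radius * radius) {  # pathological double-overshoot
          r <- sqrt(r2)
          nx <- nx * radius / r * 0.999
          ny <- ny * radius / r * 0.999
        }
      }
      x[i + 1] <- nx
      y[i + 1] <- ny
      walking_prev <- TRUE
    } else {
      if (walking_prev) { ax <- x[i]; ay <- y[i] }
      nx <- ax + jit_r[i] * cos(jit_a[i])
      ny <- ay + jit_r[i] * sin(jit_a[i])
      r2 <- nx * nx + ny * ny
      if (r2 > radius * radius * (1 - 1e-9)) {  # jitter near the wall stays inside
        r <- sqrt(r2)
        nx <- nx * radius * (1 - 1e-8) / r
        ny <- ny * radius * (1 - 1e-8) / r
      }
      x[i + 1] <- nx
      y[i + 1] <- ny
      walking_prev <- FALSE
    }
  }
  list(x = x, y = y)
}

#' Simulate an open-field locomotor session
#'
#' Generates seeded position tracks for a cohort of flies following a
#' two-state walk/pause renewal process, together with the ground truth that
#' produced them.  Walking bouts move the fly at a per-bout speed along a
#' persistent-random-walk heading with specular reflection at the arena
#' wall; pauses show only sub-threshold jitter (< 0.1 mm per step).  Pause
#' durations follow a Weibull law with shape `pause_shape_k`; bout durations
#' are exponential (or gamma).  All durations are resolved on the sampling
#' grid and the underlying scales are calibrated so the generated durations
#' have the requested means (see the package vignette).  Each session opens
#' in the equilibrium state of the renewal process — the flies have been in
#' the arena well before recording starts — so time-in-state fractions are
#' unbiased even over finite recordings.  After the end of the mechanical
#' stimulus, walking speed is shifted by `startle_delta_mm_s` for
#' `startle_window_s` seconds.
#'
#' @param config A [session_config()] or [preset_config()].
#' @return A list with class `locomotor_session`:
#' \describe{
#'   \item{trajectories}{data frame with columns `fly_id`, `t_s`, `x_mm`,
#'     `y_mm`, `condition`; attributes `arena_diameter_mm`, `stimulus`,
#'     `sample_dt_s`.}
#'   \item{truth}{list with `intervals` (per-fly walk/pause interval table
#'     with per-bout speeds and edge-censoring flags), `per_fly` (true mean
#'     speed and startle delta per fly), and the generating `config`.}
#' }
#' @examples
#' sess <- generate_locomotor_session(
#'   session_config(n_flies = 2, duration_s = 60, seed = 7))
#' head(sess$trajectories)
#' @export
generate_locomotor_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  dt <- config$sample_dt_s
  always_active <- config$pause_mean_s == 0
  bshape <- if (config$bout_family == "gamma") config$bout_gamma_shape else 1
  bout_scale <- .calibrate_scale(config$bout_family, bshape,
                                 config$bout_mean_s, dt)
  pause_scale <- if (always_active) NA_real_ else
    .calibrate_scale("weibull", config$pause_shape_k, config$pause_mean_s, dt)
  eq <- if (always_active) NULL else {
    wb <- .residual_weights(.duration_survival(config$bout_family, bshape,
                                               bout_scale), dt)
    wp <- .residual_weights(.duration_survival("weibull", config$pause_shape_k,
                                               pause_scale), dt)
    list(walk = list(cum = cumsum(wb), total = sum(wb)),
         pause = list(cum = cumsum(wp), total = sum(wp)))
  }

  n_steps <- round(config$duration_s / dt)
  t_grid <- (0:n_steps) * dt
  traj_list <- vector("list", config$n_flies)
  int_list <- vector("list", config$n_flies)
  per_fly <- vector("list", config$n_flies)
  for (f in seq_len(config$n_flies)) {
    fly_id <- sprintf("fly%03d", f)
    if (always_active) {
      intervals <- data.frame(start_s = 0, end_s = config$duration_s,
                              kind = "walk", stringsAsFactors = FALSE)
    } else {
      intervals <- .simulate_intervals(config, bout_scale, pause_scale, eq)
    }
    speeds <- pmax(1.2, stats::rnorm(nrow(intervals), config$speed_mean_mm_s,
                                     config$speed_sd_mm_s))
    speeds[intervals$kind == "pause"] <- 0
    pos <- .simulate_positions(intervals, speeds, config)
    intervals$speed_mm_s <- speeds
    intervals$censored_start <- seq_len(nrow(intervals)) == 1
    intervals$censored_end <- seq_len(nrow(intervals)) == nrow(intervals)
    intervals$fly_id <- fly_id
    int_list[[f]] <- intervals
    per_fly[[f]] <- data.frame(
      fly_id = fly_id,
      true_speed_mean_mm_s = mean(speeds[intervals$kind == "walk"]),
      true_startle_delta_mm_s = config$startle_delta_mm_s,
      stringsAsFactors = FALSE
    )
    traj_list[[f]] <- data.frame(
      fly_id = fly_id, t_s = t_grid, x_mm = pos$x, y_mm = pos$y,
      condition = config$condition, stringsAsFactors = FALSE
    )
  }
  traj <- do.call(rbind, traj_list)
  attr(traj, "arena_diameter_mm") <- config$arena_diameter_mm
  attr(traj, "stimulus") <- config$stimulus
  attr(traj, "sample_dt_s") <- dt
  truth <- list(
    intervals = do.call(rbind, int_list),
    per_fly = do.call(rbind, per_fly),
    config = config
  )
  structure(list(trajectories = traj, truth = truth),
            class = "locomotor_session")
}

#' @export
print.locomotor_session <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<locomotor_session> '%s': %d flies x %g s (%d samples/fly)\n",
              cfg$condition, cfg$n_flies, cfg$duration_s,
              round(cfg$duration_s / cfg$sample_dt_s) + 1))
  invisible(x)
}
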