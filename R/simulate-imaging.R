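# Synthetic image stacks with known ground truth: GCaMP movies driven by a
# temperature ramp, and two-channel CaMPARI photoconversion z-stacks.

#' Temperature ramp protocol
#'
#' Piecewise-linear bath temperature: a baseline hold, a linear rise to the
#' peak, a linear return, and a final hold.  The default emulates a
#' 20 -> 35 -> 20 degree C ramp with a 10-s hold on either side.
#'
#' @param frame_rate_hz Sampling rate of the trace, Hz.
#' @param base_c,peak_c Baseline and peak temperatures, degrees C.
#' @param hold_s Baseline hold before the rise and after the return, seconds.
#' @param rise_s,fall_s Durations of the heating and cooling phases, seconds.
#' @return Data frame with columns `t_s` and `temp_c`.
#' @export
temperature_ramp <- function(frame_rate_hz = 4, base_c = 20, peak_c = 35,
                             hold_s = 10, rise_s = 70, fall_s = 70) {
  stopifnot(frame_rate_hz > 0, rise_s > 0, fall_s > 0, hold_s >= 0)
  total <- 2 * hold_s + rise_s + fall_s
  t <- seq(0, total, by = 1 / frame_rate_hz)
  temp <- ifelse(t < hold_s, base_c,
          ifelse(t < hold_s + rise_s,
                 base_c + (peak_c - base_c) * (t - hold_s) / rise_s,
          ifelse(t < hold_s + rise_s + fall_s,
                 peak_c - (peak_c - base_c) * (t - hold_s - rise_s) / fall_s,
                 base_c)))
  data.frame(t_s = t, temp_c = temp)
}

#' Configuration of a synthetic GCaMP movie
#'
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param ramp Temperature ramp from [temperature_ramp()], sampled at the
#'   frame rate.
#' @param n_cells Number of circular cell ROIs.
#' @param width_px,height_px Frame size, pixels.
#' @param cell_radius_px ROI radius, pixels.
#' @param baseline_f Baseline fluorescence intensity inside each cell.
#' @param transient_amplitude_rel Peak delta-F/F0 of the embedded transient
#'   per cell (recycled to `n_cells`).
#' @param onset_temp_c Temperature at which each cell's transient starts
#'   (recycled).
#' @param decay_tau_s Exponential decay constant of the transient, seconds.
#' @param noise_sd Gaussian pixel noise SD (0 for a noiseless movie).
#' @param seed Integer seed.
#' @return An object of class `calcium_movie_config`.
#' @export
calcium_movie_config <- function(frame_rate_hz = 4,
                                 ramp = temperature_ramp(frame_rate_hz),
                                 n_cells = 4,
                                 width_px = 48, height_px = 48,
                                 cell_radius_px = 4,
                                 baseline_f = 100,
                                 transient_amplitude_rel = 0.49,
                                 onset_temp_c = 27,
                                 decay_tau_s = 15,
                                 noise_sd = 0,
                                 seed = 1L) {
  if (baseline_f <= 0) stop("`baseline_f` must be positive", call. = FALSE)
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  structure(
    list(frame_rate_hz = frame_rate_hz, ramp = ramp, n_cells = as.integer(n_cells),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         cell_radius_px = cell_radius_px, baseline_f = baseline_f,
         transient_amplitude_rel = rep_len(transient_amplitude_rel, n_cells),
         onset_temp_c = rep_len(onset_temp_c, n_cells),
         decay_tau_s = decay_tau_s, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "calcium_movie_config"
  )
}

.disc_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# transient time course on the frame grid: two-frame linear rise to exactly
# 1 at the peak frame, then exponential decay
.transient_shape <- function(n_frames, onset_frame, tau_frames) {
  s <- numeric(n_frames)
  if (is.na(onset_frame) || onset_frame > n_frames) return(s)
  peak <- min(onset_frame + 2L, n_frames)
  ramp_idx <- onset_frame:peak
  s[ramp_idx] <- seq(1 / length(ramp_idx), 1, length.out = length(ramp_idx))
  if (peak < n_frames) {
    after <- (peak + 1L):n_frames
    s[after] <- exp(-(after - peak) / tau_frames)
  }
  s
}

#' Simulate a GCaMP movie driven by a temperature ramp
#'
#' Cells are circular ROIs at fixed intensity `baseline_f` over a dim
#' background; when the ramp first crosses a cell's onset temperature the
#' cell brightens to exactly `baseline_f * (1 + amplitude)` within two
#' frames and decays exponentially.  The first five frames always precede
#' any temperature change, so the baseline-frame convention of
#' [compute_dff()] recovers the embedded amplitudes exactly in the
#' noiseless case.
#'
#' @param config A [calcium_movie_config()].
#' @return List of class `calcium_movie` with `stack` (array
#'   `height x width x frames`), `ramp` (temperature trace on the frame
#'   grid), `masks` (list of logical ROI masks), `frame_times`, and `truth`
#'   (per-cell amplitude, onset temperature, onset/peak frame).
#' @export
generate_calcium_movie <- function(config) {
  stopifnot(inherits(config, "calcium_movie_config"))
  set.seed(config$seed)
  h <- config$height_px; w <- config$width_px
  n_frames <- nrow(config$ramp)
  temp <- config$ramp$temp_c
  # cell centres on a ring around the image centre (deterministic layout)
  ang <- 2 * pi * (seq_len(config$n_cells) - 1) / config$n_cells
  rad <- min(h, w) / 3.2
  cx <- w / 2 + rad * cos(ang)
  cy <- h / 2 + rad * sin(ang)
  masks <- lapply(seq_len(config$n_cells), function(i)
    .disc_mask(h, w, cx[i], cy[i], config$cell_radius_px))
  background <- 0.1 * config$baseline_f
  tau_frames <- config$decay_tau_s * config$frame_rate_hz
  truth <- data.frame(cell = seq_len(config$n_cells),
                      amplitude_rel = config$transient_amplitude_rel,
                      onset_temp_c = config$onset_temp_c,
                      onset_frame = NA_integer_, peak_frame = NA_integer_)
  cell_f <- matrix(config$baseline_f, n_frames, config$n_cells)
  for (i in seq_len(config$n_cells)) {
    onset <- which(temp >= config$onset_temp_c[i])[1]
    if (!is.na(onset) && onset > 5) {
      s <- .transient_shape(n_frames, onset, tau_frames)
      cell_f[, i] <- config$baseline_f *
        (1 + config$transient_amplitude_rel[i] * s)
      truth$onset_frame[i] <- onset
      truth$peak_frame[i] <- min(onset + 2L, n_frames)
    }
  }
  stack <- array(background, dim = c(h, w, n_frames))
  for (i in seq_len(config$n_cells)) {
    m <- which(masks[[i]])
    for (k in seq_len(n_frames)) {
      frame <- stack[, , k]
      frame[m] <- cell_f[k, i]
      stack[, , k] <- frame
    }
  }
  if (config$noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, config$noise_sd)
    stack[stack < 0] <- 0
  }
  structure(
    list(stack = stack, ramp = config$ramp, masks = masks,
         frame_times = config$ramp$t_s, truth = truth, config = config),
    class = "calcium_movie"
  )
}

#' Configuration of a synthetic CaMPARI two-channel z-stack
#'
#' @param n_slices Number of virtual slices.
#' @param slice_thickness_um Slice spacing, micrometres (metadata only).
#' @param width_px,height_px Slice size, pixels.
#' @param green_level Green-channel intensity inside the labelled structure.
#' @param red_green_ratio_true True red/green ratio of the structure.
#' @param noise_sd Gaussian pixel noise SD.
#' @param seed Integer seed.
#' @return An object of class `campari_config`.
#' @export
campari_config <- function(n_slices = 8, slice_thickness_um = 2.5,
                           width_px = 48, height_px = 48,
                           green_level = 200, red_green_ratio_true = 0.16,
                           noise_sd = 0, seed = 1L) {
  if (green_level <= 0) stop("`green_level` must be positive", call. = FALSE)
  if (red_green_ratio_true < 0) stop("`red_green_ratio_true` must be >= 0", call. = FALSE)
  if (n_slices < 1 || width_px < 1 || height_px < 1)
    stop("stack dimensions must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(n_slices = as.integer(n_slices), slice_thickness_um = slice_thickness_um,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         green_level = green_level, red_green_ratio_true = red_green_ratio_true,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "campari_config"
  )
}

#' Simulate paired CaMPARI green/red z-stacks
#'
#' A ring-shaped structure (emulating the ellipsoid-body ring neuropil)
#' carries `green_level` in the green channel and
#' `red_green_ratio_true * green_level` in the red channel across the
#' central slices, over a dim background.  The maximum-intensity-projection
#' ROI ratio of the noiseless stacks equals the configured ratio exactly.
#'
#' @param config A [campari_config()].
#' @return List of class `campari_stacks` with `green` and `red` arrays
#'   (`height x width x slices`), the ROI `mask`, and `truth`.
#' @export
generate_campari_stacks <- function(config) {
  stopifnot(inherits(config, "campari_config"))
  set.seed(config$seed)
  h <- config$height_px; w <- config$width_px; nz <- config$n_slices
  r_out <- min(h, w) / 3
  r_in <- r_out / 2
  ring <- .disc_mask(h, w, w / 2, h / 2, r_out) &
    !.disc_mask(h, w, w / 2, h / 2, r_in)
  bg_green <- 0.05 * config$green_level
  green <- array(bg_green, dim = c(h, w, nz))
  red <- array(bg_green * config$red_green_ratio_true, dim = c(h, w, nz))
  centre <- max(1L, floor(nz / 4)):min(nz, ceiling(3 * nz / 4))
  m <- which(ring)
  for (k in centre) {
    g <- green[, , k]; g[m] <- config$green_level; green[, , k] <- g
    r <- red[, , k]; r[m] <- config$green_level * config$red_green_ratio_true
    red[, , k] <- r
  }
  if (config$noise_sd > 0) {
    green <- pmax(green + stats::rnorm(length(green), 0, config$noise_sd), 0)
    red <- pmax(red + stats::rnorm(length(red), 0, config$noise_sd), 0)
  }
  structure(
    list(green = green, red = red, mask = ring,
         truth = list(red_green_ratio = config$red_green_ratio_true,
                      roi_area_px = sum(ring)),
         config = config),
    class = "campari_stacks"
  )
}
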