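# GCaMP delta-F/F0 and CaMPARI red/green quantification.

#' Mean-intensity ROI traces from an image stack
#'
#' @param stack Numeric array `height x width x frames`.
#' @param rois Either a list of logical masks matching the frame size, or an
#'   integer labelled matrix (0 = background, each positive label one ROI).
#' @return Data frame with columns `roi_id`, `frame`, `intensity`; one row
#'   per ROI and frame (mean over the mask pixels).
#' @export
extract_roi_traces <- function(stack, rois) {
  stopifnot(length(dim(stack)) == 3)
  h <- dim(stack)[1]; w <- dim(stack)[2]; n_frames <- dim(stack)[3]
  if (is.matrix(rois) && !is.logical(rois)) {
    labels <- sort(setdiff(unique(as.vector(rois)), 0))
    rois <- lapply(labels, function(l) rois == l)
    names(rois) <- paste0("roi", labels)
  }
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  flat <- matrix(stack, nrow = h * w, ncol = n_frames)
  rows <- lapply(names(rois), function(id) {
    m <- rois[[id]]
    if (!is.logical(m) || !all(dim(m) == c(h, w)))
      stop("ROI mask does not match the frame geometry", call. = FALSE)
    px <- which(m)
    if (length(px) == 0) stop("empty ROI mask: ", id, call. = FALSE)
    data.frame(roi_id = id, frame = seq_len(n_frames),
               intensity = colMeans(flat[px, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative fluorescence change delta-F/F0
#'
#' The baseline F0 is the mean of the first `baseline_frames` images
#' (acquired before any temperature change); the trace is
#' `(F - F0) / F0`.
#'
#' @param intensity Mean ROI intensity per frame.
#' @param frame_times Optional frame times, seconds.
#' @param baseline_frames Number of leading frames defining F0 (default 5).
#' @return List of class `dff_trace` with `f0`, `dff` and `t_s`.
#' @examples
#' compute_dff(c(100, 100, 100, 100, 100, 149))$dff[6]  # 0.49
#' @export
compute_dff <- function(intensity, frame_times = NULL, baseline_frames = 5) {
  if (length(intensity) < baseline_frames + 1)
    stop(sprintf("need at least %d frames", baseline_frames + 1), call. = FALSE)
  f0 <- mean(intensity[seq_len(baseline_frames)])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline fluorescence F0 must be positive", call. = FALSE)
  structure(
    list(f0 = f0, dff = (intensity - f0) / f0,
         t_s = if (is.null(frame_times)) seq_along(intensity) - 1 else frame_times),
    class = "dff_trace"
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames, F0 = %.4g, peak dF/F0 = %.3g\n",
              length(x$dff), x$f0, max(x$dff)))
  invisible(x)
}

#' Peak and average ramp response
#'
#' Summarises a delta-F/F0 trace recorded during a temperature ramp: the
#' peak (maximum, first maximum on ties) and the average over the full ramp,
#' both as percentages, plus the bath temperature at the peak.  The
#' temperature trace is aligned to the frame times by nearest-time
#' interpolation.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param ramp Data frame with `t_s` and `temp_c`.
#' @return One-row data frame with `peak_dff_pct`, `average_dff_pct`,
#'   `temp_at_peak_c`.
#' @export
ramp_response <- function(dff, ramp) {
  stopifnot(inherits(dff, "dff_trace"))
  if (max(dff$t_s) > max(ramp$t_s) + 1e-6 || min(dff$t_s) < min(ramp$t_s) - 1e-6)
    stop("frame times extend beyond the temperature trace", call. = FALSE)
  temp_at <- vapply(dff$t_s, function(t) {
    ramp$temp_c[which.min(abs(ramp$t_s - t))]
  }, numeric(1))
  i_peak <- which.max(dff$dff)
  data.frame(
    peak_dff_pct = 100 * dff$dff[i_peak],
    average_dff_pct = 100 * mean(dff$dff),
    temp_at_peak_c = temp_at[i_peak]
  )
}

#' Detect calcium transients in a delta-F/F0 trace
#'
#' Upward threshold crossings separated by at least `min_separation_s`.
#' Each event reports its onset time, the bath temperature at onset (when a
#' ramp is supplied) and its amplitude (maximum delta-F/F0 between this
#' onset and the next, or the trace end).
#'
#' @param dff A `dff_trace`.
#' @param threshold Detection threshold on delta-F/F0 (> 0).
#' @param min_separation_s Minimum spacing between event onsets, seconds.
#' @param ramp Optional temperature trace (`t_s`, `temp_c`).
#' @return Data frame with `onset_t_s`, `onset_temp_c`, `amplitude`; zero
#'   rows when nothing crosses the threshold.
#' @export
detect_transients <- function(dff, threshold = 0.1, min_separation_s = 5,
                              ramp = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  x <- dff$dff
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  onsets <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (dff$t_s[i] - last_t >= min_separation_s) {
      onsets <- c(onsets, i)
      last_t <- dff$t_s[i]
    }
  }
  if (length(onsets) == 0) {
    return(data.frame(onset_t_s = numeric(0), onset_temp_c = numeric(0),
                      amplitude = numeric(0)))
  }
  ends <- c(onsets[-1] - 1L, length(x))
  amp <- vapply(seq_along(onsets), function(j)
    max(x[onsets[j]:ends[j]]), numeric(1))
  temp <- if (is.null(ramp)) rep(NA_real_, length(onsets)) else
    vapply(dff$t_s[onsets], function(t)
      ramp$temp_c[which.min(abs(ramp$t_s - t))], numeric(1))
  data.frame(onset_t_s = dff$t_s[onsets], onset_temp_c = temp, amplitude = amp)
}

#' Maximum-intensity projection of a z-stack
#'
#' Pixel-wise maximum over slices.
#'
#' @param zstack Numeric array `height x width x slices`, or a matrix
#'   (single slice, returned unchanged).
#' @return Matrix `height x width`.
#' @export
max_intensity_projection <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  stopifnot(length(dim(zstack)) == 3)
  apply(zstack, c(1, 2), max)
}

#' CaMPARI red/green photoconversion ratio
#'
#' Ratio of the mean red to mean green maximum-intensity-projection signal
#' within a region of interest, expressed in percent.
#'
#' @param green,red Z-stacks (arrays `height x width x slices`) of the green
#'   and red channel; must share geometry.
#' @param roi Logical mask matching the slice size.
#' @return One-row data frame with `ratio_pct` and `roi_area_px`.
#' @export
campari_ratio <- function(green, red, roi) {
  dg <- if (is.matrix(green)) c(dim(green), 1L) else dim(green)
  dr <- if (is.matrix(red)) c(dim(red), 1L) else dim(red)
  if (!all(dg == dr)) stop("green and red stacks differ in geometry", call. = FALSE)
  if (!is.logical(roi) || !all(dim(roi) == dg[1:2]))
    stop("ROI mask does not match the stack geometry", call. = FALSE)
  if (!any(roi)) stop("empty ROI mask", call. = FALSE)
  mip_g <- max_intensity_projection(green)
  mip_r <- max_intensity_projection(red)
  g <- mean(mip_g[roi])
  if (g <= 0) stop("zero green signal in the ROI", call. = FALSE)
  data.frame(ratio_pct = 100 * mean(mip_r[roi]) / g, roi_area_px = sum(roi))
}
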