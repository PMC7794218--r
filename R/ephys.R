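# Spike, f-I, passive and burst feature extraction from current-clamp traces.

#' Detect spikes by upward threshold crossing
#'
#' Counts samples where the membrane potential crosses `threshold_mv` from
#' below, enforcing a refractory period.  A sustained depolarised plateau
#' above threshold yields a single crossing at its onset and no further
#' events, matching the appearance of depolarisation block.
#'
#' @param trace List with `t_s` and `vm_mv` (uniform sampling), e.g. one
#'   element of [generate_voltage_traces()]`$traces`.
#' @param threshold_mv Detection threshold, mV.
#' @param refractory_ms Minimum spacing between detected spikes, ms.
#' @return List of class `spike_train` with `times_s` (strictly increasing)
#'   and `threshold_mv`.
#' @export
detect_spikes <- function(trace, threshold_mv = -20, refractory_ms = 2) {
  vm <- trace$vm_mv
  t_s <- trace$t_s
  dts <- diff(t_s)
  if (length(dts) > 0 && any(abs(dts - dts[1]) > 1e-9))
    stop("non-uniform sampling", call. = FALSE)
  up <- which(vm[-1] >= threshold_mv & vm[-length(vm)] < threshold_mv) + 1L
  refr <- refractory_ms / 1000
  keep <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (t_s[i] - last >= refr) {
      keep <- c(keep, t_s[i])
      last <- t_s[i]
    }
  }
  structure(list(times_s = keep, threshold_mv = threshold_mv),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike(s), threshold %g mV\n",
              length(x$times_s), x$threshold_mv))
  invisible(x)
}

#' Frequency-current (f-I) curve
#'
#' Firing rate per current step: spikes detected within the step window
#' divided by the step duration.
#'
#' @param traces List of traces, each with `t_s`, `vm_mv`, `current_pa`,
#'   `step_onset_s`, `step_dur_s` (see [generate_voltage_traces()]).
#' @param threshold_mv,refractory_ms Passed to [detect_spikes()].
#' @return List of class `fi_curve` with a data frame `curve`
#'   (`current_pa`, `rate_hz`) and `max_rate_hz`.
#' @export
fi_curve <- function(traces, threshold_mv = -20, refractory_ms = 2) {
  rows <- lapply(traces, function(tr) {
    if (is.null(tr$step_onset_s) || is.null(tr$step_dur_s))
      stop("trace lacks step metadata (`step_onset_s`, `step_dur_s`)",
           call. = FALSE)
    st <- detect_spikes(tr, threshold_mv, refractory_ms)
    in_step <- st$times_s >= tr$step_onset_s &
      st$times_s <= tr$step_onset_s + tr$step_dur_s
    data.frame(current_pa = tr$current_pa,
               rate_hz = sum(in_step) / tr$step_dur_s)
  })
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, max_rate_hz = max(curve$rate_hz)),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("<fi_curve> %d step(s), max rate %.3g Hz\n",
              nrow(x$curve), x$max_rate_hz))
  invisible(x)
}

#' Passive membrane properties from a current step
#'
#' Resting membrane potential as the mean pre-step voltage and input
#' resistance from the steady-state deflection of a (typically
#' hyperpolarising) current step, `Rin = dV / I`.
#'
#' @param trace Trace with step metadata (`current_pa`, `step_onset_s`,
#'   `step_dur_s`).
#' @param steady_frac Final fraction of the step averaged as steady state.
#' @return One-row data frame with `rmp_mv` and `rin_mohm` (`NA` when the
#'   step current is zero).
#' @export
passive_properties <- function(trace, steady_frac = 0.2) {
  t_s <- trace$t_s
  pre <- t_s < trace$step_onset_s
  if (sum(pre) < 2 || (trace$step_onset_s - t_s[1]) < 0.1)
    stop("need at least 100 ms of pre-step baseline", call. = FALSE)
  rmp <- mean(trace$vm_mv[pre])
  if (is.null(trace$current_pa) || trace$current_pa == 0) {
    return(data.frame(rmp_mv = rmp, rin_mohm = NA_real_))
  }
  t_end <- trace$step_onset_s + trace$step_dur_s
  steady <- t_s >= t_end - steady_frac * trace$step_dur_s & t_s < t_end
  defl_mv <- mean(trace$vm_mv[steady]) - rmp
  data.frame(rmp_mv = rmp, rin_mohm = defl_mv / trace$current_pa * 1000)
}

#' Burst structure of a spike train
#'
#' Bursts are maximal groups of spikes whose inter-spike intervals are all
#' below `isi_gap_ms`; groups of a single spike are not bursts.  The
#' instantaneous frequency is the reciprocal inter-spike interval within
#' bursts.
#'
#' @param spikes A `spike_train` from [detect_spikes()] (or a numeric vector
#'   of spike times, seconds).
#' @param isi_gap_ms Maximum within-burst inter-spike interval, ms.
#' @param duration_s Optional recording span used for the burst rate;
#'   defaults to the span of the spike train.
#' @return One-row data frame with `n_bursts`, `burst_rate_hz`,
#'   `mean_spikes_per_burst`, `max_spikes_per_burst`,
#'   `inst_freq_min_hz`, `inst_freq_max_hz`.
#' @export
burst_metrics <- function(spikes, isi_gap_ms = 100, duration_s = NULL) {
  times <- if (inherits(spikes, "spike_train")) spikes$times_s else spikes
  empty <- data.frame(n_bursts = 0L, burst_rate_hz = 0,
                      mean_spikes_per_burst = NA_real_,
                      max_spikes_per_burst = NA_real_,
                      inst_freq_min_hz = NA_real_, inst_freq_max_hz = NA_real_)
  if (length(times) < 2) return(empty)
  isi <- diff(times)
  gap <- isi_gap_ms / 1000
  grp <- cumsum(c(1, isi >= gap))
  sizes <- tabulate(grp)
  burst_ids <- which(sizes >= 2)
  if (length(burst_ids) == 0) return(empty)
  span <- if (is.null(duration_s)) diff(range(times)) else duration_s
  within <- isi < gap
  inst <- 1 / isi[within]
  data.frame(
    n_bursts = length(burst_ids),
    burst_rate_hz = if (span > 0) length(burst_ids) / span else NA_real_,
    mean_spikes_per_burst = mean(sizes[burst_ids]),
    max_spikes_per_burst = max(sizes[burst_ids]),
    inst_freq_min_hz = min(inst), inst_freq_max_hz = max(inst)
  )
}
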