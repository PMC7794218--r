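# Synthetic current-clamp traces with known passive and firing properties.

#' Configuration of synthetic current-clamp recordings
#'
#' One voltage trace per injected current step.  Depolarising steps fire at
#' `min(gain_hz_per_pa * I, max_rate_hz)`; steps above `block_above_pa`
#' enter depolarisation block (a sustained plateau above spike threshold
#' without discrete spikes).  Hyperpolarising steps charge exponentially to
#' the Ohmic deflection `I * rin_mohm`.
#'
#' @param rmp_mv Resting membrane potential, mV.
#' @param rin_mohm Input resistance, megaohm.
#' @param current_steps_pa Injected current per trace, pA.
#' @param gain_hz_per_pa Firing-rate gain, Hz/pA.
#' @param max_rate_hz Firing-rate ceiling, Hz.
#' @param block_above_pa Depolarisation-block threshold, pA (`NULL` for no
#'   block).
#' @param spike_amp_mv Spike height above the inter-spike baseline, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param pre_s,step_s,post_s Baseline, step and recovery durations, s.
#' @param tau_ms Membrane time constant, ms.
#' @param noise_sd_mv White-noise SD, mV.
#' @param seed Integer seed.
#' @return An object of class `voltage_trace_config`.
#' @export
voltage_trace_config <- function(rmp_mv = -52.9, rin_mohm = 1185,
                                 current_steps_pa = seq(-10, 40, by = 10),
                                 gain_hz_per_pa = 2, max_rate_hz = 80,
                                 block_above_pa = NULL, spike_amp_mv = 50,
                                 sample_rate_hz = 20000,
                                 pre_s = 0.5, step_s = 1, post_s = 0.5,
                                 tau_ms = 30, noise_sd_mv = 0, seed = 1L) {
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive", call. = FALSE)
  if (max_rate_hz <= 0) stop("`max_rate_hz` must be positive", call. = FALSE)
  if (length(current_steps_pa) == 0) stop("empty current-step list", call. = FALSE)
  if (rin_mohm <= 0) stop("`rin_mohm` must be positive", call. = FALSE)
  if (noise_sd_mv < 0) stop("`noise_sd_mv` must be >= 0", call. = FALSE)
  structure(
    list(rmp_mv = rmp_mv, rin_mohm = rin_mohm,
         current_steps_pa = current_steps_pa,
         gain_hz_per_pa = gain_hz_per_pa, max_rate_hz = max_rate_hz,
         block_above_pa = block_above_pa, spike_amp_mv = spike_amp_mv,
         sample_rate_hz = sample_rate_hz, pre_s = pre_s, step_s = step_s,
         post_s = post_s, tau_ms = tau_ms, noise_sd_mv = noise_sd_mv,
         seed = as.integer(seed)),
    class = "voltage_trace_config"
  )
}

# spike template: 1-ms rise, 1-ms fall above the local baseline
.add_spike <- function(vm, i_peak, amp, fs) {
  half <- max(2L, round(0.001 * fs))
  idx <- (i_peak - half):(i_peak + half)
  shape <- c(seq(0, 1, length.out = half + 1), seq(1, 0, length.out = half + 1)[-1])
  keep <- idx >= 1 & idx <= length(vm)
  vm[idx[keep]] <- vm[idx[keep]] + amp * shape[keep]
  vm
}

#' Simulate current-clamp voltage traces
#'
#' @param config A [voltage_trace_config()].
#' @return List of class `voltage_traces` with `traces` (one element per
#'   current step: `t_s`, `vm_mv`, `current_pa`, `step_onset_s`,
#'   `step_dur_s`) and `truth` (per-step true spike count and times,
#'   `rmp_mv`, `rin_mohm`).
#' @export
generate_voltage_traces <- function(config) {
  stopifnot(inherits(config, "voltage_trace_config"))
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  dt <- 1 / fs
  n_pre <- round(config$pre_s * fs)
  n_step <- round(config$step_s * fs)
  n_post <- round(config$post_s * fs)
  n <- n_pre + n_step + n_post
  t_s <- (seq_len(n) - 1) * dt
  tau_s <- config$tau_ms / 1000
  # sub-threshold depolarisation during spiking steps is capped well below
  # the spike threshold (spike-generating conductances shunt the membrane)
  depol_cap_mv <- 15
  traces <- vector("list", length(config$current_steps_pa))
  truth_rows <- vector("list", length(config$current_steps_pa))
  spike_times <- vector("list", length(config$current_steps_pa))
  for (j in seq_along(config$current_steps_pa)) {
    current <- config$current_steps_pa[j]
    vm <- rep(config$rmp_mv, n)
    step_idx <- (n_pre + 1):(n_pre + n_step)
    t_in <- (seq_len(n_step) - 1) * dt
    t_out <- (seq_len(n_post) - 1) * dt
    blocked <- !is.null(config$block_above_pa) && current > config$block_above_pa
    spikes <- numeric(0)
    if (blocked) {
      plateau <- 0  # mV, sustained depolarisation well above threshold
      vm[step_idx] <- config$rmp_mv +
        (plateau - config$rmp_mv) * (1 - exp(-t_in / tau_s))
      v_end <- vm[n_pre + n_step]
      vm[(n_pre + n_step + 1):n] <- config$rmp_mv +
        (v_end - config$rmp_mv) * exp(-t_out / tau_s)
    } else if (current != 0) {
      defl <- current * config$rin_mohm / 1000  # pA * Mohm -> mV
      v_target <- config$rmp_mv + if (current > 0) min(defl, depol_cap_mv) else defl
      vm[step_idx] <- config$rmp_mv +
        (v_target - config$rmp_mv) * (1 - exp(-t_in / tau_s))
      v_end <- vm[n_pre + n_step]
      vm[(n_pre + n_step + 1):n] <- config$rmp_mv +
        (v_end - config$rmp_mv) * exp(-t_out / tau_s)
      rate <- if (current > 0)
        min(config$gain_hz_per_pa * current, config$max_rate_hz) else 0
      n_spikes <- round(rate * config$step_s)
      if (n_spikes > 0) {
        spikes <- config$pre_s + (seq_len(n_spikes) - 0.5) / (n_spikes / config$step_s)
        for (ts in spikes) {
          vm <- .add_spike(vm, round(ts * fs), config$spike_amp_mv, fs)
        }
      }
    }
    if (config$noise_sd_mv > 0) vm <- vm + stats::rnorm(n, 0, config$noise_sd_mv)
    traces[[j]] <- list(t_s = t_s, vm_mv = vm, current_pa = current,
                        step_onset_s = config$pre_s, step_dur_s = config$step_s)
    truth_rows[[j]] <- data.frame(current_pa = current,
                                  n_spikes = length(spikes),
                                  blocked = blocked)
    spike_times[[j]] <- spikes
  }
  structure(
    list(traces = traces,
         truth = list(per_step = do.call(rbind, truth_rows),
                      spike_times = spike_times,
                      rmp_mv = config$rmp_mv, rin_mohm = config$rin_mohm),
         config = config),
    class = "voltage_traces"
  )
}
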