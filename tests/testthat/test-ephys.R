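# Spike detection, f-I, passive properties, bursts and junction potentials.

test_that("spike detection: silence, trains and depolarized plateaus", {
  # flat trace at rest
  flat <- list(t_s = seq(0, 1, by = 5e-5), vm_mv = rep(-52.9, 20001))
  expect_equal(length(detect_spikes(flat)$times_s), 0)
  # synthetic 80-Hz train over 1 s
  vt <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = 40, gain_hz_per_pa = 2, max_rate_hz = 80))
  st <- detect_spikes(vt$traces[[1]])
  expect_equal(length(st$times_s), 80)
  expect_true(all(diff(st$times_s) >= 0.002))
  # sustained plateau above threshold: exactly one crossing
  n <- 20001
  plateau <- list(t_s = seq(0, 1, by = 5e-5),
                  vm_mv = c(rep(-52.9, 5000), rep(0, n - 5000)))
  expect_equal(length(detect_spikes(plateau)$times_s), 1)
})

test_that("f-I curve matches the generator gain and saturates", {
  vt <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = c(10, 20, 30, 40), gain_hz_per_pa = 2,
    max_rate_hz = 80))
  fi <- fi_curve(vt$traces)
  expect_equal(fi$curve$rate_hz, c(20, 40, 60, 80))
  expect_equal(fi$max_rate_hz, 80)
  # silent traces give a zero curve
  vt0 <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = c(-10, 0)))
  expect_equal(fi_curve(vt0$traces)$curve$rate_hz, c(0, 0))
  # depolarization block: rate collapses above the block current
  vtb <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = c(20, 40, 60), gain_hz_per_pa = 2, max_rate_hz = 80,
    block_above_pa = 40))
  fib <- fi_curve(vtb$traces)
  expect_equal(fib$curve$rate_hz[1:2], c(40, 80))
  expect_lte(fib$curve$rate_hz[3], 1)
  # missing step metadata errors
  expect_error(fi_curve(list(list(t_s = 0:1, vm_mv = c(0, 0)))), "metadata")
})

test_that("spike counts rise monotonically with current below block", {
  vt <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = seq(5, 40, by = 5), gain_hz_per_pa = 2,
    max_rate_hz = 80, noise_sd_mv = 0))
  fi <- fi_curve(vt$traces)
  expect_true(all(diff(fi$curve$rate_hz) >= 0))
})

test_that("passive properties recover RMP and input resistance", {
  vt <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = -10, rmp_mv = -52.9, rin_mohm = 1185,
    noise_sd_mv = 0, tau_ms = 20))
  pp <- passive_properties(vt$traces[[1]])
  expect_equal(pp$rmp_mv, -52.9, tolerance = 0.01 * 52.9)
  expect_equal(pp$rin_mohm, 1185, tolerance = 0.01 * 1185)
  # doubling the step current leaves Rin unchanged (linearity)
  vt2 <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = -20, rin_mohm = 1185, noise_sd_mv = 0, tau_ms = 20))
  pp2 <- passive_properties(vt2$traces[[1]])
  expect_equal(pp2$rin_mohm, pp$rin_mohm, tolerance = 0.01)
  # with 1-mV noise the estimates stay within 5%
  vtn <- generate_voltage_traces(voltage_trace_config(
    current_steps_pa = -10, rin_mohm = 1185, noise_sd_mv = 1, tau_ms = 20,
    seed = 3))
  ppn <- passive_properties(vtn$traces[[1]])
  expect_equal(ppn$rmp_mv, -52.9, tolerance = 0.05 * 52.9)
  expect_equal(ppn$rin_mohm, 1185, tolerance = 0.05 * 1185)
  # zero step: Rin undefined, RMP still reported
  vt0 <- generate_voltage_traces(voltage_trace_config(current_steps_pa = 0))
  pp0 <- passive_properties(vt0$traces[[1]])
  expect_true(is.na(pp0$rin_mohm))
  expect_equal(pp0$rmp_mv, -52.9, tolerance = 0.01)
})

test_that("burst metrics group spikes by inter-spike gaps", {
  # 3 bursts of 60 spikes at 50 Hz, separated by 2-s silences
  burst <- (0:59) / 50
  times <- c(burst, burst + 5, burst + 10)
  bm <- burst_metrics(times, isi_gap_ms = 100)
  expect_equal(bm$n_bursts, 3)
  expect_equal(bm$mean_spikes_per_burst, 60)
  expect_equal(bm$max_spikes_per_burst, 60)
  expect_equal(bm$inst_freq_min_hz, 50, tolerance = 1e-9)
  expect_equal(bm$inst_freq_max_hz, 50, tolerance = 1e-9)
  # single spike and uniform slow trains have no bursts
  expect_equal(burst_metrics(1.0)$n_bursts, 0)
  expect_equal(burst_metrics(0:19, isi_gap_ms = 100)$n_bursts, 0)
})

test_that("Henderson junction potential reproduces the recording correction", {
  int <- paper_internal_solution()
  ext <- paper_external_solution()
  ljp <- henderson_ljp(int, ext)
  expect_equal(ljp, 13, tolerance = 1 / 13)   # ~13 mV, within 1 mV
  # identical solutions: zero
  expect_equal(henderson_ljp(int, int), 0)
  # antisymmetry
  expect_equal(henderson_ljp(ext, int), -ljp, tolerance = 1e-9)
})

test_that("KCl junctions are small and Henderson matches Lewis-Sargent", {
  # K+ and Cl- mobilities nearly cancel: a tenfold KCl dilution junction is
  # ~1.1 mV (Lewis-Sargent with the standard mobility table), an order of
  # magnitude below the K-gluconate/saline junction
  a <- solution_spec(KCl = 150)
  b <- solution_spec(KCl = 15)
  expect_lt(abs(henderson_ljp(a, b)), 1.5)
  expect_lt(abs(henderson_ljp(a, b)),
            0.1 * abs(henderson_ljp(paper_internal_solution(),
                                    paper_external_solution())))
  # single binary salt: closed-form Lewis-Sargent expression
  u <- ion_mobilities()
  for (salt in c("NaCl", "KCl")) {
    cat_name <- sub("Cl$", "", salt)
    up <- u$mobility[u$ion == cat_name]
    um <- u$mobility[u$ion == "Cl"]
    s1 <- solution_spec(stats::setNames(100, salt))
    s2 <- solution_spec(stats::setNames(10, salt))
    rt_f <- 1000 * 8.31446 * 298.15 / 96485.33
    lewis_sargent <- rt_f * (up - um) / (up + um) * log(100 / 10)
    expect_equal(henderson_ljp(s1, s2), lewis_sargent, tolerance = 1e-4)
    expect_lt(abs(henderson_ljp(s1, s2) - lewis_sargent), 0.01)
  }
})

test_that("unknown species and missing charge are rejected", {
  expect_error(solution_spec(unobtainium = 10), "unknown species")
  expect_error(solution_spec(KCl = -5), ">= 0")
  glc <- solution_spec(glucose = 5)
  expect_error(henderson_ljp(glc, glc), "charged species")
})
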