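# Shared fixtures: small, fast configurations used across test files.

# short locomotor session, small cohort
small_session <- function(n_flies = 3, duration_s = 300, seed = 101, ...) {
  generate_locomotor_session(
    session_config(n_flies = n_flies, duration_s = duration_s, seed = seed, ...))
}

# single-fly trajectory walking in a straight line at constant speed
straight_trajectory <- function(speed_mm_s, n_steps = 50, dt = 0.2) {
  t <- (0:n_steps) * dt
  data.frame(fly_id = "fly001", t_s = t,
             x_mm = speed_mm_s * t - speed_mm_s * max(t) / 2, y_mm = 0)
}

# trajectory alternating exact walk/pause blocks (grid-aligned)
blocky_trajectory <- function(walk_s, pause_s, duration_s, dt = 0.2,
                              speed_mm_s = 6) {
  n <- round(duration_s / dt)
  cycle <- c(rep(TRUE, round(walk_s / dt)), rep(FALSE, round(pause_s / dt)))
  active <- rep_len(cycle, n)
  step <- ifelse(active, speed_mm_s * dt, 0)
  # fold the path so it stays in a 35-mm arena
  x <- numeric(n + 1)
  dir <- 1
  for (i in seq_len(n)) {
    if (abs(x[i] + dir * step[i]) > 15) dir <- -dir
    x[i + 1] <- x[i] + dir * step[i]
  }
  data.frame(fly_id = "fly001", t_s = (0:n) * dt, x_mm = x, y_mm = 0)
}

paper_internal_solution <- function() {
  solution_spec(`K-gluconate` = 102, NaCl = 17, EGTA = 0.94, HEPES = 8.5,
                CaCl2 = 0.085, MgCl2 = 1.7)
}

paper_external_solution <- function() {
  solution_spec(NaCl = 101, CaCl2 = 1, MgCl2 = 4, KCl = 3, glucose = 5,
                NaH2PO4 = 1.25, NaHCO3 = 20.7)
}
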