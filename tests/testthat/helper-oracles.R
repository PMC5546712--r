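# Brute-force fine-step integrator for the three-state release model;
# independent oracle for the analytic ne_release() implementation.
brute_release <- function(params, ap_times, dt = 1e-5) {
  R <- 1; E <- 0; u <- 0
  t <- ap_times[1]
  out <- data.frame(time = ap_times, amplitude = NA_real_)
  for (k in seq_along(ap_times)) {
    while (t < ap_times[k] - dt / 2) {
      dR <- (1 - R - E) / params$tau_r
      dE <- -E / params$tau_i
      du <- -u / params$tau_f
      R <- R + dt * dR; E <- E + dt * dE; u <- u + dt * du
      t <- t + dt
    }
    u <- u + params$U_SE * (1 - u)
    rel <- u * R
    R <- R - rel; E <- E + rel
    out$amplitude[k] <- params$A_SE * E
  }
  out
}

# deterministic engine shortcut on a single-volume fixture
run_fixture_det <- function(fx, t_end, sample = 0.5, stim = NULL,
                            init = NULL) {
  cfg <- engine_config("deterministic", sample_interval = sample,
                       t_end = t_end)
  run_sim(fx$model, fx$mesh, stim, cfg, init = init)
}
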