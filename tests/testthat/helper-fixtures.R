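# shared fixtures for the test suite

quiet_params <- function(...) {
  # deterministic tapping: no noise, no artifacts (overridable)
  args <- list(sync_offset = 0, reaction_mean = 0, reaction_sd = 0,
               sigma_timekeeper = 0, sigma_motor = 0,
               cont_perturbation = 0, cont_steady_offset = 0,
               cont_drift_sd = 0, miss_rate = 0, extra_rate = 0,
               weak_rate = 0)
  do.call(tapping_params, utils::modifyList(args, list(...)))
}

clean_params <- function(...) {
  # noisy but artifact-free
  tapping_params(miss_rate = 0, extra_rate = 0, weak_rate = 0, ...)
}

# render a trace with the default sensor noise and drift
clean_trace <- function(taps, timeline, fp = force_params()) {
  simulate_force_trace(taps, timeline, fp)
}

# a pulse-train force trace built from first principles (triangular
# pulses), independent of the package's force renderer
pulse_trace <- function(onsets_s, peaks, fs = 1000, dur_s = 350,
                        half_width_ms = 10) {
  v <- numeric(dur_s * fs)
  hw <- round(half_width_ms / 1000 * fs)
  shape <- c(seq(0, 1, length.out = hw + 1), seq(1, 0,
                                                 length.out = hw + 1)[-1])
  for (i in seq_along(onsets_s)) {
    i0 <- round(onsets_s[i] * fs) + 1 - hw
    ii <- i0 + seq_along(shape) - 1
    ok <- ii >= 1 & ii <= length(v)
    v[ii[ok]] <- v[ii[ok]] + peaks[i] * shape[ok]
  }
  structure(list(values = v, sampling_rate = fs, run_index = 1L),
            class = "force_trace")
}
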