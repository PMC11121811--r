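# Shared fixtures: everything is generated in code at test time.

quick_waveform <- function(f0 = 180, dur = 0.1, noise = 0, seed = 1, ...) {
  simulate_transit_waveform(
    waveform_spec(wingbeat_freq = f0, transit_duration = dur,
                  noise_sd = noise, ...),
    seed = seed)
}

# a two-cluster population separated by many standard deviations in both
# frequency and ratio; no thermal slope, and spreads chosen so the
# standardized clusters are roughly spherical Gaussian blobs
two_cluster_table <- function() {
  data.frame(
    cluster_id = 1:2,
    mean_freq_ref = c(80, 400),
    freq_sd = c(10, 10),
    slope = c(0, 0),
    ratio_mean = c(0.7, 0.25),
    ratio_sd = c(0.015, 0.015),
    weight = c(0.5, 0.5))
}

# events on an exact line f = f_ref + slope * (T - 20), no noise; events sit
# exactly at the 0.5 degC bin centers so bin means lie on the line exactly
exact_line_events <- function(per_bin = 20, slope = 5, f_ref = 100,
                              t_range = c(10, 38)) {
  centers <- seq(t_range[1] + 0.25, t_range[2] - 0.25, by = 0.5)
  tt <- rep(centers, each = per_bin)
  data.frame(temperature_C = tt,
             wingbeat_hz = f_ref + slope * (tt - 20),
             ratio = 0.5,
             cluster = 1L)
}
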