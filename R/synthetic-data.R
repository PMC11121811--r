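#' Reference five-cluster population
#'
#' Cluster parameters of the five insect groups resolved by an eight-month
#' optical-sensor field campaign: mean wingbeat frequency at the 20 degC
#' reference temperature and the linear thermal slope of each cluster, spanning
#' low-frequency broad-winged fliers (cluster 1, Lepidoptera/Odonata-like) up
#' to high-frequency male mosquitoes (cluster 5). Within-cluster spreads,
#' wing-to-body ratio centers and relative abundances are not published
#' quantities; the defaults here are chosen so that a desk-scale campaign
#' (tens of thousands of events) preserves the separability of the full
#' field data set (see the methods vignette).
#'
#' @return A data.frame with one row per cluster and columns `cluster_id`,
#'   `mean_freq_ref` (Hz at the reference temperature), `freq_sd` (Hz),
#'   `slope` (Hz/degC), `ratio_mean`, `ratio_sd` (dimensionless, in (0,1)),
#'   and `weight` (relative abundance).
#' @examples
#' reference_clusters()
#' @export
reference_clusters <- function() {
  data.frame(
    cluster_id    = 1:5,
    mean_freq_ref = c(50.51, 100.42, 171.33, 290.71, 525.58),
    freq_sd       = c(3.5, 7, 12, 20, 36),
    slope         = c(2.02, 3.66, 5.10, 7.69, 9.63),
    ratio_mean    = c(0.80, 0.45, 0.35, 0.30, 0.25),
    ratio_sd      = c(0.035, 0.015, 0.010, 0.009, 0.008),
    weight        = c(0.08, 0.30, 0.28, 0.19, 0.15)
  )
}

validate_clusters <- function(clusters) {
  stopifnot(is.data.frame(clusters), nrow(clusters) >= 1)
  req <- c("cluster_id", "mean_freq_ref", "freq_sd", "slope",
           "ratio_mean", "ratio_sd", "weight")
  missing <- setdiff(req, names(clusters))
  if (length(missing))
    stop("cluster table lacks columns: ", paste(missing, collapse = ", "))
  if (any(clusters$mean_freq_ref <= 0))
    stop("mean_freq_ref must be positive")
  if (any(clusters$ratio_mean <= 0 | clusters$ratio_mean >= 1))
    stop("ratio_mean must lie strictly in (0, 1)")
  if (any(clusters$weight < 0) || sum(clusters$weight) <= 0)
    stop("weights must be nonnegative with a positive sum")
  if (any(clusters$freq_sd < 0) || any(clusters$ratio_sd < 0))
    stop("spreads must be nonnegative")
  invisible(clusters)
}

#' Campaign specification
#'
#' Describes an event-level simulated field campaign: the cluster population,
#' the number of transit events, the ambient temperature model and the
#' activity-temperature coupling.
#'
#' @param clusters cluster table as returned by [reference_clusters()].
#' @param n_events number of transit events to draw.
#' @param temp_range ambient temperature range in degC, `c(lower, upper)`.
#' @param temp_model `"uniform"` (flat ambient temperature distribution) or
#'   `"diurnal"` (sinusoidal day/night cycle over a simulated season).
#' @param activity_exponent exponent `p` of the activity model: the event rate
#'   at ambient temperature T is proportional to `(T - 10)^p` above 10 degC,
#'   emulating the concentration of insect flight at warmer temperatures.
#' @param t_ref reference temperature (degC) at which `mean_freq_ref` holds.
#' @param start campaign start time (POSIXct or ISO-8601 string, UTC).
#' @param duration_days campaign length used to spread event timestamps.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(clusters = reference_clusters(),
                          n_events = 50000,
                          temp_range = c(10, 38),
                          temp_model = c("uniform", "diurnal"),
                          activity_exponent = 1,
                          t_ref = 20,
                          start = "2022-04-20T00:00:00Z",
                          duration_days = 240) {
  validate_clusters(clusters)
  temp_model <- match.arg(temp_model)
  stopifnot(n_events > 0, length(temp_range) == 2,
            temp_range[1] < temp_range[2], activity_exponent >= 0,
            duration_days > 0)
  start <- as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (is.na(start)) stop("start must be an ISO-8601 timestamp")
  structure(list(clusters = clusters, n_events = as.integer(n_events),
                 temp_range = as.numeric(temp_range), temp_model = temp_model,
                 activity_exponent = activity_exponent, t_ref = t_ref,
                 start = start, duration_days = duration_days),
            class = "campaign_spec")
}

# Draw event temperatures: ambient model restricted to temp_range, tilted by
# the activity weighting (T - 10)^p. For the uniform ambient model this has
# closed-form inverse-CDF; the diurnal model is sampled by rejection.
draw_event_temperatures <- function(spec, n) {
  lo <- spec$temp_range[1]; hi <- spec$temp_range[2]
  p <- spec$activity_exponent
  base <- 10  # activity onset, degC
  a <- max(lo, base)
  if (spec$temp_model == "uniform") {
    if (p == 0) return(stats::runif(n, lo, hi))
    # density proportional to (T - base)^p on [a, hi]
    u <- stats::runif(n)
    base + ((hi - base)^(p + 1) * u + (a - base)^(p + 1) * (1 - u))^(1 / (p + 1))
  } else {
    # diurnal cycle: T(t) = mid + amp * sin(2 pi hour/24), season-modulated;
    # rejection-sample against the activity weight
    out <- numeric(0)
    mid <- mean(c(lo, hi)); amp <- diff(c(lo, hi)) / 2
    while (length(out) < n) {
      m <- 2L * (n - length(out)) + 16L
      hour <- stats::runif(m, 0, 24)
      seas <- stats::runif(m, -1, 1)
      tt <- mid + amp * (0.7 * sin(2 * pi * (hour - 9) / 24) + 0.3 * seas)
      tt <- tt[tt >= lo & tt <= hi]
      w <- pmax(tt - base, 0)^p
      keep <- stats::runif(length(tt)) < w / max(w, 1e-12)
      out <- c(out, tt[keep])
    }
    out[seq_len(n)]
  }
}

#' Simulate an event-level campaign
#'
#' Draws `n_events` transit events from the cluster population: each event is
#' assigned a cluster (probability proportional to the cluster weight), an
#' ambient temperature from the activity-weighted temperature model, a
#' wingbeat frequency `mean_freq_ref + slope * (T - t_ref) + N(0, freq_sd)`,
#' and a wing-to-body cross-section ratio drawn from a normal clipped into
#' (0, 1). Wing and body cross-sections consistent with the ratio are derived
#' from a log-normal total extinction cross-section per cluster.
#'
#' @param spec a [campaign_spec()].
#' @param seed integer seed; identical spec + seed give identical tables.
#' @return A data.frame of transit events with columns `timestamp`,
#'   `temperature_C`, `wingbeat_hz`, `sigma_w_mm2`, `sigma_b_mm2`, `ratio`,
#'   `cluster_truth`.
#' @examples
#' ev <- simulate_campaign(campaign_spec(n_events = 1000), seed = 1)
#' head(ev)
#' @export
simulate_campaign <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "campaign_spec"))
  cl <- spec$clusters
  if (nrow(cl) == 0) stop("empty cluster list")
  set.seed(as.integer(seed))
  n <- spec$n_events
  z <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$weight)
  tt <- draw_event_temperatures(spec, n)
  freq <- cl$mean_freq_ref[z] + cl$slope[z] * (tt - spec$t_ref) +
    stats::rnorm(n, 0, cl$freq_sd[z])
  ratio <- pmin(pmax(stats::rnorm(n, cl$ratio_mean[z], cl$ratio_sd[z]),
                     1e-3), 1 - 1e-3)
  # total optical extinction cross-section (mm^2): log-normal, larger for the
  # broad-winged low-frequency cluster; purely descriptive plumbing
  size_mu <- log(200) - 0.8 * (cl$ratio_mean[z] < 0.5)
  sigma_tot <- stats::rlnorm(n, meanlog = size_mu, sdlog = 0.4)
  ts <- spec$start + sort(stats::runif(n, 0, spec$duration_days * 86400))
  data.frame(
    timestamp     = ts,
    temperature_C = tt,
    wingbeat_hz   = freq,
    sigma_w_mm2   = ratio * sigma_tot,
    sigma_b_mm2   = (1 - ratio) * sigma_tot,
    ratio         = ratio,
    cluster_truth = cl$cluster_id[z]
  )
}

#' Waveform specification for a single transit
#'
#' Physical description of one optical transit: a constant baseline voltage
#' `baseline_v0` dipped by a Gaussian envelope whose depth has a static body
#' component (`body_depth`) and a wing-flap modulated component (`wing_depth`),
#' with the stated harmonic content, plus white detector noise.
#'
#' @param baseline_v0 background voltage V0 (volts) with no target in the beam.
#' @param body_depth envelope dip from the body silhouette (volts).
#' @param wing_depth additional dip amplitude modulated by the wing flap (volts).
#' @param wingbeat_freq fundamental wingbeat frequency (Hz).
#' @param harmonic_amps relative amplitudes of harmonics 2..H of the wing
#'   occlusion waveform (fundamental has amplitude 1).
#' @param transit_duration transit duration in seconds (0.01 to 1 for insects).
#' @param noise_sd white-noise standard deviation (volts).
#' @param sampling_rate digitizer rate (Hz).
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(baseline_v0 = 3.0,
                          body_depth = 0.6,
                          wing_depth = 0.6,
                          wingbeat_freq = 180,
                          harmonic_amps = c(0.5, 0.25),
                          transit_duration = 0.1,
                          noise_sd = 0.005,
                          sampling_rate = 30517) {
  stopifnot(baseline_v0 > 0, body_depth >= 0, wing_depth >= 0,
            wingbeat_freq > 0, transit_duration > 0, noise_sd >= 0,
            sampling_rate > 0)
  if (body_depth + wing_depth > baseline_v0)
    stop("body_depth + wing_depth exceeds the baseline: negative light is not physical")
  h <- length(harmonic_amps) + 1
  if (sampling_rate <= 2 * wingbeat_freq * h)
    stop("sampling_rate must exceed twice the highest harmonic frequency")
  structure(list(baseline_v0 = baseline_v0, body_depth = body_depth,
                 wing_depth = wing_depth, wingbeat_freq = wingbeat_freq,
                 harmonic_amps = harmonic_amps,
                 transit_duration = transit_duration, noise_sd = noise_sd,
                 sampling_rate = sampling_rate),
            class = "waveform_spec")
}

# Nonnegative periodic wing-occlusion waveform with fundamental f and the
# given harmonic content, normalized to range [0, 1] (peak occlusion 1).
wing_occlusion <- function(t, f, harmonic_amps) {
  amps <- c(1, harmonic_amps)
  m <- rowSums(sapply(seq_along(amps),
                      function(h) amps[h] * cos(2 * pi * h * f * t)))
  # normalize over one dense cycle so the range does not depend on sampling
  tc <- seq(0, 1 / f, length.out = 2048)
  mc <- rowSums(sapply(seq_along(amps),
                       function(h) amps[h] * cos(2 * pi * h * f * tc)))
  (m - min(mc)) / (max(mc) - min(mc))
}

#' Simulate a transit waveform
#'
#' Generates the voltage trace `v(t) = V0 - g(t) * (dB + dW * m(t)) + e(t)`,
#' where `g` is a unit-peak Gaussian envelope spanning the transit, `m(t)` the
#' nonnegative wing-occlusion waveform normalized to peak 1, and `e` white
#' noise. The transit is embedded centrally in a trace with flat flanks so the
#' background level can be estimated from out-of-transit samples.
#'
#' @param spec a [waveform_spec()].
#' @param seed integer seed for the noise realization.
#' @param flank flat baseline time (seconds) kept on each side of the transit.
#' @return A [transit_signal()] carrying the samples, sampling rate and a
#'   `ground_truth` attribute with the generating parameters and the transit
#'   support `(t_start, t_end)`.
#' @examples
#' sig <- simulate_transit_waveform(waveform_spec(noise_sd = 0), seed = 1)
#' range(sig$samples)
#' @export
simulate_transit_waveform <- function(spec, seed = 1, flank = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  set.seed(as.integer(seed))
  fs <- spec$sampling_rate
  dur <- spec$transit_duration
  if (is.null(flank)) flank <- max(0.05, 0.5 * dur)
  total <- dur + 2 * flank
  t <- seq(0, total, by = 1 / fs)
  tc <- total / 2
  g <- exp(-(t - tc)^2 / (2 * (dur / 6)^2))   # +-3 sd spans the transit
  m <- wing_occlusion(t, spec$wingbeat_freq, spec$harmonic_amps)
  v <- spec$baseline_v0 - g * (spec$body_depth + spec$wing_depth * m) +
    stats::rnorm(length(t), 0, spec$noise_sd)
  sig <- transit_signal(v, fs, t0 = 0)
  attr(sig, "ground_truth") <- list(
    spec = spec, t_start = tc - dur / 2, t_end = tc + dur / 2, center = tc)
  sig
}

#' Simulate a non-insect (droplet-like) transit
#'
#' A smooth Gaussian dip with no periodic modulation, as produced by falling
#' water droplets, leaves or other non-insect objects crossing the beam. Such
#' traces carry no spectral content in the insect band and must be rejected by
#' the event classifier.
#'
#' @param duration dip duration in seconds.
#' @param depth dip depth in volts (`0` gives a flat baseline).
#' @param seed integer seed for the noise realization.
#' @param baseline_v0 background voltage (volts).
#' @param noise_sd white-noise standard deviation (volts).
#' @param sampling_rate digitizer rate (Hz).
#' @return A [transit_signal()] with a `ground_truth` attribute.
#' @export
simulate_droplet_waveform <- function(duration, depth, seed = 1,
                                      baseline_v0 = 3.0, noise_sd = 0.005,
                                      sampling_rate = 30517) {
  stopifnot(duration > 0, depth >= 0, depth <= baseline_v0)
  set.seed(as.integer(seed))
  flank <- max(0.05, 0.5 * duration)
  total <- duration + 2 * flank
  t <- seq(0, total, by = 1 / sampling_rate)
  tc <- total / 2
  g <- exp(-(t - tc)^2 / (2 * (duration / 6)^2))
  v <- baseline_v0 - depth * g + stats::rnorm(length(t), 0, noise_sd)
  sig <- transit_signal(v, sampling_rate, t0 = 0)
  attr(sig, "ground_truth") <- list(
    kind = "droplet", depth = depth,
    t_start = tc - duration / 2, t_end = tc + duration / 2)
  sig
}

#' Simulate a weather-station temperature series
#'
#' One record per minute, as logged by a co-located weather station: a diurnal
#' sinusoid plus slow drift and measurement noise.
#'
#' @param start first record time (POSIXct or ISO-8601 string, UTC).
#' @param n_minutes number of one-minute records.
#' @param mean_temp,diurnal_amp mean level and day/night half-range (degC).
#' @param noise_sd measurement noise (degC).
#' @param seed integer seed.
#' @return A data.frame with columns `timestamp`, `temperature_C`, `rh_percent`.
#' @export
simulate_weather_series <- function(start = "2022-06-01T00:00:00Z",
                                    n_minutes = 1440, mean_temp = 22,
                                    diurnal_amp = 6, noise_sd = 0.2,
                                    seed = 1) {
  set.seed(as.integer(seed))
  start <- as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  ts <- start + 60 * (seq_len(n_minutes) - 1)
  hour <- as.numeric(ts - ts[1], units = "hours") %% 24
  temp <- mean_temp + diurnal_amp * sin(2 * pi * (hour - 9) / 24) +
    stats::rnorm(n_minutes, 0, noise_sd)
  data.frame(timestamp = ts, temperature_C = temp,
             rh_percent = pmin(pmax(70 - 1.5 * (temp - mean_temp) +
                                      stats::rnorm(n_minutes, 0, 3), 5), 100))
}

#' Write / read an event table as CSV
#'
#' Canonical delimited-text interchange format for event tables: comma
#' separated, header row, UTF-8, ISO-8601 UTC timestamps.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return `read_events_csv` returns the event data.frame; `write_events_csv`
#'   returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- events
  if (inherits(out$timestamp, "POSIXct"))
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(ev))
    ev$timestamp <- as.POSIXct(ev$timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  ev
}
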