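#' Transit signal container
#'
#' A raw voltage trace with sampling metadata: the light intensity reaching
#' the detector, sampled by the digitizer.
#'
#' @param samples numeric vector of voltages.
#' @param sampling_rate sampling rate in Hz.
#' @param t0 time of the first sample (seconds, or POSIXct).
#' @return An object of class `transit_signal` (a list with `samples`,
#'   `sampling_rate`, `t0`).
#' @export
transit_signal <- function(samples, sampling_rate = 30517, t0 = 0) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, t0 = t0),
            class = "transit_signal")
}

#' @export
print.transit_signal <- function(x, ...) {
  cat(sprintf("<transit_signal> %d samples @ %.0f Hz (%.3f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Instrument configuration
#'
#' Optical and filtering constants of the sensor: the beam cross-sectional
#' area used to convert relative extinction into absolute cross-sections, the
#' admissible transit-duration window, the wingbeat frequency band used to
#' discriminate insects, and detection thresholds.
#'
#' @param beam_area_A beam cross-sectional area A in mm^2. Default 2027 mm^2,
#'   a flat-top circular beam of 50.8 mm diameter.
#' @param min_duration,max_duration admissible transit duration window in
#'   seconds; shorter events are excluded, longer ones truncated and flagged.
#' @param band insect wingbeat band in Hz; events with no prominent spectral
#'   peak inside it are classified non-insect.
#' @param detection_threshold optional fixed detection threshold as a fraction
#'   of the baseline; the default `NULL` uses 3x the estimated baseline noise
#'   standard deviation.
#' @param noise_floor_mult spectral prominence threshold: a peak counts as
#'   prominent when its magnitude exceeds this multiple of the median in-band
#'   spectral magnitude.
#' @param min_cycles minimum number of wingbeat cycles that must fit inside a
#'   segment for a spectral peak to count as a wingbeat: peak candidates below
#'   `min_cycles / duration` Hz are ignored. This keeps residual energy of the
#'   transit envelope itself (which concentrates below a few cycles per
#'   segment) from masquerading as a low fundamental.
#' @param staleness_s maximum age (seconds) of the nearest weather record
#'   before an event's temperature is flagged missing.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(beam_area_A = 2027,
                              min_duration = 0.010,
                              max_duration = 1.0,
                              band = c(10, 900),
                              detection_threshold = NULL,
                              noise_floor_mult = 5,
                              min_cycles = 5,
                              staleness_s = 600) {
  stopifnot(beam_area_A > 0, min_duration > 0, min_duration < max_duration,
            length(band) == 2, band[1] > 0, band[1] < band[2],
            noise_floor_mult > 0, min_cycles > 0, staleness_s > 0)
  if (!is.null(detection_threshold))
    stopifnot(detection_threshold > 0, detection_threshold < 1)
  structure(list(beam_area_A = beam_area_A, min_duration = min_duration,
                 max_duration = max_duration, band = as.numeric(band),
                 detection_threshold = detection_threshold,
                 noise_floor_mult = noise_floor_mult,
                 min_cycles = min_cycles,
                 staleness_s = staleness_s),
            class = "instrument_config")
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) ->
    y
  # fill the filter's NA edges with the nearest computed value
  idx <- which(!is.na(y))
  if (!length(idx)) return(x)
  y[seq_len(idx[1] - 1)] <- y[idx[1]]
  y[seq(idx[length(idx)] + 1, length.out = length(y) - idx[length(idx)])] <-
    y[idx[length(idx)]]
  y
}

# Robust noise scale from first differences (insensitive to the transit dip).
estimate_noise_sd <- function(samples) {
  stats::mad(diff(samples)) / sqrt(2)
}

#' Detect transit segments in a voltage trace
#'
#' Flags maximal contiguous runs where the smoothed signal drops below the
#' baseline by more than the detection threshold. Detected runs are extended
#' outward with a lower hysteresis threshold (one third of the detection
#' threshold) so a transit's shoulders are retained, and runs separated by
#' less than half the minimum duration are merged. Runs shorter than
#' `min_duration` are discarded; runs longer than `max_duration` are truncated
#' and flagged.
#'
#' @param signal a [transit_signal()].
#' @param cfg an [instrument_config()].
#' @return A data.frame with one row per segment: `start`, `end` (sample
#'   indices, inclusive), `duration` (s), `truncated` (logical). Zero rows if
#'   nothing is detected (a flat trace is not an error).
#' @export
detect_transits <- function(signal, cfg = instrument_config()) {
  stopifnot(inherits(signal, "transit_signal"))
  x <- signal$samples
  fs <- signal$sampling_rate
  if (length(x) / fs <= cfg$min_duration)
    stop("trace shorter than the minimum transit duration")
  baseline <- stats::median(x)
  noise_sd <- estimate_noise_sd(x)
  thr <- if (!is.null(cfg$detection_threshold)) {
    cfg$detection_threshold * baseline
  } else {
    max(3 * noise_sd, 1e-3 * abs(baseline))
  }
  sm <- moving_average(x, max(3L, round(0.002 * fs)))  # ~2 ms smoothing
  below <- sm < (baseline - thr)
  runs <- rle(below)
  if (!any(runs$values)) {
    return(data.frame(start = integer(0), end = integer(0),
                      duration = numeric(0), truncated = logical(0)))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(starts[runs$values], ends[runs$values])
  # hysteresis: extend to where the smoothed trace recovers to thr/3
  lower <- baseline - thr / 3
  seg[, 1] <- vapply(seg[, 1], function(i) {
    while (i > 1L && sm[i - 1L] < lower) i <- i - 1L
    i
  }, integer(1))
  seg[, 2] <- vapply(seg[, 2], function(i) {
    n <- length(sm)
    while (i < n && sm[i + 1L] < lower) i <- i + 1L
    i
  }, integer(1))
  # merge segments separated by less than min_duration / 2
  gap <- round(cfg$min_duration * fs / 2)
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (r in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg[r, 1] - merged[last, 2] <= gap) {
        merged[last, 2] <- max(merged[last, 2], seg[r, 2])
      } else {
        merged <- rbind(merged, seg[r, ])
      }
    }
  }
  dur <- (merged[, 2] - merged[, 1] + 1) / fs
  keep <- dur >= cfg$min_duration
  merged <- merged[keep, , drop = FALSE]
  dur <- dur[keep]
  truncated <- dur > cfg$max_duration
  too_long <- which(truncated)
  if (length(too_long)) {
    merged[too_long, 2] <- merged[too_long, 1] +
      round(cfg$max_duration * fs) - 1L
    dur[too_long] <- (merged[too_long, 2] - merged[too_long, 1] + 1) / fs
  }
  data.frame(start = merged[, 1], end = merged[, 2],
             duration = dur, truncated = truncated)
}

#' Estimate the background level V0
#'
#' Robust location (median) of the out-of-transit samples flanking a segment.
#' Falls back to a one-sided estimate when the segment touches a trace edge;
#' errors when no flanking samples exist at all.
#'
#' @param signal a [transit_signal()].
#' @param segment one row of [detect_transits()] output (or a list with
#'   `start`, `end`).
#' @param flank_s flanking window on each side, seconds.
#' @param guard_s guard gap between segment edge and flanking window, seconds.
#' @return The background voltage V0.
#' @export
estimate_baseline <- function(signal, segment, flank_s = 0.05,
                              guard_s = 0.002) {
  x <- signal$samples
  fs <- signal$sampling_rate
  guard <- round(guard_s * fs)
  w <- max(round(flank_s * fs), 10L)
  li <- max(1L, segment$start - guard - w)
  lf <- segment$start - guard - 1L
  ri <- segment$end + guard + 1L
  rf <- min(length(x), segment$end + guard + w)
  left <- if (lf >= li && lf >= 1L) x[li:lf] else numeric(0)
  right <- if (ri <= rf && ri <= length(x)) x[ri:rf] else numeric(0)
  if (!length(left) && !length(right))
    stop("segment has no flanking out-of-transit samples; event unusable")
  stats::median(c(left, right))
}

# Mean of the samples lying within the deepest `frac` of the dip value range
# ("average of the 10% minimum value"): values v qualify when
# v <= min(v) + frac * (max(v) - min(v)).
lowest_fraction_mean <- function(v, frac = 0.10) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  mean(v[v <= lo + frac * (hi - lo)])
}

# Level of an envelope at its peak, from the values within the deepest `frac`
# of the envelope range. The plain average of those values over-estimates the
# peak level because the envelope droops away from its center; with enough
# qualifying points the vertex of a quadratic fit (the envelope is locally
# parabolic at its peak) removes that droop.
envelope_level <- function(t, v, frac = 0.10) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  q <- v <= lo + frac * (hi - lo)
  if (sum(q) < 5 && length(v) >= 5) q <- rank(v, ties.method = "first") <= 5
  tq <- t[q]; vq <- v[q]
  if (length(vq) >= 4 && length(unique(tq)) >= 3) {
    fit <- stats::lm.fit(cbind(1, tq, tq^2), vq)
    cf <- fit$coefficients
    if (is.finite(cf[3]) && cf[3] > 0) {
      tv <- -cf[2] / (2 * cf[3])
      if (tv >= min(tq) && tv <= max(tq)) {
        vv <- cf[1] + cf[2] * tv + cf[3] * tv^2
        return(max(vv, lo - 0.05 * (hi - lo)))
      }
    }
  }
  mean(vq)
}

#' Estimate body and wing voltage levels
#'
#' The segment is partitioned into wing cycles (one wingbeat period each) and
#' the per-cycle minima and maxima form the lower and upper wing-cycle
#' envelopes. `v_wing` -- the deepest level, body plus fully extended wings
#' occluding -- is the average of the lower-envelope values lying within the
#' lowest 10% of that envelope's range; `v_body` -- the body-only level
#' between flaps -- applies the same 10%-minimum rule to the upper envelope.
#' Both averages therefore concentrate on the transit center, where the
#' envelope peaks.
#'
#' @param signal a [transit_signal()].
#' @param segment one row of [detect_transits()] output.
#' @param freq wingbeat frequency in Hz, used to delimit wing cycles; when
#'   `NA` (no wing modulation) both levels are computed from raw samples and
#'   coincide.
#' @param frac fraction of the envelope range defining the "minimum" set.
#' @return A list with `v_wing` and `v_body`, `v_wing <= v_body`.
#' @export
estimate_levels <- function(signal, segment, freq, frac = 0.10) {
  x <- signal$samples[segment$start:segment$end]
  fs <- signal$sampling_rate
  if (length(x) < 10) stop("fewer than 10 samples in segment; event unusable")
  if (is.na(freq) || freq <= 0) {
    v <- lowest_fraction_mean(x, frac)
    return(list(v_wing = v, v_body = v))
  }
  period <- round(fs / freq)
  n_cycles <- floor(length(x) / period)
  if (n_cycles < 2) stop("segment shorter than two wingbeat cycles")
  idx <- seq_len(n_cycles * period)
  cyc <- rep(seq_len(n_cycles), each = period)
  xs <- split(x[idx], cyc)
  is <- split(idx, cyc)
  lower <- vapply(xs, min, numeric(1))
  upper <- vapply(xs, max, numeric(1))
  t_lo <- vapply(seq_along(xs),
                 function(j) (is[[j]][which.min(xs[[j]])] - 1) / fs, numeric(1))
  t_hi <- vapply(seq_along(xs),
                 function(j) (is[[j]][which.max(xs[[j]])] - 1) / fs, numeric(1))
  v_wing <- envelope_level(t_lo, lower, frac)
  v_body <- envelope_level(t_hi, upper, frac)
  if (v_wing > v_body) v_body <- v_wing
  list(v_wing = v_wing, v_body = v_body)
}

#' Optical extinction cross-sections
#'
#' Converts the relative voltage drops into absolute extinction
#' cross-sections using the known beam area A:
#' `sigma_w = (V0 - Vw) / V0 * A` and `sigma_B = (V0 - VB) / V0 * A`.
#'
#' @param v0 background voltage V0 (> 0).
#' @param v_wing,v_body wing-flap and body voltage levels.
#' @param cfg an [instrument_config()] supplying `beam_area_A`.
#' @return A list with `sigma_w` and `sigma_b` in mm^2.
#' @export
cross_sections <- function(v0, v_wing, v_body, cfg = instrument_config()) {
  if (v0 <= 0) stop("V0 must be positive")
  stopifnot(v_wing > 0, v_body > 0, v_wing <= v0 + 1e-12, v_body <= v0 + 1e-12)
  list(sigma_w = (v0 - v_wing) / v0 * cfg$beam_area_A,
       sigma_b = (v0 - v_body) / v0 * cfg$beam_area_A)
}

#' Wing-to-body cross-section ratio
#'
#' `sigma_w / (sigma_w + sigma_b)`, a beam-area-invariant shape descriptor
#' in `[0, 1]` used as the second clustering feature.
#'
#' @param sigma_w,sigma_b wing and body extinction cross-sections (mm^2).
#' @return The ratio.
#' @export
wing_body_ratio <- function(sigma_w, sigma_b) {
  if (sigma_w + sigma_b <= 0) stop("sigma_w + sigma_b must be positive")
  sigma_w / (sigma_w + sigma_b)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Magnitude spectrum of a detrended, Hann-windowed, zero-padded segment.
segment_spectrum <- function(x, fs, pad_factor = 4) {
  n <- length(x)
  # envelope removal: subtract a degree-4 polynomial trend, which tracks the
  # Gaussian-like transit envelope without touching the wingbeat oscillation
  tt <- seq_len(n) / n
  trend <- stats::lm.fit(stats::poly(tt, degree = 6, raw = FALSE) |>
                           cbind(1) |> unname(), x)
  xd <- trend$residuals
  xw <- xd * hann_window(n)
  nfft <- 2^ceiling(log2(pad_factor * n))
  sp <- stats::fft(c(xw, rep(0, nfft - n)))
  half <- seq_len(nfft %/% 2)
  list(freq = (half - 1) * fs / nfft, mag = Mod(sp[half]), nfft = nfft)
}

# Quadratic interpolation of a peak position from the log-magnitudes of the
# peak bin and its neighbors; returns the fractional bin offset in (-0.5, 0.5).
quadratic_peak_offset <- function(m_prev, m_peak, m_next) {
  a <- log(max(m_prev, 1e-300)); b <- log(max(m_peak, 1e-300))
  c <- log(max(m_next, 1e-300))
  denom <- a - 2 * b + c
  if (denom >= 0) return(0)
  off <- 0.5 * (a - c) / denom
  max(min(off, 0.5), -0.5)
}

# Prominent in-band spectral peaks: local maxima exceeding `mult` times the
# median in-band magnitude. Returns a data.frame sorted by frequency.
prominent_peaks <- function(spec, band, mult) {
  inb <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(inb)) return(data.frame(freq = numeric(0), mag = numeric(0)))
  floor_mag <- stats::median(spec$mag[inb])
  m <- spec$mag
  is_max <- c(FALSE, m[2:(length(m) - 1)] > m[1:(length(m) - 2)] &
                m[2:(length(m) - 1)] >= m[3:length(m)], FALSE)
  cand <- which(is_max & inb & m > mult * floor_mag)
  if (!length(cand)) return(data.frame(freq = numeric(0), mag = numeric(0)))
  # refine each candidate by quadratic interpolation
  df <- spec$freq[2] - spec$freq[1]
  fr <- vapply(cand, function(i) {
    spec$freq[i] + df * quadratic_peak_offset(m[i - 1], m[i], m[i + 1])
  }, numeric(1))
  out <- data.frame(freq = fr, mag = m[cand])
  out[order(out$freq), , drop = FALSE]
}

#' Extract the fundamental wingbeat frequency
#'
#' Detrends the segment (envelope removal by polynomial fit), applies a Hann
#' window, zero-pads to at least four times the segment length, and scans the
#' magnitude spectrum for prominent peaks inside the insect band. The
#' fundamental is the lowest-frequency prominent peak whose stronger peaks all
#' sit near integer multiples of it -- the fundamental need not be the tallest
#' peak. Peak positions are refined by quadratic interpolation around the
#' peak bin.
#'
#' @param signal a [transit_signal()].
#' @param segment one row of [detect_transits()] output.
#' @param cfg an [instrument_config()].
#' @return A list with `freq` (Hz, `NA` when no prominent in-band peak
#'   exists -- a non-insect signature) and `peaks` (the prominent peak table).
#' @export
extract_wingbeat_frequency <- function(signal, segment,
                                       cfg = instrument_config()) {
  x <- signal$samples[segment$start:segment$end]
  fs <- signal$sampling_rate
  if (length(x) < round(cfg$min_duration * fs))
    stop("segment shorter than the minimum transit duration")
  spec <- segment_spectrum(x, fs)
  f_floor <- max(cfg$band[1], cfg$min_cycles / (length(x) / fs))
  pk <- prominent_peaks(spec, c(f_floor, cfg$band[2]), cfg$noise_floor_mult)
  if (!nrow(pk)) return(list(freq = NA_real_, peaks = pk))
  # fundamental selection: lowest candidate within an order of magnitude of
  # the strongest peak such that every prominent peak at least as strong is
  # consistent with an integer multiple of it (the fundamental need not be
  # the tallest peak, but it is never a trace relative to the harmonics)
  tol_of <- function(f) max(2, 0.04 * f)
  pk <- pk[pk$mag >= 0.1 * max(pk$mag), , drop = FALSE]
  for (i in seq_len(nrow(pk))) {
    f0 <- pk$freq[i]
    stronger <- pk[pk$mag >= pk$mag[i] & abs(pk$freq - f0) > 1e-9, ,
                   drop = FALSE]
    ok <- TRUE
    if (nrow(stronger)) {
      mult <- round(stronger$freq / f0)
      ok <- all(mult >= 1 & abs(stronger$freq - mult * f0) <=
                  tol_of(stronger$freq))
    }
    if (ok) return(list(freq = f0, peaks = pk))
  }
  # fall back to the strongest peak
  list(freq = pk$freq[which.max(pk$mag)], peaks = pk)
}

#' Classify a detected segment as insect or non-insect
#'
#' An event is an insect transit when its duration lies within the admissible
#' window and its spectrum has a prominent peak inside the insect band
#' (10-900 Hz by default). Droplets, leaves and other smooth dips lack such
#' in-band content and are rejected; so are too-short events regardless of
#' modulation.
#'
#' @param duration segment duration in seconds.
#' @param freq extracted fundamental (Hz) or `NA` when no prominent in-band
#'   peak exists.
#' @param cfg an [instrument_config()].
#' @return `"insect"` or `"non_insect"`.
#' @export
classify_event <- function(duration, freq, cfg = instrument_config()) {
  ok_dur <- duration >= cfg$min_duration & duration <= cfg$max_duration
  ok_peak <- !is.na(freq) & freq >= cfg$band[1] & freq <= cfg$band[2]
  ifelse(ok_dur & ok_peak, "insect", "non_insect")
}

#' Extract events from a voltage trace
#'
#' Full per-trace pipeline: transit detection, background estimation,
#' frequency extraction, level and cross-section estimation, and insect /
#' non-insect classification. No detected segment is silently dropped: each
#' yields a row with `status` `"insect"`, `"non_insect"` or `"unusable"`
#' (feature extraction failed), so that detected = insect + non_insect +
#' unusable.
#'
#' @param signal a [transit_signal()].
#' @param cfg an [instrument_config()].
#' @return A data.frame with one row per detected segment: `t0`, `duration`,
#'   `truncated`, `v0`, `v_body`, `v_wing`, `sigma_w_mm2`, `sigma_b_mm2`,
#'   `ratio`, `wingbeat_hz`, `status`.
#' @export
extract_events <- function(signal, cfg = instrument_config()) {
  segs <- detect_transits(signal, cfg)
  fs <- signal$sampling_rate
  empty <- data.frame(t0 = numeric(0), duration = numeric(0),
                      truncated = logical(0), v0 = numeric(0),
                      v_body = numeric(0), v_wing = numeric(0),
                      sigma_w_mm2 = numeric(0), sigma_b_mm2 = numeric(0),
                      ratio = numeric(0), wingbeat_hz = numeric(0),
                      status = character(0))
  if (!nrow(segs)) return(empty)
  rows <- lapply(seq_len(nrow(segs)), function(r) {
    seg <- segs[r, ]
    base <- data.frame(t0 = (seg$start - 1) / fs, duration = seg$duration,
                       truncated = seg$truncated, v0 = NA_real_,
                       v_body = NA_real_, v_wing = NA_real_,
                       sigma_w_mm2 = NA_real_, sigma_b_mm2 = NA_real_,
                       ratio = NA_real_, wingbeat_hz = NA_real_,
                       status = "unusable")
    out <- tryCatch({
      v0 <- estimate_baseline(signal, seg)
      fx <- extract_wingbeat_frequency(signal, seg, cfg)
      cls <- classify_event(seg$duration, fx$freq, cfg)
      base$v0 <- v0
      base$wingbeat_hz <- fx$freq
      base$status <- cls
      if (cls == "insect") {
        lv <- estimate_levels(signal, seg, fx$freq)
        cs <- cross_sections(v0, lv$v_wing, lv$v_body, cfg)
        base$v_body <- lv$v_body
        base$v_wing <- lv$v_wing
        base$sigma_w_mm2 <- cs$sigma_w
        base$sigma_b_mm2 <- cs$sigma_b
        base$ratio <- wing_body_ratio(cs$sigma_w, cs$sigma_b)
      }
      base
    }, error = function(e) base)
    out
  })
  do.call(rbind, rows)
}

#' Attach ambient temperature to events
#'
#' Each event receives the temperature of the nearest-in-time weather record.
#' Events whose nearest record is farther than the staleness horizon are
#' flagged with `temperature_missing = TRUE` (their temperature is still the
#' nearest record's, for inspection).
#'
#' @param events event data.frame with a `timestamp` column (POSIXct or
#'   numeric seconds).
#' @param weather weather data.frame with `timestamp` and `temperature_C`.
#' @param staleness_s staleness horizon in seconds (default 600 = 10 min).
#' @return `events` with columns `temperature_C` and `temperature_missing`.
#' @export
attach_temperature <- function(events, weather, staleness_s = 600) {
  if (!nrow(weather)) stop("empty weather series")
  wt <- as.numeric(weather$timestamp)
  et <- as.numeric(events$timestamp)
  ord <- order(wt)
  wt <- wt[ord]
  temp <- weather$temperature_C[ord]
  pos <- findInterval(et, wt)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(wt))
  use_hi <- abs(wt[hi] - et) < abs(wt[lo] - et)
  nearest <- ifelse(use_hi, hi, lo)
  events$temperature_C <- temp[nearest]
  events$temperature_missing <- abs(wt[nearest] - et) > staleness_s
  events
}
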