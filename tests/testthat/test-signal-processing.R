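cfg <- instrument_config()

test_that("transit detection finds real transits and ignores flat traces", {
  flat <- transit_signal(rep(3, 5000))
  expect_identical(nrow(detect_transits(flat, cfg)), 0L)

  sig <- quick_waveform(noise = 0.005, seed = 2)
  segs <- detect_transits(sig, cfg)
  expect_identical(nrow(segs), 1L)
  gt <- attr(sig, "ground_truth")
  fs <- sig$sampling_rate
  overlap <- min(segs$end / fs, gt$t_end) - max((segs$start - 1) / fs, gt$t_start)
  expect_gte(overlap / (gt$t_end - gt$t_start), 0.90)

  # 5 ms dip: below the minimum duration, excluded even though modulated
  short <- quick_waveform(dur = 0.005, noise = 0, seed = 3)
  expect_identical(nrow(detect_transits(short, cfg)), 0L)

  expect_error(detect_transits(transit_signal(rep(3, 100)), cfg), "shorter")
})

test_that("overlong transits are truncated and flagged", {
  sig <- quick_waveform(f0 = 100, dur = 1.6, noise = 0, seed = 4)
  segs <- detect_transits(sig, cfg)
  expect_identical(nrow(segs), 1L)
  expect_true(segs$truncated[1])
  expect_lte(segs$duration[1], cfg$max_duration + 1e-9)
})

test_that("baseline estimation is robust and handles trace edges", {
  sig <- quick_waveform(noise = 0, seed = 1)
  seg <- detect_transits(sig, cfg)[1, ]
  expect_equal(estimate_baseline(sig, seg), 3.0, tolerance = 1e-3)

  noisy <- quick_waveform(noise = 0.01, seed = 5)
  segn <- detect_transits(noisy, cfg)[1, ]
  expect_equal(estimate_baseline(noisy, segn), 3.0, tolerance = 0.005)

  # transit at the very start of the trace: right-flank-only estimate
  x <- sig$samples
  gt <- attr(sig, "ground_truth")
  fs <- sig$sampling_rate
  cut <- x[(round(gt$t_start * fs)):length(x)]
  edge <- transit_signal(cut, fs)
  sege <- detect_transits(edge, cfg)[1, ]
  expect_equal(estimate_baseline(edge, sege), 3.0, tolerance = 1e-3)

  # no flanks at all
  tight <- transit_signal(x[seg$start:seg$end], fs)
  expect_error(
    estimate_baseline(tight, list(start = 1, end = seg$end - seg$start + 1)),
    "unusable")
})

test_that("wingbeat frequency round-trips across the band", {
  for (f0 in c(25, 50, 100, 180, 300, 500, 700)) {
    dur <- max(0.1, 18 / f0)
    sig <- quick_waveform(f0 = f0, dur = dur, noise = 0, seed = 2)
    seg <- detect_transits(sig, cfg)[1, ]
    got <- extract_wingbeat_frequency(sig, seg, cfg)$freq
    expect_lt(abs(got - f0), 2, label = sprintf("f0 = %g, got %.2f", f0, got))
  }
})

test_that("the fundamental wins over a stronger harmonic", {
  sig <- quick_waveform(f0 = 100, noise = 0, seed = 3,
                        harmonic_amps = c(1.2, 0.2))
  seg <- detect_transits(sig, cfg)[1, ]
  got <- extract_wingbeat_frequency(sig, seg, cfg)$freq
  expect_lt(abs(got - 100), 2)
})

test_that("pure dips have no in-band peak and are classified non-insect", {
  dro <- simulate_droplet_waveform(0.1, 0.5, seed = 4)
  seg <- detect_transits(dro, cfg)[1, ]
  fx <- extract_wingbeat_frequency(dro, seg, cfg)
  expect_true(is.na(fx$freq))
  expect_identical(classify_event(seg$duration, fx$freq, cfg), "non_insect")

  # insect-like modulation but 6 ms long: excluded by the duration rule
  expect_identical(classify_event(0.006, 180, cfg), "non_insect")
  expect_identical(classify_event(0.1, 180, cfg), "insect")

  # depth 0: flat baseline, nothing detected
  null_ev <- simulate_droplet_waveform(0.1, 0, seed = 5, noise_sd = 0)
  expect_identical(nrow(detect_transits(null_ev, cfg)), 0L)
})

test_that("levels and cross-sections recover the generating depths", {
  sig <- quick_waveform(noise = 0, seed = 1)  # V0 3.0, dB 0.6, dW 0.6
  seg <- detect_transits(sig, cfg)[1, ]
  v0 <- estimate_baseline(sig, seg)
  f0 <- extract_wingbeat_frequency(sig, seg, cfg)$freq
  lv <- estimate_levels(sig, seg, f0)
  expect_lt(lv$v_wing, lv$v_body)
  expect_lt(lv$v_body, v0)
  expect_equal(lv$v_wing, 1.8, tolerance = 0.02)
  expect_equal(lv$v_body, 2.4, tolerance = 0.02)
  cs <- cross_sections(v0, lv$v_wing, lv$v_body, cfg)
  expect_equal(cs$sigma_w, (3 - 1.8) / 3 * cfg$beam_area_A, tolerance = 0.02)
  expect_equal(cs$sigma_b, (3 - 2.4) / 3 * cfg$beam_area_A, tolerance = 0.02)

  # no wing modulation: the two levels coincide
  lv0 <- estimate_levels(quick_waveform(noise = 0, seed = 2, wing_depth = 0),
                         seg, NA)
  expect_equal(lv0$v_wing, lv0$v_body)
})

test_that("cross-section arithmetic and the ratio match hand values", {
  expect_equal(cross_sections(3.0, 2.4, 2.7,
                              instrument_config(beam_area_A = 2000)),
               list(sigma_w = 400, sigma_b = 200))
  expect_equal(cross_sections(3.0, 3.0, 3.0, cfg)$sigma_w, 0)
  expect_error(cross_sections(0, 1, 1, cfg), "V0")
  expect_equal(wing_body_ratio(400, 200), 2 / 3)
  expect_equal(wing_body_ratio(5, 5), 0.5)
  expect_equal(wing_body_ratio(0, 7), 0)
  expect_error(wing_body_ratio(0, 0), "positive")
})

test_that("noiseless cross-section round trip holds across the band", {
  for (f0 in c(50, 180, 500)) {
    dur <- max(0.1, 18 / f0)
    sig <- quick_waveform(f0 = f0, dur = dur, noise = 0, seed = 2)
    seg <- detect_transits(sig, cfg)[1, ]
    v0 <- estimate_baseline(sig, seg)
    fr <- extract_wingbeat_frequency(sig, seg, cfg)$freq
    lv <- estimate_levels(sig, seg, fr)
    cs <- cross_sections(v0, lv$v_wing, lv$v_body, cfg)
    expect_equal(cs$sigma_w, 0.4 * cfg$beam_area_A, tolerance = 0.02)
    expect_equal(cs$sigma_b, 0.2 * cfg$beam_area_A, tolerance = 0.02)
  }
})

test_that("extract_events conserves every detected segment", {
  fs <- 30517
  insect <- quick_waveform(noise = 0.004, seed = 6)$samples
  droplet <- simulate_droplet_waveform(0.08, 0.5, seed = 7,
                                       noise_sd = 0.004)$samples
  trace <- transit_signal(c(insect, droplet, insect), fs)
  ev <- extract_events(trace, cfg)
  expect_identical(nrow(ev), 3L)
  expect_identical(sum(ev$status == "insect") + sum(ev$status == "non_insect") +
                     sum(ev$status == "unusable"), 3L)
  expect_identical(ev$status[2], "non_insect")
  ins <- ev[ev$status == "insect", ]
  expect_true(all(ins$v_wing <= ins$v_body & ins$v_body <= ins$v0))
  expect_true(all(ins$ratio >= 0 & ins$ratio <= 1))
  expect_true(all(abs(ins$wingbeat_hz - 180) < 2))
})

test_that("temperature attachment uses the nearest record and flags stale ones", {
  base <- as.POSIXct("2022-06-01 12:00:00", tz = "UTC")
  weather <- data.frame(timestamp = base + 60 * (0:9),
                        temperature_C = 20 + (0:9) / 10)
  ev <- data.frame(timestamp = c(base + 30,          # tie: earlier record
                                 base + 91,          # nearer 12:02
                                 base + 120,         # exact match
                                 base + 7200))       # 2 h away: stale
  out <- attach_temperature(ev, weather, staleness_s = 600)
  expect_equal(out$temperature_C[2], 20.2)
  expect_equal(out$temperature_C[3], 20.2)
  expect_false(any(out$temperature_missing[1:3]))
  expect_true(out$temperature_missing[4])
  expect_error(attach_temperature(ev, weather[0, ]), "empty")
})
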