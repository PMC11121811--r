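test_that("noiseless linear events are recovered exactly", {
  ev <- exact_line_events(slope = 5, f_ref = 100)  # f = 100 + 5 (T - 20)
  fit <- suppressWarnings(bin_and_fit(ev, cluster_id = 1, min_bin_count = 2))
  expect_equal(fit$slope, 5, tolerance = 1e-9)
  expect_lt(fit$slope_se, 1e-7)
  expect_equal(fit$mean_freq_at_ref, 100, tolerance = 1e-9)
})

test_that("binning follows the half-open 0.5 degC grid and the cutoffs", {
  set.seed(1)
  tt <- c(rep(9.9, 50), rep(12.2, 50), rep(12.8, 50), rep(15.4, 50),
          rep(18.1, 3))
  ev <- data.frame(temperature_C = tt,
                   wingbeat_hz = 100 + 2 * (tt - 20) + rnorm(length(tt), 0, .1),
                   cluster = 1L)
  fit <- bin_and_fit(ev, 1, min_bin_count = 10)
  # 9.9 is below t_min; 18.1 has 3 < 10 events; the rest map to bin centers
  expect_equal(fit$bin_centers, c(12.25, 12.75, 15.25))
  expect_equal(fit$bin_counts, c(50L, 50L, 50L))
  expect_error(bin_and_fit(ev[1:50, ], 1), "no qualifying events")
  expect_error(bin_and_fit(ev[51:100, ], 1), "insufficient data")
})

test_that("slope polynomial fit matches a brute-force normal-equations oracle", {
  set.seed(42)
  for (i in 1:100) {
    m <- sample(3:8, 1)
    f <- sort(runif(m, 20, 700))
    s <- runif(1, -8e-5, -1e-5) * f^2 + runif(1, 0.01, 0.06) * f +
      rnorm(m, 0, 0.05)
    model <- fit_slope_polynomial(f, s)
    X <- cbind(f^2, f)
    beta <- solve(t(X) %*% X, t(X) %*% s)   # independent oracle
    expect_equal(model$a, beta[1], tolerance = 1e-10)
    expect_equal(model$b, beta[2], tolerance = 1e-10)
  }
})

test_that("exact linear slope data give a zero quadratic term", {
  f <- c(50, 150, 400, 600)
  model <- fit_slope_polynomial(f, 0.04 * f)
  expect_equal(model$a, 0, tolerance = 1e-12)
  expect_equal(model$b, 0.04, tolerance = 1e-12)
  expect_error(fit_slope_polynomial(c(1, 2), c(1, 2)), "length")
  expect_error(fit_slope_polynomial(c(0, 0, 0), c(1, 1, 1)), "degenerate")
})

test_that("slope_at evaluates the quadratic and peaks at its vertex", {
  m <- correction_model(a = -3.605e-5, b = 0.0372)
  expect_equal(slope_at(m, 0), 0)
  expect_equal(slope_at(m, 100), 3.3595)
  vertex <- -m$b / (2 * m$a)
  expect_equal(vertex, 515.95, tolerance = 0.01)
  f <- seq(0, 900, by = 1)
  s <- slope_at(m, f)
  expect_true(all(diff(s[f < floor(vertex)]) > 0))
  expect_true(all(diff(s[f > ceiling(vertex)]) < 0))
})

test_that("frequency correction is exact at the reference and symmetric", {
  m <- correction_model(a = -3.605e-5, b = 0.0372)
  f <- c(25, 100, 180, 525)
  expect_equal(correct_frequency(f, 20, m), f)
  expect_equal(correct_frequency(100, 25, m), 83.2025, tolerance = 1e-10)
  expect_equal(correct_frequency(100, 15, m), 116.7975, tolerance = 1e-10)
  # symmetric about t_ref
  expect_equal(correct_frequency(100, 25, m) + correct_frequency(100, 15, m),
               200, tolerance = 1e-10)
  expect_warning(correct_frequency(100, 45, m), "extrapolates")
})

test_that("round-trip correction inverts the shift at first order", {
  m <- correction_model(a = -3.605e-5, b = 0.0372)
  f0 <- c(60, 150, 320)
  t <- 25
  fc <- correct_frequency(f0, t, m)
  # invert using the same slope s(f0): exact recovery
  back <- fc - slope_at(m, f0) * (m$t_ref - t)
  expect_equal(back, f0, tolerance = 1e-12)
  # self-inverse application (slope re-evaluated at fc): first-order recovery
  back2 <- correct_frequency(fc, 2 * m$t_ref - t, m)
  expect_lt(max(abs(back2 - f0) / f0), 0.05)
})

test_that("corrected distributions conserve counts and shrink variance", {
  ev <- simulate_campaign(campaign_spec(n_events = 6000), seed = 13)
  truth <- reference_clusters()
  model <- fit_slope_polynomial(truth$mean_freq_ref, truth$slope)
  dist <- corrected_distribution(ev, model)
  expect_identical(sum(dist$raw), nrow(ev))
  expect_identical(sum(dist$corrected), nrow(ev))
  for (id in truth$cluster_id) {
    sel <- ev$cluster_truth == id
    expect_lt(sd(dist$corrected_hz[sel]), sd(ev$wingbeat_hz[sel]))
  }
  # all events already at the reference: identical histograms
  ev20 <- ev; ev20$temperature_C <- 20
  d20 <- corrected_distribution(ev20, model)
  expect_identical(d20$raw, d20$corrected)
})

test_that("model serialization round-trips through JSON", {
  ev <- simulate_campaign(campaign_spec(n_events = 5000), seed = 2)
  ev$cluster <- ev$cluster_truth
  fits <- fit_thermal(ev, min_bin_count = 10)
  model <- fit_slope_polynomial(
    vapply(fits, `[[`, numeric(1), "mean_freq_at_ref"),
    vapply(fits, `[[`, numeric(1), "slope"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, fits, path)
  back <- read_model_json(path)
  expect_equal(back$model$a, model$a, tolerance = 1e-12)
  expect_equal(back$model$b, model$b, tolerance = 1e-12)
  expect_equal(back$model$t_ref, 20)
  expect_equal(back$fits[[1]]$slope, fits[[1]]$slope, tolerance = 1e-12)
})
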