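#' Temperature-binned linear fit of wingbeat frequency for one cluster
#'
#' Events of a cluster are partitioned into half-open temperature bins
#' `[t, t + bin_width)` anchored at integer degrees Celsius; observations
#' below `t_min` are omitted (insect activity collapses at low temperature and
#' sparse bins are statistically unstable), as are bins holding fewer than
#' `min_bin_count` events. The per-bin mean frequencies are then regressed on
#' the bin centers by unweighted ordinary least squares, giving the cluster's
#' thermal slope in Hz/degC with its standard error.
#'
#' @param events event data.frame with `wingbeat_hz` and `temperature_C`
#'   (and `cluster` when `cluster_id` is given).
#' @param cluster_id restrict to one cluster label (`NULL`: use all events).
#' @param bin_width bin width in degC.
#' @param t_min lower temperature cutoff in degC.
#' @param min_bin_count minimum events per bin for the bin to be kept.
#' @return An object of class `cluster_thermal_fit`: `cluster_id`,
#'   `bin_centers`, `bin_means`, `bin_counts`, `slope`, `slope_se`,
#'   `intercept`, `mean_freq_at_ref` (fit evaluated at 20 degC), `n_events`.
#' @export
bin_and_fit <- function(events, cluster_id = NULL, bin_width = 0.5,
                        t_min = 10, min_bin_count = 20) {
  stopifnot(all(c("wingbeat_hz", "temperature_C") %in% names(events)))
  ev <- events
  if (!is.null(cluster_id)) {
    stopifnot("cluster" %in% names(ev))
    ev <- ev[ev$cluster == cluster_id, ]
  }
  ev <- ev[is.finite(ev$temperature_C) & is.finite(ev$wingbeat_hz) &
             ev$temperature_C >= t_min, ]
  if (!nrow(ev)) stop("no qualifying events at or above t_min")
  bin <- floor(ev$temperature_C / bin_width) * bin_width
  agg <- tapply(ev$wingbeat_hz, bin, mean)
  cnt <- tapply(ev$wingbeat_hz, bin, length)
  keep <- cnt >= min_bin_count
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 temperature bins with at least ",
         min_bin_count, " events")
  centers <- as.numeric(names(agg))[keep] + bin_width / 2
  means <- as.numeric(agg[keep])
  counts <- as.integer(cnt[keep])
  fit <- stats::lm(means ~ centers)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(cluster_id = cluster_id, bin_centers = centers,
                 bin_means = means, bin_counts = counts,
                 slope = unname(cf[2]), slope_se = unname(se[2]),
                 intercept = unname(cf[1]),
                 mean_freq_at_ref = unname(cf[1] + cf[2] * 20),
                 n_events = nrow(ev)),
            class = "cluster_thermal_fit")
}

#' @export
print.cluster_thermal_fit <- function(x, ...) {
  cat(sprintf(
    "<cluster_thermal_fit> cluster %s: slope %.3f +- %.3f Hz/degC over %d bins (%d events), %.2f Hz at 20 degC\n",
    if (is.null(x$cluster_id)) "all" else x$cluster_id,
    x$slope, x$slope_se, length(x$bin_centers), x$n_events,
    x$mean_freq_at_ref))
  invisible(x)
}

#' Thermal fits for every cluster
#'
#' Applies [bin_and_fit()] to each cluster label present in `events`.
#' Clusters with insufficient qualifying bins are reported as `NULL` with a
#' warning rather than aborting the analysis.
#'
#' @inheritParams bin_and_fit
#' @return A list of `cluster_thermal_fit` objects named by cluster label.
#' @export
fit_thermal <- function(events, bin_width = 0.5, t_min = 10,
                        min_bin_count = 20) {
  stopifnot("cluster" %in% names(events))
  ids <- sort(unique(events$cluster))
  fits <- lapply(ids, function(id) {
    tryCatch(bin_and_fit(events, id, bin_width, t_min, min_bin_count),
             error = function(e) {
               warning("cluster ", id, ": ", conditionMessage(e))
               NULL
             })
  })
  names(fits) <- ids
  fits
}

#' Temperature-correction model
#'
#' The frequency-dependent thermal slope is modeled as a second-degree
#' polynomial through the origin, `s(f) = a f^2 + b f + c` with `c = 0`: an
#' insect that does not beat its wings has no thermal response, and the
#' correction at the reference temperature is identically zero.
#'
#' @param a quadratic coefficient (Hz^-1 degC^-1).
#' @param b linear coefficient (degC^-1).
#' @param c constant term (Hz/degC), fixed at 0.
#' @param t_ref reference temperature in degC (default 20).
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(a, b, c = 0, t_ref = 20) {
  stopifnot(is.finite(a), is.finite(b), c == 0, is.finite(t_ref))
  structure(list(a = a, b = b, c = c, t_ref = t_ref),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> s(f) = %.4g f^2 + %.4g f (t_ref = %g degC)\n",
    x$a, x$b, x$t_ref))
  invisible(x)
}

#' Fit the slope-versus-frequency polynomial
#'
#' Using the per-cluster (mean frequency, thermal slope) pairs as data points,
#' fits `slope = a f^2 + b f` (no constant term) by unweighted ordinary least
#' squares, yielding the general temperature-correction model.
#'
#' @param mean_freqs cluster mean wingbeat frequencies (Hz).
#' @param slopes cluster thermal slopes (Hz/degC).
#' @param t_ref reference temperature carried into the model.
#' @return A [correction_model()].
#' @examples
#' m <- fit_slope_polynomial(
#'   c(50.51, 100.42, 171.33, 290.71, 525.58),
#'   c(2.02, 3.66, 5.10, 7.69, 9.63))
#' m
#' @export
fit_slope_polynomial <- function(mean_freqs, slopes, t_ref = 20) {
  stopifnot(length(mean_freqs) == length(slopes), length(slopes) >= 3,
            all(is.finite(mean_freqs)), all(is.finite(slopes)))
  X <- cbind(f2 = mean_freqs^2, f = mean_freqs)
  if (qr(X)$rank < 2) stop("degenerate design: frequencies are collinear")
  fit <- stats::lm.fit(X, slopes)
  correction_model(a = unname(fit$coefficients[1]),
                   b = unname(fit$coefficients[2]), t_ref = t_ref)
}

#' Thermal slope predicted at a frequency
#'
#' Evaluates `s(f) = a f^2 + b f + c` (Hz/degC).
#'
#' @param model a [correction_model()].
#' @param f wingbeat frequency (Hz), vectorized.
#' @return Slope(s) in Hz/degC.
#' @export
slope_at <- function(model, f) {
  stopifnot(inherits(model, "correction_model"), all(f >= 0))
  model$a * f^2 + model$b * f + model$c
}

#' Correct a wingbeat frequency to the reference temperature
#'
#' `f_corrected = f_initial + s(f_initial) * (t_ref - T)`: the measured
#' frequency is shifted by the modeled thermal response over the temperature
#' difference to the reference. At `T = t_ref` the correction is identically
#' zero. Temperatures outside the fitted 10-38 degC range draw an
#' extrapolation warning; temperatures outside the physically plausible
#' (-10, 50) degC are rejected. Negative corrected frequencies (possible far
#' outside the fitted domain) are flagged with a warning.
#'
#' @param f_initial measured wingbeat frequency (Hz), vectorized.
#' @param t air temperature (degC) at the time of measurement, vectorized.
#' @param model a [correction_model()].
#' @return Corrected frequency (Hz).
#' @examples
#' m <- correction_model(a = -3.605e-5, b = 0.0372)
#' correct_frequency(100, 25, m)   # 83.2 Hz
#' @export
correct_frequency <- function(f_initial, t, model) {
  stopifnot(inherits(model, "correction_model"),
            all(is.finite(f_initial)), all(is.finite(t)))
  if (any(t < -10 | t > 50))
    stop("temperatures outside the plausible (-10, 50) degC range")
  if (any(t < 10 | t > 38))
    warning("temperatures outside the fitted (10, 38) degC range: ",
            "the correction extrapolates")
  out <- f_initial + slope_at(model, f_initial) * (model$t_ref - t)
  if (any(out < 0))
    warning(sum(out < 0),
            " corrected frequencies are negative (out-of-domain extrapolation)")
  out
}

#' Raw and corrected frequency distributions
#'
#' Histograms of the measured and the temperature-corrected wingbeat
#' frequencies over one shared frequency grid, for before/after comparison.
#' Event counts are conserved by construction.
#'
#' @param events event data.frame with `wingbeat_hz` and `temperature_C`.
#' @param model a [correction_model()].
#' @param n_bins number of histogram bins.
#' @return A list with `breaks`, `raw` (counts), `corrected` (counts) and
#'   `corrected_hz` (the corrected per-event frequencies).
#' @export
corrected_distribution <- function(events, model, n_bins = 100) {
  f0 <- events$wingbeat_hz
  fc <- correct_frequency(f0, events$temperature_C, model)
  breaks <- seq(min(f0, fc), max(f0, fc), length.out = n_bins + 1)
  h0 <- graphics::hist(f0, breaks = breaks, plot = FALSE)
  h1 <- graphics::hist(fc, breaks = breaks, plot = FALSE)
  list(breaks = breaks, raw = h0$counts, corrected = h1$counts,
       corrected_hz = fc)
}

#' Serialize / restore a correction model with its per-cluster fits
#'
#' JSON round trip for the fitted thermal analysis: model coefficients,
#' reference temperature, and one record per cluster fit.
#'
#' @param model a [correction_model()].
#' @param fits list of `cluster_thermal_fit` (may contain `NULL`s).
#' @param path JSON file path.
#' @return `read_model_json` returns a list with `model` and `fits`;
#'   `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(model, fits, path) {
  fit_rec <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    f[c("cluster_id", "bin_centers", "bin_means", "bin_counts",
        "slope", "slope_se", "intercept", "mean_freq_at_ref", "n_events")]
  })
  obj <- list(model = list(a = model$a, b = model$b, c = model$c,
                           t_ref = model$t_ref),
              fits = fit_rec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$model
  model <- correction_model(a = m$a, b = m$b, c = m$c, t_ref = m$t_ref)
  fits <- obj$fits
  if (!is.null(fits)) {
    fits <- lapply(fits, function(f) {
      if (is.null(f)) return(NULL)
      structure(f, class = "cluster_thermal_fit")
    })
  }
  list(model = model, fits = fits)
}
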