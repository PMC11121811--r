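#' Pipeline configuration
#'
#' All tunable constants of the end-to-end analysis in one validated object.
#' The defaults are the instrument's and the analysis' canonical values:
#' 30,517 Hz sampling, 10-900 Hz insect band, 10 ms to 1 s transit durations,
#' 0.5 degC temperature bins above 10 degC, a 20 degC reference temperature,
#' and cluster counts 1 to 10.
#'
#' @param instrument an [instrument_config()].
#' @param sampling_rate digitizer rate in Hz.
#' @param k_max largest candidate cluster count.
#' @param seed integer seed used for every stochastic stage.
#' @param restarts K-means starts / GMM refit budget.
#' @param bin_width,t_min,t_ref,min_bin_count thermal-fit parameters (degC,
#'   degC, degC, events per bin); see [bin_and_fit()].
#' @param n_events campaign size when the pipeline simulates its input.
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(instrument = instrument_config(),
                            sampling_rate = 30517,
                            k_max = 10,
                            seed = 1,
                            restarts = 10,
                            bin_width = 0.5,
                            t_min = 10,
                            t_ref = 20,
                            min_bin_count = 20,
                            n_events = 50000) {
  stopifnot(inherits(instrument, "instrument_config"),
            sampling_rate > 0, k_max >= 2, restarts >= 1,
            bin_width > 0, min_bin_count >= 1, n_events > 0)
  if (t_min >= 38) stop("t_min must lie below the campaign temperature range")
  structure(list(instrument = instrument, sampling_rate = sampling_rate,
                 clustering = list(k_max = as.integer(k_max),
                                   seed = as.integer(seed),
                                   restarts = as.integer(restarts)),
                 thermal = list(bin_width = bin_width, t_min = t_min,
                                t_ref = t_ref,
                                min_bin_count = as.integer(min_bin_count)),
                 n_events = as.integer(n_events)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config_yaml` returns the restored `pipeline_config`;
#'   `write_config_yaml` returns `path` invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$instrument <- unclass(plain$instrument)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  plain <- yaml::read_yaml(path)
  inst <- do.call(instrument_config, plain$instrument[
    !vapply(plain$instrument, is.null, logical(1))])
  pipeline_config(instrument = inst,
                  sampling_rate = plain$sampling_rate,
                  k_max = plain$clustering$k_max,
                  seed = plain$clustering$seed,
                  restarts = plain$clustering$restarts,
                  bin_width = plain$thermal$bin_width,
                  t_min = plain$thermal$t_min,
                  t_ref = plain$thermal$t_ref,
                  min_bin_count = plain$thermal$min_bin_count,
                  n_events = plain$n_events)
}

#' Run the full analysis pipeline
#'
#' Event table in (or simulated), corrected event table out: clustering over
#' (frequency, ratio), per-cluster thermal fits, the slope-versus-frequency
#' quadratic, and the temperature correction of every event. Each stage logs
#' its input/output record counts; all randomness derives from the seed in
#' `config`, so a rerun with the same inputs is identical.
#'
#' @param config a [pipeline_config()].
#' @param events optional event data.frame (with `wingbeat_hz`,
#'   `temperature_C`, `ratio`); when `NULL` a campaign of `config$n_events`
#'   events is simulated from [reference_clusters()].
#' @param out_dir optional directory; when given, the clustered events,
#'   corrected events, model JSON and a plain-text run log are written there.
#' @return A list with `events` (clustered + corrected table), `clustering`,
#'   `fits`, `model`, `distribution`, and `log` (character vector of stage
#'   records).
#' @export
run_pipeline <- function(config = pipeline_config(), events = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$clustering$seed
  log <- c(sprintf("wingbeatr %s", as.character(utils::packageVersion("wingbeatr"))),
           sprintf("seed: %d", seed))
  if (is.null(events)) {
    spec <- campaign_spec(n_events = config$n_events)
    events <- simulate_campaign(spec, seed = seed)
    log <- c(log, sprintf("simulated campaign: %d events", nrow(events)))
  } else {
    log <- c(log, sprintf("input events: %d", nrow(events)))
  }
  usable <- is.finite(events$wingbeat_hz) & is.finite(events$ratio) &
    is.finite(events$temperature_C)
  if (any(!usable)) {
    log <- c(log, sprintf("dropped %d events with missing features",
                          sum(!usable)))
    events <- events[usable, ]
  }
  cl <- cluster_events(events, k_range = seq_len(config$clustering$k_max),
                       seed = seed, restarts = config$clustering$restarts)
  events$cluster <- cl$assignments
  log <- c(log, sprintf("clustering: k = %d (GMM %d, K-means %d, %s)",
                        cl$k_selected, cl$k_gmm, cl$k_kmeans,
                        if (cl$agreement) "agree" else "disagree"))
  th <- config$thermal
  fits <- fit_thermal(events, bin_width = th$bin_width, t_min = th$t_min,
                      min_bin_count = th$min_bin_count)
  ok <- !vapply(fits, is.null, logical(1))
  log <- c(log, sprintf("thermal fits: %d/%d clusters fitted", sum(ok),
                        length(fits)))
  if (sum(ok) < 3)
    stop("thermal stage: fewer than 3 clusters with a usable thermal fit")
  model <- fit_slope_polynomial(
    vapply(fits[ok], `[[`, numeric(1), "mean_freq_at_ref"),
    vapply(fits[ok], `[[`, numeric(1), "slope"),
    t_ref = th$t_ref)
  log <- c(log, sprintf("correction model: a = %.6g, b = %.6g, t_ref = %g",
                        model$a, model$b, model$t_ref))
  dist <- corrected_distribution(events, model)
  events$wingbeat_hz_corrected <- dist$corrected_hz
  log <- c(log, sprintf("corrected %d events (count conserved: %s)",
                        nrow(events),
                        sum(dist$raw) == sum(dist$corrected)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_csv(events, file.path(out_dir, "events_corrected.csv"))
    write_model_json(model, fits, file.path(out_dir, "model.json"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(events = events, clustering = cl, fits = fits, model = model,
       distribution = dist, log = log)
}
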