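#' Feature matrix for clustering
#'
#' Events are clustered in the two-dimensional space of wingbeat frequency and
#' wing-to-body cross-section ratio. Because the raw scales differ by roughly
#' three orders of magnitude (hundreds of Hz against a ratio in (0,1)), each
#' column is standardized to zero mean and unit variance before model fitting.
#'
#' @param events event data.frame with columns `wingbeat_hz` and `ratio`.
#' @return A standardized numeric matrix with columns `freq` and `ratio` and
#'   attributes `center` and `scale`.
#' @export
feature_matrix <- function(events) {
  stopifnot(all(c("wingbeat_hz", "ratio") %in% names(events)))
  if (nrow(events) < 2) stop("need at least 2 events to build features")
  x <- cbind(freq = events$wingbeat_hz, ratio = events$ratio)
  if (any(!is.finite(x))) stop("non-finite features; filter events first")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0))
    stop("zero-variance feature column: ",
         paste(colnames(x)[s == 0], collapse = ", "))
  scale(x)
}

# Spherical-Gaussian BIC for a k-means solution (X-means convention): all
# clusters share one spherical variance sigma^2 = RSS / (d (n - k)); the
# log-likelihood includes the mixing proportions; parameters are k centroids
# (k d), k - 1 free mixing weights and one variance.
kmeans_bic <- function(km, n, d) {
  sizes <- km$size[km$size > 0]
  k <- length(sizes)
  rss <- km$tot.withinss
  if (n <= k) return(NA_real_)
  s2 <- max(rss / (d * (n - k)), .Machine$double.eps)
  ll <- sum(sizes * log(sizes / n)) - n * d / 2 * log(2 * pi * s2) -
    rss / (2 * s2)
  npar <- k * d + (k - 1) + 1
  -2 * ll + npar * log(n)
}

fit_gmm <- function(X, k, subset_size = 2000, tol = 1e-4) {
  sub <- sample.int(nrow(X), min(subset_size, nrow(X)))
  suppressWarnings(tryCatch(
    mclust::Mclust(X, G = k, modelNames = "VVV",
                   initialization = list(subset = sub),
                   control = mclust::emControl(tol = c(tol, sqrt(tol) * 1e-3)),
                   verbose = FALSE),
    error = function(e) NULL))
}

#' BIC curves for GMM and K-means over a range of cluster counts
#'
#' For every candidate count k the Gaussian mixture model (full covariance,
#' EM initialized by model-based hierarchical clustering on a random subset)
#' yields the standard BIC, and K-means (Lloyd, `restarts` random starts)
#' yields a BIC under the equal-spherical-variance Gaussian likelihood, so the
#' two curves are comparable. Lower is better for both. Where the GMM gain
#' sequence is locally non-monotone -- the signature of an EM local optimum at
#' some k -- that k is refit from fresh initialization subsets and the best
#' (lowest-BIC) fit kept. Deterministic under a fixed seed.
#'
#' @param features standardized matrix from [feature_matrix()].
#' @param k_range candidate cluster counts (default 1:10).
#' @param seed integer seed governing initialization subsets and K-means
#'   starts.
#' @param restarts number of K-means random starts (and the refit budget for
#'   suspect GMM fits).
#' @return A list of class `bic_curves` with `k_range`, `bic_gmm`,
#'   `bic_kmeans` (numeric vectors, lower = better) and `gmm_refits` (counts
#'   of local-optimum repairs per k).
#' @export
bic_curves <- function(features, k_range = 1:10, seed = 1, restarts = 10) {
  stopifnot(nrow(features) >= max(k_range), min(k_range) >= 1)
  set.seed(as.integer(seed))
  n <- nrow(features); d <- ncol(features)
  kk <- sort(unique(as.integer(k_range)))
  # one mclustBIC call shares the hierarchical initialization across all k
  sub <- sample.int(n, min(2000, n))
  B <- suppressWarnings(tryCatch(
    mclust::mclustBIC(features, G = kk, modelNames = "VVV",
                      initialization = list(subset = sub),
                      control = mclust::emControl(tol = c(1e-4, 1e-7)),
                      verbose = FALSE),
    error = function(e) NULL))
  bic_g <- if (is.null(B)) rep(NA_real_, length(kk)) else -as.numeric(B[, "VVV"])
  for (i in which(!is.finite(bic_g))) {
    # singular fit: retry with a fresh subset, then flag with NA
    f <- fit_gmm(features, kk[i])
    bic_g[i] <- if (is.null(f)) NA_real_ else -as.numeric(f$bic)
  }
  # repair pass: a k whose gain exceeds the previous gain indicates a
  # suboptimal fit at that k; refit with fresh subsets and keep the best
  refits <- integer(length(kk))
  for (pass in 1:2) {
    gains <- -diff(bic_g)
    rng <- max(bic_g, na.rm = TRUE) - min(bic_g, na.rm = TRUE)
    # only a materially oversized gain marks a suspect previous fit; the
    # flat tail wobbles harmlessly and is not worth refitting
    bad <- which(gains[-1] > gains[-length(gains)] * 1.05 &
                   gains[-1] >= 0.02 * rng) + 1L
    if (!length(bad)) break
    for (i in bad) {
      for (r in seq_len(2)) {
        f <- fit_gmm(features, kk[i])
        if (!is.null(f) && is.finite(f$bic) && -f$bic < bic_g[i]) {
          bic_g[i] <- -as.numeric(f$bic)
        }
        refits[i] <- refits[i] + 1L
      }
    }
  }
  bic_k <- vapply(kk, function(k) {
    km <- suppressWarnings(
      stats::kmeans(features, k, nstart = restarts, iter.max = 200,
                    algorithm = "Lloyd"))
    kmeans_bic(km, n, d)
  }, numeric(1))
  structure(list(k_range = kk, bic_gmm = bic_g, bic_kmeans = bic_k,
                 gmm_refits = refits),
            class = "bic_curves")
}

#' @export
print.bic_curves <- function(x, ...) {
  cat("<bic_curves> k =", paste(range(x$k_range), collapse = ".."), "\n")
  print(data.frame(k = x$k_range, bic_gmm = round(x$bic_gmm),
                   bic_kmeans = round(x$bic_kmeans)), row.names = FALSE)
  invisible(x)
}

#' Select the cluster count at the elbow of a BIC curve
#'
#' Two elbow detectors are provided.
#'
#' `"chord"`: after normalizing both axes to the unit square, the elbow is the
#' k at maximal perpendicular distance between the curve and the chord joining
#' its endpoints (kneedle-style). Ties break toward smaller k. When no point
#' deviates from the chord by more than `flat_tol` the curve is flagged
#' no-elbow and the smallest k within `flat_tol` of the chord is returned.
#'
#' `"falloff"`: the elbow is where the marginal BIC improvement collapses --
#' the k maximizing the ratio of its own gain to the following gain, among k
#' whose gain is a non-negligible fraction (`min_gain`) of the curve range.
#' The last candidate count is never selected (its following gain is
#' unobserved). If no k has a non-negligible gain, or the best falloff ratio
#' is below 2 (no sharp bend, e.g. a straight line), the result is flagged
#' no-elbow and falls back to the smallest k within `flat_tol` of the chord.
#'
#' The chord rule reads the global bend of a curve and suits the K-means BIC,
#' which keeps improving on anisotropic clusters; the falloff rule reads the
#' saturation of the likelihood and suits the full-covariance GMM BIC, which
#' stops improving once the true component count is reached. See the methods
#' vignette for the comparison.
#'
#' @param bic numeric BIC vector over consecutive candidate counts (lower =
#'   better), ordered by k.
#' @param k_range the candidate counts the vector corresponds to.
#' @param method `"falloff"` or `"chord"`.
#' @param min_gain minimum gain, as a fraction of the curve range, for a k to
#'   be an elbow candidate under `"falloff"`.
#' @param flat_tol normalized distance below which a point counts as lying on
#'   the chord.
#' @return A list with `k` (selected count), `no_elbow` (logical flag) and
#'   `method`.
#' @export
select_k_elbow <- function(bic, k_range = seq_along(bic),
                           method = c("falloff", "chord"),
                           min_gain = 0.02, flat_tol = 0.05) {
  method <- match.arg(method)
  stopifnot(length(bic) == length(k_range), length(bic) >= 3)
  ok <- is.finite(bic)
  if (!all(ok)) {
    bic <- bic[ok]; k_range <- k_range[ok]
    if (length(bic) < 3) stop("fewer than 3 finite BIC values")
  }
  K <- length(bic)
  x <- (seq_len(K) - 1) / (K - 1)
  rng <- max(bic) - min(bic)
  if (rng <= 0)
    return(list(k = k_range[1], no_elbow = TRUE, method = method))
  y <- (bic - min(bic)) / rng
  chord_dist <- {
    x1 <- x[1]; y1 <- y[1]; x2 <- x[K]; y2 <- y[K]
    abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }
  nearest_chord_k <- function() {
    near <- which(chord_dist <= flat_tol)
    k_range[if (length(near)) min(near) else which.max(chord_dist)]
  }
  if (method == "chord") {
    if (max(chord_dist) <= flat_tol)
      return(list(k = nearest_chord_k(), no_elbow = TRUE, method = method))
    return(list(k = k_range[which.max(chord_dist)], no_elbow = FALSE,
                method = method))
  }
  # falloff
  R <- bic[1] - min(bic)
  if (R <= 0)
    return(list(k = k_range[which.min(bic)], no_elbow = TRUE, method = method))
  gains <- -diff(bic)                # gains[j]: improvement from k_j to k_j+1
  cand <- which(gains >= min_gain * R)
  cand <- cand[cand <= K - 2]        # need an observed following gain
  if (!length(cand))
    return(list(k = nearest_chord_k(), no_elbow = TRUE, method = method))
  floor_gain <- 0.005 * R
  ratio <- vapply(cand, function(j) gains[j] / max(gains[j + 1], floor_gain),
                  numeric(1))
  best <- cand[which.max(ratio)]
  if (max(ratio) < 2)
    return(list(k = nearest_chord_k(), no_elbow = TRUE, method = method))
  list(k = k_range[best + 1L], no_elbow = FALSE, method = method)
}

#' Hard cluster assignment at a chosen count
#'
#' Fits the Gaussian mixture at the selected k and assigns each event to the
#' component of maximum posterior responsibility. Components are relabeled
#' 1..k by ascending mean wingbeat frequency, so cluster 1 is always the
#' lowest-frequency group.
#'
#' @param events event data.frame (`wingbeat_hz`, `ratio`).
#' @param k cluster count.
#' @param seed integer seed (initialization subset).
#' @param features optional precomputed [feature_matrix()].
#' @return A list with `assignments` (integer vector), `centers` (data.frame
#'   of per-cluster mean frequency and ratio) and `model` (the mclust fit).
#' @export
assign_clusters <- function(events, k, seed = 1, features = NULL) {
  if (is.null(features)) features <- feature_matrix(events)
  set.seed(as.integer(seed))
  if (k == 1) {
    lab <- rep(1L, nrow(events))
    centers <- data.frame(cluster = 1L,
                          mean_freq = mean(events$wingbeat_hz),
                          mean_ratio = mean(events$ratio))
    return(list(assignments = lab, centers = centers, model = NULL))
  }
  f <- fit_gmm(features, k)
  if (is.null(f)) stop("GMM fit failed at k = ", k)
  raw <- f$classification
  mean_f <- tapply(events$wingbeat_hz, raw, mean)
  ord <- order(mean_f)                       # old label -> rank
  relabel <- match(raw, as.integer(names(mean_f))[ord])
  centers <- data.frame(
    cluster = seq_len(k),
    mean_freq = as.numeric(mean_f[ord]),
    mean_ratio = as.numeric(tapply(events$ratio, raw, mean)[ord]))
  list(assignments = as.integer(relabel), centers = centers, model = f)
}

#' Cluster events: BIC curves, elbow selection and assignment
#'
#' Runs the full cluster analysis over (wingbeat frequency, wing-to-body
#' ratio): standardized features, GMM and K-means BIC curves over `k_range`,
#' independent elbow selection on each curve, and hard GMM assignment at the
#' selected count, relabeled by ascending mean frequency.
#'
#' @param events event data.frame.
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @param restarts K-means starts / GMM refit budget.
#' @param gmm_method,kmeans_method elbow detector per curve (see
#'   [select_k_elbow()]).
#' @return An object of class `clustering_result`: `k_selected`, `k_gmm`,
#'   `k_kmeans`, `agreement`, `bic_gmm`, `bic_kmeans`, `assignments`,
#'   `centers`, `no_elbow`.
#' @export
cluster_events <- function(events, k_range = 1:10, seed = 1, restarts = 10,
                           gmm_method = "falloff", kmeans_method = "chord") {
  features <- feature_matrix(events)
  curves <- bic_curves(features, k_range, seed = seed, restarts = restarts)
  sel_g <- select_k_elbow(curves$bic_gmm, curves$k_range, method = gmm_method)
  sel_k <- select_k_elbow(curves$bic_kmeans, curves$k_range,
                          method = kmeans_method)
  k_sel <- sel_g$k
  asg <- assign_clusters(events, k_sel, seed = seed, features = features)
  structure(list(k_selected = k_sel, k_gmm = sel_g$k, k_kmeans = sel_k$k,
                 agreement = identical(sel_g$k, sel_k$k),
                 bic_gmm = curves$bic_gmm, bic_kmeans = curves$bic_kmeans,
                 k_range = curves$k_range,
                 assignments = asg$assignments, centers = asg$centers,
                 no_elbow = sel_g$no_elbow || sel_k$no_elbow),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d (GMM %d, K-means %d, %s)\n",
              x$k_selected, x$k_gmm, x$k_kmeans,
              if (x$agreement) "in agreement" else "DISAGREE"))
  print(x$centers, row.names = FALSE)
  invisible(x)
}
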