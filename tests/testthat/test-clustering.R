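test_that("feature matrix standardizes and rejects degenerate input", {
  ev <- data.frame(wingbeat_hz = c(100, 200, 300), ratio = c(0.2, 0.5, 0.8))
  X <- feature_matrix(ev)
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(unname(colMeans(X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(feature_matrix(ev[1, ]), "at least 2")
  ev$ratio <- 0.5
  expect_error(feature_matrix(ev), "zero-variance")
})

test_that("chord elbow matches a brute-force distance oracle", {
  # oracle: normalize both axes to [0,1], compute every point's perpendicular
  # distance to the segment joining the endpoints, take the argmax
  oracle <- function(b) {
    K <- length(b)
    x <- (seq_len(K) - 1) / (K - 1)
    y <- (b - min(b)) / (max(b) - min(b))
    p1 <- c(x[1], y[1]); p2 <- c(x[K], y[K])
    d <- vapply(seq_len(K), function(i) {
      v <- p2 - p1; w <- c(x[i], y[i]) - p1
      abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
    }, numeric(1))
    which.max(d)
  }
  expect_identical(select_k_elbow(c(10, 4, 3.5, 3.4, 3.3),
                                  method = "chord")$k, 2L)
  expect_identical(oracle(c(10, 4, 3.5, 3.4, 3.3)), 2L)
  set.seed(99)
  for (i in 1:50) {
    b <- sort(rnorm(10, sd = 5), decreasing = TRUE) * runif(1, 0.5, 50)
    r <- select_k_elbow(b, method = "chord")
    if (!r$no_elbow) expect_identical(r$k, oracle(b))
  }
})

test_that("falloff elbow agrees on the worked example and flags flat curves", {
  r <- select_k_elbow(c(10, 4, 3.5, 3.4, 3.3), method = "falloff")
  expect_identical(r$k, 2L)
  expect_false(r$no_elbow)
  for (m in c("falloff", "chord")) {
    lin <- select_k_elbow(seq(100, 10, length.out = 10), method = m)
    expect_true(lin$no_elbow)
  }
  expect_error(select_k_elbow(c(3, 2)), "length")
})

test_that("BIC curves are deterministic under a fixed seed", {
  ev <- simulate_campaign(campaign_spec(clusters = two_cluster_table(),
                                        n_events = 1200), seed = 5)
  X <- feature_matrix(ev)
  c1 <- bic_curves(X, 1:6, seed = 9)
  c2 <- bic_curves(X, 1:6, seed = 9)
  expect_identical(c1$bic_gmm, c2$bic_gmm)
  expect_identical(c1$bic_kmeans, c2$bic_kmeans)
})

test_that("well-separated mixtures are recovered at the generating count", {
  # k* = 2 and 3, three seeds each; both detectors must find k*
  tab3 <- data.frame(cluster_id = 1:3,
                     mean_freq_ref = c(60, 200, 480),
                     freq_sd = c(9, 9, 9),
                     slope = c(0, 0, 0),
                     ratio_mean = c(0.75, 0.4, 0.25),
                     ratio_sd = c(0.011, 0.011, 0.011),
                     weight = c(1, 1, 1) / 3)
  for (tab in list(two_cluster_table(), tab3)) {
    k_true <- nrow(tab)
    for (seed in 1:3) {
      ev <- simulate_campaign(campaign_spec(clusters = tab, n_events = 4000),
                              seed = seed)
      X <- feature_matrix(ev)
      cur <- bic_curves(X, 1:8, seed = seed)
      expect_identical(
        select_k_elbow(cur$bic_gmm, cur$k_range, method = "falloff")$k,
        k_true, label = sprintf("GMM, k*=%d, seed %d", k_true, seed))
      expect_identical(
        select_k_elbow(cur$bic_kmeans, cur$k_range, method = "chord")$k,
        k_true, label = sprintf("KM, k*=%d, seed %d", k_true, seed))
    }
  }
})

test_that("assignments match ground truth on separated clusters", {
  ev <- simulate_campaign(campaign_spec(clusters = two_cluster_table(),
                                        n_events = 2000), seed = 8)
  asg <- assign_clusters(ev, 2, seed = 8)
  expect_gte(mean(asg$assignments == ev$cluster_truth), 0.99)
  # labels ordered by ascending mean frequency
  expect_lt(asg$centers$mean_freq[1], asg$centers$mean_freq[2])
  # k = 1: everything in one cluster
  one <- assign_clusters(ev, 1, seed = 8)
  expect_true(all(one$assignments == 1L))
})

test_that("assignments are invariant to affine rescaling of raw features", {
  ev <- simulate_campaign(campaign_spec(clusters = two_cluster_table(),
                                        n_events = 1500), seed = 4)
  ev2 <- ev
  ev2$wingbeat_hz <- ev2$wingbeat_hz / 1000 + 3   # kHz with an offset
  ev2$ratio <- ev2$ratio * 100                    # percent
  a1 <- assign_clusters(ev, 2, seed = 11)
  a2 <- assign_clusters(ev2, 2, seed = 11)
  expect_identical(a1$assignments, a2$assignments)
})
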