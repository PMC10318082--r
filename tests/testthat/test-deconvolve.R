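test_that("LOF scores match the brute-force definition to 1e-9", {
  set.seed(17)
  cases <- list(
    runif(12), c(rep(0.1, 10), 0.9, 0.95), rnorm(20, 0.5, 0.2),
    c(rbeta(15, 1, 9), rbeta(5, 9, 1)))
  for (v in cases) {
    for (k in c(2, 3, 5)) {
      expect_equal(lof_scores(v, k), brute_lof(v, k), tolerance = 1e-9)
    }
  }
  # and at the plate scale with the channel-tuned neighbourhood
  v96 <- c(rbeta(70, 1, 9), rbeta(26, 9, 1))
  expect_equal(lof_scores(v96, 20), brute_lof(v96, 20), tolerance = 1e-9)
})

test_that("LOF detection flags the lone far point and nothing on uniform
           data", {
  set.seed(23)
  v <- c(runif(95, 0, 0.1), 0.9)
  det <- lof_detect(v, n_neighbors = 20)
  expect_identical(which(det$label == -1L), 96L)
  same <- rep(0.4, 96)
  det2 <- lof_detect(same, n_neighbors = 20)
  expect_true(all(det2$label == 1L))
  expect_warning(lof_detect(runif(5), n_neighbors = 20), "inliers")
})

test_that("outlier reassignment moves to the nearest inlier, prefers the
           lower value on ties, and is idempotent", {
  v <- c(0.1, 0.2, 0.9)
  lab <- c(1L, 1L, -1L)
  expect_equal(reassign_outliers(v, lab), c(0.1, 0.2, 0.2))
  # exact tie between inliers 0.25 and 0.75 for the outlier at 0.5
  v2 <- c(0.25, 0.75, 0.5)
  expect_equal(reassign_outliers(v2, c(1L, 1L, -1L)), c(0.25, 0.75, 0.25))
  # idempotence and no-outlier identity
  once <- reassign_outliers(v, lab)
  expect_identical(reassign_outliers(once, lab), once)
  expect_identical(reassign_outliers(v, c(1L, 1L, 1L)), v)
  expect_warning(out <- reassign_outliers(v, c(-1L, -1L, -1L)), "no inliers")
  expect_identical(out, v)
})

test_that("the 1-D GMM recovers separated groups and closed-form k = 1", {
  set.seed(29)
  v <- c(rnorm(48, 0.05, 0.005), rnorm(48, 0.95, 0.005))
  fit <- fit_gmm_1d(v, 2, seed = 1)
  expect_lt(abs(fit$means[1] - 0.05), 0.02)
  expect_lt(abs(fit$means[2] - 0.95), 0.02)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$variances > 0))
  # k = 1 collapses to the sample mean exactly
  one <- fit_gmm_1d(v, 1, seed = 1)
  expect_equal(one$means, mean(v))
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  # re-run EM manually with increasing iteration caps: the reported final
  # log-likelihood must be monotone in the cap
  set.seed(31)
  v <- c(rnorm(40, 0.2, 0.08), rnorm(30, 0.5, 0.08), rnorm(26, 0.85, 0.05))
  lls <- vapply(1:15, function(it)
    fit_gmm_1d(v, 3, seed = 7, max_iter = it, tol = 0)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("GMM fits agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(37)
  v <- c(rnorm(50, 0.15, 0.04), rnorm(46, 0.8, 0.06))
  fit <- fit_gmm_1d(v, 2, seed = 3)
  ref <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_gt(fit$loglik, ref$loglik - 0.5)  # same optimum, up to tolerance
})

test_that("1-D k-means equals the exhaustive contiguous-partition optimum", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    v <- round(runif(n), 3)
    for (k in 2:3) {
      if (length(unique(v)) < k) next
      fit <- cluster_1d(v, "kmeans", k = k, seed = rep)
      oracle <- brute_kmeans_1d(v, k)
      expect_equal(sort(fit$means), sort(oracle$means), tolerance = 1e-9)
    }
  }
  simple <- cluster_1d(c(0, 0, 0, 1, 1, 1), "kmeans", k = 2, seed = 1)
  expect_equal(simple$means, c(0, 1))
  expect_identical(simple$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("k-means labels are invariant under affine rescaling", {
  set.seed(43)
  v <- c(rnorm(20, 0.1, 0.02), rnorm(20, 0.6, 0.02), rnorm(20, 0.9, 0.02))
  a <- cluster_1d(v, "kmeans", k = 3, seed = 5)
  b <- cluster_1d(2.5 * v + 1, "kmeans", k = 3, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_equal(b$means, 2.5 * a$means + 1, tolerance = 1e-8)
})

test_that("DBSCAN separates groups by eps and absorbs noise points", {
  v <- c(rnorm(20, 0.1, 0.01), rnorm(20, 0.6, 0.01))
  fit <- cluster_1d(v, "dbscan", eps = 0.2, seed = 1)
  expect_equal(fit$k, 2)
  expect_identical(fit$labels, rep(1:2, each = 20))
  # eps larger than the gap merges everything
  fit2 <- cluster_1d(v, "dbscan", eps = 0.6, seed = 1)
  expect_equal(fit2$k, 1)
  # an isolated point is noise, then assigned to the nearest cluster
  v3 <- c(rnorm(20, 0.1, 0.01), rnorm(20, 0.9, 0.01), 0.45)
  fit3 <- cluster_1d(v3, "dbscan", eps = 0.1, seed = 1)
  expect_equal(fit3$k, 2)
  expect_identical(fit3$labels[41], 1L)  # 0.45 is nearer the 0.1 cluster
})

test_that("OPTICS finds the two point-mass clusters of a noiseless plate
           and one cluster on a constant plate", {
  v <- rep(c(0, 1), c(60, 36))
  fit <- cluster_1d(v, "optics", seed = 1)
  expect_equal(fit$k, 2)
  expect_equal(fit$means, c(0, 1))
  expect_identical(fit$labels, rep(1:2, c(60, 36)))
  one <- cluster_1d(rep(0.7, 96), "optics", seed = 1)
  expect_equal(one$k, 1)
  expect_equal(one$means, 0.7)
  # too few points for any core point: falls back to one cluster, loudly
  expect_warning(tiny <- cluster_1d(c(0.1, 0.2, 0.8), "optics", seed = 1),
                 "single cluster")
  expect_equal(tiny$k, 1)
})

test_that("full ON/OFF assessment compares every cluster mean to the
           cutoff", {
  m <- function(means) {
    new_model <- cluster_1d(c(0, 1), "kmeans", k = 2, seed = 1)
    new_model$means <- means
    new_model
  }
  expect_identical(full_on_off_check(m(c(0.8, 0.9)), 0.5), "ALL_ON")
  expect_identical(full_on_off_check(m(c(0.02, 0.05)), 0.5), "ALL_OFF")
  expect_identical(full_on_off_check(m(c(0.1, 0.9)), 0.5), "MIXED")
})

test_that("cluster grouping maps blue lowest-cluster and red two-lowest to
           OFF", {
  set.seed(47)
  v <- c(rnorm(30, 0.05, 0.01), rnorm(30, 0.5, 0.01), rnorm(36, 0.9, 0.01))
  fit <- cluster_1d(v, "kmeans", k = 3, seed = 3)
  blue <- group_clusters(fit, "blue")
  expect_identical(blue, rep(c(0L, 1L, 1L), c(30, 30, 36)))
  red <- group_clusters(fit, "red")
  expect_identical(red, rep(c(0L, 0L, 1L), c(30, 30, 36)))
  two <- cluster_1d(v[c(1:30, 61:96)], "kmeans", k = 2, seed = 3)
  expect_identical(group_clusters(two, "red"),
                   rep(c(0L, 1L), c(30, 36)))
  one <- cluster_1d(rep(0.5, 10), "kmeans", k = 2, seed = 1) |>
    suppressWarnings()
  expect_error(group_clusters(one, "blue"), "at least 2")
})

test_that("oracle thresholding is the exhaustive scan", {
  set.seed(53)
  for (rep in 1:10) {
    v <- runif(30)
    truth <- sample(0:1, 30, replace = TRUE)
    got <- oracle_threshold(v, truth)
    ref <- brute_threshold(v, truth)
    expect_equal(got$accuracy, ref$accuracy)
  }
  # separable data reaches 1.0; constant truth reaches prevalence
  v <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  expect_equal(oracle_threshold(v, rep(c(0, 1), each = 10))$accuracy, 1)
  expect_equal(oracle_threshold(runif(20), rep(0L, 20))$accuracy, 1)
  mixed <- oracle_threshold(runif(20), rep(c(0L, 1L), 10))
  expect_gte(mixed$accuracy, 0.5)
})

test_that("calibration puts the cutoff between the grand extreme cluster
           means", {
  fits <- lapply(1:3, function(s) {
    set.seed(s)
    cluster_1d(c(rnorm(40, 0.1, 0.02), rnorm(40, 0.9, 0.02)), "kmeans",
               k = 2, seed = s)
  })
  cut <- calibrate_cutoff(fits)
  expect_gt(cut, 0.4)
  expect_lt(cut, 0.6)
})

test_that("deconvolution is equivariant under well permutation", {
  set.seed(59)
  truth <- random_grid(61)
  reads <- simulate_plate(truth, channel_params(), fix_codes,
                          fix_index[1, ], seed = 61)
  rt <- count_and_ratio(reads, fix_codes)
  values <- rt$value[match(plate_wells(), rt$well)]
  base <- deconvolute(values, seed = 1)
  perm <- sample(96)
  shuffled <- deconvolute(values[perm], seed = 1)
  unshuffled <- integer(96)
  unshuffled[perm] <- shuffled$states
  expect_identical(unshuffled, base$states)
})

test_that("missing wells are excluded from clustering and decoded as 0", {
  set.seed(67)
  v <- c(rep(NA_real_, 6), rbeta(45, 1, 9), rbeta(45, 9, 1))
  expect_warning(dec <- deconvolute(v, seed = 2), "MISSING")
  expect_identical(dec$states[1:6], rep(0L, 6))
  expect_equal(sum(dec$states[52:96] == 1), 45)
})
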