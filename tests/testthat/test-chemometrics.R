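test_that("min-max scaling maps features to [0,1] and is replayable", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 10, 5))
  sc <- fit_minmax(x)
  s <- scale_minmax(sc, x)
  expect_equal(s[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(range(s), c(0, 1))
  expect_identical(scale_minmax(sc, x), s)    # replay reproduces exactly
  expect_warning(sc2 <- fit_minmax(cbind(k = c(3, 3, 3), a = 1:3)),
                 "constant")
  expect_equal(unname(scale_minmax(sc2, cbind(k = c(3, 3, 3), a = 1:3))[, 1]),
               c(0, 0, 0))
  expect_error(fit_minmax(cbind(c(1, NA))), "finite")
})

test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(42)
  x <- matrix(rnorm(500), 50, 10) %*% matrix(runif(100, -1, 1), 10, 10)
  model <- fit_pca(x, 10)
  # brute-force oracle: eigenvectors of the sample covariance matrix
  eg <- eigen(cov(x), symmetric = TRUE)
  expect_equal(model$explained_variance_ratio,
               eg$values / sum(eg$values), tolerance = 1e-8)
  scores <- pca_transform(model, x)
  oracle_scores <- scale(x, center = TRUE, scale = FALSE) %*% eg$vectors
  for (j in 1:10) {
    # sign of each component is arbitrary in the oracle
    expect_lt(min(max(abs(scores[, j] - oracle_scores[, j])),
                  max(abs(scores[, j] + oracle_scores[, j]))), 1e-8)
  }
  # orthonormal loadings
  expect_equal(t(model$loadings) %*% model$loadings, diag(10),
               ignore_attr = TRUE, tolerance = 1e-8)
  # full-rank reconstruction
  recon <- scores %*% t(model$loadings) +
    rep(model$center, each = nrow(x))
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
})

test_that("PCA handles degenerate and invalid inputs", {
  line <- cbind(1:10, 2 * (1:10))          # exactly collinear
  m <- fit_pca(line, 2)
  expect_equal(m$explained_variance_ratio, c(1, 0), tolerance = 1e-9)
  expect_equal(cumulative_variance(m, 1), 1, tolerance = 1e-9)
  expect_error(fit_pca(line, 0), "between 1")
  expect_error(fit_pca(line, 3), "between 1")
  expect_error(cumulative_variance(m, 3), "between 1")
  full <- fit_pca(matrix(rnorm(60), 20, 3), 3)
  expect_equal(cumulative_variance(full, 3), 1, tolerance = 1e-9)
  # sign convention: largest-magnitude loading entry is positive
  expect_true(all(apply(full$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("normalise-then-PCA pipeline is invariant to feature order", {
  set.seed(7)
  x <- matrix(rnorm(200), 40, 5)
  perm <- c(3, 1, 5, 2, 4)
  run <- function(z, k) {
    sc <- fit_minmax(z)
    m <- fit_pca(scale_minmax(sc, z), k)
    list(scores = pca_transform(m, scale_minmax(sc, z)), model = m)
  }
  a <- run(x, 3); b <- run(x[, perm], 3)
  expect_equal(a$scores, b$scores, tolerance = 1e-8)
  expect_equal(a$model$loadings[perm, ], b$model$loadings,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("shelf-life correlations have the expected magnitude and sign", {
  t <- 1:20
  expect_equal(unname(correlate_with_shelf_life(cbind(2 * t + 3), t)), 1)
  expect_equal(unname(correlate_with_shelf_life(cbind(-t), t)), -1)
  expect_warning(
    r <- correlate_with_shelf_life(cbind(const = rep(1, 20), up = t), t),
    "zero-variance")
  expect_true(is.na(r["const"]) && r["up"] == 1)
  # synthetic trial: spoilage indices fall, condition scores rise, with
  # remaining shelf life
  d <- simulate_enose(enose_config(12, seed = 13))
  sl <- remaining_shelf_life(d$labels$time_hours, d$labels$label)
  r <- correlate_with_shelf_life(d$quality[, -1], sl)
  expect_lt(r["tvbn"], -0.9)
  expect_lt(r["tpc"], -0.9)
  expect_gt(r["hardness"], 0.5)
  expect_gt(r["odor"], 0.9)
})

test_that("decay deadline is the first decayed timepoint", {
  expect_equal(decay_deadline(c(0, 2, 4, 6), c(1, 2, 3, 3)), 4)
  expect_error(decay_deadline(1:3, c(1, 1, 2)), "no timepoint")
  expect_equal(remaining_shelf_life(c(0, 2, 4), c(1, 2, 3)), c(4, 2, 0))
})

test_that("Euclidean distance agrees with the naive loop computation", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:5, 1:5), 0)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(euclidean_distance(a, b), naive_euclid(a, b))
  }
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
})

test_that("Lloyd k-means separates distant blobs and satisfies its contracts", {
  set.seed(20)
  blobs <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
                 matrix(rnorm(60, 20, 0.5), ncol = 2))  # 10+ sigma apart
  truth <- rep(1:2, each = 30)
  cl <- cluster_quality(blobs, k = 2, seed = 4)
  expect_true(all(cl$assignments == truth) || all(cl$assignments == 3 - truth))
  expect_true(all(diff(cl$wss) <= 1e-9))   # objective never increases
  # every point sits with its nearest center
  d2 <- sapply(1:2, function(j)
    apply(blobs, 1, function(p) sum((p - cl$centers[j, ])^2)))
  expect_identical(max.col(-d2, ties.method = "first"), cl$assignments)
  # deterministic under seed
  expect_identical(cluster_quality(blobs, 2, seed = 4),
                   cluster_quality(blobs, 2, seed = 4))
  # k = 1 gives the centroid; k = n gives zero within-cluster spread
  expect_equal(cluster_quality(blobs, 1, seed = 1)$centers[1, ],
               colMeans(blobs), ignore_attr = TRUE)
  expect_equal(cluster_quality(blobs[1:5, ], 5, seed = 1)$tot_withinss, 0)
  expect_error(cluster_quality(blobs[1:3, ], 4), "exceeds")
  # cross-check the objective against the reference k-means implementation
  km <- kmeans(blobs, 2, algorithm = "Lloyd", nstart = 5)
  expect_equal(cl$tot_withinss, km$tot.withinss, tolerance = 1e-8)
})

test_that("loading angles read out pairwise relationships", {
  stub <- structure(list(loadings = rbind(a = c(1, 0), b = c(0.9, 0.1),
                                          c = c(-1, 0)),
                         sdev = c(1, 1),
                         n_components = 2), class = "enose_pca")
  s <- loading_angle_signs(stub)
  expect_identical(s["a", "b"], "positive")
  expect_identical(s["a", "c"], "negative")
  expect_identical(s["a", "a"], "positive")
  one <- structure(list(loadings = cbind(c(1, 0)), sdev = 1,
                        n_components = 1),
                   class = "enose_pca")
  expect_error(loading_angle_signs(one), "at least 2")
  # quality indices: TVB-N aligns with TPC, opposes hardness
  d <- simulate_enose(enose_config(20, seed = 17))
  q <- as.matrix(d$quality[, c("tvbn", "tpc", "hardness", "color", "odor",
                               "tissue")])
  m <- fit_pca(scale_minmax(fit_minmax(q), q), 2)
  s <- loading_angle_signs(m)
  expect_identical(s["tvbn", "tpc"], "positive")
  expect_identical(s["tvbn", "hardness"], "negative")
  expect_identical(s["hardness", "tissue"], "positive")
})
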