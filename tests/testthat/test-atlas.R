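test_that("canberra matches the summation oracle", {
  expect_equal(canberra(c(1, 0), c(0, 1)), 2)
  expect_equal(canberra(c(3, -2, 0.5), c(3, -2, 0.5)), 0)
  expect_equal(canberra(c(0, 0), c(0, 0)), 0)  # 0/0 terms contribute 0
  set.seed(91)
  for (i in 1:25) {
    x <- rnorm(15); y <- rnorm(15)
    x[sample(15, 2)] <- 0
    expect_equal(canberra(x, y), oracle_canberra(x, y), tolerance = 1e-12)
    expect_equal(canberra(x, y), canberra(y, x))
  }
  expect_error(canberra(1:3, 1:4), "length mismatch")
})

test_that("fit_atlas separates constructed blobs and handles duplicates", {
  set.seed(92)
  X <- rbind(matrix(rnorm(60 * 8, mean = 0, sd = 0.05), 60, 8),
             matrix(rnorm(60 * 8, mean = 6, sd = 0.05), 60, 8))
  at <- fit_atlas(X, n_neighbors = 10, seed = 1)
  e <- at$embedding
  c1 <- colMeans(e[1:60, ]); c2 <- colMeans(e[61:120, ])
  spread <- mean(c(sqrt(rowSums(sweep(e[1:60, ], 2, c1)^2)),
                   sqrt(rowSums(sweep(e[61:120, ], 2, c2)^2))))
  expect_gt(sqrt(sum((c1 - c2)^2)), 5 * spread)
  expect_true(all(is.finite(e)))
  expect_error(fit_atlas(X[1:5, ], n_neighbors = 10), "at least")

  # duplicated rows land on near-identical coordinates
  Xd <- X[rep(1:30, each = 2) + rep(c(0, 0), 30), ]
  atd <- fit_atlas(rbind(X, X[1:10, ]), n_neighbors = 10, seed = 1)
  dup <- sqrt(rowSums((atd$embedding[121:130, ] - atd$embedding[1:10, ])^2))
  ext <- max(apply(atd$embedding, 2, function(v) diff(range(v))))
  expect_lt(max(dup) / ext, 0.05)
})

test_that("fit_atlas is deterministic and projection is stable", {
  set.seed(93)
  X <- matrix(rnorm(80 * 6), 80, 6)
  a1 <- fit_atlas(X, n_neighbors = 8, seed = 4)
  a2 <- fit_atlas(X, n_neighbors = 8, seed = 4)
  expect_identical(a1$embedding, a2$embedding)

  # single row duplicated m times projects to m identical outputs
  p <- project_atlas(a1, X[rep(3, 5), ])
  expect_equal(p, p[rep(1, 5), ])
  # self-projection stays near the training embedding
  ptrain <- project_atlas(a1, X)
  disp <- sqrt(rowSums((ptrain - a1$embedding)^2))
  ranges <- apply(a1$embedding, 2, function(v) diff(range(v)))
  expect_lt(mean(disp) / mean(ranges), 0.25)
  expect_error(project_atlas(a1, X[, 1:3]), "dimensionality")
})

test_that("grid_trim matches the brute-force binning oracle", {
  set.seed(94)
  # 12 points in one bin survive cutoff 11; 10 do not
  P <- rbind(matrix(0.5 + rnorm(24, sd = 1e-4), 12, 2),
             matrix(5 + rnorm(20, sd = 1e-4), 10, 2))
  tr <- grid_trim(P, nx = 10, ny = 10, cutoff = 11)
  expect_true(all(tr$retained[1:12]))
  expect_false(any(tr$retained[13:22]))
  expect_equal(sum(tr$grid$counts), 22)

  # random scatter: retained mask equals a per-point bin-count lookup
  Q <- matrix(runif(400), 200, 2)
  tr2 <- grid_trim(Q, nx = 7, ny = 5, cutoff = 8)
  ext <- tr2$grid$extent
  bx <- pmin(7, 1 + floor((Q[, 1] - ext[1]) / (ext[2] - ext[1]) * 7))
  by <- pmin(5, 1 + floor((Q[, 2] - ext[3]) / (ext[4] - ext[3]) * 5))
  cnt <- table(factor(bx, 1:7), factor(by, 1:5))
  expect_equal(tr2$retained,
               cnt[cbind(bx, by)] >= 8, ignore_attr = TRUE)
  # partition exactness
  expect_equal(sum(tr2$retained) + sum(!tr2$retained), 200)
})

test_that("single linkage matches the O(n^3) oracle and cuts correctly", {
  # three points on a line: nearest pair merges first
  P <- cbind(c(0, 1, 10), 0)
  cl <- cluster_single_linkage(P, n_clusters = 2)
  expect_equal(cl$labels[1], cl$labels[2])
  expect_false(cl$labels[1] == cl$labels[3])

  cl3 <- cluster_single_linkage(P, n_clusters = 3)
  expect_equal(sort(unique(cl3$labels)), 1:3)  # singletons

  set.seed(95)
  for (rep in 1:3) {
    Q <- matrix(runif(2 * 50), 50, 2)
    sl <- cluster_single_linkage(Q)
    or <- oracle_single_linkage(Q)
    expect_equal(sl$height, or$heights, tolerance = 1e-12)
    expect_equal(merge_partitions(sl$merge), or$merges)
  }
  expect_error(cluster_single_linkage(P, n_clusters = 9), "n_clusters")
})

test_that("the automatic cut finds the largest merge-distance gap", {
  set.seed(96)
  blobs <- do.call(rbind, lapply(0:3, function(k)
    cbind(rnorm(25, 10 * (k %% 2), 0.1), rnorm(25, 10 * (k %/% 2), 0.1))))
  cl <- cluster_single_linkage(blobs)
  expect_equal(cl$n_clusters, 4L)
  expect_equal(as.vector(table(cl$labels)), rep(25, 4))
})

test_that("spread_labels clamps, covers, and agrees with 1-NN on blobs", {
  set.seed(97)
  # no trimmed points: identity
  P <- matrix(rnorm(40), 20, 2)
  lab <- rep(1:2, 10)
  expect_equal(spread_labels(P, lab), lab)

  # two labeled blobs plus unlabeled midline points
  A <- cbind(rnorm(50, 0, 0.3), rnorm(50, 0, 0.3))
  B <- cbind(rnorm(50, 8, 0.3), rnorm(50, 0, 0.3))
  Mid <- cbind(runif(40, -1, 9), rnorm(40, 0, 0.5))
  pts <- rbind(A, B, Mid)
  labels <- c(rep(1L, 50), rep(2L, 50), rep(NA, 40))
  out <- spread_labels(pts, labels)
  expect_false(anyNA(out))
  expect_equal(out[1:100], labels[1:100])  # clamped
  nn1 <- FNN::get.knnx(pts[1:100, ], pts[101:140, ], k = 1)$nn.index[, 1]
  agree <- mean(out[101:140] == labels[nn1])
  expect_gte(agree, 0.95)
  expect_error(spread_labels(P, rep(NA_integer_, 20)), "no labeled")
})

test_that("convergence curve decreases on multi-patient phantom features", {
  # synthetic super-pixel features: 12 patients from the same 4-component
  # mixture; stability should improve as more patients enter the fit
  gen_patient <- function(seed) {
    set.seed(seed)
    mu <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE)
    comp <- sample(4, 60, replace = TRUE)
    cbind(mu[comp, 1] + rnorm(60, 0, 0.3), mu[comp, 2] + rnorm(60, 0, 0.3),
          matrix(rnorm(60 * 3, 0, 0.2), 60, 3))
  }
  X <- do.call(rbind, lapply(1:12, gen_patient))
  patient <- rep(sprintf("P%02d", 1:12), each = 60)
  cc <- convergence_curve(X, patient, fractions = c(1 / 6, 3 / 6, 1),
                          n_neighbors = 10, seed = 3, probe_n = 300)
  expect_equal(nrow(cc), 3)
  expect_true(all(is.finite(cc$mean_distance)))
  # the full-data fit reproduces itself (up to alignment) almost exactly
  expect_lt(cc$mean_distance[3], 0.05)
  expect_lt(cc$mean_distance[3], cc$mean_distance[1])
  expect_error(convergence_curve(X, patient, fractions = c(0, 1)),
               "fractions")
})

test_that("holdout distance is small in-distribution and bounded", {
  gen_patient <- function(seed) {
    set.seed(seed)
    mu <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
    comp <- sample(3, 50, replace = TRUE)
    cbind(mu[comp, 1] + rnorm(50, 0, 0.3), mu[comp, 2] + rnorm(50, 0, 0.3),
          matrix(rnorm(50 * 2, 0, 0.2), 50, 2))
  }
  X <- do.call(rbind, lapply(1:6, gen_patient))
  patient <- rep(sprintf("P%d", 1:6), each = 50)
  hd <- holdout_distance(X, patient, "P3", n_neighbors = 10, seed = 2)
  expect_true(is.finite(hd$mean))
  expect_lte(hd$mean, 1)  # normalization bound
  expect_gte(hd$mean, 0)
  expect_true(is.finite(hd$var))
  expect_error(holdout_distance(X, patient, "nope"), "unknown patient")
})
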