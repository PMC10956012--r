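make_feature_image <- function(X, h, w, roi = "fix") {
  # lay an n x 15 matrix of feature rows out as an h x w feature image
  stopifnot(nrow(X) == h * w, ncol(X) == 15)
  structure(list(features = array(X, c(h, w, 15)),
                 names = sprintf("f%02d", 1:15),
                 mask = matrix(TRUE, h, w), roi_id = roi),
            class = "feature_image")
}

test_that("standardization is the population z-score with stats recorded", {
  set.seed(81)
  X <- matrix(rnorm(64 * 15), 64, 15)
  # one channel with two-point support {0, 2} -> {-1, +1}
  X[, 3] <- rep(c(0, 2), 32)
  f <- make_feature_image(X, 8, 8)
  s <- standardize_features(f)
  V <- matrix(s$features, 64, 15)
  expect_equal(unique(round(V[, 3], 12)), c(-1, 1))
  expect_equal(colMeans(V), rep(0, 15), tolerance = 1e-9)
  expect_equal(apply(V, 2, polarmap:::pop_sd), rep(1, 15), tolerance = 1e-9)
  expect_equal(unname(s$scaler_stats$mean), colMeans(X))

  # constant channel: centered only, with a warning
  X[, 5] <- 4
  expect_warning(s2 <- standardize_features(make_feature_image(X, 8, 8)),
                 "constant")
  expect_equal(as.vector(matrix(s2$features, 64, 15)[, 5]), rep(0, 64))
  expect_equal(unname(s2$scaler_stats$sd[5]), 1)

  f3 <- f; f3$mask[] <- FALSE
  expect_error(standardize_features(f3), "valid pixels")
})

test_that("two separated point masses yield two exact super-pixels", {
  set.seed(82)
  X <- matrix(rnorm(64 * 15, sd = 0.05), 64, 15)
  X[33:64, ] <- X[33:64, ] + 20
  f <- make_feature_image(X, 8, 8)
  f$scaler_stats <- list(mean = rep(0, 15), sd = rep(1, 15))  # identity scaler
  sp <- build_superpixels(f, k = 2, seed = 1)
  expect_equal(sp$k, 2)
  expect_equal(sort(sp$counts), c(32, 32))
  lab <- sp$assignment[!is.na(sp$assignment)]
  expect_equal(length(unique(lab[1:32])), 1)
  expect_equal(length(unique(lab[33:64])), 1)
  expect_error(build_superpixels(f, k = 1), "k must be")
})

test_that("super-pixel partition is exact and matches nearest centroids", {
  img <- random_mueller_image(24, 24, seed = 83)
  f <- suppressWarnings(standardize_features(normalized_elements(img)))
  sp <- build_superpixels(f, k = 32, seed = 7)
  # conservation: counts sum to valid pixels, members disjoint and covering
  expect_equal(sum(sp$counts), sum(f$mask))
  expect_equal(sp$counts, vapply(sp$member_index, nrow, 0L))
  all_members <- do.call(rbind, sp$member_index)
  expect_equal(nrow(unique(all_members)), sum(f$mask))
  # assignment equals nearest-centroid recomputation
  X <- matrix(f$features, 24 * 24, 15)
  v <- which(!is.na(as.vector(sp$assignment)))
  D2 <- outer(rowSums(X[v, ]^2), rep(1, sp$k)) -
    2 * X[v, ] %*% t(sp$centroids) +
    outer(rep(1, length(v)), rowSums(sp$centroids^2))
  expect_equal(as.vector(sp$assignment)[v], apply(D2, 1, which.min))
  # within-cluster SS beats a random assignment
  wss <- sum((X[v, ] - sp$centroids[as.vector(sp$assignment)[v], ])^2)
  set.seed(1)
  rnd <- sample(sp$k, length(v), replace = TRUE)
  expect_lt(wss, sum((X[v, ] - sp$centroids[rnd, ])^2))
  # determinism
  sp2 <- build_superpixels(f, k = 32, seed = 7)
  expect_identical(sp$assignment, sp2$assignment)
  expect_identical(sp$centroids, sp2$centroids)
})

test_that("identity compression: k = number of distinct pixel values", {
  # 8 x 8 image tiling 4 distinct physical matrices; k = 4 distinct values
  set.seed(84)
  flats <- random_physical_mueller(4)
  tile <- rep(rep(1:4, each = 2), 8)[1:64]
  el <- polarmap:::mm_unflat(flats[tile, , drop = FALSE], 8, 8)
  img <- mueller_image(el)
  f <- suppressWarnings(standardize_features(normalized_elements(img)))
  sp <- build_superpixels(f, k = 4, seed = 2, max_iter = 500, tol = 1e-8)
  expect_equal(sp$k, 4)
  expect_equal(sort(unname(sp$counts)), rep(16L, 4))
  # each super-pixel is pure: its mean PBP equals the per-matrix PBP
  pb <- pbp_image(img)
  spm <- superpixel_pbp_means(sp, pb)
  for (k in 1:4) {
    mem <- sp$member_index[[k]][1, ]
    M <- img$elements[mem[1], mem[2], , ]
    ref <- c(unlist(mmpd(M)), unlist(mmt(M)), unlist(rotation_invariants(M)))
    expect_equal(unname(spm$mean_pbp[k, ]), unname(ref), tolerance = 1e-9)
  }
})

test_that("superpixel_pbp_means matches brute-force averaging", {
  img <- random_mueller_image(12, 12, seed = 85)
  f <- suppressWarnings(standardize_features(normalized_elements(img)))
  sp <- build_superpixels(f, k = 8, seed = 3)
  pb <- pbp_image(img)
  spm <- superpixel_pbp_means(sp, pb)
  for (k in c(1, 4, 8)) {
    mem <- sp$member_index[[k]]
    ref <- colMeans(pb$values[cbind(rep(mem[, 1], ncol(spm$mean_pbp)),
                                    rep(mem[, 2], ncol(spm$mean_pbp)),
                                    rep(seq_len(ncol(spm$mean_pbp)),
                                        each = nrow(mem)))] |>
                      matrix(nrow(mem)))
    expect_equal(unname(spm$mean_pbp[k, ]), ref, tolerance = 1e-12)
  }
  # weighted overall mean equals the whole-ROI pixel mean
  v <- which(!is.na(as.vector(sp$assignment)))
  roi_mean <- colMeans(matrix(pb$values, 144, length(pb$names))[v, ])
  expect_equal(unname(colSums(spm$mean_pbp * sp$counts) / sum(sp$counts)),
               unname(roi_mean), tolerance = 1e-9)
  # shape mismatch errors
  img2 <- random_mueller_image(8, 8, seed = 86)
  expect_error(superpixel_pbp_means(sp, pbp_image(img2)), "mismatch")
})

test_that("single super-pixel holds the ROI mean", {
  img <- random_mueller_image(8, 8, seed = 87)
  f <- suppressWarnings(standardize_features(normalized_elements(img)))
  sp <- build_superpixels(f, k = 2, seed = 1)
  pb <- pbp_image(img)
  spm <- superpixel_pbp_means(sp, pb)
  pooled <- colSums(spm$mean_pbp * sp$counts) / sum(sp$counts)
  expect_equal(unname(pooled),
               unname(colMeans(matrix(pb$values, 64, length(pb$names)))),
               tolerance = 1e-9)
})
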