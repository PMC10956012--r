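#' Standardize a feature image
#'
#' Removes the per-channel mean and scales to unit variance over the valid
#' pixels (population variance, so two pixels valued `{0, 2}` standardize to
#' `{-1, +1}`). Channels with zero variance are centered only (scale kept at
#' 1) with a warning. The statistics are recorded for inversion and for
#' standardizing unseen data.
#'
#' @param features a `feature_image` from [normalized_elements()].
#' @return the feature image with standardized values and a `scaler_stats`
#'   element (list with `mean` and `sd` per channel).
#' @export
standardize_features <- function(features) {
  stopifnot(inherits(features, "feature_image"))
  vidx <- which(as.vector(features$mask))
  if (length(vidx) < 2L) stopf("need at least 2 valid pixels to standardize")
  d <- dim(features$features)
  X <- matrix(features$features, d[1] * d[2], d[3])[vidx, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, pop_sd)
  zero <- sdv <= 0
  if (any(zero)) {
    warnf("%d constant feature channel(s) centered only: %s", sum(zero),
          paste(features$names[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  out <- features
  for (c in seq_len(d[3]))
    out$features[, , c] <- (features$features[, , c] - mu[c]) / sdv[c]
  out$scaler_stats <- list(mean = setNames(mu, features$names),
                           sd = setNames(sdv, features$names))
  out
}

#' Compress pixels into polarization super-pixels
#'
#' Groups all valid pixels of a (standardized) feature image into `k`
#' clusters with minibatch k-means in feature space -- no spatial contiguity
#' is enforced, so super-pixels are Voronoi cells of the 15-dimensional
#' normalized-element space. Every valid pixel is assigned to its nearest
#' centroid (Euclidean; ties to the lowest centroid index); empty clusters
#' are dropped and `k` reported as the realized count. Deterministic given
#' `seed`.
#'
#' @param features a standardized `feature_image` (see
#'   [standardize_features()]); if `scaler_stats` is absent the features are
#'   standardized first.
#' @param k target number of super-pixels (default 1024, at least 2). If the
#'   valid pixel count is below `k`, `k` is lowered with a message.
#' @param seed integer seed.
#' @param batch_size,n_init,max_iter,tol minibatch k-means controls: batch
#'   size (4096), number of k-means++ initializations (10, each drawn on a
#'   subsample of at most `init_subsample` pixels), iteration cap (300), and
#'   the RMS centroid-movement early-stopping tolerance.
#' @param init_subsample subsample size for initialization scoring.
#' @param reassignment_ratio centres whose cumulative count falls below this
#'   fraction of the largest are re-seeded onto random batch points (0
#'   disables), concentrating centres where the pixel mass is.
#' @return object of class `superpixel_set`: `roi_id`, realized `k`,
#'   `centroids` (`k x 15`), `assignment` (`H x W` integer, `NA` off-mask),
#'   `member_index` (list of `n_i x 2` matrices of 1-based (row, col)),
#'   `counts`, `scaler_stats`, `mean_pbp` (`NULL` until
#'   [superpixel_pbp_means()]), `seed`.
#' @export
build_superpixels <- function(features, k = 1024, seed = 0,
                              batch_size = 4096, n_init = 10, max_iter = 300,
                              tol = 1e-3, init_subsample = 16384,
                              reassignment_ratio = 0.01) {
  stopifnot(inherits(features, "feature_image"))
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (is.null(features$scaler_stats)) features <- standardize_features(features)
  d <- dim(features$features)
  vidx <- which(as.vector(features$mask))
  n <- length(vidx)
  if (n < k) {
    message(sprintf("only %d valid pixels; lowering k from %d", n, k))
    k <- n
  }
  X <- matrix(features$features, d[1] * d[2], d[3])[vidx, , drop = FALSE]
  fit <- with_seed(seed,
    minibatch_kmeans_cpp(X, as.integer(k), as.integer(batch_size),
                         as.integer(n_init), as.integer(max_iter), tol,
                         as.integer(init_subsample), reassignment_ratio))
  assign <- as.integer(fit$assignment)
  used <- sort(unique(assign))
  if (length(used) < k) {
    relabel <- integer(k)
    relabel[used] <- seq_along(used)
    assign <- relabel[assign]
  }
  centroids <- fit$centroids[used, , drop = FALSE]
  kr <- length(used)
  amat <- matrix(NA_integer_, d[1], d[2])
  amat[vidx] <- assign
  rows <- ((vidx - 1L) %% d[1]) + 1L
  cols <- ((vidx - 1L) %/% d[1]) + 1L
  ord <- order(assign, vidx)
  counts <- tabulate(assign, kr)
  member_index <- split.data.frame(cbind(row = rows, col = cols)[ord, , drop = FALSE],
                                   rep(seq_len(kr), counts))
  names(member_index) <- NULL
  structure(list(roi_id = features$roi_id, k = kr, centroids = centroids,
                 assignment = amat, member_index = member_index,
                 counts = counts, scaler_stats = features$scaler_stats,
                 mean_pbp = NULL, pbp_names = NULL, seed = seed),
            class = "superpixel_set")
}

#' @export
print.superpixel_set <- function(x, ...) {
  cat(sprintf("<superpixel_set> %s: k = %d, %d member pixels%s\n", x$roi_id,
              x$k, sum(x$counts),
              if (is.null(x$mean_pbp)) "" else
                sprintf(", %d PBP channels", ncol(x$mean_pbp))))
  invisible(x)
}

#' Mean polarization basis parameters per super-pixel
#'
#' Fills `mean_pbp`: the arithmetic mean of the per-pixel polarization basis
#' parameter vectors over each super-pixel's member pixels. The count-
#' weighted overall mean of `mean_pbp` equals the whole-ROI pixel mean.
#'
#' @param sp a `superpixel_set`.
#' @param pbp a `pbp_image` of the same ROI and shape.
#' @return the `superpixel_set` with `mean_pbp` (`k x P`) and `pbp_names`.
#' @export
superpixel_pbp_means <- function(sp, pbp) {
  stopifnot(inherits(sp, "superpixel_set"), inherits(pbp, "pbp_image"))
  d <- dim(pbp$values)
  if (!identical(dim(sp$assignment), d[1:2]))
    stopf("shape mismatch between super-pixels (%d x %d) and PBP image (%d x %d)",
          nrow(sp$assignment), ncol(sp$assignment), d[1], d[2])
  vidx <- which(!is.na(as.vector(sp$assignment)))
  a <- as.vector(sp$assignment)[vidx]
  P <- matrix(pbp$values, d[1] * d[2], d[3])[vidx, , drop = FALSE]
  if (anyNA(P))
    stopf("PBP image has undefined values on super-pixel member pixels")
  sums <- rowsum(P, group = a, reorder = TRUE)
  out <- sp
  out$mean_pbp <- sums / sp$counts
  out$pbp_names <- pbp$names
  colnames(out$mean_pbp) <- pbp$names
  out
}
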