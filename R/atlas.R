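#' Canberra distance
#'
#' `sum_i |x_i - y_i| / (|x_i| + |y_i|)` with `0/0` terms contributing 0.
#' Chosen as the atlas metric because it is robust to outliers and
#' sensitive near the origin of standardized polarization features. Note
#' this is the textbook definition (denominator `|x_i| + |y_i|`), not the
#' `|x_i + y_i|` variant used by [stats::dist()].
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar; `canberra(x, x) == 0`.
#' @export
canberra <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  canberra_cpp(as.numeric(x), as.numeric(y))
}

# Standardize rows with stored stats
.apply_scaler <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}

.knn_rows <- function(Xref, Xq, k, metric) {
  if (metric == "canberra") {
    knn_canberra_cpp(Xref, Xq, as.integer(k))
  } else {
    nn <- FNN::get.knnx(Xref, Xq, k = k)
    list(idx = nn$nn.index, dist = nn$nn.dist)
  }
}

#' Fit the polarization atlas embedding
#'
#' Pools super-pixel feature rows (by default their mean polarization basis
#' parameter vectors), standardizes them globally to zero mean and unit
#' variance, and embeds them to 2D with UMAP over a brute-force Canberra
#' k-nearest-neighbour graph (30 neighbours by default). The fitted model
#' retains the standardized training matrix and the UMAP model so unseen
#' rows can be projected with [project_atlas()]. Deterministic given `seed`.
#'
#' @param X numeric matrix of pooled feature rows (one row per super-pixel),
#'   or a list of `superpixel_set` objects (their `mean_pbp` rows are pooled
#'   and `source_keys` derived).
#' @param keys optional data.frame with one row per feature row (e.g.
#'   `roi_id`, `superpixel_index`, `patient_id`, `group`, `count`).
#' @param n_neighbors neighbourhood size (default 30).
#' @param metric `"canberra"` (default) or `"euclidean"`.
#' @param seed integer seed.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param n_epochs UMAP optimization epochs (`NULL` = uwot default).
#' @return object of class `atlas_model`: `embedding` (`n x 2`),
#'   `source_keys`, `scaler_stats`, `train_scaled`, `umap_model`,
#'   `retained_mask`, `linkage`, `labels` (filled by the clustering steps),
#'   `params`.
#' @export
fit_atlas <- function(X, keys = NULL, n_neighbors = 30, metric = "canberra",
                      seed = 0, min_dist = 0.1, n_epochs = NULL) {
  if (is.list(X) && !is.data.frame(X) && !is.matrix(X)) {
    pooled <- pool_superpixels(X)
    X <- pooled$X
    keys <- pooled$keys
  }
  X <- as.matrix(X)
  metric <- match.arg(metric, c("canberra", "euclidean"))
  if (nrow(X) < n_neighbors + 1)
    stopf("need at least n_neighbors + 1 = %d rows, got %d", n_neighbors + 1,
          nrow(X))
  mu <- colMeans(X)
  sdv <- apply(X, 2, pop_sd)
  sdv[sdv <= 0] <- 1
  stats <- list(mean = mu, sd = sdv)
  Xs <- .apply_scaler(X, stats)
  nn <- .knn_rows(Xs, Xs, n_neighbors, metric)
  model <- with_seed(seed,
    uwot::umap(Xs, nn_method = list(idx = nn$idx, dist = nn$dist),
               n_components = 2, min_dist = min_dist,
               n_epochs = n_epochs,
               init = "spca", ret_model = TRUE,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  emb <- unname(model$embedding)
  colnames(emb) <- c("x", "y")
  structure(list(embedding = emb, source_keys = keys, scaler_stats = stats,
                 train_scaled = Xs, umap_model = model,
                 retained_mask = NULL, linkage = NULL, labels = NULL,
                 params = list(metric = metric, n_neighbors = n_neighbors,
                               min_dist = min_dist, seed = seed)),
            class = "atlas_model")
}

#' Pool super-pixel feature rows across regions of interest
#'
#' @param sps list of `superpixel_set` objects with `mean_pbp` filled.
#' @param what `"mean_pbp"` (default) or `"centroids"` (the 15 standardized
#'   element means) as embedding features.
#' @param meta optional data.frame keyed by `roi_id` with extra columns
#'   (e.g. `patient_id`, `group`) to join onto the keys.
#' @return list with `X` (pooled matrix) and `keys` (data.frame with
#'   `roi_id`, `superpixel_index`, `count`).
#' @export
pool_superpixels <- function(sps, what = c("mean_pbp", "centroids"),
                             meta = NULL) {
  what <- match.arg(what)
  rows <- lapply(sps, function(sp) {
    m <- if (what == "mean_pbp") sp$mean_pbp else sp$centroids
    if (is.null(m)) stopf("superpixel set %s has no %s", sp$roi_id, what)
    m
  })
  keys <- do.call(rbind, lapply(sps, function(sp)
    data.frame(roi_id = sp$roi_id, superpixel_index = seq_len(sp$k),
               count = sp$counts, stringsAsFactors = FALSE)))
  if (!is.null(meta)) keys <- merge(keys, meta, by = "roi_id", sort = FALSE)
  list(X = do.call(rbind, rows), keys = keys)
}

#' Project unseen feature rows onto a fitted atlas
#'
#' Standardizes rows with the stored statistics and maps them through the
#' fitted UMAP model using their Canberra nearest neighbours among the
#' training rows. Deterministic given the model.
#'
#' @param model a fitted `atlas_model`.
#' @param rows numeric matrix with the same feature dimensionality as the
#'   training data.
#' @return `m x 2` matrix of embedding coordinates.
#' @export
project_atlas <- function(model, rows) {
  stopifnot(inherits(model, "atlas_model"))
  rows <- as.matrix(rows)
  if (ncol(rows) != ncol(model$train_scaled))
    stopf("row dimensionality %d does not match the model (%d)", ncol(rows),
          ncol(model$train_scaled))
  Xs <- .apply_scaler(rows, model$scaler_stats)
  nn <- .knn_rows(model$train_scaled, Xs, model$params$n_neighbors,
                  model$params$metric)
  # n_epochs = 0: the projection is the membership-weighted barycenter of
  # the training neighbours' coordinates -- deterministic, and identical
  # input rows map to identical coordinates
  emb <- with_seed(model$params$seed,
    uwot::umap_transform(X = NULL, model = model$umap_model,
                         nn_method = list(idx = nn$idx, dist = nn$dist),
                         n_epochs = 0,
                         n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  unname(emb)
}

#' Density grid and low-density trimming
#'
#' Bins embedding points on a regular `nx x ny` grid spanning the bounding
#' box (padded by `1e-9` of each range; bins half-open except the last) and
#' retains exactly the points whose bin holds at least `cutoff` points.
#'
#' @param points `n x 2` matrix of embedding coordinates.
#' @param nx,ny grid resolution (default 200 x 200).
#' @param cutoff minimum bin occupancy to retain (default 11; retain iff
#'   `count >= cutoff`).
#' @param extent optional `c(xmin, xmax, ymin, ymax)` to bin on a shared
#'   grid; points outside are trimmed.
#' @return list with `retained` (logical n), `grid` (a `density_grid`:
#'   `extent`, `nx`, `ny`, `counts`), and `bin` (n x 2 integer bin index,
#'   `NA` outside the extent).
#' @export
grid_trim <- function(points, nx = 200, ny = 200, cutoff = 11, extent = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stopf("need at least one point")
  g <- bin_points(points, nx, ny, extent)
  inb <- !is.na(g$bin[, 1])
  retained <- rep(FALSE, nrow(points))
  retained[inb] <- g$counts[cbind(g$bin[inb, 1], g$bin[inb, 2])] >= cutoff
  list(retained = retained,
       grid = structure(list(extent = g$extent, nx = nx, ny = ny,
                             counts = g$counts), class = "density_grid"),
       bin = g$bin)
}

#' @noRd
bin_points <- function(points, nx, ny, extent = NULL) {
  x <- points[, 1]; y <- points[, 2]
  if (is.null(extent)) {
    rx <- range(x); ry <- range(y)
    px <- max(diff(rx), 1) * 1e-9
    py <- max(diff(ry), 1) * 1e-9
    extent <- c(rx[1] - px, rx[2] + px, ry[1] - py, ry[2] + py)
  }
  ix <- findInterval(x, seq(extent[1], extent[2], length.out = nx + 1),
                     rightmost.closed = TRUE)
  iy <- findInterval(y, seq(extent[3], extent[4], length.out = ny + 1),
                     rightmost.closed = TRUE)
  ix[ix < 1 | ix > nx] <- NA
  iy[iy < 1 | iy > ny] <- NA
  bad <- is.na(ix) | is.na(iy)
  ix[bad] <- NA; iy[bad] <- NA
  counts <- matrix(0L, nx, ny)
  ok <- !bad
  if (any(ok)) {
    t <- table(factor(ix[ok], levels = 1:nx), factor(iy[ok], levels = 1:ny))
    counts <- matrix(as.integer(t), nx, ny)
  }
  list(bin = cbind(ix, iy), counts = counts, extent = extent)
}

#' Single-linkage clustering of embedded points
#'
#' Agglomerates points by minimum inter-cluster point distance (Euclidean in
#' the 2D embedding), computed via the minimum spanning tree; merge-distance
#' ties are broken by lexicographic node id. Cutting the resulting tree at
#' `n_clusters` groups -- or, when `n_clusters` is `NULL`, at the largest gap
#' between consecutive merge heights -- yields the cluster labels.
#'
#' @param points `n x d` matrix (the 2D embedding).
#' @param n_clusters desired number of clusters in `[1, n]`, or `NULL` for
#'   the automatic largest-gap cut.
#' @return list with `labels` (1-based, ordered by decreasing cluster size),
#'   `merge` and `height` (hclust-style merge encoding), `hclust` (a valid
#'   [stats::hclust] object), and `n_clusters`.
#' @export
cluster_single_linkage <- function(points, n_clusters = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.null(n_clusters)) {
    if (!is_count(n_clusters) || n_clusters < 1 || n_clusters > n)
      stopf("n_clusters must be an integer in [1, %d]", n)
  }
  if (n == 1) {
    return(list(labels = 1L, merge = matrix(integer(), 0, 2),
                height = numeric(), hclust = NULL, n_clusters = 1L))
  }
  sl <- mst_single_linkage_cpp(points)
  hc <- structure(list(merge = sl$merge, height = as.numeric(sl$height),
                       order = .leaf_order(sl$merge, n),
                       labels = NULL, method = "single",
                       call = match.call(), dist.method = "euclidean"),
                  class = "hclust")
  if (is.null(n_clusters)) {
    # cut at the largest relative jump between consecutive merge heights:
    # scale-invariant, so it finds the within-cluster -> between-cluster
    # transition rather than the single widest gap near the root
    h <- hc$height
    if (length(h) >= 2) {
      lo <- h[-length(h)]
      hi <- h[-1]
      ratio <- ifelse(lo > 0, hi / lo, -Inf)
      # only the top of the tree holds principal structure; near-zero
      # leaf-level merges would otherwise produce spurious ratios
      first <- max(1L, length(ratio) - 49L)
      ratio[seq_len(first - 1L)] <- -Inf
      if (all(!is.finite(ratio) | ratio <= 0)) {
        n_clusters <- 1L
      } else {
        j <- which.max(ratio)  # cut between merge j and j+1
        n_clusters <- n - j
      }
    } else n_clusters <- 1L
  }
  raw <- stats::cutree(hc, k = n_clusters)
  # stable relabeling: 1 = largest cluster
  sizes <- tabulate(raw, n_clusters)
  relabel <- integer(n_clusters)
  relabel[order(sizes, decreasing = TRUE)] <- seq_len(n_clusters)
  list(labels = relabel[raw], merge = sl$merge, height = as.numeric(sl$height),
       hclust = hc, n_clusters = as.integer(n_clusters))
}

# Stability-based automatic dendrogram cut: for every cut level, count the
# clusters carrying at least min_frac of the pixel mass; the principal-
# structure count is the one persisting over the widest total log-height
# range of cuts (class separations persist, incidental sub-splits do not),
# and the chosen cut is the single most persistent level with that count.
#' @noRd
.persistent_cut <- function(points, w, min_frac) {
  n <- nrow(points)
  if (n < 3) return(1L)
  sl <- mst_single_linkage_cpp(points)
  hc <- structure(list(merge = sl$merge, height = as.numeric(sl$height),
                       order = seq_len(n)), class = "hclust")
  thr <- min_frac * sum(w)
  h <- as.numeric(sl$height)
  ks <- 2:min(80L, n - 1L)
  np <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k)
    sum(vapply(seq_len(k), function(j) sum(w[lab == j]), 0) >= thr)
  }, 0L)
  wk <- vapply(ks, function(k) {
    j <- n - k
    max(0, log(max(h[j + 1], 1e-12) / max(h[j], 1e-12)))
  }, 0)
  score <- tapply(wk, np, sum)
  best <- as.integer(names(score)[which.max(score)])
  cand <- ks[np == best]
  cand[which.max(wk[np == best])]
}

# leaf ordering consistent with the merge matrix (iterative, no recursion)
#' @noRd
.leaf_order <- function(merge, n) {
  res <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    left <- if (merge[s, 1] < 0) -merge[s, 1] else res[[merge[s, 1]]]
    right <- if (merge[s, 2] < 0) -merge[s, 2] else res[[merge[s, 2]]]
    res[[s]] <- c(left, right)
  }
  as.integer(res[[n - 1]])
}

#' Recover labels of trimmed points by label spreading
#'
#' Propagates cluster labels from the retained (labeled) points to the
#' trimmed ones over a k-nearest-neighbour graph in the 2D embedding, with
#' hard clamping: labeled points never change. Unlabeled points iteratively
#' take the distance-weighted majority label of their labeled neighbours;
#' any point left unreachable falls back to its nearest labeled neighbour.
#'
#' @param points `n x 2` embedding coordinates of all points.
#' @param labels integer vector of length n; `NA` marks points to label.
#' @param k neighbourhood size of the spreading graph (default 7).
#' @return integer label vector with no `NA`; clamped entries unchanged.
#' @export
spread_labels <- function(points, labels, k = 7) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(length(labels) == n)
  if (all(is.na(labels))) stopf("no labeled points to spread from")
  out <- labels
  todo <- which(is.na(out))
  if (!length(todo)) return(out)
  k <- min(k, n - 1)
  nn <- FNN::get.knn(points, k = k)
  w <- 1 / (nn$nn.dist + 1e-12)
  for (it in seq_len(100)) {
    changed <- FALSE
    cur <- out
    for (i in todo) {
      if (!is.na(cur[i])) next
      lab <- out[nn$nn.index[i, ]]
      ok <- !is.na(lab)
      if (!any(ok)) next
      scores <- rowsum(w[i, ok], lab[ok])
      cur[i] <- as.integer(rownames(scores)[which.max(scores)])
      changed <- TRUE
    }
    out <- cur
    todo <- which(is.na(out))
    if (!length(todo) || !changed) break
  }
  if (length(todo)) {
    labeled <- which(!is.na(labels))
    nn1 <- FNN::get.knnx(points[labeled, , drop = FALSE],
                         points[todo, , drop = FALSE], k = 1)
    out[todo] <- labels[labeled[nn1$nn.index[, 1]]]
  }
  out
}

# rigid (rotation/reflection + translation) alignment of B onto A, 2D
#' @noRd
kabsch2d <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  s <- svd(H)
  R <- s$v %*% t(s$u)
  list(R = R, t = ca - as.vector(R %*% cb))
}

#' @noRd
apply_rigid <- function(X, tr) sweep(X %*% t(tr$R), 2, tr$t, "+")

# per-axis-range normalized mean displacement between paired point sets
#' @noRd
normalized_displacement <- function(P, Q, ranges) {
  dx <- (P[, 1] - Q[, 1]) / ranges[1]
  dy <- (P[, 2] - Q[, 2]) / ranges[2]
  sqrt(dx^2 + dy^2)
}

#' Embedding convergence as patients are added
#'
#' Quantifies the stability of the atlas configuration: for each fraction of
#' patients, fits an atlas on that subset, projects a fixed probe set, and
#' reports the mean displacement to the full-data fit's projection after
#' rigid (rotation + translation, reflection allowed) alignment, with each
#' coordinate normalized by the full fit's axis range. On phantoms the curve
#' is expected to decrease with the fraction of data (not strictly
#' asserted).
#'
#' @param X pooled feature matrix (one row per super-pixel).
#' @param patient character vector of patient ids, one per row.
#' @param fractions fractions of patients in `(0, 1]` (default `1:6 / 6`).
#' @param n_neighbors,metric,seed passed to [fit_atlas()].
#' @param probe_n probe subsample size (default up to 2000 rows).
#' @return data.frame with `fraction`, `n_patients`, `mean_distance`.
#' @export
convergence_curve <- function(X, patient, fractions = (1:6) / 6,
                              n_neighbors = 30, metric = "canberra",
                              seed = 0, probe_n = 2000) {
  X <- as.matrix(X)
  stopifnot(length(patient) == nrow(X))
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must lie in (0, 1]")
  pats <- unique(patient)
  if (length(pats) < 2) stopf("need at least 2 patients")
  full <- fit_atlas(X, n_neighbors = n_neighbors, metric = metric, seed = seed)
  probe <- with_seed(seed + 1L,
                     sort(sample(nrow(X), min(probe_n, nrow(X)))))
  ref <- full$embedding[probe, , drop = FALSE]
  ranges <- c(diff(range(full$embedding[, 1])),
              diff(range(full$embedding[, 2])))
  ord <- with_seed(seed + 2L, sample(pats))
  out <- lapply(fractions, function(f) {
    np <- max(1L, ceiling(f * length(pats)))
    sel <- patient %in% ord[seq_len(np)]
    if (sum(sel) < n_neighbors + 1)
      return(data.frame(fraction = f, n_patients = np, mean_distance = NA_real_))
    sub <- fit_atlas(X[sel, , drop = FALSE], n_neighbors = n_neighbors,
                     metric = metric, seed = seed)
    pr <- project_atlas(sub, X[probe, , drop = FALSE])
    tr <- kabsch2d(ref, pr)
    d <- normalized_displacement(ref, apply_rigid(pr, tr), ranges)
    data.frame(fraction = f, n_patients = np, mean_distance = mean(d))
  })
  do.call(rbind, out)
}

#' Leave-one-patient-out projection distance
#'
#' Holds out one patient's super-pixels, refits the atlas on the rest, and
#' measures the Euclidean distance between the held-out rows' projection
#' onto the leave-one-out fit and their projection onto the all-data fit.
#' The two fits are first rigidly aligned on the shared training rows
#' (independently fitted embeddings have arbitrary orientation), and
#' distances are normalized by the all-data fit's axis ranges.
#'
#' @param X pooled feature matrix.
#' @param patient patient id per row.
#' @param held_out a patient id present in `patient`.
#' @param n_neighbors,metric,seed passed to [fit_atlas()].
#' @param full optional pre-fitted all-data `atlas_model` (to amortize over
#'   folds).
#' @return list with `mean`, `var`, and the per-super-pixel `distances`.
#' @export
holdout_distance <- function(X, patient, held_out, n_neighbors = 30,
                             metric = "canberra", seed = 0, full = NULL) {
  X <- as.matrix(X)
  stopifnot(length(patient) == nrow(X))
  if (!held_out %in% patient) stopf("unknown patient '%s'", held_out)
  if (length(unique(patient)) < 2) stopf("need at least 2 patients")
  if (is.null(full))
    full <- fit_atlas(X, n_neighbors = n_neighbors, metric = metric, seed = seed)
  test <- patient == held_out
  loo <- fit_atlas(X[!test, , drop = FALSE], n_neighbors = n_neighbors,
                   metric = metric, seed = seed)
  # align the LOO space onto the full space using the shared training rows
  tr <- kabsch2d(full$embedding[!test, , drop = FALSE], loo$embedding)
  p_full <- project_atlas(full, X[test, , drop = FALSE])
  p_loo <- apply_rigid(project_atlas(loo, X[test, , drop = FALSE]), tr)
  ranges <- c(diff(range(full$embedding[, 1])),
              diff(range(full$embedding[, 2])))
  d <- normalized_displacement(p_full, p_loo, ranges)
  list(mean = mean(d), var = stats::var(d), distances = d)
}

#' Trim, cluster and spread labels on a fitted atlas
#'
#' Convenience step chaining [grid_trim()], [cluster_single_linkage()] on
#' the retained points, and [spread_labels()] back to all points. A cluster
#' is principal when it covers at least `min_frac` of the density-retained tissue area
#' (member-pixel mass, taken from the `count` column of the source keys
#' when available, otherwise super-pixel counts); smaller clusters are
#' marked artifact (`-1`). Principal clusters are numbered 1..C by
#' decreasing size.
#'
#' @param model a fitted `atlas_model`.
#' @param nx,ny,cutoff see [grid_trim()].
#' @param n_clusters number of clusters for the dendrogram cut, or `NULL`
#'   for the automatic stability rule: the principal-structure count that
#'   persists over the widest range of cut heights is selected, and the
#'   most persistent cut with that count is used.
#' @param spread_k label-spreading neighbourhood size.
#' @param min_frac minimum fraction of total pixel mass for a principal
#'   cluster (default 0.05: a principal microstructural component covers at
#'   least 5 percent of the imaged tissue).
#' @return the model with `retained_mask`, `linkage`, `labels` (length n;
#'   `-1` = artifact), `grid`, and `n_principal` filled.
#' @export
atlas_cluster <- function(model, nx = 200, ny = 200, cutoff = 11,
                          n_clusters = NULL, spread_k = 7, min_frac = 0.05) {
  stopifnot(inherits(model, "atlas_model"))
  tr <- grid_trim(model$embedding, nx = nx, ny = ny, cutoff = cutoff)
  ret <- tr$retained
  if (!any(ret)) stopf("density trimming removed all points; lower cutoff")
  w <- model$source_keys$count %||% rep(1, nrow(model$embedding))
  if (is.null(n_clusters)) {
    n_clusters <- .persistent_cut(model$embedding[ret, , drop = FALSE],
                                  w[ret], min_frac)
  }
  cl <- cluster_single_linkage(model$embedding[ret, , drop = FALSE],
                               n_clusters = n_clusters)
  mass <- vapply(seq_len(cl$n_clusters),
                 function(k) sum(w[ret][cl$labels == k]), 0)
  principal <- which(mass >= min_frac * sum(w[ret]))
  # principal clusters are ranked by pixel mass; the rest collapse to -1
  principal <- principal[order(mass[principal], decreasing = TRUE)]
  relabel <- rep(-1L, cl$n_clusters)
  relabel[principal] <- seq_along(principal)
  lab_ret <- relabel[cl$labels]
  labels <- rep(NA_integer_, nrow(model$embedding))
  labels[ret] <- lab_ret
  # spread principal labels; artifact (-1) points are clamped too
  labels <- spread_labels(model$embedding, labels, k = spread_k)
  model$retained_mask <- ret
  model$linkage <- list(merge = cl$merge, height = cl$height,
                        hclust = cl$hclust)
  model$labels <- labels
  model$grid <- tr$grid
  model$n_principal <- length(principal)
  model$params <- c(model$params,
                    list(nx = nx, ny = ny, cutoff = cutoff,
                         n_clusters = cl$n_clusters, spread_k = spread_k,
                         min_frac = min_frac))
  model
}

#' Re-cluster selected clusters at finer super-pixel granularity
#'
#' Collects the pixels of the selected atlas clusters, re-compresses them
#' with smaller super-pixels (`k_fine` per ROI), and re-runs the embedding
#' and clustering pipeline on the sub-population, revealing sub-structure
#' within a coarse cluster (e.g. splitting a nucleus cluster into benign and
#' malignant subtypes).
#'
#' @param features list of standardized `feature_image`s (one per ROI).
#' @param pbps list of matching `pbp_image`s.
#' @param masks list of `label_mask` objects from
#'   [project_labels_to_mask()].
#' @param selected integer vector of cluster ids to refine (non-empty).
#' @param k_fine super-pixels per ROI at the finer scale.
#' @param seed integer seed.
#' @param n_neighbors,metric,nx,ny,cutoff,n_clusters,spread_k,min_frac
#'   pipeline parameters, as in [fit_atlas()] and [atlas_cluster()].
#' @return list with `atlas` (clustered `atlas_model`) and `sps` (the fine
#'   `superpixel_set`s).
#' @export
refine_subclusters <- function(features, pbps, masks, selected, k_fine,
                               seed = 0, n_neighbors = 30,
                               metric = "canberra", nx = 200, ny = 200,
                               cutoff = 11, n_clusters = NULL, spread_k = 7,
                               min_frac = 0.05) {
  if (length(selected) == 0) stopf("empty cluster selection")
  stopifnot(length(features) == length(pbps), length(features) == length(masks))
  sps <- vector("list", length(features))
  keep_roi <- logical(length(features))
  for (i in seq_along(features)) {
    f <- features[[i]]
    sel <- masks[[i]]$labels %in% selected
    f$mask <- f$mask & sel & pbps[[i]]$mask
    if (sum(f$mask) < 2) next
    f$scaler_stats <- NULL  # re-standardize over the sub-population
    f <- standardize_features(f)
    sp <- build_superpixels(f, k = min(k_fine, sum(f$mask)), seed = seed + i)
    sps[[i]] <- superpixel_pbp_means(sp, pbps[[i]])
    keep_roi[i] <- TRUE
  }
  sps <- sps[keep_roi]
  if (!length(sps)) stopf("selection matched no pixels")
  atlas <- fit_atlas(sps, n_neighbors = n_neighbors, metric = metric,
                     seed = seed)
  atlas <- atlas_cluster(atlas, nx = nx, ny = ny, cutoff = cutoff,
                         n_clusters = n_clusters, spread_k = spread_k,
                         min_frac = min_frac)
  list(atlas = atlas, sps = sps)
}
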