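#' Project atlas cluster labels back to the image plane
#'
#' Gives every member pixel of a super-pixel the atlas label of that
#' super-pixel. Invalid (masked) pixels receive 0, the unassigned code;
#' artifact clusters (`-1` in the atlas) also map to 0.
#'
#' @param sp a `superpixel_set`.
#' @param labels integer vector of atlas labels, one per super-pixel of this
#'   ROI (in super-pixel index order); must have no `NA`.
#' @return object of class `label_mask`: list with `labels` (`H x W`
#'   integer, 0 = unassigned, 1..C = cluster ids) and `roi_id`.
#' @export
project_labels_to_mask <- function(sp, labels) {
  stopifnot(inherits(sp, "superpixel_set"))
  if (length(labels) != sp$k)
    stopf("expected %d labels (one per super-pixel), got %d", sp$k,
          length(labels))
  if (anyNA(labels)) stopf("missing label for some super-pixel")
  labels <- as.integer(labels)
  labels[labels < 0] <- 0L
  mask <- matrix(0L, nrow(sp$assignment), ncol(sp$assignment))
  v <- !is.na(sp$assignment)
  mask[v] <- labels[sp$assignment[v]]
  structure(list(labels = mask, roi_id = sp$roi_id), class = "label_mask")
}

#' Cluster area proportion
#'
#' Fraction of the total ROI area occupied by one cluster: the pixel count
#' of the cluster divided by the count of all in-ROI pixels (the
#' denominator includes unassigned pixels, so proportions over clusters sum
#' to at most 1 with the remainder unassigned).
#'
#' @param mask a `label_mask` (or integer matrix of labels).
#' @param cluster_id cluster id (>= 1).
#' @return proportion in `[0, 1]`.
#' @export
area_proportion <- function(mask, cluster_id) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  if (!is_count(cluster_id) || cluster_id < 1)
    stopf("cluster_id must be an integer >= 1")
  sum(labels == cluster_id) / length(labels)
}

#' Build the marker table of per-ROI cluster area proportions
#'
#' @param masks list of `label_mask` objects.
#' @param meta data.frame with columns `roi_id`, `patient_id`, `group`.
#' @param cluster_ids cluster ids to tabulate (default: all ids >= 1 present
#'   in any mask).
#' @return data.frame (class `marker_table`) with columns `roi_id`,
#'   `patient_id`, `group`, `cluster_id`, `area_proportion`.
#' @export
marker_table <- function(masks, meta, cluster_ids = NULL) {
  stopifnot(all(c("roi_id", "patient_id", "group") %in% names(meta)))
  if (is.null(cluster_ids)) {
    cluster_ids <- sort(unique(unlist(lapply(masks, function(m)
      setdiff(unique(as.vector(m$labels)), 0L)))))
  }
  rows <- lapply(masks, function(m) {
    i <- match(m$roi_id, meta$roi_id)
    if (is.na(i)) stopf("roi '%s' missing from metadata", m$roi_id)
    data.frame(roi_id = m$roi_id, patient_id = meta$patient_id[i],
               group = meta$group[i], cluster_id = cluster_ids,
               area_proportion = vapply(cluster_ids, function(cid)
                 area_proportion(m, cid), 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Rank-sum AUC of a marker
#'
#' Probability that a randomly chosen positive ROI has a larger marker value
#' than a randomly chosen negative one, ties counted one half (the
#' Mann-Whitney / ROC area statistic).
#'
#' @param values numeric marker values, one per ROI.
#' @param is_positive logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
marker_auc <- function(values, is_positive) {
  stopifnot(length(values) == length(is_positive))
  is_positive <- as.logical(is_positive)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0)
    stopf("need at least one positive and one negative value")
  r <- rank(values, ties.method = "average")
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sample t-test between marker groups
#'
#' Welch's unequal-variance t-test by default (Student's optional),
#' two-sided.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
group_t_test <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs at least 2 values")
  ht <- t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Density heatmap of an embedding subset
#'
#' Bins a subset of embedding points on the shared atlas extent so heatmaps
#' of different groups are directly comparable; the log rendering uses
#' `log10(count + 1)`.
#'
#' @param embedding `n x 2` coordinates of all atlas points.
#' @param subset logical vector selecting the points to bin.
#' @param nx,ny grid resolution.
#' @param extent optional shared extent `c(xmin, xmax, ymin, ymax)`;
#'   defaults to the padded bounding box of all points.
#' @param log_scale return `log10(count + 1)` in `log_counts`.
#' @return a `density_grid` (fields `extent`, `nx`, `ny`, `counts`, and
#'   optionally `log_counts`).
#' @export
density_heatmap <- function(embedding, subset = NULL, nx = 200, ny = 200,
                            extent = NULL, log_scale = TRUE) {
  embedding <- as.matrix(embedding)
  if (is.null(extent))
    extent <- bin_points(embedding, nx, ny)$extent
  subset <- subset %||% rep(TRUE, nrow(embedding))
  if (!any(subset)) stopf("empty subset")
  g <- bin_points(embedding[subset, , drop = FALSE], nx, ny, extent)
  out <- structure(list(extent = extent, nx = nx, ny = ny, counts = g$counts),
                   class = "density_grid")
  if (log_scale) out$log_counts <- log10(g$counts + 1)
  out
}

#' Plot a density grid
#'
#' @param x a `density_grid`.
#' @param log use the log10 counts if present.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_grid <- function(x, log = TRUE, ...) {
  z <- if (log && !is.null(x$log_counts)) x$log_counts else x$counts
  graphics::image(seq(x$extent[1], x$extent[2], length.out = x$nx),
                  seq(x$extent[3], x$extent[4], length.out = x$ny),
                  z, xlab = "UMAP 1", ylab = "UMAP 2", useRaster = TRUE, ...)
  invisible(x)
}

#' Marker report: percentiles, pairwise tests and AUCs
#'
#' For every cluster and group: the 10/25/50/75/90 percentiles of the area
#' proportion (the box-whisker statistics; linear interpolation between
#' order statistics). For every requested contrast `c(negative_group,
#' positive_group)`: the Welch p-value and the rank-sum AUC per cluster,
#' with an optional Holm-adjusted column.
#'
#' @param table a `marker_table`.
#' @param contrasts list of length-2 character vectors
#'   `c(negative, positive)`; groups must be present in the table.
#' @param holm add a Holm-adjusted p-value column across the report.
#' @return list with data.frames `percentiles` (`cluster_id`, `group`, `n`,
#'   `p10`, `p25`, `p50`, `p75`, `p90`) and `tests` (`cluster_id`,
#'   `negative`, `positive`, `t_statistic`, `p_value`, `auc`).
#' @export
marker_report <- function(table, contrasts = list(), holm = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("group", "cluster_id", "area_proportion") %in% names(table)))
  groups <- unique(table$group)
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% groups))
      stopf("contrast groups must name 2 groups present in the table (known: %s)",
            paste(groups, collapse = ", "))
  }
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  pct <- do.call(rbind, lapply(split(table, table[c("cluster_id", "group")],
                                     drop = TRUE), function(s) {
    q <- quantile(s$area_proportion, probs = probs, type = 7, names = FALSE)
    data.frame(cluster_id = s$cluster_id[1], group = s$group[1],
               n = nrow(s), p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
               p90 = q[5], stringsAsFactors = FALSE)
  }))
  rownames(pct) <- NULL
  tests <- NULL
  if (length(contrasts)) {
    tests <- do.call(rbind, lapply(contrasts, function(ct) {
      do.call(rbind, lapply(sort(unique(table$cluster_id)), function(cid) {
        neg <- table$area_proportion[table$group == ct[1] &
                                       table$cluster_id == cid]
        pos <- table$area_proportion[table$group == ct[2] &
                                       table$cluster_id == cid]
        tt <- group_t_test(neg, pos)
        data.frame(cluster_id = cid, negative = ct[1], positive = ct[2],
                   t_statistic = tt$statistic, p_value = tt$p_value,
                   auc = marker_auc(c(neg, pos),
                                    c(rep(FALSE, length(neg)),
                                      rep(TRUE, length(pos)))),
                   stringsAsFactors = FALSE)
      }))
    }))
    if (holm) tests$p_holm <- stats::p.adjust(tests$p_value, method = "holm")
  }
  list(percentiles = pct, tests = tests)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table; 1 = identical partitions (up to
#' label permutation), ~0 = chance agreement.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(if (sij == maxi) 1 else 0)
  (sij - expected) / (maxi - expected)
}
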