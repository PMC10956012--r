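make_sp_toy <- function() {
  # 4 x 4 ROI, 3 super-pixels with known member lists
  assignment <- matrix(c(1, 1, 2, 2,
                         1, 1, 2, 2,
                         3, 3, 3, 3,
                         3, 3, 3, 3), 4, 4, byrow = TRUE)
  v <- which(!is.na(assignment))
  rows <- ((v - 1) %% 4) + 1; cols <- ((v - 1) %/% 4) + 1
  member <- lapply(1:3, function(k) {
    sel <- assignment[cbind(rows, cols)] == k
    cbind(row = rows[sel], col = cols[sel])
  })
  structure(list(roi_id = "toy", k = 3L, centroids = matrix(0, 3, 15),
                 assignment = assignment, member_index = member,
                 counts = vapply(member, nrow, 0L),
                 scaler_stats = NULL, mean_pbp = NULL, seed = 0),
            class = "superpixel_set")
}

test_that("project_labels_to_mask distributes labels by membership", {
  sp <- make_sp_toy()
  m <- project_labels_to_mask(sp, c(3L, 1L, 2L))
  expect_equal(m$labels[1, 1], 3L)
  expect_equal(m$labels[1, 3], 1L)
  expect_equal(m$labels[4, 4], 2L)
  expect_equal(as.vector(table(m$labels)), c(4L, 8L, 4L))
  # constant labeling
  m2 <- project_labels_to_mask(sp, c(3L, 3L, 3L))
  expect_true(all(m2$labels == 3L))
  # artifact labels collapse to 0
  m3 <- project_labels_to_mask(sp, c(-1L, 1L, 1L))
  expect_equal(sum(m3$labels == 0L), 4L)
  expect_error(project_labels_to_mask(sp, c(1L, NA, 2L)), "missing label")
  expect_error(project_labels_to_mask(sp, 1L), "expected 3")
})

test_that("area proportions count pixels over the total ROI area", {
  lab <- matrix(0L, 10, 10)
  lab[1:5, 1:5] <- 5L
  mask <- structure(list(labels = lab, roi_id = "r"), class = "label_mask")
  expect_equal(area_proportion(mask, 5), 0.25)
  expect_equal(area_proportion(mask, 2), 0)
  full <- structure(list(labels = matrix(2L, 4, 4), roi_id = "r"),
                    class = "label_mask")
  expect_equal(area_proportion(full, 2), 1)
  expect_equal(area_proportion(full, 1), 0)
  # random mask equals brute-force counting; proportions + unassigned sum to 1
  set.seed(101)
  rnd <- matrix(sample(0:4, 144, replace = TRUE), 12, 12)
  rmask <- structure(list(labels = rnd, roi_id = "r"), class = "label_mask")
  props <- vapply(1:4, function(k) area_proportion(rmask, k), 0)
  expect_equal(props, vapply(1:4, function(k) sum(rnd == k) / 144, 0))
  expect_equal(sum(props) + sum(rnd == 0) / 144, 1)
  expect_error(area_proportion(rmask, 0), "cluster_id")
})

test_that("marker_auc equals brute-force pair counting", {
  expect_equal(marker_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)), 1)
  expect_equal(marker_auc(rep(4, 6), rep(c(FALSE, TRUE), each = 3)), 0.5)
  expect_equal(marker_auc(c(1, 2, 3, 2.5, 4, 5),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)), 8 / 9)
  set.seed(102)
  for (i in 1:20) {
    v <- sample(0:20, 30, replace = TRUE)  # with ties
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(marker_auc(v, pos), oracle_auc(v, pos))
  }
  expect_error(marker_auc(1:4, rep(TRUE, 4)), "positive and")
})

test_that("group_t_test behaves at the extremes", {
  set.seed(103)
  x <- rnorm(10)
  same <- group_t_test(x, x)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  big <- group_t_test(rnorm(4, 0, 1e-3), 1 + rnorm(4, 0, 1e-3))
  expect_lt(big$p_value, 1e-4)
  expect_error(group_t_test(1, c(1, 2)), "at least 2")
})

test_that("density heatmaps share extents and add over disjoint subsets", {
  set.seed(104)
  E <- matrix(rnorm(400), 200, 2)
  full <- density_heatmap(E, log_scale = TRUE)
  expect_equal(sum(full$counts), 200)
  expect_equal(full$log_counts, log10(full$counts + 1))
  sub <- seq_len(200) <= 120
  h1 <- density_heatmap(E, sub, extent = full$extent)
  h2 <- density_heatmap(E, !sub, extent = full$extent)
  expect_identical(h1$counts + h2$counts, full$counts)
  # all points in one bin of a fixed extent
  one <- density_heatmap(matrix(0.50123, 30, 2) +
                           1e-9 * matrix(rnorm(60), 30, 2),
                         extent = c(0, 1, 0, 1))
  expect_equal(max(one$counts), 30)
  expect_equal(sum(one$counts > 0), 1)
  expect_error(density_heatmap(E, rep(FALSE, 200)), "empty subset")
})

test_that("marker_report percentiles and contrasts are correct", {
  tab <- data.frame(
    roi_id = sprintf("r%02d", 1:20), patient_id = "p",
    group = rep(c("normal", "malignant"), each = 10),
    cluster_id = 1L,
    area_proportion = c(rep(0.3, 10), seq(0.1, 1, by = 0.1)))
  class(tab) <- c("marker_table", "data.frame")
  rep1 <- marker_report(tab, contrasts = list(c("normal", "malignant")))
  pct <- rep1$percentiles
  norm_row <- pct[pct$group == "normal", ]
  expect_equal(unlist(norm_row[c("p10", "p25", "p50", "p75", "p90")]),
               rep(0.3, 5), ignore_attr = TRUE)  # identical values
  mal_row <- pct[pct$group == "malignant", ]
  # values 0.1..1.0: type-7 linear interpolation computed by hand
  expect_equal(unlist(mal_row[c("p10", "p25", "p50", "p75", "p90")]),
               c(0.19, 0.325, 0.55, 0.775, 0.91), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(rep1$tests$auc,
               oracle_auc(tab$area_proportion, tab$group == "malignant"))
  expect_error(marker_report(tab, contrasts = list(c("normal", "nope"))),
               "present in the table")
})

test_that("adjusted_rand_index matches known values", {
  a <- c(1, 1, 1, 2, 2, 2)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 2, 1, 1, 1)), 1)  # relabeled
  set.seed(105)
  b <- sample(1:3, 600, replace = TRUE)
  r <- sample(1:3, 600, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(b, r)), 0.05)  # chance level
  # hand-checked small case
  x <- c(1, 1, 2, 2); y <- c(1, 1, 1, 2)
  # pairs: same-same = 1 (1,2), same-diff..., ARI = (1+1 - 7/3)/(0.5*(2+4)- ... )
  tab <- table(x, y)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2)); e <- si * sj / choose(4, 2)
  expect_equal(adjusted_rand_index(x, y), (sij - e) / ((si + sj) / 2 - e))
})
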