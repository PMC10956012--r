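# Independent brute-force oracles used across the suite. Each is a direct,
# unoptimized restatement of the definition, kept free of the package's
# computational path.

# dense 2D convolution with reflect padding (edge sample repeated)
oracle_conv_reflect <- function(img, kernel) {
  r <- (length(kernel) - 1) / 2
  k2 <- outer(kernel, kernel)
  h <- nrow(img); w <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in -r:r) for (b in -r:r)
      s <- s + k2[a + r + 1, b + r + 1] * img[reflect(i + a, h), reflect(j + b, w)]
    out[i, j] <- s
  }
  out
}

# term-by-term Canberra summation
oracle_canberra <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) s <- s + abs(x[i] - y[i]) / den
  }
  s
}

# O(n^3) single-linkage agglomeration; ties by lexicographic cluster pair
# (smallest member ids). Returns the sequence of merge heights and member
# partitions after each merge.
oracle_single_linkage <- function(P) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- min(D[clusters[[a]], clusters[[b]]])
      key_a <- min(clusters[[a]]); key_b <- min(clusters[[b]])
      if (d < best[1] - 1e-15 ||
          (abs(d - best[1]) <= 1e-15 &&
           (key_a < best[2] || (key_a == best[2] && key_b < best[3])))) {
        best <- c(d, key_a, key_b); ab <- c(a, b)
      }
    }
    heights[s] <- best[1]
    merges[[s]] <- sort(c(clusters[[ab[1]]], clusters[[ab[2]]]))
    clusters[[ab[1]]] <- c(clusters[[ab[1]]], clusters[[ab[2]]])
    clusters[[ab[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# pairwise AUC by explicit pair counting, ties one half
oracle_auc <- function(values, positive) {
  pos <- values[positive]; neg <- values[!positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# member partitions of an hclust-style merge matrix after each step
merge_partitions <- function(merge) {
  res <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    grab <- function(id) if (id < 0) -id else res[[id]]
    res[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
  }
  res
}

# small random valid Mueller image fixture
random_mueller_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  flat <- random_physical_mueller(h * w)
  mueller_image(polarmap:::mm_unflat(flat, h, w), roi_id = "fix")
}
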