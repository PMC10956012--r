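#' Mueller matrix image
#'
#' Container for a full 4x4 Mueller matrix image: an `H x W x 4 x 4` array of
#' real, dimensionless intensities plus acquisition metadata. Element (1,1)
#' (`m11`) is the unpolarized transmittance and must be positive on every
#' pixel that takes part in the analysis; pixels violating this (or holding
#' non-finite values) are recorded in a validity mask and excluded from all
#' downstream stages rather than clipped.
#'
#' @param elements numeric array of shape `H x W x 4 x 4` with `H, W >= 8`.
#' @param roi_id,patient_id,group identifying metadata strings.
#' @param pixel_size_um physical pixel pitch in micrometres (positive).
#' @param wavelength_nm illumination wavelength in nanometres (positive).
#' @param mask optional logical `H x W` matrix marking valid pixels; it is
#'   intersected with the finiteness / `m11 > 0` requirements.
#'
#' @return an object of class `mueller_image`.
#' @export
mueller_image <- function(elements, roi_id = "roi", patient_id = "patient",
                          group = "unknown", pixel_size_um = 1,
                          wavelength_nm = 633, mask = NULL) {
  d <- dim(elements)
  if (length(d) != 4L || d[3] != 4L || d[4] != 4L)
    stopf("elements must be an H x W x 4 x 4 array")
  if (d[1] < 8L || d[2] < 8L)
    stopf("image must be at least 8 x 8 pixels, got %d x %d", d[1], d[2])
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be positive")
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stopf("wavelength_nm must be positive")
  storage.mode(elements) <- "double"
  finite <- apply(is.finite(elements), c(1, 2), all)
  m11 <- elements[, , 1, 1]
  valid <- finite & !is.na(m11) & m11 > 0
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
      stopf("mask must be a logical H x W matrix")
    valid <- valid & mask
  }
  structure(
    list(elements = elements, mask = valid, roi_id = as.character(roi_id),
         patient_id = as.character(patient_id), group = as.character(group),
         pixel_size_um = pixel_size_um, wavelength_nm = wavelength_nm),
    class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$elements)
  cat(sprintf("<mueller_image> %s (%s / %s): %d x %d px, %d valid, %.2f um/px, %g nm\n",
              x$roi_id, x$patient_id, x$group, d[1], d[2], sum(x$mask),
              x$pixel_size_um, x$wavelength_nm))
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) dim(x$elements)[1:2]

# column order of the flat pixel-block representation: m11, m12, ..., m44
.mm_colperm <- as.vector(t(matrix(1:16, 4, 4)))

# Flatten the element array to an (H*W) x 16 block in row-major element
# order m11..m44. Pixel linear index follows R's column-major (H, W) order.
#' @noRd
mm_flat <- function(image) {
  d <- dim(image$elements)
  m <- image$elements
  dim(m) <- c(d[1] * d[2], 16L)
  m[, .mm_colperm, drop = FALSE]
}

#' @noRd
mm_unflat <- function(flat, h, w) {
  inv <- order(.mm_colperm)
  m <- flat[, inv, drop = FALSE]
  dim(m) <- c(h, w, 4L, 4L)
  m
}

#' Gaussian smoothing of a Mueller matrix image
#'
#' Convolves each of the 16 element planes independently with an isotropic
#' Gaussian kernel (radius `ceiling(3 * sigma_px)`), using reflect padding at
#' the borders so total plane sums are preserved. Metadata and the validity
#' mask are unchanged.
#'
#' @param image a [mueller_image()].
#' @param sigma_px kernel standard deviation in pixels (positive).
#' @return a smoothed `mueller_image`.
#' @export
gaussian_smooth <- function(image, sigma_px = 1) {
  stopifnot(inherits(image, "mueller_image"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || !is.finite(sigma_px) ||
      sigma_px <= 0)
    stopf("sigma_px must be a positive number")
  r <- ceiling(3 * sigma_px)
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  out <- image
  for (i in 1:4) for (j in 1:4)
    out$elements[, , i, j] <- conv_sep_reflect_cpp(image$elements[, , i, j], k)
  out
}

#' Mueller to coherency matrix (Cloude construction)
#'
#' Maps a real 4x4 Mueller matrix to its Hermitian 4x4 coherency matrix
#' `H = (1/4) * sum_ij m_ij (sigma_i x conj(sigma_j))` in the Pauli basis
#' `sigma_0 = I`, `sigma_1 = diag(1,-1)`, `sigma_2 = antidiag(1,1)`,
#' `sigma_3 = antidiag(-i, i)`. The Mueller matrix is physically realizable
#' iff `H` is positive semi-definite; `trace(H) = m11`.
#'
#' @param M real 4x4 matrix with finite entries.
#' @return complex Hermitian 4x4 matrix.
#' @export
mueller_to_coherency <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == 4L) || !all(is.finite(M)))
    stopf("M must be a finite real 4x4 matrix")
  B <- pauli_kron_basis()
  H <- matrix(0 + 0i, 4, 4)
  for (c in 1:16) H <- H + 0.25 * M[.mm_basis_idx[c, 1], .mm_basis_idx[c, 2]] * B[[c]]
  (H + Conj(t(H))) / 2
}

#' Coherency to Mueller matrix
#'
#' Exact linear inverse of [mueller_to_coherency()]:
#' `m_ij = Re trace(H (sigma_i x conj(sigma_j)))`.
#'
#' @param H complex 4x4 matrix, Hermitian within `tol`.
#' @param tol Hermiticity tolerance (largest absolute deviation).
#' @return real 4x4 Mueller matrix.
#' @export
coherency_to_mueller <- function(H, tol = 1e-8) {
  if (!is.matrix(H) || !all(dim(H) == 4L))
    stopf("H must be a 4x4 matrix")
  if (max(Mod(H - Conj(t(H)))) > tol)
    stopf("H is not Hermitian within tolerance %g", tol)
  B <- pauli_kron_basis()
  M <- matrix(0, 4, 4)
  for (c in 1:16) {
    # trace(H %*% B) with B Hermitian
    M[.mm_basis_idx[c, 1], .mm_basis_idx[c, 2]] <- Re(sum(H * t(B[[c]])))
  }
  M
}

.mm_basis_idx <- cbind(rep(1:4, each = 4), rep(1:4, times = 4))

#' @noRd
pauli_kron_basis <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s0 <- diag(2)
    s1 <- diag(c(1, -1))
    s2 <- matrix(c(0, 1, 1, 0), 2, 2)
    s3 <- matrix(c(0, 1i, -1i, 0), 2, 2)  # column-major: antidiag(-i, i)
    sig <- list(s0, s1, s2, s3)
    B <- vector("list", 16)
    c <- 0
    for (i in 1:4) for (j in 1:4) {
      c <- c + 1
      B[[c]] <- kronecker(sig[[i]], Conj(sig[[j]]))
    }
    cache <<- B
    B
  }
})

#' Cloude physicality filter
#'
#' Removes the physically unrealizable part of every pixel's Mueller matrix:
#' the coherency matrix is eigendecomposed, eigenvalues below `eig_floor` are
#' clamped up to `eig_floor`, the matrix is reconstructed, its trace rescaled
#' to the original `m11`, and mapped back to Mueller form. Pixels that are
#' already physical are returned bit-unchanged; pixels with `m11 <= 0` are
#' marked invalid and left unfiltered. The operation is idempotent.
#'
#' @param image a [mueller_image()].
#' @param eig_floor eigenvalue clamp floor (default 0).
#' @return a filtered `mueller_image` with attribute `"min_eig"` holding the
#'   per-pixel pre-filter minimum coherency eigenvalue (H x W matrix).
#' @export
cloude_filter <- function(image, eig_floor = 0) {
  stopifnot(inherits(image, "mueller_image"))
  d <- dim(image$elements)
  flat <- mm_flat(image)
  res <- cloude_filter_block_cpp(flat, eig_floor)
  out <- image
  out$elements <- mm_unflat(res$M, d[1], d[2])
  out$mask <- image$mask & matrix(res$valid, d[1], d[2])
  attr(out, "min_eig") <- matrix(res$min_eig, d[1], d[2])
  out
}

#' Cloude filter of a single Mueller matrix (reference implementation)
#'
#' Pure-R eigenvalue clamp-and-reconstruct used as the per-matrix reference
#' for [cloude_filter()]; the image path is checked against it in the tests.
#'
#' @inheritParams mueller_to_coherency
#' @param eig_floor eigenvalue clamp floor.
#' @return real 4x4 Mueller matrix.
#' @export
cloude_filter_matrix <- function(M, eig_floor = 0) {
  H <- mueller_to_coherency(M)
  e <- eigen(H, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(M)
  lam <- pmax(e$values, eig_floor)
  H2 <- e$vectors %*% diag(lam) %*% Conj(t(e$vectors))
  tr <- Re(sum(diag(H2)))
  if (tr > 0) H2 <- H2 * (M[1, 1] / tr)
  coherency_to_mueller(H2, tol = 1e-6)
}

.feature_names_15 <- {
  nm <- as.vector(t(outer(1:4, 1:4, function(i, j) sprintf("m%d%d", i, j))))
  nm[nm != "m11"]
}

#' M11-normalized Mueller element features
#'
#' Builds the 15-channel feature image of off-`m11` Mueller elements divided
#' by `m11`, in fixed row-major order `m12, m13, m14, m21, ..., m44`. Pixels
#' with `m11 <= 0` outside the current mask trigger a warning and are masked.
#' The features are invariant to any positive global gain of the image.
#'
#' @param image a [mueller_image()].
#' @return an object of class `feature_image`: list with `features`
#'   (`H x W x 15`), `names`, `mask`, and `roi_id`.
#' @export
normalized_elements <- function(image) {
  stopifnot(inherits(image, "mueller_image"))
  d <- dim(image$elements)
  m11 <- image$elements[, , 1, 1]
  bad <- image$mask & !(m11 > 0)
  if (any(bad)) {
    warnf("%d pixels with m11 <= 0 masked in normalized_elements", sum(bad))
  }
  mask <- image$mask & m11 > 0
  feat <- array(NA_real_, c(d[1], d[2], 15L))
  c <- 0L
  for (i in 1:4) for (j in 1:4) {
    if (i == 1 && j == 1) next
    c <- c + 1L
    feat[, , c] <- image$elements[, , i, j] / m11
  }
  structure(list(features = feat, names = .feature_names_15, mask = mask,
                 roi_id = image$roi_id),
            class = "feature_image")
}
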