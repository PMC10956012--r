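#' Lu-Chipman polar decomposition parameters
#'
#' Decomposes a Mueller matrix as the product `M = M_Delta M_R M_D`
#' (depolarizer, retarder, diattenuator) and returns the scalar parameters:
#' diattenuation `D = sqrt(m12^2 + m13^2 + m14^2) / m11`, depolarization
#' `Delta = 1 - |tr(m_Delta)| / 3`, total retardance
#' `R_tot = acos(tr(M_R)/2 - 1)`, linear retardance `delta_lin`, optical
#' rotation `psi`, and the retarder fast-axis orientation `theta` (radians,
#' reported mod pi, measured counterclockwise from the horizontal axis).
#' The 3x3 depolarizer block is recovered as the signed matrix square root
#' of `m' m'^T` (sign from `det(m')`).
#'
#' For `D >= 1 - 1e-9` the diattenuator is non-invertible: `D` is reported
#' as 1 and the remaining parameters as `NA` (masked), without raising.
#'
#' @param M real 4x4 Mueller matrix with `m11 > 0`.
#' @return named list with entries `D`, `Delta`, `R_tot`, `delta_lin`,
#'   `psi`, `theta` (class `mmpd_params`).
#' @export
mmpd <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == 4L) || !all(is.finite(M)))
    stopf("M must be a finite real 4x4 matrix")
  if (M[1, 1] <= 0) stopf("mmpd requires m11 > 0")
  v <- mmpd_block_cpp(matrix(t(M), nrow = 1))[1, ]
  structure(list(D = v[1], Delta = v[2], R_tot = v[3], delta_lin = v[4],
                 psi = v[5], theta = v[6]),
            class = "mmpd_params")
}

.mmt_from_norm <- function(m22, m33, m23, m32) {
  b <- (m22 + m33) / 2
  t1 <- sqrt((m22 - m33)^2 + (m23 + m32)^2) / 2
  den <- b^2 + t1^2
  # |b| keeps A in [0, 1] for compositions where m22 + m33 dips below 0;
  # identical to 2 b t1 / (b^2 + t1^2) on the usual b >= 0 domain
  A <- ifelse(den > 0, 2 * abs(b) * t1 / den, 0)
  alpha <- 0.25 * atan2(m23 + m32, m22 - m33)
  list(b = b, t1 = t1, A = A, alpha = alpha)
}

#' Mueller matrix transformation parameters
#'
#' Orientation-insensitive combinations of the central (m11-normalized)
#' Mueller elements: isotropy `b = (m22 + m33)/2`, anisotropy magnitude
#' `t1 = sqrt((m22 - m33)^2 + (m23 + m32)^2)/2`, normalized anisotropy
#' `A = 2 b t1 / (b^2 + t1^2)` (0 when `b = t1 = 0`), and the anisotropy
#' orientation `alpha = atan2(m23 + m32, m22 - m33)/4`. Note that the pair
#' `(m22 - m33, m23 + m32)` turns at four times the sample rotation angle,
#' so `alpha` is an orientation defined modulo `pi/2`.
#'
#' @param M real 4x4 Mueller matrix with `m11 > 0` (elements are normalized
#'   by `m11` before evaluation).
#' @return named list with entries `b`, `t1`, `A`, `alpha` (class
#'   `mmt_params`).
#' @export
mmt <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == 4L) || !all(is.finite(M)))
    stopf("M must be a finite real 4x4 matrix")
  if (M[1, 1] <= 0) stopf("mmt requires m11 > 0")
  Mn <- M / M[1, 1]
  out <- .mmt_from_norm(Mn[2, 2], Mn[3, 3], Mn[2, 3], Mn[3, 2])
  structure(out, class = "mmt_params")
}

#' Rotation-invariant Mueller element combinations
#'
#' Scalar element combinations unchanged under in-plane rotation of the
#' sample (`M -> R(theta) M R(-theta)`): the linear diattenuation proxy
#' `D_L = sqrt(m12^2 + m13^2)/m11`, linear polarizance
#' `P_L = sqrt(m21^2 + m31^2)/m11`, the circular-linear coupling magnitudes
#' `r_L = sqrt(m24^2 + m34^2)/m11` and `q_L = sqrt(m42^2 + m43^2)/m11`, and
#' `m44/m11`.
#'
#' @inheritParams mmt
#' @return named list with entries `D_L`, `P_L`, `r_L`, `q_L`, `m44n`.
#' @export
rotation_invariants <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == 4L) || !all(is.finite(M)))
    stopf("M must be a finite real 4x4 matrix")
  if (M[1, 1] <= 0) stopf("rotation_invariants requires m11 > 0")
  Mn <- M / M[1, 1]
  list(D_L = sqrt(Mn[1, 2]^2 + Mn[1, 3]^2),
       P_L = sqrt(Mn[2, 1]^2 + Mn[3, 1]^2),
       r_L = sqrt(Mn[2, 4]^2 + Mn[3, 4]^2),
       q_L = sqrt(Mn[4, 2]^2 + Mn[4, 3]^2),
       m44n = Mn[4, 4])
}

.pbp_mmpd_names <- c("D", "Delta", "R_tot", "delta_lin", "psi", "theta")
.pbp_mmt_names <- c("b", "t1", "A", "alpha")
.pbp_invariant_names <- c("D_L", "P_L", "r_L", "q_L", "m44n")

#' Default polarization basis parameter set
#'
#' The default registry: the six Lu-Chipman parameters, the four
#' transformation parameters, and the five rotation-invariant element
#' combinations. Additional parameters can be plugged in with
#' [register_pbp()].
#'
#' @return character vector of parameter names.
#' @export
pbp_default_set <- function() {
  c(.pbp_mmpd_names, .pbp_mmt_names, .pbp_invariant_names,
    ls(.pbp_custom_registry))
}

.pbp_custom_registry <- new.env(parent = emptyenv())

#' Register a custom polarization basis parameter
#'
#' @param name parameter name (must not clash with a built-in name).
#' @param fun function taking an `n x 16` matrix of m11-normalized Mueller
#'   elements in row-major order `m11..m44` (`m11` column is all ones) and
#'   returning a numeric vector of length `n`.
#' @return invisibly, the registered name.
#' @export
register_pbp <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  builtin <- c(.pbp_mmpd_names, .pbp_mmt_names, .pbp_invariant_names)
  if (name %in% builtin) stopf("'%s' is a built-in parameter", name)
  assign(name, fun, envir = .pbp_custom_registry)
  invisible(name)
}

#' Per-pixel polarization basis parameter image
#'
#' Evaluates the selected polarization basis parameters on every valid pixel
#' of a Mueller matrix image. Lu-Chipman parameters are computed by the same
#' decomposition as [mmpd()] (vectorized over pixels); transformation and
#' invariant parameters are closed forms of the m11-normalized elements.
#'
#' @param image a [mueller_image()].
#' @param selection character vector of parameter names (no duplicates);
#'   defaults to the full registry, see [pbp_default_set()].
#' @return object of class `pbp_image`: list with `values` (`H x W x P`),
#'   `names`, `provenance`, `mask`, `roi_id`.
#' @export
pbp_image <- function(image, selection = pbp_default_set()) {
  stopifnot(inherits(image, "mueller_image"))
  if (length(selection) == 0L) stopf("selection must be non-empty")
  if (anyDuplicated(selection))
    stopf("duplicated parameter names in selection: %s",
          paste(unique(selection[duplicated(selection)]), collapse = ", "))
  known <- pbp_default_set()
  unknown <- setdiff(selection, known)
  if (length(unknown))
    stopf("unknown parameter(s) %s; known parameters: %s",
          paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  d <- dim(image$elements)
  flat <- mm_flat(image)
  m11 <- flat[, 1]
  mask <- image$mask & matrix(m11 > 0, d[1], d[2])
  vidx <- which(as.vector(mask))
  n <- length(vidx)
  norm <- flat[vidx, , drop = FALSE] / m11[vidx]

  cols <- matrix(NA_real_, n, length(selection))
  need_mmpd <- any(selection %in% .pbp_mmpd_names)
  if (need_mmpd) mp <- mmpd_block_cpp(flat[vidx, , drop = FALSE])
  need_mmt <- any(selection %in% .pbp_mmt_names)
  if (need_mmt) {
    # row-major columns: m22 -> 6, m23 -> 7, m32 -> 10, m33 -> 11
    mt <- .mmt_from_norm(norm[, 6], norm[, 11], norm[, 7], norm[, 10])
  }
  for (ci in seq_along(selection)) {
    p <- selection[ci]
    cols[, ci] <-
      if (p %in% .pbp_mmpd_names) mp[, match(p, .pbp_mmpd_names)]
      else if (p %in% .pbp_mmt_names) mt[[p]]
      else if (p == "D_L") sqrt(norm[, 2]^2 + norm[, 3]^2)
      else if (p == "P_L") sqrt(norm[, 5]^2 + norm[, 9]^2)
      else if (p == "r_L") sqrt(norm[, 8]^2 + norm[, 12]^2)
      else if (p == "q_L") sqrt(norm[, 14]^2 + norm[, 15]^2)
      else if (p == "m44n") norm[, 16]
      else get(p, envir = .pbp_custom_registry)(norm)
  }
  # pixels where a parameter is undefined (e.g. D >= 1) are masked out
  undef <- !complete.cases(cols)
  if (any(undef)) {
    mask[vidx[undef]] <- FALSE
    vidx <- vidx[!undef]
    cols <- cols[!undef, , drop = FALSE]
  }
  values <- array(NA_real_, c(d[1], d[2], length(selection)))
  for (ci in seq_along(selection)) {
    plane <- rep(NA_real_, d[1] * d[2])
    plane[vidx] <- cols[, ci]
    values[, , ci] <- plane
  }
  prov <- ifelse(selection %in% .pbp_mmpd_names, "lu_chipman",
          ifelse(selection %in% .pbp_mmt_names, "mm_transformation",
          ifelse(selection %in% .pbp_invariant_names, "rotation_invariant",
                 "custom")))
  structure(list(values = values, names = selection,
                 provenance = setNames(prov, selection),
                 mask = mask, roi_id = image$roi_id),
            class = "pbp_image")
}
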