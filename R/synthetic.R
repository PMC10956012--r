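#' Canonical polarimetric elements
#'
#' Closed-form textbook Mueller matrices, normalized to `m11 = 1`:
#' * `depolarizer`: `diag(1, a, b, c)` with `a, b, c` in `(0, 1]` passed as
#'   `params = list(a, b, c)` (an isotropic depolarizer has `a = b = c`);
#' * `linear_retarder`: retardance `delta` (rad) with fast axis at `theta`;
#' * `rotator`: optical rotation `psi` (rad), i.e. a Stokes rotation by
#'   `2 * psi`;
#' * `diattenuator`: diattenuation `D` in `[0, 1]` along axis `theta`.
#'
#' @param kind one of `"depolarizer"`, `"linear_retarder"`, `"rotator"`,
#'   `"diattenuator"`.
#' @param params named list of parameters, see above.
#' @return real 4x4 Mueller matrix.
#' @export
canonical_mueller <- function(kind, params = list()) {
  kind <- match.arg(kind, c("depolarizer", "linear_retarder", "rotator",
                            "diattenuator"))
  p <- params
  switch(kind,
    depolarizer = {
      a <- p$a %||% 1; b <- p$b %||% a; c <- p$c %||% b
      if (any(c(a, b, c) <= 0) || any(c(a, b, c) > 1))
        stopf("depolarizer diagonal must lie in (0, 1]")
      diag(c(1, a, b, c))
    },
    linear_retarder = {
      delta <- p$delta %||% 0
      theta <- p$theta %||% 0
      if (!is.finite(delta) || !is.finite(theta)) stopf("invalid retarder parameters")
      c2 <- cos(2 * theta); s2 <- sin(2 * theta)
      cd <- cos(delta); sd_ <- sin(delta)
      rbind(c(1, 0, 0, 0),
            c(0, c2^2 + s2^2 * cd, s2 * c2 * (1 - cd), -s2 * sd_),
            c(0, s2 * c2 * (1 - cd), s2^2 + c2^2 * cd, c2 * sd_),
            c(0, s2 * sd_, -c2 * sd_, cd))
    },
    rotator = {
      psi <- p$psi %||% 0
      c2 <- cos(2 * psi); s2 <- sin(2 * psi)
      rbind(c(1, 0, 0, 0),
            c(0, c2, -s2, 0),
            c(0, s2, c2, 0),
            c(0, 0, 0, 1))
    },
    diattenuator = {
      D <- p$D %||% 0
      theta <- p$theta %||% 0
      if (D < 0 || D > 1) stopf("diattenuation must lie in [0, 1]")
      q <- sqrt(1 - D^2)
      c2 <- cos(2 * theta); s2 <- sin(2 * theta)
      rbind(c(1, D * c2, D * s2, 0),
            c(D * c2, c2^2 + q * s2^2, (1 - q) * s2 * c2, 0),
            c(D * s2, (1 - q) * s2 * c2, s2^2 + q * c2^2, 0),
            c(0, 0, 0, q))
    })
}

#' In-plane rotation of a Mueller matrix
#'
#' Returns `R(theta) M R(-theta)` where `R` is the 4x4 Stokes rotation with
#' the `cos(2 theta)/sin(2 theta)` block acting on the linear components.
#' Rotation by `theta` then `-theta` restores `M`, and rotations compose
#' additively.
#'
#' @param M real 4x4 matrix.
#' @param theta rotation angle in radians (counterclockwise).
#' @return rotated 4x4 matrix.
#' @export
rotate_mueller <- function(M, theta) {
  if (!is.matrix(M) || !all(dim(M) == 4L)) stopf("M must be 4x4")
  R <- canonical_mueller("rotator", list(psi = theta))
  Rm <- canonical_mueller("rotator", list(psi = -theta))
  R %*% M %*% Rm
}

#' Make a Mueller matrix non-physical by a stated amount
#'
#' Subtracts `eps` from the smallest coherency eigenvalue and reconstructs
#' the Mueller matrix, so that the output's smallest coherency eigenvalue is
#' exactly the original one minus `eps`. Used as the fixture generator for
#' [cloude_filter()].
#'
#' @param M real 4x4 Mueller matrix.
#' @param eps positive eigenvalue shift.
#' @return real 4x4 matrix (non-physical whenever the original smallest
#'   eigenvalue is below `eps`).
#' @export
perturb_nonphysical <- function(M, eps) {
  if (!is.numeric(eps) || eps <= 0) stopf("eps must be positive")
  H <- mueller_to_coherency(M)
  e <- eigen(H, symmetric = TRUE)
  lam <- e$values
  lam[which.min(lam)] <- min(lam) - eps
  H2 <- e$vectors %*% diag(lam) %*% Conj(t(e$vectors))
  coherency_to_mueller(H2, tol = 1e-6)
}

#' Tissue class specification for phantom generation
#'
#' @param name class name.
#' @param depol length-3 depolarizer diagonal `(a, b, c)` in `(0, 1]`.
#' @param delta linear retardance in radians.
#' @param theta fast-axis orientation in radians, or `"textured"` for a
#'   smoothly varying orientation field covering `[0, pi)`.
#' @param psi optical rotation in radians (circular retardance; the class
#'   retarder is the product of a rotator and a linear retarder).
#' @param D diattenuation in `[0, 1)`.
#' @param jitter_sd named list of Gaussian jitter standard deviations for
#'   `depol`, `delta`, `psi`, `D` (values clipped back to valid ranges
#'   after jittering).
#' @param abundance relative class weight (positive).
#' @return a `class_spec` list.
#' @export
class_spec <- function(name, depol = c(1, 1, 1), delta = 0, theta = 0,
                       psi = 0, D = 0,
                       jitter_sd = list(depol = 0, delta = 0, psi = 0, D = 0),
                       abundance = 1) {
  stopifnot(length(depol) == 3, all(depol > 0), all(depol <= 1),
            D >= 0, D < 1, abundance > 0)
  structure(list(name = name, depol = depol, delta = delta, theta = theta,
                 psi = psi, D = D,
                 jitter_sd = modifyList(list(depol = 0, delta = 0, psi = 0,
                                             D = 0), jitter_sd),
                 abundance = abundance),
            class = "class_spec")
}

#' Default six-class liver-like phantom specification
#'
#' Six generative tissue classes mirroring the microstructural families the
#' atlas is expected to separate: two depolarizers of moderate and strong
#' depolarization (normal and lesion nucleus-like), two weak retarders
#' differing in depolarization and anisotropy (cytoplasm-like), one strong
#' retarder with textured orientation (collagen-fiber-like), and one
#' strongly diattenuating retarder (fibrocyte-like). The parameter contrasts
#' are chosen so that class-mean polarization-parameter vectors are Canberra
#' separable: every pairwise between-class distance exceeds three times the
#' mean within-class spread at the default noise level.
#'
#' @return list of six [class_spec()] objects.
#' @export
liver6_classes <- function() {
  j <- list(depol = 0.015, delta = 0.02, psi = 0.01, D = 0.008)
  list(
    class_spec("nucleus_normal", depol = c(0.50, 0.44, 0.38), delta = 0.15,
               psi = 0.10, theta = 0.4, D = 0.02, jitter_sd = j,
               abundance = 0.20),
    class_spec("nucleus_lesion", depol = c(0.13, 0.10, 0.08), delta = 0.60,
               psi = 0.30, theta = 0.4, D = 0.20, jitter_sd = j,
               abundance = 0.15),
    class_spec("cytoplasm_a", depol = c(0.95, 0.91, 0.87), delta = 0.30,
               psi = 0.05, theta = 0.4, D = 0.06, jitter_sd = j,
               abundance = 0.25),
    class_spec("cytoplasm_b", depol = c(0.78, 0.72, 0.66), delta = 1.20,
               psi = 0.18, theta = 0.4, D = 0.12, jitter_sd = j,
               abundance = 0.15),
    class_spec("fiber", depol = c(0.94, 0.90, 0.86), delta = 2.00,
               psi = 0.08, theta = "textured", D = 0.05, jitter_sd = j,
               abundance = 0.15),
    class_spec("fibrocyte", depol = c(0.58, 0.49, 0.42), delta = 0.50,
               psi = 0.25, theta = 0.4, D = 0.62, jitter_sd = j,
               abundance = 0.10))
}

# Smoothed standardized Gaussian random field.
#' @noRd
smooth_field <- function(h, w, scale_px) {
  f <- matrix(rnorm(h * w), h, w)
  r <- ceiling(3 * scale_px)
  k <- exp(-((-r:r)^2) / (2 * scale_px^2))
  k <- k / sum(k)
  f <- conv_sep_reflect_cpp(f, k)
  (f - mean(f)) / pop_sd(f)
}

# Contiguous class map with abundances calibrated by iterative offset
# adjustment of per-class smoothed fields.
#' @noRd
class_map_fields <- function(h, w, weights, blob_scale_px) {
  K <- length(weights)
  weights <- weights / sum(weights)
  fields <- vapply(seq_len(K), function(i) smooth_field(h, w, blob_scale_px),
                   matrix(0, h, w))
  F <- matrix(fields, h * w, K)
  off <- rep(0, K)
  best_err <- Inf
  best_off <- off
  for (it in 1:300) {
    lab <- max.col(sweep(F, 2, off, "+"), ties.method = "first")
    err <- max(abs(weights - tabulate(lab, K) / (h * w)))
    if (err < best_err) {
      best_err <- err
      best_off <- off
      if (err < 5e-4) break
    }
    off <- off + 0.5 * (weights - tabulate(lab, K) / (h * w))
  }
  lab <- max.col(sweep(F, 2, best_off, "+"), ties.method = "first")
  matrix(lab, h, w)
}

# Multiply two stacks of 4x4 matrices stored as n x 16 row-major blocks.
#' @noRd
mm_multiply_stack <- function(A, B) {
  out <- matrix(0, nrow(A), 16)
  for (i in 1:4) for (j in 1:4) {
    acc <- 0
    for (k in 1:4) acc <- acc + A[, (i - 1) * 4 + k] * B[, (k - 1) * 4 + j]
    out[, (i - 1) * 4 + j] <- acc
  }
  out
}

# Vectorized canonical matrices over parameter vectors, n x 16 row-major.
#' @noRd
stack_depolarizer <- function(a, b, c) {
  n <- length(a)
  out <- matrix(0, n, 16)
  out[, 1] <- 1; out[, 6] <- a; out[, 11] <- b; out[, 16] <- c
  out
}

#' @noRd
stack_retarder <- function(delta, theta) {
  n <- max(length(delta), length(theta))
  delta <- rep_len(delta, n); theta <- rep_len(theta, n)
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  cd <- cos(delta); sd_ <- sin(delta)
  out <- matrix(0, n, 16)
  out[, 1] <- 1
  out[, 6] <- c2^2 + s2^2 * cd
  out[, 7] <- s2 * c2 * (1 - cd)
  out[, 8] <- -s2 * sd_
  out[, 10] <- s2 * c2 * (1 - cd)
  out[, 11] <- s2^2 + c2^2 * cd
  out[, 12] <- c2 * sd_
  out[, 14] <- s2 * sd_
  out[, 15] <- -c2 * sd_
  out[, 16] <- cd
  out
}

#' @noRd
stack_rotator <- function(psi) {
  n <- length(psi)
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  out <- matrix(0, n, 16)
  out[, 1] <- 1
  out[, 6] <- c2; out[, 7] <- -s2
  out[, 10] <- s2; out[, 11] <- c2
  out[, 16] <- 1
  out
}

#' @noRd
stack_diattenuator <- function(D, theta) {
  n <- max(length(D), length(theta))
  D <- rep_len(D, n); theta <- rep_len(theta, n)
  q <- sqrt(pmax(0, 1 - D^2))
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  out <- matrix(0, n, 16)
  out[, 1] <- 1
  out[, 2] <- D * c2; out[, 3] <- D * s2
  out[, 5] <- D * c2; out[, 9] <- D * s2
  out[, 6] <- c2^2 + q * s2^2
  out[, 7] <- (1 - q) * s2 * c2
  out[, 10] <- (1 - q) * s2 * c2
  out[, 11] <- s2^2 + q * c2^2
  out[, 16] <- q
  out
}

#' Generate a Mueller matrix phantom with known class structure
#'
#' Builds a synthetic region of interest: a contiguous ground-truth class
#' map (argmax of per-class Gaussian-smoothed random fields with abundances
#' calibrated to the specified weights), and per pixel the Mueller matrix
#' `M = M_depol . M_retarder(theta(x, y)) . M_diattenuator` with per-pixel
#' Gaussian parameter jitter, additive Gaussian measurement noise of
#' standard deviation `noise_sd` on all 16 elements, and `m11` renormalized
#' to 1. Classes with `theta = "textured"` draw their orientation from a
#' smooth random field scaled to `[0, pi)`, so orientation-sensitive raw
#' elements vary across such a region while rotation-invariant parameters
#' stay class-stable. Deterministic given `seed`.
#'
#' @param class_specs list of [class_spec()]; default [liver6_classes()].
#' @param height,width phantom size in pixels (default 256 x 256).
#' @param blob_scale_px Gaussian scale of the class-region fields (px).
#' @param noise_sd additive element noise standard deviation; the default
#'   0.01 reflects a well-calibrated instrument, preset `"rmse02"` (0.02)
#'   matches a typical reported measurement RMSE.
#' @param seed integer seed.
#' @param roi_id,patient_id,group metadata for the embedded
#'   [mueller_image()].
#' @return object of class `phantom`: list with `image` (a
#'   `mueller_image`), `class_map` (integer `H x W`), `class_names`,
#'   `patient_id`, `seed`.
#' @export
generate_phantom <- function(class_specs = liver6_classes(), height = 256,
                             width = 256, blob_scale_px = 24,
                             noise_sd = 0.01, seed = 0, roi_id = "phantom",
                             patient_id = "synthetic", group = "phantom") {
  if (length(class_specs) < 1) stopf("at least one class required")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  ab <- vapply(class_specs, function(s) s$abundance, 0)
  if (any(!is.finite(ab)) || any(ab <= 0)) stopf("abundances must be positive")
  with_seed(seed, {
    K <- length(class_specs)
    cmap <- if (K == 1) matrix(1L, height, width)
            else class_map_fields(height, width, ab, blob_scale_px)
    n <- height * width
    lab <- as.vector(cmap)
    theta_field <- (atan2(smooth_field(height, width, blob_scale_px / 2),
                          smooth_field(height, width, blob_scale_px / 2)) +
                    pi) / 2  # smooth in [0, pi)
    flat <- matrix(0, n, 16)
    for (k in seq_len(K)) {
      s <- class_specs[[k]]
      idx <- which(lab == k)
      if (!length(idx)) next
      m <- length(idx)
      jit <- s$jitter_sd
      # parameter jitter is drawn from smooth Gaussian random fields (unit
      # marginal variance, scaled by jitter_sd): tissue-like spatially
      # correlated variation rather than white pixel noise
      jf <- function(sd_) {
        if (sd_ <= 0) return(rep(0, m))
        sd_ * as.vector(smooth_field(height, width, blob_scale_px / 2))[idx]
      }
      dj <- jf(jit$depol)
      a <- pmin(1, pmax(1e-3, s$depol[1] + dj))
      b <- pmin(1, pmax(1e-3, s$depol[2] + dj))
      cc <- pmin(1, pmax(1e-3, s$depol[3] + dj))
      # keep diag(1, a, b, c) inside the physical cone
      # (1 +/- a -/+ b -/+ c >= 0): shrink jointly where jitter left it
      worst <- pmax(b + cc - a, a + cc - b, a + b - cc, 1e-12)
      shrink <- pmin(1, (1 - 1e-9) / worst)
      a <- a * shrink; b <- b * shrink; cc <- cc * shrink
      delta <- pmax(0, s$delta + jf(jit$delta))
      psi <- s$psi + jf(jit$psi)
      D <- pmin(1 - 1e-6, pmax(0, s$D + jf(jit$D)))
      th <- if (identical(s$theta, "textured")) as.vector(theta_field)[idx]
            else rep_len(s$theta, m)
      # retarder = rotator(psi) . linear retarder(delta, theta)
      Mk <- mm_multiply_stack(
        mm_multiply_stack(stack_depolarizer(a, b, cc),
                          mm_multiply_stack(stack_rotator(psi),
                                            stack_retarder(delta, th))),
        stack_diattenuator(D, th))
      flat[idx, ] <- Mk
    }
    if (noise_sd > 0)
      flat <- flat + matrix(rnorm(n * 16, 0, noise_sd), n, 16)
    flat <- flat / flat[, 1]  # renormalize m11 to 1
    img <- mueller_image(mm_unflat(flat, height, width), roi_id = roi_id,
                         patient_id = patient_id, group = group)
    structure(list(image = img, class_map = cmap,
                   class_names = vapply(class_specs, function(s) s$name, ""),
                   patient_id = patient_id, seed = seed),
              class = "phantom")
  })
}

#' Random physical Mueller matrices
#'
#' Draws matrices from the default phantom classes with parameter jitter;
#' all outputs are products of physical elements and therefore pass the
#' Cloude physicality test. Used for property tests and physicality audits.
#'
#' @param n number of matrices.
#' @param seed integer seed (optional when the caller manages the RNG).
#' @return `n x 16` matrix of row-major Mueller elements (`m11 = 1`).
#' @export
random_physical_mueller <- function(n, seed = NULL) {
  with_seed(seed, {
    # a diagonal depolarizer diag(1, a, b, c) is physical iff
    # 1 + a - b - c, 1 - a + b - c and 1 - a - b + c are all non-negative;
    # rejection-sample the diagonal until the conditions hold
    a <- runif(n, 0.2, 1); b <- runif(n, 0.2, 1); cc <- runif(n, 0.2, 1)
    repeat {
      bad <- (1 + a - b - cc < 0) | (1 - a + b - cc < 0) | (1 - a - b + cc < 0)
      if (!any(bad)) break
      a[bad] <- runif(sum(bad), 0.2, 1)
      b[bad] <- runif(sum(bad), 0.2, 1)
      cc[bad] <- runif(sum(bad), 0.2, 1)
    }
    delta <- runif(n, 0, pi)
    th <- runif(n, 0, pi)
    D <- runif(n, 0, 0.6)
    mm_multiply_stack(
      mm_multiply_stack(stack_depolarizer(a, b, cc),
                        stack_retarder(delta, th)),
      stack_diattenuator(D, runif(n, 0, pi)))
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_rois` phantom regions of interest (RDS Mueller dialect plus
#' class maps) and a manifest CSV with columns `roi_id, patient_id, group,
#' path`. ROIs are assigned round-robin to `n_patients` synthetic patients.
#' Per-group abundance overrides allow building designed contrasts (for
#' example enriching one class in a "malignant" group).
#'
#' @param dir output directory (created if needed).
#' @param n_rois number of regions of interest.
#' @param seeds integer seeds, one per ROI (default `0:(n_rois-1)`).
#' @param n_patients number of synthetic patients.
#' @param class_specs list of [class_spec()].
#' @param groups character vector recycled over ROIs (default "phantom").
#' @param group_abundances optional named list: group -> numeric abundance
#'   vector (length = number of classes) overriding the spec abundances.
#' @param height,width,blob_scale_px,noise_sd passed to [generate_phantom()].
#' @return the manifest data.frame (invisibly written to
#'   `file.path(dir, "manifest.csv")`), with an extra `class_map_path`
#'   column.
#' @export
synth_dataset <- function(dir, n_rois = 20, seeds = seq_len(n_rois) - 1L,
                          n_patients = 12, class_specs = liver6_classes(),
                          groups = "phantom", group_abundances = NULL,
                          height = 256, width = 256, blob_scale_px = 24,
                          noise_sd = 0.01) {
  stopifnot(length(seeds) == n_rois)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- rep_len(groups, n_rois)
  rows <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    specs <- class_specs
    g <- groups[i]
    if (!is.null(group_abundances) && !is.null(group_abundances[[g]])) {
      ab <- group_abundances[[g]]
      stopifnot(length(ab) == length(specs))
      for (k in seq_along(specs)) specs[[k]]$abundance <- ab[k]
    }
    pid <- sprintf("P%02d", ((i - 1L) %% n_patients) + 1L)
    rid <- sprintf("roi%03d", i)
    ph <- generate_phantom(specs, height = height, width = width,
                           blob_scale_px = blob_scale_px, noise_sd = noise_sd,
                           seed = seeds[i], roi_id = rid, patient_id = pid,
                           group = g)
    path <- file.path(dir, paste0(rid, ".rds"))
    cpath <- file.path(dir, paste0(rid, "_classmap.rds"))
    saveRDS(ph$image, path)
    saveRDS(ph$class_map, cpath)
    rows[[i]] <- data.frame(roi_id = rid, patient_id = pid, group = g,
                            path = path, class_map_path = cpath,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  # the CSV stores paths relative to its own directory
  rel <- manifest
  rel$path <- basename(rel$path)
  rel$class_map_path <- basename(rel$class_map_path)
  write.csv(rel, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
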