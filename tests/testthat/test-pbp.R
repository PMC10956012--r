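test_that("mmpd handles canonical elements", {
  p <- mmpd(diag(4))
  expect_equal(p$D, 0)
  expect_equal(p$Delta, 0, tolerance = 1e-12)
  expect_equal(p$R_tot, 0, tolerance = 1e-7)

  pol <- 0.5 * rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 0, 0),
                     c(0, 0, 0, 0))
  expect_equal(mmpd(pol)$D, 1)
  expect_true(is.na(mmpd(pol)$Delta))  # flagged undefined, no exception

  expect_error(mmpd(diag(c(-1, 1, 1, 1))), "m11")
})

test_that("mmpd recovers forward-composed Lu-Chipman products", {
  # spec example: depolarizer . retarder . diattenuator with known params
  M <- canonical_mueller("depolarizer", list(a = 0.7, b = 0.7, c = 0.6)) %*%
    canonical_mueller("linear_retarder", list(delta = 0.8, theta = 0.3)) %*%
    canonical_mueller("diattenuator", list(D = 0.2, theta = 0))
  p <- mmpd(M)
  expect_equal(p$D, 0.2, tolerance = 1e-6)
  expect_equal(p$Delta, 1 - (0.7 + 0.7 + 0.6) / 3, tolerance = 1e-6)
  expect_equal(p$delta_lin, 0.8, tolerance = 1e-6)
  expect_equal(p$theta, 0.3, tolerance = 1e-6)

  # parameter grid: D x depolarization x retardance x orientation
  for (D in c(0, 0.3, 0.6, 0.9)) {
    for (pdep in c(0.2, 0.6, 0.95)) {
      for (delta in c(0.2, 1.2, 2.6)) {
        for (theta in c(0, 0.9, 2.4)) {
          M <- canonical_mueller("depolarizer",
                                 list(a = pdep, b = pdep, c = pdep)) %*%
            canonical_mueller("linear_retarder",
                              list(delta = delta, theta = theta)) %*%
            canonical_mueller("diattenuator", list(D = D, theta = 0.5))
          p <- mmpd(M)
          expect_equal(p$D, D, tolerance = 1e-6)
          expect_equal(p$Delta, 1 - pdep, tolerance = 1e-6)
          expect_equal(p$delta_lin, delta, tolerance = 1e-6)
          expect_equal(p$theta %% pi, theta %% pi, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("mmt matches closed forms", {
  q <- mmt(diag(c(1, 0.8, 0.8, 0.7)))
  expect_equal(q$b, 0.8)
  expect_equal(q$t1, 0)
  expect_equal(q$A, 0)

  # constructed b = t1 > 0 gives maximal anisotropy A = 1
  M <- diag(4); M[2, 2] <- 0.6; M[3, 3] <- 0.0
  q2 <- mmt(M)
  expect_equal(q2$b, 0.3)
  expect_equal(q2$t1, 0.3)
  expect_equal(q2$A, 1)

  # quarter-wave linear retarder at theta = 0: symbolic values
  q3 <- mmt(canonical_mueller("linear_retarder", list(delta = pi / 2)))
  expect_equal(q3$b, 0.5, tolerance = 1e-12)
  expect_equal(q3$t1, 0.5, tolerance = 1e-12)
  expect_equal(q3$A, 1, tolerance = 1e-12)
  expect_equal(q3$alpha, 0, tolerance = 1e-12)

  # general retarder: b = (1 + cos d)/2, t1 = (1 - cos d)/2
  d <- 1.1
  q4 <- mmt(canonical_mueller("linear_retarder", list(delta = d, theta = 0.7)))
  expect_equal(q4$b, (1 + cos(d)) / 2, tolerance = 1e-12)
  expect_equal(q4$t1, (1 - cos(d)) / 2, tolerance = 1e-12)
})

test_that("rotation invariants are invariant; orientations shift", {
  ri <- rotation_invariants(diag(4))
  expect_equal(unlist(ri), c(D_L = 0, P_L = 0, r_L = 0, q_L = 0, m44n = 1))

  pol <- 0.5 * rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 0, 0),
                     c(0, 0, 0, 0))
  expect_equal(rotation_invariants(pol)$D_L, 1)
  expect_equal(rotation_invariants(pol)$P_L, 1)

  set.seed(21)
  M <- polarmap:::mm_unflat(random_physical_mueller(1), 1, 1)[1, 1, , ]
  p0 <- mmpd(M); q0 <- mmt(M); r0 <- unlist(rotation_invariants(M))
  for (th in runif(20, 0, pi)) {
    Mr <- rotate_mueller(M, th)
    expect_equal(unlist(rotation_invariants(Mr)), r0, tolerance = 1e-9)
    p <- mmpd(Mr); q <- mmt(Mr)
    expect_equal(p$D, p0$D, tolerance = 1e-9)
    expect_equal(p$Delta, p0$Delta, tolerance = 1e-9)
    expect_equal(p$R_tot, p0$R_tot, tolerance = 1e-9)
    expect_equal(q$b, q0$b, tolerance = 1e-9)
    expect_equal(q$t1, q0$t1, tolerance = 1e-9)
    expect_equal(q$A, q0$A, tolerance = 1e-9)
    # fast axis shifts by the rotation angle mod pi; the anisotropy
    # orientation alpha lives on a 4-theta cycle, i.e. shifts mod pi/2
    dth <- (p$theta - p0$theta - th) %% pi
    expect_lt(min(dth, pi - dth), 1e-6)
    dal <- (q$alpha - q0$alpha - th) %% (pi / 2)
    expect_lt(min(dal, pi / 2 - dal), 1e-6)
  }
})

test_that("pbp_image matches per-matrix calls and validates selection", {
  img <- random_mueller_image(8, 9, seed = 31)
  pb <- pbp_image(img)
  expect_equal(pb$names, pbp_default_set())
  for (px in list(c(1, 1), c(3, 7), c(8, 9))) {
    M <- img$elements[px[1], px[2], , ]
    ref <- c(unlist(mmpd(M)), unlist(mmt(M)), unlist(rotation_invariants(M)))
    expect_equal(unname(pb$values[px[1], px[2], ]), unname(ref),
                 tolerance = 1e-10)
  }
  expect_error(pbp_image(img, c("A", "A")), "duplicated")
  expect_error(pbp_image(img, "nope"), "known parameters")
  expect_error(pbp_image(img, character(0)), "non-empty")

  # selection order respected; isotropic image has zero anisotropy
  el <- array(0, c(8, 8, 4, 4))
  for (i in 1:4) el[, , i, i] <- c(1, 0.8, 0.8, 0.7)[i]
  iso <- mueller_image(el)
  pa <- pbp_image(iso, c("A", "b"))
  expect_equal(as.vector(pa$values[, , 1]), rep(0, 64))
  expect_equal(as.vector(pa$values[, , 2]), rep(0.8, 64))
})

test_that("custom parameters can be registered and used", {
  register_pbp("m22n", function(norm) norm[, 6])
  on.exit(rm("m22n", envir = polarmap:::.pbp_custom_registry))
  img <- random_mueller_image(8, 8, seed = 41)
  pb <- pbp_image(img, c("b", "m22n"))
  expect_equal(pb$values[2, 2, 2],
               img$elements[2, 2, 2, 2] / img$elements[2, 2, 1, 1])
})

test_that("D, Delta, A ranges hold on physically filtered random inputs", {
  img <- cloude_filter(random_mueller_image(12, 12, seed = 51))
  pb <- pbp_image(img, c("D", "Delta", "A"))
  v <- matrix(pb$values, ncol = 3)
  v <- v[complete.cases(v), ]
  expect_true(all(v[, 1] >= 0 & v[, 1] <= 1))
  expect_true(all(v[, 2] >= -1e-9 & v[, 2] <= 1 + 1e-9))
  expect_true(all(v[, 3] >= -1e-9 & v[, 3] <= 1 + 1e-9))
})
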