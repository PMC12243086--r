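# Real spherical harmonics, real Clebsch-Gordan coupling, block
# (de)coupling and Cartesian <-> irrep maps.

test_that("real spherical harmonics match closed forms and reject non-unit input", {
  u <- c(0.3, -0.5, sqrt(1 - 0.34))
  expect_equal(real_spherical_harmonics(0, u), 1 / sqrt(4 * pi))
  expect_equal(real_spherical_harmonics(0, c(0, 0, 1)), 1 / sqrt(4 * pi))
  # l = 1 is sqrt(3/4pi) * (y, z, x)
  expect_equal(real_spherical_harmonics(1, u),
               sqrt(3 / (4 * pi)) * c(u[2], u[3], u[1]), tolerance = 1e-13)
  z <- real_spherical_harmonics(1, c(0, 0, 1))
  expect_equal(z, c(0, sqrt(3 / (4 * pi)), 0), tolerance = 1e-14)
  expect_error(real_spherical_harmonics(1, c(0, 0, 1.001)), "normalized")
})

test_that("harmonics are orthonormal under spherical quadrature", {
  # Gauss-Legendre in cos(theta) x uniform trapezoid in phi
  gl <- effham:::.gauss_legendre(24, -1, 1)
  nphi <- 32
  phis <- 2 * pi * (seq_len(nphi) - 1) / nphi
  lmax <- 3
  pts <- list(); wts <- numeric(0)
  for (i in seq_along(gl$x)) for (p in phis) {
    st <- sqrt(1 - gl$x[i]^2)
    pts[[length(pts) + 1]] <- c(st * cos(p), st * sin(p), gl$x[i])
    wts <- c(wts, gl$w[i] * 2 * pi / nphi)
  }
  U <- do.call(cbind, pts)
  Y <- do.call(rbind, lapply(0:lmax, function(l)
    real_spherical_harmonics(l, U)))
  G <- Y %*% (wts * t(Y))
  expect_lt(max(abs(G - diag(nrow(Y)))), 1e-10)
})

test_that("real CG transforms are orthogonal and respect the triangle rule", {
  expect_equal(real_cg(0, 0, 0), matrix(1))
  # l = lp = 1, lambda = 0 column is the normalized trace map
  expect_equal(matrix(real_cg(1, 1, 0), 3, 3), diag(3) / sqrt(3),
               tolerance = 1e-14)
  expect_error(real_cg(1, 1, 3), "triangle")
  for (l in 0:3) for (lp in 0:3) {
    U <- do.call(cbind, lapply(abs(l - lp):(l + lp),
                               function(lam) real_cg(l, lp, lam)))
    expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-12)
  }
})

test_that("couple/decouple round trips, norm preservation, degenerate cases", {
  expect_equal(couple_block(matrix(-0.7), 0, 0), list("0" = -0.7))
  # 3x3 identity (l = lp = 1): only lambda = 0 survives
  cid <- couple_block(diag(3), 1, 1)
  expect_equal(cid[["0"]], sqrt(3))
  expect_equal(max(abs(c(cid[["1"]], cid[["2"]]))), 0, tolerance = 1e-14)
  set.seed(31)
  for (lp in 0:2) for (l in 0:2) {
    B <- matrix(rnorm((2 * l + 1) * (2 * lp + 1)), 2 * l + 1)
    cp <- couple_block(B, l, lp)
    expect_equal(sum(vapply(cp, function(v) sum(v^2), 0)), sum(B^2),
                 tolerance = 1e-12)
    expect_equal(decouple_block(cp, l, lp), B, tolerance = 1e-12)
  }
  # single unit top-lambda component -> unit Frobenius norm block
  cp1 <- list("0" = 0, "1" = c(0, 0, 0), "2" = c(0, 0, 1, 0, 0))
  expect_equal(sqrt(sum(decouple_block(cp1, 1, 1)^2)), 1, tolerance = 1e-13)
  expect_equal(decouple_block(list("0" = 0, "1" = numeric(3),
                                   "2" = numeric(5)), 1, 1),
               matrix(0, 3, 3))
  expect_error(decouple_block(list("0" = 1), 1, 1), "missing")
  expect_error(couple_block(matrix(0, 2, 3), 1, 1), "dimensions")
})

test_that("coupled blocks are Wigner-equivariant over seeded random rotations", {
  set.seed(2024)
  for (trial in 1:20) {
    R <- random_rotation()
    for (lpair in list(c(0, 1), c(1, 1), c(1, 2), c(2, 2))) {
      l <- lpair[1]; lp <- lpair[2]
      B <- matrix(rnorm((2 * l + 1) * (2 * lp + 1)), 2 * l + 1)
      cb <- couple_block(B, l, lp)
      cr <- couple_block(wigner_d_real(l, R) %*% B %*% t(wigner_d_real(lp, R)),
                         l, lp)
      for (lam in abs(l - lp):(l + lp)) {
        lc <- as.character(lam)
        expect_lt(max(abs(cr[[lc]] - wigner_d_real(lam, R) %*% cb[[lc]])),
                  1e-10)
      }
    }
  }
})

test_that("atom exchange transposes blocks with phase (-1)^(l+lp+lam)", {
  set.seed(5)
  for (l in 0:2) for (lp in 0:2) {
    B <- matrix(rnorm((2 * l + 1) * (2 * lp + 1)), 2 * l + 1)
    cb <- couple_block(B, l, lp)
    ct <- couple_block(t(B), lp, l)
    for (lam in abs(l - lp):(l + lp)) {
      lc <- as.character(lam)
      expect_equal(ct[[lc]], (-1)^(l + lp + lam) * cb[[lc]],
                   tolerance = 1e-12)
    }
  }
})

test_that("inverting a fixture geometry flips blocks by the parity of l + lp", {
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, bas)
  sinv <- structure_new(s$species, -s$positions, unit = "bohr", id = "inv")
  rinv <- hueckel_record(sinv, bas)
  ao <- build_ao_index(s, bas)
  P <- diag((-1)^ao$l)   # inversion acts as (-1)^l on real harmonics
  expect_equal(rinv$H, P %*% rec$H %*% P, tolerance = 1e-12)
})

test_that("Cartesian tensors decompose into the correct O(3) irreps", {
  # symmetric rank 2 -> (0, 1) and (2, 1)
  set.seed(12)
  A <- crossprod(matrix(rnorm(9), 3))
  ir <- cartesian_to_irreps(A)
  expect_equal(vapply(ir, function(x) x$lambda, 0L), c(0L, 2L))
  expect_equal(vapply(ir, function(x) x$sigma, 0L), c(1L, 1L))
  expect_equal(irreps_to_cartesian(ir), A, tolerance = 1e-12)

  idm <- cartesian_to_irreps(diag(3))
  expect_equal(idm[[1]]$values, sqrt(3))     # proportional to the trace 3
  expect_equal(max(abs(idm[[2]]$values)), 0, tolerance = 1e-14)

  v <- c(0.3, -1.2, 0.5)
  irv <- cartesian_to_irreps(v)
  expect_equal(irv$lambda, 1L)
  expect_equal(irreps_to_cartesian(irv), v)
  expect_equal(irreps_to_cartesian(list(irrep_component(0, 1, 0),
                                        irrep_component(2, 1, numeric(5)))),
               matrix(0, 3, 3))

  expect_error(cartesian_to_irreps(matrix(rnorm(9), 3)), "symmetric")
  expect_error(irreps_to_cartesian(list(irrep_component(2, 1, numeric(5)))),
               "incomplete|unsupported")
})

test_that("rotating irrep components equals rotating the Cartesian tensor", {
  set.seed(77)
  for (trial in 1:5) {
    R <- random_rotation()
    A <- crossprod(matrix(rnorm(9), 3))
    ir <- cartesian_to_irreps(A)
    rot <- lapply(ir, function(cmp)
      irrep_component(cmp$lambda, cmp$sigma,
                      as.vector(wigner_d_real(cmp$lambda, R) %*% cmp$values)))
    expect_equal(irreps_to_cartesian(rot), R %*% A %*% t(R), tolerance = 1e-10)
    v <- rnorm(3)
    irv <- cartesian_to_irreps(v)
    expect_equal(irreps_to_cartesian(
      irrep_component(1, 1, as.vector(wigner_d_real(1, R) %*% irv$values))),
      as.vector(R %*% v), tolerance = 1e-10)
  }
})
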