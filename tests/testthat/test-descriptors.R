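# Neighbor-density expansions and equivariant atom / pair features.

cfg2 <- descriptor_config(c("N", "H"), cutoff = 6, n_max = 3, l_max = 2)

test_that("density expansion: isolated atom zero, on-axis neighbor support", {
  lone <- structure_new("H", matrix(c(0, 0, 0), 1), unit = "bohr", id = "lone")
  co <- density_expansion(lone, descriptor_config("H", cutoff = 5, n_max = 2,
                                                  l_max = 2))
  expect_true(all(vapply(co[[1]], function(m) max(abs(m)), 0) == 0))

  # neighbor exactly on +z: only m = 0 components nonzero
  dimer <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2.2)),
                         unit = "bohr", id = "zdim")
  cfgH <- descriptor_config("H", cutoff = 5, n_max = 2, l_max = 2)
  co <- density_expansion(dimer, cfgH)
  expect_gt(max(abs(co[[1]][[1]])), 0)
  for (l in 1:2) {
    m0 <- l + 1
    comp <- co[[1]][[l + 1]]
    expect_gt(max(abs(comp[, m0])), 0)
    expect_equal(max(abs(comp[, -m0, drop = FALSE])), 0, tolerance = 1e-14)
  }
  expect_error(density_expansion(nh3_fixture(),
                                 descriptor_config("H", cutoff = 5)),
               "cover")
})

test_that("density coefficients rotate by Wigner matrices", {
  s <- nh3_fixture()
  set.seed(41)
  for (trial in 1:3) {
    R <- random_rotation()
    c0 <- density_expansion(s, cfg2)
    c1 <- density_expansion(rotate_structure(s, R), cfg2)
    for (i in seq_along(c0)) for (l in 0:cfg2$l_max) {
      D <- wigner_d_real(l, R)
      expect_lt(max(abs(c1[[i]][[l + 1]] - c0[[i]][[l + 1]] %*% t(D))), 1e-10)
    }
  }
})

test_that("atom features: zeros for isolated atoms, inversion selection, equivariance", {
  lone <- structure_new("H", matrix(0, 1, 3), unit = "bohr", id = "lone")
  cfgH <- descriptor_config("H", cutoff = 5, n_max = 2, l_max = 2)
  af <- atom_centered_lambda_features(lone, cfgH, 0, 1)
  # isolated atom: only the constant channel survives, all others zero
  expect_equal(sum(abs(af[[1]]) > 1e-14), 1)

  # centrosymmetric environment: odd-parity features vanish
  tri <- structure_new(c("H", "H", "H"),
                       rbind(c(0, 0, 0), c(0, 0, 2.0), c(0, 0, -2.0)),
                       unit = "bohr", id = "sym")
  af1 <- atom_centered_lambda_features(tri, cfgH, 1, 1)
  expect_equal(max(abs(af1[[1]])), 0, tolerance = 1e-13)

  s <- nh3_fixture()
  set.seed(42)
  R <- random_rotation()
  for (lam in 0:2) {
    sig <- 1
    f0 <- atom_centered_lambda_features(s, cfg2, lam, sig)
    f1 <- atom_centered_lambda_features(rotate_structure(s, R), cfg2, lam, sig)
    D <- wigner_d_real(lam, R)
    for (i in seq_along(f0))
      expect_lt(max(abs(f1[[i]] - f0[[i]] %*% t(D))), 1e-10)
  }
  expect_error(atom_centered_lambda_features(s, cfg2, 2 * cfg2$l_max + 1, 1),
               "l_max")
})

test_that("pair features: swap symmetry of the +/- channels and equivariance", {
  s <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0.3, 1.9, -0.4)),
                     unit = "bohr", id = "dim")
  cfgH <- descriptor_config("H", cutoff = 6, n_max = 2, l_max = 2)
  for (lam in 0:1) {
    pf <- pair_features(s, cfgH, lam, (-1)^lam)
    xf <- pf[["1:2"]]; xb <- pf[["2:1"]]
    xp <- (xf + xb) / sqrt(2); xm <- (xf - xb) / sqrt(2)
    # relabeling i <-> j swaps the ordered features, so + is even, - odd
    xp2 <- (xb + xf) / sqrt(2); xm2 <- (xb - xf) / sqrt(2)
    expect_equal(xp2, xp)
    expect_equal(xm2, -xm)
  }
  # homonuclear symmetric dimer: lambda = 0 antisymmetric channel vanishes
  symd <- h2_fixture()
  pf <- pair_features(symd, cfgH, 0, 1)
  expect_equal(max(abs(pf[["1:2"]] - pf[["2:1"]])), 0, tolerance = 1e-12)

  set.seed(9)
  R <- random_rotation()
  s2 <- nh3_fixture()
  for (lam in 0:2) {
    p0 <- pair_features(s2, cfg2, lam, 1)
    p1 <- pair_features(rotate_structure(s2, R), cfg2, lam, 1)
    D <- wigner_d_real(lam, R)
    for (key in names(p0))
      expect_lt(max(abs(p1[[key]] - p0[[key]] %*% t(D))), 1e-10)
  }
})

test_that("locality: an atom beyond both cutoffs changes nothing", {
  s <- nh3_fixture()
  far <- structure_new(c(s$species, "H"),
                       rbind(s$positions, c(50, 50, 50)),
                       unit = "bohr", id = "far")
  for (lam in 0:1) {
    a0 <- atom_centered_lambda_features(s, cfg2, lam, 1)
    a1 <- atom_centered_lambda_features(far, cfg2, lam, 1)
    for (i in seq_along(a0)) expect_identical(a0[[i]], a1[[i]])
    p0 <- pair_features(s, cfg2, lam, 1)
    p1 <- pair_features(far, cfg2, lam, 1)
    expect_identical(p0, p1[names(p0)])
  }
  # and the far (fifth) atom participates in no pair
  p1 <- pair_features(far, cfg2, 0, 1)
  expect_false(any(grepl("5", names(p1))))
})

test_that("features vanish continuously as a neighbor crosses the cutoff", {
  cfgH <- descriptor_config("H", cutoff = 5, n_max = 2, l_max = 1)
  normf <- function(r) {
    s <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)),
                       unit = "bohr", id = "d")
    pf <- pair_features(s, cfgH, 0, 1)
    if (is.null(pf[["1:2"]])) 0 else sqrt(sum(pf[["1:2"]]^2))
  }
  vals <- vapply(c(4.5, 4.9, 4.99, 4.999), normf, 0)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-5)
  expect_equal(normf(5.0), 0)
  expect_equal(normf(5.5), 0)
})

test_that("relabeling atoms permutes pair keys without changing values", {
  s <- structure_new(c("H", "H", "H"),
                     rbind(c(0, 0, 0), c(1.9, 0.2, 0), c(0.4, 2.0, 0.3)),
                     unit = "bohr", id = "tri")
  cfgH <- descriptor_config("H", cutoff = 6, n_max = 2, l_max = 1)
  sp <- structure_new(s$species, s$positions[c(2, 1, 3), ],
                      unit = "bohr", id = "tri_p")
  p0 <- pair_features(s, cfgH, 0, 1)
  p1 <- pair_features(sp, cfgH, 0, 1)
  # atom 1 <-> 2 relabeling: pair (1,2) -> (2,1), (1,3) -> (2,3), (2,3) -> (1,3)
  expect_equal(p1[["2:1"]], p0[["1:2"]], tolerance = 1e-12)
  expect_equal(p1[["2:3"]], p0[["1:3"]], tolerance = 1e-12)
  expect_equal(p1[["1:3"]], p0[["2:3"]], tolerance = 1e-12)
})
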