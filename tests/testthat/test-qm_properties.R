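# The differentiable property layer: eigensolve, density matrix, dipole,
# polarizability, Mayer bond order, gap, and the gradient contract.

test_that("generalized eigensolve: diagonal and 2x2 homonuclear closed forms", {
  # S = I, diagonal H: sorted eigenvalues, positive-phase permutation
  H <- diag(c(0.4, -1.1, -0.2))
  sol <- solve_generalized(H, diag(3), 2)
  expect_equal(sol$eps, c(-1.1, -0.2, 0.4))
  expect_equal(abs(sol$C), diag(3)[, c(2, 3, 1)], tolerance = 1e-14)
  expect_true(all(apply(sol$C, 2, max) > 0))
  expect_equal(sol$f, c(2, 0, 0))

  h <- -0.6; t <- -0.35; s <- 0.42
  sol2 <- solve_generalized(matrix(c(h, t, t, h), 2),
                            matrix(c(1, s, s, 1), 2), 2)
  expect_equal(sol2$eps, sort(c((h + t) / (1 + s), (h - t) / (1 - s))),
               tolerance = 1e-12)
  expect_lt(max(abs(t(sol2$C) %*% matrix(c(1, s, s, 1), 2) %*% sol2$C -
                    diag(2))), 1e-12)

  expect_error(solve_generalized(H, diag(3), 3), "even")
  expect_error(solve_generalized(H, diag(c(1, 1, -1)), 2), "positive definite")
  expect_error(solve_generalized(H, diag(3), 8), "capacity")
})

test_that("C^T S C = I and Tr(rho S) = N hold on random SPD fixtures", {
  set.seed(100)
  for (trial in 1:10) {
    d <- sample(3:8, 1)
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) / d + diag(d)
    H <- crossprod(matrix(rnorm(d * d), d)) / d - diag(d)
    nel <- 2 * sample(seq_len(d - 1), 1)
    sol <- solve_generalized(H, S, nel)
    expect_lt(max(abs(t(sol$C) %*% S %*% sol$C - diag(d))), 1e-12)
    rho <- density_matrix(sol)
    expect_equal(sum(rho * S), nel, tolerance = 1e-10)
    P <- rho %*% S
    expect_lt(max(abs(P %*% P - 2 * P)), 1e-10)   # closed-shell idempotency
  }
})

test_that("density matrix: zero electrons and the H2 bonding orbital", {
  H <- matrix(c(-0.5, -0.3, -0.3, -0.5), 2)
  s <- 0.4
  S <- matrix(c(1, s, s, 1), 2)
  sol0 <- solve_generalized(H, S, 0)
  expect_equal(density_matrix(sol0), matrix(0, 2, 2))
  sol <- solve_generalized(H, S, 2)
  expect_equal(density_matrix(sol),
               matrix(1 / (1 + s), 2, 2), tolerance = 1e-12)
})

test_that("dipole: inversion symmetry, translation gauge, point-charge limit", {
  bas <- toy_basis("toy-min", "H")
  h2 <- h2_fixture()
  rec <- hueckel_record(h2, bas)
  expect_equal(max(abs(rec$props$mu)), 0, tolerance = 1e-12)

  s <- nh3_fixture()
  basN <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, basN)
  dvec <- c(1.3, -0.7, 2.1)
  st <- structure_new(s$species, sweep(s$positions, 2, -dvec), unit = "bohr",
                      id = "shift")
  rect <- hueckel_record(st, basN)   # X translates consistently with geometry
  expect_equal(rect$props$mu, rec$props$mu, tolerance = 1e-10)

  # rho = 0: purely nuclear dipole
  ao <- build_ao_index(s, basN)
  mu_nuc <- dipole(matrix(0, nrow(ao), nrow(ao)), rec$X, s, basN)
  Q <- c(5, 1, 1, 1)
  expect_equal(mu_nuc, colSums(Q * s$positions), tolerance = 1e-14)
})

test_that("sum-over-states polarizability matches the finite-field oracle", {
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, bas)
  sol <- solve_generalized(rec$H, rec$S, rec$n_electrons)
  alpha <- polarizability(sol, rec$X)
  expect_equal(alpha, t(alpha))
  expect_true(min(eigen(alpha, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
  E <- 1e-3
  ff <- matrix(0, 3, 3)
  for (b in 1:3) for (sgn in c(1, -1)) {
    solp <- solve_generalized(rec$H + sgn * E * rec$X[[b]], rec$S,
                              rec$n_electrons)
    ff[, b] <- ff[, b] + sgn * dipole(density_matrix(solp), rec$X, s, bas) /
      (2 * E)
  }
  expect_lt(max(abs(alpha - ff)) / max(abs(ff)), 1e-4)

  # no virtual orbitals: error, not zero
  solfull <- solve_generalized(rec$H, rec$S, 2 * nrow(rec$H))
  expect_error(polarizability(solfull, rec$X), "virtual")
})

test_that("polarizability is rotation-equivariant", {
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, bas)
  set.seed(55)
  R <- random_rotation()
  recR <- hueckel_record(rotate_structure(s, R), bas)
  expect_equal(recR$props$alpha, R %*% rec$props$alpha %*% t(R),
               tolerance = 1e-8)
  expect_equal(as.vector(recR$props$mu), as.vector(R %*% rec$props$mu),
               tolerance = 1e-8)
})

test_that("Mayer bond orders: H2 single bond, separability, AO-mixing invariance", {
  rec <- hueckel_record(h2_fixture(), toy_basis("toy-min", "H"))
  expect_equal(rec$props$bond_order[1, 2], 1, tolerance = 1e-10)

  # two far-apart dimers: block-diagonal rho, S -> zero cross bond order
  s4 <- structure_new(rep("H", 4),
                      rbind(c(0, 0, 0), c(0, 0, 1.4),
                            c(40, 0, 0), c(40, 0, 1.4)),
                      unit = "bohr", id = "pair")
  rec4 <- hueckel_record(s4, toy_basis("toy-min", "H"))
  expect_lt(abs(rec4$props$bond_order[1, 3]), 1e-10)
  expect_equal(rec4$props$bond_order[1, 2], 1, tolerance = 1e-8)

  # invariance under within-atom orthogonal AO mixing
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, bas)
  ao <- build_ao_index(s, bas)
  sol <- solve_generalized(rec$H, rec$S, rec$n_electrons)
  rho <- density_matrix(sol)
  B0 <- mayer_bond_order(rho, rec$S, ao)
  set.seed(6)
  Q <- diag(nrow(ao))
  qr4 <- qr.Q(qr(matrix(rnorm(16), 4)))   # mix the four N AOs
  Q[1:4, 1:4] <- qr4
  B1 <- mayer_bond_order(Q %*% rho %*% t(Q), Q %*% rec$S %*% t(Q), ao)
  expect_lt(max(abs(B1 - B0)), 1e-12)
})

test_that("HOMO-LUMO gap arithmetic and invariances", {
  sol <- list(eps = c(-1, -0.5, 0.2, 0.9), n_occ = 2L)
  expect_equal(homo_lumo_gap(sol), 0.7)
  sol$eps <- sol$eps + 3.3
  expect_equal(homo_lumo_gap(sol), 0.7)   # rigid-shift invariance
  expect_equal(homo_lumo_gap(list(eps = c(-1, -0.3, -0.3, 1), n_occ = 2L)), 0)
  expect_error(homo_lumo_gap(list(eps = c(-1, -0.5), n_occ = 2L)), "virtual")
})

test_that("analytic d(loss)/dH matches finite differences for all four targets", {
  s <- nh3_fixture()                       # 7-AO fixture
  bas <- toy_basis("toy-min", c("N", "H"))
  rec <- hueckel_record(s, bas)
  ao <- build_ao_index(s, bas)
  set.seed(9)
  Z <- matrix(rnorm(16, 0, 0.1), 4)
  ref <- rec$props
  ref$eps <- ref$eps + 0.01 * seq_along(ref$eps)
  ref$mu <- ref$mu + c(0.02, -0.01, 0.03)
  ref$alpha <- ref$alpha + diag(0.1, 3)
  ref$bond_order <- ref$bond_order + (Z + t(Z)) / 2
  entries <- entry_sample(7, 10, seed = 3)
  for (tg in c("eps", "mu", "alpha", "bond_order")) {
    pg <- property_loss_grad(rec$H, rec$S, rec$X, rec$n_electrons, s, bas,
                             ao, ref, targets = tg)
    lf <- function(H) property_loss_grad(H, rec$S, rec$X, rec$n_electrons,
                                         s, bas, ao, ref, targets = tg)$loss
    expect_lt(grad_vs_fd(lf, pg$grad_H, rec$H, entries), 1e-5)
  }
})

test_that("derived_properties collects a consistent record", {
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  gi <- gaussian_integrals(s, bas)
  h <- effham:::.onsite_vector(s, bas)
  H <- 0.5 * 1.75 * outer(h, h, "+") * gi$S
  diag(H) <- h
  dp <- derived_properties(H, gi$S, gi$X, 8, s, bas, gi$ao_map)
  expect_equal(dp$gap, dp$eps[5] - dp$eps[4])
  expect_equal(dim(dp$bond_order), c(4, 4))
  expect_equal(length(dp$mu), 3)
})
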