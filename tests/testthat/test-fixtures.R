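# Synthetic reference engine: Gaussian integrals, Hueckel records,
# dataset builders, extrapolation series.

test_that("Gaussian overlaps match the product-theorem closed form", {
  basH <- toy_basis("toy-min", "H")
  a <- basH$species$H$exponents[1]
  # two identical s Gaussians at zero separation -> overlap 1
  s0 <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1e-12)),
                      unit = "bohr", id = "coincident")
  gi0 <- gaussian_integrals(s0, basH)
  expect_equal(gi0$S[1, 2], 1, tolerance = 1e-9)

  # s-s overlap at separation R: (4ab/(a+b)^2)^(3/4) exp(-ab R^2/(a+b))
  for (R in c(0.8, 1.4, 2.5)) {
    s <- h2_fixture(R)
    gi <- gaussian_integrals(s, basH)
    expect_equal(gi$S[1, 2],
                 (4 * a * a / (a + a)^2)^0.75 * exp(-a * a * R^2 / (a + a)),
                 tolerance = 1e-12)
  }
  expect_error(gaussian_integrals(
    h2_fixture(), basis_spec(list(H = list(shells = list(c(3, 2)), Q = 1,
                                           valence = 1,
                                           exponents = 1)))), "l <= 1")
})

test_that("position integrals satisfy the exact translation identity", {
  s <- nh3_fixture()
  bas <- toy_basis("toy-min", c("N", "H"))
  gi <- gaussian_integrals(s, bas)
  d <- c(0.7, -1.3, 2.9)
  st <- structure_new(s$species, sweep(s$positions, 2, -d), unit = "bohr",
                      id = "t")
  git <- gaussian_integrals(st, bas)
  for (ax in 1:3)
    expect_equal(git$X[[ax]], gi$X[[ax]] + d[ax] * gi$S, tolerance = 1e-12)
  # SPD overlap, symmetric operators
  expect_gt(min(eigen(gi$S, symmetric = TRUE, only.values = TRUE)$values), 0)
  for (ax in 1:3) expect_equal(gi$X[[ax]], t(gi$X[[ax]]))
})

test_that("Hueckel records: H2 levels, linearity in onsite energies", {
  rec <- hueckel_record(h2_fixture(), "toy-min")
  expect_equal(length(rec$props$eps), 2)
  expect_lt(rec$props$eps[1], rec$props$eps[2])   # bonding below antibonding
  expect_equal(rec$props$bond_order[1, 2], 1, tolerance = 1e-10)

  # scaling all on-site energies scales H exactly (S fixed)
  basH <- toy_basis("toy-min", "H")
  bas2 <- basH
  bas2$species$H$onsite <- 2 * basH$species$H$onsite
  r1 <- hueckel_record(h2_fixture(), basH)
  r2 <- hueckel_record(h2_fixture(), bas2)
  expect_equal(r2$H, 2 * r1$H, tolerance = 1e-13)

  # odd valence-electron sums are rejected
  s3 <- structure_new(rep("H", 3),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0)),
                      unit = "bohr", id = "h3")
  expect_error(hueckel_record(s3, basH), "odd")
})

test_that("datasets are byte-identical under a fixed seed", {
  d1 <- make_dataset(6, templates = c("h2o", "nh3"), seed = 77,
                     bases = "toy-min")
  d2 <- make_dataset(6, templates = c("h2o", "nh3"), seed = 77,
                     bases = "toy-min")
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- make_dataset(6, templates = c("h2o", "nh3"), seed = 78,
                     bases = "toy-min")
  expect_false(identical(d1$structures[[1]]$positions,
                         d3$structures[[1]]$positions))
  expect_error(make_dataset(3, templates = "benzene"), "unknown template")
})

test_that("two-basis datasets have a strictly positive basis-set gap", {
  ds <- make_dataset(8, templates = "h2o", seed = 11)
  gap <- mean(vapply(seq_along(ds$structures), function(i) {
    nocc <- ds$records[["toy-min"]][[i]]$n_electrons / 2
    mean(abs(ds$records[["toy-min"]][[i]]$props$eps[1:nocc] -
             ds$records[["toy-big"]][[i]]$props$eps[1:nocc]))
  }, 0))
  expect_gt(gap, 0)
  # every record passes the property-layer invariants
  for (b in c("toy-min", "toy-big")) {
    rec <- ds$records[[b]][[1]]
    sol <- solve_generalized(rec$H, rec$S, rec$n_electrons)
    expect_lt(max(abs(t(sol$C) %*% rec$S %*% sol$C -
                      diag(nrow(rec$S)))), 1e-10)
    expect_equal(sum(density_matrix(sol) * rec$S), rec$n_electrons,
                 tolerance = 1e-10)
  }
})

test_that("known-weights noise raises the recovery error monotonically", {
  world <- h_world(n = 15, seed = 3)
  gen <- ridge_pretrain(world$structures, world$records, world$basis,
                        world$config, ridge = 1e-4)
  err_at <- function(noise) {
    recs <- known_weights_dataset(gen, world$structures, world$basis,
                                  noise = noise, seed = 5)
    fit <- ridge_pretrain(world$structures, recs, world$basis, world$config,
                          ridge = 1e-12)
    sqrt(sum(vapply(names(gen$weights), function(id)
      sum((fit$weights[[id]] - gen$weights[[id]])^2), 0)))
  }
  errs <- vapply(c(0, 1e-3, 1e-2), err_at, 0)
  expect_lt(errs[1], 1e-6)
  expect_true(all(diff(errs) > 0))
})

test_that("farthest-point subselection returns the requested distinct set", {
  ds <- make_dataset(10, templates = c("h2o", "nh3"), seed = 4,
                     bases = "toy-min")
  cfg <- descriptor_config(c("O", "N", "H"), cutoff = 5, n_max = 2, l_max = 1)
  sel <- farthest_point_sample(ds$structures, cfg, 5)
  expect_length(sel, 5)
  expect_equal(anyDuplicated(sel), 0)
  expect_error(farthest_point_sample(ds$structures, cfg, 11), "exceeds")
})

test_that("extrapolation series: diatomic limit and growing per-atom response", {
  series <- extrapolation_series("chain-alkene-like", c(2, 4, 6, 8))
  expect_equal(n_atoms(series[[1]]), 2)
  basH <- toy_basis("toy-min", "H")
  apn <- vapply(series, function(s)
    sqrt(sum(hueckel_record(s, basH)$props$alpha^2)) / n_atoms(s), 0)
  expect_true(all(diff(apn) > 0))

  da <- extrapolation_series("donor-acceptor-chain", c(4, 6, 8))
  expect_equal(da[[1]]$species[1], "C")
  expect_equal(da[[1]]$species[4], "O")
  mun <- vapply(da, function(s)
    sqrt(sum(hueckel_record(s, toy_basis("toy-min"))$props$mu^2)), 0)
  expect_true(all(diff(mun) > 0))   # dipole grows with chain length

  ac <- extrapolation_series("chain-acene-like", c(2, 4))
  expect_equal(n_atoms(ac[[1]]), 4)
  expect_error(extrapolation_series("chain-alkene-like", c(4, 2)),
               "increasing")
})
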