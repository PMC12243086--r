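# Block linear models: coupling/assembly, ridge pretraining, prediction.

world <- h_world(n = 20, seed = 7)
mixed_bas <- toy_basis("toy-min", c("O", "H"))
mixed_cfg <- descriptor_config(c("O", "H"), cutoff = 6, n_max = 3, l_max = 2)
mixed_ds <- make_dataset(16, templates = "h2o", seed = 5, bases = "toy-min")
mixed_feats <- lapply(mixed_ds$structures, featurize_structure,
                      basis = mixed_bas, config = mixed_cfg)
mixed_model <- ridge_pretrain(mixed_ds$structures, mixed_ds$records[["toy-min"]],
                              mixed_bas, mixed_cfg, ridge = 1e-10,
                              feats_list = mixed_feats)

test_that("couple -> assemble is an exact round trip and output is symmetric", {
  s <- mixed_ds$structures[[1]]
  H <- mixed_ds$records[["toy-min"]][[1]]$H
  blocks <- couple_hamiltonian(H, s, mixed_bas, cutoff = 6)
  H2 <- assemble_matrix(blocks, s, mixed_bas)
  expect_equal(H2, H, tolerance = 1e-12)
  expect_identical(H2, t(H2))   # symmetric by construction, exactly

  # on-site-only blocks give a block-diagonal matrix
  blocks$pairs <- lapply(blocks$pairs, function(x) list())
  Hd <- assemble_matrix(blocks, s, mixed_bas)
  ao <- build_ao_index(s, mixed_bas)
  sl <- attr(ao, "slices")
  expect_equal(max(abs(Hd[sl[1, 1]:sl[1, 2], sl[2, 1]:sl[2, 2]])), 0)
  expect_equal(Hd[sl[1, 1]:sl[1, 2], sl[1, 1]:sl[1, 2]],
               H[sl[1, 1]:sl[1, 2], sl[1, 1]:sl[1, 2]], tolerance = 1e-12)
})

test_that("model keys respect parity and permutation constraints", {
  keys <- model_keys(mixed_bas)
  on_pp <- keys[keys$kind == "on" & keys$l1 == 1 & keys$l2 == 1 &
                keys$n1 == keys$n2, ]
  expect_true(all(on_pp$lam %in% c(0, 2)))    # symmetric same-shell blocks
  ss_diag <- keys[keys$kind == "ss" & keys$n1 == keys$n2 &
                  keys$l1 == keys$l2, ]
  expect_true(all((ss_diag$lam %% 2 == 0) == (ss_diag$channel == "+")))
  expect_true(all(keys$sigma == (-1)^(keys$l1 + keys$l2 + keys$lam)))
  expect_true(all(keys$intercept == (keys$lam == 0 & keys$channel != "-")))
})

test_that("predictions are linear, covariant, and fail on unknown keys", {
  s <- mixed_ds$structures[[2]]
  feats <- mixed_feats[[2]]
  # zero model -> zero matrix
  zero <- mixed_model
  for (id in names(zero$weights)) zero$weights[[id]][] <- 0
  for (id in names(zero$intercepts)) zero$intercepts[[id]] <- 0
  expect_equal(max(abs(predict_matrix(zero, s, mixed_bas, feats))), 0)

  # doubling weights and intercepts doubles the prediction (linearity)
  dbl <- mixed_model
  for (id in names(dbl$weights)) dbl$weights[[id]] <- 2 * dbl$weights[[id]]
  for (id in names(dbl$intercepts)) dbl$intercepts[[id]] <- 2 * dbl$intercepts[[id]]
  expect_equal(predict_matrix(dbl, s, mixed_bas, feats),
               2 * predict_matrix(mixed_model, s, mixed_bas, feats),
               tolerance = 1e-12)

  # species pair absent at training (config covers N, the model does not)
  basONH <- toy_basis("toy-min", c("N", "O", "H"))
  cfgONH <- descriptor_config(c("N", "O", "H"), cutoff = 6, n_max = 2,
                              l_max = 2)
  mON <- ridge_pretrain(mixed_ds$structures[1:4],
                        mixed_ds$records[["toy-min"]][1:4], basONH, cfgONH,
                        ridge = 1e-8)
  expect_error(predict_matrix(mON, nh3_fixture(), basONH),
               "weights for block key")
})

test_that("prediction on a rotated structure equals the rotated prediction", {
  set.seed(19)
  s <- mixed_ds$structures[[3]]
  R <- random_rotation()
  H1 <- predict_matrix(mixed_model, s, mixed_bas)
  H2 <- predict_matrix(mixed_model, rotate_structure(s, R), mixed_bas)
  D <- ao_rotation(build_ao_index(s, mixed_bas), R)
  expect_lt(max(abs(D %*% H1 %*% t(D) - H2)), 1e-10)
})

test_that("relabeling atoms leaves the predicted physical matrix unchanged", {
  s <- structure_new(c("H", "H", "H", "H"),
                     rbind(c(0, 0, 0), c(1.5, 0.2, 0),
                           c(0.1, 1.6, 0.3), c(1.4, 1.5, 1.2)),
                     unit = "bohr", id = "h4")
  perm <- c(3, 1, 4, 2)
  sp <- structure_new(s$species[perm], s$positions[perm, ], unit = "bohr",
                      id = "h4p")
  model <- ridge_pretrain(world$structures, world$records, world$basis,
                          world$config, ridge = 1e-8)
  H1 <- predict_matrix(model, s, world$basis)
  H2 <- predict_matrix(model, sp, world$basis)
  # one AO per atom here, so the AO permutation equals the atom permutation
  expect_equal(H2, H1[perm, perm], tolerance = 1e-10)
})

test_that("ridge pretraining fits Hueckel references and generalizes", {
  errs <- vapply(seq_along(mixed_ds$structures), function(i)
    max(abs(predict_matrix(mixed_model, mixed_ds$structures[[i]], mixed_bas,
                           mixed_feats[[i]]) -
            mixed_ds$records[["toy-min"]][[i]]$H)), 0)
  expect_lt(max(errs), 5e-3)
  held <- make_dataset(2, templates = "h2o", seed = 909, bases = "toy-min")
  expect_lt(max(abs(predict_matrix(mixed_model, held$structures[[1]],
                                   mixed_bas) -
                    held$records[["toy-min"]][[1]]$H)), 5e-3)
})

test_that("duplicating every training structure leaves the solution unchanged", {
  m1 <- ridge_pretrain(world$structures, world$records, world$basis,
                       world$config, ridge = 1e-6)
  m2 <- ridge_pretrain(c(world$structures, world$structures),
                       c(world$records, world$records), world$basis,
                       world$config, ridge = 1e-6)
  for (id in names(m1$weights))
    expect_equal(m2$weights[[id]], m1$weights[[id]], tolerance = 1e-8)
})

test_that("infinite-ridge limit: weights -> 0, intercepts -> per-key means", {
  m <- ridge_pretrain(world$structures, world$records, world$basis,
                      world$config, ridge = 1e12)
  expect_lt(max(vapply(m$weights, function(w) max(abs(w)), 0)), 1e-6)
  # the on-site H s-s intercept must approach the mean on-site energy (-0.5)
  onkey <- grep("^on\\.H", names(m$intercepts), value = TRUE)[1]
  expect_equal(m$intercepts[[onkey]], -0.5, tolerance = 1e-3)
})

test_that("exact parameter recovery from a zero-noise known-weights dataset", {
  gen <- ridge_pretrain(world$structures, world$records, world$basis,
                        world$config, ridge = 1e-4)
  recs <- known_weights_dataset(gen, world$structures, world$basis, noise = 0)
  fit <- ridge_pretrain(world$structures, recs, world$basis, world$config,
                        ridge = 1e-12)
  for (id in names(gen$weights)) {
    n0 <- sqrt(sum(gen$weights[[id]]^2))
    if (n0 > 1e-10)
      expect_lt(sqrt(sum((fit$weights[[id]] - gen$weights[[id]])^2)) / n0,
                1e-6)
  }
  expect_error(ridge_pretrain(world$structures, recs, world$basis,
                              world$config, ridge = 0), "ridge")
})

test_that("auto ridge (GCV) produces a usable model", {
  m <- ridge_pretrain(world$structures[1:8], world$records[1:8], world$basis,
                      world$config, ridge = "auto")
  expect_true(all(unlist(m$ridge) > 0))
  H <- predict_matrix(m, world$structures[[9]], world$basis)
  expect_lt(max(abs(H - world$records[[9]]$H)), 0.05)
})
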