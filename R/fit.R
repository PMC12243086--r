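# Featurization, ridge pretraining, prediction and the weight-gradient
# chain for the per-block linear Hamiltonian model.

#' Featurize one structure for the block model
#'
#' Computes every (sigma, lambda) feature set the model keys of `basis`
#' can consume: atom-centered features per atom and ordered pair features
#' in both directions for each canonical within-cutoff pair.
#'
#' @param structure a structure.
#' @param basis a [basis_spec()].
#' @param config a [descriptor_config()]; its cutoff also defines the
#'   block support of the model.
#' @return list with `onsite`, `pair_fwd`, `pair_bwd` (keyed by canonical
#'   `"first:second"`), `pair_table`, `ao_map`.
#' @export
featurize_structure <- function(structure, basis, config) {
  keys <- model_keys(basis, unique(structure$species))
  sl <- unique(keys[, c("sigma", "lam")])
  coeffs <- density_expansion(structure, config)
  species_order <- names(basis$species)
  pt <- .pair_table(structure, species_order, config$cutoff)
  onsite <- rep(list(list()), n_atoms(structure))
  pair_fwd <- rep(list(list()), nrow(pt))
  pair_bwd <- rep(list(list()), nrow(pt))
  for (r in seq_len(nrow(sl))) {
    sig <- sl$sigma[r]; lam <- sl$lam[r]
    id <- paste(sig, lam, sep = "|")
    af <- atom_centered_lambda_features(structure, config, lam, sig, coeffs)
    for (i in seq_along(af)) onsite[[i]][[id]] <- af[[i]]
    for (p in seq_len(nrow(pt))) {
      fi <- pt$first[p]; se <- pt$second[p]
      d <- structure$positions[se, ] - structure$positions[fi, ]
      pair_fwd[[p]][[id]] <-
        .pair_feature_one(config, d, coeffs[[fi]], coeffs[[se]], lam, sig)
      pair_bwd[[p]][[id]] <-
        .pair_feature_one(config, -d, coeffs[[se]], coeffs[[fi]], lam, sig)
    }
  }
  names(pair_fwd) <- names(pair_bwd) <-
    if (nrow(pt)) paste0(pt$first, ":", pt$second) else character(0)
  list(onsite = onsite, pair_fwd = pair_fwd, pair_bwd = pair_bwd,
       pair_table = pt, ao_map = build_ao_index(structure, basis))
}

.weight_id <- function(key, lam, channel) paste(key, lam, channel, sep = "|")

# component id used by couple_hamiltonian / assemble_matrix storage:
# "key|lam" for single-channel kinds, "key|lam|channel" otherwise
.comp_id <- function(key, lam, channel) {
  if (identical(channel, "")) paste(key, lam, sep = "|")
  else paste(key, lam, channel, sep = "|")
}

# iterate over (key row, occurrence) pairs of one featurized structure,
# calling fun(widx, xi, comp_id) where xi is the feature matrix and
# comp_id addresses blocks$onsite/pairs. Used by predict / fit / grad.
.for_each_block <- function(keys, structure, feats, fun) {
  nat <- n_atoms(structure)
  for (i in seq_len(nat)) {
    sp <- structure$species[i]
    kk <- keys[keys$kind == "on" & keys$sp1 == sp, , drop = FALSE]
    for (r in seq_len(nrow(kk))) {
      row <- kk[r, ]
      xi <- feats$onsite[[i]][[paste(row$sigma, row$lam, sep = "|")]]
      fun(row, xi, list(where = "onsite", atom = i))
    }
  }
  pt <- feats$pair_table
  for (p in seq_len(nrow(pt))) {
    fi <- pt$first[p]; se <- pt$second[p]
    sp1 <- structure$species[fi]; sp2 <- structure$species[se]
    pid <- paste0(fi, ":", se)
    if (sp1 == sp2) {
      kk <- keys[keys$kind == "ss" & keys$sp1 == sp1, , drop = FALSE]
      for (r in seq_len(nrow(kk))) {
        row <- kk[r, ]
        id <- paste(row$sigma, row$lam, sep = "|")
        xf <- feats$pair_fwd[[pid]][[id]]; xb <- feats$pair_bwd[[pid]][[id]]
        xi <- if (row$channel == "+") (xf + xb) / sqrt(2) else (xf - xb) / sqrt(2)
        fun(row, xi, list(where = "pair", pid = pid))
      }
    } else {
      kk <- keys[keys$kind == "sd" & keys$sp1 == sp1 & keys$sp2 == sp2, ,
                 drop = FALSE]
      if (nrow(kk) == 0)
        stop("no model keys for species pair ", sp1, "-", sp2)
      for (r in seq_len(nrow(kk))) {
        row <- kk[r, ]
        xi <- feats$pair_fwd[[pid]][[paste(row$sigma, row$lam, sep = "|")]]
        fun(row, xi, list(where = "pair", pid = pid))
      }
    }
  }
  invisible(NULL)
}

#' Predict channel components from a block linear model
#'
#' `c^(p sigma lambda) = w . xi (+ b for lambda = 0)`; linear in the
#' features, zero for beyond-cutoff pairs (absent entries).
#'
#' @param model an `effham_block_model` (see [ridge_pretrain()]).
#' @param structure a structure.
#' @param basis the model basis.
#' @param feats optional precomputed [featurize_structure()].
#' @return `effham_blocks` (pass to [assemble_matrix()]).
#' @export
predict_blocks <- function(model, structure, basis, feats = NULL) {
  if (is.null(feats)) feats <- featurize_structure(structure, basis, model$config)
  onsite <- rep(list(list()), n_atoms(structure))
  pairs <- list()
  fun <- function(row, xi, addr) {
    wid <- .weight_id(row$key, row$lam, row$channel)
    w <- model$weights[[wid]]
    if (is.null(w))
      stop("model has no weights for block key ", wid,
           " (species pair absent at training)")
    v <- as.vector(crossprod(xi, w))
    if (row$intercept && !is.null(model$intercepts[[wid]]))
      v <- v + model$intercepts[[wid]]
    cid <- .comp_id(row$key, row$lam, row$channel)
    if (addr$where == "onsite") {
      onsite[[addr$atom]][[cid]] <<- v
    } else {
      if (is.null(pairs[[addr$pid]])) pairs[[addr$pid]] <<- list()
      pairs[[addr$pid]][[cid]] <<- v
    }
  }
  .for_each_block(model$keys, structure, feats, fun)
  out <- list(onsite = onsite, pairs = pairs, pair_table = feats$pair_table,
              ao_map = feats$ao_map, species_order = names(basis$species))
  class(out) <- "effham_blocks"
  out
}

#' Predict a Hamiltonian matrix
#'
#' Convenience wrapper: featurize, predict blocks, assemble.
#' @inheritParams predict_blocks
#' @export
predict_matrix <- function(model, structure, basis, feats = NULL) {
  if (is.null(feats)) feats <- featurize_structure(structure, basis, model$config)
  assemble_matrix(predict_blocks(model, structure, basis, feats),
                  structure, basis)
}

# Ridge solve with optional unpenalized intercept; Z (rows x F), y vector.
# Solved through the SVD of the (centered) design rather than normal
# equations: at vanishing ridge this reaches the minimum-norm least-squares
# limit at the conditioning of Z, not of Z^T Z, which is what makes exact
# parameter recovery possible. The penalty is per sample (scaled by the row
# count), so duplicating every training structure leaves the fit unchanged.
.ridge_solve <- function(Z, y, ridge, intercept) {
  zm <- NULL; ym <- 0
  if (intercept) {
    zm <- colMeans(Z); ym <- mean(y)
    Z <- sweep(Z, 2, zm); y <- y - ym
  }
  sv <- svd(Z)
  if (ridge <= 0) {
    if (length(sv$d) && min(sv$d) < 1e-10 * max(sv$d, 1e-300))
      stop("singular normal equations at ridge = 0 for a block key; ",
           "use a ridge strength > 0")
    ridge <- 0
  }
  lam <- ridge * nrow(Z)
  shrink <- sv$d / (sv$d^2 + lam)
  w <- as.vector(sv$v %*% (shrink * crossprod(sv$u, y)))
  list(w = w, b = if (intercept) as.numeric(ym - sum(zm * w)) else NULL)
}

# generalized cross-validation over a log grid of per-sample ridges
.gcv_ridge <- function(Z, y, grid = 10^seq(-10, 2, by = 1)) {
  sv <- svd(Z)
  d2 <- sv$d^2
  uy <- crossprod(sv$u, y)
  n <- length(y)
  best <- grid[1]; bestv <- Inf
  for (g in grid) {
    shrink <- d2 / (d2 + g * nrow(Z))
    fit <- sv$u %*% (shrink * uy)
    df <- sum(shrink)
    v <- n * sum((y - fit)^2) / (n - min(df, n - 1e-8))^2
    if (v < bestv) { bestv <- v; best <- g }
  }
  best
}

#' Symmetry-adapted ridge pretraining (direct Hamiltonian model)
#'
#' Per-(key, lambda, channel) closed-form ridge regression of coupled
#' reference Hamiltonian blocks on the matching features; the same weights
#' apply to all mu components, and intercepts exist only for invariant
#' non-antisymmetric components.
#'
#' @param structures list of structures.
#' @param records list of matching reference records (same order) holding
#'   the target `H` in `basis`.
#' @param basis model basis.
#' @param config descriptor configuration.
#' @param ridge ridge strength, or `"auto"` for per-key generalized
#'   cross-validation on a log grid.
#' @param feats_list optional precomputed features.
#' @return an `effham_block_model`: list with `keys`, `weights`,
#'   `intercepts`, `config`, `basis_label`, `ridge`.
#' @export
ridge_pretrain <- function(structures, records, basis, config, ridge = 1e-8,
                           feats_list = NULL) {
  stopifnot(length(structures) == length(records))
  keys <- model_keys(basis)
  if (is.null(feats_list))
    feats_list <- lapply(structures, featurize_structure, basis = basis,
                         config = config)
  acc <- new.env(parent = emptyenv())
  for (s in seq_along(structures)) {
    blocks <- couple_hamiltonian(records[[s]]$H, structures[[s]], basis,
                                 config$cutoff)
    feats <- feats_list[[s]]
    fun <- function(row, xi, addr) {
      wid <- .weight_id(row$key, row$lam, row$channel)
      cid <- .comp_id(row$key, row$lam, row$channel)
      tgt <- if (addr$where == "onsite") blocks$onsite[[addr$atom]][[cid]]
             else blocks$pairs[[addr$pid]][[cid]]
      if (is.null(tgt)) tgt <- numeric(2 * row$lam + 1)
      e <- acc[[wid]]
      if (is.null(e)) e <- list(Z = list(), y = list())
      e$Z[[length(e$Z) + 1]] <- t(xi)
      e$y[[length(e$y) + 1]] <- tgt
      acc[[wid]] <- e
    }
    .for_each_block(keys, structures[[s]], feats, fun)
  }
  weights <- list(); intercepts <- list(); ridges <- list()
  for (r in seq_len(nrow(keys))) {
    row <- keys[r, ]
    wid <- .weight_id(row$key, row$lam, row$channel)
    e <- acc[[wid]]
    if (is.null(e)) next  # key never observed (species absent)
    Z <- do.call(rbind, e$Z)
    y <- unlist(e$y)
    g <- if (identical(ridge, "auto")) .gcv_ridge(Z, y) else ridge
    sol <- .ridge_solve(Z, y, g, intercept = isTRUE(row$intercept))
    weights[[wid]] <- sol$w
    if (!is.null(sol$b)) intercepts[[wid]] <- sol$b
    ridges[[wid]] <- g
  }
  out <- list(keys = keys, weights = weights, intercepts = intercepts,
              config = config, basis_label = basis$label, ridge = ridges)
  class(out) <- "effham_block_model"
  out
}

#' @export
print.effham_block_model <- function(x, ...) {
  cat("<effham_block_model>", length(x$weights), "weight vectors (basis",
      x$basis_label, "), feature cutoff", x$config$cutoff, "a.u.\n")
  invisible(x)
}

# ---- weight-space gradient chain ----------------------------------------

# Flatten model weights+intercepts to a vector and back.
.theta_pack <- function(model) {
  ids <- names(model$weights)
  idx <- list(); pos <- 0L
  theta <- numeric(0)
  for (id in ids) {
    w <- model$weights[[id]]
    idx[[id]] <- pos + seq_along(w)
    pos <- pos + length(w)
    theta <- c(theta, w)
  }
  bids <- names(model$intercepts)
  bidx <- list()
  for (id in bids) {
    pos <- pos + 1L
    bidx[[id]] <- pos
    theta <- c(theta, model$intercepts[[id]])
  }
  list(theta = theta, idx = idx, bidx = bidx)
}

.theta_unpack <- function(model, pack, theta) {
  for (id in names(pack$idx)) model$weights[[id]] <- theta[pack$idx[[id]]]
  for (id in names(pack$bidx)) model$intercepts[[id]] <- theta[pack$bidx[[id]]]
  model
}

# d(loss)/d(theta) for one structure given the symmetric d(loss)/dH.
# Uses couple_hamiltonian on G_H; stored components relate to the true
# block adjoints by a factor 2 except for diagonal-shell on-site and
# same-species keys, where the stored scaling already matches.
.accumulate_weight_grad <- function(gtheta, pack, model, structure, basis,
                                    feats, G_H) {
  gb <- couple_hamiltonian(G_H, structure, basis, model$config$cutoff)
  fun <- function(row, xi, addr) {
    wid <- .weight_id(row$key, row$lam, row$channel)
    if (is.null(pack$idx[[wid]])) return(invisible(NULL))
    cid <- .comp_id(row$key, row$lam, row$channel)
    g <- if (addr$where == "onsite") gb$onsite[[addr$atom]][[cid]]
         else gb$pairs[[addr$pid]][[cid]]
    if (is.null(g)) return(invisible(NULL))
    diag_shell <- (row$n1 == row$n2 && row$l1 == row$l2)
    scale <- if (diag_shell && row$kind %in% c("on", "ss")) 1 else 2
    dc <- scale * g
    gtheta[pack$idx[[wid]]] <<- gtheta[pack$idx[[wid]]] +
      as.vector(xi %*% dc)
    if (!is.null(pack$bidx[[wid]]))
      gtheta[pack$bidx[[wid]]] <<- gtheta[pack$bidx[[wid]]] + sum(dc)
  }
  .for_each_block(model$keys, structure, feats, fun)
  gtheta
}
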