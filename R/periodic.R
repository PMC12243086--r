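# Condensed-phase extension: real-space translated-cell Hamiltonians,
# Bloch summation to reciprocal space, band energies on k-grids, and
# delta-learning of small-basis -> large-basis band corrections.
#
# Translation labels t = (t1, t2, t3) are integers; R_t = t %*% lattice.
# k-points are fractional, so the Bloch phase is exp(2 pi i k . t).
# Hermiticity of H(k) rests on the stored invariant H(-t) = H(t)^T.

.t_key <- function(t) paste(t, collapse = ",")
.t_parse <- function(key) as.integer(strsplit(key, ",")[[1]])

#' Real-space extended-Hueckel Hamiltonian set for a periodic structure
#'
#' Builds S(t) from the closed-form Gaussian integrals between the home
#' cell and every translated cell within `cutoff`, and H(t) by the
#' Wolfsberg-Helmholz rule; both satisfy `M(-t) = M(t)^T` by construction.
#'
#' @param structure periodic structure (lattice required).
#' @param basis toy basis (or label).
#' @param K Wolfsberg-Helmholz constant.
#' @param cutoff interaction range (a.u.): translations whose closest
#'   atom pair exceeds it are dropped.
#' @return list with `H` and `S` (named lists keyed `"t1,t2,t3"`),
#'   `lattice`, `n_electrons`, `ao_map`, `basis`.
#' @export
periodic_hueckel <- function(structure, basis = "toy-min", K = 1.75,
                             cutoff = 8) {
  if (is.null(structure$lattice)) stop("structure must carry a lattice")
  if (is.character(basis)) basis <- toy_basis(basis, unique(structure$species))
  ao <- build_ao_index(structure, basis)
  h <- .onsite_vector(structure, basis, ao)
  n <- n_atoms(structure)
  imgs <- .lattice_images(structure$lattice, cutoff)
  Hs <- list(); Ss <- list()
  for (r in seq_len(nrow(imgs))) {
    t <- imgs[r, ]
    shift <- as.vector(t %*% structure$lattice)
    dmin <- min(vapply(seq_len(n), function(i)
      min(sqrt(rowSums((sweep(structure$positions, 2,
                              structure$positions[i, ] - shift))^2))), 0))
    if (dmin >= cutoff) next
    St <- .cross_overlap(structure, basis, shift)
    Ht <- 0.5 * K * outer(h, h, "+") * St
    if (all(t == 0)) diag(Ht) <- h
    Hs[[.t_key(t)]] <- Ht
    Ss[[.t_key(t)]] <- St
  }
  list(H = Hs, S = Ss, lattice = structure$lattice,
       n_electrons = electron_count(structure, basis), ao_map = ao,
       basis = basis)
}

# overlap block between home-cell AOs and AOs translated by `shift`
.cross_overlap <- function(structure, basis, shift) {
  if (all(shift == 0)) return(gaussian_integrals(structure, basis)$S)
  n <- n_atoms(structure)
  both <- structure_new(c(structure$species, structure$species),
                        rbind(structure$positions,
                              sweep(structure$positions, 2, -shift)),
                        unit = "bohr", id = "cross")
  S2 <- gaussian_integrals(both, basis)$S
  d <- nrow(S2) / 2
  S2[seq_len(d), d + seq_len(d), drop = FALSE]
}

#' Bloch summation
#'
#' `H(k) = sum_t H(t) exp(2 pi i k . t)` (k fractional). Errors if the
#' t = 0 term is missing; warns-by-error if the stored set violates
#' `H(-t) = H(t)^T` beyond 1e-10, which would break hermiticity.
#'
#' @param mats named list of real matrices keyed `"t1,t2,t3"`.
#' @param k fractional 3-vector.
#' @return complex hermitian matrix.
#' @export
bloch_sum <- function(mats, k) {
  if (is.null(mats[[.t_key(c(0, 0, 0))]])) stop("t = 0 matrix missing")
  for (key in names(mats)) {
    t <- .t_parse(key)
    mneg <- mats[[.t_key(-t)]]
    if (is.null(mneg)) mneg <- matrix(0, nrow(mats[[key]]), ncol(mats[[key]]))
    if (max(abs(t(mneg) - mats[[key]])) > 1e-10)
      stop("stored set violates M(-t) = M(t)^T at t = (", key, ")")
  }
  d <- nrow(mats[[1]])
  Hk <- matrix(0 + 0i, d, d)
  for (key in names(mats)) {
    t <- .t_parse(key)
    Hk <- Hk + mats[[key]] * exp(2i * pi * sum(k * t))
  }
  (Hk + Conj(t(Hk))) / 2
}

# complex hermitian generalized eigensolve (Loewdin route)
.solve_k <- function(Hk, Sk, kname = "") {
  es <- eigen(Sk, symmetric = TRUE)
  if (min(es$values) <= 1e-10)
    stop("S(k) not positive definite at k = ", kname)
  W <- es$vectors %*% (t(Conj(es$vectors)) / sqrt(es$values))
  eh <- eigen((W %*% Hk %*% Conj(t(W)) +
               Conj(t(W %*% Hk %*% Conj(t(W))))) / 2, symmetric = TRUE)
  ord <- order(eh$values)
  list(eps = eh$values[ord], C = W %*% eh$vectors[, ord, drop = FALSE])
}

#' Band energies on a set of k-points
#'
#' Diagonalizes the Bloch-summed generalized problem at each k and keeps
#' the lowest `n_bands` energies.
#'
#' @param hset,sset named H(t) / S(t) lists (e.g. from
#'   [periodic_hueckel()]).
#' @param k_points matrix of fractional k (rows), or vector for one k.
#' @param n_bands number of bands kept; defaults to all. The
#'   occupied-plus-a-few rule of band training is obtained by passing
#'   `n_occ + k`.
#' @param n_electrons electrons per cell (for the Fermi estimate).
#' @return list (`effham_bands`): `k_points`, `energies` (nk x n_bands,
#'   ascending per row), `fermi` (max occupied energy, if n_electrons
#'   given).
#' @export
band_energies <- function(hset, sset, k_points, n_bands = NULL,
                          n_electrons = NULL) {
  if (is.null(dim(k_points))) k_points <- matrix(k_points, nrow = 1)
  d <- nrow(hset[[1]])
  if (is.null(n_bands)) n_bands <- d
  if (n_bands > d) stop("n_bands exceeds the AO dimension")
  E <- matrix(0, nrow(k_points), n_bands)
  for (r in seq_len(nrow(k_points))) {
    k <- k_points[r, ]
    sol <- .solve_k(bloch_sum(hset, k), bloch_sum(sset, k),
                    paste(signif(k, 6), collapse = " "))
    E[r, ] <- sol$eps[seq_len(n_bands)]
  }
  fermi <- NULL
  if (!is.null(n_electrons)) {
    n_occ <- n_electrons / 2
    if (n_occ >= 1 && n_occ <= n_bands) fermi <- max(E[, n_occ])
  }
  out <- list(k_points = k_points, energies = E, fermi = fermi)
  class(out) <- "effham_bands"
  out
}

#' Band-energy corrections between two calculations
#'
#' `reference - baseline` on matched (band index, k) after sorting; the
#' deterministic sorted-index matching does not attempt crossing
#' resolution.
#'
#' @param baseline,reference `effham_bands` on identical k-grids.
#' @return matrix of corrections (nk x n_ref_bands).
#' @export
delta_targets <- function(baseline, reference) {
  if (!isTRUE(all.equal(baseline$k_points, reference$k_points)))
    stop("k-grids differ between baseline and reference")
  nb <- ncol(reference$energies)
  if (ncol(baseline$energies) < nb)
    stop("baseline keeps fewer bands than the reference")
  reference$energies - baseline$energies[, seq_len(nb), drop = FALSE]
}

#' Parse a k-path file
#'
#' Plain text: one fractional k per line, three numbers plus an optional
#' label; `#` comments allowed.
#' @param path file path.
#' @return list with `k_points` matrix and `labels`.
#' @export
read_kpath <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  ks <- list(); labs <- character(0)
  for (ln in lines) {
    tk <- strsplit(ln, "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tk[1:3]))
    if (any(is.na(v))) stop("malformed k-path line: ", ln)
    ks[[length(ks) + 1]] <- v
    labs <- c(labs, if (length(tk) > 3) tk[4] else "")
  }
  list(k_points = do.call(rbind, ks), labels = labs)
}

# ---- periodic block model (delta-learning) ------------------------------

# canonical periodic pair table: entries (i, j, t) with t > 0
# lexicographically, or t = 0 and i < j; species-ordered first atom.
.periodic_pair_table <- function(structure, species_order, cutoff) {
  nl <- neighbor_list(structure, cutoff)
  rows <- list()
  for (r in seq_len(nrow(nl))) {
    i <- nl$i[r]; j <- nl$j[r]; t <- c(nl$t1[r], nl$t2[r], nl$t3[r])
    si <- match(structure$species[i], species_order)
    sj <- match(structure$species[j], species_order)
    canonical <- if (si != sj) si < sj
      else if (any(t != 0)) {
        nz <- which(t != 0)[1]; t[nz] > 0
      } else i < j
    if (!canonical) next
    rows[[length(rows) + 1]] <-
      data.frame(first = i, second = j, t1 = t[1], t2 = t[2], t3 = t[3],
                 d1 = nl$d1[r], d2 = nl$d2[r], d3 = nl$d3[r])
  }
  if (length(rows) == 0)
    return(data.frame(first = integer(0), second = integer(0),
                      t1 = integer(0), t2 = integer(0), t3 = integer(0),
                      d1 = numeric(0), d2 = numeric(0), d3 = numeric(0)))
  unique(do.call(rbind, rows))
}

#' Featurize a periodic structure for the delta block model
#'
#' Periodic analogue of [featurize_structure()]: densities include lattice
#' images, pairs are (home atom, translated atom) within the cutoff.
#' @inheritParams featurize_structure
#' @export
featurize_periodic <- function(structure, basis, config) {
  keys <- model_keys(basis, unique(structure$species))
  sl <- unique(keys[, c("sigma", "lam")])
  coeffs <- density_expansion(structure, config)
  pt <- .periodic_pair_table(structure, names(basis$species), config$cutoff)
  onsite <- rep(list(list()), n_atoms(structure))
  pair_fwd <- rep(list(list()), nrow(pt))
  pair_bwd <- rep(list(list()), nrow(pt))
  for (r in seq_len(nrow(sl))) {
    sig <- sl$sigma[r]; lam <- sl$lam[r]
    id <- paste(sig, lam, sep = "|")
    af <- atom_centered_lambda_features(structure, config, lam, sig, coeffs)
    for (i in seq_along(af)) onsite[[i]][[id]] <- af[[i]]
    for (p in seq_len(nrow(pt))) {
      d <- c(pt$d1[p], pt$d2[p], pt$d3[p])
      pair_fwd[[p]][[id]] <- .pair_feature_one(config, d,
        coeffs[[pt$first[p]]], coeffs[[pt$second[p]]], lam, sig)
      pair_bwd[[p]][[id]] <- .pair_feature_one(config, -d,
        coeffs[[pt$second[p]]], coeffs[[pt$first[p]]], lam, sig)
    }
  }
  list(onsite = onsite, pair_fwd = pair_fwd, pair_bwd = pair_bwd,
       pair_table = pt, ao_map = build_ao_index(structure, basis),
       lattice = structure$lattice)
}

# iterate over periodic blocks, mirroring .for_each_block
.for_each_block_periodic <- function(keys, structure, feats, fun) {
  for (i in seq_len(n_atoms(structure))) {
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
    if (sp1 == sp2) {
      kk <- keys[keys$kind == "ss" & keys$sp1 == sp1, , drop = FALSE]
      for (r in seq_len(nrow(kk))) {
        row <- kk[r, ]
        id <- paste(row$sigma, row$lam, sep = "|")
        xf <- feats$pair_fwd[[p]][[id]]; xb <- feats$pair_bwd[[p]][[id]]
        xi <- if (row$channel == "+") (xf + xb) / sqrt(2) else (xf - xb) / sqrt(2)
        fun(row, xi, list(where = "pair", p = p))
      }
    } else {
      kk <- keys[keys$kind == "sd" & keys$sp1 == sp1 & keys$sp2 == sp2, ,
                 drop = FALSE]
      for (r in seq_len(nrow(kk))) {
        row <- kk[r, ]
        xi <- feats$pair_fwd[[p]][[paste(row$sigma, row$lam, sep = "|")]]
        fun(row, xi, list(where = "pair", p = p))
      }
    }
  }
  invisible(NULL)
}

# assemble the translated-cell correction set from predicted components
.assemble_periodic <- function(comp_onsite, comp_pairs, structure, basis,
                               feats) {
  ao <- feats$ao_map
  d <- nrow(ao)
  pt <- feats$pair_table
  tset <- unique(c("0,0,0",
                   vapply(seq_len(nrow(pt)), function(p)
                     .t_key(c(pt$t1[p], pt$t2[p], pt$t3[p])), ""),
                   vapply(seq_len(nrow(pt)), function(p)
                     .t_key(-c(pt$t1[p], pt$t2[p], pt$t3[p])), "")))
  Hset <- stats::setNames(rep(list(matrix(0, d, d)), length(tset)), tset)
  for (i in seq_len(n_atoms(structure))) {
    sp <- structure$species[i]
    shells <- basis$species[[sp]]$shells
    comp <- comp_onsite[[i]]
    for (a in seq_along(shells)) for (b in a:length(shells)) {
      s1 <- shells[[a]]; s2 <- shells[[b]]
      kid <- .key_id("on", sp, sp, s1, s2)
      cp <- list()
      for (lam in abs(s1[2] - s2[2]):(s1[2] + s2[2])) {
        v <- comp[[paste(kid, lam, sep = "|")]]
        cp[[as.character(lam)]] <- if (is.null(v)) numeric(2 * lam + 1) else v
      }
      blk <- decouple_block(cp, s1[2], s2[2])
      I <- .slice(ao, i, s1); J <- .slice(ao, i, s2)
      if (a == b) Hset[["0,0,0"]][I, J] <- (blk + t(blk)) / 2
      else {
        Hset[["0,0,0"]][I, J] <- blk
        Hset[["0,0,0"]][J, I] <- t(blk)
      }
    }
  }
  for (p in seq_len(nrow(pt))) {
    fi <- pt$first[p]; se <- pt$second[p]
    tp <- .t_key(c(pt$t1[p], pt$t2[p], pt$t3[p]))
    tm <- .t_key(-c(pt$t1[p], pt$t2[p], pt$t3[p]))
    sp1 <- structure$species[fi]; sp2 <- structure$species[se]
    comp <- comp_pairs[[p]]
    place <- function(blk, s1, s2, swap = FALSE) {
      # forward block lives in H(t)[first s1, second s2]
      I <- .slice(ao, if (swap) se else fi, s1)
      J <- .slice(ao, if (swap) fi else se, s2)
      tt <- if (swap) tm else tp
      to <- if (swap) tp else tm
      Hset[[tt]][I, J] <<- Hset[[tt]][I, J] + blk
      Hset[[to]][J, I] <<- Hset[[to]][J, I] + t(blk)
    }
    if (sp1 == sp2) {
      shells <- basis$species[[sp1]]$shells
      for (a in seq_along(shells)) for (b in a:length(shells)) {
        s1 <- shells[[a]]; s2 <- shells[[b]]
        kid <- .key_id("ss", sp1, sp2, s1, s2)
        fwd <- list(); bwd <- list()
        for (lam in abs(s1[2] - s2[2]):(s1[2] + s2[2])) {
          lc <- as.character(lam)
          vp <- comp[[paste(kid, lam, "+", sep = "|")]]
          vm <- comp[[paste(kid, lam, "-", sep = "|")]]
          if (is.null(vp)) vp <- numeric(2 * lam + 1)
          if (is.null(vm)) vm <- numeric(2 * lam + 1)
          fwd[[lc]] <- (vp + vm) / sqrt(2)
          bwd[[lc]] <- (vp - vm) / sqrt(2)
        }
        place(decouple_block(fwd, s1[2], s2[2]), s1, s2, swap = FALSE)
        if (a != b)
          place(decouple_block(bwd, s1[2], s2[2]), s1, s2, swap = TRUE)
      }
    } else {
      for (sa in basis$species[[sp1]]$shells)
        for (sb in basis$species[[sp2]]$shells) {
          kid <- .key_id("sd", sp1, sp2, sa, sb)
          cp <- list()
          for (lam in abs(sa[2] - sb[2]):(sa[2] + sb[2])) {
            v <- comp[[paste(kid, lam, sep = "|")]]
            cp[[as.character(lam)]] <- if (is.null(v)) numeric(2 * lam + 1) else v
          }
          place(decouple_block(cp, sa[2], sb[2]), sa, sb, swap = FALSE)
        }
    }
  }
  Hset
}

#' Predict a translated-cell correction set with a delta block model
#'
#' @param model `effham_block_model` over the periodic keys.
#' @param structure periodic structure.
#' @param basis model basis.
#' @param feats from [featurize_periodic()].
#' @return named list of Delta-H(t) matrices satisfying
#'   `M(-t) = M(t)^T`.
#' @export
predict_delta_set <- function(model, structure, basis, feats = NULL) {
  if (is.null(feats)) feats <- featurize_periodic(structure, basis, model$config)
  comp_onsite <- rep(list(list()), n_atoms(structure))
  comp_pairs <- rep(list(list()), nrow(feats$pair_table))
  fun <- function(row, xi, addr) {
    wid <- .weight_id(row$key, row$lam, row$channel)
    w <- model$weights[[wid]]
    if (is.null(w)) stop("model has no weights for block key ", wid)
    v <- as.vector(crossprod(xi, w))
    if (row$intercept && !is.null(model$intercepts[[wid]]))
      v <- v + model$intercepts[[wid]]
    cid <- .comp_id(row$key, row$lam, row$channel)
    if (addr$where == "onsite") comp_onsite[[addr$atom]][[cid]] <<- v
    else comp_pairs[[addr$p]][[cid]] <<- v
  }
  .for_each_block_periodic(model$keys, structure, feats, fun)
  .assemble_periodic(comp_onsite, comp_pairs, structure, basis, feats)
}

#' Zero-initialized delta block model
#'
#' @param basis model basis.
#' @param config descriptor configuration.
#' @param structure_example a periodic structure used to size the feature
#'   dimensions.
#' @export
zero_delta_model <- function(basis, config, structure_example) {
  keys <- model_keys(basis, unique(structure_example$species))
  feats <- featurize_periodic(structure_example, basis, config)
  weights <- list(); intercepts <- list()
  fun <- function(row, xi, addr) {
    wid <- .weight_id(row$key, row$lam, row$channel)
    if (is.null(weights[[wid]])) {
      weights[[wid]] <<- numeric(nrow(xi))
      if (row$intercept) intercepts[[wid]] <<- 0
    }
  }
  .for_each_block_periodic(keys, structure_example, feats, fun)
  out <- list(keys = keys, weights = weights, intercepts = intercepts,
              config = config, basis_label = basis$label, ridge = list())
  class(out) <- "effham_block_model"
  out
}

# band loss and weight gradient for one periodic sample
.band_loss_grad <- function(model, pack, sm, basis, n_bands, with_grad = TRUE) {
  dH <- predict_delta_set(model, sm$structure, basis, sm$feats)
  hset <- sm$baseline_H
  for (key in names(dH)) {
    base <- hset[[key]]
    if (is.null(base)) base <- matrix(0, nrow(dH[[key]]), ncol(dH[[key]]))
    hset[[key]] <- base + dH[[key]]
  }
  loss <- 0
  Gset <- if (with_grad)
    stats::setNames(rep(list(matrix(0, nrow(sm$feats$ao_map),
                                    nrow(sm$feats$ao_map))), length(dH)),
                    names(dH)) else NULL
  nk <- nrow(sm$k_train)
  for (r in seq_len(nk)) {
    k <- sm$k_train[r, ]
    sol <- .solve_k(bloch_sum(hset, k), bloch_sum(sm$baseline_S, k))
    res <- sol$eps[seq_len(n_bands)] - sm$ref_bands[r, seq_len(n_bands)]
    loss <- loss + mean(res^2)
    if (with_grad) {
      for (nb in seq_len(n_bands)) {
        c0 <- sol$C[, nb]
        gk <- 2 * res[nb] / (n_bands * nk) * (Conj(c0) %o% c0)
        for (key in names(Gset)) {
          t <- .t_parse(key)
          Gset[[key]] <- Gset[[key]] +
            Re(gk * exp(2i * pi * sum(k * t)))
        }
      }
    }
  }
  loss <- loss / nk
  if (!with_grad) return(list(loss = loss))
  # chain to weights: extract stored-component adjoints from Gset
  gtheta <- numeric(length(pack$theta))
  gb_on <- rep(list(list()), n_atoms(sm$structure))
  gb_pair <- rep(list(list()), nrow(sm$feats$pair_table))
  ao <- sm$feats$ao_map
  pt <- sm$feats$pair_table
  # on-site adjoints from G(0)
  G0 <- Gset[["0,0,0"]]
  for (i in seq_len(n_atoms(sm$structure))) {
    sp <- sm$structure$species[i]
    shells <- basis$species[[sp]]$shells
    for (a in seq_along(shells)) for (b in a:length(shells)) {
      s1 <- shells[[a]]; s2 <- shells[[b]]
      blk <- G0[.slice(ao, i, s1), .slice(ao, i, s2), drop = FALSE]
      cp <- couple_block(blk, s1[2], s2[2])
      kid <- .key_id("on", sp, sp, s1, s2)
      for (lam in names(cp)) {
        if (a == b && (-1)^as.integer(lam) == -1) next
        sc <- if (a == b) 1 else 2
        gb_on[[i]][[paste(kid, lam, sep = "|")]] <- sc * cp[[lam]]
      }
    }
  }
  for (p in seq_len(nrow(pt))) {
    fi <- pt$first[p]; se <- pt$second[p]
    tp <- .t_key(c(pt$t1[p], pt$t2[p], pt$t3[p]))
    tm <- .t_key(-c(pt$t1[p], pt$t2[p], pt$t3[p]))
    sp1 <- sm$structure$species[fi]; sp2 <- sm$structure$species[se]
    if (sp1 == sp2) {
      shells <- basis$species[[sp1]]$shells
      for (a in seq_along(shells)) for (b in a:length(shells)) {
        s1 <- shells[[a]]; s2 <- shells[[b]]
        kid <- .key_id("ss", sp1, sp2, s1, s2)
        gf <- couple_block(2 * Gset[[tp]][.slice(ao, fi, s1),
                                          .slice(ao, se, s2), drop = FALSE],
                           s1[2], s2[2])
        if (a == b) {
          for (lam in names(gf)) {
            ch <- if ((-1)^as.integer(lam) == 1) "+" else "-"
            gb_pair[[p]][[paste(kid, lam, ch, sep = "|")]] <-
              gf[[lam]] / sqrt(2)
          }
        } else {
          gbk <- couple_block(2 * Gset[[tm]][.slice(ao, se, s1),
                                             .slice(ao, fi, s2), drop = FALSE],
                              s1[2], s2[2])
          for (lam in names(gf)) {
            gb_pair[[p]][[paste(kid, lam, "+", sep = "|")]] <-
              (gf[[lam]] + gbk[[lam]]) / sqrt(2)
            gb_pair[[p]][[paste(kid, lam, "-", sep = "|")]] <-
              (gf[[lam]] - gbk[[lam]]) / sqrt(2)
          }
        }
      }
    } else {
      for (sa in basis$species[[sp1]]$shells)
        for (sb in basis$species[[sp2]]$shells) {
          kid <- .key_id("sd", sp1, sp2, sa, sb)
          cp <- couple_block(2 * Gset[[tp]][.slice(ao, fi, sa),
                                            .slice(ao, se, sb), drop = FALSE],
                             sa[2], sb[2])
          for (lam in names(cp))
            gb_pair[[p]][[paste(kid, lam, sep = "|")]] <- cp[[lam]]
        }
    }
  }
  fun <- function(row, xi, addr) {
    wid <- .weight_id(row$key, row$lam, row$channel)
    if (is.null(pack$idx[[wid]])) return(invisible(NULL))
    cid <- .comp_id(row$key, row$lam, row$channel)
    g <- if (addr$where == "onsite") gb_on[[addr$atom]][[cid]]
         else gb_pair[[addr$p]][[cid]]
    if (is.null(g)) return(invisible(NULL))
    gtheta[pack$idx[[wid]]] <<- gtheta[pack$idx[[wid]]] + as.vector(xi %*% g)
    if (!is.null(pack$bidx[[wid]]))
      gtheta[pack$bidx[[wid]]] <<- gtheta[pack$bidx[[wid]]] + sum(g)
  }
  .for_each_block_periodic(model$keys, sm$structure, sm$feats, fun)
  list(loss = loss, grad = gtheta)
}

#' Delta-learning of band corrections on a toy solid
#'
#' Trains a zero-initialized block model to predict the translated-cell
#' correction Delta-H(t) that, added to the small-basis baseline, brings
#' its band energies to the large-basis reference at the training
#' k-points.
#'
#' @param model starting delta model (e.g. [zero_delta_model()]).
#' @param samples list of per-structure lists with fields `structure`,
#'   `feats` ([featurize_periodic()]), `baseline_H`, `baseline_S`,
#'   `k_train` (matrix), `ref_bands` (nk x n_bands reference energies at
#'   `k_train`).
#' @param basis model basis.
#' @param n_bands number of (lowest) bands entering the loss.
#' @param n_iter L-BFGS iteration budget.
#' @return list with the trained `model` and the final training `loss`.
#' @export
finetune_delta_bands <- function(model, samples, basis, n_bands,
                                 n_iter = 150) {
  pack <- .theta_pack(model)
  fn <- function(th) {
    m <- .theta_unpack(model, pack, th)
    mean(vapply(samples, function(sm)
      .band_loss_grad(m, pack, sm, basis, n_bands, with_grad = FALSE)$loss, 0))
  }
  gr <- function(th) {
    m <- .theta_unpack(model, pack, th)
    g <- numeric(length(th))
    for (sm in samples)
      g <- g + .band_loss_grad(m, pack, sm, basis, n_bands)$grad
    g / length(samples)
  }
  opt <- stats::optim(pack$theta, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = n_iter))
  list(model = .theta_unpack(model, pack, opt$par), loss = opt$value)
}
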