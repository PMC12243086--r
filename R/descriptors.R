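# Equivariant atom-centered and two-center pair descriptors.
#
# Neighbor densities are expanded on a Loewdin-orthonormalized Gaussian
# radial grid times real spherical harmonics with a smooth cosine cutoff.
# Lambda-features are Clebsch-Gordan products of two expansions on the same
# center (atom features) or of the two-center displacement expansion with
# either endpoint's density (pair features), restricted to a requested
# (sigma, lambda) channel; sigma = (-1)^(l1 + l2 + lambda) for a product of
# l1 and l2 channels, so sigma = +1 collects proper-tensor behavior.

#' Descriptor configuration
#'
#' @param species character vector fixing the (global) species channel
#'   order; structures may contain any subset.
#' @param cutoff radial cutoff (a.u.).
#' @param n_max number of radial functions.
#' @param l_max maximum expansion angular momentum; must reach at least
#'   twice the largest basis l that will be modeled.
#' @param sigma_r Gaussian smearing width of the radial functions (a.u.);
#'   defaults to the grid spacing `cutoff / n_max` so the functions overlap.
#' @return object of class `effham_descriptor_config`.
#' @export
descriptor_config <- function(species, cutoff = 5, n_max = 4, l_max = 4,
                              sigma_r = NULL) {
  stopifnot(cutoff > 0, n_max >= 1, l_max >= 0)
  if (is.null(sigma_r)) sigma_r <- cutoff / n_max
  centers <- seq(0, cutoff, length.out = n_max)
  # Loewdin orthonormalization of the radial Gaussians on [0, cutoff]
  ng <- 64
  gl <- .gauss_legendre(ng, 0, cutoff)
  Phi <- vapply(centers, function(c0) exp(-(gl$x - c0)^2 / (2 * sigma_r^2)),
                numeric(ng))
  G <- t(Phi) %*% (gl$w * Phi)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(eg$values) < 1e-12)
    stop("radial basis nearly dependent; reduce n_max or sigma_r")
  Gih <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  out <- list(species = species, cutoff = cutoff, n_max = n_max,
              l_max = l_max, sigma_r = sigma_r, centers = centers,
              lowdin = Gih)
  class(out) <- "effham_descriptor_config"
  out
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
.gauss_legendre <- function(n, a, b) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# orthonormalized radial functions times smooth cutoff, at distances r
.radial_cut <- function(config, r) {
  raw <- vapply(config$centers,
                function(c0) exp(-(r - c0)^2 / (2 * config$sigma_r^2)),
                numeric(length(r)))
  if (length(r) == 1) raw <- matrix(raw, 1)
  fc <- ifelse(r < config$cutoff, 0.5 * (1 + cos(pi * r / config$cutoff)), 0)
  (raw %*% config$lowdin) * fc
}

# lattice image translations reaching within `cutoff` of the home cell
.lattice_images <- function(lattice, cutoff) {
  Linv <- solve(lattice)
  nmax <- integer(3)
  for (a in 1:3) nmax[a] <- ceiling(cutoff * sqrt(sum(Linv[, a]^2))) + 1L
  g <- expand.grid(t1 = -nmax[1]:nmax[1], t2 = -nmax[2]:nmax[2],
                   t3 = -nmax[3]:nmax[3])
  as.matrix(g)
}

#' Neighbor list within the descriptor cutoff
#'
#' Ordered pairs (i, j) with 0 < r_ij < cutoff; for periodic structures the
#' pair list includes lattice images (columns t1..t3 give the translation of
#' atom j).
#' @param structure a structure.
#' @param cutoff radial cutoff (a.u.).
#' @return data.frame with i, j, t1, t2, t3, r and the displacement d1..d3
#'   (from i to j).
#' @export
neighbor_list <- function(structure, cutoff) {
  pos <- structure$positions
  n <- nrow(pos)
  rows <- list()
  if (is.null(structure$lattice)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(d^2))
      if (r < cutoff)
        rows[[length(rows) + 1]] <- c(i, j, 0, 0, 0, r, d)
    }
  } else {
    imgs <- .lattice_images(structure$lattice, cutoff)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      for (k in seq_len(nrow(imgs))) {
        t <- imgs[k, ]
        if (i == j && all(t == 0)) next
        d <- pos[j, ] + as.vector(t %*% structure$lattice) - pos[i, ]
        r <- sqrt(sum(d^2))
        if (r < cutoff)
          rows[[length(rows) + 1]] <- c(i, j, t, r, d)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), j = integer(0), t1 = integer(0),
                      t2 = integer(0), t3 = integer(0), r = numeric(0),
                      d1 = numeric(0), d2 = numeric(0), d3 = numeric(0)))
  m <- do.call(rbind, rows)
  colnames(m) <- c("i", "j", "t1", "t2", "t3", "r", "d1", "d2", "d3")
  as.data.frame(m)
}

#' Atom-centered neighbor-density expansion
#'
#' `c_i[a, n, l, m] = sum_{j of species a within cutoff}
#'   R_n(r_ij) Y_lm(r_hat_ij) f_cut(r_ij)`.
#' An isolated atom has all coefficients zero.
#'
#' @param structure a structure.
#' @param config a [descriptor_config()] covering all species present.
#' @return list per atom; each atom a list over l (index l+1) of matrices
#'   with `length(species) * n_max` rows (species-major channel order) and
#'   `2l+1` columns.
#' @export
density_expansion <- function(structure, config) {
  missing_sp <- setdiff(unique(structure$species), config$species)
  if (length(missing_sp) > 0)
    stop("config species do not cover: ", paste(missing_sp, collapse = ", "))
  n <- n_atoms(structure)
  nsp <- length(config$species)
  empty <- lapply(0:config$l_max, function(l)
    matrix(0, nsp * config$n_max, 2 * l + 1))
  out <- rep(list(empty), n)
  nl <- neighbor_list(structure, config$cutoff)
  if (nrow(nl) == 0) return(out)
  R <- .radial_cut(config, nl$r)
  U <- rbind(nl$d1, nl$d2, nl$d3) / rep(nl$r, each = 3)
  Y <- lapply(0:config$l_max, function(l) real_spherical_harmonics(l, U))
  for (k in seq_len(nrow(nl))) {
    i <- nl$i[k]
    sp_idx <- match(structure$species[nl$j[k]], config$species)
    rows <- (sp_idx - 1) * config$n_max + seq_len(config$n_max)
    for (l in 0:config$l_max) {
      out[[i]][[l + 1]][rows, ] <- out[[i]][[l + 1]][rows, ] +
        outer(R[k, ], Y[[l + 1]][, k])
    }
  }
  out
}

# two-center expansion of a single displacement d (length r):
# g[n, l, m] = R_n(r) Y_lm(d_hat) f_cut(r); zero beyond cutoff.
.pair_expansion <- function(config, d) {
  r <- sqrt(sum(d^2))
  out <- lapply(0:config$l_max, function(l) matrix(0, config$n_max, 2 * l + 1))
  if (r >= config$cutoff || r == 0) return(out)
  R <- .radial_cut(config, r)
  u <- d / r
  for (l in 0:config$l_max)
    out[[l + 1]] <- outer(as.vector(R), real_spherical_harmonics(l, u))
  out
}

# append the constant scalar channel (value 1 at l = 0) to a coefficient set
.augment_const <- function(coeffs) {
  coeffs[[1]] <- rbind(coeffs[[1]], 1)
  coeffs
}

# CG product of two per-l coefficient sets restricted to (sigma, lambda):
# returns matrix n_feat x (2 lambda + 1); zero rows if no channel couples.
.couple_products <- function(A, B, lam, sigma, l_max) {
  blocks <- list()
  for (l1 in 0:l_max) for (l2 in 0:l_max) {
    if (lam < abs(l1 - l2) || lam > l1 + l2) next
    if ((-1)^(l1 + l2 + lam) != sigma) next
    A1 <- A[[l1 + 1]]; B2 <- B[[l2 + 1]]
    n1 <- nrow(A1); n2 <- nrow(B2)
    if (n1 == 0 || n2 == 0) next
    Tm <- real_cg(l1, l2, lam)
    out <- matrix(0, n1 * n2, 2 * lam + 1)
    for (mu in seq_len(2 * lam + 1)) {
      Tmu <- matrix(Tm[, mu], 2 * l1 + 1, 2 * l2 + 1)
      out[, mu] <- as.vector(A1 %*% Tmu %*% t(B2))
    }
    blocks[[length(blocks) + 1]] <- out
  }
  if (length(blocks) == 0) return(matrix(0, 0, 2 * lam + 1))
  do.call(rbind, blocks)
}

#' Atom-centered lambda-features
#'
#' Symmetry-adapted products of the neighbor-density expansion with itself
#' (plus a constant channel, so the bare density enters linearly),
#' restricted to inversion parity `sigma` and rotation order `lambda`.
#' A request with no contributing (l, l') channel yields a 0-row matrix
#' flagged with `attr(, "empty")`.
#'
#' @param structure a structure.
#' @param config a [descriptor_config()].
#' @param lam,sigma target irrep labels; `lam <= 2 * l_max`.
#' @param coeffs optional precomputed [density_expansion()].
#' @return list per atom of feature matrices `n_feat x (2 lam + 1)`.
#' @export
atom_centered_lambda_features <- function(structure, config, lam, sigma,
                                          coeffs = NULL) {
  if (lam > 2 * config$l_max) stop("lambda exceeds 2 * l_max")
  if (is.null(coeffs)) coeffs <- density_expansion(structure, config)
  lapply(coeffs, function(ci) {
    a <- .augment_const(ci)
    f <- .couple_products(a, a, lam, sigma, config$l_max)
    if (nrow(f) == 0) attr(f, "empty") <- TRUE
    f
  })
}

#' Equivariant two-center pair features
#'
#' For each ordered pair (i, j) within the cutoff, couples the two-center
#' displacement expansion g_ij with the (constant-augmented) neighbor
#' densities of both endpoints and restricts to (sigma, lambda). Pairs
#' beyond the cutoff are absent. For same-species pairs the symmetric /
#' antisymmetric channels are the combinations
#' `xi_pm = (xi_ij pm xi_ji) / sqrt(2)` of these ordered features.
#'
#' @inheritParams atom_centered_lambda_features
#' @return named list keyed `"i:j"` of feature matrices.
#' @export
pair_features <- function(structure, config, lam, sigma, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- density_expansion(structure, config)
  nl <- neighbor_list(structure, config$cutoff)
  out <- list()
  if (nrow(nl) == 0) return(out)
  mol <- nl[nl$t1 == 0 & nl$t2 == 0 & nl$t3 == 0, , drop = FALSE]
  for (k in seq_len(nrow(mol))) {
    i <- mol$i[k]; j <- mol$j[k]
    d <- c(mol$d1[k], mol$d2[k], mol$d3[k])
    out[[paste0(i, ":", j)]] <-
      .pair_feature_one(config, d, coeffs[[i]], coeffs[[j]], lam, sigma)
  }
  out
}

# Ordered pair feature from explicit displacement and endpoint
# coefficients. The constant channel is appended only on the i side, so the
# bare two-center expansion enters the feature set exactly once.
.pair_feature_one <- function(config, d, ci, cj, lam, sigma) {
  g <- .pair_expansion(config, d)
  rbind(.couple_products(g, .augment_const(ci), lam, sigma, config$l_max),
        .couple_products(g, cj, lam, sigma, config$l_max))
}
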