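# Synthetic reference engine: paired toy Gaussian bases, closed-form
# overlap / position integrals for s and p shells, and extended-Hueckel
# reference Hamiltonians whose derived properties feed every other module.
#
# The Hueckel form H = K/2 (h_eta + h_nu) S_eta_nu (Wolfsberg-Helmholz) is
# chosen because it yields hermitian, equivariant, distance-decaying
# Hamiltonians from the overlap alone, in closed form, with a genuine
# basis-set gap between the paired "toy-min" and "toy-big" bases.

.toy_species <- list(
  H = list(exps = 0.80, onsite = -0.50, ls = 0L, ns = 1L, Q = 1, valence = 1),
  C = list(exps = c(0.55, 0.50), onsite = c(-0.70, -0.40), ls = c(0L, 1L),
           ns = c(2L, 2L), Q = 4, valence = 4),
  N = list(exps = c(0.70, 0.65), onsite = c(-0.95, -0.50), ls = c(0L, 1L),
           ns = c(2L, 2L), Q = 5, valence = 5),
  O = list(exps = c(0.95, 0.85), onsite = c(-1.20, -0.60), ls = c(0L, 1L),
           ns = c(2L, 2L), Q = 6, valence = 6)
)

#' Paired toy Gaussian bases
#'
#' `"toy-min"` is a minimal single-Gaussian valence basis (H: 1s; C/N/O:
#' 2s, 2p). `"toy-big"` splits every shell into two even-tempered exponents
#' (ratio 2.5) with the diffuse copy shifted up in on-site energy, creating
#' a genuine, computable basis-set gap against `"toy-min"` so that upscaled
#' training is exercisable without external data.
#'
#' @param label `"toy-min"` or `"toy-big"`.
#' @param species which species to include.
#' @return a [basis_spec()] whose per-shell `exponents` and `onsite`
#'   energies drive the fixture integrals and Hueckel Hamiltonians.
#' @export
toy_basis <- function(label = c("toy-min", "toy-big"),
                      species = names(.toy_species)) {
  label <- match.arg(label)
  defs <- list()
  for (sp in species) {
    d <- .toy_species[[sp]]
    if (label == "toy-min") {
      shells <- mapply(function(n, l) c(n, l), d$ns, d$ls, SIMPLIFY = FALSE)
      defs[[sp]] <- list(shells = shells, Q = d$Q, valence = d$valence,
                         exponents = d$exps, onsite = d$onsite)
    } else {
      shells <- list(); exps <- numeric(0); ons <- numeric(0)
      for (k in seq_along(d$ls)) {
        shells <- c(shells, list(c(d$ns[k], d$ls[k]), c(d$ns[k] + 1L, d$ls[k])))
        exps <- c(exps, d$exps[k] * sqrt(2.5), d$exps[k] / sqrt(2.5))
        ons <- c(ons, d$onsite[k], d$onsite[k] + 0.15)
      }
      defs[[sp]] <- list(shells = shells, Q = d$Q, valence = d$valence,
                         exponents = exps, onsite = ons)
    }
  }
  basis_spec(defs, label = label)
}

# 1D Obara-Saika overlap table S[i+1, j+1], i <= imax, j <= jmax, plus the
# first moment <i| x |j> about the origin.
.os_1d <- function(a, Ax, b, Bx, imax, jmax) {
  p <- a + b
  P <- (a * Ax + b * Bx) / p
  S <- matrix(0, imax + 2, jmax + 2)
  S[1, 1] <- sqrt(pi / p) * exp(-a * b / p * (Ax - Bx)^2)
  for (i in 0:(imax + 1)) for (j in 0:(jmax + 1)) {
    if (i == 0 && j == 0) next
    if (i > 0) {
      v <- (P - Ax) * S[i, j + 1]
      if (i > 1) v <- v + (i - 1) / (2 * p) * S[i - 1, j + 1]
      if (j > 0) v <- v + j / (2 * p) * S[i, j]
      S[i + 1, j + 1] <- v
    } else {
      v <- (P - Bx) * S[1, j]
      if (j > 1) v <- v + (j - 1) / (2 * p) * S[1, j - 1]
      S[1, j + 1] <- v
    }
  }
  D <- matrix(0, imax + 1, jmax + 1)
  for (i in 0:imax) for (j in 0:jmax)
    D[i + 1, j + 1] <- S[i + 2, j + 1] + Ax * S[i + 1, j + 1]
  list(S = S[1:(imax + 1), 1:(jmax + 1), drop = FALSE], D = D)
}

# Cartesian powers of the real shell components in AO order.
# l = 0: (0,0,0); l = 1, mu = (-1,0,1) ~ (y, z, x).
.shell_powers <- function(l) {
  if (l == 0) return(matrix(0L, 1, 3))
  if (l == 1) return(rbind(c(0L, 1L, 0L), c(0L, 0L, 1L), c(1L, 0L, 0L)))
  stop("toy Gaussian integrals support l <= 1 (s, p shells) only; got l = ", l)
}

#' Closed-form Gaussian overlap and position-operator integrals
#'
#' Builds S and the three X_a = <eta| r_a |nu> matrices for single-Gaussian
#' s/p shells, normalized so diag(S) = 1. The translation identity
#' `X(r + d) = X(r) + d S` holds exactly by construction.
#'
#' @param structure a structure.
#' @param basis a toy basis carrying per-shell `exponents`.
#' @return list with `S` and `X` (list of three matrices).
#' @export
gaussian_integrals <- function(structure, basis) {
  ao <- build_ao_index(structure, basis)
  d <- nrow(ao)
  exps <- numeric(d)
  pw <- matrix(0L, d, 3)
  for (r in seq_len(d)) {
    spdef <- basis$species[[ao$species[r]]]
    shi <- which(vapply(spdef$shells, function(s)
      s[1] == ao$n[r] && s[2] == ao$l[r], TRUE))
    if (is.null(spdef$exponents))
      stop("basis '", basis$label, "' carries no Gaussian exponents")
    exps[r] <- spdef$exponents[shi]
    pw[r, ] <- .shell_powers(ao$l[r])[ao$m[r] + ao$l[r] + 1, ]
  }
  pos <- structure$positions
  S <- matrix(0, d, d)
  X <- list(matrix(0, d, d), matrix(0, d, d), matrix(0, d, d))
  for (r in seq_len(d)) for (c in r:d) {
    A <- pos[ao$atom[r], ]; B <- pos[ao$atom[c], ]
    s1 <- vector("list", 3)
    for (ax in 1:3)
      s1[[ax]] <- .os_1d(exps[r], A[ax], exps[c], B[ax], pw[r, ax], pw[c, ax])
    ov <- prod(vapply(1:3, function(ax)
      s1[[ax]]$S[pw[r, ax] + 1, pw[c, ax] + 1], 0))
    S[r, c] <- S[c, r] <- ov
    for (a in 1:3) {
      v <- s1[[a]]$D[pw[r, a] + 1, pw[c, a] + 1]
      for (ax in setdiff(1:3, a))
        v <- v * s1[[ax]]$S[pw[r, ax] + 1, pw[c, ax] + 1]
      X[[a]][r, c] <- X[[a]][c, r] <- v
    }
  }
  nrm <- 1 / sqrt(diag(S))
  S <- S * outer(nrm, nrm)
  for (a in 1:3) X[[a]] <- X[[a]] * outer(nrm, nrm)
  list(S = S, X = X, ao_map = ao)
}

# on-site energy vector h_eta for a structure under a toy basis
.onsite_vector <- function(structure, basis, ao = build_ao_index(structure, basis)) {
  h <- numeric(nrow(ao))
  for (r in seq_len(nrow(ao))) {
    spdef <- basis$species[[ao$species[r]]]
    shi <- which(vapply(spdef$shells, function(s)
      s[1] == ao$n[r] && s[2] == ao$l[r], TRUE))
    h[r] <- spdef$onsite[shi]
  }
  h
}

#' Extended-Hueckel reference record
#'
#' Deterministic synthetic reference: `H_eta_eta = h_eta` on the diagonal
#' and `H_eta_nu = K/2 (h_eta + h_nu) S_eta_nu` elsewhere
#' (Wolfsberg-Helmholz), with S and X from [gaussian_integrals()]. All
#' derived properties (MO energies, dipole, polarizability, Mayer bond
#' orders, gap) are computed through the package's own property layer and
#' stored in the record.
#'
#' @param structure a structure.
#' @param basis a toy basis (or label `"toy-min"` / `"toy-big"`).
#' @param K Wolfsberg-Helmholz constant (default 1.75).
#' @param with_alpha store the polarizability (requires a nondegenerate
#'   frontier).
#' @return a [reference_record()].
#' @export
hueckel_record <- function(structure, basis = "toy-min", K = 1.75,
                           with_alpha = TRUE) {
  if (is.character(basis)) basis <- toy_basis(basis, unique(structure$species))
  gi <- gaussian_integrals(structure, basis)
  ao <- gi$ao_map
  h <- .onsite_vector(structure, basis, ao)
  H <- 0.5 * K * outer(h, h, "+") * gi$S
  diag(H) <- h
  nel <- electron_count(structure, basis)
  if (nel %% 2 != 0)
    stop("odd valence electron count (", nel, ") for structure ",
         structure$id, ": closed-shell fixtures only")
  props <- derived_properties(H, gi$S, gi$X, nel, structure, basis, ao,
                              with_alpha = with_alpha)
  reference_record(structure$id, basis$label, H, gi$S, gi$X, nel,
                   props = list(eps = props$eps, mu = props$mu,
                                alpha = props$alpha,
                                bond_order = props$bond_order,
                                gap = props$gap),
                   ao_order = ao_fingerprint(ao))
}
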