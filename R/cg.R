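# Real Clebsch-Gordan coupling, block (de)coupling, and Cartesian <-> irrep
# decomposition of rank-1 and symmetric rank-2 tensors.
#
# The real coupling matrices are built exactly from complex Clebsch-Gordan
# coefficients (Racah's closed form) conjugated by the real <-> complex
# spherical-harmonic unitary; coefficient matrices that come out purely
# imaginary (parity-odd couplings) are rotated onto the real axis. The
# resulting stacked transform over all admissible lambda is orthogonal, so
# coupling preserves Frobenius norms and decoupling is its exact inverse.

.cg_cache <- new.env(parent = emptyenv())

.lf <- function(n) lgamma(n + 1)

# Complex Clebsch-Gordan coefficient <j1 m1; j2 m2 | J M> (Condon-Shortley).
.cg_complex <- function(j1, m1, j2, m2, J, M) {
  if (M != m1 + m2) return(0)
  if (J < abs(j1 - j2) || J > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(M) > J) return(0)
  pref <- 0.5 * (log(2 * J + 1) + .lf(J + j1 - j2) + .lf(J - j1 + j2) +
                 .lf(j1 + j2 - J) - .lf(j1 + j2 + J + 1) + .lf(J + M) +
                 .lf(J - M) + .lf(j1 - m1) + .lf(j1 + m1) + .lf(j2 - m2) +
                 .lf(j2 + m2))
  kmin <- max(0, j2 - J - m1, j1 - J + m2)
  kmax <- min(j1 + j2 - J, j1 - m1, j2 + m2)
  s <- 0
  for (k in kmin:kmax) {
    s <- s + (-1)^k * exp(pref - (.lf(k) + .lf(j1 + j2 - J - k) +
             .lf(j1 - m1 - k) + .lf(j2 + m2 - k) + .lf(J - j2 + m1 + k) +
             .lf(J - j1 - m2 + k)))
  }
  s
}

# Unitary B with S_{l,mu} = sum_m B[mu, m] Y_l^m (complex Y with CS phase).
.real_complex_unitary <- function(l) {
  B <- matrix(0 + 0i, 2 * l + 1, 2 * l + 1)
  for (mu in (-l):l) {
    i <- mu + l + 1
    if (mu == 0) {
      B[i, l + 1] <- 1
    } else if (mu > 0) {
      B[i, mu + l + 1] <- (-1)^mu / sqrt(2)
      B[i, -mu + l + 1] <- 1 / sqrt(2)
    } else {
      m <- -mu
      B[i, m + l + 1] <- -1i * (-1)^m / sqrt(2)
      B[i, -m + l + 1] <- 1i / sqrt(2)
    }
  }
  B
}

#' Real Clebsch-Gordan coupling matrix
#'
#' Returns the matrix T of shape `(2l+1)(2lp+1) x (2lam+1)` that couples a
#' real-basis pair tensor into its real lambda-components: for a block B of
#' shape `(2l+1) x (2lp+1)` (row index m, column index m'), the coupled
#' component vector is `t(T) %*% as.vector(B)` (column-major, m fastest).
#' Stacking T over all admissible lambda gives an orthogonal square matrix.
#'
#' For `l > lp` the matrix is derived from the `(lp, l)` one through the
#' exact transpose relation `couple_(lp,l)(B^T) = (-1)^(l+lp+lam)
#' couple_(l,lp)(B)`, which keeps the permutation phase of coupled blocks
#' an identity of the implementation rather than a numerical accident.
#'
#' @param l,lp angular momenta of the two factors.
#' @param lam output angular order; must satisfy `|l-lp| <= lam <= l+lp`.
#' @export
real_cg <- function(l, lp, lam) {
  if (lam < abs(l - lp) || lam > l + lp)
    stop("lambda = ", lam, " outside triangle range [", abs(l - lp), ", ",
         l + lp, "]")
  key <- paste(l, lp, lam, sep = "_")
  hit <- .cg_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (l > lp) {
    Tlp <- real_cg(lp, l, lam)
    n1 <- 2 * l + 1; n2 <- 2 * lp + 1
    # reorder rows (i2,i1) -> (i1,i2) and apply the transpose phase
    perm <- as.vector(t(matrix(seq_len(n1 * n2), n2, n1)))
    Tm <- (-1)^(l + lp + lam) * Tlp[perm, , drop = FALSE]
  } else {
    B1 <- .real_complex_unitary(l)
    B2 <- .real_complex_unitary(lp)
    BL <- .real_complex_unitary(lam)
    n1 <- 2 * l + 1; n2 <- 2 * lp + 1; nl <- 2 * lam + 1
    C <- matrix(0, n1 * n2, nl)   # rows: column-major (m1 fastest)
    for (m2 in (-lp):lp) for (m1 in (-l):l) {
      M <- m1 + m2
      if (abs(M) <= lam)
        C[(m2 + lp) * n1 + (m1 + l) + 1, M + lam + 1] <-
          .cg_complex(l, m1, lp, m2, lam, M)
    }
    Tc <- t(Conj(BL) %*% t(C) %*% kronecker(t(B2), t(B1)))
    if (max(abs(Im(Tc))) < 1e-12) {
      Tm <- Re(Tc)
    } else if (max(abs(Re(Tc))) < 1e-12) {
      Tm <- Im(Tc)
    } else {
      stop("internal error: real CG matrix neither real nor imaginary")
    }
    # deterministic overall sign: first nonzero entry (column-major) positive,
    # which makes the (l, l) -> lambda = 0 coupling the positive trace map
    nz <- which(abs(Tm) > 1e-12)[1]
    if (!is.na(nz) && Tm[nz] < 0) Tm <- -Tm
  }
  .cg_cache[[key]] <- Tm
  Tm
}

#' Couple a Hamiltonian block into lambda-components
#'
#' Implements the Clebsch-Gordan contraction of a `(2l+1) x (2lp+1)` block
#' over both magnetic indices. The map is orthogonal:
#' `sum_lam |coupled|^2 = |B|_F^2`.
#'
#' @param raw_block numeric matrix of shape `(2l+1) x (2lp+1)`.
#' @param l,lp angular momenta of the row / column shells.
#' @return named list over lambda (`"0"`, `"1"`, ...) of vectors of
#'   length 2 lambda + 1.
#' @export
couple_block <- function(raw_block, l, lp) {
  raw_block <- as.matrix(raw_block)
  if (!all(dim(raw_block) == c(2 * l + 1, 2 * lp + 1)))
    stop("block dimensions ", paste(dim(raw_block), collapse = "x"),
         " do not match l = ", l, ", lp = ", lp)
  v <- as.vector(raw_block)
  out <- list()
  for (lam in abs(l - lp):(l + lp))
    out[[as.character(lam)]] <- as.vector(crossprod(real_cg(l, lp, lam), v))
  out
}

#' Reconstruct a block from its lambda-components
#'
#' Exact inverse of [couple_block()].
#' @param coupled named list over lambda of component vectors; all lambda in
#'   `|l-lp|..l+lp` must be present.
#' @param l,lp angular momenta.
#' @export
decouple_block <- function(coupled, l, lp) {
  v <- numeric((2 * l + 1) * (2 * lp + 1))
  for (lam in abs(l - lp):(l + lp)) {
    comp <- coupled[[as.character(lam)]]
    if (is.null(comp))
      stop("missing lambda = ", lam, " component")
    if (length(comp) != 2 * lam + 1)
      stop("component lambda = ", lam, " has wrong length")
    v <- v + as.vector(real_cg(l, lp, lam) %*% comp)
  }
  matrix(v, 2 * l + 1, 2 * lp + 1)
}

#' Irreducible component of an O(3) tensor
#'
#' @param lambda angular order (>= 0).
#' @param sigma inversion parity, +1 (tensor) or -1 (pseudotensor).
#' @param values numeric vector of length 2 lambda + 1 (mu = -lambda..lambda).
#' @export
irrep_component <- function(lambda, sigma, values) {
  if (!(sigma %in% c(-1, 1))) stop("sigma must be +1 or -1")
  if (length(values) != 2 * lambda + 1)
    stop("values must have length 2*lambda + 1")
  out <- list(lambda = as.integer(lambda), sigma = as.integer(sigma),
              values = as.numeric(values))
  class(out) <- "effham_irrep"
  out
}

# axis order of the real l = 1 harmonics: mu = (-1, 0, 1) ~ (y, z, x)
.l1_axes <- c(2L, 3L, 1L)

#' Decompose a Cartesian tensor into O(3) irreducible components
#'
#' Rank-1 tensors (vectors) map to a single (lambda = 1, sigma = 1)
#' component; symmetric rank-2 tensors map to (0, 1) and (2, 1). The
#' antisymmetric part of a rank-2 input must vanish (the physical targets
#' here, polarizabilities, are symmetric); a non-symmetric input is an
#' error.
#'
#' @param tensor a 3-vector or a symmetric 3 x 3 matrix.
#' @return list of [irrep_component()] objects.
#' @export
cartesian_to_irreps <- function(tensor) {
  if (is.matrix(tensor)) {
    if (!all(dim(tensor) == c(3, 3))) stop("rank-2 tensor must be 3 x 3")
    if (max(abs(tensor - t(tensor))) > 1e-10)
      stop("rank-2 tensor must be symmetric (antisymmetric part > 1e-10)")
    blk <- tensor[.l1_axes, .l1_axes]
    cp <- couple_block(blk, 1, 1)
    list(irrep_component(0, 1, cp[["0"]]),
         irrep_component(2, 1, cp[["2"]]))
  } else {
    if (length(tensor) != 3) stop("rank-1 tensor must be a 3-vector")
    irrep_component(1, 1, tensor[.l1_axes])
  }
}

#' Reassemble a Cartesian tensor from irreducible components
#'
#' Exact inverse of [cartesian_to_irreps()].
#' @param components list of [irrep_component()] objects (or a single one);
#'   `{(1,1)}` yields a vector, `{(0,1),(2,1)}` a symmetric matrix.
#' @export
irreps_to_cartesian <- function(components) {
  if (inherits(components, "effham_irrep")) components <- list(components)
  lams <- vapply(components, function(cmp) cmp$lambda, 0L)
  if (identical(sort(lams), 1L)) {
    v <- components[[which(lams == 1)]]$values
    out <- numeric(3)
    out[.l1_axes] <- v
    out
  } else if (setequal(lams, c(0L, 2L))) {
    cp <- list("0" = components[[which(lams == 0)]]$values,
               "1" = numeric(3),
               "2" = components[[which(lams == 2)]]$values)
    blk <- decouple_block(cp, 1, 1)
    out <- matrix(0, 3, 3)
    out[.l1_axes, .l1_axes] <- blk
    out
  } else {
    stop("incomplete or unsupported component set (lambdas: ",
         paste(lams, collapse = ", "), ")")
  }
}
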