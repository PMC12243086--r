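# The quantum-mechanics property layer: generalized eigensolve, density
# matrix, dipole, sum-over-states polarizability, Mayer bond order and
# HOMO-LUMO gap. Every observable is a smooth function of the input
# Hamiltonian (at fixed overlap and operators), and qm_grad.R supplies the
# matching analytic adjoints d(loss)/dH.
#
# Matrices are interpreted through their symmetric part, so gradients with
# respect to individual entries of H are well defined and match elementwise
# finite differences.

.sym <- function(M) (M + t(M)) / 2

#' Solve the generalized eigenproblem H C = S C diag(eps)
#'
#' Loewdin route: diagonalize S, form S^(-1/2) (eigenvalue floor 1e-10),
#' solve the symmetric problem, map back. Occupations follow the aufbau
#' principle for a closed shell (2 electrons in each of the lowest
#' n_electrons/2 orbitals). Eigenvector phases are fixed deterministically:
#' the largest-magnitude entry of each column is positive.
#'
#' @param H Hamiltonian matrix (its symmetric part is used).
#' @param S symmetric positive-definite overlap.
#' @param n_electrons even electron count, at most 2 * dim.
#' @return list with `eps` (ascending), `C` (S-orthonormal columns), `f`
#'   (occupations), `n_occ`, and the `S` used; class `effham_spectral`.
#' @export
solve_generalized <- function(H, S, n_electrons) {
  H <- .sym(as.matrix(H)); S <- as.matrix(S)
  d <- nrow(H)
  if (!all(dim(S) == d)) stop("H and S dimensions differ")
  if (n_electrons %% 2 != 0) stop("closed-shell only: n_electrons must be even")
  if (n_electrons > 2 * d) stop("n_electrons exceeds basis capacity")
  es <- eigen(.sym(S), symmetric = TRUE)
  if (min(es$values) <= 1e-10)
    stop("S is not positive definite (min eigenvalue ", format(min(es$values)), ")")
  Sih <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  Ht <- .sym(Sih %*% H %*% Sih)
  eh <- eigen(Ht, symmetric = TRUE)
  ord <- order(eh$values)        # ascending
  eps <- eh$values[ord]
  C <- Sih %*% eh$vectors[, ord, drop = FALSE]
  # deterministic phases
  for (k in seq_len(d)) {
    j <- which.max(abs(C[, k]))
    if (C[j, k] < 0) C[, k] <- -C[, k]
  }
  f <- numeric(d)
  n_occ <- n_electrons / 2
  if (n_occ > 0) f[seq_len(n_occ)] <- 2
  out <- list(eps = eps, C = C, f = f, n_occ = as.integer(n_occ), S = S)
  class(out) <- "effham_spectral"
  out
}

#' One-electron density matrix
#'
#' `rho = C diag(f) C^T`; satisfies `Tr(rho S) = n_electrons` and the
#' closed-shell idempotency `(rho S)^2 = 2 rho S`.
#' @param sol output of [solve_generalized()].
#' @export
density_matrix <- function(sol) {
  occ <- sol$f > 0
  if (!any(occ)) return(matrix(0, nrow(sol$C), nrow(sol$C)))
  Co <- sol$C[, occ, drop = FALSE]
  Co %*% (sol$f[occ] * t(Co))
}

#' Molecular dipole moment
#'
#' `mu_a = -Tr(rho X_a) + sum_i Q_i r_i` in atomic units (e = 1); the first
#' term is the electronic contribution, the second the nuclear one with the
#' effective charges of the basis specification.
#'
#' @param rho density matrix.
#' @param X list of three AO position-operator matrices.
#' @param structure,basis structure and basis (for nuclear charges).
#' @return dipole 3-vector (a.u.).
#' @export
dipole <- function(rho, X, structure, basis) {
  mu <- numeric(3)
  for (a in 1:3) mu[a] <- -sum(rho * X[[a]])
  for (i in seq_along(structure$species)) {
    sp <- structure$species[i]
    if (is.null(basis$species[[sp]]))
      stop("no effective charge Q for species ", sp)
    mu <- mu + basis$species[[sp]]$Q * structure$positions[i, ]
  }
  mu
}

#' Static polarizability from the sum-over-states response
#'
#' Builds the first-order density response per field direction from the
#' occupied-virtual spectral decomposition,
#' `chi_ην = 2 sum_{r in occ} sum_{s in virt} x_rs / (eps_r - eps_s)
#' (C_ηs C_νr + C_ηr C_νs)`,
#' and contracts the induced density with the position operators. The sign
#' is fixed so that alpha is positive semidefinite for ground-state
#' occupations, consistent with the finite-field derivative of the dipole
#' under `H(E) = H + E . X`.
#'
#' @param sol output of [solve_generalized()].
#' @param X list of three AO position-operator matrices.
#' @return symmetric 3 x 3 matrix (a.u.).
#' @export
polarizability <- function(sol, X) {
  n <- length(sol$eps)
  n_occ <- sol$n_occ
  if (n_occ < 1) stop("no occupied orbitals")
  if (n_occ >= n) stop("no virtual orbitals: polarizability undefined")
  gap <- sol$eps[n_occ + 1] - sol$eps[n_occ]
  if (gap < 1e-8)
    stop("occupied-virtual degeneracy (orbitals ", n_occ, " and ", n_occ + 1,
         ", gap ", format(gap), "): response diverges")
  occ <- seq_len(n_occ); virt <- (n_occ + 1):n
  Co <- sol$C[, occ, drop = FALSE]; Cv <- sol$C[, virt, drop = FALSE]
  # MO-basis occupied x virtual position blocks
  Xov <- lapply(X, function(Xa) t(Co) %*% Xa %*% Cv)
  invD <- 1 / outer(sol$eps[virt], sol$eps[occ], "-")  # (virt, occ): eps_s - eps_r > 0
  alpha <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    alpha[a, b] <- 4 * sum(Xov[[a]] * Xov[[b]] * t(invD))
    alpha[b, a] <- alpha[a, b]
  }
  alpha
}

#' Mayer bond orders
#'
#' `B_ij = sum_{eta in i} sum_{eta' in j} (rho S)_{eta eta'} (rho S)_{eta' eta}`;
#' invariant under any orthogonal mixing of the AOs within one atom.
#'
#' @param rho density matrix.
#' @param S overlap matrix.
#' @param ao_map AO index map from [build_ao_index()].
#' @return N x N symmetric matrix of bond orders (diagonal included).
#' @export
mayer_bond_order <- function(rho, S, ao_map) {
  P <- rho %*% S
  atoms <- ao_map$atom
  n <- max(atoms)
  B <- matrix(0, n, n)
  PPt <- P * t(P)
  for (i in seq_len(n)) {
    ii <- which(atoms == i)
    for (j in i:n) {
      jj <- which(atoms == j)
      B[i, j] <- sum(PPt[ii, jj])
      B[j, i] <- B[i, j]
    }
  }
  B
}

#' HOMO-LUMO gap
#'
#' @param sol output of [solve_generalized()].
#' @return `eps[n_occ + 1] - eps[n_occ]` (>= 0 for ascending eps).
#' @export
homo_lumo_gap <- function(sol) {
  n_occ <- sol$n_occ
  if (n_occ < 1) stop("no occupied orbitals")
  if (n_occ >= length(sol$eps)) stop("no virtual orbitals: gap undefined")
  sol$eps[n_occ + 1] - sol$eps[n_occ]
}

#' All derived properties of one Hamiltonian
#'
#' Convenience wrapper running the whole property layer.
#' @param H,S,X,n_electrons matrices and electron count.
#' @param structure,basis for the nuclear dipole term and atom partition.
#' @param ao_map AO index map.
#' @param with_alpha compute polarizability (requires a nondegenerate
#'   frontier); set FALSE to skip.
#' @return list with `eps`, `mu`, `alpha`, `bond_order`, `gap`, `sol`, `rho`.
#' @export
derived_properties <- function(H, S, X, n_electrons, structure, basis, ao_map,
                               with_alpha = TRUE) {
  sol <- solve_generalized(H, S, n_electrons)
  rho <- density_matrix(sol)
  list(eps = sol$eps,
       mu = dipole(rho, X, structure, basis),
       alpha = if (with_alpha) polarizability(sol, X) else NULL,
       bond_order = mayer_bond_order(rho, S, ao_map),
       gap = if (sol$n_occ < length(sol$eps)) homo_lumo_gap(sol) else NULL,
       sol = sol, rho = rho)
}
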