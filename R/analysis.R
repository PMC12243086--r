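# Interpretation diagnostics: eigenbasis alignment, symmetry-adapted
# projection from a larger basis, and distance-decay profiles of
# Hamiltonian matrix elements.

# Loewdin orthogonalization helper: returns S^(-1/2)
.s_invsqrt <- function(S) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(es$values) <= 1e-10) stop("S not positive definite")
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

# eigenvectors with degenerate clusters aligned to a reference by an
# orthogonal Procrustes rotation within each cluster
.aligned_eigvec <- function(M, ref_vec = NULL, tol = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]; V <- e$vectors[, ord, drop = FALSE]
  if (!is.null(ref_vec)) {
    i <- 1; n <- length(vals)
    while (i <= n) {
      j <- i
      while (j < n && vals[j + 1] - vals[j] < tol) j <- j + 1
      if (j > i) {
        blk <- i:j
        Mx <- t(V[, blk, drop = FALSE]) %*% ref_vec[, blk, drop = FALSE]
        sv <- svd(Mx)
        V[, blk] <- V[, blk, drop = FALSE] %*% (sv$u %*% t(sv$v))
      }
      i <- j + 1
    }
  }
  list(values = vals, vectors = V)
}

#' Eigenbasis alignment of a predicted Hamiltonian
#'
#' `H_EA = C C_pred^T H_pred_orth C_pred C^T` in the Loewdin-orthogonalized
#' frame, where C and C_pred are the eigenvectors of the reference and the
#' prediction. The output keeps the predicted spectrum exactly; when the
#' two spectra coincide the output equals the (orthogonalized) reference.
#' Degenerate clusters are fixed by an orthogonal Procrustes step against
#' the reference eigenvectors, which makes the otherwise non-unique
#' alignment canonical.
#'
#' @param H_pred,H_ref predicted and reference Hamiltonians (same AO basis).
#' @param S overlap matrix; identity means already orthogonalized.
#' @return list with `H_ea`, `H_ref_orth`, `H_pred_orth` (all in the
#'   orthogonalized frame).
#' @export
eigenbasis_align <- function(H_pred, H_ref, S = NULL) {
  d <- nrow(H_ref)
  if (!all(dim(H_pred) == d)) stop("H_pred and H_ref dimensions differ")
  if (!is.null(S)) {
    W <- .s_invsqrt(S)
    H_pred <- W %*% H_pred %*% W
    H_ref <- W %*% H_ref %*% W
  }
  er <- .aligned_eigvec(H_ref)
  ep <- .aligned_eigvec(H_pred, ref_vec = er$vectors)
  C <- er$vectors; Cp <- ep$vectors
  H_ea <- C %*% t(Cp) %*% H_pred %*% Cp %*% t(C)
  list(H_ea = (H_ea + t(H_ea)) / 2, H_ref_orth = H_ref, H_pred_orth = H_pred)
}

#' Symmetry-adapted projected Hamiltonian (SAPH)
#'
#' Projects a large-basis Hamiltonian onto the dimension of a small
#' (effective) basis: `H_SAPH = C Cbar_LB^T H_LB Cbar_LB C^T`, with
#' `Cbar_LB` the lowest `n_keep` large-basis eigenvectors and `C` the
#' small-basis reference eigenvectors (orthogonalized frame). The spectrum
#' of the output equals the lowest `n_keep` large-basis eigenvalues
#' exactly.
#'
#' @param H_large,S_large large-basis Hamiltonian and overlap.
#' @param C_small_ref orthonormal small-basis eigenvector matrix
#'   (`n_keep x n_keep`), e.g. from the orthogonalized small-basis
#'   reference; identity gives the projected Hamiltonian in the ordered
#'   eigenbasis.
#' @param n_keep dimension of the small basis.
#' @return `n_keep x n_keep` symmetric matrix.
#' @export
saph_project <- function(H_large, S_large, C_small_ref, n_keep) {
  d <- nrow(H_large)
  if (n_keep > d) stop("n_keep exceeds the large-basis dimension")
  W <- .s_invsqrt(S_large)
  Ho <- W %*% H_large %*% W
  e <- .aligned_eigvec(Ho)
  Cbar <- e$vectors[, seq_len(n_keep), drop = FALSE]
  C <- as.matrix(C_small_ref)
  if (!all(dim(C) == n_keep)) stop("C_small_ref must be n_keep x n_keep")
  Hs <- C %*% t(Cbar) %*% Ho %*% Cbar %*% t(C)
  (Hs + t(Hs)) / 2
}

#' Distance-decay profile of interaction blocks
#'
#' Collects, for every pair of the requested species, the interatomic
#' distance and either the Frobenius norm of the corresponding Hamiltonian
#' block (`mode = "norm"`) or all its matrix elements
#' (`mode = "elements"`), together with a moving average over a distance
#' window.
#'
#' @param entries list of `list(H = matrix, structure = , basis = )`
#'   entries (reference records or predictions).
#' @param species_pair character 2-vector, e.g. `c("C", "C")`.
#' @param mode `"norm"` or `"elements"`.
#' @param window moving-average window in distance (a.u.).
#' @return list with `points` (data.frame distance, value), `curve`
#'   (data.frame distance, mean; rows only where >= 5 points fall in the
#'   window) and `empty` flag; class `effham_decay_profile`.
#' @export
decay_profile <- function(entries, species_pair, mode = c("norm", "elements"),
                          window = 0.25) {
  mode <- match.arg(mode)
  dist <- numeric(0); val <- numeric(0)
  for (en in entries) {
    s <- en$structure
    ao <- build_ao_index(s, en$basis)
    sl <- attr(ao, "slices")
    n <- n_atoms(s)
    if (n < 2) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- (s$species[i] == species_pair[1] && s$species[j] == species_pair[2]) ||
            (s$species[i] == species_pair[2] && s$species[j] == species_pair[1])
      if (!ok) next
      r <- sqrt(sum((s$positions[j, ] - s$positions[i, ])^2))
      blk <- en$H[sl[i, 1]:sl[i, 2], sl[j, 1]:sl[j, 2], drop = FALSE]
      if (mode == "norm") {
        dist <- c(dist, r); val <- c(val, sqrt(sum(blk^2)))
      } else {
        dist <- c(dist, rep(r, length(blk))); val <- c(val, as.vector(blk))
      }
    }
  }
  empty <- length(dist) == 0
  if (empty)
    warning("no pairs of species ", paste(species_pair, collapse = "-"),
            " found; empty profile")
  ord <- order(dist)
  pts <- data.frame(distance = dist[ord], value = val[ord])
  curve <- NULL
  if (!empty) {
    xs <- unique(pts$distance)
    rows <- lapply(xs, function(x) {
      inw <- abs(pts$distance - x) <= window / 2
      if (sum(inw) >= 5)
        data.frame(distance = x, mean = mean(pts$value[inw]))
    })
    curve <- do.call(rbind, rows)
  }
  out <- list(points = pts, curve = curve, empty = empty,
              species_pair = species_pair, mode = mode, window = window)
  class(out) <- "effham_decay_profile"
  out
}
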