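# Reference records: the container tying one structure at one basis level to
# its Hamiltonian, overlap, position operators and derived properties.
#
# Record sets are persisted through R's native serialization (a hierarchical
# binary container); the layout (one named entry per structure id, each a
# list with H, S, X, n_electrons, props, basis_label, ao_order fingerprint)
# is documented here and stable, so external importers can produce it from
# any quantum-chemistry engine after permuting matrices into the canonical
# AO order of build_ao_index().

#' Construct and validate a reference record
#'
#' @param structure_id id of the structure the record belongs to.
#' @param basis_label label of the basis the matrices are expressed in.
#' @param H symmetric Hamiltonian matrix (Hartree).
#' @param S symmetric positive-definite overlap matrix.
#' @param X list of three symmetric position-operator matrices (a.u.),
#'   ordered x, y, z.
#' @param n_electrons even integer electron count.
#' @param props optional named list with any of `eps` (MO energies,
#'   Hartree), `mu` (3-vector, a.u.), `alpha` (3 x 3 symmetric, a.u.),
#'   `bond_order` (N x N symmetric Mayer bond orders), `gap` (scalar).
#' @param ao_order optional AO-order fingerprint (character), as produced by
#'   [ao_fingerprint()].
#' @return an object of class `effham_record`.
#' @export
reference_record <- function(structure_id, basis_label, H, S, X, n_electrons,
                             props = list(), ao_order = NULL) {
  H <- as.matrix(H); S <- as.matrix(S)
  d <- nrow(H)
  stopifnot(ncol(H) == d, all(dim(S) == d))
  if (max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H))))
    stop("H must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("S must be positive definite (min eigenvalue ",
                             format(min(ev)), ")")
  if (length(X) != 3) stop("X must be a list of three matrices")
  for (a in 1:3) {
    X[[a]] <- as.matrix(X[[a]])
    if (!all(dim(X[[a]]) == d)) stop("X[[", a, "]] dimension mismatch")
  }
  if (n_electrons %% 2 != 0) stop("closed-shell only: n_electrons must be even")
  if (!is.null(props$alpha) &&
      max(abs(props$alpha - t(props$alpha))) > 1e-8)
    stop("alpha must be symmetric")
  out <- list(structure_id = structure_id, basis_label = basis_label,
              H = H, S = S, X = X, n_electrons = as.integer(n_electrons),
              props = props, ao_order = ao_order)
  class(out) <- "effham_record"
  out
}

#' @export
print.effham_record <- function(x, ...) {
  cat("<effham_record>", x$structure_id, "@", x$basis_label, ":",
      nrow(x$H), "AOs,", x$n_electrons, "electrons; props:",
      paste(names(x$props), collapse = " "), "\n")
  invisible(x)
}

#' Fingerprint of an AO index map
#'
#' Short digest of the (atom, species, n, l, m) sequence, stored in record
#' containers so importers can verify they permuted into the canonical order.
#' @param ao_map output of [build_ao_index()].
#' @export
ao_fingerprint <- function(ao_map) {
  paste(ao_map$atom, ao_map$species, ao_map$n, ao_map$l, ao_map$m,
        sep = ".", collapse = "|")
}

#' Write / read a record set container
#'
#' @param records named list of [reference_record()] objects (names are
#'   structure ids, possibly suffixed by basis label).
#' @param path file path (`.rds`).
#' @export
write_record_set <- function(records, path) {
  saveRDS(records, path, version = 2)
  invisible(path)
}

#' @rdname write_record_set
#' @export
read_record_set <- function(path) {
  if (!file.exists(path)) stop("record container not found: ", path)
  readRDS(path)
}
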