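# Basis specifications and atomic-orbital index maps.
#
# A basis specification lists, per chemical species, an ordered set of shells
# (n, l) together with an effective nuclear charge Q and a valence electron
# count. The AO index map fixes the canonical row/column semantics of every
# matrix in the package: atoms in input order, shells in basis order, and
# m = -l..l ascending within a shell (real spherical harmonics, no
# Condon-Shortley phase in the real basis).

#' Construct a basis specification
#'
#' @param species_defs named list; each element describes one species as
#'   `list(shells = list(c(n, l), ...), Q = <charge>, valence = <electrons>)`.
#'   Shell exponents (for the toy Gaussian bases of the fixture engine) may
#'   be carried in an optional `exponents` numeric vector parallel to
#'   `shells`, and per-shell on-site energies in `onsite`.
#' @param label text label for the basis (e.g. `"toy-min"`).
#' @return an object of class `effham_basis`.
#' @export
basis_spec <- function(species_defs, label = "basis") {
  for (sp in names(species_defs)) {
    d <- species_defs[[sp]]
    if (is.null(d$shells) || length(d$shells) == 0)
      stop("species ", sp, " has no shells")
    sh <- do.call(rbind, lapply(d$shells, function(s) as.integer(s[1:2])))
    if (any(sh[, 2] < 0)) stop("negative angular momentum for species ", sp)
    if (anyDuplicated(paste(sh[, 1], sh[, 2])))
      stop("duplicate shells for species ", sp)
    if (is.null(d$Q) || d$Q <= 0) stop("species ", sp, " needs Q > 0")
    if (is.null(d$valence)) stop("species ", sp, " needs a valence electron count")
  }
  out <- list(species = species_defs, label = label)
  class(out) <- "effham_basis"
  out
}

#' @export
print.effham_basis <- function(x, ...) {
  cat("<effham_basis>", x$label, "\n")
  for (sp in names(x$species)) {
    d <- x$species[[sp]]
    cat("  ", sp, ": shells",
        paste(vapply(d$shells, function(s) paste0("(", s[1], ",", s[2], ")"), ""),
              collapse = " "),
        " Q=", d$Q, " valence=", d$valence, "\n")
  }
  invisible(x)
}

#' Read / write a basis specification as JSON
#'
#' The JSON document maps species to
#' `{"shells": [[n, l], ...], "Q": <num>, "valence": <num>}` with optional
#' `"exponents"` and `"onsite"` arrays.
#'
#' @param path file path.
#' @return [basis_spec()] object.
#' @export
read_basis_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  label <- if (!is.null(doc[[".label"]])) doc[[".label"]] else "basis"
  doc[[".label"]] <- NULL
  defs <- lapply(doc, function(d) {
    list(shells = lapply(d$shells, function(s) as.integer(unlist(s))),
         Q = as.numeric(d$Q), valence = as.numeric(d$valence),
         exponents = if (!is.null(d$exponents)) as.numeric(unlist(d$exponents)),
         onsite = if (!is.null(d$onsite)) as.numeric(unlist(d$onsite)))
  })
  basis_spec(defs, label = label)
}

#' @rdname read_basis_spec
#' @param basis a [basis_spec()] object.
#' @export
write_basis_spec <- function(basis, path) {
  doc <- lapply(basis$species, function(d) {
    out <- list(shells = d$shells, Q = d$Q, valence = d$valence)
    if (!is.null(d$exponents)) out$exponents <- d$exponents
    if (!is.null(d$onsite)) out$onsite <- d$onsite
    out
  })
  doc[[".label"]] <- basis$label
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the atomic-orbital index map for a structure
#'
#' Deterministic ordering: atoms in structure order, shells in basis order,
#' m ascending within each shell. The map is the single source of truth for
#' the row/column semantics of every Hamiltonian, overlap and operator
#' matrix handled by the package.
#'
#' @param structure an [structure_new()] object.
#' @param basis a [basis_spec()] object covering all species present.
#' @return a data.frame with columns `atom`, `species`, `n`, `l`, `m`, one
#'   row per AO, plus attribute `slices`: per-atom `[first, last]` index
#'   bounds, and `shell_slices`: a list keyed by `"atom:n:l"`.
#' @export
build_ao_index <- function(structure, basis) {
  missing_sp <- setdiff(unique(structure$species), names(basis$species))
  if (length(missing_sp) > 0)
    stop("species missing from basis: ", paste(missing_sp, collapse = ", "))
  rows <- list()
  slices <- matrix(0L, n_atoms(structure), 2)
  shell_slices <- list()
  pos <- 0L
  for (i in seq_along(structure$species)) {
    sp <- structure$species[i]
    first <- pos + 1L
    for (sh in basis$species[[sp]]$shells) {
      n <- sh[1]; l <- sh[2]
      idx <- pos + seq_len(2L * l + 1L)
      shell_slices[[paste(i, n, l, sep = ":")]] <- idx
      rows[[length(rows) + 1L]] <-
        data.frame(atom = i, species = sp, n = n, l = l, m = (-l):l)
      pos <- pos + 2L * l + 1L
    }
    slices[i, ] <- c(first, pos)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  attr(map, "slices") <- slices
  attr(map, "shell_slices") <- shell_slices
  map
}

#' Number of AOs implied by a basis for one structure
#' @keywords internal
ao_dim <- function(structure, basis) {
  sum(vapply(structure$species, function(sp) {
    sum(vapply(basis$species[[sp]]$shells, function(sh) 2L * sh[2] + 1L, 0L))
  }, 0L))
}

#' Total valence electron count of a structure under a basis
#' @param structure a structure.
#' @param basis a [basis_spec()].
#' @export
electron_count <- function(structure, basis) {
  sum(vapply(structure$species, function(sp) basis$species[[sp]]$valence, 0))
}
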