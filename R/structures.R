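# Structures and XYZ / extended-XYZ I/O.
#
# All coordinates are stored internally in atomic units (Bohr); conversion
# from/to Angstrom happens only at the file boundary.

#' Bohr per Angstrom conversion factor
#' @keywords internal
BOHR_PER_ANGSTROM <- 1.8897259886

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

#' Create a molecular or periodic structure
#'
#' @param species character vector of element symbols.
#' @param positions N x 3 matrix of coordinates.
#' @param lattice optional 3 x 3 matrix of row lattice vectors (periodic
#'   systems only); must be nonsingular.
#' @param id text label for the structure.
#' @param unit unit of `positions` (and `lattice`): `"angstrom"` or `"bohr"`.
#'   Internally everything is stored in Bohr.
#' @return an object of class `effham_structure` with fields `species`,
#'   `positions` (Bohr), `lattice` (Bohr or NULL) and `id`.
#' @export
structure_new <- function(species, positions, lattice = NULL, id = "structure",
                          unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3)
    stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (n < 1) stop("structure must contain at least one atom")
  if (length(species) != n)
    stop("species length (", length(species), ") != number of positions (", n, ")")
  if (!all(is.finite(positions))) stop("positions must be finite")
  bad <- setdiff(unique(species), .known_elements)
  if (length(bad) > 0) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  fac <- if (unit == "angstrom") BOHR_PER_ANGSTROM else 1
  if (!is.null(lattice)) {
    lattice <- as.matrix(lattice) * fac
    if (!all(dim(lattice) == c(3, 3))) stop("lattice must be 3 x 3")
    if (abs(det(lattice)) < 1e-12) stop("lattice must be nonsingular")
  }
  out <- list(species = as.character(species),
              positions = unname(positions) * fac,
              lattice = lattice, id = as.character(id))
  class(out) <- "effham_structure"
  out
}

#' @export
print.effham_structure <- function(x, ...) {
  cat("<effham_structure>", x$id, ":", length(x$species), "atoms (",
      paste(unique(x$species), collapse = " "), ")",
      if (!is.null(x$lattice)) "[periodic]" else "", "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a structure.
#' @export
n_atoms <- function(structure) length(structure$species)

#' Read structures from an XYZ or extended-XYZ file
#'
#' Multi-frame files yield one structure per frame. Coordinates in the file
#' are interpreted as Angstrom and converted to Bohr. For extended-XYZ the
#' `Lattice="ax ay az bx by bz cx cy cz"` comment-line field is parsed into
#' row lattice vectors.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"xyz"` or `"extxyz"`.
#' @return a list of [structure_new()] objects.
#' @export
read_structures <- function(path, format = c("auto", "xyz", "extxyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip trailing blank lines
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) stop("empty structure file: ", path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("parse error at line ", i, ": expected atom count, got '", lines[i], "'")
    if (i + 1 + nat > length(lines))
      stop("parse error: truncated frame starting at line ", i)
    frame <- frame + 1L
    comment <- lines[i + 1]
    lattice <- .parse_extxyz_lattice(comment)
    body <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    sp <- character(nat); pos <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      tk <- toks[[k]]
      if (length(tk) < 4)
        stop("parse error at line ", i + 1 + k, ": expected 'El x y z'")
      sp[k] <- tk[1]
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (any(is.na(xyz)))
        stop("parse error at line ", i + 1 + k, ": non-numeric coordinate")
      pos[k, ] <- xyz
    }
    id <- .parse_extxyz_field(comment, "id")
    if (is.null(id)) id <- paste0(tools::file_path_sans_ext(basename(path)), "_", frame)
    out[[frame]] <- structure_new(sp, pos, lattice = lattice, id = id,
                                  unit = "angstrom")
    i <- i + 2L + nat
  }
  out
}

.parse_extxyz_lattice <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(m) == 0) return(NULL)
  vals <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", m)), "\\s+")[[1]])
  if (length(vals) != 9) stop("malformed Lattice field: ", comment)
  matrix(vals, 3, 3, byrow = TRUE)
}

.parse_extxyz_field <- function(comment, key) {
  pat <- paste0(key, '="?([^" ]*)"?')
  m <- regmatches(comment, regexpr(pat, comment))
  if (length(m) == 0) return(NULL)
  sub(pat, "\\1", m)
}

#' Write structures to an (extended-)XYZ file
#'
#' Coordinates are written in Angstrom; a `Lattice="..."` field is emitted
#' for periodic structures.
#'
#' @param structures a single structure or a list of structures.
#' @param path output file path.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "effham_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    n <- n_atoms(s)
    writeLines(as.character(n), con)
    comment <- paste0("id=", s$id)
    if (!is.null(s$lattice)) {
      lat <- s$lattice / BOHR_PER_ANGSTROM
      comment <- paste0(comment, ' Lattice="',
                        paste(sprintf("%.12f", as.vector(t(lat))), collapse = " "), '"')
    }
    writeLines(comment, con)
    pos <- s$positions / BOHR_PER_ANGSTROM
    for (k in seq_len(n))
      writeLines(sprintf("%-3s %18.12f %18.12f %18.12f",
                         s$species[k], pos[k, 1], pos[k, 2], pos[k, 3]), con)
  }
  invisible(path)
}
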