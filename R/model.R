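# Symmetry-adapted per-block linear models of the Hamiltonian.
#
# Every Hamiltonian sub-block (pair of shells on a pair of atoms, or on one
# atom) is coupled into lambda-components (cg.R) and modeled linearly on
# the matching (sigma, lambda) features, with an intercept only on
# invariant (lambda = 0) components. Same-species off-site blocks are
# symmetrized into +/- permutation channels so predictions are covariant
# under atom relabeling, and the assembled matrix is symmetric by
# construction.
#
# Block bookkeeping conventions (used consistently by coupling, ridge
# training, prediction, assembly and the weight-gradient chain):
#  * canonical pair order: first atom = earlier species in the basis's
#    species order, ties broken by atom index;
#  * same-species keys run over shell pairs s1 <= s2 (basis shell order),
#    with forward block H[first s1, second s2] and backward block
#    H[second s1, first s2], modeled through (fwd +/- bwd)/sqrt(2);
#  * for s1 == s2 the backward block is the transpose of the forward one,
#    so only the channel with matching permutation parity (-1)^lambda
#    survives;
#  * different-species keys run over all shell pairs (shell of first
#    species x shell of second);
#  * on-site keys run over shell pairs s1 <= s2 of one species, same-shell
#    blocks keeping only even-parity (symmetric) components.

.key_id <- function(kind, sp1, sp2, sh1, sh2) {
  paste(kind, sp1, sp2, paste(sh1, collapse = "_"), paste(sh2, collapse = "_"),
        sep = ".")
}

#' Enumerate model block keys for a basis
#'
#' @param basis a [basis_spec()].
#' @param species which species to include (default all in the basis).
#' @return data.frame with one row per (key, lambda, channel):
#'   columns `key`, `kind` (`on`, `ss`, `sd`), `sp1`, `sp2`, `n1`, `l1`,
#'   `n2`, `l2`, `lam`, `sigma`, `channel` (`""`, `"+"`, `"-"`),
#'   `intercept` (logical, lambda = 0 non-antisymmetric only).
#' @export
model_keys <- function(basis, species = names(basis$species)) {
  species <- intersect(names(basis$species), species)  # canonical order
  rows <- list()
  add <- function(kind, sp1, sp2, s1, s2, lam, channel) {
    rows[[length(rows) + 1]] <<- data.frame(
      key = .key_id(kind, sp1, sp2, s1, s2), kind = kind,
      sp1 = sp1, sp2 = sp2, n1 = s1[1], l1 = s1[2], n2 = s2[1], l2 = s2[2],
      lam = lam, sigma = (-1)^(s1[2] + s2[2] + lam), channel = channel,
      intercept = (lam == 0 && channel != "-"))
  }
  for (sp in species) {
    shells <- basis$species[[sp]]$shells
    for (a in seq_along(shells)) for (b in a:length(shells)) {
      s1 <- shells[[a]]; s2 <- shells[[b]]
      for (lam in abs(s1[2] - s2[2]):(s1[2] + s2[2])) {
        # on-site: same-shell blocks are symmetric
        if (!(a == b && (-1)^lam == -1)) add("on", sp, sp, s1, s2, lam, "")
        # off-site same species: permutation channels
        if (a == b) {
          add("ss", sp, sp, s1, s2, lam, if ((-1)^lam == 1) "+" else "-")
        } else {
          add("ss", sp, sp, s1, s2, lam, "+")
          add("ss", sp, sp, s1, s2, lam, "-")
        }
      }
    }
  }
  if (length(species) > 1) {
    for (ia in seq_along(species)) for (ib in seq_along(species)) {
      if (ib <= ia) next
      spa <- species[ia]; spb <- species[ib]
      for (sa in basis$species[[spa]]$shells)
        for (sb in basis$species[[spb]]$shells)
          for (lam in abs(sa[2] - sb[2]):(sa[2] + sb[2]))
            add("sd", spa, spb, sa, sb, lam, "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# canonical (first, second) ordering of an atom pair
.canonical_pair <- function(structure, species_order, i, j) {
  si <- match(structure$species[i], species_order)
  sj <- match(structure$species[j], species_order)
  if (si < sj || (si == sj && i <= j)) c(i, j) else c(j, i)
}

# shell slice lookup helper
.slice <- function(ao_map, atom, sh) {
  attr(ao_map, "shell_slices")[[paste(atom, sh[1], sh[2], sep = ":")]]
}

#' Couple a reference Hamiltonian into channel components
#'
#' Extracts every modeled block of H, couples it, and forms the
#' permutation-symmetrized channel components that the block model
#' predicts. Off-site blocks beyond `cutoff` are skipped (the model treats
#' them as zero).
#'
#' @param H symmetric matrix in the canonical AO order.
#' @param structure,basis geometry and basis.
#' @param cutoff pair cutoff (a.u.).
#' @return list with `onsite[[atom]][[key|lam]]` component vectors and
#'   `pairs[[\"first:second\"]][[key|lam|channel]]` vectors, plus the pair
#'   table; class `effham_blocks`.
#' @export
couple_hamiltonian <- function(H, structure, basis, cutoff) {
  ao <- build_ao_index(structure, basis)
  species_order <- names(basis$species)
  onsite <- vector("list", n_atoms(structure))
  for (i in seq_len(n_atoms(structure))) {
    sp <- structure$species[i]
    shells <- basis$species[[sp]]$shells
    comp <- list()
    for (a in seq_along(shells)) for (b in a:length(shells)) {
      s1 <- shells[[a]]; s2 <- shells[[b]]
      blk <- H[.slice(ao, i, s1), .slice(ao, i, s2), drop = FALSE]
      cp <- couple_block(blk, s1[2], s2[2])
      kid <- .key_id("on", sp, sp, s1, s2)
      for (lam in names(cp)) {
        if (a == b && (-1)^as.integer(lam) == -1) next
        comp[[paste(kid, lam, sep = "|")]] <- cp[[lam]]
      }
    }
    onsite[[i]] <- comp
  }
  pairs <- list()
  pt <- .pair_table(structure, species_order, cutoff)
  for (r in seq_len(nrow(pt))) {
    fi <- pt$first[r]; se <- pt$second[r]
    sp1 <- structure$species[fi]; sp2 <- structure$species[se]
    comp <- list()
    if (sp1 == sp2) {
      shells <- basis$species[[sp1]]$shells
      for (a in seq_along(shells)) for (b in a:length(shells)) {
        s1 <- shells[[a]]; s2 <- shells[[b]]
        fwd <- couple_block(H[.slice(ao, fi, s1), .slice(ao, se, s2), drop = FALSE],
                            s1[2], s2[2])
        kid <- .key_id("ss", sp1, sp2, s1, s2)
        if (a == b) {
          for (lam in names(fwd))
            comp[[paste(kid, lam, if ((-1)^as.integer(lam) == 1) "+" else "-",
                        sep = "|")]] <- sqrt(2) * fwd[[lam]]
        } else {
          bwd <- couple_block(H[.slice(ao, se, s1), .slice(ao, fi, s2), drop = FALSE],
                              s1[2], s2[2])
          for (lam in names(fwd)) {
            comp[[paste(kid, lam, "+", sep = "|")]] <-
              (fwd[[lam]] + bwd[[lam]]) / sqrt(2)
            comp[[paste(kid, lam, "-", sep = "|")]] <-
              (fwd[[lam]] - bwd[[lam]]) / sqrt(2)
          }
        }
      }
    } else {
      for (sa in basis$species[[sp1]]$shells)
        for (sb in basis$species[[sp2]]$shells) {
          cp <- couple_block(H[.slice(ao, fi, sa), .slice(ao, se, sb), drop = FALSE],
                             sa[2], sb[2])
          kid <- .key_id("sd", sp1, sp2, sa, sb)
          for (lam in names(cp))
            comp[[paste(kid, lam, sep = "|")]] <- cp[[lam]]
        }
    }
    pairs[[paste0(fi, ":", se)]] <- comp
  }
  out <- list(onsite = onsite, pairs = pairs, pair_table = pt,
              ao_map = ao, species_order = species_order)
  class(out) <- "effham_blocks"
  out
}

# unordered within-cutoff pairs in canonical order
.pair_table <- function(structure, species_order, cutoff) {
  n <- n_atoms(structure)
  first <- integer(0); second <- integer(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((structure$positions[j, ] - structure$positions[i, ])^2))
      if (r < cutoff) {
        cp <- .canonical_pair(structure, species_order, i, j)
        first <- c(first, cp[1]); second <- c(second, cp[2])
      }
    }
  }
  data.frame(first = first, second = second)
}

#' Assemble a symmetric Hamiltonian from channel components
#'
#' Exact inverse of [couple_hamiltonian()] for within-cutoff blocks:
#' decouples every component, reconstructs forward/backward blocks from the
#' +/- channels, and mirrors each placement by its transpose, so the output
#' satisfies `H == t(H)` identically. Missing pair entries (beyond-cutoff
#' pairs) give zero blocks.
#'
#' @param blocks an `effham_blocks` object (from [couple_hamiltonian()] or
#'   [predict_blocks()]).
#' @param structure,basis geometry and basis.
#' @return symmetric matrix in canonical AO order.
#' @export
assemble_matrix <- function(blocks, structure, basis) {
  ao <- blocks$ao_map
  d <- nrow(ao)
  H <- matrix(0, d, d)
  for (i in seq_len(n_atoms(structure))) {
    sp <- structure$species[i]
    shells <- basis$species[[sp]]$shells
    comp <- blocks$onsite[[i]]
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
      if (a == b) {
        H[I, J] <- (blk + t(blk)) / 2
      } else {
        H[I, J] <- blk
        H[J, I] <- t(blk)
      }
    }
  }
  pt <- blocks$pair_table
  for (r in seq_len(nrow(pt))) {
    fi <- pt$first[r]; se <- pt$second[r]
    sp1 <- structure$species[fi]; sp2 <- structure$species[se]
    comp <- blocks$pairs[[paste0(fi, ":", se)]]
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
        bf <- decouple_block(fwd, s1[2], s2[2])
        I1 <- .slice(ao, fi, s1); J2 <- .slice(ao, se, s2)
        H[I1, J2] <- bf
        H[J2, I1] <- t(bf)
        if (a != b) {
          bb <- decouple_block(bwd, s1[2], s2[2])
          I1b <- .slice(ao, se, s1); J2b <- .slice(ao, fi, s2)
          H[I1b, J2b] <- bb
          H[J2b, I1b] <- t(bb)
        }
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
          blk <- decouple_block(cp, sa[2], sb[2])
          I <- .slice(ao, fi, sa); J <- .slice(ao, se, sb)
          H[I, J] <- blk
          H[J, I] <- t(blk)
        }
    }
  }
  H
}
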