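# Synthetic dataset builders: randomized molecular fixtures in one or both
# toy bases, known-weights datasets for exact parameter recovery, and
# homologous series for extrapolation studies.

.templates <- list(
  h2 = list(species = c("H", "H"),
            positions = rbind(c(0, 0, 0), c(0, 0, 1.40))),
  h2o = list(species = c("O", "H", "H"),
             positions = rbind(c(0, 0, 0),
                               c(1.43, 1.11, 0),
                               c(-1.43, 1.11, 0))),
  nh3 = list(species = c("N", "H", "H", "H"),
             positions = rbind(c(0, 0, 0.2),
                               c(1.77, 0, -0.6),
                               c(-0.89, 1.54, -0.6),
                               c(-0.89, -1.54, -0.6))),
  ch4 = list(species = c("C", "H", "H", "H", "H"),
             positions = rbind(c(0, 0, 0),
                               c(1.18, 1.18, 1.18),
                               c(-1.18, -1.18, 1.18),
                               c(-1.18, 1.18, -1.18),
                               c(1.18, -1.18, -1.18))),
  h4 = list(species = c("H", "H", "H", "H"),
            positions = rbind(c(0, 0, 0), c(1.5, 0.2, 0),
                              c(0.1, 1.6, 0.3), c(1.4, 1.5, 1.2)))
)

#' Build a randomized synthetic dataset
#'
#' Structures are drawn from bond-perturbed molecular templates (Cartesian
#' Gaussian jitter of stated width plus a random rigid rotation), and each
#' structure gets an extended-Hueckel reference record in the requested toy
#' bases. Deterministic under `seed`.
#'
#' @param n_structures number of structures (>= 1).
#' @param templates template names among `r paste(names(.templates),
#'   collapse = ", ")`, cycled.
#' @param seed RNG seed; the dataset is byte-identical for equal seeds.
#' @param bases character subset of `c("toy-min", "toy-big")`.
#' @param jitter Cartesian perturbation width (a.u.).
#' @param rotate apply a random rigid rotation per structure.
#' @param K Wolfsberg-Helmholz constant of the Hueckel references.
#' @param with_alpha store polarizabilities in the records.
#' @return list with `structures` and `records` (one named list per basis
#'   label), plus the generation parameters.
#' @export
make_dataset <- function(n_structures, templates = c("h2o", "nh3", "ch4"),
                         seed = 1, bases = c("toy-min", "toy-big"),
                         jitter = 0.08, rotate = TRUE, K = 1.75,
                         with_alpha = TRUE) {
  stopifnot(n_structures >= 1)
  bad <- setdiff(templates, names(.templates))
  if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structures <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    tp <- .templates[[templates[(s - 1) %% length(templates) + 1]]]
    pos <- tp$positions + matrix(stats::rnorm(length(tp$positions), 0, jitter),
                                 nrow(tp$positions), 3)
    if (rotate) pos <- pos %*% t(random_rotation())
    structures[[s]] <- structure_new(tp$species, pos, unit = "bohr",
                                     id = sprintf("fix%03d", s))
  }
  records <- list()
  for (b in bases) {
    records[[b]] <- lapply(structures, hueckel_record, basis = b, K = K,
                           with_alpha = with_alpha)
    names(records[[b]]) <- vapply(structures, function(x) x$id, "")
  }
  list(structures = structures, records = records,
       params = list(seed = seed, templates = templates, jitter = jitter,
                     rotate = rotate, K = K))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Dataset generated by a known block model (recovery oracle)
#'
#' The reference Hamiltonian of each structure is the model's own
#' prediction, optionally perturbed by Gaussian noise on the coupled
#' components; overlap and position operators come from the closed-form
#' Gaussian integrals, and derived properties from the property layer.
#' With zero noise, ridge pretraining on this dataset must recover the
#' generating weights exactly (up to the vanishing ridge).
#'
#' @param model an `effham_block_model`.
#' @param structures list of structures.
#' @param basis the model basis (with Gaussian exponents).
#' @param noise standard deviation of the component noise (0 for exact).
#' @param seed seed for the noise draws.
#' @param with_alpha store polarizabilities.
#' @return list of reference records (one per structure).
#' @export
known_weights_dataset <- function(model, structures, basis, noise = 0,
                                  seed = 1, with_alpha = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(structures, function(s) {
    feats <- featurize_structure(s, basis, model$config)
    blocks <- predict_blocks(model, s, basis, feats)
    if (noise > 0) {
      blocks$onsite <- lapply(blocks$onsite, function(cl)
        lapply(cl, function(v) v + stats::rnorm(length(v), 0, noise)))
      blocks$pairs <- lapply(blocks$pairs, function(cl)
        lapply(cl, function(v) v + stats::rnorm(length(v), 0, noise)))
    }
    H <- assemble_matrix(blocks, s, basis)
    gi <- gaussian_integrals(s, basis)
    nel <- electron_count(s, basis)
    props <- derived_properties(H, gi$S, gi$X, nel, s, basis, gi$ao_map,
                                with_alpha = with_alpha)
    reference_record(s$id, basis$label, H, gi$S, gi$X, nel,
                     props = list(eps = props$eps, mu = props$mu,
                                  alpha = props$alpha,
                                  bond_order = props$bond_order,
                                  gap = props$gap),
                     ao_order = ao_fingerprint(gi$ao_map))
  })
}

#' Homologous chain series for extrapolation studies
#'
#' Toy series whose reference per-atom polarizability grows with chain
#' length (conjugation emulated by alternating bond lengths, which shrinks
#' the frontier gap as the chain grows), while any strictly local direct
#' property model saturates beyond its cutoff.
#'
#' * `chain-alkene-like`: linear H chain with alternating short/long bonds.
#' * `chain-acene-like`: ladder of two parallel alternating H chains.
#' * `donor-acceptor-chain`: alternating H chain terminated by a C donor
#'   and an O acceptor (on-site shifts through their Hueckel parameters;
#'   this end pair keeps the valence electron count even).
#'
#' @param family series family.
#' @param lengths increasing chain lengths (atoms per chain, even).
#' @param d_short,d_long alternating bond lengths (a.u.).
#' @return list of structures (one per length).
#' @export
extrapolation_series <- function(family = c("chain-alkene-like",
                                            "chain-acene-like",
                                            "donor-acceptor-chain"),
                                 lengths = c(2, 4, 6, 8),
                                 d_short = 1.8, d_long = 2.0) {
  family <- match.arg(family)
  if (any(diff(lengths) <= 0)) stop("lengths must be increasing")
  lapply(lengths, function(nl) {
    z <- cumsum(c(0, rep(c(d_short, d_long), length.out = nl - 1)))
    if (family == "chain-acene-like") {
      pos <- rbind(cbind(0, 0, z), cbind(2.0, 0, z))
      sp <- rep("H", 2 * nl)
    } else {
      pos <- cbind(0, 0, z)
      sp <- rep("H", nl)
      if (family == "donor-acceptor-chain") {
        sp[1] <- "C"; sp[nl] <- "O"
      }
    }
    structure_new(sp, pos, unit = "bohr",
                  id = sprintf("%s_%02d", family, nl))
  })
}

#' Farthest-point subsampling on invariant features
#'
#' Greedy max-min selection on per-structure summed invariant
#' (sigma = 1, lambda = 0) atom features.
#'
#' @param structures list of structures.
#' @param config descriptor configuration.
#' @param n_select number of structures to keep.
#' @return integer indices of the selected structures (no duplicates).
#' @export
farthest_point_sample <- function(structures, config, n_select) {
  if (n_select > length(structures)) stop("n_select exceeds dataset size")
  featvec <- function(s) {
    af <- atom_centered_lambda_features(s, config, 0, 1)
    Reduce(`+`, lapply(af, function(m) m[, 1]))
  }
  nf <- length(featvec(structures[[1]]))
  F <- t(vapply(structures, featvec, numeric(nf)))
  sel <- 1L
  dmin <- sqrt(rowSums((F - matrix(F[1, ], nrow(F), ncol(F), byrow = TRUE))^2))
  while (length(sel) < n_select) {
    cand <- which.max(dmin)
    sel <- c(sel, cand)
    d2 <- sqrt(rowSums((F - matrix(F[cand, ], nrow(F), ncol(F), byrow = TRUE))^2))
    dmin <- pmin(dmin, d2)
  }
  sel
}
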