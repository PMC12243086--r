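# Direct property models: symmetry-adapted linear regression of molecular
# dipoles and polarizabilities as sums of atomic contributions on
# atom-centered lambda-features (the baseline the Hamiltonian models are
# compared against).

# irrep channels per property
.prop_irreps <- list(mu = list(c(1, 1)), alpha = list(c(1, 0), c(1, 2)))

# per-structure, per-species summed atom features for one (sigma, lam)
.species_sums <- function(structure, config, lam, sig, coeffs = NULL) {
  af <- atom_centered_lambda_features(structure, config, lam, sig, coeffs)
  out <- list()
  for (sp in config$species) {
    idx <- which(structure$species == sp)
    if (length(idx) == 0) next
    out[[sp]] <- Reduce(`+`, af[idx])
  }
  out
}

#' Fit a direct property model
#'
#' Ridge regression of target irreducible components on per-species sums of
#' atom-centered features: the same invariant weights apply to all mu
#' components of an irrep.
#'
#' @param structures list of structures.
#' @param targets list (same length) with fields among `mu` (3-vector) and
#'   `alpha` (3 x 3 symmetric).
#' @param config descriptor configuration.
#' @param properties which properties to fit.
#' @param ridge ridge strength.
#' @return object of class `effham_property_model`.
#' @export
fit_property_model <- function(structures, targets, config,
                               properties = c("mu", "alpha"), ridge = 1e-8) {
  weights <- list()
  for (pr in properties) {
    for (ir in .prop_irreps[[pr]]) {
      sig <- ir[1]; lam <- ir[2]
      Zs <- list(); ys <- list()
      for (s in seq_along(structures)) {
        ss <- .species_sums(structures[[s]], config, lam, sig)
        comps <- cartesian_to_irreps(targets[[s]][[pr]])
        if (inherits(comps, "effham_irrep")) comps <- list(comps)
        y <- NULL
        for (cmp in comps) if (cmp$lambda == lam && cmp$sigma == sig)
          y <- cmp$values
        if (is.null(y)) stop("target lacks irrep (", sig, ",", lam, ")")
        # design row per mu: concatenated per-species feature columns
        Z <- do.call(cbind, lapply(config$species, function(sp) {
          m <- ss[[sp]]
          if (is.null(m)) matrix(0, 2 * lam + 1, .feat_dim(config, lam, sig))
          else t(m)
        }))
        Zs[[s]] <- Z; ys[[s]] <- y
      }
      # no per-structure intercept: predictions must stay strictly additive
      # over atoms (the constant atom channel plays the per-atom baseline)
      sol <- .ridge_solve(do.call(rbind, Zs), unlist(ys), ridge,
                          intercept = FALSE)
      weights[[paste(pr, sig, lam, sep = "|")]] <- sol
    }
  }
  out <- list(weights = weights, config = config, properties = properties)
  class(out) <- "effham_property_model"
  out
}

.feat_dim <- function(config, lam, sig) {
  nsp <- length(config$species)
  nch <- nsp * config$n_max
  dim <- 0
  for (l1 in 0:config$l_max) for (l2 in 0:config$l_max) {
    if (lam < abs(l1 - l2) || lam > l1 + l2) next
    if ((-1)^(l1 + l2 + lam) != sig) next
    n1 <- nch + (l1 == 0); n2 <- nch + (l2 == 0)
    dim <- dim + n1 * n2
  }
  dim
}

#' Predict properties with a direct property model
#'
#' Additive over atoms; two molecules farther apart than twice the cutoff
#' predict exactly the sum of their separate predictions.
#'
#' @param model an `effham_property_model`.
#' @param structure a structure.
#' @return list with the predicted `mu` and/or `alpha` in Cartesian form.
#' @export
predict_property_direct <- function(model, structure) {
  config <- model$config
  missing_sp <- setdiff(unique(structure$species), config$species)
  if (length(missing_sp) > 0)
    stop("species without weights: ", paste(missing_sp, collapse = ", "))
  coeffs <- density_expansion(structure, config)
  out <- list()
  for (pr in model$properties) {
    comps <- list()
    for (ir in .prop_irreps[[pr]]) {
      sig <- ir[1]; lam <- ir[2]
      ss <- .species_sums(structure, config, lam, sig, coeffs)
      sol <- model$weights[[paste(pr, sig, lam, sep = "|")]]
      Z <- do.call(cbind, lapply(config$species, function(sp) {
        m <- ss[[sp]]
        if (is.null(m)) matrix(0, 2 * lam + 1, .feat_dim(config, lam, sig))
        else t(m)
      }))
      v <- as.vector(Z %*% sol$w)
      if (!is.null(sol$b)) v <- v + sol$b
      comps[[length(comps) + 1]] <- irrep_component(lam, sig, v)
    }
    out[[pr]] <- irreps_to_cartesian(comps)
  }
  out
}
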