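# Analytic adjoints of the property layer: d(loss)/dH for losses built on
# MO energies, dipoles, polarizabilities and Mayer bond orders.
#
# The chain rule runs through the generalized eigensolve at fixed S. With
# S-orthonormal eigenvectors C and ascending eigenvalues eps,
#   d eps_k = c_k^T dH c_k,
#   d c_k   = sum_{m != k} c_m (c_m^T dH c_k) / (eps_k - eps_m),
# so any loss with per-eigenvalue sensitivities g, density-matrix adjoint
# G_rho and eigenvector adjoint U backpropagates to
#   G_H = C diag(g) C^T + C W C^T,
# with W collecting the (scaled) off-diagonal sensitivities. Exactly
# degenerate pairs carry no net sensitivity for the invariant losses used
# here and are zeroed.

#' MO-energy subset used by energy losses
#'
#' @param n_pred number of predicted MO energies.
#' @param n_occ number of occupied orbitals.
#' @param rule `"all"`, `"occupied"`, or `"occupied+k"` with integer k
#'   (e.g. `"occupied+1"`).
#' @return integer index vector into the ascending energy list.
#' @export
select_mo_indices <- function(n_pred, n_occ, rule = "all") {
  if (rule == "all") return(seq_len(n_pred))
  if (rule == "occupied") return(seq_len(min(n_occ, n_pred)))
  m <- regmatches(rule, regexec("^occupied\\+([0-9]+)$", rule))[[1]]
  if (length(m) == 2)
    return(seq_len(min(n_occ + as.integer(m[2]), n_pred)))
  stop("unknown MO selection rule: ", rule)
}

# Loss terms and output-level adjoints for one structure.
# pred/ref: lists with eps, mu, alpha, bond_order. Returns total loss,
# per-target terms, and adjoints d_eps (full-length vector), d_mu, d_alpha,
# d_B (or NULL when a target is unused).
.loss_terms <- function(pred, ref, targets, weights, norms, eps_select, n_occ) {
  terms <- list(); total <- 0
  d_eps <- NULL; d_mu <- NULL; d_alpha <- NULL; d_B <- NULL
  for (tg in targets) {
    w <- weights[[tg]]; if (is.null(w)) w <- 1
    nrm <- norms[[tg]]; if (is.null(nrm)) nrm <- 1
    if (tg == "eps") {
      if (is.null(ref$eps)) stop("reference record is missing target 'eps'")
      sel <- select_mo_indices(length(pred$eps), n_occ, eps_select)
      if (length(ref$eps) < max(sel))
        stop("reference eps has fewer levels than the selection requires")
      r <- pred$eps[sel] - sort(ref$eps)[sel]
      terms$eps <- mean(r^2) / nrm
      total <- total + w * terms$eps
      d_eps <- numeric(length(pred$eps))
      d_eps[sel] <- w * 2 * r / (length(sel) * nrm)
    } else if (tg == "mu") {
      if (is.null(ref$mu)) stop("reference record is missing target 'mu'")
      r <- pred$mu - ref$mu
      terms$mu <- mean(r^2) / nrm
      total <- total + w * terms$mu
      d_mu <- w * 2 * r / (3 * nrm)
    } else if (tg == "alpha") {
      if (is.null(ref$alpha)) stop("reference record is missing target 'alpha'")
      r <- pred$alpha - ref$alpha
      terms$alpha <- mean(r^2) / nrm
      total <- total + w * terms$alpha
      d_alpha <- w * 2 * r / (9 * nrm)
    } else if (tg == "bond_order") {
      if (is.null(ref$bond_order))
        stop("reference record is missing target 'bond_order'")
      r <- pred$bond_order - ref$bond_order
      terms$bond_order <- mean(r^2) / nrm
      total <- total + w * terms$bond_order
      d_B <- w * 2 * r / (length(r) * nrm)
    } else {
      stop("unknown training target: ", tg)
    }
  }
  list(total = total, terms = terms,
       d_eps = d_eps, d_mu = d_mu, d_alpha = d_alpha, d_B = d_B)
}

# Backpropagate output-level adjoints through the property layer to a
# symmetric d(loss)/dH. sol from solve_generalized on the *predicted* H.
.grad_H <- function(sol, S, X, ao_map, adj) {
  n <- length(sol$eps)
  C <- sol$C
  g_eps <- if (is.null(adj$d_eps)) numeric(n) else adj$d_eps
  G_rho <- NULL
  U <- NULL  # eigenvector adjoint, n x n (column k = dL/d c_k)

  # dipole: mu_a = -Tr(rho X_a) + nuclear
  if (!is.null(adj$d_mu)) {
    G_rho <- matrix(0, n, n)
    for (a in 1:3) G_rho <- G_rho - adj$d_mu[a] * X[[a]]
  }
  # Mayer bond order through P = rho S
  if (!is.null(adj$d_B)) {
    rho <- density_matrix(sol)
    P <- rho %*% S
    Gexp <- adj$d_B[ao_map$atom, ao_map$atom]
    M <- 2 * Gexp * t(P)
    if (is.null(G_rho)) G_rho <- matrix(0, n, n)
    G_rho <- G_rho + M %*% S          # S symmetric
  }
  # polarizability (sum over states)
  if (!is.null(adj$d_alpha)) {
    n_occ <- sol$n_occ
    occ <- seq_len(n_occ); virt <- (n_occ + 1):n
    Co <- C[, occ, drop = FALSE]; Cv <- C[, virt, drop = FALSE]
    Xov <- lapply(X, function(Xa) t(Co) %*% Xa %*% Cv)
    invD <- 1 / outer(sol$eps[occ], sol$eps[virt], function(er, es) es - er)
    G <- (adj$d_alpha + t(adj$d_alpha)) / 2
    Pa <- vector("list", 3)
    for (a in 1:3) {
      acc <- matrix(0, n_occ, n - n_occ)
      for (b in 1:3) acc <- acc + G[a, b] * Xov[[b]]
      Pa[[a]] <- 8 * acc * invD
    }
    # eigenvalue sensitivities through the denominators
    T2 <- matrix(0, n_occ, n - n_occ)
    for (a in 1:3) for (b in 1:3)
      T2 <- T2 + G[a, b] * Xov[[a]] * Xov[[b]]
    T2 <- 4 * T2 * invD^2
    g_eps[occ] <- g_eps[occ] + rowSums(T2)
    g_eps[virt] <- g_eps[virt] - colSums(T2)
    # eigenvector sensitivities
    U <- matrix(0, n, n)
    for (a in 1:3) {
      U[, occ] <- U[, occ] + X[[a]] %*% Cv %*% t(Pa[[a]])
      U[, virt] <- U[, virt] + X[[a]] %*% Co %*% Pa[[a]]
    }
  }

  W <- matrix(0, n, n)
  de <- outer(sol$eps, sol$eps, "-")       # de[k, m] = eps_k - eps_m
  safe <- abs(de) > 1e-10
  if (!is.null(G_rho)) {
    A <- t(C) %*% (G_rho + t(G_rho)) %*% C
    # unsymmetrized sensitivity W_{mk} = f_k A_{mk} / (eps_k - eps_m);
    # the final symmetrization turns it into A (f_k - f_m) / (2 de)
    Fk <- matrix(sol$f, n, n, byrow = TRUE)
    Wr <- matrix(0, n, n)
    Wr[t(safe)] <- (A * Fk / t(de))[t(safe)]
    W <- W + Wr
  }
  if (!is.null(U)) {
    CU <- t(C) %*% U                       # CU[m, k] = c_m^T u_k
    Wu <- matrix(0, n, n)
    Wu[t(safe)] <- (CU / t(de))[t(safe)]
    W <- W + Wu
  }
  GH <- C %*% (diag(g_eps, n) + (W + t(W)) / 2) %*% t(C)
  (GH + t(GH)) / 2
}

#' Property loss between a predicted and a reference record
#'
#' Weighted sum of per-target mean-squared errors. MO energies are compared
#' on the sorted subset picked by `eps_select`; unselected targets are
#' ignored entirely, so the loss is zero iff all selected targets match.
#'
#' @param pred list with any of `eps`, `mu`, `alpha`, `bond_order`
#'   (e.g. from [derived_properties()]).
#' @param ref same shape (e.g. the `props` field of a reference record).
#' @param targets character subset of `c("eps", "mu", "alpha", "bond_order")`.
#' @param weights named list of per-target loss weights (default 1).
#' @param norms named list of per-target normalizations (default 1);
#'   training uses the training-set target variance to make multi-target
#'   sums commensurate.
#' @param eps_select MO-energy selection rule, see [select_mo_indices()].
#' @param n_occ number of occupied orbitals of the prediction.
#' @return list with `total` and per-target `terms`.
#' @export
property_loss <- function(pred, ref, targets, weights = list(),
                          norms = list(), eps_select = "all",
                          n_occ = sum(pred$eps < 0)) {
  if (length(targets) == 0) stop("target set must be nonempty")
  lt <- .loss_terms(pred, ref, targets, weights, norms, eps_select, n_occ)
  list(total = lt$total, terms = lt$terms)
}

#' Property loss and its analytic gradient with respect to H
#'
#' Runs the full differentiable pipeline for one structure: eigensolve of
#' `H` against fixed `S`, property evaluation, loss against the reference,
#' and analytic backpropagation to `dL/dH`. The gradient matches central
#' finite differences on every entry of H (H enters through its symmetric
#' part).
#'
#' @param H predicted Hamiltonian.
#' @param S,X,n_electrons fixed operators of the model basis.
#' @param structure,basis,ao_map geometry and AO bookkeeping.
#' @param ref reference property list.
#' @param targets,weights,norms,eps_select as in [property_loss()].
#' @return list with `loss`, `terms`, `grad_H` (symmetric matrix) and the
#'   predicted `props`.
#' @export
property_loss_grad <- function(H, S, X, n_electrons, structure, basis, ao_map,
                               ref, targets, weights = list(), norms = list(),
                               eps_select = "all") {
  sol <- solve_generalized(H, S, n_electrons)
  rho <- density_matrix(sol)
  pred <- list(eps = sol$eps)
  if ("mu" %in% targets) pred$mu <- dipole(rho, X, structure, basis)
  if ("alpha" %in% targets) pred$alpha <- polarizability(sol, X)
  if ("bond_order" %in% targets)
    pred$bond_order <- mayer_bond_order(rho, S, ao_map)
  lt <- .loss_terms(pred, ref, targets, weights, norms, eps_select, sol$n_occ)
  GH <- .grad_H(sol, S, X, ao_map, lt)
  list(loss = lt$total, terms = lt$terms, grad_H = GH, props = pred)
}
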