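# Indirect training: refine block-model weights by gradient descent on
# property losses computed through the differentiable property layer.
#
# Modes: "simple" targets properties computed in the model basis itself;
# "upscaled" targets properties from a larger-basis reference while the
# effective Hamiltonian keeps the small-basis size and operators (the
# overlap and position operators stay fixed at their small-basis values,
# and are never learned). The periodic delta-learning workflow lives in
# periodic.R and reuses this machinery at the level of band energies.

#' Training configuration for indirect fine-tuning
#'
#' @param targets character subset of `c("eps", "mu", "alpha",
#'   "bond_order")`; nonempty.
#' @param weights named per-target loss weights (default 1).
#' @param mode `"simple"` or `"upscaled"`.
#' @param eps_select MO-energy subset rule (default `"all"` for simple,
#'   `"occupied"` for upscaled, where the small spectrum cannot match the
#'   full large-basis one).
#' @param optimizer `"gd"` (plain gradient descent with step halving when
#'   the trailing-window loss stops decreasing) or `"lbfgs"`
#'   ([stats::optim()] L-BFGS-B with the same analytic gradient).
#' @param lr initial step size (gd).
#' @param n_iter iteration budget.
#' @param seed controls the validation split (and nothing else; the
#'   optimization itself is deterministic full-batch).
#' @param val_fraction held-out fraction by structure-id hash.
#' @param window trailing window (iterations) for the step-halving rule.
#' @param restarts L-BFGS restart budget (fresh Hessian memory per round;
#'   deterministic). More restarts with a tight `factr` drive recovery
#'   problems to machine-level optima; the default is a single fast round.
#' @param factr L-BFGS convergence tolerance (see [stats::optim()]).
#' @export
train_config <- function(targets, weights = list(), mode = c("simple", "upscaled"),
                         eps_select = NULL, optimizer = c("gd", "lbfgs"),
                         lr = 0.01, n_iter = 200, seed = 1,
                         val_fraction = 0.1, window = 50,
                         restarts = 1L, factr = 1e7) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer)
  if (length(targets) == 0) stop("target set must be nonempty")
  bad <- setdiff(targets, c("eps", "mu", "alpha", "bond_order"))
  if (length(bad)) stop("unknown target(s): ", paste(bad, collapse = ", "))
  w <- lapply(targets, function(t) {
    v <- weights[[t]]; if (is.null(v)) 1 else v
  })
  names(w) <- targets
  if (all(unlist(w) == 0)) stop("at least one target weight must be > 0")
  if (is.null(eps_select))
    eps_select <- if (mode == "upscaled") "occupied" else "all"
  list(targets = targets, weights = w, mode = mode, eps_select = eps_select,
       optimizer = optimizer, lr = lr, n_iter = as.integer(n_iter),
       seed = as.integer(seed), val_fraction = val_fraction,
       window = as.integer(window), restarts = as.integer(restarts),
       factr = factr)
}

# small deterministic string hash (for the id-based validation split)
.id_hash <- function(id, seed) {
  v <- utf8ToInt(id)
  h <- as.double(seed %% 1009 + 1)
  for (x in v) h <- (h * 31 + x) %% 1000003
  h
}

#' Assemble training samples
#'
#' Pairs each structure with its small-basis operators and the
#' reference properties of the chosen mode.
#'
#' @param structures list of structures.
#' @param records_small list of records in the model (small) basis.
#' @param basis model basis.
#' @param config descriptor configuration.
#' @param records_target optional list of large-basis records (upscaled
#'   mode); defaults to `records_small`.
#' @param feats_list optional precomputed features.
#' @export
training_samples <- function(structures, records_small, basis, config,
                             records_target = NULL, feats_list = NULL) {
  if (is.null(records_target)) records_target <- records_small
  stopifnot(length(structures) == length(records_small),
            length(structures) == length(records_target))
  keys <- model_keys(basis)
  lapply(seq_along(structures), function(s) {
    rec <- records_small[[s]]
    feats <- if (is.null(feats_list))
      featurize_structure(structures[[s]], basis, config)
    else feats_list[[s]]
    list(structure = structures[[s]], feats = feats,
         plan = .build_block_plan(keys, structures[[s]], basis, feats),
         S = rec$S, X = rec$X, n_electrons = rec$n_electrons,
         ref = records_target[[s]]$props,
         id = structures[[s]]$id)
  })
}

# per-target variance normalizations over a sample set
.target_norms <- function(samples, targets, eps_select) {
  norms <- list()
  for (tg in targets) {
    vals <- unlist(lapply(samples, function(sm) {
      n_occ <- sm$n_electrons / 2
      if (tg == "eps") {
        np <- nrow(sm$S)
        sel <- select_mo_indices(np, n_occ, eps_select)
        sort(sm$ref$eps)[sel]
      } else as.vector(sm$ref[[tg]])
    }))
    norms[[tg]] <- max(stats::var(vals), 1e-12)
  }
  norms
}

# mean loss and flattened gradient over samples
.loss_grad_set <- function(theta, model, pack, samples, basis, tconfig, norms,
                           with_grad = TRUE) {
  model <- .theta_unpack(model, pack, theta)
  total <- 0
  terms <- stats::setNames(numeric(length(tconfig$targets)), tconfig$targets)
  g <- if (with_grad) numeric(length(theta)) else NULL
  for (sm in samples) {
    H <- assemble_matrix(.plan_predict_blocks(model, sm$plan),
                         sm$structure, basis)
    pg <- property_loss_grad(H, sm$S, sm$X, sm$n_electrons, sm$structure,
                             basis, sm$feats$ao_map, sm$ref,
                             targets = tconfig$targets,
                             weights = tconfig$weights, norms = norms,
                             eps_select = tconfig$eps_select)
    total <- total + pg$loss
    for (tg in names(pg$terms)) terms[tg] <- terms[tg] + pg$terms[[tg]]
    if (with_grad)
      g <- .plan_grad_theta(g, pack, sm$plan, pg$grad_H)
  }
  ns <- length(samples)
  list(loss = total / ns, terms = terms / ns,
       grad = if (with_grad) g / ns else NULL)
}

#' Per-target validation mean absolute errors
#'
#' @param model block model.
#' @param samples from [training_samples()].
#' @param basis model basis.
#' @param targets which targets to evaluate.
#' @param eps_select MO-energy subset rule.
#' @return named list of MAEs (plain units: Hartree for eps, a.u. else).
#' @export
evaluate_model <- function(model, samples, basis, targets,
                           eps_select = "all") {
  acc <- stats::setNames(vector("list", length(targets)), targets)
  for (sm in samples) {
    H <- if (!is.null(sm$plan))
      assemble_matrix(.plan_predict_blocks(model, sm$plan), sm$structure, basis)
    else predict_matrix(model, sm$structure, basis, sm$feats)
    sol <- solve_generalized(H, sm$S, sm$n_electrons)
    rho <- density_matrix(sol)
    for (tg in targets) {
      err <- switch(tg,
        eps = {
          sel <- select_mo_indices(length(sol$eps), sol$n_occ, eps_select)
          abs(sol$eps[sel] - sort(sm$ref$eps)[sel])
        },
        mu = abs(dipole(rho, sm$X, sm$structure, basis) - sm$ref$mu),
        alpha = abs(as.vector(polarizability(sol, sm$X) - sm$ref$alpha)),
        bond_order = abs(as.vector(
          mayer_bond_order(rho, sm$S, sm$feats$ao_map) - sm$ref$bond_order)))
      acc[[tg]] <- c(acc[[tg]], err)
    }
  }
  lapply(acc, mean)
}

#' Fine-tune a block model on derived properties
#'
#' Gradients flow prediction -> assembly -> eigensolve -> properties ->
#' loss through the analytic adjoints; optimization is deterministic
#' full-batch, so identical seeds give bit-identical traces. The returned
#' model is the best-validation iterate.
#'
#' @param model pretrained (or zero-initialized) `effham_block_model`.
#' @param samples from [training_samples()].
#' @param basis model basis.
#' @param tconfig a [train_config()].
#' @return list with `model`, `trace` (data.frame: iteration, training
#'   loss, per-target terms, validation loss), `val_ids`, `norms`.
#' @export
finetune <- function(model, samples, basis, tconfig) {
  ids <- vapply(samples, function(sm) sm$id, "")
  h <- vapply(ids, .id_hash, 0, seed = tconfig$seed)
  n_val <- max(1L, floor(tconfig$val_fraction * length(samples)))
  val_idx <- order(h)[seq_len(n_val)]
  if (length(samples) <= 1) val_idx <- integer(0)
  tr_idx <- setdiff(seq_along(samples), val_idx)
  tr <- samples[tr_idx]; va <- samples[val_idx]
  norms <- .target_norms(tr, tconfig$targets, tconfig$eps_select)
  pack <- .theta_pack(model)
  theta <- pack$theta
  trace <- list()
  best <- list(val = Inf, theta = theta)
  eval_val <- function(th) {
    if (length(va) == 0) return(NA_real_)
    .loss_grad_set(th, model, pack, va, basis, tconfig, norms,
                   with_grad = FALSE)$loss
  }
  record <- function(it, lt, vl) {
    trace[[length(trace) + 1]] <<-
      data.frame(iter = it, loss = lt$loss, t(lt$terms), val = vl)
  }
  if (tconfig$optimizer == "gd") {
    lr <- tconfig$lr
    hist <- numeric(0)
    for (it in seq_len(tconfig$n_iter)) {
      lt <- .loss_grad_set(theta, model, pack, tr, basis, tconfig, norms)
      vl <- eval_val(theta)
      record(it - 1L, lt, vl)
      if (!is.finite(lt$loss) || any(!is.finite(lt$grad)))
        stop("non-finite loss or gradient at iteration ", it)
      if (is.finite(vl) && vl < best$val) best <- list(val = vl, theta = theta)
      hist <- c(hist, lt$loss)
      w <- tconfig$window
      if (length(hist) > w && hist[length(hist)] > hist[length(hist) - w]) {
        lr <- lr / 2
        hist <- hist[length(hist)]
      }
      theta <- theta - lr * lt$grad
    }
  } else {
    it <- 0L
    fn <- function(th) {
      lt <- .loss_grad_set(th, model, pack, tr, basis, tconfig, norms,
                           with_grad = FALSE)
      lt$loss
    }
    gr <- function(th) {
      lt <- .loss_grad_set(th, model, pack, tr, basis, tconfig, norms)
      vl <- eval_val(th)
      record(it, lt, vl)
      it <<- it + 1L
      if (is.finite(vl) && vl < best$val) best <<- list(val = vl, theta = th)
      lt$grad
    }
    # optional restarts with a fresh Hessian memory until the loss stalls;
    # recovers from premature line-search termination, stays deterministic
    last <- Inf
    for (round in seq_len(max(1L, tconfig$restarts))) {
      opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = tconfig$n_iter,
                                         factr = tconfig$factr, pgtol = 0))
      theta <- opt$par
      if (!is.finite(opt$value) || opt$value < 1e-12 ||
          last - opt$value < 1e-14 + 1e-6 * abs(last)) break
      last <- opt$value
    }
  }
  final <- .loss_grad_set(theta, model, pack, tr, basis, tconfig, norms,
                          with_grad = FALSE)
  vl <- eval_val(theta)
  record(if (tconfig$optimizer == "gd") tconfig$n_iter else it, final, vl)
  if (is.finite(vl) && vl < best$val) best <- list(val = vl, theta = theta)
  out_theta <- if (length(va) > 0 && is.finite(best$val)) best$theta else theta
  list(model = .theta_unpack(model, pack, out_theta),
       trace = do.call(rbind, trace), val_ids = ids[val_idx], norms = norms)
}
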