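# Precomputed per-structure block plans: flat task lists with resolved
# slices, feature matrices and weight ids, so the inner training loop does
# no bookkeeping. Semantics identical to the generic paths in fit.R.

.build_block_plan <- function(keys, structure, basis, feats) {
  ao <- feats$ao_map
  entries <- list()
  key_rows <- split(seq_len(nrow(keys)), keys$kind)
  comp_rows <- function(kind, sp1, sp2 = sp1, s1, s2) {
    ri <- key_rows[[kind]]
    ri[keys$sp1[ri] == sp1 & keys$sp2[ri] == sp2 &
       keys$n1[ri] == s1[1] & keys$l1[ri] == s1[2] &
       keys$n2[ri] == s2[1] & keys$l2[ri] == s2[2]]
  }
  mk_comps <- function(rows_idx, fsrc) {
    lapply(rows_idx, function(r) {
      lam <- keys$lam[r]; ch <- keys$channel[r]
      list(lam = lam, channel = ch,
           wid = .weight_id(keys$key[r], lam, ch),
           cid = .comp_id(keys$key[r], lam, ch),
           fid = paste(keys$sigma[r], lam, sep = "|"),
           intercept = keys$intercept[r])
    })
  }
  for (i in seq_len(n_atoms(structure))) {
    sp <- structure$species[i]
    shells <- basis$species[[sp]]$shells
    for (a in seq_along(shells)) for (b in a:length(shells)) {
      s1 <- shells[[a]]; s2 <- shells[[b]]
      rows_idx <- comp_rows("on", sp, sp, s1, s2)
      if (length(rows_idx) == 0) next
      entries[[length(entries) + 1]] <- list(
        kind = "on", atom = i, diag = (a == b),
        l1 = s1[2], l2 = s2[2],
        I = .slice(ao, i, s1), J = .slice(ao, i, s2),
        xi = lapply(mk_comps(rows_idx), function(cmp)
          feats$onsite[[i]][[cmp$fid]]),
        comps = mk_comps(rows_idx))
    }
  }
  pt <- feats$pair_table
  for (p in seq_len(nrow(pt))) {
    fi <- pt$first[p]; se <- pt$second[p]
    sp1 <- structure$species[fi]; sp2 <- structure$species[se]
    pid <- paste0(fi, ":", se)
    if (sp1 == sp2) {
      shells <- basis$species[[sp1]]$shells
      for (a in seq_along(shells)) for (b in a:length(shells)) {
        s1 <- shells[[a]]; s2 <- shells[[b]]
        rows_idx <- comp_rows("ss", sp1, sp1, s1, s2)
        if (length(rows_idx) == 0) next
        comps <- mk_comps(rows_idx)
        xi <- lapply(comps, function(cmp) {
          xf <- feats$pair_fwd[[pid]][[cmp$fid]]
          xb <- feats$pair_bwd[[pid]][[cmp$fid]]
          if (cmp$channel == "+") (xf + xb) / sqrt(2) else (xf - xb) / sqrt(2)
        })
        entries[[length(entries) + 1]] <- list(
          kind = "ss", pid = pid, diag = (a == b),
          l1 = s1[2], l2 = s2[2],
          If = .slice(ao, fi, s1), Jf = .slice(ao, se, s2),
          Ib = .slice(ao, se, s1), Jb = .slice(ao, fi, s2),
          xi = xi, comps = comps)
      }
    } else {
      for (sa in basis$species[[sp1]]$shells)
        for (sb in basis$species[[sp2]]$shells) {
          rows_idx <- comp_rows("sd", sp1, sp2, sa, sb)
          if (length(rows_idx) == 0)
            stop("no model keys for species pair ", sp1, "-", sp2)
          comps <- mk_comps(rows_idx)
          entries[[length(entries) + 1]] <- list(
            kind = "sd", pid = pid, diag = FALSE,
            l1 = sa[2], l2 = sb[2],
            I = .slice(ao, fi, sa), J = .slice(ao, se, sb),
            xi = lapply(comps, function(cmp)
              feats$pair_fwd[[pid]][[cmp$fid]]),
            comps = comps)
        }
    }
  }
  list(entries = entries, ao_map = ao, pair_table = pt,
       n_atoms = n_atoms(structure))
}

.plan_predict_blocks <- function(model, plan) {
  onsite <- rep(list(list()), plan$n_atoms)
  pairs <- list()
  W <- model$weights; B <- model$intercepts
  for (en in plan$entries) {
    for (ci in seq_along(en$comps)) {
      cmp <- en$comps[[ci]]
      w <- W[[cmp$wid]]
      if (is.null(w))
        stop("model has no weights for block key ", cmp$wid,
             " (species pair absent at training)")
      v <- as.vector(crossprod(en$xi[[ci]], w))
      if (cmp$intercept && !is.null(B[[cmp$wid]])) v <- v + B[[cmp$wid]]
      if (en$kind == "on") onsite[[en$atom]][[cmp$cid]] <- v
      else {
        if (is.null(pairs[[en$pid]])) pairs[[en$pid]] <- list()
        pairs[[en$pid]][[cmp$cid]] <- v
      }
    }
  }
  out <- list(onsite = onsite, pairs = pairs, pair_table = plan$pair_table,
              ao_map = plan$ao_map)
  class(out) <- "effham_blocks"
  out
}

.plan_grad_theta <- function(gtheta, pack, plan, G_H) {
  for (en in plan$entries) {
    if (en$kind == "on") {
      sc <- if (en$diag) 1 else 2
      cpl <- couple_block(sc * G_H[en$I, en$J, drop = FALSE], en$l1, en$l2)
    } else if (en$kind == "sd") {
      cpl <- couple_block(2 * G_H[en$I, en$J, drop = FALSE], en$l1, en$l2)
    } else {
      gf <- couple_block(2 * G_H[en$If, en$Jf, drop = FALSE], en$l1, en$l2)
      if (en$diag) {
        cpl <- lapply(gf, function(v) v / sqrt(2))
      } else {
        gb <- couple_block(2 * G_H[en$Ib, en$Jb, drop = FALSE], en$l1, en$l2)
        cpl <- list()  # per channel below
      }
    }
    for (ci in seq_along(en$comps)) {
      cmp <- en$comps[[ci]]
      idx <- pack$idx[[cmp$wid]]
      if (is.null(idx)) next
      lc <- as.character(cmp$lam)
      g <- if (en$kind == "ss" && !en$diag) {
        if (cmp$channel == "+") (gf[[lc]] + gb[[lc]]) / sqrt(2)
        else (gf[[lc]] - gb[[lc]]) / sqrt(2)
      } else cpl[[lc]]
      gtheta[idx] <- gtheta[idx] + as.vector(en$xi[[ci]] %*% g)
      bix <- pack$bidx[[cmp$wid]]
      if (!is.null(bix)) gtheta[bix] <- gtheta[bix] + sum(g)
    }
  }
  gtheta
}
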