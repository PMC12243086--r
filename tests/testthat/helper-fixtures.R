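# Shared fixtures: tiny perturbed molecules with known toy-basis records,
# plus small utilities used across the suite. Everything is generated in
# code; no stored data.

# asymmetric 4-atom fixture with 7 AOs in toy-min (nondegenerate frontier)
nh3_fixture <- function() {
  structure_new(c("N", "H", "H", "H"),
                rbind(c(0.05, -0.03, 0.11),
                      c(1.91, 0.10, -0.20),
                      c(-0.80, 1.75, 0.10),
                      c(-0.85, -1.60, 0.43)),
                unit = "bohr", id = "nh3_fix")
}

h2_fixture <- function(r = 1.4) {
  structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)),
                unit = "bohr", id = "h2_fix")
}

# block-diagonal real Wigner rotation acting on all AOs of a structure
ao_rotation <- function(ao_map, R) {
  d <- nrow(ao_map)
  D <- matrix(0, d, d)
  i <- 1
  while (i <= d) {
    l <- ao_map$l[i]
    D[i:(i + 2 * l), i:(i + 2 * l)] <- wigner_d_real(l, R)
    i <- i + 2 * l + 1
  }
  D
}

rotate_structure <- function(s, R, id = paste0(s$id, "_rot")) {
  structure_new(s$species, s$positions %*% t(R), lattice = s$lattice,
                unit = "bohr", id = id)
}

# central finite difference of f at x (scalar input)
fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# relative max deviation between the analytic gradient matrix and
# elementwise central finite differences of loss_fn(H)
grad_vs_fd <- function(loss_fn, grad, H, entries, h = 1e-6) {
  maxrel <- 0
  for (e in entries) {
    i <- e[1]; j <- e[2]
    Hp <- H; Hp[i, j] <- Hp[i, j] + h
    Hm <- H; Hm[i, j] <- Hm[i, j] - h
    fd <- (loss_fn(Hp) - loss_fn(Hm)) / (2 * h)
    maxrel <- max(maxrel, abs(fd - grad[i, j]) / max(abs(fd), 1e-10))
  }
  maxrel
}

# deterministic entry sample for FD checks
entry_sample <- function(d, n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(k) sample.int(d, 2, replace = TRUE))
}

# small H-only training world reused by model / training tests
h_world <- function(n = 20, seed = 7) {
  basH <- toy_basis("toy-min", "H")
  cfgH <- descriptor_config("H", cutoff = 6, n_max = 2, l_max = 1)
  structs <- make_dataset(n, templates = "h4", seed = seed, bases = "toy-min",
                          with_alpha = FALSE)$structures
  recs <- lapply(structs, hueckel_record, basis = basH, with_alpha = FALSE)
  list(basis = basH, config = cfgH, structures = structs, records = recs)
}
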