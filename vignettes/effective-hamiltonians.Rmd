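---
title: "Effective Hamiltonians as a trainable, differentiable layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective Hamiltonians as a trainable, differentiable layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`effham` treats the effective single-particle Hamiltonian of a molecule or
solid as an intermediate, trainable layer between a geometric description
of the structure and the observables a quantum-mechanics calculation would
deliver. This vignette is the package's own account of the science: the
model and its assumptions, the parameters that matter, what the synthetic
reference engine does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The model

### Block structure and symmetry adaptation

In a localized atomic-orbital (AO) basis the Hamiltonian decomposes into
sub-blocks labeled by a pair of shells `(n, l)` and `(n', l')` on a pair of
atoms. Each block is re-expressed in irreducible components of O(3) by a
real Clebsch–Gordan contraction over both magnetic indices; the admissible
angular orders are `λ ∈ [|l−l'|, l+l']`, and each component carries an
inversion label `σ = (−1)^(l+l'+λ)` (the product of two real harmonics has
parity `(−1)^(l+l')`, and a natural λ-tensor carries `(−1)^λ`). The real
coupling matrices are built exactly: complex Clebsch–Gordan coefficients
from Racah's closed form, conjugated by the real↔complex spherical-harmonic
unitary; parity-odd couplings come out purely imaginary and are rotated
onto the real axis, and an overall sign is fixed deterministically so the
`(l,l) → λ=0` coupling is the positive trace map. Stacked over λ the
transform is orthogonal, so coupling preserves Frobenius norms and
decoupling is its exact inverse — properties the test suite asserts at
1e-12.

Each coupled component is modeled linearly on an equivariant pair
descriptor of matching `(σ, λ)`, with invariant weights shared across the
`2λ+1` components and an intercept only on invariant components — any
other intercept would break equivariance. Atom relabeling maps a block to
the transpose of its partner block, so same-species pair blocks are
symmetrized into even/odd permutation channels `(forward ± backward)/√2`,
each with its own weights; for coinciding shell pairs only the channel of
matching permutation parity survives. Assembly places every decoupled
block together with its transpose, making `H = Hᵀ` an identity of the
construction rather than a numerical property.

### Descriptors

Atom-centered neighbor densities are expanded on `n_max` Gaussians,
equispaced on `[0, cutoff]` and Löwdin-orthonormalized on their quadrature
Gram matrix, times real spherical harmonics up to `l_max`, times a smooth
cosine cutoff. λ-features are Clebsch–Gordan products of two expansions on
one center (atom features) or of the two-center displacement expansion
with either endpoint's density (pair features). A constant scalar channel
is appended to the density on the *first* center only, so the bare
two-center expansion enters the feature set exactly once — appending it on
both sides would duplicate rows and make the per-block weights
non-identifiable, which matters for the exact-recovery tests below.

Defaults: `cutoff = 5` a.u. (configurable; pair blocks beyond it are zero
by construction), `n_max = 4`, `l_max = 4`, radial width `cutoff/n_max` so
adjacent radial functions overlap. `l_max` must reach at least twice the
largest basis angular momentum or some block channels have no features at
all. The tests and experiments use smaller values (`n_max` 2–3, `l_max`
1–2) matched to the s/p toy bases; these sizes were chosen to keep each
experiment's feature space comfortably identifiable from a few dozen small
molecules.

### The property layer and its adjoints

From a predicted `H` (with the overlap `S`, position operators `X` and
electron count fixed by the basis — they are never learned), the package
computes MO energies, the closed-shell density matrix, dipoles,
sum-over-states polarizabilities, Mayer bond orders, the HOMO–LUMO gap,
and band energies for solids. The implemented polarizability is

    α_ab = 4 Σ_{i∈occ, s∈virt} x^a_is x^b_is / (ε_s − ε_i),

whose overall sign and factor are pinned by an oracle rather than by
transcription: it must equal the central finite-field derivative of the
dipole under `H(E) = H + E·X` (the package's tests require agreement to
1e-4 relative) and be positive semidefinite for ground-state occupations.

Every operation carries a closed-form reverse-mode gradient with respect
to `H`. With S-orthonormal eigenvectors and fixed `S`, first-order
perturbation theory gives `dε_k = c_kᵀ dH c_k` and
`dc_k = Σ_{m≠k} c_m (c_mᵀ dH c_k)/(ε_k − ε_m)`; eigenvalue, density-matrix
and eigenvector sensitivities of each loss are collected in the MO basis
and mapped back. Exactly degenerate pairs are zeroed: for the invariant
losses used here their net sensitivity cancels, and the polarizability
separately refuses occupied–virtual gaps below 1e-8 where the response
genuinely diverges. All observables are functions of the symmetric part of
`H`, so the gradient is well defined entry by entry and is verified
against central finite differences (step 1e-6, relative error < 1e-5) for
every target. Losses are restricted to degeneracy-safe functionals
(spectra, traces, quadratic property mismatches); gradients *through* a
degenerate crossing are not defined and not attempted.

### Training

Four model classes mirror the design space the package exists to explore:
a strictly local direct property model (per-species symmetry-adapted ridge
regression of dipole and polarizability irreps, intentionally without a
per-structure intercept so predictions stay strictly additive over atoms);
a direct Hamiltonian model (per-block ridge on coupled reference blocks);
and simple/upscaled indirect models obtained by fine-tuning the block
weights on property losses, where "upscaled" means the targets come from a
larger-basis reference while the model keeps the small-basis size and
operators.

The ridge systems are solved through the SVD of the (centered) design with
the penalty scaled per sample. Two consequences are deliberate: duplicating
every training structure leaves the fit unchanged, and the vanishing-ridge
limit reaches the minimum-norm least-squares solution at the conditioning
of the design itself rather than of its normal equations. That is what
makes the exact-recovery oracle meaningful: weights generated by a ridge
fit lie in the design's row space, so refitting noiseless data at ridge
1e-12 must return them to ~1e-7 — a property the acceptance suite asserts,
and that a normal-equations solver with a fixed jitter cannot deliver.
At `ridge = 0` a rank-deficient design is an error that suggests a positive
ridge. `ridge = "auto"` selects a per-key strength by generalized
cross-validation on a log grid.

Fine-tuning is deterministic full-batch optimization: either plain
gradient descent with the trailing-window step-halving rule, or L-BFGS
(`stats::optim`) driven by the same analytic gradient; identical seeds give
bit-identical traces. L-BFGS is the workhorse for the heavier experiments
because it converges in tens of evaluations where gradient descent needs
thousands; for recovery-style problems whose optimum is an exact fit, a
small number of deterministic restarts with a fresh Hessian memory and a
tight convergence tolerance (`restarts`, `factr` in `train_config`)
pushes the loss to the machine-level optimum — single L-BFGS runs can
stall at line-search breakdowns several orders of magnitude above it. Per
target, losses are mean-squared errors normalized by the training-set
target variance so multi-target sums are commensurate; MO-energy losses
compare a sorted subset (`all`, `occupied`, or `occupied+k` — the latter
reproducing the occupied-plus-one-empty-state-per-atom selection used for
band training). The validation split (default 10%) is by a deterministic
hash of structure ids, and the best-validation iterate is returned.

### Periodic systems

Real-space translated-cell matrices `H(t)` with the hermiticity tie
`H(−t) = H(t)ᵀ` are Bloch-summed with fractional k (`phase e^{2πi k·t}`)
and diagonalized against `S(k)`. Delta-learning targets the difference
between a small-basis baseline band structure and large-basis reference
bands on matched (band, k) pairs — matching is by sorted index, with no
crossing resolution, because any disentanglement heuristic would be a
second model. The correction `ΔH(t)` is predicted by the same block model
operating on periodic pair features (neighbor densities include lattice
images; pairs are canonicalized by lexicographic translation), and band
losses backpropagate through the complex eigensolve via
`dε/dΔH(t) = Re(c* ∘ c · e^{2πi k·t})`.

## The synthetic reference engine

All experiments run on fixtures built in code: closed-form Gaussian
overlap and position integrals for s/p shells (Obara–Saika recursion,
normalized so `diag(S) = 1`, satisfying `X(r+d) = X(r) + dS` exactly) and
extended-Hückel Hamiltonians `H_ηη' = K/2 (h_η + h_η') S_ηη'` with
`K = 1.75`. The Hückel form was chosen because it produces hermitian,
equivariant, distance-decaying Hamiltonians from the overlap alone, in
closed form. Two paired bases make basis-set effects computable: "toy-min"
(H: 1s; C/N/O: 2s2p, single Gaussians with roughly VSIP-scale on-site
energies) and "toy-big", which splits every shell into two even-tempered
exponents (ratio 2.5) with the diffuse copy shifted up by 0.15 Hartree.
The split creates a genuine, strictly positive gap between the bases for
every observable, which is the normalization denominator of the upscaled
experiments. Datasets are Cartesian-jittered, randomly rotated molecular
templates (water-, ammonia-, methane-like, H₂, H₄ clusters), byte-identical
under a fixed seed; effective charges equal valence counts so neutral
systems have translation-invariant dipoles.

What the engine does *not* emulate: self-consistency (the reference is a
single diagonalization by construction, matching the package's scope),
electron–electron interaction physics, chemical accuracy of any kind, core
states, shells beyond p, or open shells. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery —
equivariance, gradients, recovery, the qualitative design-space and
extrapolation phenomenology — not predictive accuracy for real chemistry,
which depends on real reference data imported through the record
container.

The extrapolation series deserves one note: conjugation is emulated by
alternating bond lengths (defaults 1.8/2.0 a.u.) on hydrogen-like chains.
Weak alternation keeps the frontier gap closing over the tested lengths,
so the reference per-atom polarizability still grows where a local model's
prediction has saturated — the contrast the series exists to exhibit;
strong alternation would saturate the reference itself within a few
repeat units. The donor–acceptor variant terminates the chain with a C/O
pair, which both shifts the end on-site energies and keeps the electron
count even.

## Numerical choices

* **Eigensolves** go through Löwdin orthogonalization with an eigenvalue
  floor of 1e-10 on `S`; below it the overlap is reported as not positive
  definite. Eigenvector phases are fixed by making the largest-magnitude
  entry positive.
* **Eigenbasis alignment** orders both spectra ascending and fixes
  degenerate clusters (gap < 1e-8) by an orthogonal Procrustes rotation
  against the reference eigenvectors; without it the alignment is
  non-unique. Outputs stay in the orthogonalized frame.
* **Decay profiles** use a 0.25 a.u. moving-average window by default and
  report a curve point only where at least five samples fall in the
  window.
* **Containers** (records, features, models, datasets) are R's native
  serialization, version 2, with a documented layout and an AO-order
  fingerprint; round trips are bit-exact. Importers of external reference
  data must permute matrices into the canonical AO order (atoms in input
  order, shells in basis order, m ascending, real harmonics without
  Condon–Shortley phase) — conventions of external engines differ and are
  deliberately not guessed.
* **Intercepts** are per full block key (finer than per species pair),
  one per invariant non-antisymmetric channel.
* **Problem sizes.** The shipped experiments use 36–50 structures,
  feature spaces of a few tens of dimensions per channel, 120–150
  optimizer iterations (with up to 3 restarts for recovery problems), 4–8
  AO matrices, and four-structure toy solids on 6-point k-grids. These
  sizes make every experiment identifiable and fully converged while each
  suite stays in the minutes range; they are stated here as the package's
  chosen study conditions.

## Known limitations

* Linear readouts only — deliberately, to keep the design space about the
  quantum-mechanics-facing choices; nonlinear models would slot in at
  `predict_blocks` without touching the property layer.
* Closed-shell, integer-occupation systems; no self-consistency, no
  finite-temperature occupations, no spin–orbit or half-integer angular
  momenta.
* Overlap and position operators are never learned; an indirect model's
  effective Hamiltonian is therefore only defined relative to the fixed
  operator set it was trained with.
* The fixture engine stops at p shells; d-shell blocks exercise the
  algebra in unit tests only.
* Band delta-learning matches bands by sorted index and will blur avoided
  crossings.
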