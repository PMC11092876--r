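---
title: "Flow matching for molecules on the simplex: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow matching for molecules on the simplex: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model and its assumptions, the parameters that matter, what
the synthetic data does and does not establish, and the places where the
design was genuinely open and a choice had to be made.

## The model

A molecule is a fully connected attributed graph `g = (X, A, C, E)`:
positions (Å), one-hot atom types, formal charges, and bond orders over all
unordered atom pairs, with an explicit "none" bond category so the pair set
is total. Bond rows are stored once per unordered pair in lexicographic
order; the directed two-edge view exists only inside the network.

Flow matching learns a time-dependent vector field whose ODE transports a
prior over such graphs to the data distribution. Conditioning on trajectory
endpoints `z = (g0, g1)` gives the deterministic linear interpolant
`g_t = (1 - alpha_t) g0 + alpha_t g1`, one cosine schedule
`alpha_t = 1 - cos^2((pi/2) t^nu)` per modality, and conditional velocity
`alpha'_t (g1 - g0)` — algebraically equal to
`(alpha'_t/(1 - alpha_t)) (g1 - g_t)` wherever `alpha_t < 1`. That second
form motivates the endpoint parameterization: the network predicts the
destination molecule `g1_hat(g_t, t)` and the velocity is reconstructed
from it. Endpoint prediction is what makes simplex constraints enforceable:
a softmax head guarantees the predicted categorical rows are distributions,
and each Euler update with step weight `dt * alpha'/(1-alpha) <= 1` is then
a convex combination of two simplex points.

Assumptions worth stating: trajectories are deterministic (no
diffusion-style stochasticity); a single `t ~ U(0,1)` is shared across
modalities per training example; the data distribution is represented by
one-hot vertices, so simplex flows terminate on the boundary that the
strict-interior definition of the simplex excludes — vertices are
deliberately admitted everywhere in this package.

## Tunable parameters

* `nu` (per modality, default 1): cosine schedule exponent; larger values
  delay the prior-to-data transformation. The exponents used by the
  original large-scale models are unpublished, so everything downstream is
  parameterized over `nu` and tests sweep `nu` in {0.5, 1, 2, 3} rather
  than asserting any particular setting.
* `eta = (3, 0.4, 1, 2)`: loss weights for X, A, C, E.
* `w(t) = min(max(0.005, alpha/(1-alpha)), 1.5)`: clamped endpoint loss
  weight; the raw weight diverges as `alpha -> 1` and is kept available
  only behind `raw_weight = TRUE` for ablation.
* `blur_sigma` (default 0.15): standard deviation of the Gaussian blur
  applied to degenerate simplex priors (marginal-simplex, barycenter)
  before projection back onto the simplex. Without blur these priors have
  support on a finite point set and training collapses. The original work
  states that blurring helps but not the width; 0.15 was chosen once as a
  value that visibly widens the support (typical blurred rows stay off the
  vertices) without drowning the marginal structure, and is configurable.
* `omega_max` (default 100): cap on the Dirichlet-path concentration
  `omega_t = omega_max * alpha_t + 1`. The Dirichlet conditional path only
  reaches the vertex delta as `omega -> infinity`, so any implementation
  needs an explicit finite cap; 100 concentrates ~99% of the mass on the
  target class at `t = 1` for d = 5.
* Network sizes (default 2 update blocks, 32 scalar / 4 vector channels, 16
  edge features, 8 radial basis functions): desk-scale defaults chosen for
  CPU training in R; all config-driven. The contracts (equivariance,
  simplex heads, pair symmetry), not the sizes, are the tested content.
* Sampling: 100 evenly spaced Euler steps by default; quality is known not
  to improve beyond that in the large-scale setting.

## Numerical choices

* **Simplex projection** is the exact Euclidean projection via the
  sort-based algorithm, validated against a barycentric grid search. The
  original work says only "projected back onto the simplex"; Euclidean
  projection is the minimal-distortion choice and is idempotent and
  non-expansive, both tested. Blur is applied per-coordinate before the
  projection only.
* **Terminal step.** The endpoint weight `alpha'/(1-alpha)` is singular at
  `t = 1`, and how the original sampler handles it is unspecified. Here
  integration runs on `[0, 1 - 1e-4]`, every step clamps
  `dt * alpha'/(1-alpha)` to 1 (preserving convex combinations, hence the
  simplex), and after the last step the categorical modalities jump to the
  final endpoint prediction while positions keep their integrated value.
* **OT alignment.** The optimal permutation + proper rotation problem is
  solved exactly (all permutations, each with a Kabsch fit) for N <= 7 and
  by multi-start alternating assignment/Kabsch above that. Plain
  alternation is the standard point-cloud practice but is a local search
  with ICP-style minima; exact search at tiny N is what makes the
  brute-force oracle test meaningful, and the alternating and
  single-assignment routes remain available behind `method=`. Rotations are
  constrained to det +1 — reflections would silently mirror chirality.
* **Cross products and vector scale.** The cross-product GVP variant makes
  the network chirality-sensitive. With node vector features initialized to
  zero (their defining contract) the only early geometric direction is the
  edge unit vector, so cross products of nearly parallel, small vectors
  start numerically negligible. The vector path therefore runs at twice the
  Xavier scale with a `tanh(|v|)/|v|` norm squash on vector outputs: the
  squash is a positive scalar per channel, so equivariance and reflection
  behavior are untouched, while channel norms are bounded and reflection
  sensitivity becomes a robust O(1e-2) effect instead of a 1e-6 one.
* **Cross-entropy on probabilities.** The loss consumes the softmax output
  (clipped at 1e-12) rather than logits, because the simplex guarantee
  places the softmax inside the model; tests cover the perfect-prediction
  and hand-computed cases.
* **Losses are per-row means** within each modality, which makes the total
  invariant under consistent atom relabeling (tested) and keeps `eta`
  comparable across molecule sizes.
* **Position loss uses the squared norm.** The endpoint objective's
  printed form is ambiguous between norm and squared norm; squared error is
  used (the conventional CFM choice), flagged here for review.
* **Argmax decoding ties** break toward the lowest category index, making
  decoding deterministic.
* **One-hot labels are 1-based** (R convention) throughout the R API.

## Training

`train_flowmol()` draws a minibatch of data molecules, pairs each with a
fresh prior sample of the same size, optionally OT-aligns the prior side
(permutation + rotation applied to g0 only, so the data distribution is
untouched), samples one t per molecule, interpolates, and takes an Adam
step on the weighted loss. Gradients come from a small reverse-mode tape
(`R/autodiff.R`) whose every operator is gradient-checked against central
finite differences in the test suite; there is no deep-learning framework
in the target environment, and numerical differentiation of a ~20k
parameter network would be hopeless. `flow_type = "dirichlet"` swaps the
interpolated categorical state for a draw from the Dirichlet conditional
path around the data class; it requires the uniform-simplex prior (the
path is not conditioned on g0) and the endpoint objective, and invalid
combinations are rejected at config validation.

## Synthetic fixtures: what a green test establishes

`generate_molecules()` grows random trees over {C, N, O, F} with exact
valence bookkeeping, caps open valences with hydrogens, optionally closes
one ring, and relaxes positions under a harmonic bond-length/soft-repulsion
objective. Every fixture is valence-exact, 100% stable against its own
valency table, and sanitizable by RDKit. `make_toy_task()` provides one-hot
draws from a fixed categorical distribution for studying simplex flows in
isolation.

What the fixtures emulate: the data types and invariants of real molecule
sets (explicit hydrogens, formal charges, bond orders including aromatic in
the hand-built benzene fixture, sane geometry scales, atom-count
histograms). What they do not: realistic chemistry (no stereochemistry, no
conformational ensembles, bond lengths from a toy objective, molecules an
order of magnitude smaller than drug-like data). A green end-to-end test
therefore establishes that the machinery — priors, alignment, training,
integration, decoding, metrics — works and that learning happens (loss
falls, some sampled molecules are valid); it says nothing about competitive
sample quality, which in the original setting requires GPU-scale training
on curated datasets. Energy-divergence tests compare distributions of MMFF
energies between fixture sets, not absolute energies.

## Open design points resolved here

* Charge vocabulary: the reference data's charge set is not enumerated in
  the source; the default codebook uses {-1, 0, +1} and the set is
  configurable.
* Time conditioning and distance featurization of the network are not
  specified at the level reproduced here; t is appended to node scalar
  features and distances enter through Gaussian RBFs — simple
  invariance-preserving substitutes, not claims about the original.
* The evaluation protocol's confidence intervals use the normal
  approximation over repeats (`eval_report()`), labeled as such.
* JS divergence is reported in nats by default (configurable to bits); the
  energy histograms share Freedman–Diaconis bins over the pooled sample
  with a floor of 20 bins.

## Known limitations

* Pure-R training is slow; desk-scale experiments (hundreds of steps,
  molecules under ~12 atoms) are the intended regime.
* Validity and energies require a Python RDKit on the PATH; stability and
  all geometry/simplex machinery are pure R.
* No stochastic (SDE) trajectories, no likelihoods, no higher-order
  integrators, no batch-level OT across molecules — all out of scope.
* The alternating OT method above N = 7 is a local search; its cost is
  bounded by its start and never beats the exact solver, but global
  optimality is not guaranteed there.
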