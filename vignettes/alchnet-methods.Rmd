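---
title: "Path-aware prediction of window-level alchemical free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-aware prediction of window-level alchemical free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchnet)
```

## The quantity being modelled

Alchemical free energy methods estimate a binding free energy by
transforming one molecular state into another along a non-physical coupling
coordinate $\lambda \in [0,1]$. A run simulates a series of "windows", one
per $\lambda$ value, and a multistate estimator turns the sampled energies
into the *cumulative* free energy of each window,
$F(\lambda) = G(\lambda) - G(0)$, with $F(0) = 0$ by definition. A
thermodynamic cycle with two legs then gives the relative binding free
energy of a ligand pair,

$$\Delta\Delta G = s_1 F_1(\lambda_{end}) + s_2 F_2(\lambda_{end}),
\qquad (s_1, s_2) = (+1, -1)\ \text{by default},$$

and the analogous combination over a complex/solvent decoupling pathway
gives an absolute binding free energy.

`alchnet` regresses $F(\lambda)$ itself — the process-level curve, not just
its endpoint. This is what enables the two downstream applications: direct
$\Delta\Delta G$/$\Delta G$ prediction, and $\lambda$-schedule design for
classical runs, where the predicted profile stands in for the trial
simulations one would otherwise need.

## Architecture

**Graphs.** Each endpoint is a molecular graph with two *distinct* edge
sets, both stored symmetrically: covalent edges from the bond list with a
bond-order one-hot (single/double/triple/aromatic/other), and non-covalent
edges between atom pairs within 4.5 Å (config
`noncovalent_cutoff_angstrom`), excluding 1-2 and 1-3 covalent neighbors,
with the distance expanded in 16 Gaussian radial basis functions on
[0, cutoff]. In a complex graph, ligand–pocket pairs within the cutoff get
cross non-covalent edges; pocket-internal edges are covalent only. We
exclude pocket–pocket non-bonded edges deliberately: the pocket is a fixed
scaffold across a perturbation and its internal non-bonded structure is
constant, so modelling it adds cost without discriminative signal. Pocket
covalent bonds are inferred from interatomic distances (≤ 1.85 Å between
heavy atoms, ≤ 1.2 Å for X–H) rather than residue templates; this treats
toy and real pockets uniformly and is insensitive to nonstandard residues.

**Features.** 28 per-atom dimensions: element one-hot over
H/C/N/O/F/P/S/Cl/Br/I plus an "other" bucket (11), degree 0–6 (7), formal
charge −2..+2 (5), aromatic flag (1), ligand/pocket origin (2), and a
2-bucket saturation flag standing in for hybridization. Everything is
invariant to rigid motion by construction — only distances and topology
enter — which carries the SE(3) invariance of the predictions (tested to
< 1e-5 kcal/mol under random rigid motions).

**Message passing.** $L = 3$ residual rounds (config `n_layers`). Each
round computes per-edge messages with separate weight matrices for
covalent and non-covalent edges (the message is a SiLU of the source
embedding and the edge feature, linearly mixed), sums them at the
destination, adds a self term, and applies SiLU. For complex-type graphs
only, a *heterogeneous block* then transforms ligand-origin and
pocket-origin nodes with distinct weights; ligand-only graphs skip it.
Readout is sum pooling over ligand nodes and pocket nodes separately,
concatenated and projected — keeping the two contributions separable was a
free choice that makes the ABFE ligand-graph case degenerate gracefully
(the pocket half is zero).

**$\lambda$ and legs.** $\lambda$ is expanded in 16 Gaussian basis
functions with centers evenly spaced on [0, 1] and width equal to the
spacing, then linearly mapped to the hidden dimension. The two legs of the
cycle share all weights and differ only in the order of endpoint
concatenation: leg 1 encodes $(g_A \| g_B)$, leg 2 $(g_B \| g_A)$. Fusion
of the leg representation with the $\lambda$ embedding is an elementwise
product followed by a linear layer and SiLU. The MLP head emits a scalar
and the prediction is $\mathrm{head}(\lambda) - \mathrm{head}(0)$.

Three exact identities follow from this construction, independent of the
weights: $F(\text{leg}, 0) = 0$ for every input; identical endpoints give
identical legs and hence $\Delta\Delta G = 0$ exactly (symmetric
perturbations); and swapping the endpoints exchanges the legs, so
$\Delta\Delta G$ negates exactly. We chose to enforce the anchor by
subtraction rather than hoping training learns it: a model whose zero is
learned can only be worse at these identities, never better.

**Defaults** (all in `alch_config()`): `d_hidden = 128`, `n_layers = 3`,
SiLU activation, sum pooling, `d_lambda_basis = 16`, `d_dist_basis = 16`.
The tests and examples use reduced widths (12–64) because the synthetic
task saturates well below the default capacity.

## Training

Labels are per-window cumulative free energies with a per-sample
uncertainty $\sigma$ (kcal/mol). The loss is a weighted MSE with
inverse-variance weights

$$w_i = \frac{1}{\sigma_i^2 + \varepsilon^2}, \qquad \varepsilon = 0.1\ \text{kcal/mol},$$

rescaled to mean 1 within each batch; $\varepsilon$ bounds the weight of a
nominally exact label and sets the scale below which uncertainties are
treated as equivalent. The weighting can be disabled
(`use_reliability_weights = FALSE`), which is the default posture we would
recommend when uncertainties are uninformative or uniformly large, as in
small noisy ABFE datasets.

Optimization is AdamW (decoupled weight decay 1e-4, biases undecayed) at
learning rate 1e-3 with linear warm-up, a reduce-on-plateau factor of 0.5
with patience 10 epochs, early stopping after 30 stalled epochs, and
best-validation checkpointing. Validation splits are drawn at the *pair*
level so that validation always measures unseen molecules. All of it is
deterministic given `seed`. Forward and backward passes are hand-written
base R matrix algebra; the backward pass is validated against central
finite differences (relative error < 1e-3 at eps = 1e-5) in the test
suite, which is the load-bearing correctness check for everything trained.

## The $\lambda$-schedule optimizer

Given a profile on a dense grid (default resolution 0.001, i.e. 1001
points), the optimizer returns the minimum-cardinality subset of grid
points, containing both ends, such that every adjacent gap is within the
threshold (default 10 kcal/mol). The gap of a jump is, by default, the
maximum deviation of $F$ over the whole jump interval from its start
(`gap_mode = "interval"`) — a conservative reading that also protects
non-monotone profiles, where the endpoint difference can be small while
the profile excursions between two windows are large. An endpoint-only
mode is available.

A subtlety worth recording: the naive greedy rule "jump to the farthest
feasible point" is *not* minimal in interval mode, because feasibility is
referenced to the window a jump starts from; on non-monotone profiles it
can land on a poorly placed reference and pay extra windows later. Since
the feasible targets from any window form a contiguous prefix (the running
maximum is nondecreasing), the minimal schedule is obtained by
reach-maximizing selection — step to the feasible point whose own feasible
range extends farthest, ties toward larger $\lambda$. The test suite
asserts equality with an exhaustive dynamic program over all grid subsets
on grids up to 200 points, and verifies every emitted schedule
independently. Infeasible profiles (a single grid step exceeding the
threshold that no reachable reference can bridge) are reported with the
offending $\lambda$ interval, never silently subdivided below the grid
resolution. Threshold comparisons carry a 1e-9 kcal/mol tolerance so that
gaps equal to the threshold up to floating-point rounding count as
feasible.

## The synthetic generator

The generator emulates the *statistical structure* of window-level AFEM
labels, not molecular physics. Each pair gets two random connected
valence-legal molecules (6–20 heavy atoms; C/N/O; random tree plus 0–2
ring closures and occasional double bonds; 3D coordinates from a
bond-length/steric objective) placed in a shared 30-atom pocket shell of
radius 6 Å. The ground-truth profiles are

$$F_2^*(\lambda) = E(\lambda), \qquad
  F_1^*(\lambda) = E(\lambda) + \Delta\Delta G^* \cdot \lambda,$$

where the implied $\Delta\Delta G^* = 0.3\,\Delta n_{heavy} +
0.7\,\Delta n_{rings}$ is a deterministic function of simple graph
descriptors (so held-out recovery is well-posed), and the shared
environment term $E$ is a descriptor-driven slope
(0.15 kcal/mol per heavy atom) plus a seeded jitter slope (±0.5 kcal/mol)
and, with probability 0.5, a smoothstep barrier of height up to
±2 kcal/mol. $F^*(0) = 0$ and the signed leg combination recovers
$\Delta\Delta G^*$ in closed form, which the tests assert to 1e-9. Labels
are $F^*(\lambda_k) + \mathcal N(0, \sigma_k)$ with $\sigma_k$ drawn
uniformly from [0.1, 0.5] kcal/mol per sample (heteroscedastic), stored as
the reliability field; an optional quality cap drops high-$\sigma$ samples,
and an optional contamination mode sets a fraction of samples to a large
$\sigma$ (default 5 kcal/mol) to probe the weighting strategy.

What passing tests on this generator do **not** show: transferability to
real protein–ligand systems, conformational-ensemble effects, force-field
error structure, or profiles whose shape depends on $\lambda$-coupling
details. They do show that the architecture can learn a structure-to-
profile map from heteroscedastic window labels and that every assembly
identity and invariance holds on realistic-sized graphs.

## Problem sizes used in the checks

Chosen to characterize behavior well at interactive scale: parameter
recovery trains on the default 40-pair / 11-windows-per-leg dataset at
`d_hidden = 64` (held-out-pair $\Delta\Delta G$: Pearson $r \ge 0.9$,
RMSE ≤ 3× mean $\sigma$); the reliability-weighting comparison runs 16
pairs at `d_hidden = 32`, trained to convergence under early stopping,
over nine seeds with 10% outlier contamination, comparing median held-out
window RMSE against the noise-free truth; schedule minimality is checked
against the DP oracle on grids of 50–200 points and the working resolution
of 0.001 is exercised on analytic and model-predicted profiles.

## Known limitations

- The heterogeneous block, $\lambda$-embedding family and exact layer
  shapes are this package's own design; they match the published
  description of the approach at the block-diagram level, not layer by
  layer.
- MOL2 partial charges are not mapped to formal charges (they are
  physically different quantities); formal charges are read from SDF
  charge codes and `M CHG` lines only.
- The maximum-common-substructure search behind `star_map()` is exact
  branch-and-bound with a node-expansion cap (2e5); for molecules far
  larger than the generator's range the result past the cap is a lower
  bound.
- Training is single-threaded, full-precision R; it is sized for
  desk-scale datasets (hundreds of pairs), not production campaigns.
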