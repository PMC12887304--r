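# alchnet

Alchemical free energy methods (AFEMs) such as the alchemical transfer
method (ATM) or FEP compute binding free energies by morphing one molecular
state into another along a coupling coordinate λ ∈ [0, 1], simulating a
"window" at each λ and accumulating the free-energy change
F(λ) = G(λ) − G(0) along the path. They are accurate but expensive, and the
placement of λ windows — whose phase-space overlap controls convergence — is
usually tuned by hand.

`alchnet` is an R implementation of a path-aware graph neural network that
learns this *process-level* quantity: it predicts the cumulative free
energy F(λ) at any λ window of a transformation directly from structure,
instead of a single endpoint affinity. From the predicted per-leg profiles
it assembles

- **RBFE**: ΔΔG = s₁·F₁(λ_end) + s₂·F₂(λ_end) over the two legs of a
  thermodynamic cycle (default signs +1, −1), and
- **ABFE**: the same signed combination over a complex/solvent decoupling
  pathway,

and it derives λ-window schedules for classical AFEM runs by predicting
F(λ) on a dense grid (resolution 0.001) and placing the minimum number of
windows such that no adjacent free-energy gap exceeds a threshold (default
10 kcal/mol).

The model: atoms are featurized (element, degree, formal charge,
aromaticity, origin), complex graphs carry distinct covalent
(bond-order-typed) and non-covalent (distance-typed, 4.5 Å cutoff) edge
sets, and L rounds of message passing with separate edge-type message
functions — plus a heterogeneous block that transforms ligand and pocket
nodes with distinct weights, used only for complex-type graphs — yield a
graph embedding. λ is expanded in a Gaussian radial basis and fused
multiplicatively with the graph representation; the two legs of the cycle
are encoded purely by the order of endpoint-feature concatenation
(leg 1 = A‖B, leg 2 = B‖A) with shared weights; and an MLP head predicts
F(λ) − F(0), anchoring every leg at F(0) = 0 exactly. Two structural
consequences are exact by construction: symmetric perturbations (A = B)
give ΔΔG = 0, and exchanging the endpoints negates ΔΔG. Training minimizes
a reliability-weighted MSE, w = 1/(σ² + ε²), that down-weights windows
whose labels carry large uncertainty, with AdamW, linear warm-up,
reduce-on-plateau and early stopping. The network and its backpropagation
are implemented in base R matrix algebra and verified against finite
differences in the test suite.

Because real window-level labels require MD, the package ships a synthetic
alchemical-path generator: random valence-legal small molecules embedded in
a toy pocket shell, smooth cumulative profiles with a closed-form ΔΔG per
pair, and heteroscedastic Gaussian label noise whose σ is stored as the
reliability field.

## Worked example

Train on the default synthetic dataset (40 pairs, 11 windows per leg,
σ ∈ [0.1, 0.5] kcal/mol) and predict ΔΔG for held-out pairs:

```r
library(alchnet)

spec <- synthetic_spec(n_pairs = 40, seed = 0)
data <- gen_dataset(spec)
cfg  <- alch_config(overrides = list(d_hidden = 64L, n_epochs = 250L,
                                     warmup_steps = 100L, seed = 0L))
fit  <- train_model(data, cfg)             # ~1 min on one CPU

pred  <- vapply(fit$val_pairs, function(pid)
  rbfe(data$pairs[[pid]], pathway_spec(), fit$params)$ddg, numeric(1))
truth <- data$truth$ddg_true[match(fit$val_pairs, data$truth$pair_id)]
print(round(rbind(predicted = pred, truth = truth), 2))
ev <- evaluate(pred, truth)
cat(sprintf("held-out ddG: Pearson r = %.2f, RMSE = %.2f kcal/mol\n",
            ev$pearson_r, ev$rmse))
```

```
          pair014 pair004 pair001 pair034 pair023 pair040 pair018 pair033
predicted    0.61    1.01    2.05   -1.28     0.7   -1.32    0.89   -0.09
truth        1.30    0.50    2.40   -2.10    -0.1   -1.40    1.10   -1.30
held-out ddG: Pearson r = 0.92, RMSE = 0.68 kcal/mol
```

The eight pairs above were never seen in training; the model recovers their
ground-truth ΔΔG (kcal/mol) from structure alone to within roughly twice
the injected label noise.

Schedule optimization on a profile climbing 100 kcal/mol:

```r
grid  <- seq(0, 1, by = 0.001)
sched <- optimize_schedule(grid, 100 * grid, threshold = 10)
sched$lam_values
#>  [1] 0.0 0.1 0.2 0.3 0.4 0.5 0.6 0.7 0.8 0.9 1.0
```

Eleven windows at 0.1 spacing — the minimum placement whose adjacent gaps
all stay at ≤ 10 kcal/mol. On model-predicted profiles the same call
concentrates windows where F(λ) changes fast and thins them over flat
stretches.

A shell entry point with subcommands (`generate-synthetic`, `train`,
`predict-rbfe`, `predict-abfe`, `optimize-lambda`) is installed at
`inst/exec/alchnet`; every run writes its effective configuration next to
its outputs.

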