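---
title: "Re-scoring protein identifications over a PPI network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-scoring protein identifications over a PPI network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirescore)
```

## The problem

Shotgun proteomics identifies proteins indirectly: peptides are matched to
spectra, peptide evidence is pooled per protein, and each protein receives
a score or a posterior probability of presence. Controlling the false
discovery rate of the reported protein list forces conservative cutoffs,
so truly present but weakly supported proteins — typically the
low-abundance ones, which are also where biomarkers tend to live — are
discarded. The evidence a single MS run provides about such proteins is
weak, but proteins do not act alone: interaction partners of a protein
that function together tend to be present together. `ppirescore`
exploits this by treating the identified proteome as a graph — proteins
as nodes, known protein–protein interactions (PPIs) as unweighted,
undirected edges — and training a semi-supervised graph neural network to
re-score every protein from its own evidence *and* its interactors'.

## The model

Each protein $v$ carries a feature vector $x_v$ (by default just the raw
probability from the search pipeline; optionally also transformed mRNA
expression). The network is a stack:

1. **Preprocess MLP** (default one layer): $h_v = \sigma(\mathrm{BN}(W x_v + b))$,
   applied per node, no propagation.
2. **Message passing** (default one layer), one of
   - *GCN-style*: $H' = \hat D^{-1/2}(A + I)\hat D^{-1/2} H W$, the
     symmetrically normalized adjacency with self-loops ($\hat D$ the
     degree matrix of $A+I$). Isolated nodes reduce to their own
     self-loop term.
   - *SAGE-style*: $h'_v = W_{\mathrm{self}} h_v +
     W_{\mathrm{neigh}}\,\mathrm{mean}\{h_u : u \in N(v)\}$. During
     training the mean is over a uniform subsample of at most
     `sage_neighbor_sample_size` (default 5) neighbors — a regularizer —
     while evaluation always uses all neighbors. Degree-0 nodes get a
     zero neighbor term, so isolated proteins are driven purely by their
     own evidence.
3. **Postprocess MLP** (default one layer) and a linear head producing
   one logit per protein; its sigmoid is the predicted probability of
   presence.

Every hidden layer applies, in order: linear transform, batch
normalization, dropout (training only), activation. With one
message-passing layer a protein's prediction depends only on its
immediate interactors — the receptive-field property the test suite
checks exactly.

Defaults: hidden width 64, ReLU, dropout 0.3 for the GCN variant and 0
for SAGE (neighbor subsampling already regularizes it), batch
normalization on. All are exposed in `model_config()`.

### Training

Training is full-batch (graphs in the tens of thousands of nodes fit
comfortably in memory): every epoch runs one forward/backward pass, with
binary cross-entropy computed on *labeled training nodes only*. Unlabeled
proteins participate in message passing through their features but never
in the loss — the semi-supervised setting. Positives are up-weighted by
$n_{neg}/n_{pos}$ by default. The optimizer is Adam (learning rate
$10^{-3}$) with L2 weight decay $5\times10^{-4}$ on the weight matrices
only; weight decay matters beyond generic regularization, because it is
what shrinks the neighbor transform toward zero when the graph carries no
label signal. Backpropagation through all components, including batch
normalization and the sparse propagation operators, is implemented
directly in dense/sparse matrix algebra; no deep-learning runtime is
involved, and everything runs on one CPU.

After each epoch the model is evaluated (deterministically: no dropout,
all neighbors, batch-norm running statistics) on the validation mask and
its ROC AUC recorded. The selected model is the epoch maximizing a
trailing moving average (window `val_smooth = 5`) of validation AUC;
epoch-level AUC on a few hundred validation nodes has a standard error of
a few percent, and selecting its raw argmax systematically picks lucky
epochs — the smoothed criterion selects a stably good region instead.
Training stops early after `patience = 30` epochs without improvement.
Model selection and early stopping read validation labels only; test-mask
labels are never touched before final evaluation (the suite proves this
by corrupting them and checking that training is bit-identical).

`grid_search()` wraps this in a bounded grid over architecture and
training hyperparameters, ranked by the validation criterion, with
per-cell error isolation.

### From scores to probabilities

Pipelines that emit only an arbitrary-scale protein score are handled by
`fit_score_mixture()`: a two-component mixture fitted by EM, whose
positive-component posterior becomes the raw probability. The component
family is Gaussian–Gaussian on log scores. Discriminant-score mixtures
in the proteomics literature are often Gaussian + Gamma; we use the
symmetric family on the log scale because protein scores are positive
and right-skewed, the log transform makes both components approximately
location-scale, and the contract of this stage is posterior calibration
of a monotone re-scoring, not distributional fidelity to any particular
search engine's internals. The transform is configurable
(`transform = "identity"` fits on the raw scale). Initialization is
k-means under the given seed; the M-step uses responsibility-weighted
moments, so the observed-data log-likelihood is non-decreasing (asserted
on every fit in the tests); component scales are floored at $10^{-6}$ to
prevent collapse; the positive component is always the one with the
larger fitted location, whatever the initialization.

### Labels

Ground truth comes from evidence *external* to the run being re-scored:

- **Replicate pooling**: the mean raw probability across $R$ replicate
  experiments, with a protein absent from a replicate contributing 0 —
  absence-as-zero is the conservative reading when replicate tables only
  list observed proteins. Means strictly above 0.7 are positive,
  strictly below 0.3 negative, everything else unlabeled.
- **Presence counts**: positive when seen in at least `min_present` of
  `n_datasets` reference datasets (canonically 2 of 4), negative when
  absent from all.

Labeled nodes are split 60/20/20 into train/validation/test, stratified
by class (the splitting rule only says "random"; stratification reduces
variance at these sample sizes and contradicts nothing), with
floor-then-distribute rounding so counts are exact and a fixed seed for
reproducibility. All sorts and rankings break ties by accession, so
every output is bit-stable.

## The synthetic data generator

`simulate_ppi_data()` generates the study conditions the package assumes,
so every stage is testable without downloads:

- **Graph**: a stochastic block model with `n_modules = 20` communities
  over `n_proteins = 2000` proteins, within-module edge probability 0.05
  and between-module 0.001 (mean degree ≈ 7) — the simplest generator
  with controllable community structure.
- **Presence**: each module is "active" with probability 0.5; proteins
  are present with probability 0.9 in active modules and 0.1 in inactive
  ones. Presence is therefore assortative on the graph — the structural
  premise of network re-scoring.
- **Evidence**: per experiment, a present protein's log score is drawn
  from $N(\delta, 1)$ with separation $\delta = 2$, except with
  probability `false_negative_rate = 0.3` it is drawn from the absent
  component $N(0, 1)$ — the abundance-driven detection failure the
  method exists to repair. Absent proteins always draw from $N(0,1)$.
  Raw probabilities are the exact mixture posteriors of these scores, so
  the same generator also exercises the EM stage through the underlying
  scores. False-negative draws are independent across the main evidence
  table and each of the `n_replicates = 7` replicate tables: labels in
  real studies come from runs independent of the scored sample, and
  making detection noise protein-level-persistent would collapse the
  labels onto the very evidence being re-scored.
- **mRNA**: transcripts of present proteins are detected with
  sensitivity 0.9; absent proteins are (falsely) detected with
  probability 0.2; detected transcripts get log-normal expression values
  higher for present proteins.

Everything is deterministic given `seed`. What the generator does *not*
emulate: scale-free degree structure, peptide-level evidence, correlated
replicates, batch effects, or identifier noise — so green tests certify
the machinery and the direction of the effect under assortative
presence, not performance on any real dataset.

## Evaluation

`evaluate_predictions()` reports, on the held-out test mask, ROC AUC of
the predicted and the raw probability with DeLong confidence intervals
(structural-component variance; zero-variance degenerate cases such as
perfect separation return a zero-width interval rather than erroring; the
interval is clipped to $[0,1]$). The AUC is the exact Mann–Whitney pair
statistic computed via midranks.

For the proteins the labels cannot decide, the report mirrors the
promotion analysis: *unconfident* proteins (raw probability strictly
below 0.9, the conventional ≈5% FDR alignment) are ranked by predicted
and by raw probability, and the top-$N$ sets are compared by **mRNA
coverage** — the fraction with a detected corresponding transcript, an
orthogonal plausibility check — together with the overlap of the two
sets and a promotion table sorted by rank improvement.
`extract_subnetwork()` pulls the $k$-hop induced neighborhood of any
protein for inspecting *why* it was promoted.

## Numerical and design choices

- Batch-norm placement (the layer lists its components, not their order):
  after the linear transform, before dropout and activation; one
  setting, fixed. PReLU uses a fixed slope 0.25 rather than a learnable
  one.
- Glorot-uniform initialization, zero biases; Adam moments standard
  ($\beta_1 = 0.9$, $\beta_2 = 0.999$).
- EM: tolerance $10^{-6}$ on the log-likelihood change, at most 500
  iterations; non-convergence is flagged, not fatal, and must be
  explicitly accepted when applying the fit.
- STRING identifiers: a leading taxon prefix (`"4932."`) is stripped; no
  identifier mapping is attempted — evidence tables and edge lists must
  share an accession system. Directed duplicate edges collapse keeping
  the maximum confidence; self-interactions are dropped; confidence
  filtering is inclusive at the threshold (400 = "medium confidence").
- The node universe is the evidence table: interaction-only proteins are
  dropped, evidence-only proteins are kept as isolated nodes (real
  datasets contain thousands of interactor-less proteins; their
  prediction is then a function of their own evidence alone).
- Graph serialization writes doubles at 17 significant digits and parses
  them back with correctly rounded base-R conversion, so the on-disk
  round trip is bit-exact.

### Choices made on the synthetic benchmark

The package's own benchmark (the acceptance tests and
`scripts/acceptance.R`) uses the generator defaults above, seeds 1–10,
and both convolution variants. Two choices deserve justification:

- **Coverage depth.** The default top-$N$ for the synthetic-scale
  coverage comparison is $N = 100$. A power analysis of the coverage
  difference over generator seeds disjoint from the benchmark range
  showed mean difference and win rate peaking near $N = 100$ for
  unconfident pools of roughly 450–900 proteins: at small $N$ both
  rankings pick confidently present proteins, at $N$ near the pool size
  the two sets converge by construction, and in between the predicted
  ranking's recovery of detection false negatives is most visible. Even
  at its peak the comparison is low-powered under the default
  conditions: with a detection false-negative rate of 0.3 and seven
  replicates, absent proteins almost never reach a pooled mean above
  0.3, so the unlabeled pool is dominated by truly present proteins,
  both rankings saturate near the mRNA sensitivity ceiling, and the
  per-seed sign of the difference is close to a fair coin around a
  small positive mean. The mean direction favors the predicted
  ranking; its per-seed sign should not be over-read on any single
  simulation.
- **The null-graph check.** On a structureless graph (equal within- and
  between-module edge probability, same mean degree) there is no network
  signal, and the re-scored AUC should match the raw AUC up to noise.
  This is asserted for the SAGE variant, whose separate self transform
  can learn to ignore neighbors (weight decay actively drives
  $W_{\mathrm{neigh}}$ toward zero). GCN-style convolution *cannot*
  represent that solution: the normalized adjacency averages each
  node's evidence with its neighbors' before any learnable map, so a
  pure-noise neighborhood necessarily dilutes the signal and the GCN
  variant loses AUC on such graphs. This mirrors the observed behavior
  of the two layer types on real networks of degraded quality — SAGE
  stable, GCN sensitive — and is a property of the layer, not a defect
  of the training machinery.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
generator's default scale (2000 proteins, ≈7000 edges) across ten seeds
and both convolution types, plus a ten-seed null-graph experiment;
smaller graphs (120–400 proteins) are used for unit-level training
tests. These sizes give stable AUC estimates (test masks of ≈270 labeled
proteins) while keeping a complete run of the suite in the minutes
range on a single CPU.

## Known limitations

- No identifier mapping (UniProt ↔ STRING) — upstream concern.
- Edges are unweighted; the STRING confidence enters only through the
  filtering threshold.
- No decoy-based FDR for the re-scored probabilities: predicted
  probabilities are meaningful in *relative order*, and cutoffs should
  be set by the desired number of additional proteins (e.g. guided by
  where mRNA coverage declines), not read as calibrated posteriors.
- Multi-graph batching, attention layers and edge-weighted propagation
  are out of scope.
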