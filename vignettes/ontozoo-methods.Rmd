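---
title: "ontozoo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ontozoo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontozoo)
```

This vignette documents the statistical models in `ontozoo`, the
assumptions behind them, the numerical choices that are not visible from
the API, and what the synthetic test bed does and does not demonstrate.

## Label spaces on a cell-type ontology

Cell-type labels are terms of a directed acyclic graph of is-a relations.
`build_label_space()` takes the set of terms observed across datasets and
returns the *leaves*: the observed terms that have no other observed term
among their ontology descendants. These leaves K are the classifier's
output classes. Every term t of the ancestor-closed subgraph then maps to
its positive leaf set K⁺(t), the leaves at or below t, which is how a
coarse annotation is interpreted: a "lymphocyte" cell is allowed to be any
of the lymphocyte leaves, and is not forced to choose.

Two conventions are worth stating explicitly.

* When observed terms are ancestrally related across datasets (one study
  reports "lymphocyte", another "T cell"), the union of observed terms is
  taken before leaf extraction, so the coarse term simply becomes an
  internal node. The alternative — resolving "most fine grained" per
  dataset — would make the label space depend on dataset order.
* Leaves are ordered case-insensitively with byte-wise tie-breaking,
  using radix ordering that ignores the session locale. Classifier output
  columns are therefore identical across machines; a plain locale-aware
  sort would order `"T cell"` and `"macrophage"` differently in C and
  UTF-8 locales.

Only is-a edges are honoured when reading OBO files; other relationship
types are ignored with a warning, because subsumption is the only
relation the aggregated loss relies on. Terms that appear in data but not
in the ontology fail loudly — extending the ontology is done by supplying
an augmented edge list, never silently.

## Aggregated cross-entropy and accuracy

For softmax outputs p over the leaves and a label with positive set K⁺,
the aggregated cross-entropy of a batch is the mean of
−log Σ_{k∈K⁺} p_k. On one-hot rows it is exactly multi-class
cross-entropy, and with two leaves it is binary cross-entropy; the test
suite verifies this chain to 1e−10. The companion metric counts a cell as
correct when its K⁺ mass strictly exceeds the best single leaf in the
complement; ties count as incorrect, and a label covering every leaf
(the subgraph root) counts as correct since there is no competing
negative leaf. The per-cell mean (rather than the sum) is the default
reduction so that learning rates are batch-size independent.

Numerical guards: probability masses are clipped below at 1e−12 before
the logarithm. An all-zero indicator row is an error, never a silent
zero-mass term.

Cells whose label sits outside the label-space subgraph cannot be mapped
and raise an error; per-leaf F1 scores are computed on leaf-labelled
cells only, because a coarse cell has no single true leaf.

## Classifier models and training

Three model kinds share the softmax head over the leaves:

* **linear** — multinomial logistic regression;
* **mlp** — dense layers with selu activations, default one hidden layer
  of 128 units;
* **marker** — each gene j is first mapped through its own sigmoid
  `sigmoid(a_j x_j + b_j)`, modelling an on/off expression threshold,
  and a dense pooling layer mixes the gene states into class logits. The
  pooling weights are deliberately unconstrained (signs free): a marker
  can be evidence against a type as well as for it. Optional
  L2-toward-prior penalties on (a, b) let users encode known marker
  thresholds; they default to off.

Training uses minibatch gradient descent with adaptive moments (Adam,
step 1e−3, batch 128) on the aggregated cross-entropy. These optimizer
settings are package choices, as are Lecun-normal initial weights (the
standard pairing with selu). All parameter draws, shuffles and the
validation split (default 0.1, stratified by dataset when dataset ids are
supplied) are governed by a single integer seed, and `epochs = 0` returns
the untouched initialisation so that initialisation and optimisation can
be tested separately. Backpropagation is derived analytically and is
checked against central finite differences in the test suite; there is no
external autodiff dependency.

## Embedding models

All embedding models consume the transformed matrix (below) and are
scored by the negative-binomial likelihood of the *raw counts*. The NB
NLL is implemented in the standard parameterisation (variance
μ + μ²/φ) and is gated in tests by two independent oracles: agreement
with `dnbinom()` on 10⁴ random triples and pmf normalisation over a
truncated support. Dispersion is either one trained parameter per gene or
a decoder head emitting one value per cell and gene.

The decoder uses an exponential inverse-link, so decoded means are
strictly positive. Because the encoder sees size-factor-normalised input,
the decoded mean is interpreted as a rate per 10⁴ counts and multiplied
by the cell's size factor (total counts / 10⁴) before entering the
likelihood. This convention — rather than decoding raw-scale means
directly — keeps the decoder's task independent of sequencing depth; it
is a package convention and is stated here because reasonable
implementations differ.

* **linear**: one linear encoder layer, one linear decoder layer.
* **ae / vae**: dense stacks, default hidden sizes (512, 64, 512) with
  the middle entry as the bottleneck, selu activations, batch
  normalisation between dense layers (running statistics at inference,
  so embeddings of a cell do not depend on its batch). The VAE places a
  unit Gaussian prior on the latent space; its loss adds
  KL(q‖N(0, I)) with a configurable weight, and evaluation uses the
  posterior mean.
* **nmf**: multiplicative-update factorisation of the transformed matrix
  under squared error; for NB scoring, the reconstruction is inverted to
  the count scale and a single dispersion is profiled from the
  likelihood afterwards. Embedding new data holds the gene factor fixed
  and runs the W-updates from a constant positive initialisation, which
  makes the embedding deterministic.
* **random_projection**: the baseline. A sparse ±1 projection with
  density 1/√J and scale √(1/(density · d)) is drawn on the training
  gene space; test cells are projected and reconstructed by multiplying
  the reduced data with the components. Reconstructed values that are
  negative or zero are replaced by 1e−10, and the reconstruction is
  scored by MSE and by the NB NLL at a constant dispersion of 1.0. The
  constant-dispersion convention is how "a constant scale of 1.0" is
  interpreted here.

Training-stability guards: the decoder's linear predictor is clipped at
30 (e³⁰ ≈ 10¹³ counts) and means are floored at 1e−12 inside the
likelihood; the analytic gradients are masked consistently with both
clips, so gradient checks pass even at pathological parameter values. A
non-finite loss raises a divergence error naming the epoch.

## Gradient-map interpretation

For a differentiable encoder, the Jacobian of the bottleneck with respect
to the input genes is computed per cell (analytically, layer by layer;
batch normalisation contributes its inference-mode affine scale),
aggregated over latent dimensions by the sum of absolute partial
derivatives (an L2 flag is provided — the choice of aggregation is not
canonical), averaged within each cell type, and row-normalised to
maximum 1. For a linear encoder this map is input-independent and equals
the column-summed absolute encoder weights, which is the factor-loadings
reading of the same idea; the package tests this identity exactly.
`gradient_correlation()` computes Pearson correlations between cell-type
rows across genes and clusters them with average linkage on 1 − r;
average linkage is a package choice. Both per-gene and per-cell-type
normalisations of the map are available since the appropriate view
depends on whether one compares genes or types. The random projection
and NMF have no encoder Jacobian and are rejected.

## Preprocessing

Each cell is scaled to a total of 10⁴ and log-transformed. The printed
plain-log form is −∞ at zero counts, and zeros dominate single-cell
matrices, so the default applies `log1p` to the scaled values; a strict
mode reproduces the plain log with zeros mapped to 0 for auditing. The
log is natural. The transform of a cell depends only on that cell, which
the tests check as `transform(concat(A, B)) = concat(transform(A),
transform(B))`; row sums of the scaled matrix equal 10⁴ to 1e−9
relative.

## Registry, splits and the model zoo

Metadata cards validate their organ against an anatomy DAG and resolve
their count matrix lazily (at most one read per process, path-keyed, with
explicit release). Ontology-valued queries expand over descendants, so
"lymphoid organ" matches spleen and thymus. Summary statistics default to
the preprocessed scale (raw counts behind a flag) and to cell-equal
weighting; dataset-equal weighting (average of per-dataset means) is
available because the right choice depends on whether large datasets
should dominate. Per-group Pearson correlations with fewer than two cells
or zero variance are reported as missing with a reason, never as 0.

Splits are either hold-one-dataset-out (the robustness-oriented scheme)
or a seeded random fraction, default 20%, rounding half away from zero —
stated because "20%" alone does not fix the cell count at small n.

Parameter bundles are write-once records keyed by model id (class,
organism, organ, topology id, feature-space tag, output version),
provider, training-data and optimisation descriptors. Payloads carry an
MD5 checksum verified on load; versions compare as dotted numeric tuples.
Publishing validates array shapes against the topology declared by the
model's spec. The id grammar is self-consistent and filesystem-safe, but
no claim is made that it reproduces any published registry's exact
string format.

## The synthetic test bed

`simulate_corpus()` draws NB counts with cell-type-specific mean
profiles: per-gene baselines are log-normal, each type upregulates its
own small marker block, profiles are scaled to a common expected library
size, and a configurable fraction of cells report only the parent term
of their true leaf. Defaults: 5 immune leaf types, 60 genes, 3 markers
per type at 5-fold enrichment, dispersion φ = 2, expected library 2000
counts, 50% coarse labels. The marker enrichment was fixed by requiring
the *task*, not any particular fit, to be learnable: with the
Bayes-optimal classifier (NB likelihood at the true profiles) as the
yardstick, 3-fold markers leave even that classifier near 0.91 held-out
accuracy, whereas 5-fold puts it near 0.99 — a regime where a logistic
model can realistically exceed 0.90 while remaining data-limited enough
that discarding coarse-labelled cells measurably hurts. Typical curated
marker genes are enriched well beyond 5-fold, so this is on the
conservative side of realistic.

The generator emulates mixed-granularity annotation, marker structure and
NB noise. It does **not** emulate batch effects, doublets, ambient RNA,
zero inflation beyond NB, or realistic gene counts — so passing tests
demonstrate the correctness and the qualitative behaviour of the methods
(coarse labels help; trained embeddings beat random projections;
gradient maps recover type structure), not performance on real tissue.

## Problem sizes and tolerances used in the checks

The shipped checks run at desk scale by design: 2000-cell corpora for
label recovery (three seeds, 150 epochs), 250–500-cell rank-2 fixtures
for embeddings (the oracle-proximity check trains 2000 epochs to
convergence at n = 400, J = 50), 5-gene networks for finite-difference
Jacobian checks (1e−4 relative), and 10⁴ random triples for the NB
oracle (1e−8). Exact identities (loss equivalences, positive-set
closures, split partitions, zoo round-trips) are tested at 1e−10 or
bitwise. Corpus-scale results from multi-million-cell collections are out
of scope here and are not claimed by any test.

## Known limitations

* Dense matrices throughout: the registry holds matrices in memory;
  out-of-core backends are not provided.
* The MLP/AE/VAE training loop is plain R; it is fast at the problem
  sizes above but not intended for atlas-scale training.
* Only the subsumption fragment of OBO is parsed (no `relationship:`,
  obsolescence or merge handling).
* The marker model's pooling stage is a free dense layer; with many
  correlated markers its interpretability depends on regularisation,
  which defaults to off.
* NB dispersion for NMF is profiled post hoc rather than jointly
  estimated, which slightly favours the other model kinds in NLL
  comparisons.
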