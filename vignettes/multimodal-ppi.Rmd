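---
title: "Multimodal PPI prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal PPI prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxppi)
```

`voxppi` predicts whether two proteins interact by fusing a volumetric
view of their 3D backbones with two classical sequence encodings. This
vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, the numerical conventions, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## Voxelizing a backbone

Only backbone atoms (amide N, alpha-carbon CA, carbonyl C) enter the
structural representation; side chains are ignored. The pipeline is a
composition of five stages, each exported separately:

1. **Attributes** (`attach_attributes()`): every atom inherits its parent
   residue's Kyte–Doolittle hydropathy, isoelectric point, and side-chain
   charge at pH 7. The tables ship as editable CSV under `extdata/`.
2. **Interpolation** (`interpolate_points()`): between consecutive atoms
   $A_i, A_{i+1}$, `p = 5` points are inserted at
   $((p-k+1)A_i + kA_{i+1})/(p+1)$, $k = 1..p$, so the discretized trace
   is continuous at voxel resolution. The same linear rule is applied to
   attribute values; a `stepwise_attributes` flag instead holds each
   segment at the preceding residue's value, since either reading of
   "interpolate coordinates and attributes" is defensible — the default
   is the linear one, applied uniformly.
3. **Centering and scaling** (`center_and_scale()`): coordinates are
   shifted to zero centroid and multiplied by
   $\lambda = \lfloor l/2 - 1\rfloor / R_{max}$. At the default grid size
   $l = 32$ and bounding radius $R_{max} = 40$ Å, $\lambda = 0.375$, so a
   point 40 Å from the centroid lands 15 voxels from the grid centre.
4. **Assignment** (`assign_voxels()`): each point occupies the voxel
   indexed by its coordinate rounded *half away from zero* plus an offset
   of $l/2$. Base R's `round()` rounds half to even, which is asymmetric
   around the centre; the explicit convention keeps the mapping
   symmetric, with the origin at 0-based index $(16,16,16)$. A voxel's
   attribute value is the **arithmetic mean** of its contributing points
   — symmetric and order-independent, where sum or max would privilege
   dense segments. Points falling outside the grid (structures wider than
   $R_{max}$) are dropped with a counted warning rather than rescaled, so
   $\lambda$ stays a constant of the representation.
5. **Pruning** (`prune_isolated()`): occupied voxels with no occupied
   neighbor are cleared. "Neighbor" defaults to 6-connectivity
   (face-adjacent), configurable to 26; decisions are taken against the
   pre-pass occupancy in a single sweep, which makes the operation
   idempotent.

The result is one binary occupancy channel plus three attribute
channels. Useful invariants, all tested: the pipeline is invariant to
rigid translations (centering removes them — rotations are deliberately
*not* normalized); attribute channels vanish wherever occupancy is zero;
pruning is idempotent.

## Sequence encodings

**Autocovariance** (`ac_encode()`). Seven physicochemical descriptor
scales (hydrophobicity, hydrophilicity, side-chain volume, polarity,
polarizability, solvent-accessible surface area, net charge index) are
z-scored over the 20 amino acids (`normalize_descriptors()`; min–max
scaling would be the main alternative, and the scale choice washes out
after the per-sequence centering below). Each descriptor then forms a
signal along the sequence whose lagged autocovariances

$$AC_{d,n} = \frac{1}{l-d}\sum_{m=1}^{l-d}
    (P_{m,n}-\bar P_n)(P_{m+d,n}-\bar P_n)$$

for lags $d = 1..30$ build a 210-vector, ordered descriptor-major. The
centring term $\bar P_n$ is the per-sequence *mean*; a `literal_sum`
flag reproduces a sum-instead-of-mean variant occasionally seen in
print, whose values grow unboundedly with sequence length — it exists
for comparison, never as a default. The encoder requires $l > $ lag and
is identically zero on homopolymers, both tested against a brute-force
double-loop oracle.

**Conjoint triad** (`ct_encode()`). Residues map to the standard seven
dipole/side-chain-volume clusters {A,G,V}, {I,L,F,P}, {Y,M,T,S},
{H,N,Q,W}, {R,K}, {D,E}, {C}; every window of three consecutive residues
(stride one) increments the count of its cluster triad, at 0-based index
$(c_1-1)\cdot 49 + (c_2-1)\cdot 7 + (c_3-1)$ of a 343-vector. Counts sum
to $l-2$. The clustering is injectable for sensitivity analyses.

## Structural embedding contract

Each voxel channel must become a fixed-length vector before fusion. The
package fixes only a *contract* (`new_embedder()`): a function from an
$l^3$ channel to `output_dim` finite values, with a declared determinism
flag; the advertised width is 2048 per channel, i.e. 4096 per pair
timestep. How a 3D grid enters a 2D pretrained network is genuinely
open; the shipped adapter (`channel_to_image()`) stacks the three
orthogonal maximum-intensity projections as a 3-plane image — it
preserves shape silhouettes along every axis, is deterministic and
cheap, and is injectable so central-slice or tiled-slice schemes can be
swapped in.

The default embedder (`stub_embedder()`) composes this projection with a
seeded fixed random Gaussian linear map. It is deliberately *not* a
trained network: it is deterministic, needs no downloads, and — being
linear in the channel — provably transports occupancy and attribute
information into the embedding, which is exactly what end-to-end tests
need. A pretrained CNN (global-average-pool features) can be registered
behind the same contract; nothing downstream changes.

## The fusion classifier

For a pair (A, B), timestep $t \in \{1..4\}$ is the concatenation of A's
and B's embeddings of channel $t$ (order: binary, hydropathy,
isoelectric, charge; A always first). A single LSTM layer — gates
$f_t, i_t, o_t$ as sigmoids of affine maps of $[h_{t-1}, x_t]$,
candidate cell $\tanh$, $C_t = f_t \odot C_{t-1} + i_t \odot c'_t$,
$h_t = o_t \odot \tanh C_t$ — is written out explicitly in
`lstm_step()`, and its batched forward/backward pass is verified against
both a scalar transliteration and central-difference gradients.

The paired AC and CT vectors (A-then-B concatenation: 420 and 686
values) are compressed by single-hidden-layer autoencoders fit on the
training pairs only and then frozen. Encoder and decoder are **linear**:
the optimum then coincides with the principal subspace, convergence is
easy to reason about (and is tested by exact subspace recovery), and
no representational capacity is needed at this stage — the codes feed a
trained head. Before autoencoding, AC columns are z-scored; CT counts
are first normalized to per-protein window *frequencies* and centred
with a single pooled scale, because z-scoring 343 sparse count columns
individually amplifies rare-triad noise until it drowns the
compositional signal.

The fused vector $[h_4, z_{AC}, z_{CT}]$ enters one sigmoid unit;
probability strictly above 0.5 means "interacting" (an exact 0.5 is
negative, following the strict reading of the decision rule). The
`modalities` option ablates the AC and/or CT segments for
unimodal/bimodal comparisons.

**Training.** LSTM and output layer are fit jointly by minibatch Adam on
binary cross-entropy. Defaults (`fusion_config()`): hidden and code
sizes 512 (so all fused segments share one feature-axis length),
learning rate $10^{-3}$, batch 32, 30 epochs — all unspecified upstream
and therefore explicit, logged configuration here. Decoupled L2 weight
decay on the weight matrices (not biases) is the regularizer; it matters
at synthetic-study scale (hundreds of pairs), where an unregularized
model simply memorizes the training set. All randomness flows from one
run seed; two runs with the same seed and data are bit-identical, which
is asserted in the tests. The training log records the epoch curve and
the ids the autoencoders were fit on, making train/test leakage
checkable after the fact.

`study_config()` is the configuration used for every synthetic
experiment in the package: hidden and code sizes 16, 60 epochs, weight
decay 10, with the stub embedder at width 128. These sizes are matched
to the synthetic study (600 pairs over 80 proteins); the 512-dim
defaults remain the documented contract for data at real-benchmark
scale.

## Evaluation protocol

`metrics_from_confusion()` implements accuracy, sensitivity,
specificity, precision, F-score and MCC from the 2×2 table. A metric
whose denominator is zero is reported as `NA` with an `"undefined"`
flag, never silently coerced to 0. AUROC uses the rank (midrank for
ties) form — the probability that a random positive outscores a random
negative, ties counted half — and is tested against exhaustive pairwise
comparison and against pROC. AUPRC is the step integral of precision
over increases in recall, with tied scores collapsed into single
threshold steps.

`repeated_kfold()` runs stratified 3-fold cross-validation three times
(re-randomized folds per repeat), yielding 9 fold evaluations summarized
as mean and sample (n−1) standard deviation per metric. Stratification
keeps class counts within one sample per fold and is configurable off.
`train_test_split()` provides the stratified 80/20 protocol.
`welch_t_test()` (unequal-variance t, Welch–Satterthwaite df, two-sided
p, 0.05 flag) compares result sets, e.g. per-fold accuracies of a model
against its shuffled-label null.

## The synthetic study design

Real PPI benchmarks need thousands of PDB structures and a pretrained
CNN; the package instead generates fixtures with the *structure* the
pipeline assumes, plus a planted signal whose recovery is the end-to-end
test.

Each protein $i$ carries a latent propensity $u_i \sim N(0,1)$ that is
expressed in both modalities:

* **Sequence**: residues are drawn i.i.d. from background frequencies
  tilted by $\exp(s\, u_i\, w_{aa})$, where $w_{aa}$ is the hydropathy
  scale normalized to $[-1, 1]$ and $s$ is `signal_strength`. At $s = 2$
  the hydrophobic content of a sequence tracks $u_i$ closely; at $s = 0$
  the tilt vanishes.
* **Structure**: the CA trace is a persistent self-avoiding random walk
  (consecutive spacing 3.8 ± 0.1 Å, pairwise CA distances > 2 Å) whose
  stiffness increases with $s\,u_i$, and whose residues are the
  generated sequence — so the attribute channels also carry the
  composition tilt. The walk is confined to an 18 Å ball and re-centred,
  keeping every atom well inside the 40 Å bounding radius so no point is
  ever dropped at voxelization. N and C atoms are placed at bonded
  distances around each CA. Geometry stops at CA-spacing realism:
  no Ramachandran validity, secondary structure, or packing — enough to
  exercise the voxel pipeline, not to fool a structural biologist.

A pair is labeled interacting when $u_a + u_b$ exceeds the threshold
that realizes the requested positive fraction exactly (the threshold is
recorded in the dataset's rule object); labels are then flipped at a 1%
noise rate. The **summed-propensity rule** is a deliberate choice over a
latent-*distance* rule: labels must be monotone in each protein's
latent for the planted signal to be representable by the fusion head,
which is a linear map over frozen linear codes — a distance rule is
XOR-like in the per-protein features and unlearnable by that
architecture by construction, which would test the architecture's
limits, not its correctness. Minimum residue length is 50, mirroring the
usual short-protein exclusion in PPI benchmarks.

What passing means — and does not. On `synth_config(n_pairs = 600)`
(80 proteins, 50–150 residues, $s = 2$) the full pipeline recovers the
planted signal at ≥ 0.90 held-out accuracy, scores at chance
(0.5 ± 0.07) when labels are shuffled, and accuracy is non-decreasing in
signal strength. This validates the plumbing: information demonstrably
present in structure and sequence flows through voxelization, embedding,
encoding and fusion into correct predictions, with no leakage. It says
nothing about accuracy on real interactomes, where the signal is not a
single scalar propensity, negatives are sampled by subcellular location,
and structural information arrives through a pretrained CNN.

## Numerical conventions and degenerate inputs

* Rounding at voxel assignment: half away from zero (see above).
* Probability exactly 0.5 → negative class (strict inequality).
* Zero-denominator metrics → `NA` + flag; all-zero confusion → error.
* Welch's test with two equal constant samples → explicit
  undefined-statistic error; separated constant samples → ±Inf, p = 0.
* Sequences must be longer than the AC lag and at least 3 residues for
  CT; violations are classed errors (`voxppi_error_sequence_too_short`),
  as are empty structures, all-outside grids, constant descriptor
  columns and embedder contract violations.
* PDB reading: first MODEL only, first altLoc conformer kept, HETATM
  skipped, chains concatenated in file order; insertion codes and chain
  gaps are taken as-is (no repair). Residue names outside the 20
  standard amino acids are rejected rather than guessed.
* Sequence symbols outside the 20-letter alphabet (U, X, B, Z, ...) are
  rejected at read time, mirroring standard benchmark cleaning.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons use 50–500 random instances per operation; voxelizer
invariants are checked on 50 random traces; the learnability and null
experiments use the 600-pair study above (a few minutes end to end on
one CPU). Feature stores are plain TSV with a self-describing header —
portable, diffable, and bit-exact on round trip at `%.17g` precision.

## Known limitations

* No rotation normalization or augmentation: two rotated copies of one
  structure voxelize differently. This mirrors the representation's
  design; orientation-sensitive applications need canonical alignment
  upstream.
* The stub embedder is linear; it transports signal faithfully but
  learns nothing. Plugging in a trained CNN is supported but not
  shipped.
* The LSTM consumes exactly 4 timesteps (the 4 channels); variable-depth
  channel sets would need a configuration extension.
* Training is plain R + BLAS, sized for hundreds-to-thousands of pairs,
  not for benchmark-scale datasets on GPU.
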