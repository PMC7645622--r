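# voxppi

Multimodal protein–protein interaction (PPI) prediction in R: voxelized
3D backbone structure fused with sequence-derived encodings through an
LSTM classifier.

## The problem

Whether two proteins interact is a binary question at the heart of
pathway reconstruction, disease biology and drug-target discovery, yet
experimentally mapped interactomes cover a small fraction of known
proteins. Computational predictors traditionally use sequence alone;
`voxppi` implements a multimodal approach that combines two views of each
protein:

* **Structure** — the backbone atoms (N, CA, C) of a PDB model are
  rasterized into a 32×32×32 voxel grid: one binary occupancy channel plus
  three attribute channels painting each occupied voxel with the
  hydropathy index, isoelectric point, and side-chain charge of the
  residues passing through it. Each channel is mapped to a fixed-length
  feature vector by a pluggable *embedder* (a deterministic projection
  stub ships with the package; a pretrained CNN can be plugged in behind
  the same contract).
* **Sequence** — two classical fixed-length encodings:
  **autocovariance (AC)**, the lagged covariance of seven standardized
  physicochemical descriptor signals along the chain,

  $$AC_{d,n} = \frac{1}{l-d}\sum_{m=1}^{l-d}
      (P_{m,n}-\bar P_n)(P_{m+d,n}-\bar P_n),$$

  giving a 7 × 30 = 210-vector, and **conjoint triad (CT)**, counts of
  all 3-residue windows after mapping the 20 amino acids to 7
  physicochemical clusters, giving a 7³ = 343-vector.

For a protein pair, the four channel embeddings of the two proteins are
concatenated channel-wise into a 4-timestep sequence and run through an
LSTM; the final hidden state is concatenated with single-hidden-layer
autoencoder codes of the paired AC and CT vectors, and a sigmoid output
unit yields the interaction probability (label 1 when strictly above
0.5). Performance is reported as accuracy, sensitivity, specificity,
precision, F-score, MCC, AUROC and AUPRC under repeated stratified 3-fold
cross-validation or a stratified 80/20 split, with Welch's t-test for
comparing result sets.

Because real PPI benchmarks require bulk PDB downloads and pretrained-CNN
feature extraction, the package ships a synthetic-fixture generator that
plants a known, learnable interaction signal (a latent per-protein
propensity expressed in both the backbone geometry and the residue
composition), so the entire pipeline is testable end to end without any
network access.

## Worked example

```r
library(voxppi)

ds <- synth_ppi_dataset(synth_config(n_pairs = 600, seed = 11))
ds$pairs
#> # A tibble: 600 × 3
#>    id_a    id_b    label
#>    <chr>   <chr>   <int>
#>  1 prot030 prot049     1
#>  2 prot021 prot062     0
#>  3 prot035 prot052     0
#>  # ...

res <- run_ppi_pipeline(ds, study_config(seed = 11))
res$metrics
#> # A tibble: 1 × 8
#>   accuracy sensitivity specificity precision f_score   mcc auroc auprc
#>      <dbl>       <dbl>       <dbl>     <dbl>   <dbl> <dbl> <dbl> <dbl>
#> 1    0.925       0.933       0.917     0.918   0.926 0.850  0.97 0.976

glance(res$model)
#> # A tibble: 1 × 6
#>    seed epochs final_loss final_train_accuracy fused_dim n_train_pairs
#>   <dbl>  <int>      <dbl>                <dbl>     <int>         <int>
#> 1    11     60      0.213                0.988        48           480
```

The generator draws 80 proteins (50–150 residues each), plants the
propensity signal at strength 2, and labels 600 pairs at a 50% positive
rate with 1% label noise. `run_ppi_pipeline()` voxelizes every backbone,
embeds the channels with the deterministic stub, encodes every sequence
with AC and CT, holds out 20% of the pairs, trains the fusion classifier
on the rest, and reports held-out metrics: here the planted signal is
recovered at 92.5% accuracy (MCC 0.85). With `shuffle_labels = TRUE` the
same pipeline scores at chance, confirming that the learned signal lives
in the features and not in any leak.

Individual stages are exposed as ordinary functions
(`read_pdb_backbone()`, `voxelize_protein()`, `ac_encode()`,
`ct_encode()`, `embed_protein()`, `ppi_train()`, `repeated_kfold()`,
...), return tibbles or plain matrices, and come with `tidy()`,
`glance()` and `autoplot()` methods for fitted models, cross-validation
results and voxel grids. A thin command-line wrapper is installed at
`exec/voxppi` (subcommands `synth`, `encode-seq`, `embed`, `train`,
`predict`, `evaluate`).

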