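# sctab

Cross-tissue cell-type annotation for single-cell RNA-seq with a
feature-attention tabular neural network, implemented end to end in R.

Annotating cell types across a whole-organism scRNA-seq corpus runs into
three practical problems: author annotations come at different granularities
of the Cell Ontology, donors induce strong batch effects that a classifier
must generalize across, and labels are heavily imbalanced. This package
implements a complete workflow built around a TabNet-style classifier
("scTab") that addresses these problems:

* **Model** — a feature transformer (stacks of fully-connected + ghost
  batch-norm + gated-linear-unit blocks with √0.5-scaled skip connections)
  combined with per-cell **feature attention**: a mask over genes obtained by
  applying the sparse 1.5-entmax transform

  `entmax₁.₅(z) = argmax_{p ∈ Δ} pᵀz + H₁.₅(p)`,  `H₁.₅(p) = Σⱼ (pⱼ − pⱼ^1.5)/0.75`,

  whose solution has the closed form `pᵢ = max(0, zᵢ/2 − τ)²` with τ chosen so
  that Σp = 1. The mask multiplies the (log1p, size-factor-10,000 normalized,
  batch-normalized) input before a second feature-transformer pass; a single
  decision step feeds a linear head. Training uses class-weighted
  cross-entropy, `w_c = n_samples / (n_classes · n_c)`, plus a mask-entropy
  sparsity term, optimized by AdamW with a ×0.9-per-epoch learning-rate
  schedule and early stopping on validation macro F1. Linear and MLP
  baselines share the same training loop.
* **Ontology-corrected evaluation** — predicting a *subtype* of the author
  label counts as right, predicting a *parent* counts as wrong; per-class
  F1 = 2tp/(2tp+fp+fn) is macro-averaged over classes present in the truth
  set. Fine labels can be collapsed to coarse ones through an
  information-content map (keep terms with IC ≤ 60; assign each term to its
  highest-IC candidate ancestor).
* **Donor-difference augmentation** — sparse gene-space vectors computed as
  centroid differences of the same cell type across donor pairs
  (band-zeroed in [−0.25, 0.25], clamped to [−1.5, 1.5], filtered to large
  k-means clusters), applied as `x' = clamp(x ± v, 0, 9)` during training to
  simulate unseen donors. An OLS variance decomposition
  (`y ~ 1 + onehot(cell type) + onehot(donor)`, mean per-gene R²) quantifies
  how much structure augmentation preserves.
* **Corpus construction** — the six filtering criteria (primary data, 10x
  assays, subtype of the root "native cell" term, ≥ 5,000 cells, ≥ 30 donors,
  ≥ 7 ontology ancestors per cell type), donor-based 70-15-15 splits,
  incremental cell/donor subsampling, and a chunked Parquet store with a
  block-shuffled batch stream for out-of-core training.
* **Uncertainty** — deep ensembles: average the softmax probabilities of
  independently initialized members; uncertainty = 1 − max averaged
  probability; evaluate by the ROC-AUC separating correct predictions from
  incorrect ones and from cell types absent from training.
* **Synthetic data** — a seeded generator of toy ontologies and
  negative-binomial corpora with planted markers, donor shifts, mixed label
  granularity, and held-out types; all tests run on it.

## Worked example

```r
library(sctab)

fx <- make_fixture("donor-shift")          # 4,800 cells, 500 genes, 12 donors
sp <- donor_split(fx$corpus$obs$donor_id, seed = 1)
train <- subset_cells(fx$corpus, sp[fx$corpus$obs$donor_id] == "train")
val   <- subset_cells(fx$corpus, sp[fx$corpus$obs$donor_id] == "val")
test  <- subset_cells(fx$corpus, sp[fx$corpus$obs$donor_id] == "test")

av  <- compute_augmentation_vectors(normalize_corpus(train),
                                    augmentation_config(scale = 0.02, seed = 1))
cfg <- sctab_config(n_d = 16, n_a = 8, n_shared = 2, n_independent = 2,
                    batch_size = 256, virtual_batch_size = 128,
                    max_epochs = 15, augment_training_data = TRUE)
fit <- train_classifier(train, val, "sctab", cfg, augmentation = av, seed = 1)
pred <- predict(fit, test)
ontology_macro_f1(pred$label, test$obs$cell_type, fx$graph)$macro_f1
#> [1] 0.9874854
```

The printed number is the ontology-corrected macro F1 on cells from donors
never seen in training: with augmentation the classifier reaches ≈ 0.99 here
versus ≈ 0.97 without it (the augmentation acts as a regularizer — its
training loss is visibly higher in `fit$history`).

A shell interface covering `synth`, `prepare`, `augvec`, `train`, `predict`,
`evaluate`, and `uncertainty` is installed at
`system.file("cli/sctab.R", package = "sctab")` and is a thin wrapper over
the functions above.

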