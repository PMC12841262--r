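# castehub

Classify honeybee castes (queen, worker, drone) from small, high-dimensional
expression panels, and rank candidate hub genes behind the classification.

## The problem

Caste differentiation studies typically provide a genes × samples expression
matrix over a few hundred to a few thousand genes but only a handful of
biological replicates per caste (six per class is the design castehub is
built around). Standard deep classifiers overfit badly at this sample size,
and ordinary differential-expression rankings say little about which genes a
*discriminative* model actually relies on. castehub implements a pipeline
that addresses both:

1. **Class-aware augmentation.** Each caste is expanded to 50–100 samples
   from a mixture of four strategies: a per-class Wasserstein GAN with
   gradient penalty (WGAN-GP; 30% of synthetic samples), SMOTE interpolation
   (15%), Gaussian jitter scaled to 5–15% of the feature-wise sd (35%), and
   within-class Mixup with a Beta(0.4, 0.4) coefficient (20%). GAN outputs
   are kept only if their median distance to the class's real samples stays
   below twice the median within-class distance.
2. **A hybrid windowed-attention / convolution classifier.** A two-layer
   embedding maps the gene vector to 7 tokens × 64 dims; one block runs
   Swin-style windowed multi-head attention with a relative positional bias,

   `Attention(Q, K, V) = softmax(Q Kᵀ / √d_k + B) V`,

   in parallel with a depthwise-separable convolution branch over the shared
   V projection, fused by learnable scalars:

   `Output = α · Attention_branch + β · Conv_branch`.

   Training uses AdamW (lr 1e-4, weight decay 1e-3), 10-epoch warmup +
   cosine annealing, label smoothing 0.05, cross-class Mixup (α = 0.2),
   gradient clipping at 1.0 and early stopping on validation loss.
3. **Gradient × Input attribution and hub scoring.** Per-gene importance is
   `Importanceᵢ = (∂Loss/∂xᵢ) · xᵢ` (mean absolute product over samples;
   class-specific scores use the class logit instead of the loss), combined
   with co-expression network scores as

   `Combined = w_DL · DL_score + (1 − w_DL) · WGCNA_score`

   (with `WGCNA_score` built from gene significance GS and module membership
   MM; a product rule `DL · GS · |MM|` is also available). The top 20
   overall and top 10 per-caste genes form the hub selection.

A built-in synthetic caste-expression generator with known ground truth
(planted marker genes and correlated gene modules) makes every stage
testable end to end without any downloads.

## Worked example

Simulate a caste study (300 genes, 3 castes × 6 replicates, 10 planted
3-sd markers per caste, three correlated modules), then run the full
pipeline — augment, train, evaluate, attribute, select hubs — with GAN and
classifier training shortened to 100 epochs so the example finishes in a
few minutes on a laptop:

```r
library(castehub)

sim <- generate_caste_dataset(seed = 7)

cfg <- pipeline_config(
  out_dir = "castehub_demo", timestamp = FALSE, seed = 7,
  wgan  = wgan_config(epochs = 100),
  train = train_config(max_epochs = 100)
)
res <- run_pipeline(cfg, expr = sim$expr, meta = sim$meta)

res$metrics
#> <metrics_report> accuracy 1.000 | macro P 1.000 R 1.000 F1 1.000
#>         predicted
#> truth    queen worker drone
#>   queen      1      0     0
#>   worker     0      1     0
#>   drone      0      0     1

res$hubs
#> <hub_selection> 20 overall hubs; per class: queen (10), worker (10), drone (10)
#>   top overall: g0014, g0236, g0177, g0214, g0280, g0180, g0185, g0017, g0252, g0158

glance(res$fit)
#> # A tibble: 1 × 7
#>   n_parameters alpha  beta best_epoch best_val_loss epochs_run stopped_early
#>          <int> <dbl> <dbl>      <int>         <dbl>      <int> <lgl>
#> 1       214317 0.505 0.495         79         0.212        100 FALSE
```

The metrics report shows the held-out confusion matrix (one test sample per
caste under the default 70/15/15 split) — here all three castes are
classified correctly. `glance()` summarizes the fit: the learnable fusion
weights ended at α = 0.505 (attention) and β = 0.495 (convolution), the
best validation loss was 0.212 at epoch 79, and training ran its full 100
epochs without early stopping. The hub listing gives the top genes by
combined score; `g0014` and `g0017` are planted worker markers, and
`tidy(res$hubs)` returns the full ranked table. Every artifact (resolved
config, augmented matrix with provenance tags, GAN diagnostics, training
history, importance tables, hub lists, hub network edge list, log) is
written as delimited text under `res$run_dir`.

Useful entry points beyond the pipeline: `cross_validate()` (stratified
folds with augmentation refitted inside each training fold),
`run_baselines()` (KNN, RBF-SVM, logistic regression, random forest, MLP,
1D-CNN, LSTM, Transformer on identical folds), `run_ablations()` (branch
removals and hyperparameter variants), `autoplot()` methods for GAN
diagnostics, training history, confusion matrices and benchmarks, and
`plot_hub_network()`.

A thin command-line wrapper ships in `inst/cli/castehub`
(`castehub simulate | augment | netscores | cv | benchmark | ablate | run`,
each with `--seed`, `--out` and `--config`).

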