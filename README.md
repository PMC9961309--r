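# mgmtfuse

Radiogenomic classification of MGMT promoter methylation status from 2-D
brain-MRI slices, for researchers working on imaging-based surrogates of
molecular tumor markers in glioblastoma. MGMT promoter methylation silences
the O6-methylguanine-DNA methyltransferase repair gene; methylated tumors
(class 1, MGMT+) respond better to alkylating chemotherapy, so predicting
the status non-invasively from MRI is clinically valuable.

The package implements a two-stage pipeline:

1. **Rejection filter (RA).** Slices whose pixel-value sum is at or below a
   threshold T_h (default 0, i.e. blank slices) are removed per class
   before any split, with full per-class bookkeeping.
2. **Latent CNN features.** A small three-block CNN
   (3×3 convs with 64/128/256 filters, ReLU + 2×2 max pooling, batch norm
   after block 2, 20% dropout after block 3, then FC layers 512/64/2) is
   trained with SGD (momentum 0.99, lr 1e-4, batch 16, L2 1e-4,
   cross-entropy). The raw activations of the two hidden FC layers are
   harvested as latent features: x_latent = x_FC1 ‖ x_FC2 ∈ R^576.
3. **Hand-crafted texture features.** 13 direction-averaged Haralick
   features from gray-level co-occurrence matrices (d = 3, θ ∈ {0°, 45°,
   90°, 135°}, 8 gray levels), a 36-long HOG descriptor (9 unsigned bins,
   32×32 cells, one 2×2-cell L2-normalised block on 64×64 input), and a
   59-bin uniform LBP histogram (p = 8 neighbours, radius r = 5).
4. **Fusion + classification.** The hybrid feature set
   x_HFS = x_FC1 ‖ x_FC2 ‖ x_GLCM ‖ x_HOG ‖ x_LBP ∈ R^684 is min-max
   normalised to [0, 1] per training fold and classified by k-NN
   (Minkowski/Euclidean/Chebyshev/Mahalanobis distances, majority or
   inverse-distance-weighted voting) or soft-margin SVM (linear, RBF,
   polynomial kernels). Evaluation is stratified 10-fold cross-validation
   reporting every metric as mean ± sample standard deviation across folds
   (K − 1 denominator): accuracy, sensitivity, specificity, precision,
   NPV, FPR, F1, MCC, and rank-statistic ROC-AUC.

A deterministic texture-phantom generator (`generate_phantoms()`) produces
two-class synthetic datasets — Gaussian random fields vs. oriented gratings,
with injected blank slices — so the entire pipeline is testable without any
imaging download.

## Worked example

```r
library(mgmtfuse)

root <- file.path(tempdir(), "phantoms")
idx  <- generate_phantoms(phantom_spec(n_per_class = 40, blank_frac = 0.1,
                                       seed = 42), root)
ra   <- apply_rejection(idx, rejection_config(0))
print(ra$report)
#> <rejection_report T_h = 0>
#>   class 0: kept 36 / 40 (rejected 4, 10.00% reduction)
#>   class 1: kept 36 / 40 (rejected 4, 10.00% reduction)

cfg <- pipeline_config(training   = training_config(epochs = 2, seed = 42),
                       classifier = knn_config(k = 1), K = 5,
                       per_fold_net = FALSE, seed = 42)
res <- run_pipeline(root, config = cfg)
print(res$fold_results)
#> <fold_results: 5 folds>
#>   A    100.00 +/- 0.00
#>   S_n  100.00 +/- 0.00
#>   S_p  100.00 +/- 0.00
#>   F1   1.00 +/- 0.00
#>   MCC  1.00 +/- 0.00
#>   AUC  1.00 +/- 0.00
```

The rejection report shows that exactly the injected blank slices were
dropped (4 per class = 10%), and the cross-validated metrics show the
phantom classes are perfectly separable by the fused features — expected,
since the two texture families differ strongly in orientation and
correlation structure. On a single slice the 13 Haralick features look like:

```r
round(glcm_feature_vector(load_image(idx$path[1])), 4)
#>      F1      F2      F3      F4      F5      F6      F7      F8      F9     F10
#>  0.1535  0.4618  0.7292  0.8495  0.7944  8.5909 47.5274  1.9137  2.2520  0.2846
#>     F11     F12     F13
#>  0.7482 -0.2987  0.7391
```

A thin command-line wrapper over these functions ships at
`inst/cli/mgmtfuse.R` with subcommands `make-phantoms`, `reject`,
`train-dlrfe`, `extract-latent`, `extract-radiomic`, `fuse`, `evaluate`,
and `run`.

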