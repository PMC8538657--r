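# renodce

Automated analysis of renal dynamic contrast-enhanced MRI (DCE-MRI) in R:
whole-kidney segmentation with a convolutional network, voxel-wise
classification of cortex / medulla / pelvis from signal time-courses, and
single-kidney glomerular filtration rate (SK-GFR) from pharmacokinetic
model fitting — with a ground-truthed synthetic phantom generator so the
entire pipeline is testable without clinical data.

## Who this is for

Researchers quantifying renal perfusion/filtration from DCE-MRI who need a
reproducible, annotation-free segmentation and quantification chain, and
methodologists who want a self-contained, fully seeded reference
implementation of the two-stage segmentation + two-compartment filtration
model (2CFM) workflow to benchmark against.

## The method

**Stage 1 — coarse segmentation.** The enhancement-phase volume is split
per slice into left/right 96-pixel sides; a U-Net (paired 3×3 conv +
batch-norm layers, dropout 0.2 in the encoder, transposed-convolution
upsampling with skip connections, sigmoid head) classifies each 96×96
single-kidney patch pixel-wise. Training uses binary cross-entropy,

    H = −(1/N) Σᵢ [ yᵢ log p(yᵢ) + (1 − yᵢ) log(1 − p(yᵢ)) ],

SGD (lr 0.01, momentum 0.99), a 1/3 validation split with
minimum-validation-loss checkpointing, and vertical-offset + mirror patch
augmentation. Predictions are refined to the largest connected component
per side. The CNN engine itself (im2col + GEMM convolutions, batch norm,
backprop) is implemented in the package with Rcpp/RcppArmadillo.

**Stage 2 — fine segmentation.** Each in-mask voxel's baseline-normalised
signal time-course is compressed by PCA to ≥20 feature aggregates
(≥90% variance explained) and classified as cortex / medulla / pelvis by
an RBF-kernel SVM (γ = 0.05, C = 1; multinomial logistic regression and
XGBoost are alternatives, DWT features and k-means clustering are
baselines). Classes are balanced to the pelvis count before training.

**Quantification.** The mean cortical signal is converted to gadolinium
concentration by inverting the SPGR signal equation, and fitted with the
two-compartment filtration model

    C_tissue(t) = Ktrans ∫₀ᵗ Cp_kid(τ) dτ + v_p · Cp_kid(t),
    Cp_kid = Cp_art ⊗ g(t),   g(t) = (1/T_g) e^{−(t−Δ)/T_g} for t ≥ Δ,

by bounded nonlinear least squares (Ktrans ∈ [0.05, 0.40] min⁻¹,
v_p ∈ [0.2, 0.9], Δ ∈ [1.0, 3.5] s, T_g ≥ 0.02 s; 17 deterministic
multistarts). SK-GFR = Ktrans × cortex volume, optionally per 1.73 m² BSA.
Repeatability (CoV = √2·σ_diff/μ_pool, paired t-test) and Bland–Altman
agreement statistics are included, as are IoU / Dice (F1 = 2·IoU/(1+IoU))
and balanced-accuracy evaluation.

## Worked example

Simulate four subjects, train on three, evaluate the held-out one:

```r
library(renodce)

subjects <- lapply(1:4, function(i)
  phantom_config(dim = c(96L, 96L, 8L), semi_axes = c(11, 18, 3),
                 noise_sigma = 0, seed = i))
names(subjects) <- paste0("s", 1:4)

cfg <- pipeline_config(
  subjects, test_subject = "s4",
  unet = list(depth = 2, base_filters = 16, dropout = 0.2),
  train = train_config(epochs = 10, batch_size = 8, seed = 1),
  n_offsets = 2L, seed = 1L)

report <- run_pipeline(cfg)
report
#> <pipeline_report> whole-kidney IoU: 0.917 | weighted compartment IoU: 0.917
#> # A tibble: 2 x 7
#>   side  gfr_est gfr_true cortex_volume_est cortex_volume_true ktrans_est
#>   <chr>   <dbl>    <dbl>             <dbl>              <dbl>      <dbl>
#> 1 left     5.28     5.28              21.1               21.1       0.25
#> 2 right    5.28     5.28              21.1               21.1       0.25
#> # i 1 more variable: pct_error <dbl>
```

The held-out whole-kidney IoU (here 0.917) is the overlap between the
refined network prediction and the phantom's true kidney mask; `gfr_est`
against `gfr_true` shows the end-to-end SK-GFR recovery of the whole chain
(segmentation → classification → SPGR inversion → 2CFM fit → Ktrans ×
cortex volume). On these noiseless phantoms the network over-segments only
into background that the classifier assigns to non-cortical classes, so the
cortex volume — and with it SK-GFR — is recovered essentially exactly;
with the default 3% noise the per-kidney error stays well under 1%. `tidy()` on a fit and
`autoplot()` on training histories, phantoms and Bland–Altman results give
the usual tabular/graphical views.

A thin command-line front-end wrapping these functions (subcommands
`simulate`, `segment`, `classify`, `fit-pk`, `evaluate`) is installed at
`inst/cli/renodce.R`.

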