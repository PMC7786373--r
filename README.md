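# wmh2view

Two-view compressed residual networks for classifying paired 3D brain
volumes — a T2-FLAIR-like intensity volume plus a binary white-matter
hyperintensity (WMH) mask per subject — into two demyelinating-disease
classes (neuromyelitis optica spectrum disorder, NMOSD, vs multiple
sclerosis, MS). It is aimed at neuroimaging researchers working with
small cohorts of automatically segmented lesion volumes, where
conventional 3D CNNs are too parameter-hungry to train and no 3D
pretrained backbone exists.

## The model

The core operator is a **compression block** that folds one spatial axis
of a volume `x(h, w, l)` into the channel axis of a single strided 2D
convolution:

    x(h, w, l)  ⇒  x1(c, w, l)        (axis h folded to channels)
    x(h, w, l)  ⇒  x2(c, h, l)        (axis w folded)

    y_i = ReLU(BN(conv2d(x_i)))       kernel 7, stride 3, 32 channels
    y   = concatenate(y1, y2)         64-channel 2D map

so a 100-voxel extent compresses to `floor((100 − 7)/3) + 1 = 32`
positions. The fused 64-channel map enters a standard 18- or 34-layer
residual backbone (`y = F(x, θ) + x` blocks) at its first pooling stage —
the 7×7 stem is omitted, which is also what makes ImageNet-style 2D stage
weights drop-in transferable (`load_pretrained_backbone()`). Global
average pooling, dropout 0.15 and a 2-unit head produce the logits.
Matching-depth 3D residual baselines are included, together with exact
parameter accounting:

| model          | learnable parameters |
|----------------|---------------------:|
| two-view 2D, depth 18 | 11,475,330 |
| two-view 2D, depth 34 | 21,583,490 |
| 3D baseline, depth 18 | 33,161,986 |
| 3D baseline, depth 34 | 63,471,618 |

All network computation (conv2d/conv3d forward and backward via
im2col + GEMM, batch norm, pooling, SGD with momentum) is implemented in
R and C++ (RcppArmadillo) — no external deep-learning framework.

The package also provides NIfTI/CSV ingestion, the crop → paired-crop →
resize-to-100³ → shift/flip-augment preprocessing pipeline, a synthetic
lesion-phantom generator calibrated to the two cohorts' lesion burdens
(0.66% vs 0.26% of intracranial volume), and a repeated 5-fold
cross-validation harness reporting accuracy / sensitivity / specificity
as mean ± sd with full provenance, no-leakage and metric-algebra checks.

## Worked example

Build the depth-18 two-view classifier and simulate a small, deliberately
separable cohort ("easy mode": lesion loads 2% vs 0.2%, periventricular
affinity 1 vs 0) at cube side 32:

```r
library(wmh2view)

m <- build_model(model_spec("two_view_2d", depth = 18))
m
#> <wmh_model> two_view_2d depth 18, 11,475,330 parameters

p <- phantom_params(side = 32, easy = TRUE)
cohort <- generate_cohort(p, n_ms = 10, n_nmosd = 10, seed = 1)
cohort_summary(cohort)
#>   label  n lesion_fraction_mean lesion_fraction_sd lesion_voxels_mean
#> 1    MS 10          0.020897239       0.0035832939              218.0
#> 2 NMOSD 10          0.002032209       0.0002990634               21.2

ids <- vapply(cohort, function(s) s$subject_id, "")
plan <- make_fold_plan(ids, k = 5, repeats = 2, master_seed = 1)
spec <- model_spec("two_view_2d", 18,
                   compression = compression_config(per_view_in_channels = 30))
report <- run_repeated_cv(cohort, spec, train_config(epochs = 10, seed = 1), plan)
report
#> <cv_report> 5-fold x 2 repeats, positive class NMOSD
#>   accuracy    0.900 +/- 0.141
#>   sensitivity 0.900 +/- 0.141
#>   specificity 0.900 +/- 0.141
```

The summary says the simulated MS subjects carry a mean lesion load of
2.09% of brain volume against 0.20% for NMOSD, and the report says that a
freshly initialized model, trained from scratch inside each of the 10
(repeat, fold) splits, classifies held-out subjects at 90% accuracy
averaged over repeats (±1 repeat-to-repeat sd). With default (non-easy)
phantom parameters the two classes overlap like the real cohorts and the
task is intentionally hard. `check_no_leakage(report)` and
`check_metric_algebra(report)` verify the protocol invariants on the
emitted report.

A command-line front end is installed as `exec/wmh2view` with
`simulate`, `preprocess`, `count-params` and `cv` subcommands, e.g.
`wmh2view count-params --family two_view_2d --depth 18`.

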