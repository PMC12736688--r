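# ricesits

Phenology-aware paddy rice mapping from Sentinel-2-like satellite image
time series, built for the places where rice mapping is hardest: cloudy,
rainy growing seasons over fragmented field landscapes.

**Who it is for.** Remote-sensing and agricultural researchers who classify
per-pixel multispectral time series into rice / non-rice, need the
preprocessing to survive heavy cloud loss, and want the evaluation done
without spatial leakage.

## What it does

The package implements the full chain as tested, composable functions:

1. **Reconstruction.** Scene-classification quality masking, Savitzky–Golay
   smoothing formulated on the day-of-year axis (exact for low-degree
   polynomials even on cloud-gapped, irregular grids), and harmonic
   regression (OLS on `{1, cos(2πkt/365), sin(2πkt/365)}`, K = 2) that
   fills cloud gaps while never overwriting valid observations.
2. **Phenological features.** Per time step NDVI, LSWI and EVI, plus two
   temporal-derivative families computed between consecutive valid steps:

   - TDVI = VI(t+Δt) − VI(t) — positive during green-up, negative during
     senescence;
   - NCRVI = (VI(t₂) − VI(t₁)) / VI(t₁) × 100 — the baseline-normalized
     change rate.

   Presets `baseline` (3 channels), `+tdvi`, `+ncrvi` (6), `complete` (9).
3. **Classifier.** An enhanced time-series transformer (d_model 64,
   4 layers × 8 heads, feed-forward 256, GELU, dropout 0.1): parallel
   three-branch feature embedding (affine / MLP / pairwise interactions)
   recalibrated by channel attention; adaptive positional encoding
   (learnable phenological-stage embedding + projected DOY sinusoids); a
   phenology attention gate scaling encoder outputs; optional
   3D-convolutional spatio-spectral patch branch; masked global average
   pooling and a softmax head. Forward, backward and AdamW are implemented
   from first principles in RcppArmadillo (no deep-learning framework) and
   verified by finite-difference gradient checks.
4. **Training & evaluation.** Polygon-grouped, label-stratified train/test
   splitting (no field straddles the split); AdamW (lr 1e-3, batch 32,
   gradient-norm clip 1.0, cosine annealing or reduce-on-plateau);
   accuracy/precision/recall/F1 and Cohen's kappa
   κ = (P₀ − Pₑ)/(1 − Pₑ); paired McNemar tests
   χ² = (|b − c| − 1)²/(b + c) for model comparison.
5. **Synthetic scenes.** A generator producing labeled Sentinel-2-like
   scenes — double-logistic rice phenology with flood-drawdown LSWI,
   phase-shifted confuser crops, polygon-correlated sampling, Bernoulli
   cloud loss — so everything above runs end to end with no downloads.

See the methods vignette (`vignettes/rice-mapping-methods.Rmd`) for the
models, parameter meanings and design rationale.

## Worked example

```r
library(ricesits)

cfg <- pipeline_config(
  scene    = scene_config(n_polygons = 400, points_per_polygon = 3,
                          gap_rate = 0.3, seed = 7),
  training = train_config(epochs = 10, seed = 7),
  seed     = 7)
res <- run_pipeline(cfg, out_dir = "run")
print(res$report)
```

Output (single CPU core, ~25 s):

```
[simulate] done in 0.0s
[preprocess] done in 1.0s
[featurize] done in 0.0s
[split] done in 0.0s
[train] done in 20.5s
[evaluate] done in 1.2s
pipeline complete in 23.1s (config 3ceb3c90849315a362aa64b8aa579ef4)
eval_report on 240 samples (threshold 0.5 )
  TP 118  FN 2  FP 0  TN 120
  accuracy 0.992  precision 1.000  recall 0.983  F1 0.992  kappa 0.983
  probability overlap 0.017
```

Reading it: the 400-polygon scene (1,200 samples, 30% simulated cloud
loss) was split 80/20 at polygon level; after 10 epochs the transformer
classifies the 240 held-out points with 2 misses (both rice missed, none
falsely claimed), kappa 0.983, and the class-conditional rice-probability
histograms barely overlap (0.017) — the classifier is not just right but
confidently right. Stage artifacts (checkpoint, evaluation JSON, history)
land in `run/`, stamped with the configuration hash.

Individual stages are plain functions when you want control:
`build_dataset()`, `reconstruct_scene()`, `featurize_scene()`,
`group_split()`, `train_sits_former()`, `predict()`, `eval_report()`,
`mcnemar_compare()`. A thin command-line wrapper with the same stages as
subcommands is installed as `exec/ricesits`.

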