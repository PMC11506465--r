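# freshnose

Intelligent freshness grading of chilled oysters (and similar seafood) from
a 10-channel metal-oxide gas-sensor array — an electronic nose. The package
is aimed at food-quality and chemometrics researchers who want a fully
scripted, reproducible version of the standard e-nose analysis chain:
spoilage-index grading, sensor preprocessing, and a neural classifier whose
initial weights are found by a genetic algorithm.

## What it implements

Freshness is a three-level grade — 1 = fresh, 2 = sub-fresh, 3 = decayed —
anchored in conventional spoilage indices:

* **TVB-N** (total volatile basic nitrogen, mg/100 g): `< 15` → 1,
  `15–25` → 2, `> 25` → 3. This rule defines the classifier's target labels.
* **TPC** (total plate count): `< 6.70` → 1, `6.70–7.70` → 2,
  `> 7.70` → 3 (log₁₀ CFU/g).
* **Sensory**: mean of three 10-point sub-scores; `≥ 8` → 1, `[5, 8)` → 2,
  `< 5` → 3.
* Dimethyl sulfide, a late-spoilage marker, is quantified from GC-MS peak
  areas by the internal-standard ratio *X₀ = Xst·A₀/Ast*.

The classifier pipeline is: min–max normalisation of the ten sensor
voltages → PCA to 3 components → **GA-BP network**. A real-coded genetic
algorithm searches the flattened weight/bias vector θ of a 3–10–3 sigmoid
network, scoring each chromosome by fitness 1/(1 + SSE) against one-hot
targets; the best individual initialises full-batch backpropagation
(momentum plus adaptive learning rate). Evaluation uses a stratified 8:2
train/test split, a 3×3 confusion matrix, overall accuracy
(100·trace/total) and per-class recall.

Because raw instrument recordings for this kind of study are not
distributable, the package includes a first-class synthetic trial generator
(`simulate_enose()`) reproducing the storage-trial structure at four
temperatures (4/12/20/28 °C; 4200/4800/4200/7800 rows): logistic channel
responses with alcohol-sensitive, amine-sensitive and late sulfide
channels, monotone quality-index trajectories, and TVB-N-derived labels.
See the methods vignette (`vignettes/freshness-grading.Rmd`) for every
modelling choice.

## Worked example

```r
library(freshnose)

signif(quantify_dms(xst = 0.3821, a0 = 1900211.5, ast = 18796229), 3)
#> [1] 0.0386            # ppm dimethyl sulfide in the sample headspace

trial <- simulate_enose(enose_config(28, seed = 11))
trial
#> Synthetic e-nose storage trial at 28 °C
#>   7800 sensor rows over 48 h; grades: 3632×fresh, 2340×sub-fresh, 1828×decayed

v      <- as.matrix(trial$sensors[, paste0("S", 1:10)])
scaler <- fit_minmax(v)
pca    <- fit_pca(scale_minmax(scaler, v), 3)
pca
#> PCA: 10 features -> 3 components
#> cumulative explained variance: 83.5%, 96.5%, 98.1%

scores <- pca_transform(pca, scale_minmax(scaler, v))
y      <- trial$labels$label
split  <- split_train_test(y, ratio = 0.8, seed = 12)
fit    <- gabp(scores[split$train, ], y[split$train], seed = 13)
fit
#> GA-BP freshness classifier (3-10-3 network, ga init)
#>   trained on 6240 samples; final loss 0.01041; training accuracy 99.25%

evaluate_model(fit, scores[split$test, ], y[split$test], label = "28C")
#> Evaluation report [28C]
#>   test samples: 1560
#>   overall accuracy: 99.0385%
#>   per-class accuracy: fresh 99.3%, sub-fresh 97.9%, decayed 100.0%
#>   confusion matrix (true x predicted):
#>       721     5     0
#>        10   458     0
#>         0     0   366
```

The three first principal components retain 98% of the sensor variance,
and the GA-BP model grades about 99% of held-out readings correctly — well
above the 95% working threshold for this kind of storage trial. The
confusion matrix shows errors confined to the fresh/sub-fresh boundary,
where the headspace changes gradually.

`run_experiment(experiment_config(seed = 1))` runs the same pipeline for
all four storage temperatures and returns per-temperature reports plus a
summary table.

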