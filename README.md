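# fatiguecg

Binary mental-fatigue classification from single-lead ECG.

Prolonged cognitive effort shifts autonomic nervous activity, and with it
the beat-to-beat rhythm of the heart. `fatiguecg` implements an end-to-end
pipeline that classifies 10-second windows of 130 Hz single-lead ECG
(the sampling rate of common chest-strap recorders) as *fatigued* (`F`) or
*non-fatigued* (`N`), where a session is labeled `F` iff its visual
analogue scale (VAS) fatigue self-report exceeds 80%.

The pipeline, each stage an exported tidyverse-style function over tibbles:

- **Synthetic cohort generator** — labeled, noisy 130 Hz ECG with
  PQRST morphology, class-conditional RR-interval statistics
  (mean RR / SDNN), white + baseline-wander + powerline noise, monotone VAS
  trajectories, and age/gender demographics. Suitable labeled ECG corpora
  are private, so the generator is a first-class, tested module.
- **Preprocessing** — 9-level Daubechies-5 wavelet decomposition
  (`cA9`, `cD9 … cD1`), universal thresholding of the detail bands,
  reconstruction, DC removal, and per-record z-scoring.
- **Featurization** — non-overlapping 130-sample (1 s) segments, grouped
  ten at a time into 1300-sample examples; per-segment short-time Fourier
  transform `S[n,k] = Σ_m x_m g_{n−m} e^{−i2πkm/N}` (Hann window, N = 32,
  hop 4) yielding 17 × 25 log-magnitude images.
- **Hybrid classifier** — three feature branches fused by a transformer
  encoder: a 1D ResNet + BiLSTM over the raw group (T), a 2D ResNet +
  BiLSTM over the ten spectrogram images (S), and a physiological encoder
  (100-dim age one-hot + learned gender embedding through a 6-layer fully
  connected net) (P); softmax head trained with cross-entropy
  `L = −(1/N) Σ_q Σ_r S_qr log P_qr`. The network engine (convolutions,
  BiLSTM, multi-head attention, Adam) is implemented in R with C++ inner
  loops — no deep-learning framework required.
- **Baselines & harness** — SVM (C = 0.1, γ = 10, sigmoid), random forest
  (100 trees, seed 40, depth 100), an 18-layer 3×3 CNN on spectrograms,
  and 6-layer LSTM/BiLSTM (dim 64); 9:1 train/test splitting
  (example-random or subject-grouped), accuracy/F1, and the
  six-configuration feature ablation S, S+P, T, T+S, T+P, T+S+P.

## Worked example

Simulate a small cohort, preprocess and featurize it, then train and
evaluate the full hybrid model on the standing benchmark:

```r
library(fatiguecg)

cohort <- generate_cohort(n_subjects = 4, duration_s = 60, seed = 1)
cohort[, c("subject_id", "class", "age", "gender", "vas")]
#> # A tibble: 4 × 5
#>   subject_id class   age gender   vas
#>   <chr>      <chr> <int> <chr>  <dbl>
#> 1 S01        F        27 male    96.7
#> 2 S02        N        22 male    71.9
#> 3 S03        F        27 male    92.0
#> 4 S04        N        20 male    64.5

dataset <- cohort |> preprocess_cohort() |> build_dataset()
nrow(dataset)          # 4 records x floor(60 / 10) groups
#> [1] 24
dim(dataset$spectrograms[[1]])
#> [1] 10 17 25
```

The standing benchmark is 20 subjects with 300-s records (600 examples);
the fatigue class beats slower and steadier (mean RR 0.90 s, SDNN 0.02 s)
than the non-fatigue class (0.80 s, 0.06 s):

```r
bench <- synthetic_benchmark(seed = 1)
parts <- split_dataset(bench, split_spec(seed = 11))        # 9:1
fit   <- fit_fatigue_model(parts$train, model_config(seed = 12))
evaluate(predict(fit, parts$test, type = "class"), parts$test$label)
#> # A tibble: 1 × 8
#>   accuracy    f1 macro_f1    tp    fp    fn    tn     n
#>      <dbl> <dbl>    <dbl> <int> <int> <int> <int> <int>
#> 1      100     1        1    29     0     0    31    60
```

Accuracy is the percentage of correctly classified held-out 10-s examples;
F1 uses the fatigue class as positive. `tidy(fit)` returns the per-epoch
training history, `glance(fit)` a one-row model summary, and
`autoplot(fit)` the loss curves; `autoplot(cohort)` and
`autoplot(stft(dataset$signal[[1]][1:130]))` draw the signals and
spectrograms.

Baselines and the feature-branch ablation run on the same split for paired
comparison:

```r
run_baselines(bench, split = split_spec(seed = 11), seed = 12)
run_ablation(bench, split = split_spec(seed = 11), seed = 12) |> tidy()
```

On this benchmark the full T+S+P fusion dominates every reduced
configuration, and the deep baselines dominate the classical ones — the
sigmoid-kernel SVM with its reference hyperparameters sits below chance
(see the methods vignette for why γ = 10 saturates the kernel).

A thin command-line wrapper over the same functions lives at
`inst/cli/fatiguecg.R`
(`Rscript inst/cli/fatiguecg.R simulate --subjects 20 --duration 300 --seed 1 --out data/`).

## Package layout

- `R/synthetic-ecg.R` — beat template, RR models, noise, cohort generator
- `R/wavelet.R`, `R/preprocess.R` — DB-5 DWT/IDWT, thresholding, z-scoring
- `R/features.R` — segmentation, grouping, VAS labels, STFT
- `R/nn-core.R`, `R/nn-seq.R`, `src/kernels.cpp` — the network engine
- `R/model.R` — branch encoders, transformer fusion, cross-entropy
- `R/baselines.R` — SVM / RF / CNN / LSTM / BiLSTM
- `R/harness.R` — splits, training loop, metrics, ablation, benchmark
- `vignettes/fatiguecg-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations
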