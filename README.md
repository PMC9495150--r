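# birdcall

Bird-call species identification from acoustic features, as a complete,
reproducible R pipeline. Built for bioacousticians and biodiversity-survey
tooling: it turns labelled WAV recordings into a trained multi-species
classifier and a full evaluation report, and ships a synthetic-birdsong
generator so the entire pipeline can be exercised end-to-end on a laptop
in minutes, without any corpus download.

## What it implements

* **Synthetic corpora** — species as harmonic chirp "voices" (syllables of
  50–500 ms with species-specific frequency bands and rhythms, Gaussian
  background noise at a stated SNR), written as 16-bit / 16 kHz WAV with a
  CSV manifest. Bit-reproducible per seed.
* **Preprocessing** — zero-phase Butterworth high-pass (0–150 Hz removal),
  short-time RMS noise gate, syllable detection, the "at least one 50–500 ms
  syllable" validity rule, silence trimming that keeps rhythmic gaps (≤ 1 s),
  and standardization to exactly 10 s at 0 dBFS peak.
* **Features** — STFT (window 400, hop 200, centered framing), 128-band Mel
  spectrogram (`f_mel = 2595·log10(1 + f/700)`), dB scaling, 20-order MFCCs
  via orthonormal DCT-II, per-block standardization
  `(x − mean(x))/sd(x)`, and fusion into a **148 × 801** matrix per clip.
* **Model** — coordinate attention over the fused map
  (`y(i,j) = x(i,j)·g_h(i)·g_w(j)` with learned sigmoid gate vectors),
  a stacked 2-layer LSTM following the standard gate equations

      f_t = σ(W_f[h_{t−1}, x_t] + b_f)        i_t = σ(W_i[h_{t−1}, x_t] + b_i)
      Ĉ_t = tanh(W_C[h_{t−1}, x_t] + b_C)     C_t = f_t ⊙ C_{t−1} + i_t ⊙ Ĉ_t
      o_t = σ(W_o[h_{t−1}, x_t] + b_o)        h_t = o_t ⊙ tanh(C_t)

  then two fully connected layers with SiLU (`x·σ(x)`) and a softmax over
  species. Forward *and* backward passes are implemented in base R and
  verified against finite differences and scalar oracles.
* **Training** — stratified 4:1 split, summed binary cross-entropy over
  classes (canonical softmax CE available), AdamW with ×0.1 learning-rate
  decay every 10 epochs, fully seed-deterministic.
* **Evaluation** — per-species and aggregate accuracy, precision, recall,
  F1, pairwise-indicator AUC (micro/macro), top-5 accuracy, average
  precision / mAP, ROC curves, and 2-D PCA embeddings.

## Worked example

```r
library(birdcall)

res <- run_all(list(
  seed = 5L, out_dir = "my_run",
  simulate = list(n_species = 3L, clips_per_species = 3L, noise_db = -30,
                  duration_min_s = 4, duration_max_s = 6),
  model = list(hidden = 8L),
  train = list(epochs = 2L, batch_size = 8L, learning_rate = 1e-3)))
print(res$report)
#> <metrics_report: acc 0.3333  prec 0.1111  rec 0.3333  F1 0.1667  AUC 0.6667  top5 NaN  mAP 0.7778>
```

Two epochs of a hidden-8 model on nine clips is (deliberately) barely
better than chance — accuracy 1/3 over three species, mAP 0.78 on the
three-clip test set; top-5 is
undefined below five classes and reported as `NA`. The same pipeline at
desk scale (8 species × 25 clips, hidden 64, 30 epochs, ~6 minutes on one
CPU) reaches test accuracy and mAP of 1.00 on the synthetic corpus:

```r
res <- run_all(list(seed = 101L, out_dir = "desk_run",
                    train = list(epochs = 30L)))
```

Every stage is also exposed directly (`make_species_specs`,
`build_dataset`, `preprocess_clip`, `featurize`, `bc_model`,
`train_model`, `evaluate_model`, `feature_comparison`, ...), and
`inst/cli/birdcall.R` is a thin command-line front end with subcommands
`simulate`, `preprocess`, `featurize`, `train`, `evaluate`, `run-all` and
`compare-features`.

```sh
Rscript inst/cli/birdcall.R simulate --out-dir corpus --n-species 8 --clips 25 --seed 1
Rscript inst/cli/birdcall.R preprocess --in-manifest corpus/manifest.csv --out-dir clean --gate-db -20
```

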