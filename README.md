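# neuroalign

Tools for testing whether per-word patterns of intracranial neural activity
("brain embeddings") share geometric structure with word-embedding spaces
from language models — and for doing so *zero-shot*, so that success cannot
come from memorising word identities.

## The problem and for whom

Dense multielectrode recordings during natural listening give one activity
pattern per heard word: a vector with one dimension per electrode. Language
models give another vector per word (contextual embeddings, or static
GloVe-style vectors, or binary symbolic features). If the two spaces share
geometry, a linear map fit on one set of word types should predict the
patterns of *entirely different* word types. This package implements that
test for researchers working with ECoG-style recordings and word-level
embeddings:

- signal preprocessing: despiking (median ± 4·IQR, cubic imputation),
  common average referencing, six-cycle Morlet high-frequency broadband
  power (70–200 Hz, line-noise centres excluded), log + z-scoring,
  zero-phase 50-ms Hamming smoothing;
- lagged epoching into per-word electrode patterns (200-ms windows, −4 to
  +4 s in 25-ms steps — 321 lags);
- zero-shot cross-validation: one instance per word type, ten contiguous
  folds of disjoint types;
- **encoding** (`zs_encode`): per-lag OLS from embeddings to electrode
  patterns, scored by per-word pattern correlation

  *r*(word) = cor(ŷ<sub>word</sub>, y<sub>word</sub>) across electrodes,
  ŷ = X<sub>test</sub>Ŵ, Ŵ = argmin ‖X<sub>train</sub>W − Y<sub>train</sub>‖²,

  with nearest-neighbour (memorisation) and shuffled (chance) controls;
- **decoding** (`zs_decode`): a six-member ensemble of small convolutional
  networks mapping binned activity (10 × 62.5 ms) to embeddings, classified
  by cosine-softmax among the test fold's words and scored as single-positive
  ROC-AUC (chance 0.5, perfect 1);
- inference: word-level bootstrap (5000 resamples) per lag,
  Benjamini–Hochberg FDR at q = 0.01, sign-flip permutation and paired-t /
  Bonferroni contrasts;
- a synthetic-data generator with known linear ground truth (`W`), so every
  stage is testable end to end without any restricted-access data.

## Worked example

Simulate a 700-s stream of 120 word types, give every occurrence a
cone-structured 50-dim contextual embedding, map embeddings to 20
electrodes through a hidden linear code with noise, and run the zero-shot
encoding analysis at six lags:

```r
library(neuroalign)

stream <- generate_stream(n_types = 120, n_tokens = 360, duration_s = 700,
                          seed = 1)
embeds <- generate_contextual_table(stream, embed_dim = 50,
                                    cone_angle_deg = 20, seed = 2)
set.seed(3)
truth  <- ground_truth(matrix(rnorm(20 * 50), 20), noise_sd = 0.3)

sel    <- select_unique_instances(stream, seed = 4)
folds  <- make_folds(sel, k = 10)
sel_embeds <- embeds[sel$row_idx, ]
brain  <- oracle_brain_embeddings(folds$events, sel_embeds, truth,
                                  lag_grid(-400, 600, 200), seed = 5)

fit <- zs_encode(sel_embeds, brain, folds, seed = 6)
fit
#> Zero-shot encoding model
#>   embedding kind: contextual; 10 folds; 6 lag(s); variants: actual, nearest, shuffled
#>   peak mean r (actual) = 0.158 at lag 200 ms

summary(fit)[summary(fit)$variant == "actual", ]
#>   lag_ms variant      mean_r       se_r   n
#> 1   -400  actual -0.01598607 0.02091784 120
#> 2   -200  actual -0.05035761 0.01779497 120
#> 3      0  actual  0.06291322 0.02117129 120
#> 4    200  actual  0.15761077 0.01741793 120
#> 5    400  actual  0.05004192 0.01976122 120
#> 6    600  actual -0.04752712 0.02211215 120

encoding_significance(fit, n_boot = 1000, seed = 7)
#>   lag_ms           p significant
#> 1   -400 0.768231768       FALSE
#> 2   -200 0.997002997       FALSE
#> 3      0 0.003996004        TRUE
#> 4    200 0.000999001        TRUE
#> 5    400 0.002997003        TRUE
#> 6    600 0.981018981       FALSE
```

The mean correlation peaks at the ground truth's +200 ms response peak and
survives FDR only around it; the `nearest` and `shuffled` rows of
`summary(fit)` show the memorisation and chance baselines. `plot(fit)`
draws the per-lag curves with standard-error bars. The decoding direction
works the same way from binned tensors (`bin_signal` on real recordings,
`oracle_decoder_input` on synthetic ground truth) through `zs_decode`.

For raw-signal workflows, `generate_recording` → `preprocess_recording` →
`epoch_lags` replaces the oracle shortcut; `run_pipeline(pipeline_config())`
orchestrates the whole chain into an immutable, manifest-carrying run
directory, and `pipeline_report` summarises it.

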