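---
title: "Zero-shot alignment of brain embeddings and word embeddings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot alignment of brain embeddings and word embeddings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroalign)
```

## The question and the method

When a listener hears a word in a natural narrative, a language-selective
region such as the inferior frontal gyrus produces a distributed pattern of
high-frequency activity across electrodes. Treating that per-word pattern as
a vector — a *brain embedding*, one dimension per electrode — we can ask
whether its geometry (which words are close, which are far) matches the
geometry of word-embedding spaces from language models.

The test must be *zero-shot* to be meaningful. Contextual embeddings of the
same word type in different contexts are highly similar (they occupy a
narrow cone around the type's average direction), so any analysis that puts
occurrences of one type on both sides of a train/test split can succeed by
memorisation. The procedure here therefore:

1. selects exactly one occurrence of every word type
   (`select_unique_instances()`),
2. partitions the selected words by *type* into ten contiguous folds
   (`make_folds()`; contiguity in stimulus time limits temporal leakage
   through slow signal drift),
3. fits, per lag, a linear map between embedding space and electrode space
   on nine folds and evaluates it on the held-out types only.

`assert_zero_shot()` re-checks the disjointness on every fit, not just at
construction.

**Encoding** (`zs_encode()`) maps embeddings to electrode patterns with OLS
(intercept, no regularisation; ridge exists behind a flag but is off by
default because the reference procedure is plain least squares). Each
held-out word is scored by the Pearson correlation between its predicted and
observed electrode pattern, across electrodes — the correlation is taken
over electrodes per word, not over words per electrode, because the claim
under test concerns per-word patterns. Two controls:

* *nearest* replaces each test embedding with its most cosine-similar
  training embedding. If performance survives, the model has only memorised
  neighbourhoods; if it drops, the map interpolates more precisely than its
  nearest training memory. The similarity is computed in the reduced space
  the model actually sees. A less conservative variant drawing the
  neighbour from the test fold is available (`nearest_from = "test"`).
* *shuffled* permutes the test fold's word-to-embedding assignment. Words
  are matched with *mismatching* embeddings: fixed points are rejected, so
  the permutation is a uniform derangement. This matters at desk scale: a
  plain permutation self-matches with probability 1/110 per word, which at
  noiseless precision shows up as a spurious positive bias of about 1/110
  in the mean correlation of a control that should sit at chance. The
  control averages over 10 permutations (the reference count is unstated;
  10 stabilises the per-word average at negligible cost).

**Decoding** (`zs_decode()`) reverses the direction with a small
convolutional network: the signal is averaged into ten 62.5-ms bins
spanning 625 ms (32 samples per bin at 512 Hz), and the network maps the
electrodes-by-bins array to the embedding, trained with MSE on eight folds,
early-stopped on one development fold, evaluated on the held-out fold. Six
members with different initialisations and batch orders are trained per
fold; each member's predictions are turned into cosine similarities against
the test fold's embeddings, softmaxed into probabilities (temperature 1),
and the member probabilities are averaged. Each label's one-vs-rest ROC-AUC
has a single positive, so it equals the normalised rank of the true word's
probability among the other test words — asserted against an exhaustive
pair-counting oracle in the tests. The candidate set defaults to the test
fold ("each test word evaluated against the other test words"); a
dataset-wide candidate mode exists because the reference description is
ambiguous on this point. A linear decoding variant
(`linear_decode_variant()`, OLS on the single 200-ms window, 9 train / 1
test) mirrors the encoding analysis.

The reference decoder architecture is not public; the default here is the
smallest network honouring "deep convolutional network + MSE + early
stopping": one 1-D convolution over the bins (kernel 3, 32 channels), one
dense hidden layer (128), dropout 0.2, Adam, batch 32, patience 10. All of
it is exposed in `decoder_config()`, including a `"linear"` activation mode
that makes the network a factored linear map for parameter-recovery tests.

## Preprocessing chain

`preprocess_recording()` applies, in fixed order (recorded in the output's
provenance): despiking, common average referencing, wavelet high-frequency
broadband power, zero-phase smoothing.

* **Despiking** flags samples outside median ± 4·IQR per electrode and
  imputes them by natural cubic spline through the retained samples.
  The reference description ("four quartiles above and below the median")
  does not pin down a scale; the IQR-multiple reading is the only one that
  defines one, and is the documented choice. Non-finite samples are treated
  as spikes. On Gaussian noise the threshold sits at ±5.4 SD, so the
  false-positive rate is far below 1%.
* **CAR** subtracts the across-electrode mean at every sample.
* **HFBB power** uses six-cycle complex Morlet wavelets at centre
  frequencies every 5 Hz across 70–200 Hz, dropping centres within 5 Hz of
  60/120/180 Hz line noise (spacing and exclusion half-width are artifact
  choices — the reference is silent — set so the spacing stays below the
  wavelet bandwidth). Linear power is averaged across retained centres,
  then log-transformed, then z-scored per electrode over the full
  recording (not per epoch: the transformation is applied to the continuous
  series). The order "average power, then log" follows from the reference
  wording that power is computed and then log-transformed.
* **Smoothing** convolves with a unit-sum 50-ms Hamming kernel forward and
  backward (zero net phase), reflect-padded.

**Epoching** (`epoch_lags()`): at each lag of the grid (default −4000 to
+4000 ms in 25-ms steps, 321 lags), each word contributes the mean of
`floor(window_ms · fs / 1000)` samples — 102 at 512 Hz for the 200-ms
window — centred at onset + lag. The window is centred, not left-aligned,
and the sample index of the centre is computed as
`floor((onset + lag) · fs)` so that epoching and decoder binning share one
convention. One reference figure caption says "200 ms resolution" while the
methods text says 25-ms shifts of a 200-ms window; both step and window are
configurable, with the 25-ms step as default.

## The synthetic-data generator

There is no public generative model for this kind of data; the generator is
the package's own construction, with every choice an explicit artifact
decision. It emulates exactly the features the downstream stages rely on:

* a token stream with Zipf-weighted type frequencies, uniform-order-statistic
  onsets with a 100-ms minimum gap (avoids degenerate overlap), every type
  forced to occur at least once;
* per-occurrence contextual embeddings on a *cone*: each type has a unit
  base direction and each occurrence is rotated away by a uniform angle up
  to `cone_angle_deg`. At 0° the table degenerates to a static table; at
  large angles within-type similarity falls toward the between-type level.
  The default 20° keeps within-type cosines far above between-type ones,
  qualitatively matching how contextual embeddings of a type cluster;
* electrode signals whose 70–200 Hz amplitude envelope is
  `1 + gain · (W_e · x_i)`, time-locked to onsets and shaped by a Gaussian
  response kernel (peak +200 ms, SD 150 ms, optional pre-onset lobe at
  −500 ms), so the preprocessing chain's HFBB estimate recovers the latent
  linear code `W`. The default gain 0.6 keeps the envelope positive and the
  log transform quasi-linear. White noise, 60/120/180 Hz line sinusoids and
  impulsive spikes (indices recorded for despike testing) are added on top.

Two carrier details matter and are deliberate. Carrier frequencies sit on a
single grid with exactly 10 Hz separation (random overall offset), so every
beat between components completes whole cycles inside a 200-ms epoch
window and averages out — the baseline envelope is flat *at the epoch
scale*, which is the scale the analysis reads. Irregularly spaced
frequencies would beat arbitrarily slowly and masquerade as word responses.
Second, the per-electrode phases are rotated by 2πe/E so the carriers sum
to zero across the array: otherwise common average referencing leaks every
electrode's carrier into every other electrode, and the cross-electrode
beats dominate the noiseless error budget. With both choices the full chain
(synthesis → preprocessing → epoching) reproduces the analytic target
`W · x` with per-word pattern correlations above 0.9 in the noiseless
setting, which is what the end-to-end tests assert.

What the generator does **not** emulate: 1/f spectra, cortical anatomy,
speech acoustics, autocorrelated language (types are drawn independently),
or any nonlinearity between embedding and response. Passing tests on this
generator therefore demonstrates that the pipeline recovers a linear code
it is designed to recover — correctness of the machinery, not evidence
about real brains.

`oracle_brain_embeddings()` / `oracle_decoder_input()` bypass signal
synthesis (kernel-weighted `X Wᵀ` plus noise) for fast unit tests; their
agreement with the full chain is itself a test.

## Embedding families

Contextual and static tables are consumed from TSV (the package does not
run language models; the extraction contract is: rows aligned to word
events, contextual tables may carry fold-isolation and includes-self
provenance flags, and the pipeline refuses to mix fold-isolated and global
tables). `pca_reduce()` brings high-dimensional tables to 50 components;
the fit scope is the caller's choice, with training-folds-only as the
leakage-safe recommendation and a global fit reproducing the reference
description. The 75-dimensional symbolic inventory (11 coarse POS, a
stopword flag, 16 shape classes, 19 prefixes, 28 suffixes) is a documented
default with the group cardinalities enforced — the reference's exact
feature list is unpublished — and is fully overridable; symbolic context
concatenates the three preceding words' vectors, and pseudo-contextual
tables concatenate the ten preceding static vectors.

## Inference

Per lag, the mean of the per-word correlations is tested against zero by a
word-level bootstrap (5000 resamples by default) with a +1/(n+1) continuity
correction so Monte-Carlo p-values are never exactly zero; lags are then
controlled at FDR q = 0.01 by Benjamini–Hochberg (via `p.adjust`,
cross-checked against a direct step-up enumeration in the tests).
Variant contrasts use a sign-flip permutation of per-word differences;
region contrasts use a paired t per lag with Bonferroni correction.
One-sided conventions are the default, matching the directional claims;
two-sided versions are behind flags. Calibration is itself tested: across
50 replicate null pipelines the fraction of FDR-significant lags stays at
or below q within binomial error.

## Problem sizes and numerical choices

The configuration arithmetic of the full-scale analysis (321 lags, 102
samples per window, 32 samples per bin, 110 words per fold) is asserted
exactly. The simulation-based checks run at deliberately chosen sizes: the
encoding recovery at the full 1100 types × 81 electrodes × 50 dimensions
(noiseless, single peak lag — OLS at this size is instant); decoder
calibration at 200 types × 16 electrodes (the ensemble's cost is dominated
by 6 members × folds × epochs); null calibration at 80 types × 10
electrodes × 21 lags × 50 replicates; the signal-level chain at 60 types ×
10 electrodes. These sizes give stable Monte-Carlo behaviour while keeping
the whole suite interactive.

Degenerate inputs are handled explicitly: zero-variance observed patterns
drop the word with a message; zero-norm decoder predictions fall back to
uniform probabilities; an all-spike electrode, a singular design, and a
rank-deficient PCA fit are errors naming the culprit. Cosine ties in the
nearest-neighbour control break toward the earliest training word;
remainder words in fold construction go to the earliest folds.

## Limitations

The decoder is intentionally small and its reference architecture is
unknown; absolute AUC values on real data would depend on that choice. The
generator's linear ground truth cannot probe nonlinear brain-embedding
relationships, and its noise model is white — conclusions about real ECoG
noise robustness require real data. HDF5 containers are not read or
written; all I/O is TSV.
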