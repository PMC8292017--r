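# songcontext

Detection of stereotyped song notes in long passive-acoustic recordings,
using the temporal context carried by song rhythm. The motivating signal is
the fin whale (*Balaenoptera physalus*) 20 Hz pulse: a ~1 s downswept call
near 20 Hz, repeated in songs whose inter-note intervals (INIs) cluster at
characteristic values (a doublet alternating ~16.9 s and ~21.5 s in the
emulated region). The package is for bioacousticians who need a per-segment
detector that keeps working when notes are weak, by letting a recurrent
model read the song's rhythm.

## The method

Audio is resampled to 500 Hz and cut into 4 s segments advanced by 1 s;
each segment becomes a band-limited (10–54 Hz) power-spectral-density tile
of shape 36 × 21 (1.25 Hz × 0.16 s resolution). Two independently trained
stages score each segment:

1. **Base CNN** — a small quasi-DenseNet (~21k parameters) whose first
   layer is a fixed pre-conditioning unit: one-dimensional
   Laplacian-of-Gaussian filters at scales σ = 2 and 4 along frequency,
   each followed by twelve trainable 3 × 3 convolutions (26 channels).
   Four quasi-dense blocks (sizes 2, 2, 2, 1, growth rate 12) feed global
   average pooling, a 32-unit embedding layer (FCN-1) and a softmax. It
   emits, per tile, a score p(note) and the 32-d embedding.
2. **Hybrid LSTM heads** — with the CNN frozen, sequences of T = 108
   consecutive cached outputs (111 s of audio) feed LSTM(32) → LSTM(16) →
   sigmoid. Three variants consume the score (width 1), the embedding
   (width 32), or both (width 33). The label of a window belongs to its
   *prediction point*, placed at 100%, 75%, 67% or 50% of the window to
   set the past/future context ratio.

Evaluation is score-based: min–max scaled scores, precision–recall curves
over all thresholds, step-wise AUC-PR, peak F1, class-prior-calibrated
precision π·r / (π·r + (1−π)·f), false positives per hour, and recall as a
function of each note's preceding INI.

A seeded synthetic soundscape generator (chirp notes in INI-patterned
songs, shaped ambient noise, ship-like interference, exact annotations)
makes the whole pipeline trainable and testable without field data.

## Worked example

Simulate a five-minute soundscape with one doublet song, train nothing —
just inspect the front end and labels:

```r
library(songcontext)

spec <- soundscape_spec(
  duration_s = 300,
  songs = list(list(spec = song_spec("DOUBLET", c(16.9, 21.5),
                                     n_notes = 10, snr_db = 6),
                    start_s = 12)),
  seed = 42)
out <- synth_soundscape(spec)
ext <- extract_tiles(out$recording)
labels <- label_segments(ext$grid, out$annotations)
table(labels)
#> labels
#> NEGATIVE  PARTIAL POSITIVE
#>      248       18       31
compute_inis(out$annotations)$value_s
#> [1] 16.43553 21.95107 16.93000 21.42294 16.70149 21.35934 17.07705 21.19681
#> [9] 17.26694
```

Ten notes produce nine INIs alternating near 16.9 s and 21.5 s (0.3 s
jitter), 31 POSITIVE segments (each ~1 s note is fully contained by 3–4
overlapping segments), and 18 PARTIAL segments that clip a note.

The full experiment — train the CNN, cache its outputs, train the three
hybrid heads, evaluate — is packaged as:

```r
res <- run_context_benchmark(seed = 1, n_seeds = 3)
round(colMeans(res[, c("auc_cnn", "auc_score", "auc_feature", "auc_sf")]), 3)
#>     auc_cnn   auc_score auc_feature      auc_sf
#>       0.904       0.911       0.927       0.924
```

About 5 minutes per replicate on one CPU. The embedding-fed heads beat the
frozen CNN on mean AUC-PR over the three seeds, and in the same run the
score-fed head's note recall drops at the 25 s INI never seen in training
(mean 0.62 vs 0.85 at the dominant doublet intervals) while the
embedding-fed head holds 0.88 at the dominant intervals — the
temporal-context signature the method is built around.

A thin command-line wrapper (`exec/songcontext`) exposes `simulate`,
`train-cnn`, `precompute`, `train-hybrid`, `detect`, `evaluate` and
`run-grid` for shell pipelines over WAV files and Raven-style selection
tables.

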