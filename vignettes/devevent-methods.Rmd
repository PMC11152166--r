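---
title: "Detecting developmental event onsets in embryo time-lapse video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting developmental event onsets in embryo time-lapse video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Developmental biologists time-stamp embryonic development with discrete
events — gastrulation, the appearance of eye spots, the first heartbeat, the
onset of crawling, hatching, death. Scoring these events by eye from
time-lapse recordings is slow and subjective, and several of the most
informative events (heartbeat, radular rasping, crawling) are *functional*:
they are invisible in a still image and only recognisable from motion.
`devevent` automates this scoring. An embryo is filmed for a short clip every
hour; a video classifier assigns each hourly clip to one of ten event classes;
the resulting per-hour class probabilities form a trajectory from which each
event's onset hour is read off. Because each event's onset is extracted
independently, shifts in the *relative* timing of events across treatments
(heterochrony) are directly measurable.

## The classifier

The core model is a compact residual video network that factorises 3D
convolution into a 2D spatial convolution (kernel 1×3×3) followed by a 1D
temporal convolution (3×1×1) — the "(2+1)D" construction — each followed by
batch normalisation and ReLU. A residual block applies two such
spatial–temporal pairs and adds a shortcut, projected through a 1×1×1
convolution whenever the stride or the channel width changes. A stride-2
block halves the temporal and both spatial dimensions. Classification uses
global average pooling over all three spatio-temporal axes and a fully
connected softmax layer.

The default configuration consumes clips of 12 frames at 128×128×1 —
obtained by keeping every 10th of the first 120 frames of a 30 frames/s
recording, an effective rate of 3 frames/s — and comprises a 48-filter stem
(stride-2 spatial convolution, then 1×2×2 max-pooling) and four stages of two
blocks with widths 40/80/160/288 and strides 1/2/2/2. This configuration has
5,204,018 trainable parameters (~5.2 M) and ~3.7 GFLOPs per forward pass
under the 2-operations-per-multiply-accumulate convention. The per-stage
widths are config-overridable (`model_spec()`); the parameter/FLOP
calibration is asserted by a test, and `model_summary()` prints the full
machine-readable layer table.

Design points that were genuinely open, and the choices made:

* **Mid-channel policy.** In a factorised block the spatial convolution's
  output width is a free parameter. The default (`equal_to_out`) sets it to
  the block's output width; the `matched_3d` alternative chooses the width
  that equates the pair's parameter count with a full 3×3×3 convolution.
  Both are implemented; the default keeps the width bookkeeping simple and
  calibrates to the intended model size.
* **Normalisation order and padding.** Batch normalisation precedes ReLU;
  padding is "same" everywhere; odd kernels are centred, stride-2 outputs
  are anchored at even input positions. `ceiling(n/stride)` gives every
  output length.
* **Global pooling** is an average (not max) over l, h, w, which also fixes
  the embedding width of the metric-learning head to the final stage width
  (288 by default).
* **Biases.** All convolutions carry biases. A bias feeding a batch-norm
  layer is redundant (its gradient is annihilated by mean subtraction) but
  harmless; keeping a uniform rule makes the closed-form parameter count
  `K·C_in·C_out + C_out` hold for every convolution.
* **FLOP convention.** One multiply-accumulate counts as 2 operations;
  convolutions and dense layers are counted, batch-norm and activations are
  excluded as negligible. The alternative 1-op-per-MAC convention is
  `count_flops(..., ops_per_mac = 1)`.

The engine itself is written in R on BLAS matrix primitives: convolutions
gather neighbour rows through precomputed index maps and reduce to one
matrix multiply, with gradients scattered back per kernel offset. All
analytic gradients are verified against central finite differences in the
test suite, and evaluation-mode forward passes are bit-for-bit
deterministic.

## Training protocol

Classifier training uses sparse categorical cross-entropy and Adam at a
fixed learning rate, for a fixed number of epochs, batch size 32 — no early
stopping and no best-checkpoint selection: final-epoch weights are returned,
and the validation set is only monitored. The package defaults
(`train_config()`) are the full-scale settings: learning rate 1e-6, 50
epochs. The bundled synthetic studies are four orders of magnitude smaller
than a real training set, so they override these to lr 1e-3 to 3e-3 and
5–12 epochs; at 1e-6 a freshly initialised network cannot move measurably
in 50 epochs on a few hundred clips. These scales are stated in each test
and in the acceptance script.

Two details matter for short runs. First, batch-norm running statistics are
re-estimated with one pass over the training inputs after the last epoch
(`calibrate_bn`), because exponentially averaged statistics are poorly
converged after a handful of batches; this affects only evaluation-mode
inference and is deterministic. Second, every source of randomness —
initialisation, shuffling, augmentation, batch composition — derives from
one seed through an avalanche-mixed integer hash, so a (config, seed) pair
reproduces results exactly.

The metric-learning variant replaces the classification layer with a linear
fully connected layer of the same width as the pooled features, followed by
L2 normalisation, and trains with triplet semi-hard loss (margin 1.0 by
default; the margin is a config knob): for each anchor–positive pair the
selected negative is the closest one farther than the positive but within
the margin, falling back to the hardest negative. Batches are composed by
class-balanced sampling so every batch contains valid triplets; a batch
without one is skipped and counted. Mining is treated as constant under
differentiation, as is standard.

## Augmentation and class balance

Event classes are naturally imbalanced: an embryo spends many more hours
crawling than developing eye spots. `balance_classes()` removes the
imbalance *selectively*: every class is upsampled to the pre-balancing
maximum count with augmented copies of clips drawn uniformly (with
replacement) from that class's originals; originals are kept unmodified and
identity plans are redrawn. The augmentations are horizontal/vertical flips,
intensity scaling by 0.5×/1×/2× (clipped to 8 bits), Gaussian blur, and
salt-and-pepper noise. A plan is a pure function of (sample id, seed), and
the *same* transform — including the same noise mask — applies to every
frame of a clip, so augmentation cannot inject spurious temporal signal.
Activation probabilities (0.5 each; intensity uniform on {0.5, 1, 2}),
the corrupted-pixel fraction (0.02) and the blur sigma range (0.5–1.5 px)
are package choices exposed in the `augment.*` config block; plain
non-selective upsampling (`augment_dataset()`) is provided for comparison.

## From probabilities to onsets

`predict_trajectory()` classifies every hourly clip of an embryo, producing
an hours × 10 matrix of softmax probabilities. `extract_timing()` reads one
onset per event:

* **Peak rule** (default for Gastrula through Crawling): the hour of the
  event's maximum probability, earliest hour on ties. Multi-modal columns
  take the earliest global maximum — a documented choice; smoothing is
  available (`traj_smooth` style moving average) but off by default since
  the pipeline applies none.
* **Threshold rule** (Radula 0.6, Hatch 0.4, Dead 0.3 by default): the first
  hour with probability *strictly* greater than the threshold; absent if
  never exceeded. Thresholds differ because the attainable probability
  ceiling differs by event; `calibrate_thresholds()` re-derives them from
  annotated embryos by exhaustive grid search on mean absolute onset error
  (ties to the lower threshold), which is how users should set them for a
  new system.
* **Pre-Gastrula is excluded**: it denotes development before any event,
  not an event.

Missing imaged hours are skipped, never interpolated; onsets are reported on
the imaged-hour grid; absent events are `NA`, never sentinels. Each event's
column is read independently of the others, which is what makes decoupled
event timing (heterochrony) detectable.

## Treatment summaries and thermal performance

`summarize_treatments()` reports mean ± s.d. and n of onset hours per
(temperature, event); embryos lacking an event reduce n rather than being
imputed, and a single-embryo cell is flagged. `thermal_curve()` converts
mean onsets to developmental rates (1/mean onset hour) and reports T_opt as
the assayed temperature with the highest rate, ties to the lower
temperature. T_opt is reported on the assayed grid — treatments are compared
directly, with optional quadratic-peak interpolation available but off.

Embedding visualisation: `project_embeddings()` offers the top-2 principal
components and a nonlinear neighbour embedding — a k-nearest-neighbour
Laplacian eigenmap (symmetric kNN graph, Euclidean metric, 15 neighbours;
the two smallest non-trivial eigenvectors of the normalised graph
Laplacian). The spectral method is fully deterministic, which the tests
exploit; like other neighbour-graph embeddings it preserves local structure,
not global distances. Relative developmental time for colouring is each
clip's hour divided by the embryo's terminal (hatch or death) hour, clamped
to [0, 1]; embryos with neither terminal event are excluded with a warning.

## The synthetic generator

Real training data cannot ship with a package, so every stage is exercised
against a deterministic generator. Each event class maps to a parametric
motif: a spatial pattern (plain disc, spotted disc, shelled disc with a
rotation-revealing notch, empty capsule, speckled decay field) with distinct
size and intensity, plus a motion (none, sinusoidal intensity pulse, rigid
rotation, oscillatory translation, linear drift). Frames are rendered
analytically from the geometry at each time point — rotation re-renders spot
positions rather than resampling pixels — so exact oracles exist: a pulse at
f cycles/s puts the dominant discrete-Fourier component of the mean
intensity series in bin f·n/fps + 1, and (motif, seed) determines the output
bits. Noise is additive Gaussian clipped to 8 bits; salt-and-pepper is
reserved for the augmentation module so the two noise types are never
confounded. Frames default to 64×64 (tests mostly use 32×32); all
shape-dependent code accepts any size ≥ 16.

An embryo series is generated from a schedule of onset hours (strictly
increasing in the canonical event order unless heterochrony is explicitly
requested): the clip at hour h uses the motif of the latest event with onset
≤ h, which is exactly the labelling rule used for annotation — a clip is
labelled as the previous event until the next event occurs.

`make_temporal_only_pair()` constructs the pair used to demonstrate that
temporal information is necessary: two motifs with identical static
appearance, one static and one pulsing at 7.5 cycles/s with phase zero at
frame 1. First frames are bit-identical at matched seeds by construction, so
a first-frame classifier is at chance by design, while the temporal model
separates the pair easily. (At 30 frames/s a 7.5 Hz pulse has period 4, so
frames 1, 5, 9, … alias onto the static image; frames 2, 4, 6, … carry the
signal.)

`simulate_thermal_timings()` generates per-embryo onset hours across the
eight assayed temperatures (15–32.5 °C at the per-temperature replicate
counts of the thermal study) from Gaussian thermal performance curves for
developmental rate, with the optimum temperature declining linearly from
30 °C (first event) to 25 °C (last) and 5 % Normal noise — so the
early-versus-late T_opt reduction is a built-in ground truth the analysis
stage must recover.

**What passing these tests shows — and does not.** The generator produces
*distinguishable signatures*, not embryo morphology: real clips have far
lower class separability, imaging artefacts, and genuinely ambiguous
transitional hours. Synthetic results therefore validate the machinery
(shapes, gradients, rules, determinism, end-to-end plumbing) and the
qualitative properties (temporal information helps; balancing helps minority
recall; stride is immaterial when classes are spatial), not real-data
accuracy levels.

## Scales, numerics, degenerate inputs

The bundled studies run on one CPU: the temporal-information comparison uses
200 training and 100 test clips of 8 frames at 32×32 over three seeds; the
end-to-end onset-recovery study trains on 8 embryos and evaluates 20, with
the nine events compressed into a 2–18 h schedule; the triplet study uses
three well-separated classes at 40/20 clips per class; the stride sweep uses
three spatial-only classes with 30 source frames at strides 3/5/10 over
three seeds. Because the synthetic classifier is near-perfect within each
event's span, its probability trajectories are plateaus rather than the
transient peaks real confidence curves show; the end-to-end study therefore
reads all onsets with the plateau (threshold 0.5) rule, while the peak rule
is validated against a brute-force argmax oracle on 1,000 random
trajectories.

Numerical conventions: batch-norm epsilon 1e-5, momentum 0.9; Adam betas
0.9/0.999, epsilon 1e-7; He-scaled Gaussian initialisation; softmax rows sum
to 1 within 1e-6; embedding norms within 1e-5 of 1. Ties: argmax takes the
earliest hour; T_opt takes the lower temperature; threshold calibration
takes the lower threshold. Degenerate inputs fail loudly and early: clips
shorter than the subsampling window, labels outside the taxonomy, empty
datasets or test sets, batches without a valid triplet (skipped with a
counted warning), trajectories whose rows do not sum to 1, peak extraction
on an all-zero column (absent onset, with a warning).

## Known limitations

* Egg localisation is out of scope: frames are resized directly (area
  interpolation) from the acquisition crop; whether square-padding before
  resizing would help real data is untested here.
* The classifier operates at a single temporal stride; multi-rate
  architectures are deliberately not implemented.
* Onset estimates carry no uncertainty; the extraction rules return point
  estimates on the imaged-hour grid.
* Stored clip datasets are 8-bit grayscale multi-page TIFF stacks with a CSV
  manifest; model-ready scaling to [0, 1] happens only at the model
  boundary. Arbitrary container video codecs are not read; hourly TIFF frame
  directories are.
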