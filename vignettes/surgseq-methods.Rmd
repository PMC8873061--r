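---
title: "Models and methods behind surgseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind surgseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(surgseq)
```

## The segmentation problem

Laparoscopic sacrocolpopexy divides into five phases — promontory
preparation, dissection of vault and gutter, mesh fixation to vault, mesh
fixation to promontory, peritonealisation — whose durations differ by two
orders of magnitude between phases and vary strongly between procedures.
A per-clip video classifier (a 3D CNN over 16 consecutive frames at
2.4 fps) sees roughly 6.7 seconds of context, so its output is noisy and
temporally fragmented. `surgseq` models the *coarse* level: windows of
100 clips (about 11 minutes of video) processed by a sequential model
that outputs a refined label per clip.

Two ideas distinguish the seq2seq formulation from a conventional
many-to-many recurrent refiner. First, an encoder–decoder structure
decouples the input and output sequence lengths. Second, the decoder
receives a *target sequence* of labels alongside the encoder's feature
sequence, so label context and visual evidence are fused explicitly.
What the target sequence is — groundtruth, corrupted groundtruth,
fine-level predictions, or the model's own earlier outputs — defines both
the training strategies and the inference schemes.

### Window configurations

*Time-synchronous* (`shift = 0`): target, input and output all cover the
same 100 clips. Whole-video inference tiles the video with
non-overlapping windows whose targets come from the fine-level
classifier; the model acts as a learned filter of those predictions.

*Time-shifted* (`shift = 10`, `out_len = 90`): the target covers window
positions 1–90 and the output positions 11–100, so 80 labels overlap and
10 output positions extend past the target. Only the first window needs
fine-level labels; each subsequent window (advancing by `stride = shift`
clips) takes the current working labels as its target, and every clip's
final label is the mode over all predictions recorded for it. The
default stride equals the shift because it is the only value that both
covers every clip with model output and reproduces the 80-label overlap
between consecutive target/output spans. During recursion the working
sequence is updated with the latest window's predictions
(`update = "latest"`); taking the running mode instead is available via
`update = "mode"`, and the two orders only differ when consecutive
windows disagree.

### Architectures

Both seq2seq bodies and the many-to-many baseline are implemented on a
small reverse-mode autodiff engine over dense matrices (`R/autodiff.R`);
gradient correctness is asserted against central finite differences in
the test suite, to machine-precision-level tolerances.

* **LSTM seq2seq** — stacked LSTM encoder over the feature window; its
  final hidden and cell states initialise a stacked LSTM decoder that
  consumes the embedded target labels; a linear head maps hidden states
  to class logits. The label embedding (a learned 7 × `d_model` table
  over the codes non-phase, phases 1–5, transition) is the package's
  choice of injection mechanism; the coupling through final states is the
  standard encoder–decoder initialisation.
* **Transformer seq2seq** — input projection plus sinusoidal positional
  encoding, post-norm encoder layers (multi-head self-attention +
  feed-forward), decoder layers with causal self-attention over the
  embedded target, cross-attention over the encoder memory, and a linear
  head. Causal masking is kept by default, matching the original
  transformer's decoder; since the full target is known in advance the
  mask is optional (`causal_decoder = FALSE`) — the forward pass is a
  single evaluation either way, never an autoregressive loop.
* **Many-to-many LSTM** — stacked LSTM over features with a per-step
  head; no target sequence.

Production-scale defaults mirror the clinical setup: `d_model` 1200 (the
fc8 feature width), 3 LSTM layers, 6 transformer layers with 8 heads and
a 1000-unit feed-forward inner layer. All tests and examples use reduced
geometries (`d_model` 32, 1–2 layers, feature dimension 16–32) so the
whole suite runs on one CPU in a few minutes; the defaults are kept at
the clinical values because they document the intended deployment scale.

The network outputs 6 classes (5 phases + transition) by default. The
transition class is kept at the output because the loss explicitly
weights it; a 5-class variant is available through `n_classes`.

### Loss and training recipe

The loss is the weighted sequence cross-entropy
\[
L(y, x) = -\frac{1}{t\,d} \sum_{k=1}^{t}\sum_{j=1}^{d}\sum_{i=1}^{n}
w_i\, y_{i,j,k}\, \log x_{i,j,k},
\]
with phase weight 1, transition weight 0.1 (ten times smaller, to avoid
overestimating the short transition segments) and non-phase positions
excluded (weight 0). At `t = 1` it reduces exactly to the per-clip
classification loss, an identity asserted numerically in the tests. The
leading minus sign makes it a proper minimisation objective.
Probabilities are clamped at 1e-12 before the logarithm.

Windows are sampled evenly — `windows_per_video` (default 200) starts
spread over `[0, n_clips - window_len]`, first at 0 and last flush with
the video end — so window index *i* means the same *relative* position in
every video, and batches are formed from same-index windows across
videos. The optimiser is Adam at `lr = 1e-5` decayed by 0.93 every fifth
epoch (the recipe of the fine-level stage, reused because no separate
recipe is specified for the sequential stage); the small-scale test runs
use larger rates (1e-3–1e-2) appropriate to their tiny models.
Validation micro accuracy — phases only, transition and non-phase
excluded — is computed four times per epoch and the best-in-history
parameters are kept. Validation targets are the *fine-level* predictions
rather than groundtruth, so checkpoint selection measures the deployment
condition and does not leak labels.

Three target strategies: `baseline` feeds groundtruth (vulnerable to
exposure bias at deployment); `noised` replaces exactly
`round(0.4 · L)` uniformly chosen positions with a uniform draw from the
phase+transition vocabulary excluding the original label, resampled
fresh every epoch (fresh resampling regularises more than a frozen
corruption; both are reachable through `inject_noise`'s seed argument);
`pred` feeds the fine-level predictions, preserving their internal error
structure.

## Evaluation methodology

Frame(clip)-based metrics: per-phase precision and recall are computed
over positions whose groundtruth is not non-phase; the macro averages run
over the phases present in the groundtruth (transition predictions count
as errors but transition is not an averaged class); F1 is the harmonic
mean of macro precision and recall; micro accuracy is correct/total over
positions whose groundtruth is a phase.

Event-based metrics follow the Ward error taxonomy, applied one phase at
a time and summed. An event is a maximal run of one class; two events
overlap when they share at least one clip index (inclusive integer
intervals). Each groundtruth event is Correct, Deleted, Fragmented,
Merged, or Fragmented-and-Merged; each predicted event is Correct,
Inserted, Fragmenting, Merging, or both. The matched-pair count C is
identical from either side (a property checked on randomised inputs
against an independent brute-force oracle, together with the
conservation identities `n_gt = C+D+F+M+FM` and
`n_pred = C+I'+F'+M'+FM'`). The event ratio `n_gt / n_pred` is reported
as-is above 1 and defined as 0 when there are no predicted events (the
worst case). Transition and non-phase are not scored classes but remain
in the timeline, where they legitimately separate runs of a phase;
how real annotation pipelines treat transition segments at event
boundaries is unknown, so this retention convention is explicit rather
than buried.

Metrics are computed at clip resolution — the native unit of the coarse
predictions; multiply by `clip_len_frames` for frame-level reporting.

## The synthetic study system

The simulator emulates what the models need from real data and nothing
more:

* **Durations.** Per-phase normal draws with the clinical means and
  standard deviations (633±365, 3097±1212, 3888±879, 211±157, 1073±548
  seconds), floored at `max(30, mean - 2·sd)` s. The floor guarantees
  positive durations; a proper resampling truncation was rejected
  because it shifts the short fourth phase's mean upward by tens of
  seconds, which would decalibrate the generator against its own
  configuration.
* **Order.** Phases run 1→5; with probability `p_phase5_before_4`
  peritonealisation starts before mesh fixation to the promontory, the
  order variant seen clinically (default 0 so tests are deterministic in
  structure).
* **Transitions and pauses.** Inter-phase transitions are uniform on
  10–120 s (transitions are described only as few and short; this range
  is the package's choice). Each phase pauses at most once with
  probability 0.2, for a uniform 10–120 s, in the middle 80 % of the
  phase; a pause freezes the phase, so the drawn duration is the active
  duration. Paused spans are labelled transition — the procedure is not
  in any phase there — and the convention is configurable at the
  annotation level because real groundtruth policies may differ.
  Non-phase head and tail spans are uniform on 30–120 s.
* **Features.** Each label class has a fixed mean direction in feature
  space (unit Gaussian direction scaled by `class_separation = 3`,
  drawn from `mean_seed`, which is deliberately separate from the
  per-video noise seed so every video of an experiment shares one
  feature geometry). Consecutive phase pairs are pulled toward their
  midpoints by `adjacency_shrink = 0.3`, emulating the confusability of
  neighbouring phases; isotropic noise has `noise_sd = 1`. With these
  defaults a nearest-mean classifier sits in the 80–90 % range per clip
  — informative but imperfect, like a real backbone.
* **Fine-level predictions.** A two-state Markov chain corrupts the
  groundtruth: the stationary error fraction is `1 - fine_accuracy`
  (default 0.69, the ballpark of a clip-level 3D CNN on this procedure)
  and error runs are geometric with mean `error_burst_len = 5` clips,
  each burst holding a single wrong label biased toward phase
  neighbours. Real fine-level errors are temporally correlated, and
  independent errors would make the event-based metrics trivially easy.

What the generator does **not** emulate: appearance drift within a
phase, tool-usage signals, annotation ambiguity at boundaries,
inter-surgeon variability, or any correlation between feature noise and
the fine classifier's errors (features and predicted labels are
corrupted independently). Passing tests on synthetic data therefore
demonstrate that the machinery — models, training loop, recursion,
metrics — behaves correctly and can learn a workflow with realistic
duration statistics; they do not certify clinical-grade accuracy.

## Numerical and design choices

* Clip labels are the modal frame label; ties break toward the lowest
  code, trailing partial clips are dropped, and frame *t* covers
  `[t/fps, (t+1)/fps)` with 0-based indexing throughout the timeline
  conversions.
* The mode filter and the per-clip vote of the recursive scheme use the
  same lowest-code tie-break, making every inference path deterministic.
* Window starts use half-up rounding (`floor(x + 0.5)`); R's banker's
  rounding would make the evenly spaced start grid irreproducible across
  platforms at exact halves.
* Parameter initialisation is Glorot-uniform with zero biases and LSTM
  forget-gate bias 1. Softmax and cross-entropy are computed with
  max-subtraction; attention masking uses −1e9 rather than −Inf so the
  softmax backward stays finite.
* Time-synchronous tiling right-aligns its final window when the video
  length is not a multiple of 100, and clips already covered keep the
  earlier window's label. Videos shorter than one window are rejected
  with advice to use the fine predictions directly.
* A single experiment seed fans out to stage seeds through a string hash
  (`derive_seed`), so simulate/emit/train/segment are independently
  reproducible and two pipeline runs with the same config produce
  identical label files.
* Problem sizes in the test suite were chosen for single-CPU runs: the
  learnability experiments train `d_model` 32 models on 8 simulated
  videos (~1100–1800 clips each) with 30–40 windows per video and 4–10
  epochs, and evaluate on 2 held-out videos by full-video segmentation.

## Known limitations

* The autodiff engine is plain R matrix code; it is fast enough for the
  reduced geometries used here but not for `d_model` 1200 at scale —
  the production defaults document intent rather than a tested runtime.
* LSTM state is propagated left-to-right only; there is no bidirectional
  encoder option.
* The recursive time-shifted scheme propagates only label information
  forward: once the working sequence loses a phase, target copying alone
  cannot recover it — recovery must come from the features. This is
  intrinsic to the configuration, not an implementation artefact, and is
  the reason exposure-robust training (`noised`) matters.
* `event_ratio` compares event *counts* only; a sequence with the right
  number of badly misplaced transitions still scores 1. It is designed
  to complement, never replace, the frame-based metrics.
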