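---
title: "Annotation efficiency for surgical-video feature recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation efficiency for surgical-video feature recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Training classifiers that recognise intraoperative events from surgical video
requires per-frame expert annotation, and expert time is the bottleneck. The
conventional approach selects frames at a fixed time interval (equidistant
sampling, EQS), which under-samples rare but clinically important events: an
instrument present in 1% of frames yields one positive per hundred annotated
frames. Active learning (AL) instead lets the model pick the frames it is
least certain about, concentrating annotation effort where it matters.

`surgal` implements a prospective comparison of the two strategies for
multi-feature tagging of procedure-video frames: ten features in three
groups — two ordinal surgical-field scales (blood, graded 0 "no blood" to 4
"blood amount requiring immediate intervention"; smoke, graded 0 to 3 "no
visibility"), two binary anatomic structures (azygos vein, gastric tube) and
six binary instruments — annotated by majority vote over three raters,
classified by Bayesian networks with Monte-Carlo dropout, and compared with
budget-matched statistics. Because real surgical video cannot be
redistributed, the package ships a seeded synthetic procedure-video generator
that reproduces the *structure* of such data; every experiment in the test
suite runs end-to-end on synthetic cohorts.

## The synthetic cohort

`generate_cohort()` builds procedures with per-frame ground-truth feature
tracks:

* **Binary features** follow two-state Markov chains parameterised by the
  stationary positive prevalence and the mean dwell time of the positive
  state. Defaults span common instruments (suction 35%, permanent cautery
  hook 30%) down to rare ones (metal clip applier 3%, large clip applier 1%).
  Dwell times reflect how the instruments are used: clip appliers act in
  brief episodes (10 s), the suction stays in view for tens of seconds.
  Short dwell times for the rare instruments also mean their few positive
  frames are spread over several episodes, which is what makes a start set
  that covers every feature attainable from two videos.
* **Ordinal features** follow bounded birth–death (Metropolis) chains whose
  stationary distribution equals a configured occupancy target exactly;
  defaults make high blood/smoke levels rare (level 4 blood and level 3
  smoke each below 1% of frames), reproducing the rare-class problem.
* **Out-of-body segments** (camera outside the patient) are replaced by
  completely white frames; they keep their duration but are excluded from
  every sampling pool.
* **Two center styles**: videos alternate between centers A and B, and the
  suction motif is silver in A but black in B — a deliberate appearance
  confound between sites.

Frames are rendered at 60×80 pixels: a center-tinted textured background,
one distinct geometric motif per present binary feature, a red region whose
area grows monotonically with the blood level, and a white haze whose
opacity grows with the smoke level, plus seeded pixel noise. Rendering is
deterministic in (video seed, frame index).

**What the generator does not emulate:** photorealistic anatomy, motion
blur, occlusion between instruments, rater drift, or frame-difficulty
dependent annotation error. Passing tests therefore demonstrate that the
pipeline's logic and statistics are correct and that uncertainty sampling
finds rare, visually distinct events; they do not certify performance on
real endoscopic video.

## Simulated annotators

Six rater profiles tag frames independently: binary tags flip with a small
per-rater probability (0.002–0.004) and ordinal tags receive an additive
offset (zero with probability 0.76–0.80, otherwise mostly ±1). These values
were calibrated once so that agreement is far higher on binary than on
ordinal features — the mean one-rater Fleiss kappa is about 0.85 for binary
presence and about 0.52 for the graded scales — and so that merging raters
(majority of 3, then 5) increases kappa monotonically. The binary mean sits
below the high agreement a clinical annotator group reaches on crisp
instrument features because chance-corrected agreement on a 1%-prevalence
feature is structurally low at a 500-frame test size; the ordering and the
binary≫ordinal gap are the calibration targets.

Consensus (`consensus_labels()`) uses exactly three raters per frame:
unanimous, 2-vs-1 majority, or — only possible for ordinal features — a
three-way split that is adjudicated. Adjudication emulates the panel
discussion of a clinical annotation workflow: mode `"oracle"` returns the true level
(a panel that reaches the right answer), `"median"` the median vote. Test
frames carry all six raters for agreement analysis, but their reference
label uses the first three by rater id, keeping the pipeline symmetric.

## The Bayesian classifiers

One model per feature group: a softmax head per ordinal feature (levels are
mutually exclusive within a feature) in the blood/smoke model, and
multi-label sigmoid heads for anatomy and instruments. The backbone is a
small feed-forward network: frames are block-mean pooled (a fixed
average-pooling stem) to 15×20×3 inputs during selection cycles and 30×40×3
for post-hoc evaluation, centred on the training-set pixel means, then passed
through one ReLU hidden layer (24 units by default; the reference protocol
experiments use 96) with dropout (rate 0.3). No
deep-learning framework is used; forward pass, backpropagation, SGD with
momentum and the one-cycle learning-rate schedule are implemented directly
in R. This takes the proxy-model idea — selection does not need the full
evaluation network — one step further to desk scale; the motifs the
generator draws are large and position-coded, so a pooled-pixel network
separates them.

The dropout layer stays active at inference. `predict_mc()` runs `T`
stochastic forward passes and reports the per-class mean probability and the
across-inference standard deviation; `frame_uncertainty()` aggregates the
per-class standard deviations to one score per frame. The default
aggregation is the mean over all classes of the group's heads, treating
every label of a multi-label head equally; `method = "max"` is available for
workflows that want a single alarming class to dominate. Selection uses
T = 20 inferences (cost), post-hoc evaluation T = 100.

The configuration defaults are 100 epochs of SGD under a one-cycle
schedule with peak learning rate 3e-3 and batch size 16.
For protocol experiments the package uses 40 epochs at peak rate 0.02 — on
this small network the higher rate converges in far fewer epochs to the same
training accuracy, and six models are retrained per cycle — and widens the
hidden layer to 96 units. The width matters for the cold start: with a
single positive start-set example of a rare instrument, a narrow hidden
layer only sometimes contains features responsive to that motif, so whether
the model generalises (and hence whether uncertainty ever flags the rare
frames) becomes an initialisation lottery; at 96 units the bootstrap is
reliable. Batch size stays at 16 — with larger batches the single positive
receives too few gradient updates per epoch to shape the representation. Evaluation models
train with lightweight augmentation: ±1-pixel shifts on the pooled grid,
additive brightness and per-channel color scaling — a desk-scale stand-in
for random scaling, rotation, brightness and color jitter.

## The prospective protocol

`run_protocol()` executes the experiment exactly once per seed, with no
between-cycle evaluation:

1. **Start set**: frames every two minutes (configurable) from the first
   video of each center; any feature level the equidistant grid missed is
   filled in with one frame found in the same videos' ground truth, added to
   the affected model group's set only. Both arms start from this set.
2. **Per cycle**: one new video joins in chronological order. EQS selects
   equidistant frames from the new video only (white-frame hits are skipped
   without substitution, preserving strict equidistance — the alternative,
   substituting a neighbour, was rejected as it biases toward segment
   boundaries). Each AL group model scores *all* unlabeled frames of *all*
   available videos and takes exactly the EQS budget, ties broken by
   chronology; the three groups may pick different frames.
3. Both arms' batches receive simulated three-rater consensus annotation,
   and all six models are retrained from scratch on their cumulative sets.
   Retraining from scratch (rather than warm-starting) keeps every cycle a
   pure function of its cumulative data and seed.

The held-out test videos never enter any pool. `posthoc_validation()`
retrains evaluation-resolution models on each cycle's cumulative sets,
scores the test set with 100 inferences, and optionally adds the upper
baseline trained on the union of both arms' data. `mcnemar_cycles()` runs
the Edwards-corrected McNemar test per feature and cycle on the paired
correctness of the two arms, plus combined tests per group and overall by
summing contingency tables; cycles where both arms classify identically are
left blank, and displayed p-values floor at "<0.001".

All randomness derives from one master seed through a documented splitting
scheme (`seed_stream()`), so a ledger is exactly rerunnable.

### Reference study conditions

`annotation_efficiency_experiment()` fixes the desk-scale conditions used by
the test suite and the acceptance script: 14 videos (2 start + 10 cycles +
2 test) of 20 minutes sampled at one frame per 4 s (300 frames per video),
EQS every 30 s (a budget of roughly 38 frames per cycle, scaled to the
20-minute videos the way a two-minute interval scales to multi-hour
procedures), the large clip applier at 1% prevalence as the rare instrument,
and final-cycle post-hoc validation of the instruments group. One replicate
runs in just under two minutes on a single CPU; the ten-replicate
acceptance test takes roughly 19 minutes.

## Evaluation statistics

* `binary_prf()`: positive-class precision, recall, F1 with support;
  zero-division yields 0, so a never-predicted class scores 0.00 rather
  than dropping out.
* `hierarchical_macro_f1()`: one-vs-rest metrics per ordinal level (first
  averaging over images), then the unweighted mean over levels (second
  averaging over levels). Levels with zero support in both truth and
  prediction are dropped; a supported level that is never predicted
  contributes 0. Whether zero-support levels should enter the mean is
  genuinely open; dropping them avoids rewarding or punishing a model for
  levels absent from the test set.
* `mcnemar_edwards()`: statistic `(|b − c| − 1)² / (b + c)` on the
  discordant counts, 1 degree of freedom, blank when `b + c = 0`. Note the
  correction applies for `b = c` as well (statistic `1/(b+c)`), where base
  R's `mcnemar.test()` switches the correction off; tests cross-check
  against base R on the `b ≠ c` cases and against the closed form elsewhere.
* `fleiss_kappa()`: the classical multi-rater chance-corrected agreement;
  undefined (NA) when all ratings fall in one category.
* `merged_rater_kappa()`: the 1-rater score is the raw six-rater kappa; for
  merge sizes 3 and 5 each of the `choose(6, m)` rater combinations is
  merged per item by majority (three-way ordinal ties by median) and the
  resulting pseudo-raters are scored with a single Fleiss kappa. The
  wording "kappa of all possible combinations" also admits averaging a
  kappa per combination; that reading is implemented as `method = "mean"`,
  computing the Fleiss kappa within each raw m-rater combination and
  averaging. The pooled pseudo-rater form is the default because it yields
  one agreement coefficient for the merged annotation process itself.

## The report

`surgomic_report()` condenses one procedure's prediction stream into a
one-page overview: a videogram (the center pixel column of one frame per
minute, concatenated), one barcode per feature and per-feature summaries.
Barcodes compress the stream to at most 800 bins by contiguous chunks whose
sizes differ by at most one — the minimal-variance partition — so the
chunk-size-weighted bin mean equals the raw stream mean exactly. Ordinal
barcodes display the relevant-level indicator (blood above level 2, smoke
above level 1), matching the duration summaries; the raw level track is
recoverable from the prediction CSV. Summaries (total duration, relevant
duration, per-mille presence, mean/max/min certainty) are always computed
from the raw stream, never from the bins. Certainty for display is
`1 − u/max(u)` over the procedure's frame uncertainties — the method
reports an uncalibrated spread, so only its within-procedure ordering is
meaningful, and the normalisation makes that explicit. `render_report()`
writes a deterministic PNG page plus a JSON summary.

## Numerical choices and degenerate inputs

* Weight initialisation is He-scaled Gaussian, seeded; training and
  Monte-Carlo inference restore the caller's RNG state.
* `predict_mc()` requires `T ≥ 2` (the spread is undefined otherwise) and
  returns exact zeros for dropout rate 0.
* Uncertainty ties in frame selection break by (video chronology, frame
  index); budgets larger than the pool return the whole pool with a warning.
* A feature level absent from a training set only warns — the model may
  simply never predict it, which is precisely the failure mode the start-set
  fill exists to prevent.
* Prevalence 0 is allowed (a constant all-absent track); prevalence ≥ 1 is a
  configuration error.

## Known limitations

* The rendered scenes are schematic; conclusions about real endoscopic video
  require real data.
* Model uncertainties are not calibrated; selection relies only on their
  ranking.
* The rater error model is i.i.d. per frame and feature — no drift, no
  difficulty modulation — which makes the agreement gap reproducible but
  understates the structure of real disagreement.
* Acquisition is pure uncertainty ranking; diversity-aware or hybrid
  acquisition is out of scope.
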