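---
title: "Methods: quantifying sleep, memory, and synaptic change in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sleep, memory, and synaptic change in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormsleep)
```

`wormsleep` quantifies a chain of measurements linking post-training sleep
to olfactory memory consolidation and synaptic remodeling in *C. elegans*.
This vignette records the models each stage assumes, the parameters that
matter and their defaults, the numerical conventions at edge cases, and
what the synthetic-data generators do and do not emulate.

## Quiescence from displacement video

Single animals in multi-well (WorMotel-style) agar devices are imaged at
one frame per 3 s and movement is reduced upstream to an inter-frame pixel
displacement per animal. `detect_bouts()` calls a frame *still* when its
displacement is at or below `zero_threshold`, and a *quiescent bout* is a
maximal run of at least `min_run` still frames.

Parameters and defaults:

* `zero_threshold = 0` (displacement units, typically px). Displacement
  from frame subtraction is effectively binarized upstream, so stillness
  is exact zero; the threshold is exposed for un-binarized input.
* `min_run = 9` frames. At 3 s/frame this is the 27 s criterion that
  separates sleep-like quiescence from pauses; `min_run` counts
  displacement values (inter-frame intervals), not camera images.
* `dt = 3` s/frame.

Conventions: bouts are half-open `[start, end)` intervals over 0-based
frame indices, so `seconds = (end - start) * dt` with no fencepost
ambiguity. A missing (`NA`) frame splits any run — a gap never fabricates
stillness, which biases conservatively against calling quiescence. Hour
bins are half-open `[k*3600, (k+1)*3600)` anchored at the end of training
(`t0 = 0`); a bout straddling a boundary contributes its frames to each
bin separately, since no attribution rule is canonical for boundary
bouts. Total quiescence is conserved exactly: summed bin minutes equal
`dt/60` times the bout frames. Group summaries report both means ± SEM
and medians (different panels of a typical study use each), and a
trial-mode first averages animals within a trial. Pumping rate is the
15 s count times 4; feeding quiescence is the proportion of animals
pausing ≥ 4 s, with the binomial proportion SE.

## Posture and locomotion from 17-point skeletons

Skeletons are 17 ordered midline points, head = point 1, midpoint =
point 9, tail = point 17. The midpoint bending angle treats
(p1, p9, p17) as a triangle and reports
`theta_m = 180 - (theta1 + theta2)` (degrees), the angle-sum complement
of the interior angles at head and tail; by construction it equals the
direct interior angle at the midpoint, and the package asserts that
identity to 1e-6 degrees. A straight animal scores 180°; a right-angle
fold scores 90°. The measure is invariant under translation, rotation,
uniform scaling and reflection, so the dorsoventral ambiguity of
skeletonization is irrelevant. If head and tail coincide exactly (a fully
folded posture), the triangle degenerates; the midpoint angle is then
taken directly at p9 and the flank angles are reported `NA`.

Locomotion uses point 9 as the body center: per-step speed
`|p9(t+1) - p9(t)|/dt`, track length as the summed step lengths (which
therefore can never be smaller than the net displacement), and a
peristaltic forward/backward split by projecting each step on the
tail-to-head chord (positive = toward the head). The chord projection is
an approximation — the study's tracker does not define its
operationalization of peristaltic movement. The moving-average speed
window defaults to 10 frames (30 s), matching the posture-analysis
window; only "moving average" is specified by the protocol, so the window
is a package choice and is configurable. `stillest_window()` returns the
*first* window minimizing the windowed mean — the tie rule matters for
reproducibility and "earliest" is the deterministic choice. Posture
overlays translate each skeleton so p9 is at the origin, with no rotation
or scaling: alignment "to the midpoint" only, an exact per-frame
isometry.

## Chemotaxis, learning, censoring, gates

`CI = (N_odor - N_diluent) / (N_total - N_origin)`. Worms still at the
origin never made a choice and are excluded from the denominator; worms
elsewhere on the plate did leave and are retained. A plate where no worm
left the origin has no defined CI and errors. Trials whose buffer-trained
control scored CI < 0.5 (strictly) are censored — the control population
could not chemotax, so the trial's learning index is uninterpretable;
censored trials are flagged and excluded from summaries but never
silently dropped.

The learning index is defined here as `LI = CI_buffer - CI_butanone`, so
that successful aversive learning is positive. Read literally, the
source protocol's prose subtracts in the opposite order, which would make
every reported LI negative and contradict the printed 0.4–1.2 range; the
package fixes the sign so learning is positive and locks it as a
documented convention.

Imaging-batch gates are a pure function of (condition, sleep status, CI):
butanone-trained batches allowed to sleep pass iff CI < 0.5 (they should
have learned to ignore the odor); buffer-trained batches and
sleep-disturbed butanone batches pass iff CI > 0.5 (they should still be
attracted). Both inequalities are strict, so CI = 0.5 always fails —
neither printed rule admits it.

Memory decay is compared across genotypes/conditions by regressing LI on
time within each condition and testing pairwise slope equality through
the time-by-condition interaction of a joint linear model, two-sided. On
noiseless data the residual SE is floating-point dust; the package pins
the exact-fit case (p = 1 for a zero interaction, p = 0 otherwise) rather
than reporting an arbitrary ratio of rounding errors. The same
convention applies to the spline slope-change test below.

## Calcium responses and synaptic intensities

`F = roi_mean - bg_mean` per frame (background ROI drawn off-animal);
`F0` is the mean of the first three background-subtracted frames, and
`dF/F0 = 100 * (F - F0) / F0` percent. F0 ≤ 0 is an acquisition failure
and errors. The odor-switch response magnitude is the absolute
difference of the mean dF/F0 in the 20–30 s window (10 s before the
switch at 30 s) and the 30.5–40.5 s window; at 2 fps with inclusive
bounds and `t = frame/fps`, those windows are exactly frames 40–60 and
61–81 — the half-frame offset at 30.5 s is honored, not rounded. A
missing frame inside a window averages over the available frames and
clears a completeness flag.

Punctal-cluster intensity is the pixel sum over a hand-drawn mask. For
markers imaged over autofluorescent tissue, the minimum intensity of a
disjoint surrounding region is first subtracted from every mask pixel,
with negatives clamped to 0 (intensities are sums of nonnegative signal;
negatives can only be noise below the surround minimum). Subtracted
intensity therefore never exceeds the raw sum, and raw sums are additive
over disjoint masks.

Cross-sectional intensities are normalized per assay day to the *median*
raw intensity of that day's reference animals — buffer-trained, allowed
to sleep, imaged at 16 h — as `normalized_pct = 100 * raw / ref_median`.
Median (not mean) normalization follows the protocol's use of median
intensity values and is robust to the long right tail of punctal sums.
The transform is within-day monotone and day-scale-free, which is what
lets animals from different imaging days share one axis. Whether each
animal or only treatment medians were normalized in the source figures is
ambiguous; per-animal normalization is this package's reading, and it
reproduces median-based statements either way. For single worms imaged
twice, the first timepoint is set to 100% and a reduction of at least
50% (boundary inclusive) flags the animal as reduced — the coarse
photobleaching-tolerant classification used for paired images.

## The sqrt-scale piecewise-linear time course

Synaptic change after training is rapid for ~2 h (the critical period)
and slower afterwards. The package models intensity `y` at `t` hours
post-training as

```
sqrt(y) = a + b_early * min(t, k) + b_late * max(0, t - k) + e,  k = 2 h
```

fit by least squares on the hinge basis `{1, t, max(0, t - k)}`. The
square-root transform stabilizes the skewed intensity residuals toward
normality; the knot is fixed at 2 h (a biological constant here, exposed
as a parameter but never estimated — knot search would change the test's
null distribution). The fitted mean is continuous at the knot by
construction, asserted to 1e-9. The slope change `delta = b_late -
b_early` is the hinge coefficient, tested with `t = delta/SE(delta)`
against Student's t with `n - 3` df, two-sided — the standard
least-squares contrast; the protocol states only that the slopes can be
tested, so this operationalization is the package's documented choice.
Fits default to normalized percentages (the display scale); raw-intensity
mode is available. Normalized values are pooled across assay days; a
day covariate is a plausible refinement the package deliberately omits to
match the source analysis.

Calibration, verified by the test suite at these problem sizes: with
noiseless hinge data the coefficients are recovered to 1e-9; with
sigma = 0.5 at n = 200 per fit, 3-SE coverage of (a, b_early, delta)
exceeds 95% over 200 seeded replicates; under the equal-slope null
(sigma = 1, n = 60) the slope-change test rejects at the 5% level in
5% ± 1.5% of 2000 seeded replicates.

## The statistical decision tree

Every multi-group comparison runs through one gate: Shapiro-Wilk
normality per group at alpha = 0.05. If all groups pass, the parametric
branch runs — one-way ANOVA omnibus, pairwise two-sided t-tests,
Bonferroni adjustment. Otherwise the nonparametric branch runs —
Kruskal-Wallis omnibus, pairwise two-tailed Mann-Whitney U-tests (normal
approximation with tie correction; the protocol is silent on ties),
Hochberg step-up adjustment. With exactly two groups the omnibus is
skipped. A constant sample short-circuits the gate to nonparametric
(Shapiro-Wilk is undefined there, and a constant sample is certainly not
normal). The branch-specific adjustments mirror the source analyses; both
can be forced. `hochberg_adjust()` is the package's own step-up
implementation (the operation is part of the contract) and is
cross-checked against `stats::p.adjust` in the tests. Pearson
correlations use the exact t transform `t = r*sqrt((n-2)/(1-r^2))`;
two-proportion comparisons use the pooled-SE z statistic, returning p = 1
with a warning when the pooled proportion is degenerate.

## What the synthetic generators emulate

The generators produce inputs with the statistical structure the analyses
assume, with known ground truth:

* **Displacement**: a two-state Markov chain per animal (active ↔
  quiescent), quiescent frames emitting exactly 0 and active frames a
  half-normal displacement (scale 4 px/frame by default). Bout calling
  only distinguishes zero from nonzero, so any positive emission law
  would do; half-normal is a concrete documented choice. Animals start
  active — they are moving when loaded into wells after training.
  Default per-frame rates (enter, exit) are naive (0.002, 0.10), buffer
  (0.010, 0.08), butanone (0.030, 0.07): after the 9-frame rule discards
  sub-threshold runs these give roughly 1, 5, and 15 min of called
  quiescence in the first hour, the ordering and scale of the measured
  phenotype. Rates may vary by hour bin to emulate decaying sleep
  pressure.
* **Plates**: one multinomial draw over (odor, diluent, origin,
  elsewhere) per plate, so the empirical CI converges on the closed form
  `(p_odor - p_diluent)/(1 - p_origin)`.
* **Synapse time course**: sqrt-scale hinge means plus Gaussian noise
  (sigma on the sqrt scale), squared into intensities; draws whose sqrt
  would be negative are truncated at intensity 0 and counted in an
  attribute, since intensities are nonnegative sums. Defaults: a = 10,
  b_early = -2, knot 2 h, sigma 0.5, timepoints {0, 2, 16} h, 80
  animals/condition/timepoint spread over 4 assay days.
* **Sleep–memory pairs**: a bivariate normal with population correlation
  rho (default 0.61 across a default 47 trials, the observed study
  scale), then clipped to plausible ranges (quiescence 0–60 min, LI −2
  to 2). Clipping after the correlated draw biases r toward zero, so the
  clipped fraction is recorded and flagged when above 1%.
* **Skeletons**: straight, sinusoid, shepherd's crook (posterior 75%
  straight, anterior quarter on a circular arc — 120° total turn by
  default, a gentle hook whose 17-point chord spacing stays within 1% of
  arc-uniform), and V-bends with an exact configured angle at point 9.
  Frames translate rigidly, giving a known track length.

Determinism: every generator derives an independent sub-stream from the
root seed keyed by stage and animal/trial index (a polynomial hash mod
2^31 − 1, exact in doubles), so identical configurations are bit-identical
and adding animals never perturbs existing series.

What the generators do **not** emulate: spatial video (no images or
segmentation), temporally correlated displacement magnitudes within the
active state, behavioral state structure beyond two states (no
lethargus-like bout clustering), plate spatial structure, day effects in
synaptic intensities beyond the day key itself, or photobleaching in
paired single-worm images. Green tests therefore certify the
*quantification arithmetic and inference machinery* on data satisfying
the models' assumptions; they do not certify robustness to segmentation
error, tracking loss, or optical artifacts in real recordings.

## Known limitations

* The bout caller assumes displacement is already animal-resolved; well
  segmentation and multi-animal disambiguation are upstream.
* The peristaltic split and the 10-frame moving-average window are
  package choices where the protocol is silent (both documented above).
* The spline fit pools assay days after normalization; day-level random
  effects are out of scope.
* Gate and censoring thresholds are fixed constants of the assay design;
  changing them changes the meaning of downstream summaries.
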