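---
title: "Methods: simulating and analyzing array-microscope migration screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing array-microscope migration screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(migrascreen)
```

# Scope

`migrascreen` models the computational side of a high-throughput
migration screen performed on a multi-lens array video microscope: 16
lenses at 96-well pitch image 16 wells of a 96-well plate — or, by
stepping the optics over a 2 x 2 grid of 4.5 mm moves, 64 wells of a
384-well plate — at one frame per 8 s, fast enough to track
fMLP-stimulated human neutrophils. The package covers five connected
pieces: the closed-form optics/bandwidth budget of such an instrument, a
simulator of its acquisition loop, a ground-truthed synthetic data
generator, Earth Mover's Distance (EMD) single-cell tracking, and the
per-round control-normalized screen analytics with hit calling. No real
movies are required anywhere; the generator produces every input with
known truth.

# Optics and bandwidth budget

Lateral resolution follows the Abbe criterion $d = \lambda / (2\,\mathrm{NA})$:
an NA 0.3 lens at 550 nm resolves 917 nm, a conventional NA 0.4
comparison lens 688 nm (`abbe_resolution()` reports both the integer-nm
value, rounded half-up, and the exact quotient). Field of view is active
sensor area divided by magnification; the default WXGA sensor
(1280 x 800 px on 3888 x 2430 um) at magnification 4.708 gives the
825.8 x 516 um field and 0.645 um/px used throughout the package. We
expose the sensor/FOV quotient rather than hard-coding a magnification,
because the printed dimensions determine it more precisely than any
rounded nameplate value.

Data rates are reported in binary gigabits per second (bits/s divided by
$2^{30}$): the only reading under which the 16-sensor raw stream
(1280 x 800 x 30 bit x 30 fps x 16) reproduces the instrument's 13.73
figure. The reduced stream is modeled as 720p 8-bit grayscale
(1280 x 720), which reproduces both the ~3.3 Gbit/s rate and — with two
ping-pong frame memories per channel — the ~28 MB intermediate buffer
(1280 x 720 x 1 byte x 16 channels x 2 = 28.125 MiB). The full-height
1280 x 800 geometry reproduces neither figure, so 720 rows is the
default and the geometry stays configurable. Free-running autofocus adds
a third (sharpest-frame) memory block per channel.

# Acquisition loop

`sharpness_score()` is a Tenengrad functional: the mean squared gradient
magnitude from 3 x 3 Sobel kernels, computed on the interior of the
frame. It is zero for constant images, invariant to intensity offsets,
and decreases monotonically under Gaussian blur, which is what a focus
metric needs; the instrument-side sharpness indicator is not publicly
specified, so the metric is a package design choice and alternatives can
be swapped in wherever a score function is accepted.

Two autofocus modes are modeled after the instrument's two operating
modes. In *triggered* (focus-position-map) mode the last complete frame
in the ping-pong memory at trigger time is kept; per-well focal planes
come from `build_focus_map()`, the argmax of sharpness over a
calibration z-stack (flat stacks fall back to the midpoint with a
warning). In *free-running* mode the sharpest frame of the whole ~1.5 s
sweep is kept, ties going to the earliest frame for determinism.

`simulate_cycle()` builds the event timeline of one frame interval with
constant-velocity stage kinematics (only speeds are published; the
0.45 s vs < 0.5 s margin on a 4.5 mm move absorbs acceleration ramps).
The 384-well cycle is four sequential position blocks of
move (0.45 s) + sweep (1.5 s) + exposure (1/30 s) ≈ 1.98 s each, 7.93 s
total — inside the 8 s interval, which is exactly why four positions per
lens are schedulable. Whether sweep and move overlap in the real
instrument is unknown; we assume sequential execution, which is the
conservative choice and still fits the budget. In triggered mode the
per-position ~40 ms dwell extends the sweep only when
`n_positions * dwell` exceeds the nominal sweep duration. Infeasible
configurations return `feasible = FALSE` naming the violated budget
rather than throwing.

# Synthetic data generator

**Tracks.** Cells follow a persistent random walk: heading
$\theta_{t+1} = \theta_t + \mathcal N(0, \sigma_\theta^2)$ with
$\sigma_\theta = 0.6$ rad per 8 s step, and a per-cell speed drawn once
from $\mathcal N(15, 5^2)$ um/min truncated at zero. Drawing speed once
per cell (rather than per step) produces the broad, stable per-well
speed distributions seen in leukocyte migration data and keeps the two
screen read-outs separable: *speed* is a property of moving cells,
*activity* (default active fraction 0.7) is the fraction that moves at
all. Inactive cells jitter with 0.2 um/frame zero-mean noise.
Boundaries reflect (cells cannot teleport across the field, which would
corrupt tracking gates). The defaults — 450 frames at 8 s (one hour),
15 um/min — are the conditions of an fMLP-stimulated neutrophil assay;
speeds in the low tens of um/min are the textbook range for
chemokinetically stimulated human neutrophils.

**Images.** Cells render as radially symmetric Gaussian-profile blobs
(sigma = radius/2, default radius 5 um) on a uniform background with
additive Gaussian pixel noise; defocus applies a uniform blur of
sigma = 0.8 px per um of distance from the focal plane. Ground-truth
masks are noise-free discs; where discs overlap, pixels go to the
nearest center, so every rendered cell keeps exactly one label.

What the generator deliberately does *not* emulate: neutrophil
morphology and uropod dynamics, shape changes under compounds,
chemotactic gradients, uneven illumination, and imaging artifacts other
than Gaussian noise and symmetric defocus. Passing tests therefore
demonstrate the correctness of the algorithms under controlled
conditions, not segmentation robustness on real bright-field movies —
which is why the segmenter is pluggable (`track_movie(..., masks = )`
accepts externally produced label masks, e.g. from a learned model).

**Screens.** `simulate_screen()` lays out rounds of 64 wells — 61
compounds plus three controls (stimulated normalization control,
vehicle, unstimulated) — and applies per-compound multiplicative effects
to the stimulated baseline: `speed_multiplier` scales the per-cell speed
distribution, `activity_multiplier` the active fraction. True relative
read-outs equal the multipliers by construction. Wells regenerate
deterministically from per-well seeds, so a full 1000-compound screen
(1051 wells) streams through `screen_pipeline()` one well at a time.

# EMD tracking

Each frame's detections form a weighted point set: one point per cell at
its centroid, weighted by segmented area and normalized to total mass 1.
One point per cell (not pixel clouds) keeps the problem tractable at
~1200 cells/frame while staying faithful to mask-level matching.
Matching consecutive frames is the discrete transportation problem —
minimize total flow x distance — solved exactly by a successive-
shortest-path min-cost-flow solver (compiled code, sparse arcs).
Numerical choices:

* **Gate.** Pairs farther than 20 um per 8 s frame (150 um/min,
  several-fold above fast neutrophil speeds) are forbidden arcs: true
  links are never gated out, teleport links always are.
* **Partial transport.** A dummy source/sink pair absorbs unmatched
  mass at cost gate/2 per side, so a real link is cheaper than an
  appearance-plus-disappearance exactly when its distance is below the
  gate; the balancing dummy-dummy arc costs nothing.
* **Flow-to-link rule.** A pair is linked when its optimal flow reaches
  half of `min(w_i, w_j)` (majority mass); greedy selection by
  descending flow keeps links one-to-one, with ties broken by label
  order. With equal counts and weights and nothing gated out, the
  optimal plan is a permutation and the rule reduces to minimum-cost
  perfect matching — the tests verify this against exhaustive
  enumeration and against an independent Hungarian solver.
* **Tie-breaking.** Arcs enter the solver in (label_t, label_t1) order
  and the label-correcting search relaxes them deterministically, so
  identical inputs give identical matchings.

Linking concatenates matched chains; an unmatched later detection starts
a track, a disappearance ends one. There is no gap closing: the
evaluation scheme counts untracked cells instead of bridging detection
gaps, and bridging would silently hide segmentation failures. Only
tracks of at least 8 frames (one minute at 8 s/frame) are reported.

# Baseline segmentation

Otsu's bimodal threshold, followed by a watershed on the lightly
smoothed (sigma 1 px) intensity image restricted to the foreground, and
an area filter (20-5000 px). The watershed runs on intensity rather
than on the distance map because touching bright blobs keep two
distinct intensity peaks well after their outlines merge; the 0.02
tolerance (on the [0, 1]-normalized scale) merges noise-born peaks while
preserving genuine two-cell contacts. Deliberate limits: heavily
overlapping cells still merge into one detection (merge handling is out
of scope), and the thresholding approach assumes bright cells on a
darker background as the renderer produces.

# Evaluation scheme

`evaluate_frame_pairs()` is the automated analogue of manually
inspecting sampled consecutive frame pairs, judged on the basis of the
former frame: each former-frame detection is matched one-to-one to the
nearest true cell within 5 um (well under a cell diameter); detections
with no correspondence are former-frame segmentation errors and are
excluded from the counts. A predicted link is *correct* when its later
endpoint lies within 5 um of the followed cell's true later position,
*erroneous* otherwise. A correctly detected former-frame cell with no
link is *untracked*, attributed to false-negative segmentation when no
detection at all lies near the cell's later position. The summary
statistic is

$$\text{track correctness} = 100 \cdot
\frac{\text{created} - \text{erroneous}}{\text{created} + \text{untracked}}$$

the unique reconstruction that maps the reference evaluation's counts
(2207 created, 7 erroneous, 43 untracked) onto its reported 97.78%.
We judge links against the followed cell's position rather than by
double one-to-one correspondence because a merged later-frame detection
corresponds to only one of its two constituent cells; the double
correspondence rule would then count one tracking error and one
untracked cell for what is a single segmentation failure, which is not
how the manual bookkeeping treats such cases. Known limitation: two
cells crossing within 5 um of each other can swap identities without
being counted as errors — a limit shared by any distance-based
automated judgment.

# Screen analytics

Per track: path length, net displacement, duration, mean speed
(path/duration), confinement ratio (net/path). A track counts as
*migrating* when its lifetime net displacement reaches 10 um, about one
cell diameter — the criterion separates translocation from jitter and
keeps activity independent of the speed metric; it is configurable
because the underlying assay literature does not pin a single
definition. Well mean speed averages over tracks, not cell-frames, so
long tracks are not over-weighted.

Normalization divides each well's mean speed and migrating count by the
same-round stimulated control (relative values; the control itself is
exactly 1.0). Hit thresholds: strong inhibitor < 0.6 relative speed
(> 40% reduction), moderate in [0.6, 0.8), enhancer > 1.2, activity hit
< 0.8 — all strict on the hit side, so exactly 0.6 is moderate, not
strong. Classes: 1 = speed reduced with activity inside the
"unaffected" band [0.8, 1.2]; 2 = activity reduced with speed in the
band; 3 = both reduced. The band is symmetric with the 20% thresholds;
no tighter definition is published, so it is a declared default.

# Problem sizes and numerical tolerances in the shipped checks

The test-suite and acceptance-script runs use deliberately scaled
problem sizes chosen to exercise every code path at full field
resolution while keeping a complete run in minutes: the end-to-end
imaging pipeline uses one movie of 300 cells over 60 frames (8 min of
recording) on the full 825.8 x 512 um field; the screen pipeline runs
all 1000 compounds and 17 rounds but at 200 cells/well and 40 frames,
which puts the standard error of a well's relative speed near 2-3% —
an order of magnitude below the 40% hit threshold; defocus stacks use a
quarter-size field with 11 planes at 2 um steps. With these sizes the
pipeline recovers the generator's mean speed to within ~5% (centroid
noise slightly inflates path lengths; the bias shrinks with longer
steps) and the active fraction to within a few percent, plants and
recovers 17/17 strong inhibitors with no false positives, and tracks at
~98-99% frame-pair correctness.

# Known limitations

* The baseline segmenter is a stand-in for a learned cell segmenter;
  on real bright-field movies a trained model should be plugged in via
  the mask interface.
* Stage kinematics ignore acceleration; the published speed/time margins
  absorb this, but sub-50 ms scheduling claims are outside the model.
* The evaluation's 5 um correspondence cannot detect identity swaps
  between nearly coincident cells.
* Rendering models neither morphology nor illumination gradients, so
  segmentation performance numbers from synthetic movies do not
  transfer to real data.
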