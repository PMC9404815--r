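---
title: "Hybrid spiral images and off-the-shelf deep features: the spiralAD methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid spiral images and off-the-shelf deep features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-stage Alzheimer's disease degrades fine motor control long before
drawing shape degrades visibly.  An Archimedes spiral drawn on a
digitizing tablet is therefore recorded not as a picture but as an
*online* signal: position $x(t), y(t)$, pen pressure $p(t)$, the barrel
orientation angles azimuth $Az(t)$ and altitude $Alt(t)$, sampled at
125 Hz, including the in-air trajectory while the pen hovers near the
surface.  The question this package operationalizes is how to exploit
that dynamic information with transfer learning when only a few dozen
subjects are available.

## Hybrid trajectory images

The core encoding embeds one dynamic parameter at a time into the spiral
trajectory image, pointwise.  Velocity and acceleration magnitudes come
from finite differences of position,

$$v(t) = \sqrt{v_x^2(t) + v_y^2(t)}, \qquad
  v_x(t) = \frac{x(t+1) - x(t)}{\Delta t},$$

$$a(t) = \sqrt{a_x^2(t) + a_y^2(t)}, \qquad
  a_x(t) = \frac{v_x(t+1) - v_x(t)}{\Delta t},$$

with the signed component velocities (not the speed) differenced for
acceleration.  Each parameter is min–max normalized against the extrema
of the *whole population*, so images of different writers share one
scale, and mapped to gray with low values white (255) and high values
black (0).  Four views exist — pressure, altitude, velocity,
acceleration — plus the raw shape-only image.

Pen-state handling is view-specific and is what gives the views their
character: pressure is identically zero in air, so pressure views render
pen-down samples only and show *broken* trajectories wherever the pen
lifted; velocity and acceleration views render the in-air samples too,
*bridging* those gaps with the (typically fast, hence dark) in-air
trace.  Altitude also renders in-air samples by default — the digitizer
keeps reporting the angles in air — but this is configurable
(`includePenups`), since either convention is defensible.

Several rasterization choices are deliberately explicit because they are
not dictated by the method itself:

* canvas 512×512 px, aspect-preserving, centered, 5% margin, y flipped
  so tablet "up" is image "up";
* consecutive rendered samples joined by thick segments (width 3 px); a
  dots-only mode (`connectSegments = FALSE`) exists for ablation;
* a pixel is inked when its center lies within half a stroke width of a
  segment; where strokes overlap the darker gray wins, which makes
  rendering order irrelevant and preserves the monotonicity "larger
  parameter value never lightens a pixel";
* gray levels round half-up; a segment's gray is the rounded mean of its
  endpoint grays;
* degenerate normalization (max = min) maps everything to white and
  flags the image, a fail-soft rule for synthetic edge cases.

## Off-the-shelf features

Images are bilinearly resized to 224² (227 selectable), replicated to
three channels, scaled to $[0,1]$ and normalized with the conventional
per-channel constants.  A fixed AlexNet-architecture network
(conv 64/192/384/256/256, fc 4096/4096) is evaluated feed-forward and
*tapped* at six points: Conv1, Conv2 and Conv5 after their max-pooling,
Conv3 and Conv4 after their ReLU, and fc7 after its ReLU.  Tapping after
pooling is the conventional "off-the-shelf feature" choice and bounds
the SVM input dimension; at 224 input the dimensions are 46656, 32448,
64896, 43264, 9216 and 4096.  Activations are flattened channel-major,
then row, then column — frozen so vectors are comparable across runs.

The package has no deep-learning framework dependency: the forward pass
is im2col plus BLAS matrix products.  Weights are either supplied
externally (`weightsMode = "pretrained"`; nothing is bundled, and
requesting it without weights raises an instructive error) or drawn once
from a seeded He initialization (`random_seeded`).  Seeded-random
features are not semantically meaningful ImageNet features, but they are
a deterministic, information-preserving projection of the image — random
convolution features are a classical baseline — and they make every
pipeline property testable offline.  Claims about *which* layer is most
discriminant for clinical data require pretrained weights and real
cohorts; nothing in this package's tests speaks to that.

## The evaluation protocol

With one spiral per subject (reference cohort: 45 HC, 30 AD), the
protocol balances classes by repetition: each of 10 repetitions draws 30
of the 45 HC, trains on 20 HC + 20 AD and tests on the held-out 10 + 10.
HC subsamples are drawn independently across repetitions (whether the
original protocol constrained them to cover all 45 is unknowable; we do
not).  Per repetition an RBF-SVM is grid-searched by stratified 5-fold
cross-validation on the training split: default grid
$C \in 10^{-2..3}$, $\gamma \in 10^{-5..1}$ plus the variance-scaled
heuristic $1/(p\,\overline{\mathrm{var}})$; ties break toward the
smallest $C$, then the smallest $\gamma$, and the winner is refit on the
full split.  Features are z-scored per dimension, fit on the training
split only — RBF kernels are scale-sensitive and conv activations
heavy-tailed.  Internally the grid reuses one precomputed
squared-distance matrix per repetition, so the search costs little even
at 64k dimensions; `kernlab` solves the SVM on the precomputed kernel.

Metrics are accuracy, sensitivity (% of AD classified AD) and
specificity (% of HC classified HC), averaged over the 10 repetitions
with their *population* standard deviation (the repetitions are the
whole population of runs, not a sample).

Decision fusion combines experts by hard majority vote.  All reference
configurations use 3 or 9 experts, so odd counts are enforced instead of
inventing a tie rule.  Experts in a fusion run share the sampling plan
and the per-repetition CV fold seeds, so decisions align
subject-by-subject.  Per-expert grids are re-optimized independently
(whether the original nine-expert runs re-optimized per expert is
unstated).  Low-level fusion instead places the pressure, altitude and
velocity views into the three input channels of a single image and
trains one expert.

## The synthetic cohort

The clinical dataset this methodology was developed on is private, so
the package ships a generator whose defaults define the study
conditions for all quantitative tests:

* Archimedes spiral $r = 10\,\theta$, 4 turns, traversed at a mean
  angular speed of 1.5 rad/s perturbed by an Ornstein–Uhlenbeck process
  (relative SD 0.05 for HC, time constant 0.5 s), sampled at 125 Hz
  (about 17 s and 2100 samples per spiral);
* radial tremor $A\sin(2\pi f t + \varphi)$ with $f \sim U[4, 7]$ Hz —
  the classic action-tremor band — and $A = 0.5$ tablet units for HC;
* pressure: AR(1) (lag-1 correlation 0.98) around a mean of 600 device
  units drifting −2/s, marginal SD 60, clipped at 0; zero in air;
* altitude: AR(1) around 55° (SD 3°), clipped to $[0°, 90°]$; azimuth
  drifts 2°/s with a small random walk;
* in-air excursions: Poisson count (rate 0.5 per spiral for HC),
  uniform start angles, exponential durations (mean 0.25 s), angular
  speed inflated 2.5× while in air — in-air traces are faster than
  on-paper ones.  Excursions are placed without overlap (a two-sample
  pen-down cooldown separates them) so the realized run count equals
  the Poisson draw and calibration tests are exact.

The AD profile is the HC profile plus an effect size $\varepsilon \in
[0,1]$ times six deltas: tremor amplitude +2.5, speed jitter +0.20,
pressure mean −250, pressure SD +100, pen-up rate +2.5, altitude SD +5.
At $\varepsilon = 0$ the classes are generatively identical — the null
configuration used for calibration checks.  The magnitudes echo the
qualitative contrasts the method was designed around (lighter and more
irregular pressure, more and faster in-air excursions, less smooth
velocity); they are configuration, **not** claims about clinical AD.
What passing tests on this cohort demonstrate is that the pipeline
detects a planted dynamic contrast and is calibrated under the null —
not that it detects Alzheimer's disease; the generator has no notion of
hesitation strokes, micrographia, fatigue over the task, or
age-correlated covariates.

## Problem sizes used by the test suite

The acceptance tests run the complete pipeline (cohort 45 + 30, three
hybrid views, Conv3 features with seeded-random weights, full default
SVM grid, three-expert fusion) at effect sizes 0, 0.5 and 1.  The
primary cohort seed runs the full 10-repetition protocol at each effect
size; two replicate seeds use 5 repetitions each and enter the
effect-size monotonicity check through the three-seed average.  The
acceptance script (`scripts/acceptance.R`) re-runs the 10-repetition
protocol at all three effect sizes for its seed and reports fused
accuracy/sensitivity/specificity, the null and mid-effect accuracies,
and the Conv5/fc7 dimensions verified by forward-pass shape inspection.

## Known limitations

* Population min–max normalization follows the reference protocol but
  leaks test-set ranges; `scope = "train_only"` exists for leak-free
  variants and shifts results slightly.
* Kinematics at pen-state transitions are included (surface→air steps
  can produce large velocities); the alternative of excluding them is
  untested here.
* The rasterizer is not anti-aliased by design — gray encodes dynamics,
  so blending ink with background would corrupt the code.
* Seeded-random weights bound what the layer-comparison machinery can
  show: layer rankings under random weights do not transfer to
  pretrained ones.
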