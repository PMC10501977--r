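---
title: "Automated positioning quality control for knee radiographs"
author: "kneeqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated positioning quality control for knee radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeqc)
```

## The problem

Positioning quality control (QC) of knee radiographs asks whether an
anteroposterior (AP) or lateral (LAT) exposure was acquired in an acceptable
posture.  Three criteria are both clinically central and error-prone: the
overlap ratio of the fibular head with the tibia on the AP projection, the
same overlap ratio on the LAT projection, and the knee flexion angle on the
LAT projection.  Manual measurement is subjective and slow; kneeqc automates
it in two steps:

1. **Landmark detection.**  Nine labeled key points are localized by heatmap
   regression with a high-resolution multibranch convolutional network:
   A/B on the fibular diaphysis axis, C and D at the fibular-head extremes
   closest to and furthest from the tibia, E where the tibia edge crosses
   the fibular head, F/G on the femoral and H/I on the tibial diaphysis
   axis.  AP radiographs use A-E only; LAT radiographs use all nine.
2. **Geometric calculation.**  The landmarks are converted into the three
   criteria by exact planar geometry.

## The geometric model

Let $L_1$ be the line through A and B (the fibular shaft axis) and let
$S_C$, $S_D$, $S_E$ be the *signed* perpendicular distances of C, D, E from
$L_1$, with the sign fixed so that C's side is positive.  The overlap ratio
is

$$ r = \frac{S_C - S_E}{S_C - S_D}, $$

clamped to $[0, 1]$.  The signed convention merits a note: the definition
of $r$ is sometimes written as a two-branch case split depending on whether
E lies on C's side of $L_1$ or on the opposite side.  With signed distances
a single formula covers both branches — when E crosses to D's side, $S_E$
becomes negative and the ratio keeps growing continuously toward 1.  The
boundary behaviour is exact: $E = C$ gives $r = 0$ (the tibia edge just
reaches the fibular-head point nearest to it) and $E = D$ gives $r = 1$
(full overlap).  Clamping is recorded in a flag because a clamped value
means the annotation, not the formula, is suspect.

The flexion angle is the angle between the femoral shaft vector
$\mathbf{u} = F - G$ (pointing proximally) and the tibial shaft vector
$\mathbf{v} = I - H$ (pointing distally), in degrees.  A fully extended,
collinear limb reads 180 and flexion reduces the angle; the reported range
is $[0, 180]$ and the normalized value divides by 180.  Whether the
measurement should use directed shaft vectors or undirected lines is a
genuine modelling choice; we chose directed vectors because only they give
the stated 0-180 range a consistent meaning, and we fixed the orientation
convention (proximal femur, distal tibia) so that extension reads 180
rather than 0.

Degeneracy handling: points closer than $10^{-9}$ pixels cannot define a
line, and $|S_C - S_D| < 10^{-9}$ (a fibular head with no transverse width)
cannot define a ratio; both raise errors rather than returning arbitrary
numbers.  The tolerance is far below any annotation precision, so it only
catches genuinely degenerate input.  Coordinates everywhere are 0-based
pixel centers, `x` = column, `y` = row.

```{r geometry}
kps <- keypointSet(rbind(A = c(0, 0), B = c(0, 100), C = c(10, 50),
                         D = c(-6, 50), E = c(2, 50)), view = "AP")
computeQC(kps)
```

## Heatmap encoding, decoding and view identification

Targets for the detector are amplitude-1 isotropic Gaussians with
$\sigma = 2$ heatmap pixels, one channel per landmark in the fixed order
A-I, at a stated stride (input pixels per heatmap pixel; the network's
output stride is 4).  Channels of absent landmarks — F-I on AP images — are
identically zero regression targets rather than being masked out.  That
choice is what lets one network serve both projections: an AP image simply
produces four silent channels, and the projection is identified
automatically from the detected-landmark count.  We call a radiograph LAT
when at least 3 of the 4 LAT-only channels fire above the detection
threshold; requiring all 4 would misclassify a LAT image on a single missed
landmark, and 2 would flip on two spurious peaks.

Decoding takes the per-channel maximum activation: position = argmax x
stride, score = peak value, visible iff score reaches the threshold $\tau$
(default 0.1; the amplitude-1 convention makes peak height directly
interpretable).  Ties break deterministically to the smallest (row,
column).  Optional sub-pixel refinement fits a known-sigma Gaussian to the
log-activations over a window around the peak by weighted least squares
(weights = squared activations, so the separable-weight algebra makes the
fit exact on true Gaussian targets and well-behaved on noisy predicted
maps).  It is off by default — plain argmax matches the
maximum-activation definition — but the QC pipeline turns it on because
argmax quantization at stride 4 would otherwise dominate the landmark
error.

## The detector

The network follows the high-resolution design: a stem of two stride-2
3x3 convolutions brings the input to 1/4 resolution; four stages run
parallel branches at 1/4, 1/8, 1/16, 1/32 resolution with channel counts
C, 2C, 4C, 8C; each exchange block applies residual units per branch and
then fuses every branch into every other (chains of stride-2 3x3
convolutions downward, 1x1 convolution plus nearest-neighbour upsampling
upward, contributions summed); the head maps all branches to C channels,
upsamples to 1/4 resolution, concatenates and projects to 9 channels with
a 1x1 convolution.  The full-scale `reference` preset uses C = 32, input
short side 288, and 1/4/3 exchange blocks in stages 2-4.

Two departures from common practice are deliberate:

* **No pretraining.**  Weights are He-initialized from a seed; the package
  trains from scratch on synthetic phantoms.  Everything is plain
  double-precision R, so a fixed seed gives bit-identical runs on one CPU.
* **Instance normalization.**  Each convolution is followed by per-channel
  spatial standardization with learned scale and shift.  Normalization of
  some form is essential to train a deep fusion network with plain SGD;
  instance statistics (rather than batch statistics) keep every sample's
  forward pass independent, behave identically at training and inference
  time, and need no running averages.  Residual-branch and cross-branch
  normalization scales start small (0.1 / 0.5) so the identity path
  dominates early training.

Training minimizes the mean per-pixel squared error over all 9 channels
with SGD (momentum 0.9, weight decay $10^{-4}$ on convolution weights).
The reference schedule is 60 epochs at learning rate 0.002 with 10-fold
decays after epochs 50 and 56 and batch size 4, with two augmentations at
probability 0.5 each: a horizontal flip (x coordinates remapped; the nine
labels have no left/right pairs so none are swapped) and an intensity
inversion (value to 1 - value), our reading of "random inversions".
Averaging (not summing) the squared error over pixels is arbitrary but
fixes the meaning of the learning rate.

### The tiny preset and the scaled-down experiment

The `tiny` preset (C = 8, input 64, stride 4, exchange counts 1/2/2, 2
residual units per block) is the default test configuration: a single
forward pass takes about 35 ms on one CPU.  The standard capability
experiment trains it from scratch on 64 easy synthetic LAT phantoms
(overlap 0.2-0.8, flexion 120-175 degrees, noise sd 0.005-0.015, no blur
or occlusion; LAT is the projection on which all nine landmarks exist)
for 30 epochs and evaluates detection on 32 held-out phantoms from the
same distribution.  A second, short (10-epoch) run on a half-AP/half-LAT
set exercises the view-identification mechanism: AP images train the four
LAT-only channels toward zero, and after a few epochs the trained peak
heights separate the projections cleanly (LAT-only peaks above ~0.7 on
LAT images versus below ~0.2 on AP images in our runs).  For this scaled run we use learning
rate 0.4 with decays after epochs 26 and 29, batch size 1, and no
augmentation: the reference learning rate 0.002 is tuned for pretrained
weights at batch 4 over thousands of images and is far too small to move a
fresh 650k-parameter network in 30 short epochs, and flip/inversion
augmentation roughly doubles the task diversity of a 64-phantom set and
visibly underfits the 30-epoch budget (the phantom set already spans its
generative variation, which is what augmentation would otherwise supply).
The scaled schedule is the package's own choice and sits in one place
(`trainConfig`) for anyone who wants to vary it.  Detection on the
held-out set decodes with sub-pixel refinement at threshold tau = 0.3, the
operating point separating the trained detector's genuine LAT-only peaks
(>= 0.77 in our runs) from its spurious responses on AP images (<= 0.21).
Problem sizes (64/32 phantoms, 64x64 pixels, 30 epochs) keep the whole
experiment in the minutes range.

## The synthetic phantom generator

No patient radiographs ship with the package, so the generator stands in
for them.  Phantoms are deliberately stylized rather than anatomically
realistic: bones are bright capsules on a dark background (bone-bright
intensity convention, range [0, 1]) and the fibular head is an ellipse.
The fibular shaft axis, the head ellipse, and the tibia edge are laid out
analytically so that the generative overlap ratio and flexion angle are
recovered *exactly* by the geometry module — the tibia's near edge runs at
signed transverse distance $S_E = a_t(1 - 2r)$ from the fibular axis,
where $a_t$ is the head's transverse semi-axis.  This round-trip (ratio to
1e-6, angle to 1e-4 degrees, verified over 200 phantoms) is the
load-bearing property: it ties the generator, the landmark schema and the
geometry to each other.

Default conditions: 64x64 pixels (matching the tiny preset), head
semi-axis 5 px, fibular shaft 3 px wide, additive Gaussian noise sd 0.02,
blur sigma 0.6, landmarks kept at least 8 px inside the canvas (infeasible
layouts raise an error rather than silently clipping).  Corruption modes —
noise, blur, occlusion bands — are applied after landmark placement and so
never move the ground truth; occlusion emulates the overlying-structure
artifacts that make the fibular head ambiguous on real LAT radiographs.
Each case draws its parameters from one random stream derived from
(dataset seed, case index), so datasets are reproducible case by case.

What passing tests on phantoms do *not* show: robustness to real
anatomical variation (curved fibular heads, osteophytes), real radiographic
texture, exposure differences between centers, or annotation ambiguity
along the diaphyseal axes.  The package's accuracy numbers on phantoms are
a capability floor for the machinery, not a clinical validation.

## The evaluation stack

**Object keypoint similarity.**  OKS compares a detection to ground truth
as $\mathrm{OKS} = \sum_i \exp(-d_i^2 / 2 s^2 k_i^2) \, [v_i > 0] /
\sum_i [v_i > 0]$, where $s^2$ is the area of the smallest axis-aligned
bounding box containing the visible ground-truth landmarks and
$k_i = 2\sigma_i$ with per-label $\sigma$ = 0.083 for the diaphyseal
landmarks (whose position along the shaft is not unique) and 0.029 for the
tightly defined head landmarks C, D, E.  A visible ground-truth landmark
with no detection contributes 0.  Detection AP/AR rank the per-image
detections by confidence (mean decoded peak score — the ranking score is a
package choice, as is the 101-point COCO-style interpolation of the
precision-recall curve); AP50/AP75 sit at OKS thresholds 0.50/0.75 and
mAP/mAR average thresholds 0.50 to 0.95 in steps of 0.05.

**Agreement.**  Human-machine agreement uses ICC(2,1) — two-way random
effects, absolute agreement, single rater — computed from the two-way
ANOVA mean squares, with the F-based McGraw-Wong 95% confidence interval
(the CI method is a package choice; the interval is exact under the
random-effects model).  Deviation statistics report mean, sample SD and
maximum of absolute deviations, with angle statistics additionally divided
by 180 and rounded to 3 decimals so ratio and angle criteria are
comparable.  Group comparisons use the pooled-variance (Student) t test,
the plain reading of an "independent-samples t test".

```{r icc}
set.seed(1)
truth <- runif(40, 0.2, 0.8)
clin <- truth + rnorm(40, 0, 0.03)
model <- truth + rnorm(40, 0, 0.03)
icc21(cbind(clin, model))[c("estimate", "ci")]
```

## Numerical choices and degenerate inputs

* Coincident-point tolerance $10^{-9}$ px; degenerate geometry raises
  errors, never silent NA.
* The overlap ratio is clamped to [0, 1] with a logged flag.
* Heatmap decode ties break lexicographically by (row, column).
* Sub-pixel refinement clamps its offset to one cell and falls back to
  plain argmax when neighbour activations are non-positive.
* Images are zero-padded to a multiple of 32 before the forward pass (the
  deepest branch stride) and heatmaps cropped back.
* ICC with zero error *and* zero rater variance returns CI (1, 1); zero
  total variance is an error.
* `detectionMetrics` treats images without a detection as false negatives
  at every threshold.

## Known limitations

* The detector trains on stylized phantoms; no claim is made about real
  radiographs without retraining and revalidation.
* DICOM reading is out of scope (no DICOM reader is available to the
  package); convert to 16-bit PNG first.  CLAHE parameters follow the
  EBImage convention.
* The full-scale `reference` preset (C = 32, input 288) is provided and
  exercised for shape/parameter contracts, but the package's tests train
  only the tiny preset; reproducing clinical-cohort agreement values
  requires real annotated radiographs.
* Only the three positioning criteria are computed; femoral-condyle
  overlap, patella position, condyle symmetry, joint-space centering and
  image-quality metrics (noise, sharpness, artifacts) are not modelled.
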