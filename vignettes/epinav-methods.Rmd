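---
title: "Quantifying epidermal macrophage behavior with epinav: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epidermal macrophage behavior with epinav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinav)
```

# Scope

Langerhans cells — the tissue-resident macrophages of the epidermis — survey
the skin with long dynamic dendrites, engulf debris after keratinocyte
damage, and migrate through a densely packed epithelium toward wounds,
steering around obstacle keratinocyte nuclei. `epinav` implements the image
quantification used to measure these behaviors in calibrated 2D
multi-channel time-lapse microscopy: cell segmentation and skeleton-based
dendrite morphometry, Sholl profiles, linear-assignment tracking with
motility metrics, front–rear reporter polarity by mask bisection,
wound-margin counting, MTOC-led obstacle-navigation scoring, and
debris-engulfment modality classification. Because no raw imaging data are
redistributed with the package, a seeded synthetic-scene generator with
exact ground truth stands in for the microscope, and every analysis stage
is validated against it.

All physical quantities are micrometres and seconds. Images are matrices
indexed (row, column), row 1 at the top; the centre of pixel $(r, c)$ sits
at $x = (c - 0.5)\,p$, $y = (r - 0.5)\,p$ for pixel size $p$.

# The synthetic scene model

`generateScene()` separates trajectory simulation (cheap, exact ground
truth) from pixel rendering (optional, streamable frame by frame via
`renderSceneFrame()`).

**Cells.** Each cell is a soma disk (radius 5 µm by default) with 3–10
straight, tapering dendrites whose count and length are drawn from
configurable $(\mu, \sigma)$ pairs (defaults $5 \pm 1$ dendrites of
$12 \pm 3$ µm; $\sigma = 0$ forces the mean exactly). Each dendrite carries
microtubule (EMTB) signal with probability `emtb_positive_p` (default 0.7,
inside the reported per-cell range). One bright perinuclear MTOC focus is
rendered as a Gaussian spot in the EMTB channel and is always the per-cell
intensity maximum, matching the identification rule of the assay
(brightest EMTB focus per cell).

**Kinematics.** Per-frame step lengths are gamma distributed with mean
equal to speed × frame interval (coefficient of variation 0.25, giving
near-Gaussian speed histograms). Everything contextual — persistence,
wound-directed bias, obstacle avoidance, neighbor repulsion, MTOC tethering
near the nucleus, and homing toward debris — modulates only the step
*direction*. This makes realized mean per-step speeds equal the configured
speeds by construction, which is what the speed-recovery studies rely on.
Defaults: cell centroid 1.0 µm/min; MTOC 1.4 µm/min at steady state rising
to 1.8 µm/min for cells within the response radius of an ablation — the
speeds reported for this system.

**Obstacles and navigation.** Static keratinocyte nuclei (radius 4 µm) are
scattered at `obstacle_density_per_100um2`. In scratch-wound scenes a
migrating cell whose MTOC comes within 5 µm of an obstacle boundary, with
the obstacle ahead along the wound axis, opens a passage event: the cell
pauses, then with probability `navigation_success_p` (vehicle 0.76) its
MTOC moves past the obstacle so that the encounter-to-pass duration equals
a draw from `navigation_pause_s` (vehicle $675 \pm 135$ s; paclitaxel
$2175 \pm 435$ s), with the MTOC leading the nucleus with probability
`mtoc_first_p` (0.84) and the other structure offset by a fixed 90 s.
Failed passages hold position for the 55-minute observation window and then
reroute. The pause parameter is defined as the *MTOC's* encounter-to-pass
time regardless of which structure leads, so its distribution is exactly
what the navigation-time scorer should recover.

**Wound and phenotypes.** The scratch is a polygon whose area closes
linearly at `closure_rate_per_h`. End-of-movie phenotypes are drawn per
cell (vehicle defaults: 20% engulfing, 4.7% stretching); engulfing cells
start within reach of the wound, chemotax strongly, enter it and round up
(dendrites retract), stretching cells halt just outside and extend one
dendrite across the outline, and all other cells hold a standoff beyond
their own dendrite reach so that their tips never cross the outline. These
placement and choreography rules reflect that the cells scored at a wound
margin in the assay are, by selection, the ones that reached it.

**Ablation and engulfment.** A laser-ablation event creates debris at a
given site and frame, or — when the site is omitted — at a point 10–14 µm
from a cell, mirroring the protocol of ablating keratinocytes one cell
diameter away. The responding cell draws a modality
(`modality_dendritic_p`, vehicle 0.825): *dendritic* events keep the soma
in place and extend the nearest dendrite to the debris; *motility* events
migrate the whole cell to within 2 µm before engulfing at the cell body.
The MTOC homes to the debris in either case. Engulfment succeeds with
probability `engulf_success_p` 12 frames after first contact.

**Forced outcomes.** Any probability slot accepts a logical vector
instead; the generator then realizes exactly those outcomes, in order, by
routing cells to per-cell assigned obstacles or debris and suppressing
incidental events. This removes sampling noise from worked examples (for
instance a run constructed to contain exactly 21 MTOC-first and 4
nucleus-first passages).

**Noise and rendering.** Signal plus constant background passes through
Poisson shot noise (at `poisson_scale` photons per camera unit) and
additive Gaussian read noise. Dendrites taper geometrically (half-width
1.0 → 0.45 µm) with a mild intensity taper (150 → 120 camera units), a
near-flat-topped profile chosen so that thresholding recovers the drawn
footprint closely. Default calibration is 0.5 µm/pixel and 30 s/frame;
both are configuration fields, never constants inside any metric.

# Analysis conventions

**Segmentation.** Otsu per frame by default (the acquisition protocol says
only that cells were thresholded, so the method is an enum), connected
components above `min_area_um2`, labels ordered deterministically by
bounding-box (top, left).

**Dendrites.** The soma is the maximal inscribed disk of the mask (via the
distance transform, dilated 1 px). The mask skeleton comes from Zhang–Suen
thinning; skeleton pixels inside the soma are removed and each remaining
piece attached to the soma is traced root-to-tip over an 8-connected graph
with Euclidean weights. Per root, the longest geodesic is the primary
dendrite; other endpoints count separately only when their private branch
exceeds 2 µm (figures show mostly unbranched primary dendrites, so
root-to-tip paths dominate). Lengths are polyline arc length, decimated
every 3 px to suppress pixel-staircase inflation, measured from the soma
boundary, with the thinning-eroded tip recovered by marching a small fan
of directions from the endpoint to the mask boundary and pulling back by
the local half-width. On noise-free scenes the test suite checks that
drawn arm lengths are recovered within 10%; thinning-induced error is
largest for diagonally oriented arms. A dendrite is EMTB-positive when
mean EMTB / mean
cytosol over the 1-px-dilated path neighborhood strictly exceeds 0.5.

**Sholl.** Circles step by 10 µm from the soma centroid (the protocol
leaves the centre to the operator; the inscribed-disk centre is the
deterministic stand-in). Crossings are counted analytically by solving
each polyline segment against each circle, which a dense-resampling oracle
confirms in the tests. Profiles sum five timepoints, chosen evenly spaced
(the selection rule was not specified; even spacing is recorded in the
output metadata).

**Tracking.** Frame-to-frame linking minimizes total squared displacement
by a shortest-augmenting-path assignment over the standard augmented
matrix with birth/death alternatives priced at `max_link_um`² (default
10 µm), then gap closing bridges up to `max_gap = 2` missed frames. The
solver is oracle-tested against exhaustive permutations. MTOC detection
median-filters the EMTB channel (3 px), takes the per-cell maximum — or,
without masks, thresholds bright foci at half the frame maximum — and
localizes each focus by an intensity-weighted centroid for sub-pixel
accuracy; without it, 0.5 µm quantization would bias per-step speeds of
0.7 µm steps upward noticeably.

**Motility.** Total distance, displacement, and meandering index
(displacement / total distance; 0/0 defined as 0 and flagged) per track;
tracks displacing under 10 µm are flagged excluded, as in the assay.
Speeds are per-step, unsmoothed, from centroids.

**Polarity.** The mask is bisected through its centroid perpendicular to
the motion vector, computed over a centred 3-frame window (the acquisition
description says only "bisected"; the windowed-motion axis is the declared
convention for curved paths). On-line pixels go to the leading half —
deterministic, and well under 1% of pixels at realistic sizes. The summary
is the mean of per-frame trailing means over the mean of per-frame leading
means.

**Wound analysis.** The margin rectangle is exactly 150 µm × 1.2 × wound
length, centred on the wound centroid along its principal axis (the class
validity enforces the formula); a circular outline takes the x-axis by a
documented tie rule and is flagged. Cells count when strictly more than
50% of their area is inside; series normalize to the first timepoint.
"Rounded, phagocytic" is operationalized as circularity $4\pi A/P^2 >
0.6$ (scored by eye in the assay; the threshold is a parameter).

**Navigation scoring.** A structure passes when its projection on the
approach axis exceeds the obstacle centroid projection plus radius
(passage was scored by eye; the axial rule is the declared surrogate).
Ties at the same frame score MTOC-first. Success requires an MTOC pass
within 55 minutes of encounter; observations shorter than the window are
*censored* and excluded from rate denominators — a category the original
scoring implied by requiring at least a 55-minute observation. Summaries
are per event; per-cell reductions are available through the `cell`
column.

**Engulfment modality.** The qualitative distinction (reaching with one
dendrite versus repositioning the whole cell) is operationalized as:
*motility* when the centroid closes more than 50% of its initial distance
to the debris between ablation and engulfment, else *dendritic*. The
threshold is a parameter; it is a surrogate convention, not the original
authors' rule.

**Statistics.** Group comparisons delegate to the standard
implementations (Mann–Whitney, Fisher's exact on raw counts, chi-squared,
Kolmogorov–Smirnov, one- and two-way ANOVA with Bonferroni-adjusted
pairwise tests); significance stars at 0.05/0.01/0.001/0.0001 are
cosmetic output only.

# Condition presets

`conditionPreset()` encodes the drug effects in their observed directions:

* **nocodazole** (microtubule depolymerization): fewer (3 ± 0.8) but longer
  (18 ± 4 µm) dendrites; faster (1.5 µm/min) but less directed migration
  (persistence 0.5, wound bias 0.25, hence lower meandering index and
  fewer cells reaching the margin); trailing-edge actin enrichment
  (polarity ratio 1.5); more motility-based engulfment
  (`modality_dendritic_p` 0.45) and lower engulfment success (0.6).
* **paclitaxel** (stabilization): morphology and speeds unchanged;
  navigation success drops to 0.23 and successful passages slow to
  2175 ± 435 s.
* **noc_rocki** (nocodazole + ROCK inhibitor): as nocodazole but with the
  polarity ratio restored to 1.0, reproducing the rescue of actin
  distribution.
* **vehicle** equals the documented defaults.

Where the quantitative magnitude behind a direction is unpublished (the
nocodazole motility-modality fraction, engulfment success rates, closure
rate, obstacle density), the preset value is a single realistic choice
documented here and never revisited by the tests.

# What passing tests do and do not show

The generator draws straight dendrites, circular somata, piecewise-simple
kinematics, static circular obstacles and a linearly closing polygonal
wound. Passing recovery tests therefore demonstrates that the measurement
code is correct *given* geometry of this kind — it does not demonstrate
robustness to real-tissue complications such as curved or branching
dendrites in contact between neighboring cells, intensity heterogeneity,
focus drift, segmentation merge/split events, or wound outlines that
change topology. Engulfment events on real data would additionally require
a phagosome marker; here they are ground-truth records, and on real images
they would be annotation-driven.

# Problem sizes and numerical choices

The validation studies use, as the package's own choices: 50 MTOC tracks
of 500 frames (five scenes of ten cells, 120 µm square at 0.5 µm/pixel)
for steady-state speed recovery; the same layout restricted to a 5-minute
post-ablation window for the stimulated speed; 120 forced-success passages
for navigation-time recovery; 5000 Bernoulli events for the success rate;
and scenes of 8–25 cells for the directional contrasts. Tolerances in the
tests mirror the generator's statistical precision at those sizes (10% for
stochastic recoveries, 2 percentage points at n = 5000, exact equality for
forced counts). Degenerate inputs are defined rather than rejected
wherever a convention is defensible: empty frames segment to empty lists,
zero-length paths have meandering index 0 (flagged), zero initial target
distances normalize by a 0.1 µm floor (flagged), a zero first-frame margin
count normalizes by 1 (flagged), and an all-equal speed sample returns its
mean with a flagged non-fit.

# Known limitations

2D only, matching the analyzed single slices/projections; no track
merging/splitting; no Kalman prediction; no Strahler branch ordering; no
sub-pixel skeletonization; the navigation scorer assumes static obstacles;
and the pipeline's wound axis requires either a wound outline or an
explicit approach axis for steady-state scenes.
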