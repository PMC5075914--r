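---
title: "Distance-banded quantification of peri-implant tissue response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-banded quantification of peri-implant tissue response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaband)
```

# The measurement problem

Chronically implanted cortical microelectrodes provoke a foreign-body
response: astrocytes proliferate and up-regulate GFAP, encapsulating the
device in a glial scar, while neurons within the first tens of micrometres
die or retract. Both effects degrade recordings and both are graded with
distance from the device, so the natural quantification is a *profile*:
a stain measurement as a function of distance from the track void the
explanted device leaves in the section, compared across the implant's
surface types.

`gliaband` implements this profile analysis as a deterministic pipeline:

* the manually drawn track outline, a simple polygon with one surface
  label per edge, defines distance zero;
* a Euclidean distance transform on the rasterized outline bins tissue
  pixels into 50 µm bands out to 500 µm (half-open intervals
  `[k·50, (k+1)·50)`, ten bands);
* each banded pixel takes the surface label of its nearest polygon edge;
* per (band, face), mean GFAP intensity and NeuN-nucleus density are
  normalized to the 400–500 µm zone of the same face;
* the four surface groups are compared per band with a tie-corrected
  Kruskal–Wallis test and Dunn–Bonferroni post-hoc pairs at α = 0.05.

# Geometric conventions

Pixel centres sit at `(i + 0.5)·pixel_size` with the origin at the
top-left corner and y pointing down; all distances are in micrometres.
The distance of an exterior pixel is measured centre-to-centre to the
nearest track pixel (`EBImage::distmap`), which has an exact brute-force
oracle and matches the dilation-band construction used in common
ImageJ-style workflows. Band intervals are half-open on the right so
bands are disjoint and exhaustive; the outer limit (500 µm) is excluded.
Pixels inside the track are coded −1, pixels beyond the limit or outside
the analysis mask are excluded (`NA`), and the three classes partition
the image exactly — an invariant asserted throughout the test suite.

Face assignment automates what is otherwise a manual per-side ROI choice:
each pixel takes the label of the nearest polygon edge
(point-to-segment distance), with exact ties — pixels on a corner
bisector — resolved to the lowest edge index. Ties are detected with a
relative tolerance of 1e-9 on the distance so the rule is deterministic
under floating-point evaluation. Per-pixel face masks can be supplied
instead by editing the band map, but nearest-edge is the reproducible
default.

Sections flagged as damaged (massive tissue damage or fissures around the
track) are loaded, reported in the exclusion table, and excluded from all
analysis. The flag is always supplied by the annotator, never inferred
from the image: that judgement belongs to the histologist.

# Profiles and normalization

Intensity profiles are arithmetic means of pixel values per (band, face)
region. Stain polarity matters: bright-field DAB material is dark-on-light,
so `polarity = "invert"` maps the image to `max − I` before measurement;
fluorescence-like (and the default synthetic) material is measured as-is.
All downstream results are invariant to positive affine rescaling of the
image after normalization.

Density profiles count annotated nuclei per region and divide by the
region's analyzable area, `n_pixels · pixel_size² · 10⁻⁶` mm². A point is
assigned the band and face of the *pixel containing it*, so counts and
areas share one discretization and the density estimator is unbiased for
the in-region intensity of the point process. Points that fall in the
track, beyond 500 µm, or outside the layer mask are tallied as
*unassigned* and reported — never silently dropped; the counts plus the
tally always equal the number of detections.

Normalization divides each band's raw value by the face's own background
— the pooled 400–500 µm zone, treated as unaffected tissue. Per-face
normalization is the default because it removes face-level illumination
and staining gradients; `normalize = "global"` pools one background per
section instead, and the choice is recorded in the profile metadata and
the provenance record. A profile whose background zone has no analyzable
pixels (or non-positive signal) is flagged non-normalizable and excluded
from aggregation with a warning, since every normalized number would be
meaningless.

Bands emptied by the layer mask are reported `missing`, not zero: a zero
would masquerade as a measured absence.

# Statistics

Profile values are typically non-normal (ratios of means and of Poisson
counts), which is why the group comparison is rank-based throughout;
Shapiro–Wilk normality tests are computed per group per band and
reported, but gate nothing.

The Kruskal–Wallis statistic uses mid-ranks and the standard tie
correction `1 − Σ(t³−t)/(N³−N)`; if every pooled value is identical the
statistic is defined as 0 with p = 1. The p-value comes from the χ²
approximation with k−1 degrees of freedom — the convention of standard
statistical packages — and for pooled samples of at most 8 observations an
exact permutation p over all distinct group assignments is computed
alongside. Dunn's post-hoc z uses the mean-rank difference with the usual
tie-corrected variance, and Bonferroni adjustment multiplies raw p-values
by the number of pairs (6 for four groups), capped at 1.

Two design choices mirror the per-distance study design and are recorded
as limitations:

* **No across-band multiplicity correction by default.** Each band is
  tested at α = 0.05 independently. `across_band_bonferroni = TRUE`
  provides a conservative sensitivity variant. The consequence is a
  non-trivial probability — roughly `1 − (1 − q)⁹` with q ≈ 0.02–0.03 the
  per-band family-wise rate of the gated post-hoc battery — of at least
  one falsely significant pair somewhere among nine null bands; the
  power simulations in the acceptance suite measure exactly this.
* **The sampling unit is one (section, face) value per band.** Sections
  from one animal are treated as independent; animal-level clustering is
  not modelled.

# The synthetic-data generator

Because real sections carry no ground truth, validation runs on synthetic
material whose truth is analytic.

**Gliosis field.** Expected GFAP intensity at distance d on face f is
`background · (1 + A_f · e^{−d/τ})` plus iid Gaussian pixel noise.
Defaults: background 100 (arbitrary stain units), τ = 100 µm, noise SD 5,
amplitudes `A = 1` for all faces except the nanostructured one
(`A = 0.85`) — a strong scar at the interface, a few-percent side
difference at intermediate distances, and a profile flat to ~1 % beyond
400 µm. The exponential decay is a *modelling choice* to make recovery
testable, not a claim about real tissue; the analysis never assumes it.
The track void renders at the background level. Both stain polarities are
supported and the choice is recorded.

**Neuron field.** Nuclei are an inhomogeneous Poisson process with
intensity `baseline · (1 − B_f · g(d))` outside the track and zero inside,
realized by thinning a homogeneous draw (rejection inside the polygon
preserves the Poisson property). `g` is exponential with a 75 µm scale by
default — neuronal loss concentrated in the first 50–100 µm — or a step
confined to `d < depletion_length` (`depletion_shape = "step"`), which
expresses band-limited effects for power studies. Defaults: baseline
1000 neurons/mm² (a plausible single-layer areal density in sections),
depletion fractions 0.85/0.75/0.7/0.5 (worst at the fluorocarbon-polymer
face, mildest at the nanostructured face). Accepted nuclei render as
Gaussian spots (SD 2 µm, nominal radius 4 µm).

**Truth profiles** are the analytic models averaged over the pixel
centres of each (band, face) region — independent of the rendered noise
and of any particular point draw, but sharing the analysis
discretization, so recovery tests measure estimation error rather than
rasterization differences. Distances in the analytic models are exact
polygon-boundary distances.

**Height maps** come in four forms: flat and tilted planes and sinusoids
with analytically known area ratios (the sinusoid's by 1-D quadrature of
its surface integrand), and pillar fields — Gaussian apexes with heights
drawn from 520–800 nm at ~18–70 pillars/µm², placed on a jittered lattice
by default, since self-organized etched nanopillar fields are
quasi-regular and a pure Poisson placement at realistic densities would
merge apexes below any detector's resolution.

What the generator does *not* emulate: microglia, vasculature, bleeding,
tissue tearing, section-to-section registration, uneven illumination, or
staining artefacts. Passing on synthetic material therefore demonstrates
the correctness of the measurement chain, not robustness to real-world
artefacts — which is also why manual nucleus annotations remain the
primary input and automated detection is a convenience for clean images.

# Surface morphology

Area-ratio roughness triangulates each height-map quad into two triangles
along a fixed diagonal and divides the summed 3-D area by the projected
area; the fixed diagonal keeps results deterministic and differs from the
opposite choice by well under 0.1 % on smooth surfaces. The ratio is ≥ 1,
exactly 1 for horizontal planes, and invariant to height offsets.

Pillar density counts local maxima above a relative threshold (default:
20 % of the height range) with non-maximum suppression at 3 grid steps,
normalized to the analyzed area in µm². Pillar height converts annotated
base-to-tip segments on tilted cross-sections by an *explicit*
multiplicative correction factor, recorded in the output; the geometric
conversion from a stage tilt to true height depends on the imaging
convention, so the factor is exposed rather than guessed (factor 1
corresponds to a pure side view).

# Numerical and degenerate-input choices

* Band width must be positive and no larger than the outer limit; the
  background zone must align to whole bands within range.
* Empty track masks, zero-area or self-intersecting polygons, unlabeled
  edges, dimension mismatches, constant samples (Shapiro–Wilk), n < 3
  groups (Dunn), and zero-length height segments raise immediate errors.
* Bands with fewer than two non-missing groups are reported untestable
  rather than tested vacuously.
* All generators consume a single integer seed through a local RNG stream
  that leaves the caller's RNG state untouched; identical configuration
  and seed reproduce every image, point set and CSV byte for byte.

# Problem sizes used in validation

The test and acceptance suites run at sizes chosen to exercise the full
geometry while keeping a complete run in minutes: synthetic sections at
4 µm/px (≈ 355 × 305 px, full 500 µm band range), 1 µm/px for
detection-fidelity checks, 20-section cohorts for profile recovery,
10-seed cohorts for density recovery, 100 random small instances for the
exhaustive geometry oracle, 1000–2000 replicates for test-calibration
simulations, and 200 replicates of 12-section cohorts for the band-0
effect-detection power study. Statistical calibration uses the study's
group sizes (132/66/31/35).

# Known limitations

* Nearest-edge face assignment differs from a human's side selection in
  the corner wedges, where attribution is genuinely ambiguous.
* Per-band testing without across-band correction trades specificity for
  sensitivity by design; users scanning many bands should consult the
  `across_band_bonferroni` variant.
* Animal-level clustering is not modelled in the statistics.
* The nucleus detector is validated on rendered Gaussian spots; on real
  bright-field material with artefacts, manual counts should be used.
* 16-bit TIFF export quantizes intensities to ~1.5 × 10⁻⁵ relative
  precision; the recorded scale restores units on read.
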