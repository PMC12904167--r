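---
title: "Quantifying sarcomere transverse splitting, Z-line disarray and NSP hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomere transverse splitting, Z-line disarray and NSP hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question and the measurements

Skeletal muscle fibers grow longitudinally by adding sarcomeres in
series.  A leading structural hypothesis is that new in-series sarcomeres
arise by transverse splitting of pre-existing sarcomeres: a Z-line forks
across the fiber width, so that one lateral side of the fork carries one
more in-series sarcomere than the other.  Regions rich in such splits
show *disarray* — locally misaligned Z-lines — and, if they are sites of
active sarcomere assembly, they should be enriched in newly synthesized
proteins (NSPs, visualized by click-chemistry labelling of an
azide-bearing methionine analog).

`sarcsplit` implements the image-quantification side of this program as
a reusable, tested pipeline:

1. **Continuous Z-line length** (`zline_analysis()`): a disarray
   statistic.  Z-lines are segmented, thinned to a skeleton, and traced
   into orientation-coherent segments; misalignment breaks traces, so
   the mean segment length drops where splitting is frequent.
2. **Net transverse-split counts** (`splits_per_fiber()`): an A-band
   (inter-Z-line gap) is traced across the full fiber width; each fork
   of a bounding Z-line is an event, and the net count
   |bifurcations − merges| is normalized to splits per 10 µm of width.
3. **NSP hotspot detection** (`find_hotspots()`): loci at least
   2.0-fold above the *local* background with transverse dimensions
   consistent with a sarcomere (400–1900 nm) qualify; fibers with ≥ 2
   qualifying hotspots are called hotspot-positive.
4. **Hotspot morphology classification** (`hotspot_morphology()`):
   each qualifying hotspot's axial span, in units of the local sarcomere
   length, and the registration of its boundaries to the flanking
   Z-lines decide which sarcomerogenesis model it matches.
5. **Single-fiber morphometry and statistics**
   (`serial_sarcomere_number()`, `compare_groups()`): fiber length over
   mean sarcomere length gives the serial sarcomere number, the readout
   of longitudinal growth, analyzed with the study-style statistical
   toolkit (3-SD outlier rule, relative-to-control normalization,
   t tests, one/two-way ANOVA with Tukey or Fisher-LSD post hocs).

Because no real micrographs ship with the package, module 0 is a
**synthetic fiber generator** (`render_fiber()`, `simulate_cohort()`)
that renders two-channel striated-fiber images with *exact planted
ground truth* — the oracle for every recovery test in the suite.

## The synthetic fiber model

A fiber is a straight horizontal band of width `width_um` (default
24 µm) in a raster of pitch 0.103 µm/px (back-computed from the
200 px ≡ 20.6 µm ROI convention of high-magnification muscle imaging).
Channel 0 renders each Z-line as a Gaussian ridge (σ = 0.15 µm) at
`zline_intensity` over an A-band plateau; channel 1 is a uniform NSP
background on which hotspots are painted as flat-topped rectangles at
`fold ×` background, so that the mean over the blob mask equals the
detection rule's operand exactly.

**Split geometry.**  A planted split forks one Z-line at a lateral
fraction *f*: for rows beyond *f* the parent line is replaced by two
daughters at ± SL/4 (SL = sarcomere length, default 2.4 µm — a stated
assumption for resting mouse plantaris fast fibers, configurable and
never hard-coded in analysis code).  The perturbation is confined to one
sarcomere length axially, and the in-series count on the far side is
exactly one higher, so the conservation law *count(row) = base + signed
splits crossed* holds by construction.  The fork is rendered as a sharp
lateral step rather than a gradual wedge: the analysis operates on the
fork's topology, not its curvature, and a sharp step keeps the planted
pixel geometry exact.

**Hotspot geometry per class.**  With Z-lines *z_i*: one-sarcomere
Z-to-Z blobs span [*z_i*, *z_{i+1}*]; two-sarcomere blobs
[*z_i*, *z_{i+2}*]; H-zone-splitting blobs span one sarcomere length
centered on a Z-line (the adjacent inner halves of two in-series
sarcomeres); short- and long-atypical blobs span < 2 and > 2 sarcomeres
without Z-registration.  Planted hotspots whose masks would 8-connect
are rejected so ground truth stays one-to-one — except under
`allow_contiguous = TRUE`, which exists precisely to study the known
ambiguity that two adjacent one-sarcomere events merge into a blob
indistinguishable from a two-sarcomere event.

**Degradation.**  `add_noise()` applies Gaussian PSF blur (default
σ = 0.2 µm, the scale of a deconvolved high-NA widefield system), then
Poisson shot noise and additive Gaussian read noise, all driven by the
spec's seed: identical seed and spec give bit-identical images.

**What the generator does *not* emulate** — and hence what passing
tests do and do not show: out-of-focus light and 3-D sectioning effects,
fiber curvature and tapering, intensity gradients along the fiber,
labelling heterogeneity, and sarcomere-length variation within a fiber.
Recovery rates measured here are upper bounds for real tissue; the
tests establish that the *algorithms* are correct and calibrated, not
that real-image performance will match.

## Algorithmic choices and tunable parameters

**Z-line segmentation** is difference-of-Gaussians ridge enhancement
(fine σ = 1 px against a broad σ of half a sarcomere, the ridge scale)
followed by Otsu thresholding; the dominant striation direction is
estimated from directional gradient energy, which makes the result
equivariant under 90° rotation.  An external MATLAB program popularized
this statistic; it is re-specified here rather than wrapped, because the
scientific content is the statistic (continuous length under
misalignment), not any particular implementation's bit pattern.

**Tracing** uses run-center thinning (one skeleton pixel per mask run
across the ridge), then walks 8-connected paths gated by local
orientation: a step is allowed when the PCA-derived local orientations
of consecutive pixels differ by at most `theta_max` (default 20°, chosen
to break at split-induced kinks while tolerating PSF wobble).  Branch
points always terminate lines — a fork is by construction a
discontinuity.  Ties between admissible continuations go to the smaller
orientation change, deterministically.  Lines shorter than 3 px are kept
(they legitimately depress the mean in disarrayed regions); a
`min_length_um` floor exists for noisy real data but defaults to 0.
The mean is unweighted over lines by default; `weighting = "length"`
(Σl²/Σl) is provided because either reading of "average continuous
Z-line length" is defensible.

**A-band tracing** follows per-row Z-line crossings.  Boundary matching
uses a tolerance of 0.3 SL; fork detection compares candidates against
the boundary position three rows back (tolerance 0.35 SL), because under
PSF blur the two daughters emerge gradually and row-to-row matching
alone would let the boundary drift onto one daughter before the other
appears.  After any event, detection pauses for three rows while the
reference history refills.  A boundary with no candidate within
tolerance is re-matched within 0.7 SL as a merge (the merged line sits
half a sarcomere away).  Event signs are defined by the in-series count
on the higher-lateral side, which makes the net count invariant to the
traverse direction.

**Local background** for hotspot detection is a trimmed median: within
a 5 µm window (about two sarcomeres — large enough that a hotspot cannot
dominate it, small enough to track fiber-scale gradients) restricted to
the fiber mask, the brightest 10% of pixels are discarded and the median
of the rest is taken, evaluated on an 8 px grid and bilinearly
interpolated.

**Size gate.**  Qualification requires fold ≥ 2.0 (inclusive) and a
size of 400–1900 nm (inclusive).  The gated measure is the **minimum
Feret diameter** — the transverse width — because the 400–1900 nm range
describes sarcomere *diameters*, and morphologies spanning two or more
sarcomeres legitimately exceed 1900 nm axially; gating the whole-mask
equivalent diameter would discard exactly the multi-sarcomere classes
the morphology analysis exists to count.  The equivalent diameter is
computed and reported for every candidate and can be selected
(`size_measure = "equiv"`).  Candidate components are detected at a
lower threshold (1.5 × background) so that near-threshold blobs appear
in the output with reason codes instead of vanishing silently.

**Morphology tolerances.**  Span and registration tolerances default to
τ = 0.25 sarcomere — halfway between the ideal classes, making the three
model acceptance regions pairwise disjoint (any τ < 0.5 does).  The rule
order (one-sarcomere Z-registered → two-sarcomere Z-registered →
Z-centered) resolves the merged-adjacent-pair ambiguity in favour of the
two-sarcomere class, the same resolution the field applies.  Spans are
measured on the ≥ 2 × background mask (consistent with the detection
operand; for a blurred flat-topped blob of fold 3, the 2 × background
contour sits at the original boundary).  The axial footprint takes the
columns covered by at least half the blob's peak lateral thickness, so
single-row noise excursions cannot stretch the span.  Hotspots whose
local Z-line grid cannot be resolved (fewer than two peaks) are excluded
with a reason and never enter the mix denominator.

**Disarray classification of ROIs** reuses the module-1 statistic: an
ROI (10 × 10 µm, i.e. 100 µm²) is *disarrayed* when its mean continuous
Z-line length falls below `f` × the fiber-level median of ROI means,
with `f = 0.6` as default — motivated by the magnitude of disarray
reduction this kind of overload produces (tens of percent), while the
original classification in the field was visual.

**Statistics.**  Outliers are excluded once, per group, strictly beyond
3 sample SDs (a value at exactly 3.0 SD is retained); the rule is
deliberately not iterated, since re-application to retained values can
exclude more.  Two-way ANOVA uses Type-II sums of squares (the designs
of interest are unbalanced, 9–36 per group), computed through
`car::Anova` and cross-checked in the test suite against an
independently written projection-matrix oracle to 1 × 10⁻⁸.  Sarcomere
period estimation uses the first autocorrelation peak with parabolic
sub-pixel interpolation, because the length differences of interest
(< 5%) are sub-pixel at 0.103 µm/px.

## Study conditions baked into the generator defaults

`cohort_config()` fixes the emulated contrast once: a sham group with
0.05 bifurcations per interior Z-line and 0.35 expected hotspots per
fiber, and an overloaded group at 4.9 × the split density (0.245) and
2.0 hotspots per fiber — values chosen so that the emergent
hotspot-positive-fiber rates land near 5% and 60% and the split
fold-change near 4.9, the effect sizes this class of experiment
reports; cohorts default to 3 muscles per group with 30 fibers per
muscle, the sampling depth typical of single-fiber immunofluorescence
studies.
The hotspot class mixture plants 69.6% one-sarcomere, 17% two-sarcomere,
0.3% Z-centered, and 13% atypical (one-third short, two-thirds long)
morphologies.  Hotspots are planted before splits; splits then avoid the
registration neighbourhood of each hotspot so every planted morphology
is measurable against an unforked local Z-line grid.
`single_fiber_params()` plants a 7.5% overload effect on fiber length
at unchanged sarcomere length, identically in the vehicle and rapamycin
arms — the structural statement that longitudinal growth is
rapamycin-insensitive — with lognormal lengths (positivity at specified
CV; 10% for fiber length, 2% for sarcomere length, 30 fibers per arm).

## Numerical conventions and degenerate inputs

Coordinates in all outputs are 0-based (row, col) pixel indices with
pixel centers on the integer grid; CSV output is UTF-8, comma-separated,
with units in the column names.  A uniform raster segments to an empty
mask that is *flagged*, and downstream operations raise rather than
return 0.  An isolated skeleton pixel is a line of length 0.  A trace
that exits the fiber prematurely is flagged partial and its count
reported as a lower bound.  Gates are inclusive and compared with a
10⁻⁶ nm / 10⁻⁹ fold epsilon so that boundary values expressed in
non-representable floating point (e.g. 19 px × 0.1 µm) still pass.  A
fiber lacking either a normal or a disarrayed ROI is excluded from the
paired comparison, with a message.  All randomness flows from explicit
integer seeds; per-item seeds are derived from a root seed
(`derive_seeds()`), so any single fiber of a cohort can be regenerated
alone.

## Problem sizes used by the shipped checks

The test-suite and `scripts/acceptance.R` exercise: 20 ROIs per split
density for the monotonicity of the disarray statistic; 3 noise-free
fibers (120 A-bands) for exact oracle agreement plus 8 fibers per group
× 40 A-bands for the 4.9-fold recovery; 100 degraded images (300
hotspots) at SNR 5 for detection recall; 50 images per condition for
the 5-class confusion matrices; a 2-group × 3-muscle × 30-fiber cohort
for positive-fiber rates; and 2000 null replicates for the type-I error
of the generator → morphometry → t-test pipeline.  These sizes were chosen
as the smallest that make the binomial/Monte-Carlo error of each check
comfortably smaller than the property being asserted.

## Known limitations

* The tracer assumes striations roughly perpendicular to the fiber axis
  (axis-aligned or 90°-rotated rasters); arbitrarily oriented fibers
  should be rotated upstream, e.g. during ROI extraction.
* Merge-type events (sense −1) are supported and tested, but biological
  interpretation in a growth context focuses on bifurcations; the
  default cohorts plant bifurcations only.
* Hotspot lateral extent is recorded but not used in classification;
  whether partial-width hotspots should classify differently is an open
  question the data model leaves to the user.
* The 2-D analysis shares the plane-of-section blind spot of the assay
  it models: hotspots immediately above or below a disarrayed region are
  counted against the ROI class visible in the imaged plane.
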