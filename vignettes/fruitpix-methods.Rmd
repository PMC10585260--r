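---
title: "fruitpix: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fruitpix: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitpix)
```

This vignette is the package's own account of its model: what each stage
computes, the assumptions behind it, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## The measurement model

`fruitpix` treats a staged photograph as a classification problem over
pixels. Fruit sit on a uniform, contrasting background (a green cutting
board in the motivating blackberry work), and both "fruit vs background"
and "feature vs rest of fruit" are defined *by color alone*, as
conjunctions of per-channel intervals across three colorspaces:

* sRGB `R`, `G`, `B` on 0–255,
* HSB: hue in degrees `[0, 360)`, saturation and brightness in `[0, 1]`,
* CIELAB: `L*` in `[0, 100]`, opponent axes `a*` (green ← 0 → red) and
  `b*` (blue ← 0 → yellow).

A pixel passes a threshold iff it satisfies *every* configured interval;
channels not mentioned are unconstrained ("full range"). In practice a
single `a*` lower bound does most of the work for red-feature detection
on green backgrounds: board ≈ −33, black berry surface slightly
positive, reverted red ≈ +45. Bounds are strict (`>`) by default because
that is the convention in which published cutoffs such as `a* > 7.51`
are stated; inclusive bounds are available per interval. Hue is the one
channel where `min > max` is legal, denoting a wraparound interval such
as 350°–10°.

The headline feature quantity is a **pixel fraction**:
`100 · |feature| / |fruit|` percent. It is a pure ratio — independent of
calibration, resolution (to first order), and fruit count — and it
accounts naturally for partially affected drupelets, which per-drupelet
manual counts cannot.

### Colorimetry

CIELAB is computed as sRGB companding → linear RGB → XYZ → Lab under the
**D65/2° white point**, the native choice for sRGB-encoded photographs;
the source material for this kind of pipeline never states a working
illuminant, so the sRGB-native one is the only defensible default. The
reference white is taken as the row sums of the sRGB→XYZ matrix so that
pure white maps to exactly `L* = 100, a* = b* = 0`. Everything is
floating point; nothing is quantized to 8 bits internally. Rasters are
numeric `H × W × 3` arrays on the 0–255 scale and fractional values are
legal everywhere — this is deliberate, so that a color constructed from
an exact Lab triple round-trips to machine precision instead of being
truncated at the 8-bit grid (≈ 0.2 ΔE of quantization noise).

ImageJ expresses Lab on a 0–255 scale (`L·255/100`, `a+128`, `b+128`).
`lab_to_imagej_scale()` exposes the mapping, and `lab_scale: imagej` in
a configuration interprets Lab bounds on that scale, so threshold sets
tuned in ImageJ (e.g. fruit at `a > 110`, reverted at `a > 138`) port
directly.

## Preprocessing

Fixed order: **downsize → contrast normalization → enhancement**, then
exclusion-zone flagging.

* `downsize()` caps the maximum dimension at 1500 px (bilinear), the
  standard throughput/resolution compromise for desk-scale batches. The
  applied scale factor is recorded on the image because pixel
  calibrations are usually measured on the original.
* `normalize_contrast()` stretches to `[0, 255]` using the **joint**
  min/max over all three channels. Per-channel stretching would be a
  per-image white-balance shift: it changes hue, and therefore silently
  moves pixels across the very CIELAB thresholds the user calibrated.
  The joint stretch only rescales lightness/chroma.
* `enhance()` is a median filter (radius 1 by default) followed by an
  unsharp mask (`x + amount·(x − blur(x))`, Gaussian σ = 1). The
  published description of this stage names effects ("sharpened",
  "reduce noisy pixel values"), not algorithms, so the concrete
  operators and their strengths are this package's choice; both are
  individually disableable (`sharpen_amount: 0, denoise_radius: 0`)
  to mimic a pipeline with no pre-processing at all.

Cropped regions (typically the area around the size reference) are
flagged through an **exclusion mask** rather than removed geometrically,
so pixel coordinates remain comparable across every stage. Regions are
fractional, hence one region applies batch-wide across resolutions.

## Segmentation

`despeckle()` is morphological opening with a disc structuring element
(`dx² + dy² ≤ r²`; the shape of the "shrink and swell" element is not
pinned down by any published description, and a disc is the isotropic
choice). The mask is padded with background before the opening so border
behavior is unambiguous. Opening is anti-extensive and idempotent, and
any connected group that cannot survive the erosion — dust, juice
splatter, debris — vanishes entirely; large regions only get convex
corners rounded. Radii are configuration: default 2 for the fruit mask
and 1 for feature masks. The feature radius must stay below the
feature's own length scale (a drupelet disc radius is ≈ 4–8 px at
working resolution), otherwise the opening eats the features themselves.

Feature masks are computed as `threshold ∧ fruit`, despeckled, then
re-intersected with the fruit mask so the invariant **feature ⊆ fruit**
holds even at despeckle boundaries.

`label_objects()` produces **8-connected** components (diagonal contact
connects; connectivity is a convention choice, and 8 is the tolerant one
for berries touching at a corner pixel), filtered by a minimum area and
renumbered deterministically in row-major order of each component's
first pixel. Touching fruit are *not* split — no watershed — because
per-image aggregate traits are unaffected by merging; instead,
suspiciously large objects (> 2.5× the median object area) are flagged
`merged_suspect`, and objects clipped by the image border are flagged
`touches_border`.

## Measurement

* **Length** is the vertical image-axis extent of an object — the
  distance from its uppermost to its lowest detected pixel — *not* the
  major-axis (Feret) diameter. This follows the operational definition
  used in the motivating work and makes results orientation-dependent by
  design: fruit must be staged upright. A `length_mode: major_axis`
  option exists for unoriented material but is off by default.
* **Width** is the horizontal extent. No published operational
  definition exists for width in this pipeline family (the caliper
  definition — maximum equatorial distance — is not computable from a
  top-down mask), so the horizontal bounding-box extent is this
  package's documented choice.
* Extents are inclusive (`max − min + 1`), so a single-pixel object has
  size one pixel, not zero.
* **Area** is `n_pixels · (mm/px)²`.

Calibration is `mm_per_px = reference_length_mm / (reference_px ·
downsize_scale)`, taken from a single sample image and applied
batch-wide. The implicit assumption — fixed camera height across the
batch — is the user's to uphold; violations bias all sizes
proportionally.

The **color profile** reports, for the feature region, the pixels of
minimum and maximum luminance (CIE Y of linear RGB, ties broken
lexicographically) and the channel-wise median color, each matched to
the nearest entry of a named-color table by Euclidean ΔE in CIELAB. The
Royal Horticultural Society chart that practitioners quote is
proprietary and unpublished, so the bundled table
(`rhs_chart_synthetic.csv`) is a *synthetic approximation*: 37
representative anchors converted to Lab, carrying the one value that is
public — Greyed-Purple 185-A, `L*a*b = (34.4, 42.0, 12.7)`, the manual
scoring reference for reverted drupelets — verbatim. Supply your own CSV
(`name, L, a, b`) for faithful chart matching. A nearest-match distance
is reported with each name: distances under ~2 ΔE mean the name is a
good description, large distances mean the region's color is simply not
in the table.

## The synthetic validation scenes

`render_scene()` emulates what matters about the staged photographs and
nothing more: a green board, berries as filled dark ellipses carrying
hexagonally packed *reverted* drupelet discs, background debris specks,
and a reference bar of declared physical length. Two properties make it
a usable oracle:

* **Exactness.** With `anti_alias = FALSE`, every pixel is exactly one
  palette color and the truth masks coincide with the rendering
  pixel-for-pixel, so threshold-and-count recovery is *exact* (tested as
  identity, not approximation). With `anti_alias = TRUE` the scene is
  rendered at 3× and block-averaged, giving realistic blended boundary
  pixels; truth stays defined on the exact 1× geometry.
* **Palette discipline.** The default palette's a\* values straddle the
  cutoffs used in practice — board −32.9 < −12, berry body +5.3 inside
  (−8.5, 7.51), reverted +45.5 > 16.15 — asserted at render time
  (`validate_palette()`), so background-removal and detection behave on
  the scenes exactly as they would on the photographs those cutoffs were
  calibrated for.

`reverted_fraction` is the target *pixel* fraction: discs are added (in
seeded random order) until the red pixel budget `f · berry_area` is met,
with `f = 1` filling the berry entirely. Defining `f` over pixels rather
than over discs keeps the generator's dial on the same scale as the
quantity the instrument measures; a disc-count fraction would differ
from the measured value by the packing density (≈ 0.7) and make every
recovery statement awkward. The granularity of one disc (~50 px against
~12 000 px berries) bounds |truth − f| well under 0.01.

### Threshold calibration for the synthetic campaign

`scene_analysis_config()` disables pre-processing (the palette is
designed directly against the thresholds; a contrast stretch would move
the colors, exactly as re-white-balancing a calibrated chart would) and
sets the feature cutoff to the a\* of the **50/50 sRGB blend** of the
body and reverted colors (27.89 for the default palette). This mirrors
the per-campaign threshold calibration step any real deployment
performs on a sample image, and it is the *unbiased* choice at
boundaries: an anti-aliased edge pixel is counted as reverted exactly
when it is majority-covered. A cutoff much closer to the body color
(such as 16.15, calibrated for real berries whose "black" is darker and
whose boundary mixes differ) counts edge pixels as red from ~28%
coverage upward and overestimates the fraction by the perimeter/area
ratio of the discs — a real effect worth knowing about when porting
thresholds between imaging conditions.

### What the scenes do not model

Specular gloss (which masks reverted color in real photographs),
lighting gradients and white-balance drift, berry surface texture and
drupelet shading, soft shadows, lens distortion, and EXIF-rotated
inputs. Passing the synthetic validation therefore demonstrates that the
*computational* pipeline — thresholding, morphology, labeling,
calibration, accounting — is correct, not that any particular threshold
set is right for a given camera and crop; thresholds must still be
calibrated on representative photographs per campaign.

## Numerical and determinism choices

* Validation problem sizes: scenes are 440 × 330 px with three berries
  (~16 000 fruit pixels); the fraction-recovery sweep uses 100
  anti-aliased scenes (5 true fractions × 20 seeds) with the tolerance
  set at ±0.02 absolute, covering anti-aliasing and despeckle boundary
  effects; exactness claims (fraction, length, width) are tested as
  identities on aliased scenes with despeckling off, since opening may
  legitimately shave single boundary pixels even of large objects;
  oracle-equivalence suites run on 64 × 64 random masks against
  brute-force shift-AND morphology and flood-fill labeling.
* Analysis consumes no randomness anywhere: identical input and
  configuration give byte-identical CSV output. Seeds exist only in the
  scene generator, which saves and restores the caller's RNG state.
* Configurations are validated before any image is touched (unknown
  keys are rejected, listing all of them; size traits without a
  calibration fail upfront) and round-trip losslessly through YAML and
  through the JSON settings sidecar written next to every results file.
* Degenerate inputs have defined behavior: empty threshold specs accept
  everything with a warning; an empty segmentation yields a summary row
  with zero objects and a 0% feature fraction rather than an error;
  undecodable files become `decode_error` rows and the batch continues;
  constant images pass through contrast normalization unchanged.

## Known limitations

Touching fruit are measured merged (flagged, not split). Only the
camera-facing half of each fruit is measured, so surface fractions
underestimate whole-fruit severity — a protocol issue (image more
fruit), not a computational one. EXIF orientation tags are ignored; all
staged rigs produce consistently oriented images, but phone photographs
may need rotating beforehand. Width is a bounding-box quantity and will
disagree with caliper equatorial width on tilted fruit.
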