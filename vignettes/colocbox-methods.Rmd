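---
title: "Object-based colocalization analysis with colocbox: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based colocalization analysis with colocbox: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocbox)
```

## The problem

Multi-fluorescence imaging of dense tissue asks, cell by cell, *which
labels does each object carry*? Pixel-based colocalization coefficients
cannot answer this — they quantify per-pixel co-intensity, and they cannot
relate markers that live in different compartments (a nuclear transcription
factor versus a cytoplasmic tracer). Object-based colocalization analysis
(OBCA) instead identifies discrete objects (usually nuclei) and annotates
each with a *category string* — a sorted set of digits 1–8, so `"358"`
marks an object positive for categories 3, 5 and 8, and 8 category slots
span 2^8 = 256 combinations.

Two imaging artifacts corrupt naive OBCA on Z-stacks:

1. **Z-projection artifacts.** Two objects at the same XY location but
   different Z fuse in a maximum projection and masquerade as one
   double-labeled cell.
2. **Transection artifacts.** An object cut by a physical section face can
   lack the compartment carrying one of its labels, producing false
   negatives.

`colocbox` is a scriptable re-implementation of a semi-automatic OBCA
workflow built around these two problems: declarative *image elements*
render the raw channels into a colocalization-ready visualization, a
special Z-projection suppresses stacking artifacts at the object level,
point-based counting with category strings quantifies the result, and a
serial-section layer organizes, scores and reconstructs the data in 3D.

## Image elements

An *image element* is a declarative recipe turning one or more input
channels into a contribution to an output channel.

**Grayscale elements** are brightness-adjusted (linear rescale of a
`display_range` to [0, 1], clamped), optionally filtered, and multiplied by
a color. Multiple grayscale inputs mix additively with a saturating clamp —
this is deliberately *discouraged* (it reintroduces projection artifacts),
so multi-input specs log a warning. A *verification channel* is the
degenerate case: a single unfiltered white grayscale element in its own
output channel, reproducing the rescaled raw data for visual cross-checks.

**Binary elements** run the pipeline: per-channel global thresholding →
Boolean AND across channels → subtraction of binarized NOT-channels →
optional filters → small-particle removal → optional 3D edge-object
removal → optional outline conversion → colorization with one of seven
palette colors (white, yellow, cyan, magenta, green, red, blue).

Numerical conventions, chosen once and frozen by tests:

* **Auto-threshold** is the iterative intermeans (IsoData-style) rule — the
  behavior of the classic default global threshold — iterated to a
  fixpoint from the overall mean; manual thresholds are inclusive (≥).
  A constant volume thresholds to all-false with a warning.
* **Connectivity** is 8 in 2D and 26 in 3D throughout.
* **Rank-filter discs** contain the offsets with dx² + dy² ≤ r² + 1
  (the ImageJ rank-filter footprint: radius 1 is the full 3×3 box), with
  replicate edge padding; `fill_holes` fills per-slice via border flooding
  of the complement (4-connected background).
* **NOT-subtraction** happens immediately after the AND, before filters:
  the subtraction acts on raw binarized signal, not on smoothed masks.
* **Outlines** are per-slice borders: `thin` = mask minus its erosion by
  radius 1 (1 px), `thick` = radius 2 (2 px). The width of a "thick"
  outline is not canonically defined anywhere; 2 px is this package's
  documented choice.
* The **small-particle filter** works per 2D slice on 8-connected
  components, removing those with `n_px · xy_um_per_px² < min_area_um2`.
  At 0.21 µm/px, a 20 µm² cutoff removes particles below ⌈20/0.21²⌉ = 454
  px. The **3D edge filter** removes whole 26-connected components touching
  any stack face — the robust guard against transected objects.

### Mixing rules

Within one output channel, grayscale elements sum additively (clamped);
binary elements never blend. Binary elements are drawn lowest-priority
first, each overwriting prior content on its nonzero voxels, so on overlap
only the highest-priority color survives (default order white > yellow >
cyan > magenta > green > red > blue, editable as a priority table). Outline
elements overwrite only their border voxels, so underlying content remains
visible "inside" the object. These rules guarantee that every rendered
binary pixel is an exact palette color — which is what makes downstream
color-keyed detection (`color_to_detect`) lossless.

## The artifact-suppressing Z-projection

For Z-stacks each output channel also receives a single-plane projection
built at the *object* level:

1. All binary voxels of the channel are decomposed into 26-connected 3D
   objects (across all binary elements, all colors competing in one pool).
2. Objects are sorted by representative slice — minimum z under the `top`
   policy, maximum z under `bottom` — with ties broken by color priority,
   then object id, and accepted greedily; an object whose XY footprint
   intersects any already-accepted footprint is rejected *entirely*.
   Accepted footprints are therefore pairwise disjoint, and no projected
   pixel can fuse two stacked objects.
3. Accepted solid objects paint their footprint in their color. Accepted
   outline objects paint the projected border of their footprint; the
   interior is filled only from content that overlaps the object's own
   voxel set in XYZ — binary content picks, per pixel, the overlapping
   object nearest the policy end (ties by color priority), and grayscale
   content is max-projected over the outline object's own voxels. Outside
   all accepted footprints, grayscale elements are max-projected over the
   full stack and mixed additively.
4. A single-plane stack projects to the plain channel composition.

Whole-object suppression (rather than per-pixel occlusion) is a design
choice: a partially occluded footprint fragment would corrupt the
point-based counting that follows, and the alternative reading is not
well-defined for counting. The footprint-overlap threshold is zero pixels —
any intersection rejects.

If objects are uniformly distributed in Z and object size is unrelated to
label identity, this selection is *unbiased*: the accepted objects preserve
the relative ratio of object classes. The package asserts this property
empirically — over 200 seeded scenes with two colors placed 2:1 uniformly
in z, the accepted color fraction stays inside the 95% binomial interval
of 2/3. The price of suppression is a reduced absolute count, which is why
absolute quantification should use the full stack (or stereology), not the
projection.

## Point-based counting

Objects are quantified as *points with categories*, not as delineations —
this makes the result robust to imperfect segmentation and lets markers in
disjoint compartments be assigned to one cell.

**2D detection** is prominence-based: pixels are flooded in order of
decreasing intensity and a maximum is reported iff its height above the
highest saddle connecting it to any higher maximum reaches the
`noise_tolerance`. A connected equal-valued plateau yields one point at its
pixel-rounded centroid; constant planes yield nothing; equal-maxima ties
resolve in raster order (smallest y then x). **3D detection** reports
voxels that are the strict maximum of an ellipsoidal `(rx, ry, rz)`
neighborhood and at least the tolerance, with the same raster tie-break
(z, then y, then x). Both accept a Gaussian `pre_blur_radius` (which also
centers points on objects), `light_background` inversion, border exclusion,
`color_to_detect` (exact palette-color keying with proportional intensity,
so white grayscale content keys correctly at any brightness), and
`only_inside_outlines` restriction via the projected outline footprints.

**Conversion modes** turn point lists into persistent circular overlays:
`add` inserts the active digit into the category of the overlay containing
the point (nearest center on overlap ties; a point outside every overlay
creates a new one), `set` replaces the category, `delete` removes marked
overlays. "Inside" is a closed disc in XY with matching slice; the `NA`
slice sentinel (projection mode) matches any z. Category insertion is
commutative and idempotent, so repeated detections of one cell are
harmless. Manual verification — the "semi" in semi-automatic — is modeled
as editing the point list between detection and conversion; the package
has no interactive UI by design.

All counting state persists as CSV under `Counts/` next to the images
(`image, id, x_px, y_px, z_slice, category, radius_px`; categories are
verbatim text so `"13"` never becomes the number 13), with every operation
appended to `Counts/Counting_log.txt`. Origin/north reference frames and
tissue contours live in the same folder.

## Serial-section organization and scoring

Sections are stacked along Z at `round(interval × thickness / xy_um_per_px)`
pixels — analyzing every 6th section of 20 µm at 0.21 µm/px gives 120 µm ≡
571 px, with a default jitter amplitude of ⌊spacing/3⌋ = 190 px. Jitter is
`Uniform[−a/2, +a/2]`, independent per object and seeded, so objects do
not lie exactly on section planes in the reconstruction; the distribution
shape is this package's choice (nothing canonical exists) and is
documented here once. Per-image coordinates are translated so the recorded
origin maps to (0, 0) and rotated so the recorded north vector maps to
screen-up (0, −1) — an isometry, verified to 1e−9 on random clouds.

Benchmark scoring matches predictions to ground truth greedily by
ascending XY distance within a match radius (each side matched at most
once; the radius defaults to the overlay radius). With counts
`correct / incorrect_markers / false_target / omitted` out of
`truth_total`:

* `% accurate = 100 · correct / (correct + incorrect_markers + false_target)`
* `% omitted = 100 · omitted / truth_total`, with
  `omitted = truth_total − correct − incorrect_markers`

both rounded half-up to one decimal. These denominators are the ones that
reproduce every published column pair of the user-consistency benchmark
exactly (e.g. 223/(223+48+8) → 79.9% with 13/284 → 4.6% omitted), which is
why they were adopted; the regression test pins all eight columns.

## 3D reconstruction

`build_scene()` makes one scatter point per object, colored by category
via a fixed documented palette cycle, plus an alpha-shape surface from all
contour vertices jointly (per-section contours lofted by their z — joint
shaping matches the single tissue surface of the worked reconstruction;
the parameters of record there are point size 30 and alpha 1200). The
alpha complex keeps Delaunay tetrahedra with circumradius ≤ alpha; the
tetrahedralization is an incremental Bowyer–Watson construction with a
deterministic ~1e−8-of-bounding-box perturbation so that cospherical
inputs (e.g. box corners) resolve consistently. For large alpha the shape
converges to the convex hull; the tests verify the cube-corner volume
analytically and the total Delaunay volume against an independent
convex-hull implementation. Rendering writes a depth-sorted orthographic
PNG or a standalone HTML page embedding it.

## The synthetic tissue generator

Every end-to-end claim is tested against `generate_stack()` /
`generate_series()`, which emulate 4-channel labeled neural tissue:
channel 1 a nuclear stain in every cell, channels 2–3 two cytoplasmic
labels (A, B) in overlapping subsets, channel 4 a nucleus-restricted
marker M. Geometry is spherical nuclei inside ellipsoidal somata (z
semi-axis 60% of the XY radius) — the simplest shapes that still exercise
partial-inclusion statistics. Default conditions: 60 cells in a
128×128×16 stack at 1 µm/px, nuclei 2–2.5 µm in somata of 4–5 µm, p(A) =
0.4 and p(B) = 0.6 independently, p(M|A) = 0.85 and p(M|¬A) = 0.25
(echoing the strongly A-biased marker mix of the motivating data set),
10% of cells transected at a Z face, labels at 50% of the 16-bit range
over a 5% background with 2% Gaussian noise after a 1 px PSF blur.
Cytoplasmic labels bleed 1 px into the nuclear rim — small tracers do
cross the nuclear envelope — which is also what makes the
nucleus-AND-label binarization well-posed, mirroring how real cytoplasmic
signal overlaps nuclear outlines in confocal data. Designated *stacked
pairs* coincide in XY at separated Z (first member label A, second label
B): exactly the configuration that fakes colocalization in a naive
projection.

What the generator does **not** emulate: realistic confocal PSF
anisotropy, spectral bleed-through, Poisson photon statistics, irregular
cell shapes, or densely abutting somata. Passing tests therefore
demonstrate the correctness of the algorithms under controlled geometry,
not segmentation performance on difficult real tissue — on real data the
semi-automatic verification step carries that load.

## End-to-end study conditions

The full-pipeline check simulates a 3-section series of ~167 cells each
(500 total) at 0.5 µm/px in 440×440×14 stacks — the sub-micron sampling a
confocal section would have, at a field size that keeps the run in
minutes. Elements follow the worked large-image example: per output
channel a magenta thick-outline element (nuclei AND label B, 3D
edge-excluded — so transected cells never produce a countable outline)
plus a solid green element ANDing in the third label (nuclei AND B AND A,
respectively nuclei AND B AND M). Counting runs three automatic detection
passes on the projections: targets via the magenta outlines (tolerance
0.05, pre-blur 2), then each marker via its green fill inside the
existing overlays (tolerance 0.3, pre-blur 1 — smaller blur because the
marker fills are only tens of pixels). Detection parameters are analyst
settings in this workflow, exactly as in the interactive original; these
values were fixed by inspecting the generator's intensity design (labels
at half range over 5% background) and are part of the recorded study
conditions. Recovered per-category proportions are required to fall
within the 95% binomial interval of the realized ground-truth proportions,
and the scored accuracy of the fully automatic pass lands in the
high-nineties with single-digit omission — consistent with the
relationship between automatic and semi-automatic performance reported
for the original tools.

## Known limitations

* Abutting objects can merge into one binary object; on real data this is
  mitigated interactively, here by nucleus-restricted elements.
* Whole-object projection suppression lowers absolute counts at high
  density; use the full stack for absolute quantification.
* The TIFF writer available to this package cannot embed calibration tags,
  so voxel geometry and channel count travel in a JSON sidecar; foreign
  TIFFs without one read as single-channel with defaults and a warning.
* `fill_holes` and outlines operate per slice (the 3D reading is neither
  needed by the workflow nor canonically defined for it).
* Only global thresholding is offered; pre-segment externally if adaptive
  methods are required.
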