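---
title: "Slice-to-atlas registration and region quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-to-atlas registration and region quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoslice)
```

## Overview

`histoslice` maps manually counted cells from 2D histology sections of
mouse brain into a 3D reference atlas and tallies them by named structure.
The model of the data is deliberately simple and fully geometric: a counted
cell is a coordinate, a slice is a (possibly oblique) plane through the
annotation volume, and registration is a fitted planar transform from
user-identified landmark pairs. No intensity-based optimisation is
involved, which is exactly why the approach tolerates torn tissue, missing
hemispheres and other defects that defeat edge- or threshold-driven
automatic registration.

This vignette records the assumptions, parameter conventions, numerical
choices and known limitations, in the order the pipeline runs.

## Coordinate conventions

* Volumes are stored AP × DV × ML (anterior→posterior, superior→inferior,
  left→right). Loaders re-permute any declared input axis order.
* Voxel indices and pixel coordinates are **0-based**, matching the Common
  Coordinate Framework convention; conversion to R's 1-based arrays happens
  only at the point of array access.
* Point coordinates are `x` = column, `y` = row, origin at the top-left
  pixel — the convention of FIJI's "measure" export on an uncalibrated
  image. A `calibrated_um` flag divides micron-calibrated exports back to
  pixels.
* Bregma defaults to voxel (AP 540, DV 0, ML 570) on the 10 µm grid. This
  follows the convention of the upstream landmark-registration toolkit this
  workflow descends from; since reference atlases do not themselves define
  bregma, the value is a configurable field of the atlas bundle, not a
  constant. With it, a coronal plane at +1.35 mm AP maps to fractional
  index 540 − 135 = 405, and −5.34 mm to 1074.
* Plane position signs: anterior positive (coronal), animal's-right
  positive (sagittal), ventral positive (transverse). Positive `ml_tilt`
  moves the sampled plane toward lower normal-axis index with increasing
  column; positive `dv_tilt` does the same with increasing row. The tilt
  sign convention is arbitrary (only signed values, not definitions, are in
  common use) and is documented rather than guessed at: both tilts flip by
  negating the angle.

## Ingest geometry

Images are downsampled from acquisition resolution (e.g. 0.5 µm/px) to the
atlas grid (10 µm/px) by **area averaging**: the output pixel is the
overlap-weighted mean of input pixels. For integer factors this is the
exact block mean (computed as a reshaped column mean, which keeps a full
4000 × 5600 image under half a second); for non-integer factors a sparse
row/column aggregation matrix carries the exact overlap weights. Bilinear
filters were rejected because they under-use the input when the factor is
large; nearest-neighbour because it aliases.

The downsampled image is centred on the canvas with symmetric padding.
Whether the original workflow centres or corner-anchors is not observable
from its outputs, so centring was chosen and the offsets are recorded in a
`canvas_record` side-car; nothing downstream depends on the choice, and the
mapping is exactly invertible (`unpad_points()` recovers raw coordinates to
< 1e-9 px).

Cell coordinates are **not** rasterised into a binary occupancy matrix and
warped as an image; they are carried as float coordinates and transformed
analytically by the same maps. This is mathematically the identical
mapping, but it preserves multiplicity when two cells fall into one 10 µm
pixel — a binary matrix cannot. `points_to_mask()` exists for visual parity
with mask-based workflows and documents its multiplicity loss; the
quantification path never uses it. Contrast adjustment (quantile or
absolute linear rescale, per channel) changes intensities only — never
shape or coordinates — and is applied before downsampling so that
landmark-relevant detail is stretched at full resolution.

## Oblique sectioning

A section at base index $n_0$ with tilts $(\theta_{dv}, \theta_{ml})$
samples normal-axis coordinate
$n(r,c) = n_0 + \tan\theta_{ml}\,(c - c_{ctr}) + \tan\theta_{dv}\,(r - r_{ctr})$
at each canvas pixel. Labels are sampled **nearest-neighbour**:
interpolating categorical structure ids would fabricate labels that exist
nowhere in the ontology. Tilts are capped at |45°|; beyond that a "section"
is no longer meaningfully a section. Pixels whose sampling coordinate
leaves the volume take label 0 and an `NA` sentinel in the coordinate map —
they participate in quantification as "outside brain". At zero tilt the
sampler is bit-identical to direct array slicing (a tested invariant).

The per-pixel coordinate map (the 3D voxel each canvas pixel was sampled
from) is the single source of truth for everything downstream: region
assignment and the 3D micron-space lift both read it, which is what makes
`lookup_region(coord_map[p]) == labels[p]` a structural identity rather
than a coincidence.

## Landmark registration

Landmarks arrive as a CSV of numbered pairs (padded-frame point,
atlas-frame point) — the file contract that replaces interactive clicking,
and the one substantive interface change needed to make the workflow
headless. Three families are offered:

* **projective** (default): 8-parameter homography via the normalized DLT
  (Hartley normalization, SVD null vector). The default because the
  upstream landmark workflow is homography-like; exact for 4 points,
  least-squares beyond.
* **affine**: 6 parameters by QR least squares; minimum 3 points.
* **thin-plate spline**: landmark-interpolating (regularization 0, so fit
  residuals are exactly zero), for local tissue deformation. Since a TPS
  has no closed-form inverse, a reverse spline (atlas→slice) is fitted from
  the same pairs at fit time and used as the inverse map for image
  resampling; point warping always uses the exact forward spline.

Strict mode (default on) requires ≥ 10 landmarks — the widely recommended
minimum for reliable slice registration — and refuses to fit with fewer,
naming the threshold; `strict = FALSE` overrides. Degenerate configurations
(collinear points, vanishing eighth singular value) are rejected rather
than silently producing unstable fits.

Images are warped by inverse mapping with bilinear intensity interpolation;
out-of-source pixels are 0, and pixels where a projective inverse is
undefined (vanishing homogeneous denominator) are zeroed and counted in a
warning. Points are warped **forward through the same transform** — the
"identical way" contract; a tested property places a warped impulse within
1 px of its warped coordinate.

Transforms serialize to versioned JSON. Numeric parameter blocks are
written as 17-significant-digit strings because standard JSON number
emission rounds the last ulp; 17 digits round-trip IEEE doubles exactly,
which makes `load(save(T))` reproduce the mapping bit-for-bit — a property
the multi-channel reuse path (`apply_saved_transform()`) relies on.

## Quantification

Atlas-frame coordinates are rounded half-up to a canvas pixel before
consulting the coordinate map: region borders below the 10 µm atlas
resolution are not meaningful, and a deterministic tie-break beats an
epsilon-dependent one. Counts are reported at the annotation's leaf label;
`rollup = TRUE` optionally accumulates them into ancestors. "Outside brain"
is a first-class row — warped points legitimately leave the annotation —
so every tally's total equals the number of ingested coordinates, an
invariant tested end-to-end from the coordinate files.

Sagittal sections cannot be quantified under the Chon (modified
Franklin–Paxinos) labels; the restriction is enforced with a specific
error. Point curation (add / move / delete / polygon group edits, even-odd
rule with boundary inclusion, self-intersecting polygons rejected) is
applied deterministically in order and appended to an edit log for
provenance; editing a slice record recomputes its assignments.

The two-ontology comparison reports the Pearson correlation of paired
per-slice totals, a paired t statistic on the number of structures hit per
slice, and the count of structure names shared verbatim. Exact-name
matching is a deliberate, flagged simplification: expert-curated
cross-ontology concordances exist, but encoding one is out of scope and
would silently embed anatomical judgements.

## Synthetic fixtures

The generator emulates the study conditions the pipeline targets: a 10 µm
labeled volume (nested ellipsoidal regions inside an ellipsoidal brain
mask, every brain voxel labeled, as in a real annotation), slices rendered
at 0.5 µm/px — the resolution of typical example acquisitions — as 16-bit
TIFFs with a tissue silhouette, Gaussian cell blobs and Gaussian sensor
noise, FIJI-dialect coordinate CSVs, and ≥ 10 exact landmark pairs placed
on distinctive outline positions. Ground-truth deformations are mild
homographies of the kind produced by mounting distortion. Cells are
sampled ≥ 3 voxels inside their regions (Chebyshev erosion) so that
assignment accuracy under landmark noise measures registration error, not
border ambiguity. All randomness flows through one seeded generator
(`withr::with_seed`), so same-seed regeneration is byte-identical.

What the fixtures do **not** emulate: point-spread functions, channel
bleed-through, stitching seams, tissue folding or staining variability.
Passing tests therefore certify the geometry and bookkeeping of the
pipeline — not robustness to real microscopy artifacts, which lives in the
user's landmark choices exactly as it does in the GUI original.

Default problem sizes (60 × 80 × 100 toy volumes, 50–200 cells per slice,
2-slice simulated projects) were chosen as the smallest sizes at which
every geometric property is non-trivially exercised — oblique planes cross
several regions, every region affords a 3-voxel interior margin — while
the full suite stays fast.

## Pipeline and configuration

The batch pipeline mirrors the six interactive steps (pre-process,
register, warp points, quantify, aggregate, render 3D) over a project
directory with basename pairing between images and coordinate files;
unpaired basenames are an error by name. Configuration is YAML; every step
is also a plain function, and `simulate` scaffolds a complete synthetic
project. Outputs are pure functions of (inputs, config, seed); a manifest
logs package version and parameters per step.

## Known limitations

* Mouse only; one annotation grid per bundle pair (Allen and Chon variants
  must share the voxel grid for totals to be comparable).
* Landmark quality is the accuracy ceiling: the package validates counts
  and geometry, not anatomical correctness of the clicks.
* The thin-plate-spline image inverse is an approximation (reverse-fitted
  spline); for strongly folded deformations the forward and reverse
  splines can disagree away from landmarks. Point quantification is
  unaffected since it only uses the forward map.
* Nomenclature overlap between ontologies is exact-name only.
* The 3D rendering is a static three-projection figure with a CSV
  companion; interactive inspection is out of scope.
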