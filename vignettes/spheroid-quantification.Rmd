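---
title: "Quantifying 3D spheroid invasion cultures: models, parameters and validation"
author: "spheroidquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D spheroid invasion cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and its readouts

A multicellular tumor spheroid embedded in a collagen matrix reorganizes,
over days of culture, into three compartments: a residual cell-dense **core**,
a compact concentric **rim** at the former spheroid-matrix interface, and an
**invasion zone** of individually migrating cells that disseminate radially
into the matrix, with density decreasing toward the invasion front. A
chromatin-bound nuclear reporter (H2B-GFP-like) makes every nucleus visible;
nuclear fragmentation of that reporter marks apoptosis, and bright condensed
figures mark mitoses. Because light scattering limits confocal imaging of
native specimens to a few tens of micrometers of depth, specimens are
optically cleared by dehydration and refractive-index matching, which extends
the usable imaging depth severalfold.

`spheroidquant` turns calibrated image stacks of such cultures into
per-compartment counts and rates:

* nucleus counts per z-slice and per zone (core / rim / invasion),
* radial invasion distances (maximum, 95th percentile, median),
* cell-death frequency from clustered nuclear fragments,
* mitosis frequency from manual annotations,
* a signal-to-noise-versus-depth profile quantifying the clearing benefit,
* an exact Mann-Whitney U comparison of two spheroid groups.

Because real microscope data cannot ship with a package, a first-class
synthetic-specimen generator reproduces the geometry and optics of the assay
with exported ground truth, and the whole analysis chain is validated by
parameter recovery against that truth.

# The segmentation chain

Segmentation is 2D and per slice, matching the assay's slice-count readout
(counts are reported per slice; no 3D object linking is attempted). The
operator chain and its defaults are:

1. **Gaussian blur**, sigma 1.5 micrometers, converted to pixels via the
   mandatory pixel calibration. Physical units make the chain invariant to
   resampling.
2. **Phansalkar local adaptive threshold**. The slice is rescaled to [0, 1]
   by its global minimum and maximum; for each pixel, with `m` and `s` the
   mean and population standard deviation of a circular window (radius 15 px
   by default), the threshold is `t = m (1 + p e^(-q m) + k ((s/r) - 1))`
   with `k = 0.25`, `r = 0.5`, `p = 2`, `q = 10`. This local rule tolerates
   the strong intensity variation of nuclei at different z-positions.
   *Degenerate-input caveat:* the min/max rescaling means a slice containing
   no signal at all (pure noise) is stretched to full range and thresholds
   everywhere; a constant slice is detected and returns an empty mask with a
   warning. Slices with any real signal behave as intended.
3. **Binary median filter**, disc of radius 3 px: majority vote, removing
   speckle below roughly half the disc area.
4. **Watershed separation** of touching nuclei: Euclidean distance transform,
   regional maxima as seeds (maxima closer than 2 px merge), watershed on the
   negated distance map restricted to the mask. Separation lines are assigned
   to background, and labels are 8-connected consecutive integers.
5. **Particle filter**: pixel counts convert to areas via `xySize^2`; labels
   with area between 45 and 700 square micrometers become nucleus records
   (intensity-weighted centroid, mean intensity). The band is read as an
   *area* band: 700 micrometers of length would exceed any nucleus. Labels
   below 45 are retained as fragment candidates for apoptosis detection
   rather than discarded; labels above 700 are debris.

All constants are configurable (`SegmentationParams`); the defaults are the
established interactive-analysis defaults for this assay.

# Zonal geometry

Zone boundaries are supplied as polygons (interactively drawn ROIs or JSON)
and straightened into ellipses that preserve the polygon's area, centroid and
second-moment structure: semi-axes come from the eigenvalues of the
normalized second central moment matrix and are rescaled so the ellipse area
equals the polygon area exactly. Pixels inside the core/rim ellipse are core,
between the ellipses rim, outside invasion zone; every pixel has exactly one
label, and zone membership of a record is decided by its centroid pixel (the
cheapest rule consistent with counting; boundary-adjacent cells can flip
zone, which the recovery tests budget for). Boundaries are assumed constant
across the three analysis slices.

An automatic estimator is provided for simulated or well-behaved specimens:
it computes the radial mean-intensity profile about the intensity centroid,
places the rim/invasion radius at the half-level crossing beyond the densest
ring (the half-maximum of a blurred edge sits at the outermost cell centers),
and the core/rim radius at the inner edge of that ring (midpoint between the
interior level and the ring peak). It requires genuine ring contrast — the
rim must be visibly denser than the core — and falls back with a warning or
fails with an error otherwise. User ROIs always take precedence.

Invasion-zone counting is restricted to **one random quadrant** anchored at
the spheroid centroid: quadrants are axis-aligned sign patterns of
(row, col) offsets, drawn uniformly with a recorded seed, so the draw is
reproducible. Core and rim counts always use the full regions. Whether
apoptosis events and mitoses are also restricted is configurable; the same
flag applies uniformly to all invasion-zone records, and the choice is
echoed in the run metadata.

Radial distance is the in-plane Euclidean distance from the record centroid
to the spheroid centroid times the pixel size; it estimates the distance
migrated by each cell.

# Event quantification

**Apoptosis.** Fragment candidates with calibrated areas of 3-25 square
micrometers are clustered per slice by single linkage with a 20 micrometer
linking distance; clusters of at least 2 fragments become events (center =
mean of member centroids, one event = one dead cell). Single linkage with
the published radius is our fixed operationalization of "fragments within 20
micrometers of the segmented event"; the original detector is proprietary.
Death frequency per zone is `events / (events + intact nuclei)` — the
denominator choice is recorded in the metadata since published plots do not
define it. Frequencies are pooled across the analysis slices by default.

**Mitosis.** Mitotic figures are annotation-driven (condensed chromosomes
are counted manually in this assay); annotations are validated against the
image bounds, duplicates within 5 micrometers on a slice collapse to one,
and frequency is `mitoses / (mitoses + nuclei)` per zone.

**Two-group comparison.** `mannWhitney()` computes the exact two-sided
p-value by full enumeration of rank assignments (mid-ranks for ties) when
`n1 + n2 <= 12`, and the normal approximation with tie and continuity
correction otherwise; the branch taken is recorded. The exact branch is
validated against an independent pair-counting enumeration oracle.

# SNR-versus-depth

Per slice, `SNR = (I_mean - B_mean) / SD_mean` with `I_mean` the mean of the
brightest 5 percent of all slice pixels (ceiling of 0.05 N) and `B_mean`,
`SD_mean` the mean and population (divisor N) standard deviation of a
user-supplied dark rectangle (default: the top-left 10 percent-by-10 percent
corner). Taking the top 5 percent over the whole slice (rather than a signal
ROI) is a documented choice; SNR is invariant under global offset and gain,
which the tests assert. The segmentability threshold is configurable with
default 5 — the published figure shows the threshold only as a dashed line —
and the segmentable depth is the greatest depth whose SNR reaches it.

# The synthetic specimen generator

`simulateSpheroid()` emulates the day-7 specimen and its optics:

* **Geometry.** `nCore` cells uniform in a ball (default radius 150 um),
  `nRim` in the adjacent shell (thickness 30 um), `nInvading` at radii
  beyond the rim with density proportional to `exp(-d / 300 um)` out to 850
  um — the dissemination extent and gradual density decrease of the real
  assay. Defaults (1500 / 1700 / 400 cells) give central-slab packing
  fractions of roughly 0.15 (core) and 0.3 (rim), a regime where per-slice
  2D segmentation is meaningful; the generator refuses scenes above 0.9.
  Core and rim cells are placed with a hard-core minimum separation of 0.75
  nucleus diameters (nuclei in compact tissue have excluded volume and do
  not interpenetrate); invading cells are sparse migrating singles placed
  independently, which preserves the exponential radial law exactly.
* **Invasion slab.** Invading cells are placed in an equatorial slab
  (half-depth 15 um). The central-slice protocol images only that slab;
  cells invading above or below it would contribute to no readout, so the
  generator does not spend them. This is the one deliberate reduction of the
  specimen's 3D symmetry.
* **Nuclei.** Gaussian blobs (diameter 12 +/- 1.5 um; sigma = diameter/4, so
  the footprint segmented by the adaptive threshold matches the nominal
  cross-section after blur), with radial elongation (aspect 1.8) for
  invading cells, mirroring their polarization toward the invasion front.
  Mitotic cells (2 percent) are 0.7x diameter at 2x intensity.
* **Apoptosis.** Apoptotic cells (0.5 percent per zone by default, matching
  the below-1-percent control rate) are rendered as 4-6 fragments of 2.2-3.2
  um diameter at 3x chromatin intensity (pyknotic condensation), placed at
  evenly spaced jittered angles in an annulus of the 18 um scatter disc.
  Even spacing keeps fragments separated beyond the ~7 um optical merging
  scale — apoptotic bodies are distinct membrane-bound objects — so the
  rendered morphology stays inside the published detector band (3-25 um2
  within 20 um) after PSF and preprocessing blur. The fragment cluster's
  axial extent (sigma_z = diameter/3) slightly exceeds an intact nucleus's
  (diameter/4) because the bodies disperse through the former cell volume.
  Fragment count, size and placement are modeling choices: the assay
  literature specifies only the detector's limits.
* **Optics.** Single-exponential (Beer-Lambert) depth attenuation
  `I(z) = I0 exp(-z / lambda)` with lambda = 500 um for cleared and 25 um
  for uncleared specimens; in-plane PSF blur (sigma 1 um), background offset
  10, Poisson shot noise on the signal and Gaussian read noise (sd 2).
  Depth-dependent blur growth is not modeled; attenuation alone reproduces
  the SNR-depth phenomenology, including the 20-40 um usable depth of
  uncleared specimens and the more-than-twofold gain from clearing.
* **Reproducibility.** One RNG stream per simulation, seed mandatory. The
  sampling order is documented in the code (positions, diameters, apoptosis
  draws, mitosis draws, intensity jitter, fragments per event), so any draw
  can be reproduced independently; treatment pairs derive their kill /
  conversion draws from `seed + 2` and noise realizations from `seed + 1` /
  `seed + 3`.

`simulateTreatmentPair()` models irradiation as observed in the assay:
invading cells are removed independently (default preset 50 percent), the
invasion front is truncated (100 um), surviving invasion-zone cells convert
to apoptosis up to roughly 8 percent, and core and rim populations are
untouched.

## What passing recovery tests do and do not show

The generator exercises threshold, watershed, area-band, clustering,
zonal and SNR logic at realistic densities and noise levels. It does not
render chromatin texture, collagen fibers, imaging artifacts (stripes,
bleaching), nor cell movement during acquisition; nuclei are smooth blobs.
Recovery of a simulated parameter therefore demonstrates that the
implementation of the published operator chain is faithful and
self-consistent — not that the chain is optimal on any particular
microscope's data. Calibration, boundary placement and the segmentability
threshold remain the user's responsibility on real data.

# Validation strategy and problem sizes

The test suite validates every pixel-level operator against brute-force
oracles (literal per-pixel Phansalkar evaluation, disc majority vote,
enumeration Mann-Whitney), geometry against closed forms (polygon moments,
ring areas, attenuation law, truncated-exponential radii), and the
end-to-end chain by parameter recovery: segmentation precision/recall at
least 0.9 on 500-cell scenes (384 px slices, 10 seeds), an injected 8
percent invasion-zone apoptotic fraction recovered within 2 points (600-cell
quasi-planar scenes at 1 um/px, isolating the detector from 3D sectioning
losses), a 50 percent invasion kill measured as a 0.5 +/- 0.1
count ratio (10 seeds), and a greater-than-twofold segmentable-depth gain
from cleared versus uncleared optics on a 40-slice stack. These scene sizes
are chosen so the full suite runs in minutes on a laptop while keeping
per-scene counts large enough for stable frequencies (invasion-zone
denominators of at least 500 where rates are asserted).

# Numerical and design choices

* Coordinates are (row, col), 0-based, pixel centers at integer positions,
  slice 0 shallowest; every module uses this convention, and CSV outputs
  carry it.
* Calibration is explicit user input everywhere; file metadata is never
  trusted (a mismatching resolution tag only warns).
* Areas always convert via `xySize^2`; distances via `xySize`.
* The watershed tolerance (1 px saddle depth) errs toward under-splitting:
  over-splitting would push half-nuclei below the 45 um2 floor and into the
  fragment band, which is the more damaging failure mode.
* Population (divisor N) standard deviations are used for both the
  Phansalkar window and the SNR background, matching the interactive tools'
  conventions.
* Ties in the exact Mann-Whitney use mid-ranks; the two-sided p-value counts
  assignments at least as extreme in |U - n1 n2 / 2|.
* TIFF export is 8/16-bit integer; non-integer intensities round with a
  warning. Round trips are voxel-identical for integer stacks.
* Degenerate inputs: constant slices threshold to empty masks with a
  warning; empty zones give zero frequencies with a warning; coincident
  zone boundaries give an empty rim with a warning; crossing boundaries,
  zero-area polygons and saturated packing are errors.

# Known limitations

* 2D per-slice counting double-counts cells that span two analysis slices;
  ratio and frequency readouts are unaffected, absolute counts inherit the
  same convention as the original assay.
* The boundary auto-estimator needs rim/core intensity contrast; specimens
  without a visible ring require manual ROIs.
* The simulator's exponential attenuation ignores depth-dependent scattering
  blur, so simulated deep slices are sharper than real ones.
* Mitosis detection is annotation-driven by design; no automatic detector is
  shipped.
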