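---
title: "Methods: quantifying monolayer morphology, junctions, gaps and stress fibres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying monolayer morphology, junctions, gaps and stress fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monolayerq)
```

# What the package measures

`monolayerq` quantifies four families of readouts from multichannel
fluorescence micrographs of cell monolayers (endothelial barriers and
adherent tumour cells are the motivating systems), given per-cell masks and
a µm/pixel calibration:

1. **Per-cell morphometrics.** Area $A$, perimeter $P$, the axes of the
   equivalent ellipse, the shape index
   $$\mathrm{SI} = \frac{4\pi A}{P^2},$$
   which is 1 for a perfect circle and tends to 0 for elongated cells, and
   the tortuosity index
   $$\mathrm{TI} = \frac{P}{P'},$$
   where $P'$ is the perimeter of the ellipse sharing the region's central
   second moments: TI $\approx 1$ for smooth circular or elliptical
   outlines and $> 1$ for irregular, star-shaped profiles.
2. **Junction-protein border profiling** (VE-cadherin-like stains). The
   junction channel is sampled along each cell border; each sample is
   corrected against the mean cytoplasmic intensity $\bar I_c$ as
   $$v_i = \frac{I_i - \bar I_c}{I_i},$$
   so the sign marks junctional staining (positive) versus inter-cell gaps
   (negative) and the value is bounded above by 1. The per-cell summary is
   the percentage of border samples with $v_i > 0$.
3. **Intercellular gap quantification** in confluent monolayers: gaps are
   enclosed background regions in the binarized junction channel, reported
   as a count, per-gap areas, an open-area percentage (total gap area over
   analyzed field area), and a size histogram.
4. **Actin stress-fibre density** from line scans: one scan per cell along
   the minor-axis direction (perpendicular to fibres), background-corrected
   and smoothed; peaks above a baseline are counted with a minimum
   separation rule — two neighbouring maxima count separately only when
   they are at least 3 µm apart (a separation of exactly 3 µm counts as
   two) — and density is peaks per µm of scan.

A thin statistics layer (`compare_groups()`) reports one-way ANOVA with
Tukey HSD pairs and the conventional significance tiers
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001).

# Outline tracing and the isoperimetric bound

All morphometrics start from `trace_outline()`, which extracts a closed
sub-pixel contour at the 0.5 iso-level of a binary mask
(`grDevices::contourLines`). The binary mask is first blurred with a small
Gaussian (`smooth_sigma = 1.2` px). This anti-aliasing step is load-bearing:
on 0/1 data every iso-level crossing falls on an edge midpoint, and that
"midpoint polygon" overestimates the perimeter of smooth shapes by about 5%
on average over edge orientations — enough to push the SI of a perfect disk
down to ~0.90 and destroy the isoperimetric bound SI $\le 1$. With the blur,
crossings interpolate the true edge position; the residual disk-SI error is
below 1% at radii from 25 to 200 px, and the bound holds with the
rasterization tolerance $\varepsilon = 0.02$.

The cost of anti-aliasing is corner rounding over roughly one blur sigma:
sharp convex corners (star points, square corners) lose about 1 px² each,
so the traced perimeter of a spiky star sits a few percent below the ideal
polygon's. This biases TI of very spiky shapes slightly toward 1 and is the
right trade-off for cells, whose outlines are smooth at the pixel scale.

Other numerical choices:

* **Equivalent ellipse.** Moment matching on the *filled* region: pixel
  centre covariance plus the 1/12 per-pixel footprint term; full axes are
  $4\sqrt{\lambda_{1,2}}$ of the covariance eigenvalues. (The alternative
  reading — matching area and aspect instead of moments — is not used;
  moment matching is the standard convention.)
* **Ellipse perimeter.** Ramanujan's second approximation, with error well
  under 0.1% for aspect ratios up to 20; the numerical complete elliptic
  integral serves as the oracle in the tests only.
* **Degenerate inputs.** Empty or multi-component masks raise a
  `segmentation_error`; zero-area polygons a `degenerate_geometry` error;
  non-positive axes, areas or perimeters an `invalid_parameter` error. All
  errors carry condition classes so pipelines can skip-and-log per cell.

# Junction profiling choices

The border is resampled at 1 px arc-length steps; each sample averages a
band of ±`band_halfwidth_px` (default 1) pixels along the local normal.
The cytoplasm reference averages `n_regions = 5` seeded-random disks of
radius 5 px placed fully inside the mask eroded by band + disk radius, so
no reference region overlaps the border band.

The per-pixel normalisation $v_i = (I_i - \bar I_c)/I_i$ was chosen over
dividing by the *mean* border intensity because it is the only per-pixel
form consistent with the intended sign semantics (positive exactly when the
border is locally brighter than the cytoplasm) while staying bounded above
by 1. The mean-denominator variant is available via
`corrected_profile()`'s inputs if needed, but the sign pattern — and hence
the positivity percentage — is identical for any positive denominator, so
the choice does not affect the headline statistic. Samples with raw
intensity below $10^{-6}$ of the profile maximum are treated as invalid and
excluded; $v = 0$ counts as non-positive (strict positivity). Percentages
are computed per cell and then averaged per condition, matching a
50-cells-over-8-images sampling design.

# Gap segmentation

Confluent junction images have three intensity classes: dark intercellular
gaps, the diffuse cytoplasmic pool of the junction protein, and bright
border staining. The default binarization (`"median_fraction"`) calls
background any pixel darker than half the image median: the median sits
robustly inside the dominant cytoplasm class, so the rule separates true
gaps from stained monolayer regardless of how much border staining is
present. Two-class Otsu is kept as an option but is *bistable* on
three-class images — when gaps are scarce it splits cytoplasm from border
instead and misreads every enclosed cell interior as background — which is
why it is not the default. After thresholding, the foreground is closed
with a 2 px disc; gaps are background components that do not touch the
image border (border-touching background is out-of-monolayer, not an
enclosed gap) with area at least `min_gap_area_um2 = 5` µm².

The open-area percentage normalizes total gap area by the total analyzed
field area — the only denominator available per image. Histogram bins
default to log-spaced edges {5, 10, 20, 50, 100, 200, 500, 1000} µm²;
right-open bins, last bin closed, with an explicit logged overflow bin.

# Line-scan fibre density

Scan lines pass through the region centroid along the equivalent-ellipse
minor-axis direction (stress fibres align with the major axis), clipped to
the mask with a 2 px inset; profiles are sampled by bilinear interpolation
at 0.25 px steps. Background is a rolling-minimum envelope (window 6 µm)
subtracted from the raw profile, followed by a 0.75 µm moving average.
Residuals may be slightly negative; no floor is imposed.

The peak rule is implemented exactly as stated above: candidate local
maxima (plateau-aware) above the baseline; among maxima closer than 3 µm
only the highest survives, ties broken in favour of the smaller position;
exactly 3 µm counts as separate. The *baseline* itself is the one genuinely
free parameter. The default `"auto"` baseline splits the corrected-profile
values into valley and peak classes with Otsu's method and thresholds
between them. This is duty-cycle-free: a quantile- or MAD-based rule that
works for sparse fibres (spacing 8 µm, ~20% of samples on peaks) saturates
for dense fibres (spacing 4 µm, ~40% on peaks), whereas the two-class split
tracks the valley/peak structure in both regimes. A fixed numeric baseline
can be supplied instead, and raising the baseline can only remove peaks.

# The synthetic scene generator

Because the analyses are meant to be validated against known ground truth,
the package ships a seeded generator rather than fixture images:

* **Geometry.** `n_cells` uniform seed points, discrete nearest-seed
  (Voronoi) assignment, 2 Lloyd relaxation steps by default — roughly
  convex, evenly sized cells resembling an endothelial monolayer. A
  connectivity pass keeps each label's largest component and regrows stray
  bisector-tie pixels. Sub-confluent scenes erode every region by 3 px
  (and clear the same margin at the field edge) so each border faces a dark
  corridor; confluent scenes share borders.
* **Junction channel.** Cytoplasmic pool at 120 counts, border staining at
  220 painted over a ~2 µm-wide band on the positive arc intervals
  (`junction_positive_fraction` of the border, in `n_positive_arcs`
  evenly spaced intervals at a random phase), ambient background at 5.
  The cytoplasmic level is deliberately well above background — as in real
  confluent VE-cadherin images, where a diffuse cytoplasmic pool is always
  present — which is also what makes threshold-based gap detection
  well-posed. Gaps are carved as background-level discs centred on interior
  cell-cell borders, mutually disjoint, with the staining retracted from
  the gap rim (an annulus reverts to the cytoplasmic level) the way
  junction protein retracts from a real opening.
* **Actin channel.** Parallel Gaussian ridges (intrinsic half-width 0.3 µm)
  at the prescribed spacing, oriented along each cell's major axis, random
  phase per cell; cytoplasmic base 40, ridge amplitude 180.
* **Optics and camera.** Isotropic Gaussian PSF (default sigma 1 px,
  replicate boundary), then Poisson shot noise (gain 2 counts/photon) plus
  additive read noise (sigma 3 counts), quantised to 16-bit integer counts.
  At these defaults the fibre ridge SNR is above 5.
* **Ground truth.** Realized positive arc fractions and intervals, realized
  gap areas, and per-cell fibre spacing/orientation/count are recorded at
  render time; `write_dataset()` emits multipage TIFFs (junction/actin/
  nuclei page order), pooled truth CSVs and a flat key=value manifest.
  Identical parameters and seed reproduce scenes, images and files
  byte-identically.

What the generator does **not** emulate: junction phenotype subtypes
(reticular versus linear configurations), fibre curvature and branching,
cell motility or temporal dynamics, uneven illumination, and optical
aberrations beyond an isotropic PSF. Passing recovery tests therefore
demonstrates that the analysis chain measures what it claims on images
whose statistics are known — not that segmentation-free analysis of real
micrographs is solved; per-cell masks remain an input, as in the manual
workflow the package automates.

# Sampling design and problem sizes

The default pipeline configuration mirrors the motivating study's sampling
plan: per condition, ~50 cells spread over 8 sub-confluent fields for
morphology, junction and fibre metrics, and 30 confluent fields for gap
metrics. The packaged defaults use 256x256 px fields at 0.5 µm/px with 6-7
cells per field, which keeps a full two-condition run (two regimes, all
four metric families, both conditions) around a minute on one core while
preserving the cells-per-image density of the original design. The
recovery tests run the same design at true positive fractions
{0.2, 0.5, 0.8}, fibre spacings {4, 5, 8} µm and gap areas 20-500 µm².

The reporting layer leaves the aggregation unit (cell, image, or
experiment) to the caller: `compare_groups()` consumes whatever long-format
table the pipeline produced, so SEM over cells and SEM over images are both
one `aggregate()` away rather than a hard-coded choice.

# Known limitations

* Perimeters of shapes with sub-resolution spikes are smoothed toward the
  ellipse, deflating TI slightly for very spiky outlines (see corner
  rounding above).
* Gap detection assumes gaps are the darkest class and the monolayer covers
  most of the field; sparse cultures with large empty regions touching the
  image border will have those regions (correctly) excluded, but enclosed
  bare patches of substrate would be counted as gaps.
* The fibre readout is strictly the 1-D line-scan density; no 2-D fibre
  segmentation, orientation fields or anisotropy measures are attempted.
* Micrometre calibration is always taken from the configuration, never from
  TIFF metadata; mixing files with differing true calibrations is the
  caller's responsibility.
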