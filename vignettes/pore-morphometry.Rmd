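---
title: "Pore morphometry with poremorph: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore morphometry with poremorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremorph)
```

## The measurement problem

Porous biomaterials — freeze-dried collagen scaffolds, space-holder metal
foams, sintered implant coatings — derive their biological and mechanical
behaviour from the geometry of their pore space: how big the pores are, how
irregular their walls, how evenly they are dispersed. A cross-sectional
micrograph reduces this to a 2D stereological problem: given a binary
pore/solid image and a physical scale, quantify per-pore size and shape and
the spatial arrangement of the pore population.

poremorph computes, per pore:

* **area** (filled pixel count) and the **equivalent-circle diameter**
  $d_{eq} = 2s\sqrt{A/\pi}$, with $s$ the scale in µm/px;
* the **LSTP radius** (largest sphere through pore): the radius of the
  largest circle fully inscribed in the pore, a proxy for the largest
  particle that could pass it and a far better size measure than $d_{eq}$
  for irregular pores;
* **circularity** $f_c = 4\pi A / P^2$ (ISO 9276-6), 1 for a circle;
* **waviness** $f_w = P_{convex}/P$, the fraction of the boundary that is
  locally convex (centre of curvature inside the pore) — shapes with
  concave re-entrants score below 1, and pure convex shapes score exactly 1;
* **aspect ratio** $AR = d_{min}/d_{max}$: the minimum rotated extent over
  the extent perpendicular to it;

and, per image, the total porosity, a **territory map** assigning every
pixel to its nearest pore, the per-pore **local area fraction** (pore area /
territory area — the homogeneity metric), radial **ring-band profiles**, and
rendered homogeneity colour maps.

## Segmentation

Thresholding is deliberately manual. The satisfactory threshold depends on
imaging modality, material contrast, and magnification, and automatic
selection hides that judgement; `suggest_threshold()` offers an Otsu
starting point whose use is recorded in the mask's provenance, but
`binarize()` always applies the value the analyst chose. By default dark
pixels are pore (backscatter SEM convention); `invert = TRUE` handles
modalities where pores image bright.

The optional FFT band-pass (`fft_bandpass()`) evens out illumination before
thresholding: a Gaussian transfer function in Fourier space suppresses
features larger than `large_cut` px (shading, uneven brightness) and smaller
than `small_cut` px (shot noise). Defaults are `small_cut = 3` px and
`large_cut = 40%` of the smaller image dimension. The filter is linear,
removes the DC component exactly, and mirror-pads odd dimensions so
wrap-around artefacts stay off the frame. When the filter is skipped,
thresholding applies to the image as passed, and the mask records which.
Features of interest should span at least 12–15 px; below that all
boundary-derived metrics degrade, and `fft_bandpass` warns if `small_cut`
encroaches on that range.

## Contours and the smoothing band

Pore components are labelled 8-connected (background 4-connected) and each
external boundary is traced with a Moore-neighbour walk; interior solid
islands ("pore within a pore") are ignored, and the pore area includes any
enclosed holes. Ids follow the row-major scan order of the topmost-leftmost
boundary pixel, so numbering — and everything downstream — is identical
across platforms. Border-touching pores are measured but flagged, so
population statistics can exclude them.

A traced boundary is a half-pixel staircase: its chain length overestimates
smooth perimeters and its derivatives are useless for curvature. poremorph
therefore resamples each contour at uniform arc length (20× the original
point density) and low-pass filters $x(t)$ and $y(t)$ in the Fourier domain
with a **Gaussian spectral roll-off** — hard truncation rings on straight
edges, and the ringing corrupts curvature signs downstream.

The cutoff adapts to the boundary's character. A boundary made of genuinely
straight edges needs a short cutoff wavelength (corners are real detail); a
smoothly curved boundary carries only staircase at short wavelengths and
wants a long one. The rule is $\lambda = 12 - 8\,s$ px of arc, where $s$ is
the fraction of the perimeter lying in same-direction chain runs longer
than $2\sqrt{L/\pi}$ — the longest staircase tread a circle of the same
perimeter $L$ would produce, so true edges and long shallow treads are
distinguished at any size. The kept harmonic count is $K = L/\lambda$
(Gaussian 1-sigma point, floor 8). The smoothed curve preserves enclosed
area and centroid; corners of a 100 px square stay within 2 px, and its
perimeter within 3%.

Three operations use three different bands, because their noise/detail
trade-offs differ:

| consumer | cutoff wavelength | why |
|---|---|---|
| circularity, perimeter | adaptive $12-8s$ px | keep real corner detail, drop staircase |
| LSTP distances | 8 px | suppress staircase only; longer cutoffs round concave notches outward and bias inscribed radii |
| waviness curvature | 40 px | curvature-sign classification needs the staircase fully gone |

## LSTP: two-stage inscribed-circle search

A coarse point grid (pitch `max(1, min(bbox)/64)` px) spans the contour
bounding box; points inside the raw contour (even-odd rule) are kept and
the minimum distance from each to the smoothed boundary polyline is
computed. The best point seeds progressively finer local grids (window ±2
pitches, pitch /8 per stage) down to `refine_step` (default 0.1 px).
Distances carry a **+0.5 px digitisation correction**: traced contours pass
through boundary-pixel centres, half a pixel inside the physical pore edge.
Pores thinner than the grid retry at 1 px and 0.25 px pitch; a pore thinner
than a quarter pixel everywhere reports the 0.25 px bound (in practice such
specks fall below `min_area`).

On rasterised discs this reproduces radii to a few tenths of a percent
(r = 27 px → 26.66; r = 200 → 199.51), and on random overlapping-circle
blobs it agrees with an exact Euclidean distance transform maximum to
within 0.4 px — the suite asserts 0.5 px, with `EBImage::distmap()` as the
independent oracle.

## Waviness: turning-angle classification

The textbook estimator — classify each boundary sample by the sign of
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$ — fails on digitised shallow
arcs: an arc of curvature radius 3,600 px (the inner ellipse of the
shallowest validation horseshoe at the ×8 raster) has $|\kappa| \approx
3\times10^{-4}$/px, below the residual staircase noise at any cutoff that
still resolves the cusps. poremorph instead classifies on the **tangent
turning angle** $\theta(t) = \int \kappa\, ds$:

1. a hysteresis walk over two laps of $\theta$ detects concave cores —
   stretches where the tangent direction reverses by more than `turn_tol`
   (default 0.2 rad). Flat edges have zero net turning and can never be
   classified concave, so convex polygons score exactly 1 regardless of
   pixel noise;
2. core endpoints are refined with a circular running median of the turning
   rate (window $L/15$): on a shallow decline the position of the
   $\theta$ peak/trough jitters by noise amplitude divided by trend slope,
   and the median — immune to the sharp positive spikes at cusps and
   corners — recovers the true transition points.

Both thresholds are dimensionless or perimeter-relative, so waviness is
rotation- and scale-invariant (verified at four rotations and three scales
within 0.005). The estimator's floor is the cusp-cap resolution: the
smoothing band replaces each cusp by a rounded cap of width ~2 smoothing
sigmas whose assignment between convex and concave is ambiguous, giving a
systematic +1–3% on horseshoes with shallow inner arcs — the same cases and
the same order of deviation the reference measurements show.

## Aspect ratio

The contour is swept through (−90°, 90°] in `angle_step` = 0.5° steps
(directional extents have period 180°, so this covers the full rotation the
definition asks for at half the cost); $d_{min}$ is the smallest extent,
ties resolved to the smallest angle, and $d_{max}$ is the extent
perpendicular to the $d_{min}$ orientation — deliberately *not* the global
maximum Feret diameter, which differs for skewed shapes. Raw contour points
are used: extents are max/min projections and gain nothing from smoothing.

## Territory maps and homogeneity

Every pixel is assigned to the pore whose nearest pore *pixel* is closest
(exact Euclidean nearest-site transform, Felzenszwalb–Huttenlocher
lower-envelope algorithm in C++). Distance is measured to the pixel set,
not the centroid: centroid-based Voronoi partitions misattribute space
around elongated or irregular pores, which is precisely the regime these
materials occupy. Equidistant pixels go to the site first reached in the
transform's scan order (smallest site column, then row) — a deterministic
rule verified against a brute-force all-pairs search on 64×64 fixtures,
ties included. Territories partition the image exactly; the local area
fraction $af = A_{pore}/A_{territory}$ is 1 when a pore fills its
territory, and a periodic lattice of circles recovers the analytic
$\pi r^2/s^2$ within 2%.

Ring-band profiles assign each pore whole to the annulus containing its
centroid (band width is the user's `step` about the image centre). With the
recommended feature-to-step ratio of at least 1:10, features straddling
band boundaries have negligible effect on band means; conversely a pore
much larger than its band can push that band's porosity above 1 — the
convention is documented rather than clamped. A single all-covering band
reproduces the global statistics exactly.

Homogeneity maps paint each territory by its pore's local area fraction on
a fixed colour range (default 0–0.5) so maps of different samples share a
colour bar; pore interiors can be overlaid in a contrasting colour.

## The synthetic validation suite

`make_polygon()`, `make_overlapping_circles()`, `make_horseshoe()` and
`make_mesh_grid()` generate the validation inputs with closed-form ground
truths; all rasterise by the pixel-centre rule (unbiased area) and are
bit-deterministic. The horseshoe — the region between an outer semicircle
of radius $a$ and an inner half-ellipse with semi-axes $(a, b)$ — is the
waviness fixture: its boundary is one convex arc of length $\pi a$ and one
concave arc of half the ellipse perimeter, so
$f_w = \pi a / (\pi a + E_{1/2}(a,b))$ exactly, with $E_{1/2}$ from the
binomial series truncated below $10^{-10}$ relative (cross-checked against
adaptive quadrature of the arc-length integral to $10^{-8}$).
`reference_pore_specs()` ships eight overlapping-circle configurations
whose largest radii (27…200 px) are the inscribed-circle truths; satellites
overlap at 60–80% of the radius sum, placed so the union never enlarges the
maximal inscribed disc.

What the suite does *not* emulate: SEM texture and noise, grayscale edge
gradients, partial-volume effects, or real pore-size distributions. Passing
it demonstrates the geometry engine is correct and calibrated at the
50–500 px feature scale; segmentation quality on real micrographs remains
the analyst's responsibility (and is, in our experience as in the
reference's, the dominant error source).

```{r horseshoe, fig.alt = "horseshoe validation"}
hs <- make_horseshoe(240, 160)       # x8 raster of the a=30, b=20 case
m  <- measure_pore(extract_contours(hs$mask)[[1]])
c(measured = m$waviness, analytic = hs$truth$waviness)
```

## Numerical and design choices

* **Coordinates**: matrices are `[y, x]`, pixel centres at 1-based integer
  coordinates, x right, y down; contours are normalised counter-clockwise
  (positive shoelace area).
* **Units**: all geometry in pixels, converted once by `scale` (µm/px).
* **Determinism**: there is no randomness anywhere in the measurement path;
  identical input and configuration give bit-identical masks, tables and
  maps. Per-pore records are independent, so any parallel schedule would
  reproduce the same table.
* **min_area** defaults to 5 px²: removes speckle while keeping the
  unreliable-but-measurable 12–15 px regime observable.
* **Degenerate inputs**: all-solid masks yield an empty result with a
  warning (exit 0 at the CLI); 1–2 px components cannot form a polygon and
  are dropped; contours under 8 points skip Fourier smoothing for plain
  linear interpolation (logged).
* **Summary statistics** weight pores equally (not by area); "mean pore
  size" refers to the LSTP radius, with the equivalent diameter reported
  separately.
* **Gaussian histogram fits** (`gaussian_histogram()`) use least squares on
  relative-frequency bins (Freedman–Diaconis by default) and fall back to
  moment estimates when the optimiser leaves the data range (few-bin or
  strongly non-Gaussian samples).

## Problem sizes

The shipped tests and the acceptance script run the full suite at the
validation scale the package targets: shapes of 50–500 px on canvases up
to ~520 px, lattices of a few dozen pores, and 64×64 brute-force oracles.
A 1552×1051 micrograph with a few thousand pores processes in seconds; the
per-pore cost is dominated by the LSTP grid search and scales with contour
length, not image size.

## Known limitations

* Waviness of shapes whose concave arcs reverse the tangent by less than
  `turn_tol` (0.2 rad ≈ 11°) is reported as 1; extremely shallow
  re-entrants are below the estimator's resolution.
* Sub-pixel edge localisation from grayscale gradients is out of scope:
  the mask is the measurement substrate.
* Shapes under ~15 px across carry digitisation errors of several percent
  in every boundary-derived metric.
* The half-pixel LSTP correction assumes the mask's true boundary lies
  mid-crack; for masks produced by morphological erosion/dilation the
  systematic offset differs.
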