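---
title: "Quantifying planar cell polarity: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar cell polarity: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Epithelial planar polarity is read out as the asymmetric distribution of a
junctional protein around each cell: a bipolar enrichment on two opposite
junction sets. At confocal resolution the signal on the two apposed membranes
of a junction is inseparable, so a one-sided (unipolar) enrichment is
indistinguishable from a two-sided one; every method here therefore measures
**bipolarity**, and all polarity angles are axial — defined modulo 180° and
reported in (−90°, +90°], with 0° along the image x-axis and +90° up the
image.

The inputs are a grayscale intensity image and a 1-pixel-wide skeletonized
segmentation of the apical boundaries (produced by external watershed tools;
this package consumes that format). From the skeleton we label the
4-connected complement regions as cells (the boundary network itself is
treated as 8-connected, the standard complementary pairing that prevents
regions from leaking through diagonal gaps), detect the boundary-network
vertices (foreground pixels whose 3×3 neighborhood contains k ≥ 3 other
foreground pixels; rasterization clusters of such pixels are merged at their
mean position), identify edge-sharing neighbors (two cells must co-occur at
≥ 2 boundary pixels, which excludes vertex-only diagonal contact), and filter
image-border and sub-threshold cells before analysis. Cells are filtered
first and adjacency is rebuilt afterwards, so neighbor links into removed
cells disappear.

Every polarity method consumes the same per-cell **angular intensity
profile**: for each boundary pixel (the skeleton pixels 8-adjacent to the
cell region), the mean image intensity in a disk of diameter `thickness`
(default 3 px, roughly a junctional signal width; see "Sampling thickness"
below), the centroid-relative angle θᵢ, the angular midpoint weight dθᵢ
(half the gap to each angular neighbor, summing to exactly 2π), and the
raster arc length dlᵢ. Boundary pixels are ordered by angle around the area
centroid, which equals the traversal order for cells that are star-shaped
about their centroid — true of epithelial apical profiles, but not of
strongly concave outlines, which is a stated limitation.

# The three polarity readouts

**PCA method.** The shape-insensitive readout proceeds in four steps.

1. *Compression.* A direct least-squares ellipse is fitted to the boundary
   (see below); the boundary is rotated so the major axis lies along x,
   scaled along that axis by α = b/a, and rotated back, all relative to the
   centroid. The fitted ellipse of the compressed cell is a circle, so an
   elongated cell is mapped to a regular one while its angular intensity
   pattern is preserved. α is derived per cell from its own fit rather than
   being a global constant: a constant α < 1 would distort regular cells
   along an arbitrary axis. Angles and both weightings are recomputed on the
   transformed coordinates (compression changes angular density, so
   recomputing after the transform is the consistent choice).
2. *Intensity normalization.* I′ᵢ = k·Iᵢ / S(I) with k = 10³ and
   S = the 95th percentile of the sampled intensities. A *scale-type*
   normalizer (a high quantile) rather than the profile mean is essential:
   it leaves the normalized two-level contrast independent of how much of
   the boundary carries peak signal, which is what makes the magnitude
   profile across a coverage sweep rise and fall symmetrically instead of
   being dominated by the changing mean. The 95th percentile is a robust
   maximum — a literal max would be destroyed by a single bright noise
   pixel. The normalization makes the readout exactly invariant to global
   brightness changes and to bit depth (an 8-bit image and its 12-bit
   rescaling normalize identically), which is the purpose of this step.
3. *Embedding.* Each point is placed at its intensity used as a radius:
   (x̂ᵢ, ŷᵢ) = I′ᵢ (cos θᵢ, sin θᵢ).
4. *Eigen readout.* With σ the dθ-weighted covariance matrix of the cloud
   (weighted means subtracted) and eigenvalues λ₁ ≥ λ₂, the raw magnitude is
   **p = λ₁ − λ₂** and the angle is ½·atan2(2σ_xy, σ_xx − σ_yy), the
   principal-axis direction. A homogeneous distribution gives λ₁ = λ₂ and
   p = 0 with an undefined (NA) angle; the difference grows with bipolarity.
   The difference λ₁ − λ₂ is used rather than the normalized ratio
   (λ₁ − λ₂)/(λ₁ + λ₂): the ratio form is scale-free, which would make the
   intensity normalization pointless, and it saturates quickly as the
   peak-to-base contrast grows, compressing exactly the dynamic range the
   method is meant to resolve. With the difference form, the magnitude grows
   smoothly (approximately like 1 − (base/peak)²) over the full contrast
   range and the coverage response is symmetric about half coverage.

**Fourier Series method.** The second-harmonic tensor of the profile:
Q₁ = Σᵢ Iᵢ dlᵢ cos 2θᵢ / N, Q₂ = Σᵢ Iᵢ dlᵢ sin 2θᵢ / N with N = Σᵢ Iᵢ dlᵢ;
p = √(Q₁² + Q₂²) ∈ [0, 1-ish], angle = ½·atan2(Q₂, Q₁). The weights here are
per-pixel arc lengths, *not* the angular weights: this is the classical
pixel-sum construction, and it is deliberately retained because the
resulting density weighting is precisely why this method responds to cell
eccentricity (junctions close to the centroid contribute more boundary
pixels per unit angle). Using dθ weights instead would make the method
nearly shape-insensitive and erase the documented contrast with the PCA
readout.

**Ratio method.** The profile is linearly interpolated onto a uniform
angular grid (`resample_step`, default 1°), a square-wave template of four
90° bins is rotated over trial angles φ (`angle_step`, default 1°; 90° is a
full period because opposite bins pair up), and at each φ the asymmetry is
(mean of bin φ + mean of bin φ+180°) / (mean of bin φ+90° + mean of bin
φ+270°), oriented to be ≥ 1 and rounded to a precision of 10⁻³. The raw
magnitude is the maximum asymmetry (1 = unpolarized) and the angle is the
circular mean, on doubled angles, of all trial angles attaining the rounded
maximum. Quadrant means over the uniform grid are angle-domain means, which
keeps the readout independent of junction length; the rounding-and-ties rule
matters because the asymmetry is *exactly constant* over a range of trial
angles whenever the enriched region fits strictly inside a quadrant — the
tie set then spans a plateau and its circular mean recovers the center. A
degenerate consequence, visible in the noise simulations: any perturbation
that breaks the ties lets the maximizer land anywhere on that plateau, so
the angle readout of this method carries an intrinsic uncertainty of about
the plateau half-width (±15° for a peak spanning a 60° sector).

**Normalization across a dataset.** Raw magnitudes live on method-specific
scales. `normalize_across_dataset()` maps them onto [0, 1] per method within
an image (p/max for PCA and Fourier; (r−1)/max(r−1) for Ratio). Per-image
normalization is the default; for cross-image comparisons normalize over the
combined table instead.

# Morphology

* **Area** is the pixel count of the labeled region; **perimeter** is the
  path length of the region's own ordered contour (diagonal steps √2) —
  not of the surrounding skeleton ring, which runs about one pixel outside
  and would systematically overestimate.
* **Ellipse fit**: the numerically stable direct least-squares conic fit
  with the ellipse constraint 4AC − B² = 1, so noisy rasters cannot return
  hyperbolas. Before fitting a traced boundary, the ordered loop is smoothed
  with a 7-px circular moving average: raster edges carry a deterministic
  half-pixel placement error which otherwise inflates the apparent
  eccentricity of near-circular cells (ε is a square-root function of the
  axis ratio, so a 1% axis error already reads as ε ≈ 0.15 — this residual
  floor on raster data is a real limitation near ε = 0 and is why the
  generator's ground-truth eccentricity is measured on the continuous
  outline).
* **Eccentricity** ε = √(1 − b²/a²); **orientation** is the major-axis
  angle.
* **Regularity** μ ∈ [0, 1] scores equilateral and equiangular deviation of
  the cell polygon: with chord lengths lᵢ (median l_med, total l_Σ) and
  interior angles φᵢ, D = Σ|lᵢ − l_med|/l_Σ + mean(|φᵢ − φ_reg|)/φ_reg,
  φ_reg = (n−2)π/n, and μ = max(0, 1 − D). The exact functional form is this
  package's own construction from those named ingredients; treat μ as
  method-internal rather than comparable across tools. The polygon is taken
  at lattice vertices when ≥ 3 lie on the loop; isolated cells fall back to
  geometric corner detection (closed-loop Douglas–Peucker at `corner_tol`,
  default 1.5 px, followed by pruning of corners whose removal changes the
  polygon by less than the tolerance). Edge lengths for μ and junction
  counting are vertex-to-vertex chords; raster path lengths would make
  pixel-level staircase noise dominate.
* **Junction count**: edges shorter than 10% of the cell's mean edge length
  are not counted as sides; for interior cells the count equals the number
  of neighbors.

# Tissue statistics

All tissue statistics treat angles as axial by doubling them.
`average_magnitude` ignores angles; `vector_average` averages the axial
vectors (p cos 2θ, p sin 2θ) and is ≤ the average magnitude with equality
iff all angles agree; `coarse_grain` tiles the centroid cloud into balanced
spatial groups of ≈ `group_size` cells (more columns along the cloud's wider
axis — the partition rule is a package choice, since only "equal-count
groups" is specified by convention); `neighbor_vector` runs the vector
average over each cell plus its immediate neighbors and averages the local
magnitudes; `angle_variance` is 1 − |mean(exp(2iθ))| ∈ [0, 1];
`mean_angle_difference` is the mean axial angle difference (≤ 90°);
`weighted_circular_histogram` duplicates each axis at θ and θ+180°, bins
into 20 closed-left bins from 0°, and weights each bin's frequency by its
mean magnitude.

# The synthetic-cell generator

`synthetic_cell()` builds single rasterized polygonal cells with exact
ground truth; these are the validation conditions for the methods, not
simulations of real tissue. Defaults are the standard study conditions: a
regular hexagon of perimeter 440 px, two intensity levels (peak 255 a.u.,
base 40 a.u.), 8-bit range.

* *Geometry*: regular n-gon (n = 6), oriented with one edge centered on
  each x-pole, so the "vertical junctions" are the two edges whose outward
  normals lie within 45° of the x-axis. Shape regularity targets are reached
  by seeded vertex jitter with bisection on the jitter amplitude; the jitter
  is mirror-symmetric about the x-axis so the fixture's ground-truth
  polarity axis stays exactly 0° (an asymmetric perturbation would move the
  true axis itself, confounding angle checks). Eccentricity targets are
  reached by the area-preserving stretch (x·s, y/s), s = (1 − ε²)^(−1/4),
  refined against a dense-outline ellipse fit; the same normalization is
  applied at target 0 to remove the net anisotropy of a jitter draw, so the
  geometric factors vary one at a time. Because regularity and eccentricity
  interact, the jitter is re-targeted against the composite for a few
  rounds (tolerances: ε within ±0.02, μ within ±0.02, area within ±5%).
  Elongation is along the polarity axis, the direction epithelial cells
  elongate relative to their polarity in the motivating tissues.
* *Intensity models*: `two_level` paints peak on a placement (whole
  vertical/horizontal junction edges, an axial angular sector, or `coverage`
  perimeter-px grown symmetrically from the two x-pole points of the
  outline); `puncta` paints Gaussian bumps (floor = base, amplitude = peak)
  centered every 15° along the boundary, keeping only puncta whose centers
  lie on the peak placement — a punctate version of the two-level cell with
  the same ground-truth axis. The Gaussian σ (default 4.47) is interpreted
  in **degrees** (converted through perimeter/360): with σ in arc pixels the
  angular profile would depend on cell size and even the size-insensitive
  methods would read different polarities across an area sweep, which
  contradicts the methods' documented behavior; px units remain available.
  Punctum centers are offset by half a spacing so none sits exactly on a
  polygon vertex, a degenerate alignment whose include/exclude status would
  otherwise flip with rounding across cell sizes.
* *Rasterization*: the outline is rasterized as a thin 8-connected loop
  (the skeleton), and the intensity image is a band of width `band`
  (default 5 px) around the continuous outline in which each pixel takes
  the intensity of its *nearest* outline sample, so model borders land on
  geometric bisectors without traversal-order bias. The band is wider than
  the default sampling disk so that sampled profiles reproduce the specified
  intensity model up to border anti-aliasing. Images are rounded to integer
  intensities and clipped to the bit range.
* *Noise*: `add_noise()` adds zero-mean Gaussian noise with sd = (mean
  junctional signal)/SNR, clipped to the bit range, deterministic given the
  seed.

What the generator does **not** emulate: multicellular packing and shared
junctions (each fixture is one cell), point-spread blur, photobleaching,
background autofluorescence, and genuinely concave or multinucleate cell
shapes. Passing the synthetic suite therefore demonstrates correctness of
the readouts under controlled geometry and signal structure, not performance
on any particular microscope's data.

# Sampling thickness

The junction sampling width on real images is a free parameter. The package
default is 3 px (a typical junctional signal width at high-NA confocal
sampling). Sensitivity, measured on the synthetic suite: a 1-px centerline
sampling removes a small-cell artifact (on a 1,500-px² cell a 3-px disk
spans ≈ 7° of boundary and smooths punctate profiles noticeably, moving the
PCA magnitude by several percent across an area sweep) but is markedly less
robust for the PCA readout at low SNR, where the disk average suppresses the
noise entering the covariance and the quantile normalizer. Conclusions that
depend on punctate structure at small cell sizes should check both settings.

# Numerical choices and degenerate inputs

* Angular weights use the circular midpoint rule and are renormalized to sum
  to exactly 2π; profiles need ≥ 3 points.
* All-zero intensity profiles are errors ("degenerate signal"), not zero
  readouts; a homogeneous profile returns p = 0 (PCA/Fourier) or asymmetry
  1 (Ratio) with an NA angle rather than a fabricated 0° axis.
* The Ratio scan skips trial angles with a zero-denominator pair and errors
  only if every trial angle is undefined.
* Ellipse fitting requires ≥ 6 non-collinear points; collinear input is an
  error. The eigenvector with 4AC − B² > 0 is selected, guaranteeing an
  ellipse.
* Complement regions touching all four image sides are background, not
  cells; regions touching at least one side are flagged image-border cells.
* Ties in the Ratio maximizer set are resolved by the circular mean on
  doubled angles; ties in quantiles follow the default type-7 rule.

# Problem sizes used by the test suite

The shipped tests and the acceptance script regenerate all fixtures in code:
single cells with perimeters 200–440 px and areas 1,500–46,000 px² (the
sweep ranges above), an eccentricity grid 0–0.8 in steps of 0.1, a
regularity grid 0.5–0.85 in steps of 0.05, an SNR grid {15, 10, 5, 3} with
20 noise replicates per level, and small square-grid tissues for the
segmentation and tissue statistics. The full suite runs in well under a
minute on one CPU.

# Known limitations

* Boundary ordering assumes star-shaped cells; strongly concave cells would
  need a true contour walk.
* Raster eccentricity has a ≈ 0.15 noise floor near circularity
  (half-pixel edge placement); compression is insensitive to this (α stays
  ≈ 1) but reported ε of near-circular cells should be read with that floor
  in mind.
* The Ratio method's angle carries the tie-plateau uncertainty described
  above whenever the enrichment fits inside one quadrant pair.
* μ (regularity) values are internally consistent but not comparable with
  other tools' regularity scores.
* Tricellular-junction enrichment is not a supported signal model: none of
  the three readouts is suited to it, and the generator does not emulate it.
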