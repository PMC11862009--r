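---
title: "Models and methods: nuclear confinement, HP1 condensates, and confined polymer simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleoscope)
```

# Scope

`nucleoscope` reimplements, as a tested pipeline driven entirely by synthetic
data, the computational analysis of nuclei under mechanical confinement:
3D morphometry of nuclei and their HP1α condensates, condensate tracking and
anomalous-diffusion analysis, FRAP recovery fitting, and a ChIP-weighted
confined bead-spring chromosome model with condensate clustering. No raw
microscopy or ChIP-seq download is required: every input the pipeline
consumes can be generated with known ground truth.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the places where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# Synthetic data: the stated world

## Nucleus phantoms

`gen_nucleus_stack()` renders an ellipsoidal nucleus (semi-axes in µm,
arbitrary orientation) on an anisotropic voxel grid, default
0.08 × 0.08 µm laterally and 0.14 µm axially — the z-step used for the
live-cell stacks the package emulates. Condensate spots are **uniform
spheres** of the stated diameter placed strictly inside the ellipsoid with a
minimum pairwise separation (rejection sampling, 10,000-attempt cap). The
rendered scene is blurred with an anisotropic Gaussian PSF (default
σ = 0.06 µm lateral, 0.15 µm axial; Airyscan-scale resolution) and
corrupted with Poisson shot noise plus Gaussian read noise. SNR is defined
as (spot peak − nucleoplasm level) / nucleoplasm-noise SD.

Two deliberate choices:

* **Solid spots, not Gaussian blobs.** For a Gaussian intensity profile the
  volume above a threshold depends strongly on where the threshold lands on
  the profile skirt — skirt voxels outnumber core voxels, the Otsu threshold
  settles at roughly a quarter of the amplitude, and the "measured diameter"
  becomes a measurement of the threshold, not of the object (≈1.5× the
  nominal FWHM). A dense condensate body with a boundary, convolved with the
  PSF, keeps the within-nucleus histogram bimodal, puts the threshold near
  half-amplitude, and makes the threshold-equivalent diameter track the
  stated size. The residual bias is about +4% (PSF smear at a sub-half-max
  threshold), within the 10% recovery tolerance the tests enforce.
* **Two seeds.** `geometry_seed` fixes spot placement (the ground truth);
  `seed` fixes the noise realization. The same phantom geometry can thus be
  imaged under independent noise draws, and detection-count stability across
  noise is testable without re-randomizing the scene.

What the phantoms do **not** emulate: Airyscan optics and deconvolution
artifacts, chromatin texture (the nucleoplasm is uniform), spot brightness
heterogeneity, and z-dependent aberrations. A green detection test therefore
establishes correctness of the labeling algorithm on well-posed scenes, not
robustness to every real-microscopy pathology.

## Tracks, FRAP curves, ChIP-like signal

* `gen_tracks_fbm()` draws 2D fractional Brownian motion by Cholesky
  factorization of the exact fractional-Gaussian-noise covariance,
  independently per axis, so `E[MSD(t)] ∝ t^(2H)` exactly and the
  ground-truth anomalous exponent is `α = 2H`.
* `gen_frap_curve()` samples the single-diffusion recovery model (below),
  optionally multiplied by `exp(-k t)` to emulate acquisition bleaching,
  plus Gaussian noise.
* `gen_chip_track()` produces a 1-Mb-binned nonnegative signal with
  contiguous on/off domains (two-state Markov chain; geometric domain
  lengths, default mean 5 Mb on, stationary bound fraction 0.4 — typical of
  H3K9me3 domain organization in fibroblasts) and one log-normal intensity
  per domain. Zero bins mark monomers with no HP1 binding. The default five
  arms (chr8p, chr13q, chr14q, chr19p, chr22q) use lengths
  44 + 92 + 84 + 22 + 16 = 258 Mb; the total is fixed by the model size,
  the per-arm split is a configuration value because no per-arm bin counts
  are published.

# Morphometry

Segmentation is anisotropy-aware Gaussian blur (default σ = 0.1 µm,
converted per axis to voxels) followed by Otsu thresholding and 26-connected
component labeling; the largest component is the nucleus unless multi-nucleus
mode is requested.

Principal axis lengths are measured by mapping voxel centers to physical
coordinates, centering, rotating into the principal frame (eigenvectors of
the coordinate covariance), and taking extents plus the voxel footprint
projected on each direction. Along the minor (confinement) axis a
`trim_fraction` (default 0.001, i.e. 0.1% of voxels from each extreme) is
removed by quantile clipping before the extent is taken, suppressing
single-voxel irregularities. Note the quantile is slice-discrete: trimming
can remove at most about one voxel slice, so trimmed and untrimmed extents of
a clean body agree to a slice, and an axis sampled at the 0.14 µm z-pitch
carries an irreducible ±1-slice uncertainty. This is why the acceptance
tolerance on a 2.57 µm height is one z-step, not a blanket 2%.

Shape descriptors:

* `elongation = 1 − sqrt(intermediate / major)`
* `flatness = 1 − sqrt(minor / major)` (1 = flat plane)
* `sphericity = (36 π V²)^(1/3) / A` (1 = perfect sphere)

`V` is voxel count × voxel volume. For `A` two estimators exist: summing
exposed voxel faces (the literal voxel-counting convention) overestimates
curved surfaces by a staircase factor of about 1.5, which would make the
sphericity of a true sphere ≈ 0.67; the default is therefore a
marching-tetrahedra isosurface (Kuhn 6-tetrahedron cube decomposition) of the
lightly smoothed mask at iso 0.5, accurate to well under 3% on spheres at
r ≥ 20 voxels. The voxel-face estimator remains available as
`area_method = "voxel_faces"`.

The main-text description of flatness (square root of the minor/major ratio)
and the methods formula (1 minus that square root) disagree in direction;
only the latter increases under confinement and reaches 1 for a plane, so
the package implements it.

# Condensate detection and spatial statistics

`detect_condensates()` implements eroded-Otsu labeling: Gaussian blur → Otsu
threshold computed over the nucleus interior → binary erosion (6-connected
cross, default 2 iterations) → 26-connected labeling → constrained
re-expansion of each label within the un-eroded mask (multi-source BFS, no
label merging) → drop objects under `min_voxels` (default 5). Equivalent
diameter is `(6V/π)^(1/3)`.

The condensate-detection blur defaults to 0.05 µm — below the lateral PSF —
because the object mask is measured on the blurred image: smoothing beyond
the optical scale inflates the threshold-equivalent size of spot-scale
objects (nucleus segmentation keeps its own 0.1 µm default). Erosion is
anisotropy-aware: z erosions are scheduled so the removed depth stays
approximately isotropic in micrometres (at the default 0.08/0.14 µm pitch,
two xy erosions and one z erosion), since two isotropic-in-voxel erosions
would remove 0.28 µm axially and can delete a 0.6 µm object outright —
defeating the stated purpose of the default (splitting touching spots
without deleting paper-scale objects).

Three guards make the data-driven threshold well-posed:

* the threshold is computed on the interior excluding a boundary margin
  (default 0.3 µm): the blurred nucleus edge forms an intensity ramp that
  otherwise dominates the histogram and Otsu splits edge-versus-interior
  instead of nucleoplasm-versus-condensate;
* an Otsu split always exists, even on featureless noise, so the threshold
  must clear the nucleoplasm median by `min_contrast` (default 4) robust
  SDs (MAD), otherwise the result is empty. This is what makes "zero spots →
  zero detections" true;
* because condensates occupy well under 1% of the nuclear volume, a single
  Otsu split occasionally settles on the nucleoplasm noise; the threshold is
  therefore applied iteratively (Otsu on the values above a rejected
  threshold, at most two retries), the standard remedy for strongly
  imbalanced foregrounds.

Radial and peripheral statistics follow the figure conventions: the radial
distance from the condensate center to the nucleus center is scaled by the
nucleus diameter, and the minimum Euclidean distance to the periphery — the
outer 0.05-fraction EDT shell of the nucleus — is scaled by the nucleus
height (minor axis). "Nucleus diameter" is not defined in the source
methods; the default is the volume-equivalent spherical diameter
`(6V/π)^(1/3)`, well-defined for arbitrary shapes, with the major axis
available behind a flag.

Radius-matched controls: for each condensate the nucleus mask is eroded by
that condensate's radius (EDT threshold in µm) and one voxel is sampled
uniformly from the eroded region; if the region is empty the EDT-argmax
voxel is used with a warning. Each condensate consumes an independent
sub-seed derived from the run seed by a counter scheme, so extending a
record set never reshuffles earlier controls. For zero-radius condensates in
a sphere the mean scaled radial distance converges to 3/8 (uniform-in-ball
`E[r] = 3R/4`, divided by the diameter), which the tests verify.

Mander's M1 is the intensity of channel A inside both channels' objects over
the intensity of channel A inside its own objects.

# Tracking and anomalous diffusion

Linking minimizes total squared displacement per frame pair by an exact
Jonker–Volgenant-style linear assignment over a padded cost matrix with
birth/death alternatives priced at the cost cutoff; links with squared
distance above `cost_cutoff` (default 16,900, i.e. a 130-pixel gating
radius — the units are squared distances in whatever unit the detections
use) are forbidden. A track starting at frame t is assigned a parent if some
track terminated at frame t−1 within `split_cutoff` (default 100). Nucleus
motion is removed by subtracting the per-frame nucleus center.

MSD uses the reference-point form — each condensate's squared displacement
from its own first position, averaged across condensates per lag, SD across
condensates — with a time-averaged variant behind a flag. The anomalous
exponent is the slope of the least-squares line on (log t, log MSD) over
lags within the fit window (default the first 7 h). On ensembles of 200
tracks × 30 steps this estimator scatters by about ±0.03 (SD) around 2H,
which is why single-ensemble tests use a ±0.05 band and the property test
averages a few ensembles.

# FRAP

Normalization is double: the ROI trace is divided by the reference trace
(removing acquisition bleaching exactly when both bleach proportionally) and
scaled so the pre-bleach level is 1. The recovery model is

F(t) = (F0 + F∞ (t/t1)/2) / (1 + (t/t1)/2)

fitted by bounded nonlinear least squares (`port`), with a logarithmic
multi-start grid over `t1` because the profile likelihood is flat at the
extremes. Under this model the half-recovery time — where F crosses
(F0 + F∞)/2 — is analytically `2 t1`; both `t1` and `t_half` are reported,
as is the immobile fraction `1 − F∞` and the mean of the last 5% of frames
(the "last-frame" plateau reading, since published recovery maxima may be
either). The printed acquisition interval ("0,002101 s" for 600 frames) is
kept as a configurable default and flagged as a likely transcription
ambiguity; the fit itself is invariant to time rescaling up to `t1` units.

# Confined polymer model

Kremer–Grest bead-spring chains in reduced units (σ = monomer diameter =
1 Mb of chromatin, kBT = 1, τ = 1): FENE bonds
(`k = 30 ε/σ²`, `R0 = 1.5 σ`) with a WCA core, bending penalty
`k_θ (1 − cos θ)` with `k_θ = 1`, and Lennard-Jones attraction between
HP1-bound monomers with `ε_ij = sqrt(ε_i ε_j)` (geometric mixing preserves
zero for unbound partners), truncated and shifted at 2.5 σ; all other pairs,
and the wall, are WCA. Per-monomer ε comes from the 1-Mb signal:
`ε_i = level_scale × signal_i / mean(positive signal)`, so relative values
equal the signal ratios exactly and the level (E1..E4 = 0.5, 1.0, 1.5,
2.0 kBT on the mean) sets only the absolute scale, bracketing the
phase-separation onset for bead-spring melts. No direct mapping between
ChIP enrichment and kBT exists, so these scales are configuration, not
reconstruction.

**Local stiffness and the Kuhn length.** The model is stated to be
equivalent to a worm-like chain with Kuhn length 2 σ at `k_θ = 1`, i.e.
`⟨cos θ⟩ = coth(1) − 1 ≈ 0.313` and
`l_k = l_b (1+⟨cos θ⟩)/(1−⟨cos θ⟩) ≈ 1.9 σ`. That mapping holds only if the
bond angles are governed by the bending term alone: WCA repulsion between
1-3/1-4/1-5 neighbors along the contour forbids back-folded angles and
stiffens the chain to l_k ≈ 2.8 σ. The engine therefore excludes nonbonded
interactions between monomers within four bonds along a chain (bonded pairs
interact through FENE+WCA; distant pairs keep full excluded volume),
yielding l_k ≈ 2.1 σ. The residual ⟨cos θ⟩ bias (~+0.04 from 1-6 and
further neighbors) is documented in the tests.

The confinement shell solves `V = n (π/6) σ³ / φ` at the shape's aspect
ratio (sphere, oblate c/a = 1/2, oblate c/a = 1/3; all three shapes hold the
same volume at fixed φ = 0.10, the chromatin volume fraction of human
nuclei). Wall monomers (diameter σ, zero dynamics — rigid confinement) are
placed by a Fibonacci lattice mapped to the spheroid at surface density
≥ 1.2 σ⁻²; the build fails if the worst nearest-neighbor spacing exceeds
σ (a leaky wall).

Dynamics: BAOAB Langevin splitting at kBT = 1, default `dt = 0.01 τ`,
`γ = 1/τ`, with a deterministic counter-based RNG (PCG32) so trajectories
are bit-identical per seed on any platform. Initial states are grown as
self-avoiding random walks (bond 0.97 σ, no pair closer than 0.8 σ) strictly
inside the shell and relaxed by a two-stage soft-potential push-off. A
Verlet neighbor list (skin 0.5 σ, short list radius for WCA-only pairs,
cached wall binning) keeps force evaluation O(N); an exact all-pairs
route exists implicitly through the energy functions used by the tests.
FENE overstretch aborts the run with diagnostics. Every sampled frame logs
energies, bond statistics and the count of monomers outside the shell
(asserted zero in the tests).

# Condensates in simulations

Bound monomers (ε > 0) of each sampled frame are clustered by single-linkage
agglomerative clustering; candidate cuts are the distinct merge heights, the
cut maximizing the mean silhouette coefficient is chosen (ties toward fewer
clusters; sklearn convention, singletons score 0), and if no cut achieves a
positive silhouette all monomers form one cluster. Clusters of at least
`min_size = 3` monomers count as condensates (a bonded pair is trivially
within linkage distance). An exhaustive-cut oracle (graph threshold
components, no `hclust`) verifies the selected partition exactly for
n ≤ 30.

One caveat found empirically: *sparse uniform* point sets do **not**
generally fall back to a single cluster — single-linkage cuts that isolate
chance clumps achieve genuinely positive silhouettes. The fallback applies
when no positive-silhouette cut exists (e.g. symmetric degenerate
configurations), and the tests exercise it on such a case.

Normalized positions: `R = |centroid − center| / a` (semi-major axis, the
stated convention) and `P` = distance to the nearest point of the spheroid
surface (1D numerical minimization in the meridian plane) divided by `c`.
A second convention, `normalization = "ray"` (distance as a fraction of the
shell radius along the centroid's direction; identical for spheres), is
provided because the semi-major convention makes identically-distributed
material score lower R in flatter shells for purely geometric reasons
(uniform mass in an oblate with c/a = 1/3 has `E[|r|]/a ≈ 0.59` versus 0.75
in a sphere), which matters when comparing shapes.

## The scaled-down shape-trend experiment

The headline qualitative claim — condensates sit more centrally in flattened
shells, increasingly so at stronger attraction, with shape-independent
counts — is probed by a desk-scale grid: 10 seeds × {sphere, oblate 1/3} ×
{E1, E4}, with 6×10⁴ + 4×10⁴ steps for E1 and 1.5×10⁵ + 5×10⁴ steps for E4
(deeper quenches equilibrate more slowly) at γ = 0.1 for faster positional
sampling. These step counts are orders of magnitude below a converged
production study. Pilot grids showed that the slow mode is lateral
coalescence and centering of condensates in the oblate shell (length scale
a ≈ 9.9 σ versus 6.9 σ in the sphere), with large seed-to-seed variance:
individual oblate runs that do reach the collapsed state score markedly
lower R than spheres, while laggards score higher. At this scale the
first clause of the trend is borderline and the "gap grows from E1 to E4"
clause is not attainable — at E1 the apparent gap is dominated by geometry
and wall depletion rather than by attraction. The acceptance test states
the full property faithfully and is expected to be partially red; the
decisions ledger carries the analysis.

# Statistics

Two-sided Mann–Whitney tests: exact U distribution when min(n, m) ≤ 8 with
no ties, otherwise the tie-corrected normal approximation with continuity
correction; a fully tied pooled sample reports p = 1. Stars follow the
printed thresholds (`*` 0.01 < p ≤ 0.05 down to `****` p ≤ 1e-4, `ns`
above). Boxplot summaries use median, quartiles and 1.5 × IQR whiskers.
KDE uses a Gaussian kernel with Scott's-rule bandwidth and a bandwidth
floor (with warning) for zero-variance input. The observed-versus-control
distribution comparison additionally reports a KS statistic, labeled as an
extension beyond the purely visual published comparison. No
multiple-testing correction is applied anywhere, matching the source
analysis.

# Reproducibility contracts

Every generator and the simulation engine are pure functions of their
configuration plus seed (bit-identical reruns). Sub-seeds are derived by a
documented counter scheme (`master × 10007 + index mod 2³¹−1`) so grids and
record sets are extensible without reshuffling. Run configuration is JSON
(the environment provides no TOML parser; `jsonlite` is the one
serialization dependency), every pipeline output embeds the configuration
MD5 hash, and tables round-trip CSV at 17 significant digits. TIFF I/O is a
minimal uncompressed little-endian codec (32-bit float, JSON ImageDescription
metadata) written for this package because the deployment environment has no
TIFF library; files without voxel-size metadata are an explicit error, never
a silent default.

# Known limitations

* Surface areas and axis extents carry voxelization uncertainty of order one
  voxel; sub-voxel boundary estimation is out of scope.
* The diameter recovered by eroded-Otsu labeling carries a small positive
  bias (about +4%: PSF smear at the data-driven threshold), within 10% at
  the default optics but not corrected.
* The polymer engine targets canonical sampling, not real-time dynamics;
  friction is a sampling knob, and no hydrodynamics, replica exchange or
  explicit HP1 particles are modeled.
* Desk-scale simulation grids are far from coalescence equilibrium; only
  trends robust at that scale can be asserted, and the tests say which ones
  are not.
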