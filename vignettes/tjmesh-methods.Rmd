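---
title: "Methods: quantifying tight-junction meshworks and their ion permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tight-junction meshworks and their ion permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjmesh)
```

## The problem

Claudins polymerize into ~10 nm strands that interweave into tight-junction
(TJ) meshworks at epithelial cell–cell contacts. Different claudins build
morphologically different meshworks, and co-expressed claudins organize at
the nanoscale in characteristic ways — from complete intermixing to strict
segregation into alternating single-claudin strand segments. Because
channel-forming claudins conduct specific ions through their strands while
barrier-forming claudins seal, this nanoscale organization has direct
electrophysiological consequences. `tjmesh` provides the measurement side
of this biology: objective classification of meshwork morphology from
super-resolution images, quantification of two-channel co-organization,
strand-width measurement, and the permeability calculations for
Ussing-chamber experiments.

STED images of such meshworks carry a practical constraint that shapes the
design throughout: low photon counts, ~50 nm lateral resolution, 8-bit
quantization, and pixel sizes near 19–20 nm. All defaults below are chosen
for that regime.

## Texture features

Images are smoothed with a 3×3 kernel sampled from a σ = 1 px Gaussian and
renormalized to sum 1 (reflected borders), then gray-level co-occurrence
matrices (GLCMs) are computed at distances 1, 3, 5 and 10 px — probing
intensity covariation across 20–200 nm — in the four standard directions.
Three Haralick statistics are kept, each averaged over the directions: sum
average, sum variance, and variance (sum of squares). With 1-based
gray-level indexing,

$$f_{SA} = \sum_k k\,p_{x+y}(k), \qquad
  f_{SV} = \sum_k (k - f_{SA})^2\,p_{x+y}(k), \qquad
  f_{VAR} = \sum_{i,j} (i-\mu)^2\,p(i,j).$$

Decisions the data format forced: 8-bit images are used at their native
256 levels; higher-bit-depth input is linearly rebinned to 256 levels.
GLCMs are accumulated symmetrically (each ordered pair counted in both
directions) and normalized to sum 1. Only relative feature values matter
downstream (columns are rescaled before clustering), so the 1-based index
convention is a labeling choice, not a science choice. The implementation
is verified against a brute-force pair-enumeration oracle to 1e-10.

## Segmentation and morphometry

Strands are enhanced with a multiscale curvilinear (tubularity) filter: at
each scale $r$ the scale-normalized Hessian of a Gaussian of σ = r px is
applied (the smoothed-Hessian formulation of oriented gradient flux
through a circle of radius r); the response is the negated smaller
eigenvalue clamped at 0, maximized over scales. Scales default to
r ∈ {2, 3, 4} px, bracketing a strand FWHM of ≈ 3 px at 20 nm/px. The
truncated derivative kernels are zero-sum corrected so constant images
produce exactly zero response.

A fixed threshold then binarizes the response and only the largest
8-connected component is kept (ties broken by first topmost-leftmost pixel
in row-major scan order; an all-below-threshold ROI is returned flagged
empty rather than as an error so the quality filter can drop it). The
fixed threshold itself is not a universal constant of the method; to make
it reproducible the package freezes the mean Otsu threshold of the
tubularity responses over a calibration set (`calibrate_threshold()`) and
applies it unchanged to every image of an analysis. Single-image use falls
back to the per-image Otsu threshold.

The mask is thinned (Zhang–Suen) to a 1-px 8-connected skeleton and
decomposed into a graph: pixels with ≥ 3 skeleton neighbours are junction
pixels, merged into junction clusters when adjacent; pixels with exactly
one neighbour are endpoints. Branches are walked between node pixels;
branch length sums the inter-pixel steps (1 or √2 px) times the pixel
size. Two conventions are fixed and documented because the measurement
literature varies: branches begin at the junction-cluster rim (steps
interior to a cluster belong to no branch), and junction multiplicity is
the number of incident branches (3 → triple, 4 → quadruple). Meshes are
the 4-connected components of the inverted mask that do not touch the ROI
border (8-connected mask with 4-connected background is the standard
complementary pair avoiding topological paradoxes); areas convert to nm²
via the squared pixel size. The quality filter keeps ROIs with 10 % ≤
segmented area ≤ 90 % (boundary values inclusive — the exclusion rules are
strict inequalities) and ≥ 10 branches.

## Classification

Per-ROI rows are aggregated per sample by arithmetic mean; the combined
analysis uses the 12 texture plus 10 morphometry features, the
texture-only analysis the 12 texture features. Cells are transformed by
ln(x+1) — rather than ln(x), because morphometry counts can be 0 — and
each column is centered and scaled to unit variance (constant columns are
zeroed with a warning). Clustering is agglomerative with average linkage
under correlation distance (1 − Pearson between rows) for the combined
analysis, euclidean distance for the texture-only analysis. Tie-breaking
among equal merge candidates follows the clustering library; the oracle
tests use continuous features where ties have probability zero.

A dendrogram does not by itself choose a cluster count, and a visual cut
is not reproducible, so the package cuts at each candidate k and keeps the
assignment maximizing the mean silhouette width under the same distance
(ties to the smallest k). On synthetic three-class libraries this selects
k = 3.

## Colocalization and strand widths

Costes thresholding: the ch2-vs-ch1 relation is fit by orthogonal (total
least squares) regression; T1 descends the sorted unique ch1 intensities
(an exact discrete search, not a fixed step) with T2 = a·T1 + b until the
Pearson of the pixels below both thresholds reaches ≤ 0. The coefficient
is then computed over pixels above threshold in either channel (the OR
rule; AND is available via a flag since conventions differ between tools).
If the global Pearson or the regression slope is non-positive there is no
meaningful threshold pair: the thresholds fall to the channel minima and
the reported coefficient is the global Pearson, which preserves the
negative values that signal segregation or exclusion. One behaviour of the
OR rule worth knowing: on channels with no true correlation the union of
"high in ch1 or high in ch2" pixels is anti-correlated by construction, so
weakly-positive-noise inputs can report moderately negative coefficients —
never spuriously positive ones. The `psf_px` parameter (default 2 px) is
metadata for block-scramble significance testing and never changes the
coefficient.

Strand widths: intensity profiles are sampled at 1 px steps along a line
(default 0.3 µm) and averaged across parallel offsets spanning a 10 px
band, with bilinear interpolation; a four-parameter Gaussian is fit by
Levenberg–Marquardt, initialized from the max/argmax/half-range
heuristics, and the FWHM is reported as 2.35·σ — the fixed conversion
factor used for all strand-width numbers. Fits that do not converge or pin
σ at its bounds are flagged rather than reported.

## GHK permeability analysis

For a NaCl dilution experiment the GHK dilution potential is

$$V = \frac{RT}{F}\,\ln\frac{r\,c_{Na}^{baso} + c_{Cl}^{api}}
                            {r\,c_{Na}^{api} + c_{Cl}^{baso}},
  \qquad r = P_{Na}/P_{Cl},$$

with V defined apical minus basolateral; the standard solutions (140 mM
Na⁺/128.8 mM Cl⁻ Ringer basolaterally, 80.5 mM Na⁺/69.3 mM Cl⁻ apically)
have equal Na⁺ and Cl⁻ dilution deltas, so r = 1 gives exactly V = 0 —
this anchors the sign convention. The inverse is closed-form; potentials
outside the two limiting values ((RT/F)·ln(140/80.5) = +14.79 mV and
(RT/F)·ln(69.3/128.8) = −16.57 mV at 310 K) are rejected. For replicate
measurements `estimate_ratio()` minimizes the squared potential residuals
over log r instead of inverting each replicate, which stays well-behaved
when noise pushes individual potentials past a limit.

Absolute permeabilities use the Kimizuka–Koketsu partition of the measured
conductance G = 1/TER:

$$P_{Cl} = \frac{G\,R\,T}{F^2\,(r\,c_{Na} + c_{Cl})}, \qquad
  P_{Na} = r\,P_{Cl},$$

with concentrations (not activities) in mol/cm³ and results reported in
10⁻⁶ cm/s. A blank-resistance subtraction is available but off by
default. Tracer flux uses the ordinary-least-squares slope of the
basolateral concentration over time and
$P_{app} = (dC/dt \cdot V)/(A \cdot C_0)$ with minutes converted to
seconds and ml ≡ cm³; a negative fitted slope is reported with a warning,
not clamped. Single-direction potentials are analyzed; averaging paired
dilution directions is left to the caller.

## Spectral FRET

The measured λ-stack is decomposed by linear least squares onto donor and
acceptor reference emission spectra (unit peak; negative coefficients are
clamped with a refit). The FRET ratio divides the crosstalk-corrected
acceptor emission at the acceptor readout wavelength by the donor emission
at the donor readout wavelength; the directly-excited-acceptor (crosstalk)
coefficient must come from an acceptor-only control and is subtracted from
the unmixed acceptor coefficient. Two instrument presets are provided
(readouts 532/468 nm and 530/478 nm). The bundled reference spectra are
synthetic two-component Gaussian emission models — adequate for testing
the unmixing algebra, not spectra of real fluorophores.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth; its
defaults are the study conditions of the package's tests.

* **Meshwork classes.** Classes A and B are jittered-lattice tessellations
  (a seeded perturbed square lattice partitioned by nearest-seed
  assignment): target mean mesh diameters 600 nm (A) and 250 nm (B),
  lattice jitter 0.2 of the spacing — regular enough that noiseless mesh
  counts are unambiguous, irregular enough to vary mesh areas. Class C is
  rendered as gently crossing near-parallel sinusoids at 150 nm spacing;
  the occasional crossings make the strand network connected, as dense
  parallel TJ networks are. Non-meshwork phenotypes (uniform, punctae,
  clusters) are provided for the texture-only analysis.
* **Rendering.** Strand centerlines are 1 px rasterized curves; the
  Gaussian strand cross-section (σ 14 nm) and Gaussian PSF (σ 21 nm,
  ≈ 50 nm FWHM) compose analytically into a single Gaussian of
  σ = √(14² + 21²) ≈ 25 nm evaluated on the distance transform of the
  centerline, giving rendered strands of ≈ 59 nm FWHM — the measured
  width of fixed claudin strands. The identity FWHM = 2.35·√(σ_strand² +
  σ_PSF²) is exact for straight strands and holds to ≈ 1 % for rasterized
  oblique ones.
* **Noise.** Poisson photon counts (peak expectation `photon_scale`,
  default 50) plus additive Gaussian read noise (SD 1 count), clipped at
  0 — the standard photon-counting model for STED detectors.
* **Two-channel modes.** Intermix, integrate and induction render the same
  centerlines into both channels with independent noise — the distinction
  between those three patterns is biological (which claudin can polymerize
  alone), not geometric, so one geometry serves all three. Segregate
  partitions every tessellation edge into alternating single-channel runs
  of 500 nm (a free parameter: tissue strand segments vary widely, and the
  rendered strand FWHM is a hard lower bound). Exclude builds two
  independent tessellations in opposite image halves.
* **Ground truth.** Tessellation truth reports the interior cells (no
  pixel on the image border) to match the border exclusion of the mesh
  measurement. Truth areas are tessellation cell areas; measured mesh
  areas are strand-interior areas, systematically smaller by about one
  strand-width band, so truth-vs-expected comparisons use a 15 % band.
  Mesh recovery is validated by overlap correspondence
  (`mesh_correspondence()`) rather than raw counts: the segmented strand
  band is thicker than the half-maximum truth band, so a cell that opens
  onto the image border through a narrow gap can be sealed shut by
  segmentation and appear as an extra enclosure at the border — a
  finite-field-of-view effect, reported separately from genuine merges,
  splits, or spurious interior detections. On noiseless renders every
  true mesh at least 5x the strand width is recovered one-to-one.

What the generator does not emulate: labeling noise and antibody size,
strand curvature at the 10 nm polymer scale, depth-dependent blur,
detector afterpulsing, vesicular/ER background, or time-lapse dynamics.
Passing tests therefore show the algorithms are correct on images with the
right scales, contrast and noise statistics — not that biological images
will cluster as cleanly.

## Numerical choices and problem sizes

Intensities are promoted to double at load; coordinates are 0-based,
x-right/y-down, ROIs half-open. All randomized generators take explicit
seeds (identical seed ⇒ bit-identical output). The test suite exercises:
three-class recovery on libraries of 5 images per class over 10 seeds
(each 200×200 px); oracle equivalence on 1000 random 8×8 images (GLCM),
500 random 15×15 masks (mesh statistics) and n ≤ 8 feature rows (average
linkage); 20-seed colocalization sign checks; 1000-profile σ recovery at
5 % noise; and GHK recovery at n = 200 replicates, 0.5 mV noise, for
r ∈ {0.25, 1, 4, 15} — the range spanning anion-selective, non-selective
and strongly cation-selective junctions.

## Known limitations

* The tubularity filter is the smoothed-Hessian formulation of oriented
  flux; at sub-pixel radii the two differ, which is irrelevant at the
  r ≥ 2 px scales used here.
* The silhouette criterion replaces visual dendrogram cutting; on data
  without clear cluster structure it will still return some k, so the
  per-k score table is exposed for inspection.
* Absolute permeabilities assume a two-ion (Na⁺/Cl⁻) system; K⁺, divalent
  and bi-ionic extensions are out of scope.
* The branch-length conventions (√2 diagonal steps, cluster-rim origin)
  are one consistent choice among several in use; comparisons across
  software should compare conventions first.
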