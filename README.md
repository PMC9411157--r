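# tjmesh

Quantitative analysis of tight-junction (TJ) meshworks in super-resolution
(STED-like) fluorescence images, and of the paracellular ion permeability
those meshworks control.

Tight junctions seal the space between epithelial cells with polymeric
strands of claudin proteins, woven into polygonal meshworks a few hundred
nanometres across. Some claudins form pure barriers; others form
charge-selective paracellular ion channels. `tjmesh` implements the
quantitative pipeline needed to study this system from images and
Ussing-chamber records:

* **Texture features** — gray-level co-occurrence matrices at 1, 3, 5 and
  10 px and three selected Haralick statistics (sum average `f_SA = Σ_k
  k·p_{x+y}(k)`, sum variance `f_SV = Σ_k (k − f_SA)²·p_{x+y}(k)`, and
  variance `f_VAR = Σ_{i,j} (i − μ)²·p(i,j)`), averaged over the four
  standard directions, after a 3 px σ = 1 Gaussian prefilter.
* **Meshwork segmentation and morphometry** — multiscale curvilinear
  (tubularity) filtering, fixed thresholding with largest-component
  selection, skeletonization into a branch/junction graph (branch counts
  and lengths, triple/quadruple junctions), and mesh-size statistics from
  the border-excluded inverted mask, plus the quality filter (10–90 %
  segmented area, ≥ 10 branches).
* **Classification** — per-sample feature aggregation, ln(x+1) transform
  and column unit-variance scaling, hierarchical clustering (correlation or
  euclidean distance, average linkage), silhouette-based cluster-count
  selection, and PCA.
* **Colocalization and strand widths** — Costes automatic thresholds with
  orthogonal regression and the Pearson coefficient above threshold;
  averaged line profiles with Gaussian fits reporting FWHM = 2.35 σ;
  polyline strand lengths.
* **Electrophysiology and FRET** — Goldman–Hodgkin–Katz (GHK) dilution
  potentials `V = (RT/F)·ln[(r·c_Na^baso + c_Cl^api)/(r·c_Na^api +
  c_Cl^baso)]` with `r = P_Na/P_Cl`, the exact inverse, absolute
  permeabilities from TER via the Kimizuka–Koketsu partition, apparent
  tracer permeability `P_app = (dC/dt·V)/(A·C0)`, and linear spectral
  unmixing with the acceptor/donor FRET ratio.
* **Synthetic data** — a seeded generator of STED-like meshwork images
  (three meshwork morphology classes plus non-meshwork phenotypes),
  two-channel co-expression patterns (intermix, integrate, induction,
  segregate, exclude), line profiles, dilution-potential datasets and
  emission spectra, all with known ground truth.

## Worked example

```r
library(tjmesh)

# simulate a small library: 5 images per meshwork class, extract features
rows <- simulate_library(n_per_class = 5, seed = 1)
res  <- classify_library(rows)
res$assignment$k      # 3
res$purity            # 1

# colocalization of a segregating claudin pair
cfg <- synth_config("class_B_small_mesh", seed = 1)
seg <- make_two_channel(cfg, "segregate")
pearson_above_threshold(seg$ch1, seg$ch2)$pearson_above_threshold
# -0.3307045

# a 4-fold Na+-selective junction measured in an Ussing chamber
ds <- make_dilution_dataset(r_true = 4, TER_true = 100, n = 200,
                            noise_sd_mV = 0.5, seed = 7)
estimate_ratio(ds)
# 4.058035
absolute_permeabilities(4, 100)
# $ratio 4; $p_na 16.09; $p_cl 4.02   (1e-6 cm/s)
```

The cluster count of 3 with purity 1 means the three synthetic morphology
regimes (large meshes, small meshes, dense parallel strands) are fully
separated by the combined texture + morphometry features. The negative
thresholded Pearson flags segregation (anti-colocalization) of the two
channels, while intermixed pairs score ≈ 0.9. The dilution-potential
estimator recovers the simulated 4-fold Na⁺/Cl⁻ selectivity within a few
percent, and the Kimizuka–Koketsu partition converts it plus the TER into
absolute permeabilities in 10⁻⁶ cm/s.

A thin command-line wrapper over the same functions is installed at
`inst/cli/tjmesh.R` (subcommands `synth`, `features`, `classify`, `coloc`,
`fwhm`, `physiol`).

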