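---
title: "Methods: multi-scale orchard phenotyping with orchardphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale orchard phenotyping with orchardphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardphen)
```

# The problem

Phenotyping hundreds of fruit-tree genotypes in the field requires trading
leaf-by-leaf measurements for remote, high-throughput proxies, then checking
that those proxies carry genetic signal. `orchardphen` implements one such
multi-scale chain for an orchard grown under two watering regimes
(well-watered, WW, and water-deficit, WD, rows):

1. **Crown architecture** from terrestrial-LiDAR point clouds: convex-hull
   volume (`c_volume`), alpha-hull volume (`a_volume`), convexity index
   (`c_i = a_volume / c_volume`) and the silhouette to total leaf area ratio
   (`STAR`).
2. **Canopy state** from airborne multispectral + thermal rasters:
   per-tree NDVI, GNDVI, MCARI2, PRI, canopy-minus-air temperature
   (`Tsurf - Tair`) and the trapezoid-based Water Deficit Index (`WDI`).
3. **Leaf photosynthesis** via the semi-empirical index `I_PL`, a linear
   combination of a fluorescence-derived predictor and the leaf-to-air
   temperature difference, calibrated per gas-exchange device.
4. **Quantitative genetics**: per-trait mixed models with a random genotype
   effect, BLUPs, broad-sense heritability
   `H2 = sigmaG2 / (sigmaG2 + sigmaR2 / n)`, and a multivariate layer
   (genotypic correlations, PCA, Ward clustering into genotype groups).

Because no orchard data ship with the package, a synthetic-data module
generates all four input families with known ground truth (leaf areas,
canopy temperatures, model coefficients, variance components), and the test
suite checks each stage against that truth or against closed-form oracles.

# Crown geometry

## Delaunay backbone

All hull volumes derive from one 3D Delaunay tetrahedralization
(`delaunay_tetrahedra()`), implemented in C++ (Bowyer–Watson with walk-based
point location). Predicates run on coordinates normalised to the unit box
and perturbed by a deterministic per-index jitter of relative size `1e-9`,
which resolves degenerate inputs (grids, cospherical corners) without
affecting reported volumes: volumes and circumradii are always measured on
the original coordinates. Consequences worth knowing:

* the convex-hull volume is the total volume of the tetrahedra, exact for
  reference solids (unit cube, regular tetrahedron) to ~1e-9;
* hull volumes are invariant under rigid motion to ~1e-9 relative, because
  the jitter pattern depends on point indices, not coordinates;
* degenerate clouds (fewer than 4 points, coplanar) are rejected with an
  explicit error rather than returning a zero volume.

## Alpha-shape convention

`alpha_hull_volume()` keeps a tetrahedron iff its **circumsphere radius is
smaller than alpha (in meters)** — the radius-bound convention of the
alphashape3d/CGAL family. The alpha complex is therefore non-decreasing in
alpha, bounded by the convex hull, and may fragment into several components
whose volumes are summed (crowns do fragment at small alpha). The packaged
default `alpha = 0.15` is the value retained in the study this package
models; because published alpha values are convention-dependent, the
convention is stated here and in the function documentation rather than
inferred. `select_alpha()` reproduces the calibration protocol: over a
grid, pick the alpha maximizing the Pearson correlation between
`a_volume(alpha)` and measured total leaf area on a subset of trees.

## STAR

`compute_star()` renders every point as an opaque disk of radius
`leaf_radius` facing the viewing direction, rasterizes the projection onto
a grid orthogonal to that direction (cell centre in circle), and reports the
mean over directions of silhouette area / total one-sided leaf area.
Choices and their rationale:

* **Directions**: an equal-area ring discretization of the upper hemisphere,
  default 46 sectors (a standard sky-sector count), with a single-zenith
  option for quick work. The study's source defers its direction set to a
  cited implementation, so the set here is pinned, not inferred.
* **Disk radius**: defaults to half the median nearest-neighbour distance
  (scale-free). On synthetic crowns sampled with `k` returns per leaf the
  physically consistent radius is `leaf_radius / sqrt(k)` (equal-area
  rendering), which the pipeline uses.
* **Total leaf area**: the known TLA on synthetic crowns; `n_points x
  per-point area weight` otherwise.
* **Resolution**: `grid_resolution` must be below `leaf_radius`; the default
  `leaf_radius / 4` keeps the rasterization bias of a disk union below a few
  percent, and coincident disks obey the exact `1/N` law because they share
  one rasterization.

# Imagery

Band rasters are plain matrices with an affine transform (`phen_raster`,
`band_stack`); on disk they are ESRI ASCII grids — a text format every GIS
reads — and crown clouds are ASCII PLY.

* **Thermal calibration**: OLS of target temperature on camera digital
  number (`calibrate_thermal()`), applied pixel-wise.
* **Indices**: NDVI and GNDVI as normalized differences on (850, 675) and
  (850, 570) nm; PRI on (530, 570); MCARI2 in its published improved form on
  (850, 675, 570). GNDVI uses the 570 nm green band because 530 nm is
  reserved for PRI (configurable); pixels with vanishing denominators are
  missing, not infinite.
* **Vegetation classification**: `NDVI > 0.3` by default. The synthetic soil
  is low-NIR/high-red so the two classes separate cleanly at that threshold,
  which is what makes classification testable without a trained model; real
  scenes with mixed pixels will not separate as cleanly.
* **Buffer**: pixels whose centres fall within 0.70 m of the tree centre
  (pixel-centre-in-circle; unambiguous and testable). `Tsurf - Tair` uses
  vegetation pixels only; multispectral indices average over all buffer
  pixels; the per-tree SD uses the sample (n-1) convention because per-tree
  pixel counts are small.
* **WDI**: position of `(NDVI, Tsurf - Tair)` between the wet and dry edges
  of a trapezoid, clipped to [0, 1] (observed pixels fall slightly outside
  any fitted trapezoid). Per tree it is evaluated at the tree's mean NDVI
  and mean temperature difference.

## Trapezoid estimation

The study's source prints the four vertex temperatures of its 27-July
trapezoid (0.87, -1.34, 21.86, 5.6 degC) but not the procedure that produced
them, so `fit_trapezoid()` offers a manual mode that takes four vertex
temperatures directly, and a pinned automatic mode: NDVI edge abscissae at
the 5th/95th NDVI percentiles; per-NDVI-bin temperature percentiles
(2.5/97.5 by default) trace the wet and dry edges; each percentile pair is
extrapolated to the 0/100 edge under the trapezoid's own uniform-fill model
(so interior percentiles do not bias the edges inward, while staying robust
to stray pixels, unlike a raw min/max); straight lines through the bin
envelopes, evaluated at the edge abscissae, give the vertices. On pixels
generated uniformly inside a planted trapezoid the vertices are recovered
to well under 0.5 degC. Fits fail loudly with fewer than 100 pixels, fewer
than 3 usable bins, or a wet edge above the dry edge.

# I_PL

The fluorescence chain is `PhiPSII = (Fm' - Fs)/Fm'`, `J_PSII = PhiPSII x
PPFD x absorptance x f_PSII`, `P_KO/KC = J_PSII x K_O/K_C(Tleaf)`, and the
index itself is the OLS fit `An ~ P_KO/KC + (Tleaf - Tair)` per device —
devices carry their own internal calibrations, so coefficients are never
pooled across devices. Constants and their defaults:

* `absorptance = 0.84`, `f_PSII = 0.5`: the widely used leaf-level defaults;
  the original index formulation does not print its constants, so these are
  pinned and recorded in the model object.
* `K_O/K_C`: Arrhenius-form temperature response with Bernacchi-style
  reference values, K_O in mmol mol-1 and K_C in umol mol-1 so the ratio is
  ~0.69 at 25 degC and `P_KO/KC` stays on the umol m-2 s-1 scale of
  `J_PSII`. Because carboxylation has the larger activation energy the ratio
  decreases with leaf temperature. A constant-ratio mode exists because the
  downstream linear calibration absorbs any fixed scale.
* **Split**: random 2/3 calibration / 1/3 validation with a recorded seed
  (the original split method is unstated); calibration and validation R2
  are squared Pearson correlations between observed and predicted, RMSE is
  in An units, and set disjointness is asserted in the tests.

On synthetic campaigns with the field geometry (98 + 132 records, noise SD
3 umol m-2 s-1) the 95% confidence intervals cover the true coefficients at
their nominal rate and the median relative error of the slope coefficients
is below 10%.

# Quantitative genetics

`fit_mixed()` fits `value ~ fixed effects + (1 | genotype)` by REML (lme4).
On a balanced one-way design the REML components equal the ANOVA
method-of-moments estimators — the tests assert agreement to 1e-6 — and the
BLUPs are the usual shrunken genotype means. Specifics:

* **BIC**: model selection compares candidate fixed-effect sets, so the BIC
  is computed from a maximum-likelihood refit of each candidate (REML
  criteria are not comparable across fixed-effect sets); the reported
  variance components always come from the REML fit. `select_model()`
  returns the lowest-BIC candidate plus the full table.
* **n in H2**: the mean number of non-missing replicates per genotype for
  that trait — the design is nominally balanced (4 trees/genotype) but
  missingness occurs; the arithmetic mean is the pinned choice where the
  source says only "the number of replicates per genotype".
* A genetic variance estimated at the 0 boundary is flagged (`boundary`),
  not an error.
* `genotypic_cv()` is the sample SD of genotypic values (BLUP + intercept
  scale) over their mean.

# Multivariate layer

Traits are standardized before PCA and Ward clustering because their units
are incommensurable (m3 against dimensionless indices). PCA is the
eigendecomposition of the correlation matrix with a deterministic sign
convention (largest-magnitude loading per axis positive). Clustering is
`hclust(method = "ward.D2")` on Euclidean distances of the standardized
BLUP matrix — the canonical Ward criterion — cut at `k = 6` groups by
default; whether the original analysis clustered raw BLUPs, standardized
BLUPs or PCA scores is unstated, and standardized BLUPs are the pinned
choice. Group summaries report per-group means, a one-way ANOVA p per trait
and a compact letter display from Tukey HSD at 0.05; singleton groups are
excluded from the pairwise comparisons with a warning. Correlation tables
report signed squared Pearson correlations with significance stars at the
0.08 / 0.05 / 0.01 / 0.001 thresholds.

# What the synthetic orchard does and does not emulate

`run_pipeline()` wires everything together on a simulated orchard: genotype
effects on crown size, canopy temperature and photosynthesis; WW/WD rows on
a 5 x 2 m planting grid; crowns as clumped leaf-disk clouds; rasters with
circular canopy footprints over hot soil; a two-device gas-exchange
campaign. Planted contrasts propagate end-to-end: WD trees come out with
higher WDI and `Tsurf - Tair` and lower `I_PL`, and traits planted with
strong genetic signal recover higher heritability. One master seed fans out
to per-stage sub-seeds, so re-running a configuration is bit-identical.

The generator is deliberately simple: leaves are planar disks, reflectances
are Gaussian around two class means, soil is uniformly hot, there is no
radiative transfer, no wind or illumination artifacts, no mixed pixels, no
registration error, and crowns never overlap their neighbours' buffers.
Passing tests therefore demonstrate that the estimators are correct and
well-calibrated under the stated models — not that the proxies are accurate
on real orchards, where classification, georeferencing and physiological
variation add errors this generator does not produce.

## Problem sizes

Default sizes were chosen so a full check runs comfortably on a laptop: the
demo pipeline uses 24 genotypes x 4 trees with ~660-point crowns; the
recovery studies use the field-campaign geometries (98 + 132 gas-exchange
records; 240 genotypes x 4 replicates, 200 replicate tables; 500 replicate
calibration campaigns). Hull volumes on 10^4-point clouds take well under a
second each.

# Known limitations

* The alpha-shape volume depends on the stated radius-bound convention;
  values published under another convention need rescaling before
  comparison.
* The automatic trapezoid assumes pixels fill the trapezoid roughly
  uniformly; strongly clustered scenes (all vegetation, no soil) are
  rejected rather than extrapolated.
* The rasterized STAR carries a resolution-dependent bias of a few percent;
  halve `grid_resolution` where that matters.
* `H2` uses the genotype-mean formulation with a single `n`; designs with
  strong per-genotype imbalance would need a harmonic-mean or per-genotype
  weighting that is not implemented.
* PLY support is ASCII-only, and rasters are single-band text grids; binary
  formats are out of scope.
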