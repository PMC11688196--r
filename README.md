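# nisslcolumn

Layer-resolved cell-density quantification for Nissl-stained cortical
columns.

## What this package is for

Counting cells in Nissl (cresyl violet) histology is the standard way to
measure how densely the cerebral cortex is populated, layer by layer. Modern
workflows segment every soma in a high-resolution slide scan and export one
row per cell (centroid, diameters, area, distance to the pia) together with
region annotations (the cortical-band polygon, the pia outline, corner
reference points). `nisslcolumn` takes it from there: it implements the
post-segmentation analysis a neuroanatomy lab needs to turn those per-cell
tables into unbiased densities, layer assignments, per-layer volumes and
soma-size statistics. It is aimed at users of QuPath/Cellpose-style
pipelines who analyse cortical columns in rodent brains, and at
methodologists who want a fully synthetic, seedable test bed for such
pipelines.

The analysis stages are:

- **Stereological z-exclusion.** Consecutive sections are thin (50 um), so a
  soma cut by the upper slice surface would be counted twice across
  sections. Each cell gets a virtual depth `z ~ U(0, T)` and a diameter
  estimate `d_i` (mean representative diameter of its 6 nearest
  neighbours); it is excluded when `z + d_i/2 > T`. Bootstrapping the z
  draws (100 iterations) yields per-cell exclusion probabilities and an
  excluded fraction whose expectation is `E[d]/(2T)`.
- **Depth-density profiles.** A nonlinear 10 x 20 grid is fitted inside the
  cortical-band polygon: rows follow the blended shape of the pia-side and
  white-matter-side outlines (constant fractions of cortical depth),
  columns follow straight cuts at equal arc-length fractions. Per-bin
  densities `count / (area x thickness)` give cell density as a function of
  percent cortical depth, averaged within and then across images.
- **Cell-level layer classification.** Random forest and distance-weighted
  KNN classifiers assign each cell to one of the layers LI ... LVIb (or the
  merged LII/III paradigm) from positional and morphological features plus
  their 50-um spatially smoothed counterparts, with permutation-importance
  feature selection, image-grouped 10-fold cross-validation and
  macro-averaged metrics.
- **Per-layer volumes, densities and heights.** The alpha-concave hull
  (Delaunay triangles with circumradius `< 1/alpha`; `alpha -> 0` gives the
  convex hull) wraps each layer's cells — `alpha = 0.05` generally,
  `0.005` for the sparse Layer I; density is `count / (hull area x
  thickness)`. Layer heights come from the depth at which the predicted
  label switches in each grid column.
- **Soma-diameter mixtures and statistics.** Equivalent circular diameters
  `d = 2 sqrt(A/pi)` are fitted per image and layer with a two-component
  Gaussian mixture (EM, seeded restarts), separating the small-cell and
  large-cell populations; Welch t-tests, Kruskal-Wallis across layers and
  Bonferroni-adjusted adjacent-layer t-tests (`alpha = 0.05/6`) complete
  the battery.
- **Segmentation quality.** Object-level matching of predicted versus
  ground-truth outlines (greedy by IoU at a 0.5 threshold) with accuracy
  `TP/(TP+FP+FN)`, Dice (`DSC = 2 IoU / (1 + IoU)`) and IoU, and Welch
  comparison of segmenters.

A synthetic cortical-column generator (`column_spec()`, `simulate_column()`)
draws layered Poisson point patterns with literature-derived default
densities, thicknesses and diameter mixtures, so every stage is testable
without any image data.

## Worked example

Simulate a seven-layer column at the packaged defaults, run the
stereological exclusion, the depth grid and the per-layer hull densities:

```r
library(nisslcolumn)

spec <- read_column_spec()   # packaged seven-layer defaults
spec$seed <- 42L
col   <- simulate_column(spec)
cells <- filter_in_polygon(col$cells, col$regions)

excl <- bootstrap_exclusion(cells, thickness_um = 50, n_iterations = 100, seed = 42)
excl
#> <exclusion_result> 7527 cells, 100 iterations, thickness 50 um
#>   excluded fraction: 0.0791 +- 0.0032 (7.91%)

grid <- bin_densities(build_depth_grid(col$regions), cells, exclusion = excl)
head(depth_profile(list(grid)), 3)
#>   depth_percent mean_density sd_density n_images
#> 1           2.5       25546.          0        1
#> 2           7.5       61075.          0        1
#> 3          12.5       80461.          0        1

tidy(layer_density(cells, exclusion = excl))
#>   layer_label alpha  volume_mm3 n_cells density_cells_mm3
#> 1          LI 0.005 0.005579647  177.50          31812.05
#> 2         LII 0.050 0.005450915  500.60          91837.79
#> 3        LIII 0.050 0.017141797 1467.34          85600.12
#> 4         LIV 0.050 0.006606030  699.68         105915.35
#> 5          LV 0.050 0.023732298 1658.75          69894.20
#> 6        LVIa 0.050 0.021526899 1875.32          87115.20
#> 7        LVIb 0.050 0.006951965  546.68          78636.77
```

About 8 % of cells are excluded as surface-touching — the expected
`E[d]/(2T)` for ~8-um somata in a 50-um slice. The first depth bins climb
from the sparse Layer I toward the dense upper layers, and the
exclusion-weighted hull densities land close to the generating per-layer
intensities (Layer I ~32k, Layer IV ~106k cells/mm^3). The sparsest, thinnest
band (LVIb) reads high: a tight hull around a sparse pattern under-covers
empty space — see the methods vignette for this limitation.

Soma-size structure in one layer:

```r
fit_diameter_mixture(
  diameter_from_area(cells$area_um2[cells$layer_label == "LIII"]), seed = 1)
#> <mixture_fit> n = 1603
#>   pop 1: 6.25 +- 1.60 um (w = 0.54)
#>   pop 2: 10.90 +- 2.24 um (w = 0.46)
```

The two recovered populations match the generating small-cell and
large-cell components (6.09 and 10.74 um).

Each fitted object has `tidy()`/`glance()` methods and an `autoplot()`
(exclusion histograms, depth profiles, hull maps, confusion matrices). A
thin command-line wrapper for shell use lives at
`inst/cli/nissl_column.R` (subcommands `simulate`, `stereology`,
`depth-density`, `layer-density`, `morphometry`, `seg-eval`, `run`).

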