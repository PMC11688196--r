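---
title: "Methods: quantifying layered cell densities in Nissl-stained cortical columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying layered cell densities in Nissl-stained cortical columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures behind `nisslcolumn`, the
assumptions they rest on, the parameters that matter, and the places where
the design was genuinely open and a choice had to be made.

## The measurement problem

A Nissl stain marks every cell body, so a segmented whole-slide scan of a
cortical column yields tens of thousands of per-cell records: centroid (in
micrometres, image frame, y increasing downward), maximum and minimum soma
diameter, soma area, and the distance from the centroid to the "Outside
Pia" annotation. The quantities of interest are volumetric: cells per cubic
millimetre, per cortical layer and as a function of depth. Three obstacles
stand between the table and those numbers: somata cut by the section
surface are double-counted across consecutive sections; the cortical band
is curved, so "depth" is not a coordinate but a fraction of the local
pia-to-white-matter distance; and layer boundaries are not given — they
must be inferred per cell.

## Stereological exclusion along the virtual z axis

Because consecutive 50-µm sections are all counted (nothing is subsampled
in x/y), the only overcounting is across the slice surfaces. The classical
disector idea is adapted: each cell receives a virtual depth
$z \sim U(0, T)$ within the slice of thickness $T$, and a diameter estimate
$\hat d_i$ taken as the mean representative diameter
($(d_{\max}+d_{\min})/2$) of its six nearest neighbours in the plane,
excluding the cell itself — the neighbour average is robust to the cell's
own segmentation error. A cell is excluded when $z_i + \hat d_i/2 > T$
strictly: a soma touching the surface exactly counts as inside. The strict
inequality is the conservative reading of "touching the upper surface";
the boundary case has probability zero under the continuous model, so the
choice is a tie-break, not a bias.

Under this model the excluded fraction has expectation
$\mathbb{E}[\hat d]/(2T)$ — about 8–10 % for 8–10 µm somata at $T = 50$ µm.
The z draw is repeated (default `n_iterations = 100`) to bootstrap the
fraction and to attach a per-cell exclusion probability
$p_i = \#\{\text{excluded}\}/100$. Downstream counts use the *effective*
weight $1 - p_i$ per cell rather than a single realisation; this equals
the mean over bootstrap iterations in expectation and removes one source
of Monte-Carlo noise. Neighbour diameters are computed once per dataset:
the in-plane geometry does not change between iterations, so re-estimating
them would change nothing.

## Depth profiles on a nonlinear grid

The cortical band polygon is split by its four corner reference points into
a pia-side outline (top-left to top-right) and a white-matter-side outline
(bottom-left to bottom-right). Both are resampled uniformly in arc length
(201 points, so that the 10 column cuts land exactly on resampled
vertices); the row polyline at depth fraction $t$ is the pointwise linear
blend $(1-t)\,\text{top} + t\,\text{bottom}$, rows cut at $t = j/20$ and
columns by the straight segments joining top and bottom points at
arc-length fractions $i/10$. Linear blending is the simplest
shape-preserving interpolation between the two outlines; since the blend
is linear in $t$ at fixed arc-length fraction, the column cuts pass
exactly through every intermediate row, and the 200 bins tile the band
with no overlap. In the zero-curvature limit the construction degenerates
exactly to uniform rectangular binning (this is asserted in the tests
against a direct binning oracle).

The construction assumes the corner quadrilateral is convex; on concave
bands the rows are no longer ordered in depth and cells from different
depths would share a bin, so such slices are refused with an explicit
error rather than silently misbinned — mirroring the exclusion of concave
slices from the study design this mirrors.

Cells are assigned to bins by inclusive point-in-polygon tests; a cell on
a shared edge goes to the larger (column, row) index, which reproduces
half-open binning in the rectangular limit. Bin density is
$\text{count}/(\text{area} \times T)$ in cells/mm³; zero-area bins report
a missing density, never infinity. The depth profile averages bin
densities over the 10 columns within each image first and only then takes
the mean and standard deviation ($n-1$) across images, so images with
different cell counts contribute equally. Row centres are reported at
2.5 %, 7.5 %, …, 97.5 % depth — unbiased plot positions for 20 bins.

## Cell-level layer classification

Layer assignment is a seven-class (or six-class, when Layers II and III
are merged) classification problem at the cell level. Features are the
positional and morphometric columns (distance to pia, soma area, max/min
diameter, aspect ratio, an elliptical perimeter estimate and the derived
circularity) plus their "smoothed 50 µm" counterparts: the unweighted mean
over all cells, self included, within 50 µm in the same image. Smoothing a
spatially constant feature returns the constant, and an isolated cell
keeps its own value. The full feature list of the original workflow is
not available; this catalogue is the implementable counterpart, and
permutation-importance selection (mean held-out accuracy drop over
repeated column permutations; only positive-importance features kept) is
re-run per dataset, so the selection adapts to the data at hand. On
synthetic columns, as in real ones, the distance-to-pia features dominate.

Two model families are provided: a random forest (ranger, 500 trees,
unlimited depth) and a distance-weighted k-nearest-neighbour classifier
(k = 15, features standardised by the training moments, weights
$1/(d+10^{-6})$). The hyperparameters are not prescribed by the source
workflow; these are robust defaults, echoed into every report, and
overridable (`hyper = list(...)`). Evaluation uses 10-fold
cross-validation *grouped by image*: cells of one image are strongly
spatially dependent, so splitting an image across folds would leak
position information and inflate scores. The pooled confusion matrix
(rows = truth) yields per-class precision, recall, F1 and one-vs-rest
accuracy; macro metrics are unweighted class means, so small classes count
as much as large ones. Classes absent from a fold's training images are
warned about and their metrics reported as undefined rather than zeroed.

## Per-layer volumes from alpha-concave hulls

The footprint of a layer is estimated as the alpha-concave hull of its
cells: keep the Delaunay triangles whose circumradius is below
$1/\alpha$, take the largest edge-connected region, and return its outer
boundary. This is the inverse-characteristic-scale convention of the
common alpha-shape toolbox — $\alpha = 0$ is the convex hull, larger
$\alpha$ tightens the outline — so the published values 0.05 (all layers)
and 0.005 (the sparse Layer I, one tenth of the common value) are usable
verbatim; both are exposed as parameters because alpha conventions differ
between implementations. `select_alpha()` implements the calibration rule
that produced those values: the admissible candidate (no cell rejected)
with minimal hull area, falling back to the convex hull with a warning if
nothing admissible exists. Points on the hull boundary count as inside.

Numerical choices worth recording: the Delaunay triangulation is a
Bowyer–Watson implementation in C++ (cocircular degeneracies broken by a
relative epsilon in the in-circle test; duplicate points collapsed); the
outer boundary is assembled from directed boundary edges (region kept on
the left), and where the region pinches at a single vertex the walk takes
the sharpest right turn, which keeps the exterior ring on one face — this
matches the exterior produced by a polygon-union reference implementation
exactly. Hull area uses the shoelace formula; density is
$n_\text{cells}/(\text{area} \times T)$ with effective (probability-
weighted) counts when a stereology result is supplied.

**Known limitation — thin, sparse bands.** A concave hull hugs the point
pattern: empty margins and voids are carved away, so the hull area
under-covers the true support and the density reads high. The effect
grows with the ratio of nearest-neighbour spacing to the alpha scale
$1/\alpha$ and with the perimeter-to-area ratio of the band. At the
published Layer IV density in a 1,000 × 500 µm slab the bias is ~5 %; in a
1,200 × 120 µm band at the Layer VIb density it can exceed 30 %, and at
low enough density the kept triangles fragment into several regions (the
largest is used; cells outside it are not counted but also not part of
the area). The acceptance checks therefore pin the recovery claim to the
wide-slab regime; analyses of very sparse thin layers should prefer the
looser Layer-I alpha, as the original calibration did.

Layer heights are estimated per grid column: the boundary between two
adjacent layers is the depth at which the predicted label switches —
operationally, the candidate split (midpoint between consecutive cells
ordered by depth) minimising the number of misordered labels, which
reduces to the midpoint between the last cell of the upper layer and the
first of the lower in the noise-free limit. The pia (depth 0) tops the
first layer, the deepest cell of the last layer bottoms the column, a
layer absent from a column contributes no estimate, and heights aggregate
as mean ± SD over columns (and images). The underlying "fit the density
predictions" idea is not given as a formula anywhere; this choice is
deterministic, testable, and exact on noise-free labels. Shuffled labels
blow up the between-column SD rather than crashing — a deliberate alarm.

## Soma-diameter mixtures and the statistical battery

Soma diameter is derived from area under a circular assumption,
$d = 2\sqrt{A/\pi}$. Per image and layer, a two-component Gaussian
mixture is fitted by EM with unequal component variances: the first start
splits the sample at the median (small/large halves), the remaining
starts (default 5 total) are seeded random perturbations, the best
log-likelihood wins, and components are sorted by mean so "population 1"
is always the smaller-soma population. Component SDs are floored at
$10^{-4}$ of the sample SD to keep degenerate spikes from collapsing the
likelihood. Whether the original fits shared variances is unknown;
unequal variances is the more general model and matches the reported
per-population spreads. A separation diagnostic
$|\mu_2-\mu_1|/\sqrt{\sigma_1\sigma_2}$ flags near-unimodal samples.

Across images, the two population-mean vectors are compared per layer
with a two-sample t-test. The variance assumption behind the original
"two-sample t-tests" is unstated; the default here is the Welch flavour
(no equal-variance assumption), with the pooled-variance option one
argument away. Density differences across the seven layers use the
Kruskal–Wallis H test (tie-corrected, $\chi^2_6$ p-value); adjacent-layer
differences use six two-sample t-tests at the Bonferroni-adjusted level
$\alpha = 0.05/6 = 0.0083$. Degenerate inputs follow explicit
conventions rather than erroring: all-identical samples give $t = 0$,
$p = 1$ (flagged), and a fully tied Kruskal–Wallis gives $H = 0$,
$p = 1$ (flagged).

## Segmentation metrics

Object-level evaluation matches predicted to ground-truth outlines
greedily by descending pairwise IoU among pairs at or above the threshold
(default 0.5) — each object in at most one pair; unmatched predictions
are false positives, unmatched references false negatives. The matching
rule behind the published scores is not stated; greedy-at-0.5 is the
common convention and the threshold is a parameter. Detection accuracy is
$TP/(TP+FP+FN)$; per matched pair, IoU and Dice are related by
$DSC = 2\,IoU/(1+IoU)$, asserted to $10^{-9}$ in the tests. Overlaps are
computed on polygon areas (Sutherland–Hodgman clipping, exact when at
least one of the two outlines is convex — soma outlines are near-convex);
a rasterised mode at a configurable pixel size (default 0.346 µm, the
scan resolution this pipeline targets) handles arbitrary shapes
bit-comparably. Segmenter comparisons are unpaired Welch t-tests on
per-image scores with the usual asterisk rendering.

## What the synthetic generator emulates — and what it does not

`column_spec()` describes an ordered stack of layers (pia to white
matter) with mean thickness, Poisson density and a two-component diameter
mixture per layer; the packaged defaults are the published seven-layer
values for the juvenile rat somatosensory column (densities 32,568 …
103,016 cells/mm³, heights 129 … 517 µm, population means 4.80–6.09 µm
and 8.14–10.74 µm). Mixture weights are not published; the default is an
even 0.5/0.5 split, stated in the config and overridable. Diameter draws
are truncated at 0.39 µm, the smallest observed soma. Cell positions are
uniform within each layer band (homogeneous Poisson); a curved pia is
modelled as a circular arc of given sagitta so that layer bands are exact
constant-depth offsets (the sagitta must keep the arc radius above the
column depth; the constructor enforces this). Each layer draws from a
sub-stream seeded from the global seed and the layer label, so editing
one layer leaves the others' draws untouched. An optional label-noise
hook re-assigns labels from a depth jittered by a Gaussian SD, emulating
human boundary uncertainty.

The generator deliberately does **not** emulate: within-layer density
gradients or clustering (real somata are not Poisson — they avoid each
other at contact range and cluster at larger scales), staining-intensity
features, segmentation errors (merged/split somata), anisotropic soma
orientation, or inter-animal variability. Passing tests on this
generator therefore validates the estimators under their stated
assumptions — unbiasedness on homogeneous patterns, exact geometry,
correct statistics — not robustness to every artefact of real histology.

## Problem sizes and numerical tolerances

The test-suite simulations are sized to run on one CPU in a few minutes:
three-layer columns of a few thousand cells for unit tests, twelve
columns (~25,000 cells) for the image-grouped cross-validation checks,
100,000 cells for the analytic exclusion check, 1,000 replicates for the
type-I-error checks, and 20 Poisson slabs of ~800–2,600 cells for the
density-recovery checks. Geometric identities (tiling, count
conservation, oracle comparisons) are asserted exactly or at $10^{-9}$;
stochastic recoveries at 3 Monte-Carlo standard errors or the stated
5 % bias budget; round-trips at $10^{-6}$ relative.
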