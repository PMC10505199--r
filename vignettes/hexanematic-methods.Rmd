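---
title: "Multiscale shape order in epithelial monolayers: models and methods"
author: "hexanematic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale shape order in epithelial monolayers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexanematic)
```

# The model

A confluent epithelial monolayer is represented as a space-filling
tiling of simple polygons: every cell is the straight-line polygon
through its junction vertices, carries an area centroid, and is linked
to the cells it shares an edge with. All coordinates are in
micrometres. Cells touching the field-of-view boundary are kept in the
`Monolayer` container but flagged as border cells and excluded from
every ensemble statistic, because their shapes are clipped by the
imaging window rather than by their neighbors.

## Per-cell descriptors

For a cell with vertices $\mathbf r_v$, $v = 1\dots V$, relative to its
center of mass, the $p$-fold shape function is

$$\gamma_p \;=\; \frac{\sum_{v=1}^{V} |\mathbf r_v|^p \, e^{i p \phi_v}}
                      {\sum_{v=1}^{V} |\mathbf r_v|^p},$$

where $\phi_v$ is the angular coordinate of vertex $v$. By the triangle
inequality $|\gamma_p| \le 1$; the magnitude measures resemblance to a
regular $p$-gon ($p = 2$: a rod) and $\mathrm{Arg}(\gamma_p)/p$ is the
cell's $p$-fold orientation, defined modulo $2\pi/p$. $\gamma_p$ is
invariant under translation and uniform scaling and covariant under
rotation ($\gamma_p \mapsto \gamma_p e^{ip\alpha}$); these symmetries
are asserted over a thousand random polygons in the test suite. The
shape index $p_0 = P/\sqrt{A}$ is computed alongside ($\ge 2\sqrt\pi$;
$\approx 3.7224$ for a regular hexagon).

Two conventions exist for the "center of mass" of a polygon: the area
centroid and the plain vertex average. They differ for irregular cells.
The package defaults to the area centroid — the center of mass of the
cell as a lamina — and exposes `com = "vertex-mean"` on every entry
point for comparability with pipelines that use the other convention.

## Coarse-graining and the hexanematic crossover

The scale-dependent shape parameter at position $\mathbf r$ and radius
$R$ is the plain complex average of $\gamma_p$ over interior cells whose
centroid falls strictly inside the disk:

$$\Gamma_p(\mathbf r, R) = \frac{1}{N_\mathrm{disk}}
  \sum_c \gamma_p(\mathbf r_c)\,\Theta(R - |\mathbf r - \mathbf r_c|),$$

with $\Theta$ the strict step function ($\Theta(0) = 0$, so a centroid
at distance exactly $R$ is excluded — the convention is pinned by a
dedicated test on exactly representable distances). $\Gamma_p$ is
sampled on a square grid of spacing exactly $R_\mathrm{cc}/2$ centered
in the field of view (default 124 µm, clipped to the data box), where
$R_\mathrm{cc}$ is the mean centroid distance over unordered interior
neighbor pairs. Grid nodes are sampling positions, not cell centers.
Nodes whose disk is empty are missing values and drop out of the grid
average

$$\overline{|\Gamma_p(R)|} = \frac{1}{N_\mathrm{grid}}
  \sum_n |\Gamma_p(\mathbf r_n, R)|$$

(magnitude first, then average — the reverse order would let phases
cancel and measure something else). The radius ladder runs from
$R_\mathrm{cc}/2$ in steps of $R_\mathrm{cc}/2$ up to half the
field-of-view diagonal. No minimum disk occupancy beyond
$N_\mathrm{disk} \ge 1$ is imposed, and nodes near the border keep
whatever interior cells fall inside their disk; this is the simplest
faithful reading of the disk average, at the cost of a known variance
increase at the largest radii.

The crossover scale $R_\times$ is the first radius interval on which
$\Delta(R) = \overline{|\Gamma_6|} - \overline{|\Gamma_2|}$ changes sign
from positive to non-positive, located by linear interpolation between
ladder points; when several crossings exist the first is reported,
matching the expected structure of hexatic order at small and nematic
order at large scales. Profiles that never change sign are reported as
`"hexatic-dominated"` (no crossover up to the maximal radius) or
`"nematic-dominated"` ($\Delta \le 0$ already at the first rung), with
`NA` as the numeric crossover. Downstream trend statistics treat
hexatic-dominated profiles as right-censored (largest possible
$R_\times$). Crossovers are computed per monolayer and then averaged
within density groups, rather than on group-pooled fields; both modes
can be assembled from the exported pieces, but per-monolayer-first is
the default because it keeps monolayers exchangeable units.

## Topological defects

The orientation field $\theta = \mathrm{Arg}(\Gamma_p)/p \in
[0, 2\pi/p)$ is scored plaquette by plaquette on the sampling grid: the
winding number is the sum of the four consecutive corner differences,
each wrapped to the symmetric branch $(-\pi/p, \pi/p]$, divided by
$2\pi$, then snapped to the nearest multiple of $1/p$ (tolerance
$10^{-6}$). The symmetric branch makes the charge antisymmetric under
conjugation of the field; elementary defects are $\pm 1/2$ (nematic) and
$\pm 1/6$ (hexatic). Plaquettes with an undefined corner (empty disk or
zero field) are skipped, never interpolated. Defect abundance is
reported per 100 interior cells, counting both signs (positive and
negative totals are also emitted separately). The density at the
crossover scale is evaluated at the ladder radius nearest to $R_\times$:
the winding number is defined only on the ladder grids, so no
re-gridding at the interpolated crossover is attempted.

# Segmentation

The image pipeline mirrors the standard junction-marker workflow:

1. optional Gaussian pre-smoothing (`smoothSigmaPx`, default 1 px) and
   thresholding (Otsu by default; a fixed threshold can be given);
2. removal of suprathreshold components smaller than `minComponentPx`
   (default 10 px) and Zhang–Suen thinning to a 1-px skeleton, followed
   by pruning of spur branches up to 6 px;
3. vertex detection at skeleton branch points, established by the
   crossing number (cyclic background-to-foreground transitions
   $\ge 3$) rather than a raw neighbor count, which staircase pixels on
   diagonal lines would fool; branch pixels are merged by single
   linkage within 2 px — thinning splits one biological junction into
   adjacent branch pixels — and each cluster is refined to the local
   intensity-weighted centroid of the junction signal (sub-pixel
   localization, removing the inward bias of the raw cluster centroid);
4. faces of the skeleton complement (4-connected, against the
   8-connected skeleton) become cells; each face's polygon is the set
   of vertices assigned to it, ordered by angle about the face
   centroid. A vertex is assigned to the faces whose nearest pixels lie
   within 1.5 px of its overall nearest face pixel — the junction blob
   is locally symmetric about the vertex, so incident faces sit at
   nearly equal distances while non-incident faces lie a ridge width
   away;
5. adjacency is the union of two constructions that fail in
   complementary ways: faces separated by a skeleton pixel away from
   any vertex (a junction edge), and faces sharing two vertices (an
   edge of the straight-line tiling). Faces reaching within 4 px of the
   image edge are border cells; faces with fewer than 3 vertices are
   dropped with a warning, not an error.

Pixels are converted to micrometres exactly once, at polygon
construction (origin top-left, x right, y down, pixel centers at
half-integers). Vertices shared by four or more cells are kept as
single vertices (rosettes are not split). On rendered fixtures with
additive noise at 10% of the ridge intensity the round trip recovers
$\ge 95\%$ of interior cells with median area error below 5% and
neighbor-relation F1 above 0.95; these margins are asserted in the test
suite, with the caveats about synthetic data below.

# The synthetic-monolayer generator

The generator provides ground truth with the statistical structure the
analysis assumes: space-filling tilings (cell areas sum exactly to the
box area), controllable density, controllable elongation, and — the
structurally important ingredient — *finite-range* hexatic order.

Cell centers are seeded on a polycrystal of triangular-lattice grains:
grain centers are a Poisson process with one grain per `grainSize`²
(default 42 µm), each grain carries its own lattice orientation
(uniform on $[0, \pi/3)$) and offset, and each lattice site belongs to
its nearest grain. A single Lloyd relaxation sweep then moves every
seed to the centroid of its Voronoi cell, relaxing the grain seams
without changing the seed count — which keeps the mean cell area, and
hence the realized $R_\mathrm{cc}$, calibrated to `targetRcc` (within
5% on the default conditions, asserted over seeds). Independent
per-seed jitter (`jitter` × a uniform draw from a disk of half a
lattice constant, default 0.3) adds cell-scale disorder. A plain
jittered single lattice (`grainSize = Inf`, used by the exact lattice
fixtures) retains long-range 6-fold phase coherence, so its hexatic
order never decays; real epithelia lose hexatic coherence beyond
finite patches of cells, and the grain size is the absolute tissue
scale that encodes this.

Elongation is imposed by the area-preserving stretch $(e, 1/e)$ along
`elongationAxis`, applied to the *tessellation*: the Voronoi tiling of
the unstretched pattern is computed first and every cell polygon is
mapped affinely, then clipped to the box. Cells are therefore exact
affine images of isotropic Voronoi cells, so their 2-fold orientation
equals the elongation axis exactly and $|\gamma_2|$ grows strictly with
$e$ (both asserted). Tessellating the stretched *points* instead would
make $|\gamma_2|$ of the resulting cells non-monotonic in $e$ and flip
their apparent axis in an intermediate range — an instructive artifact
of discrete vertex-based shape functions. Because the stretch inflates
mean neighbor distances by the angular mean
$m(e) = \tfrac2\pi\int_0^{\pi/2}\sqrt{e^2\cos^2 t + e^{-2}\sin^2 t}\,dt$,
the lattice constant is divided by $m(e)$, keeping density and
elongation independently controllable.

The renderer rasterizes every tiling edge once as a ridge of width
`lineWidthPx` (intensity 1) at `pixelSize` µm/px, applies a Gaussian
blur (`blurSigmaPx`) and adds clipped Gaussian noise (`noiseSd`, in
ridge-intensity units; default 0.1). One integer seed determines
everything; the generator and the renderer each seed their stream from
it, and identical configurations give bit-identical output.

## Study conditions and the density–shape coupling

`studyEnsemble()` fixes the conditions used by the package's own
validation: densities `targetRcc` ∈ {12, 16, 20} µm (inside the
9.7–28.5 µm range typical of MDCK monolayers), four phenotypes, five
seeds, and boxes sized for ≈200 interior cells. Cell elongation
covaries with density,

$$e(R_\mathrm{cc}) = 1 + 0.0125\,(R_\mathrm{cc} - 9.7) + \text{offset},$$

because in epithelial monolayers sparser tissue means more elongated,
more mesenchymal cells — the shape index and the nematic shape function
rise together with the cell–cell distance, and the crossover scale of
these tilings responds to cell shape, not to cell size: at fixed cell
shape the tiling statistics are scale-invariant in $R/R_\mathrm{cc}$,
so a density trend of $R_\times/R_\mathrm{cc}$ *requires* the
density–shape coupling. The phenotype offsets {0, 0.03, 0.06, 0.09}
emulate lines with progressively reduced cell–cell adhesion at equal
density. The coupling slope and offsets were fixed once, so that total
elongation spans ≈1.03–1.22: within this window the crossover scale of
the generated tilings decreases monotonically with elongation, while
6-fold order still dominates 2-fold order for every single fixture at
the cell scale. Beyond $e \approx 1.25$ the global stretch starts to
bias every grain's 6-fold phase toward the stretch axis, creating
cross-grain hexatic coherence that pushes the crossover back out — a
property of affinely stretched polycrystals worth knowing when
choosing conditions.

## What the generator does and does not emulate

It emulates confluency, density control, elongation control,
finite-range hexatic order, and junction images with ridge blur and
additive Gaussian noise. It does not emulate curved junctions,
intensity inhomogeneity, uneven illumination, out-of-focus light,
nuclei bleed-through, cell divisions, motility, or mechanical
force balance (it is not a vertex model). Passing the round-trip and
trend tests therefore demonstrates the correctness and internal
consistency of the analysis chain on data with the assumed structure —
not segmentation robustness on arbitrary microscopy, for which the
thresholds (`threshold`, `minComponentPx`, `smoothSigmaPx`) exist as
tuning points.

# Density grouping and statistics

Monolayers are grouped by $R_\mathrm{cc}$ into contiguous half-open
intervals of width 2.6 µm labelled D1, D2, … (histograms use 0.2 µm
bins). The left edge of D1 defaults to the minimum observed
$R_\mathrm{cc}$ and is configurable, since the absolute anchor of the
labels is a reporting convention. Values on an edge belong to the
interval on the right; an epsilon of $10^{-9}$ in the bin arithmetic
absorbs float representation of edge values. Two-group comparisons use
the two-sided Wilcoxon rank-sum test (`stats::wilcox.test`) with the
conventional significance labels (`*` p ≤ 0.05 through `****`
p < 0.0001, `ns` above 0.05); multi-group testing is deliberately left
to standard Kruskal–Wallis/Dunn routines rather than re-implemented.

# Numerical choices and problem sizes

* Voronoi cells are computed by half-plane clipping with per-edge
  neighbor attribution and an early-termination bound (no neighbor can
  cut once half its distance exceeds the cell circumradius); the
  construction is exact for the point counts used here and is tested
  against lattice closed forms and Euler's mean of six neighbors.
* Degenerate tessellation inputs error with the offending indices
  (duplicates) or a collinearity message.
* Cells tangent to the box boundary count as border cells even when no
  clipping occurred.
* The test suite runs monolayers of ≈50–250 cells and ensembles of 60
  monolayers (≈200 cells each); rendered fixtures are 124 × 124 µm at
  0.5 µm/px (248² px). These sizes give stable statistics for every
  asserted margin while keeping the default suite fast.
* Trend assertions use pooled Spearman rank correlations across
  fixtures, with hexatic-dominated profiles censored as the largest
  crossover rank.

# Known limitations

* The generator's noise model is a stand-in, not a claim about any
  microscope; no attempt is made to match empirical noise statistics.
* Grid nodes near the field-of-view border average over truncated
  disks; no edge correction is applied, which biases the largest-radius
  rungs toward fewer contributing cells.
* The segmentation assumes a bright-junction, dark-interior contrast
  and a mostly convex tiling; strongly concave cells would need a
  different polygonization than angular ordering about the face
  centroid.
* Defect statistics at a single radius on a single monolayer are
  small-count quantities; aggregate over seeds or radii before
  comparing densities.
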