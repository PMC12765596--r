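---
title: "Constructing ecological security patterns with espkit"
author: "espkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing ecological security patterns with espkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espkit)
```

## The problem

An ecological security pattern (ESP) is a spatial scaffold for regional
conservation: *sources* (habitat patches large and intact enough to export
ecological flow), *corridors* (the least-cost linkages along which organisms
move between sources), and *nodes* (cells where corridors or pressures
concentrate). In mountainous regions all three respond strongly to vertical
zonation — climate, vegetation and human pressure are stratified by
altitude — so the choice of how sources are identified changes the whole
pattern. espkit implements three source strategies and carries each through
an identical corridor/node/metrics pipeline so they can be compared:

* **ESP1 — connectivity.** The land-cover map is binarized into ecological
  foreground (woodland, grassland, water) and background; morphological
  spatial pattern analysis (MSPA) classifies the foreground into core,
  islet, edge, perforation, bridge, loop and branch; connected core
  components above a minimum area become sources.
* **ESP2 — importance.** Legally designated nature-reserve polygons are
  rasterized (cell-centre rule) and taken as sources directly.
* **ESP3 — integrated.** The union of ESP1 and ESP2 cells is filtered by a
  comprehensive niche-suitability surface; cells above the suitability
  threshold are relabelled and small fragments dropped.

## The niche-suitability model

Six indicators are computed on co-registered grids, three per dimension.
Ecosystem services: biodiversity maintenance
$NPP \cdot F_{pre} \cdot F_{tmp} \cdot (1-F_{ele})$, water supply
$NPP \cdot F_{sic} \cdot F_{pre} \cdot (1-F_{slo})$, and soil and water
conservation $NPP \cdot (1-K) \cdot (1-F_{slo})$. Ecological sensitivities:
soil-and-water-loss $(R_i K_i LS_i C_i)^{1/4}$, land desertification
$(I_i W_i D_i C_i)^{1/4}$, and human activity intensity, the
construction-land share (in %) inside a moving circular window. Because
the raw layers mix units (g C/m², mm, °C, m, %), every factor is min-max
normalized to $[0,1]$ before entering its product; slope comes from the DEM
by Horn's 3×3 method and the infiltration factor from a soil-texture
lookup.

Each indicator $X_k$ is turned into a membership
$$F_k = \begin{cases} 0 & X_k < D_{min} \\ X_k / D_{opt} & D_{min} \le X_k <
D_{opt} \\ 1 & X_k \ge D_{opt}, \end{cases}$$
and the comprehensive niche is the weighted overlay
$F = \sum_k W_k F_k$ with service weights 0.25/0.45/0.30, sensitivity
weights 0.26/0.55/0.19, and the two dimensions combined 0.5/0.5 by
default. Cells with $F > 0.4$ qualify as optimal sources.

Design choices that were genuinely open, and how they are resolved here:

* The membership's jump from 0 to $D_{min}/D_{opt}$ at $X = D_{min}$ is
  kept exactly as defined rather than smoothed to
  $(X-D_{min})/(D_{opt}-D_{min})$; the branch behaviour is pinned by unit
  tests.
* $D_{opt}$ and $D_{min}$ are the 90th and 10th percentile of each
  indicator over the study area — a scale-free rule robust to outliers;
  both are configurable.
* Sensitivity indicators (and human activity) measure *badness*; their
  values are inverted ($X' = 1 - $ normalized value) before membership so
  that "suitability above 0.4" reads the same way in both dimensions. This
  is the only polarity under which a single threshold is coherent.
* The 0.4 threshold is applied to the combined $F$, not per dimension.
* The moving window for the construction-land share defaults to a 500 m
  radius; it is a free parameter with no canonical value.
* ESP3 combines ESP1 and ESP2 by union-then-filter (intersection would
  discard reserves lying outside MSPA cores, defeating the purpose of the
  reserve strategy); intersection is available as an option.

## The resistance surface and corridors

Movement cost is a weighted sum of seven classified factors (weights
0.23 MSPA element, 0.25 land use, 0.19 elevation, 0.14 slope, 0.07 road
proximity, 0.04 water proximity, 0.08 nighttime light), each mapped to
class values on the 10–100 scale; the surface is therefore bounded by the
extreme class values cell-wise. Bins follow the lower-exclusive /
upper-inclusive convention, so an elevation of exactly 373 m falls in the
"≤ 373" class. Two gaps in the published class tables had to be closed:
the perforation class (absent from the element table) is scored with edge
— both are one-cell boundary zones of core — and shrubland (absent from
the land-use table) with the sparse-forest/grassland class, its nearest
ecological analogue. Nightlight is min-max normalized to 0–100 before
binning; road and water proximities are exact Euclidean distances.

Corridors are least-cost paths over this surface between all unordered
pairs of source patches: cost distance is an exact multi-source Dijkstra
on the 8-neighbour lattice with step cost
$\text{cellsize}_{km} \cdot (R_a+R_b)/2$ (×$\sqrt2$ diagonally), verified
against exhaustive-relaxation and path-enumeration oracles to 1e-9.
Determinism is guaranteed by a fixed neighbour scan order
(E, N, W, S, NE, NW, SW, SE) for all tie-breaks. Deduplication counts each
cell-to-cell step once in the network length $C$, and a corridor ≥95%
contained in another is dropped from the count — the containment level is
a free parameter.

## Nodes, network indices and zonation

Ridge lines are the high-flow-accumulation channels of D8 routing on the
*inverted* resistance surface (its crest network is the low-resistance
travel system); valley lines come from routing the surface itself.
Strategic nodes are corridor × ridge intersections, artificial nodes are
road × valley intersections; intersections tolerate one cell of
8-neighbour dilation, clusters collapse to their centroid cell, and nodes
of the same type merge within a 2-cell radius. Flats are resolved by
iteratively draining toward already-resolved equal-elevation cells;
unresolved flats become pits, and no depression filling is applied — the
routed surface is resistance, not terrain, and its basins are meaningful.

The connectivity indices operate on a *structural* graph: one vertex per
source patch plus every junction where ≥3 corridor segments meet, links
being the maximal segments between vertices (an out-and-back excursion
touching a patch boundary is not a link, since a link joins two distinct
vertices). With $L$ links, $V$ vertices and total length $C$:
$\alpha = (L-V+1)/(2V-5)$, $\beta = L/V$, $\gamma = L/(3(V-2))$, and
cost ratio $= 1 - L/C$ (the count-over-kilometres form is the index's
convention; at small synthetic extents it can be negative). Indices are
reported at 4 decimals. On dense multigraphs $\alpha$ and $\gamma$ can
exceed 1; they are reported as the formulas evaluate.

Altitudinal profiles use bands anchored at 0 m (default width 200 m):
source cells are assigned by their DEM value, each corridor step by the
elevation of its midpoint (the simplest rule that makes band lengths sum
exactly to $C$), nodes by the DEM at their cell. Unimodality of a band
profile is checked directly (rises to the maximum, then falls, plateaus
allowed) with a deviation score from the best up-then-down isotonic fit.

## The synthetic landscape

All tests and examples run on a seeded synthetic mountain landscape
(`generate_landscape()`), 256×256 cells of 30 m by default (≈59 km²):

* The DEM sums several anisotropic Gaussian massifs placed on a jittered
  lattice (so saddles between massifs stay low and the mid-elevation belt
  breaks into distinct habitat patches), a weak central dome, and spectral
  fractal noise; it is min-max anchored to 0–2200 m.
* Temperature falls at 0.006 °C/m from an 18 °C valley base, so the
  800–1000 m belt averages ≈12.6 °C; precipitation follows a humped
  elevation profile peaking mid-mountain (≈720 mm at 900 m). NPP and NDVI
  are unimodal in elevation with the maximum near 1000 m.
* Land use is drawn per 400-m elevation band from a probability table
  (lowlands dominated by cropland and construction, the 800–1200 m belt by
  closed forest and grassland, high elevations by shrub, sparse forest and
  unused land). A rank-uniform transform of a clustered suitability field
  — autocorrelated noise mixed with massif proximity, ecological classes
  at the top of the within-band ordering — makes classes spatially
  coherent while matching the band proportions essentially exactly.
* Water is carved along the top flow-accumulation percentile of the DEM,
  nightlight decays exponentially with elevation, roads are
  least-elevation paths between low-elevation endpoints (hence
  valley-following), and reserve polygons are irregular dodecagons centred
  at 800–1800 m.
* Every layer draws from its own stream derived from the master seed by a
  fixed labelled offset, so adding a layer never perturbs existing ones
  and bundles are bit-reproducible.

What the generator emulates is the *vertical structure* of a mid-latitude
mountain region; what it does not emulate includes real land-cover
autocorrelation regimes, hydrographic networks with realistic topology,
anthropogenic road hierarchies, and any particular region's geography.
Passing tests therefore demonstrate algorithmic correctness and the
qualitative vertical-zonation behaviour, not fidelity to any real
landscape.

## Numerical choices and problem sizes

Grid registration (shape, cell size, origin) is asserted, never silently
resampled; missing cells propagate through every derived layer. The
default pipeline scale is the generator's 256×256 grid, which a full
three-strategy run completes in a few seconds; unit and oracle tests use
4×4 to 96×96 fixtures (the MSPA classifier is checked against an
independent set-computation oracle on all 65,536 4×4 binary grids, cost
distance against exhaustive relaxation on ≤6×6 grids). The source
minimum-area default is 0.5 km² at the default extent. Degenerate inputs
fail loudly: constant grids cannot be normalized, an empty feature set has
no distances, a strategy with fewer than two source patches cannot grow
corridors, and a cycle in a flow-direction grid (impossible under the
tie-break rules) is an internal error.

## Known limitations

* Rasters are exchanged as ESRI ASCII text grids and vectors as GeoJSON;
  there is no reprojection, resampling or multi-band support, and inputs
  must already be on a projected metric grid.
* The MSPA classifier is a simplified reimplementation: the
  transition-style boundary semantics are fixed, internal/external
  subclasses are not distinguished, and for edge widths above 1 the
  boundary zone is assigned geodesically through the foreground.
* Corridor importance is not ranked (no gravity model, no circuit-theory
  current flow); corridors are unbuffered cell-centre polylines.
* The index formulas are evaluated on whatever graph the corridors induce;
  on dense small graphs they leave the 0–1 range that planar networks
  respect.
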