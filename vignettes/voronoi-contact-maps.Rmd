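---
title: "Voronoi density estimation for chromosome conformation capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi density estimation for chromosome conformation capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorocc)
library(ggplot2)
```

## The estimator

Chromosome conformation capture assays (Hi-C, micro-C) produce read
pairs: each sequenced ligation product marks two genomic loci that were
spatially close, and is naturally a point $(x, y)$ in the plane spanned
by two chromosomal axes. The conventional summary is the interaction
matrix — read-pair counts in fixed-size square bins — whose bin size
trades resolution against noise and whose counts depend on where points
fall relative to the arbitrary bin grid.

`vorocc` instead treats the read pairs as seeds of a Voronoi
tessellation. Every read pair owns the convex polygon of locations
nearer to it than to any other pair, clipped to the query viewport, and
the reciprocal polygon area is a local density estimate:

$$\hat\lambda(p_i) \;=\; \frac{m_i}{\operatorname{area}(V_i)} ,$$

where $m_i$ is the multiplicity of coincident pairs collapsed onto seed
$i$ and $V_i$ its clipped cell. This is an adaptive-binning estimator:
small cells where pairs cluster (focal contacts), large cells where
they are sparse. Cell areas partition the viewport, so
$\sum_i \hat\lambda_i \, \operatorname{area}(V_i)$ returns exactly the
number of retained pairs — a conservation property the test suite
checks to $10^{-9}$ relative tolerance.

Cells are computed exactly: the Voronoi cell of a seed restricted to a
convex window is the intersection of the window with the bisector
half-planes between the seed and its Delaunay neighbours. The Delaunay
structure comes from `interp`'s sweep-hull triangulation, the clipping
is a compiled Sutherland–Hodgman pass per cell, and correctness is
validated in the tests against brute-force nearest-seed labelling and
against an independent tessellation implementation (`deldir`). All-
collinear seed sets, for which a triangulation does not exist, are
handled directly: their cells are the slabs between perpendicular
bisectors of adjacent points along the line.

### Coordinate conventions

Pairs files store 1-based positions (the pairs standard). All internal
interval arithmetic is 0-based half-open; the conversion `pos - 1`
happens exactly once, at the parsing boundary, and every public
function documents which convention it speaks. Region strings such as
`"chr3:3,000,001-4,500,000"` follow the 1-based closed genomics
convention and are converted by `parse_region()`. Points exactly on
the viewport edge are retained; clipping treats the boundary as
closed. Viewports larger than $2^{53}$ bp$^2$ are rejected because
their coordinates are not exactly representable in doubles; internally
the tessellation runs in viewport-scaled coordinates for the same
reason.

## Large inputs

Three devices keep the tessellation tractable, mirroring the display
semantics of interactive use:

* **Fallback binning.** Above `max_points` (default 100,000) points,
  cells would be smaller than an output pixel, so points are binned to
  the output resolution and a count grid is returned; a zoomed query
  that falls back under the threshold gets a true diagram again.
* **Upper-triangle reflection.** Intrachromosomal maps are symmetric,
  so only the upper-triangle points are tessellated, constrained to
  the triangle, and mirrored across $x = y$. For a mirror-symmetric
  point set this is exact, not an approximation: no location above the
  diagonal is nearer to a mirrored seed than to its original.
* **Filter distance.** Points with perpendicular distance to the
  diagonal below $d$ (i.e. $|x - y| < d\sqrt2$) can be dropped before
  tessellating, since most pairs sit near the diagonal and long-range
  queries do not need them. The geometric (perpendicular) reading of
  the distance is a documented interpretation choice.

## Centroidal smoothing

`smooth_diagram()` performs Lloyd iterations: each seed moves to the
area centroid of its clipped cell (signed-area decomposition formula)
and the diagram is rebuilt. Multiplicities move with their centroids —
mass is conserved, never re-split. Smoothing locally equalizes cell
areas, which makes focal structure easier to see; display functions
default to a single iteration, and `smooth = 0` is the identity.
Iteration stops early when the maximum seed displacement falls below
`1e-6` of the larger viewport side: the textbook stopping rule (exact
co-location of centroids and seeds) is unattainable in floating
point. Lloyd's algorithm never increases the quantization energy
$\sum_i \int_{V_i} \lVert p - s_i\rVert^2 \, dp$; the tests assert
this numerically over 50 iterations with a fixed Monte-Carlo sample.
When a diagram is built with reflection, smoothing is applied to the
triangle-constrained diagram *before* mirroring, so both halves stay
exact mirror images.

## Identifying high-frequency contacts

The caller works per chromosome on the raw (unsmoothed) diagram over
the full chromosome square:

1. every intrachromosomal pair yields an observation
   $(\log s_i, \log \hat\lambda_i)$, with $s_i = |pos_2 - pos_1|$;
   pairs with $s_i$ below `min_distance` (default 1,000 bp, excluding
   self-ligation artefacts) are excluded from fitting but still shape
   their neighbours' cells;
2. a robust linear model $\log \hat\lambda = a + b \log s$ is fitted
   by MM-estimation (bisquare $\psi$, 95% Gaussian efficiency,
   `MASS::rlm`); its prediction is the expected background density at
   each distance and its robust residual scale $\hat\sigma$ calibrates
   the test;
3. each pair gets a one-sided z-score
   $z_i = (\log\hat\lambda_i - a - b\log s_i)/\hat\sigma$ and
   $p_i = 1 - \Phi(z_i)$;
4. Benjamini–Hochberg selection retains pairs at a 10% false discovery
   rate;
5. retained pairs are counted in 5,000 bp square bins (grid anchored
   at coordinate 0) and bins with at least `min_support = 5` retained
   pairs are reported.

The robust-regression variant and its tuning constants are fixed
(MM/bisquare/95%) for reproducibility and exposed through the
`estimator` argument; the fit is per chromosome by default (distance
decay varies between chromosomes) with a `pooled` option.
Interchromosomal pairs carry no distance and are excluded. The bin
grid anchor, the per-chromosome fit scope and the minimum distance are
all configurable because none of them is canonical.

### What the z-test does and does not control

Under a homogeneous background the per-pair noise of
$\log \hat\lambda$ is not Gaussian: normalized Voronoi cell areas are
approximately Gamma distributed, so $-\log(\text{area})$ has a
subexponential upper tail. The one-sided z-test is therefore
anti-conservative far in the tail, and in pure power-law null
simulations (50,000 pairs) Benjamini–Hochberg retains a few hundred
background pairs per replicate — the acceptance script computes this
realized pairwise false-discovery proportion and reports it without
adjustment. What keeps the final calls clean is the support filter:
retained background pairs are scattered, so the requirement of five
retained pairs in one 5 kb bin yields zero spurious bins per null
replicate in the test suite, while planted focal loops (15 extra
pairs) are recovered essentially completely. Treat the per-pair FDR
as a ranking device, not a calibrated error rate; the bin-level
support threshold is the operative filter.

## Pileups and signal enrichment

For each candidate bin, a 21×21 window of observed counts (the bin
extended by 10 bins = 50 kb in every direction) is divided pixel-wise
by an expected model. The expected value at diagonal offset $d$ (in
bins) is the mean observed count over all bins at that offset, zeros
included — a self-contained distance-decay expected, computed from the
same data, with no balancing. Matrix balancing is deliberately out of
scope, so absolute enrichment values on real data will differ from
pipelines that divide by a balanced expected track.

The signal enrichment statistic is the mean of the 3×3 centre block
divided by the mean over five 3×3 background blocks (upper left, upper
middle, upper right, middle right, lower right, at the printed 1-based
coordinates, used exactly as stated — the middle-column blocks are not
trimmed around the centre strip). Pixels with zero expected are
missing and are dropped from block means rather than imputed; a zero
background mean makes the enrichment infinite and such loops are
excluded from averages, with the number of finite loops reported
alongside the mean. Candidate bins closer than 10 bins to the matrix
edge or the diagonal are excluded with a warning; window pixels that
fall below the diagonal read the mirrored bin, which is exact because
the count table is symmetric.

## The synthetic data generator

`simulate_pairs()` emulates the statistical structure the estimator is
designed for, without mechanistic polymer simulation:

* background distances follow a truncated power law
  $P(s) \propto s^{-\alpha}$ on `min_distance .. chrom_length`
  (default $\alpha = 1$, floor 1,000 bp to mirror the caller's
  minimum distance), sampled by continuous inverse CDF and rounded to
  integer bp — a discrete CDF over $5\times10^7$ support values would
  cost more memory than the rounding error is worth; midpoints are
  uniform;
* TAD blocks multiply within-block contact frequency via rejection
  sampling, so the requested pair count is exact;
* planted loops add a fixed number of extra pairs per anchor with
  Gaussian positional jitter, and the truth table records each
  anchor's 5 kb bin on the same 0-anchored grid the caller uses.

Identical spec and seed give byte-identical files. The generator does
**not** emulate A/B compartment checkerboards, fragment-level biases,
duplicate reads or interchromosomal background, so green tests say the
method recovers focal enrichments over a smooth distance decay — not
that it is robust to every artefact of real libraries.

Default study conditions used throughout the tests and the acceptance
script: a 50 Mb chromosome, 50,000 background pairs, $\alpha = 1$;
planted loops carry 15 extra pairs with 500 bp jitter at distances of
100 kb–1 Mb. Unit tests use scaled-down versions of the same
conditions (20 Mb / 20,000 pairs) so the default suite runs in a few
minutes.

## Display conventions

Heatmaps remove the diagonal band (width one bin on each side by
default), square-root transform the counts and saturate the colour
scale at the 99.9% quantile of the nonzero transformed values (whether
zeros enter the quantile is configurable; excluding them is the
default because long-range views are mostly zeros). Voronoi figures
fill cells by log area with smaller (denser) cells hotter; the exact
palette is an aesthetic choice, not a claim. The triangle view rotates
an on-diagonal square viewport by 45° so the diagonal becomes the
horizontal baseline; the rotation is rigid, so areas are unchanged and
the rendered width is $\sqrt2$ times the viewport span. On-diagonal
heatmaps are completed symmetrically: a pair strictly off the diagonal
also counts at its mirror position, which reproduces the worked
counting examples for clusters that straddle bin corners.

## A worked example

```{r example, fig.width = 5, fig.height = 4.5, eval = requireNamespace("interp", quietly = TRUE)}
loops <- tibble::tibble(pos1 = 4e6 + 2500, pos2 = 4.4e6 + 2500,
                        n_pairs = 15, jitter_sd = 500)
sim <- simulate_pairs(sim_spec(chrom = "chrS", chrom_length = 2e7,
                               n_pairs = 20000, loops = loops, seed = 1))

called <- call_loops(sim$pairs)
called

truth_eval(called, sim$truth)

vp <- viewport("chrS", 3.5e6, 5e6)
d <- voronoi_diagram(sim$pairs, vp, reflect = TRUE, smooth = 1)
autoplot(d)
```

## Known limitations

* The pairwise FDR is not calibrated under the true Voronoi noise
  distribution (see above); bin support is the operative filter.
* Clipping the full-chromosome diagram at the rectangle (rather than
  mirroring across the diagonal) deflates densities for near-diagonal
  pairs, which the distance-decay fit absorbs only approximately; the
  fitted slope in $\alpha = 1$ nulls is correspondingly a little
  shallower than $-1$.
* The expected model is unbalanced; enrichment values are comparable
  within a data set, not across differently processed ones.
* BGZF files are read through R's gzip stream: indexed queries skip
  parsing outside the requested byte ranges but still decompress the
  stream up to them, so random access into very large compressed
  files is linear in offset, not constant.
* Weighted (power) Voronoi diagrams, balancing/normalization, TAD
  calling and duplicate filtering are out of scope.
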