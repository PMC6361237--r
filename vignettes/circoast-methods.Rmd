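---
title: "Testing cell-network colocalization against random placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cell-network colocalization against random placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Disk-shaped objects — injected stem cells, microspheres, vesicles — often
appear to sit on top of a network structure such as the microvasculature in
2D projected fluorescence images. Whether they do so *more often than
chance* cannot be decided by counting colocalization events per field of
view, per millimetre of vessel, or per cell: every one of those ratios
shifts when either the cell density or the network density changes between
study groups, and in disease models both routinely do. This package tests
colocalization against an explicit null model of random placement that is
built per image, so the test is unconfounded by density by construction.

## The null model

Segment the network channel with a user-chosen global threshold, then
dilate the binary network by the cell radius r. A cell whose centre falls
anywhere in the dilated region overlaps the network by at least one pixel;
the dilated area fraction is the **cell-dilated network fraction (CDNF)**,
written p. Under uniform random placement of n independent cell centres the
number of colocalized cells is *exactly*

c ~ Binomial(n, p),

with mean np and standard deviation sqrt(np(1-p)). The mean intercellular
colocalization fraction (ICF = c/n) under randomness is therefore p itself.
The agent-based Monte Carlo model (`mcmrp_distribution()`) samples this
distribution directly and exists to validate the closed form and to support
constrained variants (non-overlap, clumping); the binomial form
(`circoast_image_p()`) is what the tests use.

* **Single image**: upper tail P(X >= c), computed as a direct tail sum
  (`pbinom(..., lower.tail = FALSE)`), never 1 − CDF, so small p-values do
  not cancel. c = 0 gives exactly 1.
* **One replicate, many images**: sampling adequacy is set by the number of
  cells, not fields of view, so images are pooled — dilated pixels and image
  areas are summed (an area-weighted CDNF) and cell counts are summed.
  Pooling a dilate-then-split partition of an image reproduces the
  whole-image p-value exactly; splitting before dilating loses
  cross-boundary dilation and is only approximate.
* **One study group** (`one_sample_circoast()`): under the null every
  replicate p-value is Uniform(0,1), so the group mean p-value follows the
  Bates distribution (mean of N uniforms). The pseudo-null is simulated
  (default 1e7 trials, chunked) and the reported value is the add-one
  corrected fraction of null means at or below the observed mean;
  `bates_mean_cdf()` provides the exact CDF as an analytic cross-check.
* **Two study groups** (`two_sample_circoast()`): a standard two-sample test
  (Wilcoxon rank-sum by default; Student's t optionally) gives an observed
  p, whose null distribution is built by permuting group labels and
  recomputing the same test. The reported value is the fraction of permuted
  test p-values <= the observed one (ties count, as stated), add-one
  corrected in Monte Carlo mode and exact in exhaustive mode. Default input
  granularity is one pooled p-value per biological replicate — replicates,
  not images, are the independent units; per-image p-values can be passed
  instead when images are the replicate.

## One rasterization rule everywhere

A pixel at offset (dx, dy) from a disk centre belongs to the pixelated disk
iff dx² + dy² <= r² (pixel-centre convention). The same rule drives network
dilation, the overlap test, non-overlap placement, the packing estimator
and the synthetic generator's vessel rasterization. This consistency is
what makes "centre inside the dilated network" *identical* to "disk
overlaps the network", and hence makes the binomial model exact rather than
approximate. Dilation is clipped at the image border (nothing is known
about network outside the field of view); centres may fall anywhere in the
image, matching the Monte Carlo placement rule.

## The synthetic network generator

`generate_network()` emulates arborized microvascular networks in four
stages: a dart-thrown point cloud with an enforced minimum distance (the
mesh scale), the pixelated Voronoi boundaries of those points (ridges of
the watershed of the distance transform; exact integer arithmetic, ties to
the lowest seed index, thinned to a strictly 1-px skeleton), seeded
uniform-random removal of skeleton segments until the rasterized network
fraction (or centreline length density) first drops to the target, and
dilation of the surviving centreline by the network radius. Removal states
are nested, so the stopping state is found by bisection over the removal
order — the result is identical to one-at-a-time removal. The stop rule
undershoots by at most one segment's rasterized contribution; a target
above the unpruned skeleton's value returns the skeleton unchanged with a
warning and a `target_unreachable` flag.

What the generator does *not* emulate: vessel calibre variation along a
branch, hierarchical branching statistics, flow-oriented anisotropy, image
noise, or segmentation artifacts. A green test on synthetic networks
establishes the statistics' behaviour for controllable, plausibly
vessel-like geometry — not the performance of any particular segmentation
pipeline on real images.

## Constrained placement and the hypergeometric variant

Real cells cannot overlap (overlapping cells are counted as one), which
caps the number of placeable cells. `place_cells_nonoverlapping()` places
fully contained, pairwise-disjoint pixelated disks at centres drawn
uniformly from the still-admissible sites — distributionally identical to
rejection sampling, with saturation detected exactly from the emptied
free-position set. `saturate_packing()` runs this to saturation; random
sequential packing stays well below the hexagonal bound of 0.901 and varies
with both cell diameter and image size, so the packing ratio is tabulated
by Monte Carlo (`build_packing_table()`, exact keys, opt-in
interpolation). The hypergeometric model then uses N = round(A·eta/(pi r²))
placeable cells of which K = round(N·p) colocalize (half-away-from-zero
rounding; fractional populations are meaningless in the pmf). Its mean ICF
equals the binomial p up to the 1/N rounding quantum, which is why the
binomial model is the one used for inference; the hypergeometric variant is
kept for model comparison only, and diameters under 5 px are rejected as
unresolvable.

Clumped placement (`place_clumps()`) answers whether homotypic clustering
distorts the null: anchors are uniform, members sit on the touching ring
(non-overlap) or within one radius (overlap), and member positions wrap
toroidally at the border. The wrap is a deliberate design choice — it keeps
each cell's marginal position distribution exactly uniform, which is the
property under which clumped and independent placement share the same mean
ICF. Note that two disjoint pixelated disks cannot sit closer than about
one pixel beyond the cell diameter, so "touching" members lie at diameter
+ ~1 px from their anchor.

## Quantification error experiments

`miscount_experiment()` reproduces the connected-components failure mode:
at high density, overlapping cells merge into single components (8-connected
— diagonal contact merges too), counts drop and apparent per-object network
overlap rises, inflating false positives. The mitigation recovers an
effective disk from the mean component area (diameter = 2·sqrt(area/pi),
`effective_cell_model()`). Cells in this experiment are placed fully
contained, and the CDNF is evaluated over the admissible centre region, so
that component areas are not clipped at the border and the ground-truth arm
is exactly calibrated; the paper's border policy for this experiment is not
stated, and this is the package's choice. A quantified component counts as
colocalized iff its pixel set intersects the network.
`heterogeneous_diameter_check()` shows that a mixture of diameters is
closely approximated by the single mean-diameter disk (not identical — the
CDNF is not linear in diameter — but with negligible standardized effect
size).

## Numerical and algorithmic choices

* **Thinning** (centreline recovery in `measure_network()`, ridge cleanup in
  the generator) uses Guo–Hall parallel thinning. Zhang–Suen was evaluated
  first and rejected: its parallel form annihilates 2-px staircases
  (which the ridge marking produces on diagonal boundaries) and its
  sequential form leaves them unthinned.
* **Centreline length** counts unit steps as 1 and diagonal steps as
  sqrt(2), skipping diagonal pairs bridged by a shared 4-neighbour. This
  chamfer convention runs a few percent long on oblique segments, while the
  digital band width lies between 2r and 2r+1; the two biases nearly cancel,
  so the thin-vessel identity fraction ≈ 2r × length density holds to ~10%.
* **Tie and edge conventions**: permutation comparisons use "<= observed"
  exactly; Monte Carlo p-values carry the add-one correction and are never
  exactly 0; hypergeometric sd at N = 1 is 0 by convention; `round` in the
  HMRP parameters is half-away-from-zero.
* **Determinism**: every stochastic operation takes an optional seed and
  restores the caller's RNG state (`withr::with_seed`); compiled placement
  code draws from R's RNG, so `set.seed()` governs everything, including
  the C++ paths.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| cell diameter | px | user input | sets r for dilation; >= 1 px (>= 5 px for packing/HMRP) |
| global threshold | intensity | user input | the paper's adjustable segmentation; no auto-threshold |
| MCMRP trials | — | 2,000–10,000 | mean-ICF SE = sqrt(p(1−p)/(n·trials)) |
| pseudo-null trials | — | 1e7 | resolves group p-values down to ~1e-7 |
| permutations | — | 1e7 or exhaustive | exhaustive is exact and cheap for <= 6+6 replicates |
| network target fraction | — | 0.05–0.6 (sweep) | spans vascularized-tissue densities |
| network radius | px | 2–10 (sweep) | vessel half-thickness |
| min point distance | px | 15–40 (sweep) | Voronoi mesh scale; varies length density |

The sweep ranges reconstruct unavailable supplementary detail and are
documented as such; they were fixed before any acceptance measurement.

## Known limitations

2D projections only (a cell may colocalize in projection but not in z);
disks only — elongated morphologies are out of scope; no power analysis or
effect-size machinery; the hypergeometric variant's parameters are costly
to estimate and it is deliberately not wired into the hypothesis tests; at
the scaled-down validation size (300 images × 2,000 trials) the z-scored
regression coefficient on CDNF carries a standard error of ~8e-4, so its
third decimal is not a reproducible constant — only at the full published
scale (2,500 × 10,000, SE ~5e-5) is "1.000 to three decimals" a stable
statement. The package's acceptance suite records this distinction rather
than hiding it.

## A worked example

```{r, eval = FALSE}
library(circoast)

net <- generate_network(512, 512, min_dist = 25, network_radius = 4,
                        target = 0.3, seed = 42)
cell <- cell_model(12)
cdnf <- compute_cdnf(net$mask, cell)

# one experimental image: 150 detected cells, 120 on the network
obs <- coloc_observation(150, 120)
circoast_image_p(obs, cdnf)

# a replicate pooled over images, a group over replicates
rep1 <- replicate_test(list(list(network = net$mask,
                                 centers = place_cells_uniform(150, 512, 512,
                                                               seed = 7))),
                       cell = cell)
one_sample_circoast(c(0.02, 0.11, 0.35), trials = 1e6, seed = 1)
```
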