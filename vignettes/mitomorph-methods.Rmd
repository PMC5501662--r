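---
title: "Quantifying mitochondrial network length and connectivity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network length and connectivity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The problem

Mitochondria form a network that continuously fuses and fragments, and the
length and connectivity of that network track metabolic state, stress
responses and cell fate. Measuring them from confocal images is hard for a
specific reason: once mitochondria overlap, a 2-D image no longer contains
the information needed to decide whether two crossing or touching tubules
are one organelle or two. Any single topology assigned to the network is a
guess; quantification based on branch-point-to-branch-point distances
systematically underestimates organelle length, while chaining everything
into maximal paths overestimates it.

mitomorph takes the probabilistic view: it enumerates (or samples) the
admissible local topologies of every ambiguous branch point, scores them
with equal probability, and reports the resulting *distribution* of
mitochondrial lengths with a confidence band, together with connectivity
metrics that do not depend on resolving the ambiguity at all.

## Pipeline overview

1. **Segmentation** — a grayscale image becomes a binary mask
   (`segment_confocal()` for real images, `segment_synthetic()` for
   simulated ones).
2. **Skeletonization** — the mask is thinned to a 1-pixel centerline that
   preserves topology (`skeletonize()`).
3. **Structural elements** — each skeleton pixel is typed by its
   8-connected neighbour count (1 end, 2 tubule, >= 3 junction), same-type
   pixels are merged, and 4-way junctions are split into crossing tubules
   (`classify_and_merge()`, `split_four_way()`).
4. **Clusters** — connected sets of elements are analysed independently
   (`extract_clusters()`, `filter_dense_clusters()`), and connectivity is
   summarised (`connectivity_metrics()`).
5. **Interpretation** — per cluster, junction patterns are enumerated or
   sampled and averaged into a length distribution
   (`length_distribution()`).
6. **Comparison** — distributions are compared with the 1-D earth mover's
   distance and a within/between-condition protocol (`emd()`,
   `condition_emd_protocol()`).

The whole pipeline is exposed as a model fit: `mito_network()` returns a
classed object with `print()`, `summary()`, `coef()`, `plot()` and
`simulate()` methods, and `length_distribution()` is the estimator proper.

## Segmentation

The confocal recipe is: median smoothing (radius 2 px), contrast
enhancement, a local median threshold (radius 10 px, one mitochondrial
width), an intersecting global threshold, and one pass of count-based
erosion (a foreground pixel is dropped when at least 4 of its 8 neighbours
are background). The local threshold finds everything locally brighter than
its surroundings, including dim noise; the global threshold removes the dim
background; their intersection keeps exactly the mitochondrial signal, and
the erosion clears residual speckle.

Two steps of the published recipe are under-specified and were fixed here
as one consistent reading:

* *Contrast enhancement* ("0.4% saturated pixels; normalised, equalised
  histogram") is implemented as a percentile clip at 0.2/99.8%, a rescale
  to [0, 1], and histogram equalization anchored so that the minimum maps
  to 0. Manual global thresholds are therefore expressed on this enhanced
  [0, 1] scale.
* The *automatic* global threshold (used when no manual value is given) is
  the triangle method on a 256-bin histogram of the enhanced image — a
  standard choice for strongly skewed fluorescence histograms. The
  reference procedure sets this threshold manually per image, and so can
  users of this package.

Filter windows use reflect padding. A segmentation-free path exists for
synthetic images: a single global intensity threshold, by construction of
the simulator.

## Skeletonization

No installed R package provides 2-D topology-preserving thinning, so
mitomorph implements Guo–Hall thinning in C++: two sub-iterations per pass,
candidates marked on a snapshot and deleted sequentially under a
simple-point guard, so that connectivity can never break regardless of
evaluation order. A final cleanup removes redundant pixels — staircase
corners, residual 2x2 blocks and pixels closing trivial 3-cycles — defined
as non-endpoint pixels whose skeleton neighbours form one mutually
8-connected group. Line interiors (two opposite neighbour groups) and
endpoints (one neighbour) are untouchable, which preserves tip length.

Because ties are resolved in scan order, the skeleton is deterministic but
only *near*-equivariant under rotation and reflection: the element census
of a rotated image can differ by a pixel or two. The test suite asserts
census agreement within a small absolute tolerance rather than pixel
identity.

## Structural elements and connectivity

Merged junction pixels form one junction element whose degree is the number
of attached branches. Degree-2 "junctions" (an artifact of merging) are
dissolved back into tubule pixels and the map rebuilt until stable. An end
pixel directly adjacent to a junction receives an explicit zero-length
connector tubule, so that every junction slot carries a tubule and the
handshake identity `2T = E + sum(junction degrees)` holds on every acyclic
cluster — this identity is asserted by the test suite on synthetic runs.

Four-way junctions are overwhelmingly two independent mitochondria crossing
rather than true branch points, and are disconnected before interpretation.
Branch directions are estimated by least squares over the five tubule
pixels nearest the junction, and branches are paired to minimise the summed
angular deviation from straight continuation (exhaustive over pairings for
even degree; greedy with a warning for odd degree >= 5, which leaves a
3-way junction behind).

Connectivity metrics per image: element counts and percentages, mean
elements per cluster `E_C` (3 for an isolated mitochondrion: one tubule,
two ends), junction/end ratio `J/E` (0 for a fully fragmented network),
tubule/end ratio, and connections per unit length. Shape classes follow the
operational definitions: a *donut* is a junction connected twice to the
same tubule with its third connection leading to an end; a *blob* is an
isolated 3-element cluster shorter than 1 um; isolated clusters of 1–2 um
are counted separately. Junction-free closed rings (1 closed tubule, no
ends) are reported separately and exempted from the handshake identity and
from `E_C >= 3`.

Clusters sitting in regions too dense to skeletonize reliably are excluded:
the foreground fraction is measured in the cluster's bounding box expanded
by 10 px (one mitochondrial width) and compared against 0.6. The margin
matters: an isolated *straight* tubule fills its own tight bounding box
almost completely and would otherwise be excluded spuriously, while for
genuinely dense regions the margin hardly dilutes the measurement.

## The interpretation model

Every end admits one local pattern (terminate) and every tubule interior
one (pass through). A degree-3 junction admits the patterns of the packaged
interpretation table, all with equal probability:

* all three branches terminating (1 pattern),
* one pass-through pair, third branch terminating at the junction (3),
* one pass-through pair, third branch abutting but unconnected (3),
* a true three-way junction joining all branches into one organelle (1).

The table lives in `inst/extdata/interpretation_table.json`, is regenerated
by `scripts/generate_interpretation_table.R`, and can be swapped via
`interpretation_table(path = ...)`; the pattern count is a configuration
property, not a constant of the code. The terminate/abut distinction does
not change path lengths, but it doubles the weight of the pair-plus-single
class relative to all-terminate, which is the intended prior: real contact
without fusion and real termination at a junction are separate events.

An interpretation picks one pattern per junction. Under this table every
combination is admissible — pass-through pairing is a matching on
attachment slots, so no tubule can be claimed by two paths and no rejection
sampling is needed. Clusters whose interpretation tree has at most 10,000
leaves are enumerated exhaustively; larger clusters are sampled (default
1000 interpretations, seeded). Junction-free clusters have exactly one
interpretation and zero variance.

**Lengths.** Tubule length is the Euclidean arc length of its ordered pixel
path (unit and sqrt(2) steps). A path crossing a junction adds the shortest
Euclidean path through the junction pixels between its entry and exit
contacts; a path terminating at a junction adds the contact step plus half
the junction extent; a true 3-way junction adds all three contact steps
plus the extent. Ends contribute their own pixel length. Choosing
connections redistributes length between organelles but never creates it.

**Distributions.** Each interpretation yields a normalized histogram of
path lengths (default bin width 0.5 um, half-open bins); the cluster
distribution is the per-bin mean with the per-bin standard deviation across
interpretations as the confidence band (1 SD), and the mean number of paths
as the expected organelle count. Cluster profiles are combined into the
image distribution weighted by expected counts and renormalized; per-bin
SDs combine as the count-weighted root mean square, treating clusters as
independent.

Two deterministic extremes bracket the estimate: `branchpoint_lengths()`
(every tubule its own organelle) and `longest_path_lengths()` (greedily
extract the longest admissible simple path, remove it, repeat;
equal-length ties are broken by the lexicographically smallest element-id
sequence). The expected mean length E[total]/E[count] lies between the two
extremes up to junction-interior bookkeeping — a true 3-way pattern counts
three contact steps where a simple path counts two — which stays below 1%
of a path length; the test suite asserts the ordering with that tolerance.

## Earth mover's distance

On shared bins, the 1-D EMD is the area between cumulative distributions,
`sum(|CDF1 - CDF2|) * bin_width`, in the units of the bin axis (um here;
reports carry a units flag, since pixel-binned and um-binned values are not
comparable). The test suite verifies the metric axioms and agreement with
an independent greedy transport solver, which is exact for 1-D convex
costs.

The replicate protocol compares each replicate's distribution against its
own condition's average (experimental variability, "within") and against
the other condition's average (treatment effect, "between"); averages are
per-bin arithmetic means renormalized after averaging. Pooling
(`pool_clusters()`) concatenates the clusters of several small image
sections into one analysis unit before interpretation, giving sparse
sections statistical weight.

For two-channel comparisons (outer-membrane vs matrix markers),
`channel_metric_ratio()` reports `E_C` and `J/E` ratios between channels —
near 1 for identical signals — and `cell_phenotype_scatter()` builds the
per-cell connectivity-vs-length cloud, both normalized to control means,
with lengths summarized as the reciprocal of the 1-um-bin mass.

## The synthetic image simulator

`generate_image()` emulates the validation setup: 500 x 500 px at
15 px/um, a configurable number of mitochondria with lengths drawn from D1
(Gaussian, mean 3 um, sigma 0.75 um), D2 (equal mixture at 2.5 and 5 um,
sigma 0.5 um), D3 (a packaged fibroblast-like table: truncated log-normal
with mode near 2 um, spanning 1–10 um), or any custom length table; draws
are truncated to 1–10 um. The sigmas and the D3 table are explicit
surrogates where only the means are documented, and all are configurable.

Centerlines grow as bounded-turn random walks **on the integer pixel
grid**: the heading diffuses and each step moves to the 8-neighbour nearest
the current heading, reflecting off borders. This serves two purposes:
seed determinism across platforms (integer pixel operations only), and
consistent length bookkeeping — the recorded true length is the Euclidean
chain length of the path, measured exactly as a skeleton is measured, so
the pre/post comparison is not biased by rasterization. The walk stops when
the accumulated chain length reaches the drawn target, so recorded lengths
match targets within one pixel step and their total is conserved exactly.

The heading diffusion is 15 degrees per square root of micrometer of arc
(about 3.9 degrees per pixel at 15 px/um), which puts the radius of
curvature on the micrometer scale — gentle bends, as in real mitochondria.
A per-*pixel* 15-degree step was rejected during development because it
bends tubes tighter than their own width; the skeleton of such a tube
sprouts spurious junctions and isolated mitochondria no longer read out as
exactly 3 elements per cluster, contradicting the intended baseline.

Tubes are widened by a Gaussian cross-section (sigma 2 px): the intensity
at a pixel is the maximum response along its own centerline, and
*overlapping mitochondria add*, as fluorescence does. At the half-maximum
threshold of 0.5 an isolated tube is ~5–6 px wide, and two tubes fuse in
the mask when their centerlines approach within about 6.7 px. In
no-overlap mode (used for isolated-mitochondrion baselines) a placement is
rejected if its centerline comes within 12 px of an existing one or within
8 px of itself at arc separation above 12 px — both clearances exceed the
fusion distance, guaranteeing exactly one unbranched mask component per
mitochondrion.

`skeleton_accuracy()` scores a computed skeleton against ground truth:
`length_ratio` is total true length over total skeleton length (1 means
equal), and `position_match` is the fraction of skeleton pixels within 1 px
(Chebyshev) of any true centerline pixel, with 0.95 as the
positional-agreement criterion. `density_sweep()` runs the generator across
mitochondrion counts and aggregates both scores by measured area fraction.

### What the simulator does and does not emulate

It reproduces the geometry of the validation images: scale, densities,
length models, tortuosity, apparent width, overlap. It does **not** model
photon noise, point-spread-function anisotropy, uneven illumination,
labelling heterogeneity or out-of-focus light. Passing tests on synthetic
images therefore validate the topological and probabilistic machinery, not
robustness to real-world noise — on real data, segmentation quality is the
user's responsibility and should be validated per imaging setting.

### Known limitations

* **Positional agreement at high density.** Wherever two tubes run within
  the fusion distance, the skeleton of the merged mask lies *between* the
  two true centerlines, more than 1 px from either. On isolated
  mitochondria the positional match is 1.0, but at several hundred
  overlapping mitochondria per image a growing minority of skeleton pixels
  sits off-band, and many images fall below the 0.95 criterion. This is a
  property of skeletons of fused masks, not of the implementation; only a
  looser notion of "same place" recovers very high per-image pass rates at
  perinuclear densities.
* **Band coverage of recovered distributions.** With the packaged 8-pattern
  table, terminate/abut patterns cut some merged clusters into sub-1.5-um
  fragments that the true distribution does not contain, so at overlapping
  densities the input histogram leaves the 1-SD band in roughly a quarter
  of bins even though the recovered mean is within 0.3 um. The pattern
  table governs this trade-off and is deliberately swappable.
* **Pre/post length ratio under overlap.** Because merged stretches are
  skeletonized once but counted once per mitochondrion in the ground
  truth, the true/skeleton length ratio rises above 1 as density grows and
  explodes near full coverage; it does not dip below 0.9. The density
  filter's 60% cutoff is therefore conservative for the metrics this
  package computes.

## Numerical choices and degenerate inputs

* 8-connectivity throughout; isolated skeleton pixels are degenerate
  1-tubule + 2-end clusters (consistent with blob accounting).
* All-zero images segment to an empty mask with a warning, not an error;
  empty masks yield empty skeletons and empty cluster lists.
* A network with no ends (pure rings) has undefined `J/E`, reported as
  `NA` with a warning.
* Unnormalized distributions passed to `emd()` are renormalized with a
  warning; mismatched bin edges are an error.
* Randomness: every stochastic routine takes a seed; derived child seeds
  stay below 2^31. The caller's RNG state is saved and restored.
* Problem sizes in the test and acceptance runs are chosen for desk-scale
  reproduction: 10–500 mitochondria per image, 2–10 replicates per
  condition, 1000–5000 sampled interpretations, density sweeps to ~2400
  mitochondria. These reproduce every qualitative regime (isolated,
  cell-range, saturated) at a few minutes of CPU.

## Reading the outputs

`write_cluster_csv()` emits one row per cluster (element counts, length,
donut/blob flags) plus a summary row; `write_distribution_csv()` emits
`bin_lo, bin_hi, mass, sd`; `write_emd_csv()` the replicate protocol table;
`write_run_metadata()` a JSON sidecar with package version, seed,
parameters and the full interpretation table, so a run is reproducible
bit-for-bit from its outputs.
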