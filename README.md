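# mitomorph

Probabilistic quantification of mitochondrial network length and
connectivity from confocal images.

## The problem

Mitochondria form a dynamic network whose length distribution and
connectivity report on metabolism, stress responses and cell fate. In a 2-D
confocal image, however, overlapping mitochondria are ambiguous: nothing in
the image says whether two touching tubules are one fused organelle or two
crossing ones. Distances between branch points underestimate organelle
length; maximal paths overestimate it; the truth lies in between.

mitomorph resolves the ambiguity probabilistically. The segmented image is
skeletonized and decomposed into typed structural elements — ends, tubules
and junctions — grouped into clusters of connected mitochondria. Every
degree-3 junction admits a set of equally probable local connection
patterns (pass-through pairs, terminations, abutting contacts, true
three-way junctions); enumerating or sampling these patterns and averaging
yields, per image, the probability distribution of mitochondrial length

&nbsp;&nbsp;&nbsp;&nbsp;P(L) = Σ_clusters  w_c · P_c(L),&nbsp;&nbsp; w_c = E[mitochondria in cluster c],

with a per-bin 1-SD confidence band, alongside topology-free connectivity
metrics: the mean number of structural elements per cluster (*E_C*, = 3 for
an isolated mitochondrion), the junction/end ratio (*J/E*, = 0 for a fully
fragmented network), donut and blob counts. Distributions are compared with
the one-dimensional earth mover's distance, EMD = Σ |CDF₁ − CDF₂| · Δbin,
including a within/between-condition replicate protocol. A seeded synthetic
image simulator with exported ground truth (500×500 px at 15 px/µm,
tortuous centerlines widened by a Gaussian profile) validates the whole
pipeline.

It is intended for cell biologists quantifying mitochondrial morphology —
fragmentation, stress-induced elongation, inner-membrane remodeling via
two-channel ratios — from single-cell image crops.

## Worked example

```r
library(mitomorph)

## simulate a fibroblast-like cell image (120 mitochondria, seeded),
## segment it with a global threshold and fit the network model
sim <- generate_image(synthetic_spec(120, "D3", seed = 20))
net <- mito_network(sim$image, threshold = 0.5)
summary(net)
#> Mitochondrial network fit
#>   image: 500 x 500 px at 0.06667 um/px
#>   area fraction: 0.118
#>   clusters: 63 kept, 0 excluded (0%)
#> Mitochondrial network connectivity
#>   clusters: 63   elements: 404 (E 176 / T 172 / J 56)
#>   E_C: 6.41   J/E: 0.318   T/E: 0.977
#>   total length: 336 um   connections/um: 0.5
#>   donuts: 0   blobs: 2   isolated 1-2 um: 13

ld <- length_distribution(net, seed = 1)
ld
#> mito_length_dist (image): 101 bins of 0.5 um, 116 expected mitochondria
#>   mean length 3.11 um, mass sums to 1
plot(ld)           # distribution with its 1-SD confidence band
```

The 120 simulated mitochondria overlap into 63 clusters; the fit finds 56
junctions, an `E_C` of 6.4 (well above the isolated-mitochondrion minimum
of 3, i.e. a partly connected network), and recovers an expected count of
116 organelles with a mean length of 3.1 µm — close to the simulated
fibroblast-like distribution it was given. `coef(net)` returns the metric
vector, `simulate(net)` draws new synthetic images from the fitted length
distribution, and `emd()` / `condition_emd_protocol()` quantify shifts
between conditions:

```r
emd(length_distribution(net_control), length_distribution(net_starved))
```

A thin command-line front end covers the same pipeline
(`inst/cli/mitomorph.R`, subcommands `simulate`, `segment`, `analyze`,
`compare`, `sweep`).

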