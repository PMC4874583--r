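# cisgraph

Graph-based identification of common viral integration sites.

## The problem

Insertional-mutagenesis screens and gene-therapy follow-up studies recover
thousands of viral integration sites (IS) per experiment.  Genomic loci
that collect integrations far more densely than chance — *common
integration sites* (CIS) — flag genes under selection.  The classic
caller, the standard window method (SWM), requires a fixed number of sites
within a rigid window (2 within 30 kb, 3 within 50 kb, …), which fractures
elongated hotspots.  `cisgraph` replaces the rigid window with a
"stretchy" graph definition: every IS is a node, an edge joins two
same-chromosome sites at distance `< threshold`, and each connected
component of the graph is one CIS — equivalently, single-linkage
clustering of the positions cut at the threshold.

For every CIS the package computes order *O*, dimension
*d = IS_last − IS_first + 1*, average position *(IS_first + IS_last)/2*,
median position, Shannon entropy of the member labels normalized to
[0, 1] (*E = −Σ (nᵢ/O) log(nᵢ/O) / log n*, plus a variant normalized by
the dataset-wide label count *N*), a clustering p-value
*P[X ≥ O], X ~ Binomial(M, d/G)* under uniform placement of all *M*
sites on a *G*-bp genome, and the Poisson log-likelihood ratio of the
local rate *O/d* against the global rate *M/G*.  Downstream steps link
each CIS to its *gene atmosphere* (transcriptional elements with a TSS
within a distance threshold of its member sites) and compare the caller
gene-for-gene against the SWM baseline with next-gene annotation.  A
seeded synthetic generator with planted hotspots makes the whole pipeline
testable without external downloads.

## Worked example

```r
library(cisgraph)
sim <- simulate_is_data(simulation_config(seed = 42))   # 290 IS, 300 TEs, 6 planted hotspots
cis <- gbf_identify(sim$sites, threshold = 30000, min_order = 2)
as.data.frame(cis)[, c("cis_name", "order", "dimension", "entropy",
                       "norm_entropy", "p_value", "loglik_ratio")]
```

```
  cis_name order dimension   entropy norm_entropy      p_value loglik_ratio
1      1_1    15      3204 0.0000000    0.0000000 1.411981e-50    224.27566
2      1_2     2     10655 1.0000000    0.6309298 5.352194e-05     17.05726
3      1_3    15      3637 0.9182958    0.5793802 9.449906e-50    220.47373
4      2_4     2     23321 0.0000000    0.0000000 2.543135e-04     13.94868
5      2_5    15      3032 0.9877812    0.9877812 6.172256e-51    225.93065
6      2_6    15      3568 0.0000000    0.0000000 7.090497e-50    221.04822
7      3_7    15      3765 0.8366407    0.5278615 1.587466e-49    219.43632
8      3_8    15      3086 0.7312088    0.7312088 8.043118e-51    225.40116
```

The six order-15 components are the planted hotspots (their tight spans of
~3–4 kb and vanishing p-values reflect 15 sites packed into a 2 kb
hotspot on a 300 Mb genome); the two order-2 components are chance
background pairs with correspondingly modest significance.
Entropy 0 marks single-virus hotspots, 1 a perfectly mixed
one; the normalized variant discounts by the three labels present in the
whole dataset, so it only matches the plain entropy when a CIS contains
all of them.

```r
ga <- gbf_enhance(cis, sim$tes, ga_threshold = 100000)  # gene atmospheres
gbf_compare(sim$sites, sim$tes)$comparison
#> gene-set comparison: 0 GBF-only, 7 SWM-only, 1 shared
```

A command-line front-end wrapping the same functions ships with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "gbf.R", package = "cisgraph"))') \
    identify --is is.tsv --out cis.tsv --threshold 30000 --min-order 2
```

with `enhance`, `compare` and `simulate` subcommands (exit codes: 0 ok,
2 schema error, 3 parameter error).

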