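# otucoherence

Do abundance patterns of high-rank bacterial groups mean anything for the
taxa inside them? When a bacterial class (say, Betaproteobacteria) declines
downstream of a chain of reservoirs, that class-level trend is often read
as an ecological property of the whole lineage. `otucoherence` implements
the analyses needed to test that reading on a river metacommunity sampled
along a dam-regulated gradient: it asks which fraction of a class's
operational taxonomic units (OTUs, 16S rRNA clusters at 97% identity)
actually share the class's abundance trajectory, and which respond
differently — or in the opposite direction.

The package is aimed at microbial ecologists working with OTU count
tables, taxonomy assignments, a rooted phylogeny and sample metadata from
spatially structured surveys (rivers, transects, gradients).

## The core statistic

For a class *K* with per-sample abundance
$C_j = \sum_{i \in K} x_{ij}$ (non-rarefied counts, campaigns pooled),
every member OTU *i* is tested by the two-sided Pearson correlation
$r_i = \mathrm{cor}(x_{i\cdot}, C_\cdot)$, with p-values from the
*t* transform on *n* − 2 degrees of freedom and a Bonferroni correction
over the class's testable OTUs. Each OTU receives one verdict:

* **positive** — r > 0 and adjusted p < α: the OTU moves with its class;
* **negative** — r < 0 and adjusted p < α: it moves against it;
* **nonsignificant** — its dynamics are invisible at class level;
* **untestable** — constant count vector.

The positive group's share of OTUs and of class sequences, and the
diversity (Shannon, mean pairwise phylogenetic distance) of the positive
vs. non-correlated subgroups, quantify the class's *ecological
coherence*. Around this sit the standard stages: seeded rarefaction,
alpha diversity and upstream/downstream ANOVA contrasts, Bray-Curtis and
weighted-normalized UniFrac distances with rank-based ANOSIM permutation
tests, OTU origin assignment under unidirectional flow, reach-dominance
categorization, and an oblimin-rotated PCA of environmental variables
whose axes are correlated against OTU and class abundances.

A synthetic river-metacommunity generator (`simulate_dataset()`) emulates
the whole study design — 12 sites in three reaches, three campaigns,
multinomial sampling at realistic depths, planted coherent /
anti-responding / null OTUs with exported ground truth — so every stage
can be exercised and validated without any sequencing data.

## Worked example

```r
library(otucoherence)

b <- simulate_dataset(sim_config(), seed = 42)   # full study-shaped bundle
b$table
#> OTU table: 956 OTUs x 36 samples; 125,339 sequences

rar <- rarefy(b$table, 1000, seed = 42)
d <- bray_curtis(rar)
reach <- setNames(as.character(b$frames$reach), b$frames$sample_id)
keep <- rownames(d)[reach[rownames(d)] != "reservoir"]
anosim(d[keep, keep], reach[keep], n_permutations = 9999, seed = 42)
#> ANOSIM: R = 0.9981 , p = 1e-04 ( 9999 permutations, seed 42 )

part <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
part
#> Coherence partition for class Betaproteobacteria (n = 36 samples,
#> alpha = 0.05, family = 147):
#>       positive       negative nonsignificant     untestable
#>             17              0            130              3

pf <- positive_fraction(part, b$table)
round(c(otu = pf$otu_percent, sequence = pf$sequence_percent))
#>      otu sequence
#>       12       47

subgroup_summary(part, b$table, b$tree, flag_dominant_otus(b$table))
#>                class         group n_sequences n_otus pct_dominant shannon  mpd
#> 1 Betaproteobacteria      positive        8580     17         32.1    1.69 1.39
#> 2 Betaproteobacteria noncorrelated        9492    130         67.9    3.94 1.30
```

Reading the output: the simulated river separates upstream from
downstream communities almost perfectly (ANOSIM R ≈ 1); yet only 12% of
Betaproteobacteria OTUs — carrying 47% of the class's sequences — track
the class's own abundance trend, and the tracking subgroup is markedly
less diverse (Shannon 1.7 vs 3.9) and holds a minority of the class's
dominant OTUs. The non-correlated majority is invisible in the
class-level pattern.

`run_pipeline()` executes every stage end-to-end from a YAML
configuration and writes each result as a tab-separated table with a
manifest; see `?run_pipeline`.

## Vignette

`vignettes/class-otu-coherence.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the simulator does and does not emulate, and the package's numerical
conventions.
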