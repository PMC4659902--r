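---
title: "Measuring class-OTU ecological coherence along a river gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring class-OTU ecological coherence along a river gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otucoherence)
```

## The question and the model

High-rank bacterial lineages — phyla and classes — are routinely treated
as ecological units: when a class's sequence abundance rises or falls
along an environmental gradient, the trend is read as a shared preference
of its members. That reading is only justified if the class is
*ecologically coherent*: if most of its OTUs respond in the same
direction. This package quantifies coherence for a river metacommunity
interrupted by reservoirs, where an abrupt environmental step (the dam
system) separates upstream from downstream conditions and communities.

The pipeline treats the OTU-by-sample count table as its single
substrate. Samples belong to sites ordered along the flow, grouped into
three reaches (upstream, reservoir, downstream), and to repeated
campaigns. All stages are deterministic given their seed arguments.

### The coherence partition

For a class $K$ with member counts $x_{ij}$ the class abundance is
$C_j = \sum_{i\in K} x_{ij}$. Each OTU is scored by the Pearson
correlation between its count vector and $C$, using the non-rarefied
table with campaigns pooled, so that both spatial and seasonal variation
contribute. Two-sided p-values come from the $t$ transform with $n-2$
degrees of freedom; significance uses Bonferroni over the family of
testable OTUs, and each OTU receives exactly one verdict (positive,
negative, nonsignificant, untestable).

Open choices we fixed, and why:

* **Self-inclusion.** The class vector includes the focal OTU, because
  "class abundance" is simply the sum of its members. In tiny classes
  the self-term inflates positives (a single-OTU class is trivially
  positive with $r=1$), so a leave-one-out mode
  (`self_inclusion = FALSE`) is provided; under leave-one-out a class
  whose total is exactly constant remains testable, and an OTU mirroring
  the rest of its class is perfectly negative.
* **Bonferroni family.** The default family is the number of testable
  OTUs *within the focal class*, matching the per-class framing of the
  partition; a global family over all analyzed classes is available
  (`family = "global"`). Enlarging the family can only demote verdicts.
* **Untestable OTUs** (zero variance) count in neither numerator nor
  denominator of the OTU percentage but do count in sequence totals —
  a constant vector has no defined correlation, but its sequences are
  still part of the class.
* **Subgroups.** Summaries compare the *positive* group against the
  *non-correlated* (nonsignificant) group; significant negatives belong
  to neither. Reported percentages are rounded to integers in the
  headline figures; the underlying tables keep full precision.

### Diversity and distances

Alpha diversity per sample uses observed richness, the Shannon index
$H=-\sum p_i\log p_i$ in nats (the common ecology default; base 2 is
available), and the mean pairwise phylogenetic distance (MPD): the mean
patristic distance over all unordered pairs of distinct taxa present.
MPD is presence-based by default; the abundance-weighted variant weights
each distinct pair by the product of relative abundances, so equal
abundances reproduce the unweighted value exactly.

Upstream/downstream contrasts exclude the reservoir and report a signed
fold-change — $+\,\mathrm{up}/\mathrm{down}$ when the upstream mean is
larger, $-\,\mathrm{down}/\mathrm{up}$ otherwise, so the sign always
points at the richer reach and the magnitude is a ratio of means — plus
a log2 ratio and a one-way ANOVA p-value. In the degenerate equal-means
case ($F=0$) the p-value is defined as 1.

Beta diversity uses Bray-Curtis dissimilarity and weighted-normalized
UniFrac,
$d(x,y)=\sum_b \ell_b\,|p_b(x)-p_b(y)| \,/\, \sum_b \ell_b\,(p_b(x)+p_b(y))$,
where $p_b$ is the fraction of a sample's sequences descending from
branch $b$. Both are computed on the rarefied table so samples are
directly comparable; both are symmetric, zero-diagonal and bounded in
[0, 1]. Group differences use ANOSIM (Clarke's rank statistic) with
seeded label permutations and the $+1$ p-value correction, so p is never
exactly zero; R is invariant under monotone transforms of the distances.

### Rarefaction

Rarefaction draws without replacement (hypergeometric) to an exact
per-sample depth; samples below the depth are dropped and reported, not
padded — mirroring the usual exclusion of under-sequenced samples. The
seed is a required argument.

### Origin and dominance categorization

Under unidirectional flow, an OTU detected anywhere upstream must have
been transported downstream, so its *origin* is the farthest-upstream
reach (or site) of first detection, pooling campaigns, on the
non-rarefied table. *Dominance* is the reach with the strictly greatest
summed abundance; any tie yields "no change". Reach sums pool sites and
campaigns despite the unequal site counts (6/1/5), because the category
is defined on total sequence mass; a per-site-mean variant is available.
Figure-style reach summaries compute per-campaign fractions first (sites
pooled by summation within a campaign) and then average campaigns —
pooling-then-averaging and averaging-then-pooling differ, and the
per-campaign average is the documented choice. A class with no
sequences in a reach yields missing fractions, not zeros.

### Environmental axes

Environmental variables are standardized and the first two components
extracted from the correlation matrix. An oblimin (quartimin) rotation —
implemented in-package via oblique gradient projection — lets the two
axes correlate, so a seasonal and a spatial gradient can each be read
off one component; the inter-component correlation is reported, never
assumed zero. Rotation preserves per-variable communalities, and the
rotated total communality never exceeds the unrotated two-component
variance. Because component signs are arbitrary, each component is
flipped so its largest-|loading| variable loads positively. Oblique
factor scores are not unique; we use the regression method on the
standardized variables (with a pseudo-inverse when variables are
collinear). Correlations of OTU and class abundances with the axes are
reported unadjusted by default — the per-axis screening this mirrors
uses raw p < 0.05 — with a Bonferroni flag available; this divergence
from the partition's correction is deliberate and noted in the output.

## What the simulator emulates

`simulate_dataset()` generates the full input bundle under the study
design: 6 upstream, 1 reservoir and 5 downstream sites sampled in three
campaigns (36 samples); six dominant classes with sequence shares 68, 15,
6, 0.6, 4 and 3 % and class sizes on the scale of the observed inventory
(390/150/80/45/65/36 OTUs), plus ~190 rare filler OTUs carrying the
residual share so the 0.1% dominance threshold has realistic tails;
per-sample depths uniform on 1000–6222.

Expected log abundance of OTU $i$ in sample $s$ is
$\log b_i + \sigma_i\,\beta\,(\mathrm{space}_s - \tfrac12) +
g_i\,\gamma\,(\mathrm{season}_s - \tfrac12) + \varepsilon_{is}$,
with $b_i$ a within-class lognormal rank-abundance baseline (sdlog 1.5),
`space` a step function at the reservoir, `season` the winter-campaign
indicator, and $\varepsilon$ a lognormal jitter with CV 0.3 so that
correlation recovery is not unrealistically easy. A planted fraction
`coherent_fraction` of each class's OTUs shares the class's spatial sign
$\sigma$, `anti_fraction` takes $-\sigma$, the rest are null; seasonal
signs follow the same pattern around a per-class seasonal sign. Counts
are multinomial at the drawn depth, so column sums are exact. Each OTU
also has a true origin reach (92/4/4 % by default) and is absent from
reaches upstream of it. Environmental variables are linear combinations
of the same space/season factors plus noise (sd 0.3), half loading on
each factor. The tree is random bifurcating with exponential branch
lengths, classes monophyletic by default. The exported ground truth
carries every planted label and sign.

What it does **not** emulate: sequencing error, chimeras and read-level
artifacts; taxonomic misannotation; phylogenetic signal in the response
labels (responders are placed randomly within their class, so subgroup
MPD contrasts on simulated data are conservative); temporal
autocorrelation beyond a single seasonal step; and tributary inputs or
soil recruitment. Passing tests therefore demonstrate correctness of the
statistical machinery under a faithful *design*, not robustness to every
artifact of real amplicon data.

## Validation experiments and problem sizes

The test suite validates each stage against independent oracles:
hand-computed patristic and branch-sum values, picante (MPD), vegan
(Shannon, ANOSIM statistic), phyloseq (weighted-normalized UniFrac),
exhaustive enumeration of all 720 label orderings for the ANOSIM
permutation p on 6-sample instances, and the simulator's ground truth.

The recovery experiment measures how well the partition recovers a
planted coherent fraction $f \in \{0.25, 0.5, 0.75\}$: one focal class
of 40 OTUs carrying half the community, flat-ish rank-abundance
(sdlog 1), a strong reservoir step ($\beta = 3$), depth 2000, 32 samples
(the 36-sample design minus four winter samples), 20 seeds per $f$,
scored by the median absolute error of the recovered positive fraction.
No anti-responders are planted in this experiment, deliberately: the
recovery target assumes the class-level signal expresses the coherent
group. A separate experiment plants an anti-responder group of
comparable mass and shows the opposite — the class abundance vector
flattens and coherent OTUs lose their correlation. That cancellation is
not a failure mode of the method but the central scientific phenomenon:
a class containing balanced opposing subgroups has an abundance pattern
that represents almost none of its members.

Problem sizes throughout (full-design bundles of ~950 OTUs for
structural checks, 120-OTU communities for the replicated experiments,
9999 permutations where a p-value is reported, 99 where only the
statistic matters) were chosen so the whole suite exercises every stage
at study-realistic scale while remaining quick to run.

## Known limitations

* Pearson correlations on counts are sensitive to compositional
  coupling: under fixed sequencing depth, a strongly responding class
  induces apparent responses in unrelated taxa. The simulator reproduces
  this (null responders can acquire significant negative correlations),
  and interpretation of negative verdicts should keep it in mind.
* Bonferroni within class is conservative for large classes; rare OTUs
  with few sequences are usually nonsignificant regardless of their true
  response, so the positive fraction is a lower bound for lineages
  dominated by rare members.
* The oblimin implementation targets exactly the two-component solution
  the analysis needs; it is not a general factor-rotation toolbox.
* Origin assignment treats any single detection as presence; with
  shallow sampling an OTU truly present upstream can be first detected
  downstream, biasing origins downstream. The effect shrinks with depth
  and campaigns pooled.
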