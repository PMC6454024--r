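---
title: "Methods: cross-species contrast of hormone-responsive pathway networks"
author: "netcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species contrast of hormone-responsive pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcontrast)
```

## The analysis problem

`netcontrast` compares how two species respond transcriptionally to the same
stimulus — the motivating case is a thyroid-hormone (T~3~) challenge of
homologous amphibian tissues — when each species contributes exactly one
treated and one control RNA-seq library. Three things make this setting
awkward for standard tooling: there are no replicates, so no
dispersion-based test is possible; the two species' genes live in different
identifier spaces and must be linked through sequence similarity; and the
biologically interesting question is not which genes respond but *where* in
the shared pathway network the responses concentrate.

The package implements the full chain: threshold-based differential
expression (DE) per species, reciprocal-best-hit (RBH) homology, merging of
pathway collections into one functional-interaction network, hub and
degree-distribution statistics, and a label-permutation z-score test for DE
enrichment in the graph neighborhood of seed genes. A synthetic-data
generator with planted ground truth makes every stage testable without any
external download.

## Differential expression without replicates

Genes whose raw counts summed over all samples of a species fall strictly
below 50 are discarded; the bound is strict, so a total of exactly 50
survives. Library depth is equalized with median-of-ratios size factors:
for sample $j$,
$$ s_j = \operatorname*{median}_{i \in R}
   \frac{k_{ij}}{(\prod_j k_{ij})^{1/m}}, $$
where $R$ is the set of genes with strictly positive counts in every
sample. The median is taken in linear space, directly on the ratios; with
an even number of reference genes this differs (slightly) from
exponentiating a median of log-ratios, and the linear form is the one the
accessor functions and tests define. Per gene, the response is summarized
as a pseudocount-stabilized fold change
$$ \mathrm{lfc}_i = \log_2
   \frac{\bar{n}_{i,\mathrm{treated}} + c}{\bar{n}_{i,\mathrm{control}} + c},
   \qquad c = 1, $$
on normalized counts. The pseudocount keeps the statistic finite and
monotone for genes observed in one condition only and leaves high-count
genes essentially untouched (a true 8-fold change at 1000 counts reads as
2.9988 rather than 3). A gene is called `up` when $\mathrm{lfc} \ge 1$,
`down` when $\mathrm{lfc} \le -1$; the threshold is inclusive in both
directions. There is deliberately **no** p-value at this stage: with $n=1$
per condition a dispersion estimate would be fiction, and the threshold is
the call. `qcPCA()` provides the usual sanity check that the leading
principal components of the log-normalized matrix track the design rather
than technical noise.

Two normalization caveats are worth recording. First, median-of-ratios was
chosen over trimmed-mean-of-M-values as the single supported method; the two
are near-equivalent for the depth-equalization role they play here, and
keeping one code path keeps the fold-change contract exact. Second, because
the pseudocount interacts with depth, the DE counts produced on real data by
any reimplementation of this style of analysis are sensitive to these
choices; the package's own counts are the reproducible quantity, and no
attempt is made to re-derive any particular published DE tally.

## Homology by reciprocal best hits

Cross-species links are built from two similarity hit tables (A→B and B→A,
BLAST tabular layout). Hits with bit-score strictly below 100 are dropped.
Multiple local alignments of the same query/subject pair collapse to their
best score. When several queries claim one subject, the winner is resolved
by score, then query length, then lexicographic id — the last step only to
make results deterministic. A pair $(a, b)$ enters the map iff $b$ is $a$'s
top-scoring subject *and* $a$ is $b$'s; the result is one-to-one by
construction and the package asserts bijectivity on every output. Mapped
pairs DE in both species are classified by sign agreement (concordant up /
concordant down / opposite); pairs DE in one species count as
species-specific.

## The merged pathway network

Pathways enter as GMT membership plus SIF interaction lines; an interaction
belongs to every pathway whose membership contains both endpoints
(induced-subgraph semantics, as in curated pathway databases — this also
makes GMT+SIF round-trips lossless). All pathways containing at least one
DE gene are selected and their interaction graphs merged into one simple
undirected network: duplicate edges collapse, self-loops are dropped.
Members that carry no interaction anywhere are *singletons*: they are
reported, but excluded from the graph and from every degree-based
statistic, since a degree-0 node says nothing about connectivity structure.

Topology annotation computes, per node, the degree, the hub flag (degree
strictly greater than 20 — degree 21 is a hub, degree 20 is not), and the
neighborhood connectivity (mean degree of the node's neighbors).
`excludeGeneModule()` removes a named node set and re-derives all three;
its intended use is excising a self-contained, densely interconnected
complex (e.g. a ribosomal-protein cluster) that would otherwise dominate
the degree distribution. Degree ECDFs are computed separately for DE and
non-DE nodes. Cross-network node overlap is counted through the homology
map and reported as integer percentages, rounded half up (95.49 → 95,
88.63 → 89), matching the reporting style of the field's tables.

## The neighborhood permutation test

Given seed nodes, the neighborhood is the union of all nodes at graph
distance 1..2 from any seed, seeds excluded. Seeds are excluded because in
the intended use they are DE by construction, and counting them would bias
the statistic they anchor. The observed statistic is the number of DE nodes
in the neighborhood. The null is built by shuffling: each permutation
reassigns the same number of DE labels to a uniformly random node subset of
the connected network and recounts; 1000 permutations estimate the null
mean and standard deviation (sample sd, $n-1$), giving
$z = (X_{\mathrm{obs}} - \hat\mu)/\hat\sigma$ and a two-sided normal tail
$p = 2(1 - \Phi(|z|))$. An empirical two-sided p-value — add-one-corrected
upper tail, doubled, capped at 1 — is always reported alongside, because
the normal reading is only trustworthy when the null is comfortably
non-degenerate; when $\hat\sigma = 0$ the result is flagged degenerate
rather than returning NaN. This permutation null is hypergeometric in the
limit, and the test suite holds the machinery to the closed form
($\mu = nK/N$, $\sigma^2 = nK(N-K)(N-n)/(N^2(N-1))$) within Monte-Carlo
error.

Two design points were genuinely open. (i) Whether the statistic should
count all DE genes or only DE *hubs* in the neighborhood: both readings are
defensible, so both are implemented; the default counts all DE genes, and
`restrictToHubs = TRUE` restricts both the observed count and the label
universe to hubs. (ii) Whether labels should shuffle over all members or
only the connected network: the default shuffles over the connected
network, because that is the object on which degrees, hubs and
neighborhoods are defined; singletons never enter any neighborhood, so
including them could only dilute the null.

## What the synthetic generator emulates — and what it does not

`simulateDataset()` emulates the study design end to end: two species with
a complete one-to-one homolog map; log-normal baseline means
($\log\mu \sim \mathcal{N}(5.5, 1)$, median ≈ 245 counts); negative-
binomial counts with dispersion 0.05 (variance $\mu + 0.05\mu^2$); one
library per condition; exactly $\lfloor 0.05\,n_{\mathrm{genes}} \rfloor$
genes planted DE per species at $|\mathrm{lfc}| = 1.5$ with random signs;
25 pathways of 10–30 members with intra-pathway edge density 0.15 (merged
mean degree around 6, comparable to a merged curated-pathway network); seed
genes wired to merged degree ≥ 25 so they are hubs under the default
threshold; optional relabeling of the seeds' radius-2 neighborhood to DE
with probability 0.7; and reciprocal hit tables in which every true pair
scores in 150–400 while decoys (0.2 per true pair) score in 60–200, one of
them pinned to 99 so the score filter's boundary is always exercised. When
neighborhood planting rewrites labels, the treated counts of the affected
genes are re-drawn so that expression-derived DE calls agree with the
stored truth — the planted network signal is therefore visible to the
*whole* pipeline, not only to the graph stage. The same pathway topology is
expressed in each species' own namespace through the homolog map,
mirroring a shared pathway database annotated per species.

The generator does **not** emulate read-level artifacts (assembly chimeras,
multi-mapping, GC bias), gene–gene correlation within pathways, overlap
between the two species' DE programs beyond chance, or hit-table paralogy
structure. Consequently, passing tests demonstrate that the pipeline's
logic and calibration are correct under the stated generative model; they
do not certify performance on real libraries, where normalization stress
and annotation error dominate.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs in well under a minute of
CPU apart from the calibration studies: type-I error uses 400 replicates
(20 independent unplanted networks of 300 genes × 20 label draws each, 1000
permutations, random seed pairs constrained to neighborhoods of at least 30
nodes with a DE fraction of 0.2 — inside the regime where the normal
reading of a discrete permutation null is honest); planted recovery uses 20
datasets of 400 genes, comparing the true seeds' z against the median over
50 random seed pairs. Determinism is contract, not accident: every
stochastic stage derives its own stream from one integer seed, restores the
caller's RNG state, and the pipeline writes byte-identical report bundles
under a fixed seed. Ties and degenerate inputs are handled explicitly:
inclusive DE thresholds, strict count/score/hub bounds, deterministic RBH
tie-breaks, warnings (not errors) for empty filters and absent removal
targets, and errors that name the offending gene, seed or file.

## Limitations

The DE caller is a threshold rule; it inherits the usual bias of
fold-change-only calls toward low-count genes (mitigated, not removed, by
the pseudocount) and cannot control any error rate. The homology map is
only as good as the hit tables; paralog families violate its one-to-one
assumption. The permutation test conditions on the observed network and DE
total, so its p-values are about label placement, not about network
inference uncertainty. And the term-profile contrast treats annotations as
flat labels — no ontology structure is used.
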