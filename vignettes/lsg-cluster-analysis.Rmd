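---
title: "Methods: chromosomal clustering and expression states of lineage-specific genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosomal clustering and expression states of lineage-specific genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsgclust)
```

## The problem

Lineage-specific genes (LSGs, "orphan" genes) have no detectable homologs
outside a focal lineage — here, a fungal genus such as *Neurospora*. Two
empirical regularities motivate this package: LSGs aggregate in clusters
near chromosome ends, interleaved with HET-domain allorecognition genes,
and their expression is unusually often switched fully on or off by
developmental and environmental perturbations rather than modulated.
`lsgclust` provides the complete analysis chain needed to quantify both
phenomena, together with seeded simulators so that every stage is testable
without any external download.

## Lineage classification

Input is a homology hit table: one row per (query gene, subject taxon)
with the taxonomic rank of their most recent common ancestor, an E-value,
and a reciprocal-best flag. Hits are filtered at a broad cutoff
(default `0.05`, the conventional homology-detection threshold). A gene's
phylostratum is the **most inclusive** MRCA rank among retained hits: one
retained out-of-genus hit removes lineage specificity, so
`is_lsg` is true iff every retained hit is in-genus. Genes with no
retained hits are reported as `unclassified-self-only` and flagged; they
count as LSGs because no external homology contradicts it, but downstream
users can exclude them via the flag. In-genus orthologs are confirmed at a
stricter cutoff (default `1e-10`) plus the reciprocal-best requirement.
The rank ladder is configurable; the default
(`Neurospora`, `Sordariomycetes`, `Pezizomycotina`, `Ascomycota`,
`Dikarya`, `Eukaryota`) mirrors the strata used in Sordariomycete
phylostratigraphy. Where conflicting rank evidence exists, the rule is
explicit: deepest rank of any retained hit wins; lowering the cutoff can
therefore only move genes toward more exclusive strata (a tested
invariant).

## Max-gap clustering and its permutation null

Genes are reduced to a 0/1 label vector in chromosomal order. A *max-gap
cluster* at parameter *g* is a maximal run of labeled genes in which
consecutive labeled genes are separated by at most *g* unlabeled genes.
Gaps are counted in genes, not base pairs, and the minimum cluster size is
2 — singletons are never clusters. Because maximal runs under this rule
are unique, a greedy left-to-right scan is exact; the test suite still
checks it against a brute-force enumeration of all maximal valid groups on
thousands of random vectors.

Significance uses the minimal exchangeability assumption: labels are
permuted uniformly **within each chromosome**, preserving per-chromosome
label counts. For an observed cluster of size *s*,

$$p = \frac{1 + \#\{\text{permutations with a run of size} \ge s\}}{1 + n_{\text{perm}}}$$

which is a valid (super-uniform) p-value; calibration is verified by a
one-sided Kolmogorov–Smirnov test over 500 null replicates. Because a
chromosome can contribute several clusters, p-values are
Benjamini–Hochberg adjusted across all clusters genome-wide before the
`p < 0.01` report filter; both raw and adjusted values are always kept.
Percentages in the per-size summary are always `count / class_total`;
published per-size tables of this kind occasionally print percentages that
do not exactly equal that ratio (e.g. 444 clustered genes of 670 reported
as 66.8% rather than 66.3%), so the package never copies a denominator it
cannot reproduce.

## Window-free model-averaged clustering profiles

A complementary, window-free view treats the label vector as a Bernoulli
sequence and considers **every partition into contiguous segments** (up to
`max_segments`). A model with segments $(m_j, k_j)$ (length, label count)
has maximized log-likelihood
$\sum_j [k_j \ln(k_j/m_j) + (m_j-k_j)\ln(1-k_j/m_j)]$ with
$0\ln 0 \equiv 0$, and parameter count $2s-1$ ($s$ rates, $s-1$
breakpoints) — stated explicitly because information-criterion parameter
counting is a genuine free choice here. Models are weighted by
$w_i \propto \exp(-(IC_i - IC_{\min})/2)$ under BIC (default; sample size
= number of positions), AIC, or AICc. The per-position profile is the
weighted average of the containing segment's rate; the 95% envelope is
the weighted 2.5%/97.5% quantile of that rate across models. Two
numerical conventions: the envelope is clamped to contain the averaged
rate (the mean of a discrete distribution may fall outside its central
quantiles), and models more than 50 IC units above the optimum are pruned
only if their collective normalized weight is below 1e-8.

Exhaustive enumeration ($2^{n-1}$ models) is feasible to $n = 20$ and
serves as the oracle. The production path is a dynamic program over
(position, segment count) with log-sum-exp accumulation: prefix and
suffix partition sums give each segment's total posterior weight, and
difference arrays accumulate per-position means in $O(n^2 S)$. The
averaged rate is exact at any length; the envelope is exact to $n = 64$
and otherwise computed on a 1024-bin rate grid (resolution ~0.001,
itself validated against the exact path at $n = 60$). The profile is
mirror-symmetric under sequence reversal, and BIC profiles are at least
as flat as AIC profiles for $n \ge 8$ (where $\ln n > 2$), both tested.
Chromosome-scale vectors ($n \approx 1500$) take a few seconds; $n$ near
$10^4$ is supported but takes minutes.

The flat partition space is a deliberate re-specification of the
hierarchical "clusters and subclusters" recursion of the original
model-averaging literature: it is exactly enumerable, which buys a real
oracle, and its profile answers the same question (regionalized
probability that a gene is labeled).

## Relative expression, states, and categories

Counts are normalized to counts per million; a gene is *measurable* in a
condition iff it reaches `detect_threshold` (default 1 CPM — the
threshold is an explicit choice, since "measurable expression" is rarely
defined operationally) in at least half of the replicates. Pooling
replicates, the condition's transcription rate has a Gamma posterior
$\Gamma(K + \tfrac12, N)$ (Jeffreys-style prior; $K$ summed counts, $N$
summed library size in millions). Levels are rescaled so the lowest
measurable condition equals 1; unmeasurable conditions are reported as 0
with interval [0, 0]. Ratios of independent Gamma posteriors are scaled-F
distributed, which gives closed-form 95% intervals and two-sided contrast
p-values — a deterministic stand-in for sampling-based Bayesian
relative-expression tools, preserving their output contract
(lowest condition = 1, unmeasurable = 0, 95% intervals).

On top of this sit three callers: `call_dynamic` (fold $\ge$ 5 between
extreme detectable conditions *and* BH-adjusted contrast significance at
$\alpha = 0.05$; genes measurable in fewer than two conditions are
excluded and flagged), `status_across_stages` (expressed overall iff
detected at $\ge 2$ sampled points, single-point detections tallied
separately), and `classify_pair` (six exhaustive, mutually exclusive
mutant-vs-wildtype categories: detectability first, then BH-adjusted
contrast direction). Whether published fold-change calls used raw or
adjusted p-values is ambiguous in this literature; both are exposed in
the detail table.

## Enrichment and coordination

`chi_square` is the textbook Pearson statistic without continuity
correction (counts at genome scale are large; a `correct` flag exists),
erroring on zero margins and warning when expected counts drop below 5.
`class_state_tables` builds LSG-vs-other tables per expression state,
excluding plain HET-domain genes from the comparison margin by default
(comparing lineage-specific genes against non-HET non-LSG genes), and
BH-adjusts across the family. `bh_adjust` is the step-up rule; note that
BH is *not* idempotent on arbitrary re-input — re-adjusting an adjusted
vector inflates its smallest entries — so the tests assert the step-up
definition, monotonicity and the cap instead.

Coordination within a cluster is the maximum pairwise Pearson correlation
(a Spearman flag exists) of member relative-expression profiles over the
conditions where **both** genes are measurable (dropped pairwise, never
imputed; at least 3 shared conditions). Constant or all-zero profiles have
undefined correlation and are excluded rather than scored 0 — a constant
gene carries no coordination signal. A cluster is coordinated iff the
maximum exceeds 0.5. Under independence with 6 timepoints the
false-positive rate of that rule is $P(r > 0.5) = P(t_4 > 1.1547) \approx
0.156$, and the implementation reproduces this analytic rate. Flanking
non-LSG neighbors can be included via a flag (default off, since it is
ambiguous whether neighbor pairs should count toward cluster
coordination).

## What the simulators emulate — and what they do not

`simulate_genome` plants contiguous LSG clusters with sizes drawn from
the observed cluster-size tally (57:2, 28:3, 8:4, 14:5, 5:6, 3:7, 2:8,
3:9, 1 each of 11/16/23) on seven 1500-gene chromosomes by default, LSG
fraction 670/10592 and 68 HET-domain genes, three of which sit on LSGs.
Telomere bias: with probability `telomere_bias` (default 0.9) a cluster's
anchor falls in the outer 10% of gene order, positioned by a Beta(0.5, 3)
draw mirrored at either end so density rises toward the very tip;
otherwise placement is uniform over the middle 80%. No quantitative
telomere-distance statistic exists to calibrate against, so the knob is
validated qualitatively (planted LSGs are rank-significantly closer to
chromosome ends). Planted clusters are separated by $\ge 3$ non-LSG genes,
making them exactly recoverable at `max_gap = 0` when the background rate
is 0. Physical coordinates mimic compact fungal gene density (~1 gene /
2.5 kb), 0-based half-open internally, 1-based inclusive in GFF3.

`simulate_hits` encodes class labels into hit structure (LSGs: in-genus
hits only; others: a defining out-of-genus hit at their simulated
stratum), so classification must round-trip exactly — a structural test of
the classifier, not a statistical one. `simulate_counts` draws
negative-binomial counts (dispersion 0.1, library size 5e6, mild
per-sample size factors) around smooth per-gene latent log-profiles whose
max/min fold spans `fold_change_range`; coordinated planted clusters
share one profile plus independent log-noise. Silencing is drawn per
gene × condition block (all replicates zero) with the marginal
probability `silent_gene_fraction`, correlated within genes through a
Beta(0.5f, 0.5(1−f)) propensity so that fully silent genes — the
"not expressed at all" state — actually occur.

Not emulated: sequence content (no FASTA, no alignment), repeat-induced
point mutation, physical intergenic-distance effects on clustering (the
max-gap rule is ordinal by design), read-level artifacts
(mapping ambiguity, GC bias), and between-gene count correlation beyond
the planted coordination. A green test therefore establishes correctness
of the statistical machinery on data satisfying the stated generative
assumptions — not robustness to, e.g., mappability artifacts.

## Fixed numerical choices

| Parameter | Default | Why |
|---|---|---|
| broad / ortholog E-cutoff | 0.05 / 1e-10 | conventional detection vs strict ortholog confirmation |
| max-gap scan | 5, 1, 0 | the standard parameter set for this analysis |
| min cluster size | 2 | per-size summaries start at 2; singletons are not clusters |
| cluster report filter | BH-adjusted p < 0.01 | family-adjusted version of the published per-cluster filter |
| detect threshold | 1 CPM in ≥ half replicates | explicit stand-in for an undefined "measurable" |
| pseudocount | 0.5 | Jeffreys-style Gamma shape |
| dynamic call | fold ≥ 5, BH α = 0.05 | published thresholds |
| coordination | Pearson r > 0.5, ≥ 3 shared conditions | published rule plus a minimal-overlap guard |
| profile criterion | BIC, `max_segments` 30 | the conservative criterion; 30 segments suffice for chromosome-arm structure |
| IC weight pruning | ΔIC > 50, only if pruned mass < 1e-8 | numerical hygiene without changing results |

Acceptance-style checks in `tests/testthat/test-acceptance.R` recompute
the published contingency enrichments from their printed tables, verify
oracle equivalence (greedy scan vs brute force; DP vs exhaustive
enumeration at 1e-9), calibration (permutation super-uniformity, dynamic
false-positive rate, the analytic coordination null), and recovery on a
1500-gene chromosome with two 50-gene telomeric blocks at label rate 0.6
over a 0.05 background — the block geometry is this package's choice, as
only the rates and length were prescribed. `scripts/acceptance.R` writes
the contingency p-values as a JSON report.

## A small worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  genome = genome_sim_config(n_chromosomes = 2, genes_per_chromosome = 250),
  expression = expression_sim_config(n_timepoints = 4, library_size = 2e5),
  n_perm = 500, seed = 42, outdir = "lsg_run")
report <- run_pipeline(cfg)
report$cluster_summary[["1"]]
report$enrichment
head(report$coordination)
```

Every artifact (GFF3, label/hit/count TSVs, cluster BED, profile,
relative-expression, enrichment and coordination tables) lands in
`outdir` with an md5 manifest; two runs with the same seed produce
identical manifests.

## Limitations

The permutation null conditions on per-chromosome label counts only; if
label density itself varies systematically along chromosomes for reasons
other than clustering (e.g. assembly artifacts), p-values inherit that
signal. The Gamma–Poisson stand-in pools replicates and therefore models
between-replicate variation only through the NB-like widening of the
pooled posterior, not as an explicit random effect. The flat partition
space grows profiles that are exact within `max_segments`; structure
finer than the bound is smoothed. Self-only genes (no hits at any cutoff)
are LSGs by convention and should be sensitivity-checked via their flag.
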