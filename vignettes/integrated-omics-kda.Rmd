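---
title: "Integrated transcriptome-metabolome analysis with network key driver discovery"
author: "OmicKDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated transcriptome-metabolome analysis with network key driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OmicKDA)
```

## The analysis this package implements

Short-term air-pollution exposure studies in rodents commonly profile the
same tissue on two platforms: expression microarrays on one cohort
(typically ~8 animals per group) and untargeted metabolomics on another
(typically ~5 per group), contrasting an exposed group against filtered-air
controls, sometimes with a third "washout" group. OmicKDA implements the
analysis chain such studies use to move from raw feature tables to a
mechanistic hypothesis:

1. **Differential analysis** per platform: Welch's two-sample t test on
   log2 values, Benjamini-Hochberg adjusted p values and Storey q values,
   fold changes as treated/control ratios of arithmetic group means on the
   original scale, and directional signatures at an adjusted-p cutoff.
2. **Enrichment**: gene set enrichment analysis (the weighted
   Kolmogorov-Smirnov running-sum statistic with permutation-based NES,
   nominal p and sign-stratified FDR) for the ranked transcriptome, and
   over-representation with the fold-enrichment ratio
   $\mathrm{Enrichment} = \frac{k/K}{n/N}$
   (significant-in-pathway fraction over the global significant fraction,
   with a one-sided hypergeometric p) for metabolite pathways.
3. **Key driver analysis (KDA)**: on a directed gene regulatory network,
   each gene's h-hop neighborhood is tested for enrichment of the
   differential signature with a one-sided Fisher's exact test; genes
   passing Bonferroni-adjusted p < 0.05 over the candidates tested are
   reported as key drivers.
4. **Classification**: a random-forest-style ensemble classifies exposure
   groups from metabolite profiles, yielding an accuracy estimate and a
   permutation-importance ranking of biochemicals.
5. **Integration**: differential genes and metabolites are joined on a
   shared pathway namespace (flagging pathways significant in both omics)
   and assembled into a key-driver-centered reaction map with per-node
   up/down/unchanged/unmeasured states.

Because raw study data are typically not redistributable, the package
ships synthetic-data generators that plant known effects and record them
(`SyntheticTruth`), so the whole chain is exercised and benchmarked by
truth recovery rather than by fixtures copied from any particular study.

## Statistical details and the choices behind them

### Differential analysis

`welchTest()` is the exact unequal-variance t with Welch-Satterthwaite
degrees of freedom (it agrees with `stats::t.test` to 1e-10; the
vectorized path is used across features). Features with fewer than two
observed values in a group are flagged untested and excluded from the FDR
family *m*, which is logged. Metabolite tables are min-imputed per feature
before the log transform (values below a detection floor are treated as
censored at the feature's observed minimum — the convention of commercial
profiling platforms), while fold changes are computed on the original
scale as ratios of arithmetic means, matching how profiling reports
tabulate them. Whether a ratio of arithmetic or geometric means is meant
is genuinely ambiguous in most reports; the arithmetic ratio is
implemented and documented.

Proprietary scanner-vendor differential algorithms are not emulated:
Welch's t (default) or Student's t is used, so absolute DEG counts from
studies that used such algorithms are not comparable, only the behavior of
the procedure.

The significance cutoff is a parameter everywhere (default 0.05), never a
constant: published analyses mix q < 0.12, FDR < 0.1 and p <= 0.05 between
their methods and results sections, so no single number deserves to be
hard-coded.

`qValues(method = "storey")` estimates the null proportion
$\pi_0$ on the grid $\lambda = 0.05, 0.10, \dots, 0.95$ via
`smooth.spline` (df = 3) evaluated at $\lambda = 0.95$, clamped into
$(0, 1]$; fewer than 100 p values fall back to BH with a warning, since
$\pi_0$ smoothing is meaningless on tiny families.

### Rank-invariant normalization

`rankInvariantNormalize()` selects, per sample, probes whose rank differs
from the reference ranking by at most 5% of the probe count, iterated
twice (re-ranking within the surviving set), and rescales by the median
reference/sample ratio over that set. The literature names this method
without fixing its tolerance; 5% with two passes keeps hundreds of probes
on realistic array sizes. The minimum invariant-set size is 50 probes or
5% of probes, whichever is smaller — below that the fit is refused with
advice to choose a different reference. A sample exactly proportional to
the reference is mapped onto it exactly (all ranks preserved), and the
reference sample itself has scaling factor 1.

### GSEA

`gseaES()` is the weighted KS running sum: hit increments proportional to
|score|^exponent (normalized to sum 1), miss decrements 1/(N - |S|), ES =
the extremum of larger magnitude. Exact |max| = |min| ties resolve toward
the positive extremum (a convention; antisymmetry under ranking reversal
holds whenever the extremum is unique). The weight exponent defaults to 1
(classic weighted GSEA). Permutations default to gene-set permutation —
random same-size sets, shared across sets of equal size — because with 8
samples per group phenotype permutation is feasible but noisy; phenotype
permutation is implemented and falls back to gene-set permutation with a
warning below 3 samples per group. NES divides ES by the mean |permuted
ES| of the same sign; nominal p uses the same-sign tail with add-one
continuity; the FDR q pools permuted NES across sets per sign. Set-size
filters default to 15-500 after intersection with the ranked universe.
Ranking ties break by feature id so results are input-order invariant.

### Key driver analysis

The neighborhood defaults to radius 1 in both edge directions — the
common choice in the KDA lineage, where "neighboring subnetwork" means
the immediate undirected neighborhood — and both radius and direction are
exposed. The background universe is the network's node set, not all
assayed genes: the test asks a topological question, so the signature is
intersected with the network first (the discarded count is logged).
Candidates need at least 5 neighbors (tiny Fisher tables are
uninformative), and the Bonferroni divisor is the number of candidates
actually tested. The per-candidate 2x2 table excludes the candidate
itself from both margins. `extractSubnetwork()` ranks weakly connected
components of the seed-expanded induced subgraph by edge count, breaking
ties by smallest lexicographic node id.

### Classification

`rfClassify()` grows randomized decision trees on log2 abundances via
\pkg{ranger}. Two deliberate departures from textbook bagging + Gini
follow from the tiny-n, wide-p geometry of metabolomics designs:

* **Randomized split thresholds** (extremely-randomized-trees splits,
  one random cut per candidate feature): with 10 samples and hundreds of
  features, dozens of null features separate a bootstrap sample
  perfectly by chance and tie with true effects under exhaustive split
  search — the ensemble vote then carries almost no signal. A random
  threshold only yields a clean split when the feature's between-group
  margin is wide, which is exactly what distinguishes a 100-fold planted
  effect from a lucky null. A third of the features is drawn per split.
* **Stratified leave-one-out** (`scheme = "loocv"`, the default): each
  fold holds out one sample per group, keeping training folds balanced.
  Plain leave-one-sample-out makes the held-out sample's class the
  training minority, which at n = 5/group biases votes against the true
  class severely; correcting votes by training prevalence overshoots in
  the opposite direction. Within each fold trees are grown on the full
  training fold (ensemble randomness comes from the split
  randomization). Out-of-bag estimation (`scheme = "oob"`) is available
  for larger designs.

Importance is permutation importance (mean decrease in out-of-bag
accuracy) from a bootstrap ensemble on all samples, with lexicographic
tie-breaks. The forest size defaults to 500 trees; all randomness is
controlled by the seed and single-threaded, so reports are exactly
reproducible.

### Integration

`jointPathwayTable()` runs the over-representation analysis per omics on
its own detected universe and flags pathways whose BH-adjusted enrichment
p passes the cutoff in both omics; it is symmetric in the omics order.
`kdMap()` consumes a user-supplied reaction annotation (published
integrative maps are hand-curated; the package automates the state
annotation and export, not the biochemistry) and labels nodes `up`,
`down`, `unchanged` (measured, not significant) or `unmeasured` — the
latter two deliberately distinct, since absence of evidence is not
evidence of no change.

## The synthetic benchmark: what it emulates and what it does not

The generators' defaults are the study conditions the package is
benchmarked under:

* `simulateExpression()`: 10,000 genes, 8 samples/group, baseline per-gene
  means ~ Normal(8, 1.5²) on log2 (plausible normalized bead-array
  intensities), residual SD 0.25, 5% of genes shifted by a signed log2
  effect drawn from [1, 3] with a 2:1 up:down sign ratio (exposure
  signatures typically skew upward). A third group, when requested,
  receives the effect attenuated by a washout factor (default 0.5).
* `simulateMetabolome()`: 500 metabolites, 5 samples/group, log-normal
  abundances (per-metabolite location ~ Normal(10, 1), residual SD 0.4 on
  the natural log — a ~40% CV typical of untargeted profiling). The
  default planted fold-change palette spans 0.35x to 104.13x — the scale
  observed for glycogen-breakdown products and TCA-cycle intermediates in
  diesel-exhaust liver studies (values such as 104.13, 18.13, 9.6, 4.52,
  3.6, 3.26, 2.46, 1.72, 0.35).
* `simulateNetwork()`: preferential-attachment graph with 6 edges per
  node (mean degree ~12), random edge orientation, drivers placed on
  top-decile-degree hubs, signature membership 0.7 inside driver
  neighborhoods vs 0.05 outside. The density is a design choice: with
  sparser graphs (2-3 edges per node) the lowest-degree hubs have
  neighborhoods too small for a Bonferroni-corrected Fisher test to ever
  call, so the planted truth would be unrecoverable by *any* method —
  the benchmark is constructed so that the planted drivers are
  statistically identifiable. Drivers themselves are not signature
  members (they regulate the signature); the emitted signature plays the
  role a differential signature plays in a real analysis.
* `simulatePathways()`: random, possibly overlapping member sets; seeded
  pathways receive half their members from the planted features and are
  recorded as enriched by construction.

One global seed expands into per-stage child seeds by a fixed affine
scheme (`childSeed()`), so each stage is independently reproducible and
two runs of `runPipeline("all", seed = s)` are byte-identical.

What the generators do **not** emulate: probe-level array artifacts,
batch or chip effects, heteroscedastic mean-variance trends, correlated
co-regulated gene blocks, missing-not-at-random censoring beyond a hard
detection floor, and biologically structured networks (the graph is
scale-free but otherwise unstructured). Passing the truth-recovery
benchmarks therefore demonstrates that the statistics are implemented
correctly and have power under honestly noisy conditions — not that the
pipeline's operating characteristics transfer to any particular real
data set.

## Numerical conventions

* Identifier matching is case-sensitive exact string comparison
  everywhere; silent case-folding hides annotation bugs (mouse/human
  symbol conventions differ, e.g. Pck1 vs PCK1, and cross-species
  mapping is the user's responsibility).
* Missing-value tokens on input: empty cell, `NA`, `NaN` (counted and
  logged per file).
* Zero-variance features with different group means report p = 0 with a
  logged note rather than erroring.
* A significant feature with fold change exactly 1 joins neither
  signature direction (logged).
* Fisher/hypergeometric tails are computed as P(X >= k) via the
  hypergeometric distribution function; p = 1 whenever the observed
  overlap is 0.
* Ties everywhere (rankings, component ranking, importance) break by
  feature/node id, so all outputs are deterministic and input-order
  invariant.

## Problem sizes used by the test suite

The suite benchmarks at the design scales above: differential recovery on
10,000-gene matrices over 10 seeds; KDA on twenty 1,000-node networks
(plus a 4 x 10-seed sweep of the neighborhood signature probability);
classification on twenty 506-metabolite tables plus fifty label-permuted
nulls; GSEA against a brute-force running-sum oracle on 200 random
instances and 1,000-permutation planted-set detection over 20 seeds; exact
enumeration of every 2x2 table with margins up to 25; and Welch
calibration as fifty replicates of 10,000 null features at 5 samples per
group (the replicate average estimates the test's level — a single draw
has Monte-Carlo noise comparable to the distance between the exact
Welch level at n = 5, about 0.0443, and the nominal 0.05).

## Limitations

* The KDA tests 1-hop (configurable) neighborhood enrichment with
  unweighted edges; edge-weighted and directed-cascade variants are out
  of scope, as is learning the network itself — networks are consumed as
  input or simulated.
* GSEA's gene-set permutation null ignores inter-gene correlation; with
  real data and enough samples, phenotype permutation is preferable.
* The classifier's accuracy estimate at n = 5/group has irreducibly high
  variance (10 held-out predictions); treat it as a coarse separability
  statement, as the source studies do.
* Fold changes on min-imputed censored values are biased toward 1 for
  heavily censored metabolites.

## A worked run

```{r, eval = FALSE}
out <- runPipeline("all", outDir = tempfile(), seed = 7)
str(out$recovery)
```

This simulates all four inputs, runs both differential tables, GSEA, ORA,
KDA, classification and integration, writes every artifact (TSV, GMT,
SIF, GraphML, JSON) plus `recovery_report.json` (truth recovery) and
`run-report.json` (per-stage counts), and returns the recovery summary.
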