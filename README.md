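# OmicKDA

Integrated transcriptome–metabolome analysis with network key driver
discovery, for two-group (plus optional washout) exposure studies of the
kind run in inhalation toxicology: expression microarrays on ~8 animals
per group, untargeted liver metabolomics on ~5 per group, a directed gene
regulatory network, and pathway annotations linking genes and
metabolites.

The package implements, as tested reusable functions:

* **Differential analysis** — rank-invariant normalization; Welch's
  two-sample *t* test (Student's as option) on log2 values; fold changes
  as treated/control ratios of arithmetic group means;
  Benjamini–Hochberg adjustment and Storey *q*-values; directional
  signatures and Venn overlap counts.
* **Enrichment** — GSEA: the weighted Kolmogorov–Smirnov running-sum
  enrichment score with permutation NES, nominal *p* and sign-stratified
  FDR; ORA: one-sided hypergeometric *p* with the fold-enrichment ratio

  $$\mathrm{Enrichment} = \frac{k/K}{n/N}$$

  (*k* significant of *K* detected pathway members, against *n*
  significant of *N* detected overall).
* **Key driver analysis (KDA)** — for every network gene with a large
  enough *h*-hop neighborhood, a one-sided Fisher's exact test of
  signature enrichment in that neighborhood, Bonferroni-corrected over
  the candidates tested; seed-based extraction of the most-connected
  subnetwork; annotated GraphML export for Cytoscape.
* **Classification** — a randomized-decision-tree ensemble over
  metabolite profiles with a cross-validated (or out-of-bag) accuracy
  estimate and a permutation-importance ranking of biochemicals.
* **Integration** — a joint gene–metabolite pathway table flagging
  pathways significant in both omics, and a key-driver-centered reaction
  map with up/down/unchanged/unmeasured node states.
* **Synthetic benchmarks** — generators for expression matrices,
  metabolite tables, scale-free directed networks and pathway
  annotations with planted, recorded ground truth (`SyntheticTruth`), so
  every stage is validated by truth recovery.

`runPipeline("all", outDir, seed)` runs the whole chain end to end on
synthetic data and writes every artifact plus a truth-recovery report;
individual stages run against files (TSV / GMT / SIF / GraphML / JSON).
A thin command-line wrapper ships in `inst/scripts/omickda`.

## Worked example

Simulate a 1,000-gene network with 10 planted key drivers whose 1-hop
neighborhoods are enriched (70% vs 5% background) for a gene signature,
then recover them:

```r
library(OmicKDA)
sim <- simulateNetwork(nNodes = 1000, nDrivers = 10, rhoIn = 0.7,
                       rhoBg = 0.05, seed = 42)
res <- keyDriverAnalysis(sim$network, sim$signature,
                         radius = 1, direction = "both", alpha = 0.05)
head(res, 5)
#>          gene neighborhood_size overlap fisher_p bonferroni_p is_kd
#> 8   gene00008                76      52 6.46e-20     6.46e-17  TRUE
#> 22  gene00022                53      33 5.64e-11     5.64e-08  TRUE
#> 18  gene00018                38      25 2.96e-09     2.96e-06  TRUE
#> 66  gene00066                30      21 1.14e-08     1.14e-05  TRUE
#> 133 gene00133                28      20 1.52e-08     1.52e-05  TRUE
sum(res$gene[res$is_kd] %in% sim$truth@plantedDrivers)
#> [1] 9   # of 10 planted drivers, with 9 drivers called in total
```

Each row is a candidate gene: its neighborhood size, the overlap with the
signature, the one-sided Fisher *p* for that 2×2 enrichment table, the
Bonferroni-adjusted *p* over all candidates tested, and the key-driver
call at α = 0.05. Here all 9 calls are planted drivers (precision 1.0,
recall 0.9 on this seed).

The full pipeline on defaults (10,000 genes at n = 8/group, 500
metabolites at n = 5/group with planted fold changes spanning ~0.35× to
~104×, the network above):

```r
out <- runPipeline("all", outDir = "run1", seed = 7)
out$recovery$deg
#> $planted: 500   $called: 525   $recall: 1   $observed_fdr: 0.0476
out$recovery$classification$accuracy
#> [1] 1
```

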