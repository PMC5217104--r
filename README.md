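# iseqr

Analysis of pooled double-barcode ("interaction sequencing") fitness
assays in yeast, for groups measuring genetic interactions across
environments by competing hundreds of uniquely barcoded deletion strains
in one culture.

In these assays every clonal strain carries a unique double DNA barcode
at a single locus. A pool of single-deletion proxies, double deletions
and wild-type (WT) controls is propagated by serial batch transfer
(1:8 dilution, ~3 generations per daily cycle) and the barcode locus is
sequenced at each transfer. iseqr implements the computation end to end:

* **Counting** — demultiplex paired-end amplicon reads on multiplex tags
  and count known double barcodes (Hamming matching with strict
  unique-nearest tie-breaking; chimeric pairings are never assigned).
* **Fitness** — per strain, normalize counts to relative frequency, to
  the summed WT-control frequency, and to the first time point; fit
  ln(trajectory) against cycle index 0–3 with a zero intercept; fitness
  is `1 + slope` per cycle.
* **Interaction scores** — `eps = f_ij − f_i · f_j`, the deviation of a
  double mutant's fitness from the product of its single-mutant proxy
  means; Student-t 95% CIs across the 4–8 replicate strains of each gene
  pair drive positive/negative calls, and Wilcoxon rank-sum tests with
  Benjamini–Hochberg correction (10% FDR) call interactions that change
  between environments.
* **Growth curves** — doubling times from plate-reader OD curves by
  10-point sliding-window maximum-slope regression on ln(OD); OD fitness
  = WT doubling time / strain doubling time.
* **Variant provenance** — classify per-strain SNPs/indels and
  whole-chromosome duplications as inherited vs de novo against a strain
  pedigree, with cohort summaries.
* **Simulator** — a seeded Wright–Fisher-with-selection model of the
  whole experiment (multinomial transfer bottlenecks and sequencing,
  multiplicative double-mutant fitness with configurable true
  interactions, per-strain jitter, OD curves, FASTQ emission) with
  recorded ground truth for every estimator.

## Worked example

Simulate the pilot-scale design and score it:

```r
library(iseqr)
set.seed(42)
panel  <- make_strain_panel(sim_config())       # 9 genes, ~360 strains
counts <- simulate_pool(panel, n_replicates = 3)
ctrl   <- panel$genotypes$strain_id[panel$genotypes$type == "control"]
fit    <- pool_fitness(counts, ctrl)            # fitness = 1 + slope
eps    <- strain_interaction_scores(fit, panel$genotypes)
aggregate_interactions(eps)
```

```
# A tibble: 36 × 9
  pair        gene_a gene_b condition n_strains mean_eps  ci_low ci_high sign_call
1 GENE1:GENE2 GENE1  GENE2  YPD               6   0.124   0.0770   0.171 positive
2 GENE1:GENE3 GENE1  GENE3  YPD               4   0.0897 -0.0339   0.213 none
3 GENE1:GENE4 GENE1  GENE4  YPD               8   0.148   0.0685   0.228 positive
...
```

Each row is one gene pair in one condition: `mean_eps` is the mean
interaction score over its replicate strains, the CI is the Student-t
95% interval across those strains, and `sign_call` is `positive`/
`negative` when the interval excludes 0 (here, pairs whose simulated
true interaction was large enough to resolve).

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow (simulate two conditions → round-trip FASTQ counting
→ fitness → interactions → OD validation → variant provenance), writing
tables under `results/`. Sample of their printed findings:

```
YPD truth recovery: r = 0.939, RMSE = 0.0512 over 361 strains
error-free round trip: 59453 read pairs, all recovered exactly
1% per-base errors: 62.9% recovered at 0 mismatches, 93.9% at <= 2
pooled vs OD fitness: Spearman rho = 0.930 over 361 strains
unique SNPs/indels: 57, of which 39 inherited (68%)
strains with >= 1 duplicated chromosome: 54%
```

## Repository layout

```
R/                  package code (counting, fitness, interactions,
                    growth curves, provenance, simulator, pipeline)
analysis/           numbered workflow scripts over the package
scripts/acceptance.R  headline-quantity reproduction
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette (model, assumptions, parameters)
```
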