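#!/usr/bin/env Rscript
# Simulate the pooled double-barcode experiment in two conditions.
#
# Builds the pilot-scale strain panel (9 genes -> 36 pairs, ~390 strains
# plus 8 WT controls), then simulates three replicate serial-transfer
# cultures in a rich-medium baseline ("YPD") and in an alternate carbon
# source ("YPEG") where two chosen pairs acquire a negative interaction
# — the scenario the differential caller is meant to detect.

suppressPackageStartupMessages({library(iseqr); library(dplyr); library(readr)})
set.seed(20260922)
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()           # desk-scale defaults, sigma_b = 0.04
panel <- make_strain_panel(cfg)
shifted_pairs <- c("GENE1:GENE2", "GENE3:GENE7")
counts <- bind_rows(
  simulate_pool(panel, n_replicates = 3, condition = "YPD")$counts,
  simulate_pool(panel, n_replicates = 3, condition = "YPEG",
                truth = perturb_truth(panel, shifted_pairs, -0.2))$counts)

write_tsv(counts, file.path(out, "counts.tsv"))
write_tsv(panel$truth, file.path(out, "truth_strains.tsv"))
write_tsv(panel$truth_pairs, file.path(out, "truth_pairs.tsv"))
write_tsv(panel$genotypes, file.path(out, "genotypes.tsv"))
write_tsv(panel$map$entries, file.path(out, "barcode_map.tsv"))

cat(sprintf(
  "panel: %d strains (%d single-proxy, %d double, %d control)\n",
  nrow(panel$truth), sum(panel$truth$type == "single"),
  sum(panel$truth$type == "double"), sum(panel$truth$type == "control")))
cat(sprintf("conditions: YPD baseline; YPEG with eps shifted -0.2 for %s\n",
            paste(shifted_pairs, collapse = ", ")))
cat(sprintf("wrote %s/{counts,truth_strains,truth_pairs,genotypes,barcode_map}.tsv\n",
            out))
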