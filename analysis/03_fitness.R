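#!/usr/bin/env Rscript
# Estimate per-strain relative fitness from the simulated count
# trajectories and check how well the estimates track the simulator's
# ground truth and reproduce across replicate cultures.

suppressPackageStartupMessages({library(iseqr); library(dplyr); library(readr)})
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_count_table("results/sim/counts.tsv")
geno <- read_tsv("results/sim/genotypes.tsv", show_col_types = FALSE)
truth <- read_tsv("results/sim/truth_strains.tsv", show_col_types = FALSE)
ctrl <- geno$strain_id[geno$type == "control"]

fitness <- pool_fitness(counts, ctrl)
write_tsv(fitness, file.path(out, "fitness.tsv"))

cat(sprintf("estimated fitness for %d strain x replicate x condition cells (%d censored)\n",
            nrow(fitness), sum(fitness$censored)))

cmp <- fitness |>
  filter(condition == "YPD", !censored) |>
  inner_join(truth, by = "strain_id") |>
  group_by(strain_id, fitness_true) |>
  summarise(fitness = mean(fitness), .groups = "drop")
cat(sprintf("YPD truth recovery: r = %.3f, RMSE = %.4f over %d strains\n",
            cor(cmp$fitness, cmp$fitness_true),
            sqrt(mean((cmp$fitness - cmp$fitness_true)^2)), nrow(cmp)))

lab <- ifelse(is.na(geno$pair), paste0(geno$gene_a, ":", geno$gene_b),
              geno$pair)
for (cc in unique(fitness$condition)) {
  fc <- fitness |> filter(condition == cc, !censored)
  s <- summarize_reproducibility(tibble::tibble(
    strain_id = fc$strain_id, replicate = fc$replicate, value = fc$fitness,
    genotype = lab[match(fc$strain_id, geno$strain_id)]))
  cat(sprintf(
    "%s: replicate rho %.3f-%.3f; median SD same barcode %.4f, same genotype %.4f (rank-sum p = %.2g)\n",
    cc, min(s$replicate_rho$rho), max(s$replicate_rho$rho),
    s$median_sd_same_barcode, s$median_sd_same_genotype,
    s$sd_comparison_p))
}
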