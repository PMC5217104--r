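#!/usr/bin/env Rscript
# Classify the synthetic whole-genome-sequencing cohort's variants as
# inherited vs de novo against the strain pedigree and tabulate the F2
# summaries.

suppressPackageStartupMessages({library(iseqr); library(dplyr); library(readr)})
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- make_provenance_fixture()
cl <- classify_provenance(fx$variants, fx$pedigree)
tab <- tabulate_events(cl, fx$pedigree, generation = "F2")

write_tsv(cl, file.path(out, "provenance.tsv"))
write_tsv(tab$unique_events, file.path(out, "provenance_summary.tsv"))
write_tsv(tab$aneuploid_chrom_freq, file.path(out, "aneuploid_chroms.tsv"))

snp <- tab$unique_events |> filter(kind == "snp_indel")
cat(sprintf("F2 cohort: %d strains\n", tab$n_strains))
cat(sprintf("unique SNPs/indels: %d, of which %d inherited (%d%%)\n",
            sum(snp$n_unique),
            snp$n_unique[snp$provenance == "inherited"],
            tab$pct_inherited_snp))
cat(sprintf("strains with >= 1 duplicated chromosome: %d%%\n",
            tab$pct_strains_aneuploid))
cat(sprintf("modal duplicated chromosome: %s (%d strains)\n",
            tab$aneuploid_chrom_freq$chrom[1],
            tab$aneuploid_chrom_freq$n_strains[1]))
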