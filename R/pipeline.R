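#' Run the full counts-to-interactions pipeline
#'
#' Orchestrates the analysis end to end: ingest a count table (or count
#' reads first when FASTQ inputs are configured), estimate per-strain
#' fitness per condition, score per-strain interactions, aggregate with
#' confidence intervals, call differential interactions between every
#' pair of conditions, and summarize reproducibility. All stage outputs
#' are written as headered UTF-8 TSVs plus a JSON manifest recording the
#' inputs, parameters and seed, so a run is reproducible from the
#' manifest alone. Inputs are never mutated.
#'
#' @param config Named list:
#'   \describe{
#'     \item{counts}{Count tibble / `iseq_counts`, or path to a count
#'       TSV. Alternatively `r1`, `r2`, `barcode_map`, `tag_map`,
#'       `layout`, `max_mismatch` to count reads first.}
#'     \item{genotypes}{[genotype_map()] tibble or path to a genotype
#'       TSV (`strain_id gene_a gene_b`) plus `dubious` gene names.}
#'     \item{control_ids}{Character vector, or path to a one-id-per-line
#'       file. Defaults to the genotype map's control strains.}
#'     \item{timepoints}{Regression time points (default 0:3).}
#'     \item{alpha}{CI level for sign calls (default 0.05).}
#'     \item{fdr}{Differential-call FDR (default 0.10).}
#'     \item{seed}{Integer seed recorded in the manifest (default 1).}
#'   }
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with every stage's tibble
#'   (`counts`, `fitness`, `eps_strain`, `eps_pair`, `differential`,
#'   `reproducibility`, `edges`).
#' @export
run_pipeline <- function(config, out_dir) {
  # validate configuration before any computation
  for (f in c("counts", "genotypes")) {
    v <- config[[f]]
    if (is.null(v)) stop(sprintf("config field '%s' is required", f))
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      stop(sprintf("config file for '%s' not found: %s", f, v))
    }
  }
  if (is.character(config$control_ids) && length(config$control_ids) == 1 &&
      grepl("[/.]", config$control_ids) &&
      !file.exists(config$control_ids)) {
    stop(sprintf("controls file not found: %s", config$control_ids))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  counts <- config$counts
  if (is.character(counts)) counts <- read_count_table(counts)
  if (inherits(counts, "iseq_counts")) counts <- counts$counts
  genotypes <- config$genotypes
  if (is.character(genotypes)) {
    genotypes <- genotype_map(
      readr::read_tsv(genotypes, show_col_types = FALSE),
      dubious = config$dubious %||% character())
  }
  control_ids <- config$control_ids
  if (is.null(control_ids)) {
    control_ids <- genotypes$strain_id[genotypes$type == "control"]
  } else if (length(control_ids) == 1 && file.exists(control_ids)) {
    control_ids <- readLines(control_ids)
  }
  timepoints <- config$timepoints %||% 0:3
  alpha <- config$alpha %||% 0.05
  fdr <- config$fdr %||% 0.10

  message(sprintf("pipeline: %d strains, %d samples, %d controls",
                  length(unique(counts$strain_id)),
                  nrow(dplyr::distinct(counts[, c("condition", "replicate",
                                                  "time_point")])),
                  length(control_ids)))
  fitness <- pool_fitness(counts, control_ids, timepoints = timepoints)
  message(sprintf("fitness: %d estimates, %d censored", nrow(fitness),
                  sum(fitness$censored)))
  eps_strain <- strain_interaction_scores(fitness, genotypes)
  eps_pair <- aggregate_interactions(eps_strain, alpha = alpha)
  message(sprintf("interactions: %d pairs, %d called (%d+, %d-)",
                  nrow(eps_pair), sum(eps_pair$sign_call != "none"),
                  sum(eps_pair$sign_call == "positive"),
                  sum(eps_pair$sign_call == "negative")))

  conditions <- sort(unique(counts$condition))
  differential <- NULL
  if (length(conditions) >= 2) {
    cmb <- utils::combn(conditions, 2)
    differential <- dplyr::bind_rows(lapply(seq_len(ncol(cmb)), function(k) {
      differential_interactions(eps_strain, cmb[1, k], cmb[2, k], fdr = fdr)
    }))
    message(sprintf("differential: %d tests, %d significant at %d%% FDR",
                    nrow(differential), sum(differential$q_significant),
                    round(100 * fdr)))
  }

  geno_lab <- genotypes$pair
  geno_lab[is.na(geno_lab)] <- paste0(genotypes$gene_a[is.na(geno_lab)], ":",
                                      genotypes$gene_b[is.na(geno_lab)])
  repro <- dplyr::bind_rows(lapply(conditions, function(cc) {
    ftc <- fitness[fitness$condition == cc & !fitness$censored, ]
    tbl <- tibble::tibble(strain_id = ftc$strain_id,
                          replicate = ftc$replicate, value = ftc$fitness,
                          genotype = geno_lab[match(ftc$strain_id,
                                                    genotypes$strain_id)])
    s <- summarize_reproducibility(tbl)
    tibble::tibble(condition = cc,
                   median_rho = stats::median(s$replicate_rho$rho),
                   median_sd_same_barcode = s$median_sd_same_barcode,
                   median_sd_same_genotype = s$median_sd_same_genotype)
  }))

  edges <- eps_pair[, c("gene_a", "gene_b", "condition", "mean_eps",
                        "sign_call")]

  readr::write_tsv(counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(fitness, file.path(out_dir, "fitness.tsv"))
  readr::write_tsv(eps_strain, file.path(out_dir, "eps_strain.tsv"))
  readr::write_tsv(eps_pair, file.path(out_dir, "eps_pair.tsv"))
  if (!is.null(differential)) {
    readr::write_tsv(differential, file.path(out_dir, "differential.tsv"))
  }
  readr::write_tsv(repro, file.path(out_dir, "reproducibility.tsv"))
  readr::write_tsv(edges, file.path(out_dir, "network_edges.tsv"))

  manifest <- list(
    package = "iseqr",
    version = as.character(utils::packageVersion("iseqr")),
    seed = seed, timepoints = timepoints, alpha = alpha, fdr = fdr,
    conditions = conditions, n_strains = length(unique(counts$strain_id)),
    n_controls = length(control_ids),
    inputs = Filter(is.character, config[c("counts", "genotypes",
                                           "control_ids")]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(counts = counts, fitness = fitness,
                 eps_strain = eps_strain, eps_pair = eps_pair,
                 differential = differential, reproducibility = repro,
                 edges = edges))
}
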