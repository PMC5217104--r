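#' Configuration for the pooled serial-transfer simulator
#'
#' Defaults emulate the pilot-scale design the package targets: 9
#' deleted genes, 12-16 double-barcode strains per single-deletion proxy
#' genotype and 4-8 per double deletion, 8 wild-type (double-dubious)
#' control strains mixed 50:50 with the mutant pool, serial batch
#' transfer with 1:8 dilution (3 generations of regrowth per daily
#' cycle), 8 sampled time points and ~100 sequencing reads per strain
#' per time point. The population size defaults to a desk-scale 1e6
#' cells (configurable; it must stay below 2^31 - 1, the limit of exact
#' multinomial sampling here).
#'
#' Fitness units are per transfer cycle, matching [estimate_fitness()]:
#' a strain with true fitness `f` changes in expected abundance by the
#' factor `exp(f - 1)` per cycle relative to the controls (true fitness
#' 1), so `1 + slope` of the log-linear trajectory fit recovers `f`
#' directly. True double-mutant fitness is built multiplicatively,
#' `f_ij = f_i * f_j + eps*`, plus per-strain jitter `N(0, sigma_b)`
#' representing the segregating variation and de novo mutations that
#' make replicate constructions of one genotype genuinely differ.
#'
#' @param n_genes Number of deleted genes (default 9 -> 36 pairs).
#' @param barcodes_single,barcodes_double Range `c(lo, hi)` of strains
#'   per single (12-16) / double (4-8) genotype.
#' @param n_controls Wild-type double-dubious control strains (8).
#' @param wt_mix_fraction Fraction of cells that are controls at t0 (0.5).
#' @param dilution Serial-transfer dilution factor D (8).
#' @param cycles Number of sampled time points, t = 0 .. cycles-1 (8).
#' @param pop_size Effective population size N (default 1e6, desk scale).
#' @param reads_per_strain Mean sequencing reads per strain per time
#'   point R (100).
#' @param single_fitness Optional named per-gene true fitness; default
#'   drawn Uniform(0.7, 1.0) (deletions with mostly deleterious,
#'   occasionally near-neutral effects).
#' @param epsilon_true Optional per-pair true interaction scores (named
#'   `"A:B"`); default drawn Uniform(-0.1, 0.1).
#' @param sigma_b SD of per-strain fitness jitter around the genotype
#'   value (default 0.04, the scale implied by replicate-strain
#'   variability exceeding replicate-culture variability).
#' @param barcode_length Barcode length in nt (20).
#' @return List of class `iseq_sim_config`.
#' @export
sim_config <- function(n_genes = 9L, barcodes_single = c(12L, 16L),
                       barcodes_double = c(4L, 8L), n_controls = 8L,
                       wt_mix_fraction = 0.5, dilution = 8, cycles = 8L,
                       pop_size = 1e6, reads_per_strain = 100,
                       single_fitness = NULL, epsilon_true = NULL,
                       sigma_b = 0.04, barcode_length = 20L) {
  stopifnot(n_genes >= 2, dilution > 1, cycles >= 2, reads_per_strain >= 1,
            wt_mix_fraction > 0, wt_mix_fraction < 1, pop_size > 0)
  if (pop_size >= 2^31) {
    stop("pop_size must be below 2^31 - 1 for exact multinomial sampling; scale down")
  }
  structure(list(n_genes = n_genes, barcodes_single = barcodes_single,
                 barcodes_double = barcodes_double, n_controls = n_controls,
                 wt_mix_fraction = wt_mix_fraction, dilution = dilution,
                 cycles = cycles, pop_size = pop_size,
                 reads_per_strain = reads_per_strain,
                 single_fitness = single_fitness,
                 epsilon_true = epsilon_true, sigma_b = sigma_b,
                 barcode_length = barcode_length),
            class = "iseq_sim_config")
}

random_barcodes <- function(n, length, existing = character()) {
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      bc <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
      if (!bc %in% existing && !bc %in% out[seq_len(i - 1)]) break
      if (try == 100) stop("barcode collision after 100 draws; increase barcode length")
    }
    out[i] <- bc
  }
  out
}

#' Build a simulated strain panel with recorded ground truth
#'
#' Emits single-deletion proxy strains (gene + dubious-ORF placeholder),
#' double-deletion strains for every gene pair, and double-dubious
#' wild-type controls, each with a unique random double barcode and a
#' true per-cycle fitness: genotype fitness plus `N(0, sigma_b)`
#' per-strain jitter (controls stay at exactly 1, defining the
#' reference).
#'
#' @param config An [sim_config()].
#' @return List: `genotypes` (a [genotype_map()] tibble), `truth`
#'   (tibble `strain_id`, `type`, `gene_a`, `gene_b`, `pair`,
#'   `fitness_true`), `truth_pairs` (tibble `pair`, `eps_true`,
#'   `fitness_a`, `fitness_b`), `map` (an [barcode_map()] with an empty
#'   tag map, filled by [emit_fastq()] callers), `config`.
#' @export
make_strain_panel <- function(config) {
  stopifnot(inherits(config, "iseq_sim_config"))
  genes <- sprintf("GENE%d", seq_len(config$n_genes))
  dubious <- c("DUB1", "DUB2")
  s_gene <- config$single_fitness
  if (is.null(s_gene)) {
    s_gene <- stats::setNames(stats::runif(config$n_genes, 0.7, 1.0), genes)
  }
  pairs <- utils::combn(genes, 2)
  pair_lab <- paste(pairs[1, ], pairs[2, ], sep = ":")
  eps_true <- config$epsilon_true
  if (is.null(eps_true)) {
    eps_true <- stats::setNames(stats::runif(ncol(pairs), -0.1, 0.1),
                                pair_lab)
  }

  rows <- list()
  for (g in genes) {
    n_bc <- sample(seq(config$barcodes_single[1], config$barcodes_single[2]),
                   1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_a = g, gene_b = dubious[1 + (seq_len(n_bc) %% 2)],
      geno_fitness = unname(s_gene[g]))
  }
  for (k in seq_len(ncol(pairs))) {
    n_bc <- sample(seq(config$barcodes_double[1], config$barcodes_double[2]),
                   1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_a = rep(pairs[1, k], n_bc), gene_b = pairs[2, k],
      geno_fitness = unname(s_gene[pairs[1, k]] * s_gene[pairs[2, k]] +
                              eps_true[pair_lab[k]]))
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    gene_a = rep(dubious[1], config$n_controls), gene_b = dubious[2],
    geno_fitness = 1)
  panel <- dplyr::bind_rows(rows)
  panel$strain_id <- sprintf("s%04d", seq_len(nrow(panel)))

  geno <- genotype_map(panel, dubious = dubious)
  jitter <- stats::rnorm(nrow(panel), 0, config$sigma_b)
  jitter[geno$type == "control"] <- 0
  truth <- tibble::tibble(
    strain_id = panel$strain_id, type = geno$type, gene_a = geno$gene_a,
    gene_b = geno$gene_b, pair = geno$pair,
    fitness_true = panel$geno_fitness + jitter)

  bc5 <- random_barcodes(nrow(panel), config$barcode_length)
  bc3 <- random_barcodes(nrow(panel), config$barcode_length)
  map <- barcode_map(
    tibble::tibble(strain_id = panel$strain_id, bc5 = bc5, bc3 = bc3),
    tibble::tibble(tag = "AAAAAA", condition = "sim", replicate = "1",
                   time_point = 0L))

  list(genotypes = geno, truth = truth,
       truth_pairs = tibble::tibble(
         pair = pair_lab, eps_true = unname(eps_true),
         fitness_a = unname(s_gene[pairs[1, ]]),
         fitness_b = unname(s_gene[pairs[2, ]])),
       map = map, config = config)
}

#' Simulate pooled serial-transfer growth and barcode sequencing
#'
#' Discrete Wright-Fisher-with-selection dynamics: controls start with
#' `wt_mix_fraction` of the `pop_size` cells (mutants share the rest
#' equally); each daily cycle every strain's expected share grows by
#' `exp(fitness_true - 1)`, the transfer bottleneck is a multinomial
#' draw of `pop_size / dilution` cells, and sequencing at each time
#' point is a multinomial draw of `reads_per_strain * n_strains` reads
#' from the post-growth frequencies (time point 0 is sampled from the
#' inoculum). Fully reproducible under `set.seed()`.
#'
#' @param panel Output of [make_strain_panel()].
#' @param n_replicates Independent growth cultures (default 3).
#' @param condition Condition label stamped on the output (default
#'   `"YPD"`).
#' @param truth Optional alternative truth table (e.g. from
#'   [perturb_truth()]) for condition-specific fitness.
#' @return `iseq_counts` object (zero `unmatched`/`untagged`, as no
#'   reads are lost in silico).
#' @export
simulate_pool <- function(panel, n_replicates = 3L, condition = "YPD",
                          truth = panel$truth) {
  cfg <- panel$config
  n_strains <- nrow(truth)
  n_bottleneck <- round(cfg$pop_size / cfg$dilution)
  if (n_bottleneck < n_strains) {
    stop("bottleneck pop_size/dilution smaller than the strain panel")
  }
  grow <- exp(truth$fitness_true - 1)
  is_ctrl <- truth$type == "control"
  n0 <- numeric(n_strains)
  n0[is_ctrl] <- cfg$wt_mix_fraction * cfg$pop_size / sum(is_ctrl)
  n0[!is_ctrl] <- (1 - cfg$wt_mix_fraction) * cfg$pop_size / sum(!is_ctrl)
  n_reads <- cfg$reads_per_strain * n_strains

  res <- list()
  take_sample <- function(p, r, tp) {
    tibble::tibble(strain_id = truth$strain_id, condition = condition,
                   replicate = as.character(r), time_point = tp,
                   count = as.integer(stats::rmultinom(1, n_reads, p)))
  }
  for (r in seq_len(n_replicates)) {
    n <- n0
    res[[length(res) + 1]] <- take_sample(n / sum(n), r, 0L)  # inoculum
    for (tp in seq_len(cfg$cycles - 1L)) {
      ng <- n * grow                       # one cycle of relative growth
      p <- ng / sum(ng)
      res[[length(res) + 1]] <- take_sample(p, r, tp)
      n <- as.numeric(stats::rmultinom(1, n_bottleneck, p))  # transfer
    }
  }
  counts <- dplyr::bind_rows(res)
  samples <- dplyr::distinct(counts[, c("condition", "replicate",
                                        "time_point")])
  samples$unmatched <- 0L
  structure(list(counts = counts, unmatched = samples, untagged = 0L),
            class = "iseq_counts")
}

#' Deterministic expected frequency trajectories (infinite-depth limit)
#'
#' The exact expected relative frequencies under the simulator's growth
#' model, with no bottleneck or sequencing sampling — the R -> infinity
#' limit used to verify that the fitness estimator inverts the
#' generative model exactly.
#'
#' @inheritParams simulate_pool
#' @return Frequency tibble as produced by [relative_frequencies()]
#'   (single replicate `"1"`).
#' @export
analytic_frequencies <- function(panel, condition = "YPD",
                                 truth = panel$truth) {
  cfg <- panel$config
  is_ctrl <- truth$type == "control"
  n0 <- numeric(nrow(truth))
  n0[is_ctrl] <- cfg$wt_mix_fraction / sum(is_ctrl)
  n0[!is_ctrl] <- (1 - cfg$wt_mix_fraction) / sum(!is_ctrl)
  res <- lapply(0:(cfg$cycles - 1L), function(tp) {
    w <- n0 * exp((truth$fitness_true - 1) * tp)
    tibble::tibble(strain_id = truth$strain_id, condition = condition,
                   replicate = "1", time_point = tp, freq = w / sum(w))
  })
  dplyr::bind_rows(res)
}

#' Shift true interaction scores for selected pairs
#'
#' Returns a modified truth table in which the double-mutant strains of
#' `pairs` have their true fitness shifted by `delta_eps` (a changed
#' interaction, e.g. a condition-specific synthetic sickness).
#'
#' @param panel Output of [make_strain_panel()].
#' @param pairs Character vector of `"A:B"` pair labels.
#' @param delta_eps Additive shift applied to those pairs' strains.
#' @return A truth tibble for [simulate_pool()]'s `truth` argument.
#' @export
perturb_truth <- function(panel, pairs, delta_eps) {
  truth <- panel$truth
  hit <- !is.na(truth$pair) & truth$pair %in% pairs
  truth$fitness_true[hit] <- truth$fitness_true[hit] + delta_eps
  truth
}

#' Write a count table back out as paired FASTQ
#'
#' Emits one read pair per count, carrying the sample's multiplex tag
#' and the strain's double barcode at the configured layout positions
#' (filler bases `A` elsewhere), with optional per-base substitution
#' errors. Used to round-trip-test [count_double_barcodes()].
#'
#' @param counts Count tibble or `iseq_counts`.
#' @param map [barcode_map()] whose tag map covers every sample in
#'   `counts`.
#' @param layout [read_layout()].
#' @param r1_path,r2_path Output FASTQ paths (gzip if ending `.gz`).
#' @param error_rate Per-base substitution probability (default 0).
#' @param read_length Length of each emitted mate (default: just long
#'   enough for the layout's spans).
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
emit_fastq <- function(counts, map, layout, r1_path, r2_path,
                       error_rate = 0, read_length = NULL) {
  if (inherits(counts, "iseq_counts")) counts <- counts$counts
  counts <- counts[counts$count > 0, ]
  tagm <- map$tag_map
  key <- paste(counts$condition, counts$replicate, counts$time_point)
  tag_of <- tagm$tag[match(key, paste(tagm$condition, tagm$replicate,
                                      tagm$time_point))]
  if (anyNA(tag_of)) stop("tag map does not cover every sample in counts")
  ent <- map$entries
  eidx <- match(counts$strain_id, ent$strain_id)
  if (anyNA(eidx)) stop("counts contain strains absent from the barcode map")

  need_len <- function(mate) {
    ends <- vapply(layout, function(sp) if (sp[1] == mate) sp[2] + sp[3] else 0L,
                   numeric(1))
    max(ends, 1)
  }
  len1 <- if (is.null(read_length)) need_len(1) else read_length
  len2 <- if (is.null(read_length)) need_len(2) else read_length

  n <- rep(seq_len(nrow(counts)), counts$count)
  build_mate <- function(mate, len) {
    tmpl <- strrep("A", len)
    reads <- rep(tmpl, length(n))
    place <- function(reads, field, values) {
      sp <- layout[[field]]
      if (sp[1] != mate) return(reads)
      paste0(substr(reads, 1, sp[2]), values,
             substr(reads, sp[2] + sp[3] + 1L, len))
    }
    reads <- place(reads, "tag", tag_of[n])
    reads <- place(reads, "bc5", ent$bc5[eidx[n]])
    reads <- place(reads, "bc3", ent$bc3[eidx[n]])
    reads
  }
  r1 <- build_mate(1L, len1)
  r2 <- build_mate(2L, len2)
  if (error_rate > 0) {
    mutate_reads <- function(reads) {
      vapply(reads, function(rd) {
        hit <- which(stats::runif(nchar(rd)) < error_rate)
        if (!length(hit)) return(rd)
        ch <- strsplit(rd, "", fixed = TRUE)[[1]]
        for (i in hit) {
          ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    r1 <- mutate_reads(r1)
    r2 <- mutate_reads(r2)
  }
  write_fq <- function(reads, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    ids <- sprintf("@read%d", seq_along(reads))
    writeLines(rbind(ids, reads, "+", strrep("I", nchar(reads))), con)
  }
  write_fq(r1, r1_path)
  write_fq(r2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Simulate a plate-reader optical density curve
#'
#' Lagged logistic growth `od(t) = K / (1 + (K/od0 - 1) exp(-r (t -
#' lag)))` for `t > lag` (flat at `od0` before), with multiplicative
#' log-normal noise; sampled every `dt` minutes for `n_cycles` readings.
#'
#' @param od0 Inoculum OD (> 0).
#' @param K Carrying-capacity OD (> od0 for growth; `K = od0` gives a
#'   flat no-growth curve).
#' @param r Maximum specific growth rate per minute (doubling time
#'   `ln(2)/r` in exponential phase).
#' @param lag Lag time in minutes (default 0).
#' @param noise_sd SD of log-normal multiplicative noise (default 0).
#' @param dt Sampling interval in minutes (default 15).
#' @param n_cycles Number of readings (default 90).
#' @return Tibble `time`, `od`.
#' @export
simulate_od_curve <- function(od0, K, r, lag = 0, noise_sd = 0, dt = 15,
                              n_cycles = 90L) {
  stopifnot(od0 > 0, K >= od0, r > 0)
  times <- (seq_len(n_cycles) - 1) * dt
  od <- ifelse(times <= lag, od0,
               K / (1 + (K / od0 - 1) * exp(-r * (times - lag))))
  if (noise_sd > 0) od <- od * exp(stats::rnorm(n_cycles, 0, noise_sd))
  tibble::tibble(time = times, od = od)
}

#' Synthetic pedigree-and-variants fixture at whole-experiment scale
#'
#' A deterministic, fully synthetic strain cohort shaped like a
#' two-round crossing design: sequenced F1 parents and 39 sequenced F2
#' double-deletion strains carrying 57 unique SNPs/indels (39 of them
#' present in an F1 parent) and 30 whole-chromosome duplication events
#' across 21 strains, chromosome V being the modal duplication (16 of
#' the 21). Used to exercise [classify_provenance()] and
#' [tabulate_events()] at realistic scale.
#'
#' @return List `variants`, `pedigree` ready for
#'   [classify_provenance()].
#' @export
make_provenance_fixture <- function() {
  f1 <- sprintf("F1_%02d", 1:20)
  f2 <- sprintf("F2_%02d", 1:39)
  pedigree <- dplyr::bind_rows(
    tibble::tibble(child = f1, parent1 = NA_character_,
                   parent2 = NA_character_, generation = "F1"),
    tibble::tibble(child = f2,
                   parent1 = f1[1 + (seq_along(f2) - 1) %% 20],
                   parent2 = f1[1 + seq_along(f2) %% 20],
                   generation = "F2"))
  p1 <- pedigree$parent1[match(f2, pedigree$child)]

  # 57 unique SNPs in F2: the first 39 also placed in the strain's parent1
  snp_key <- sprintf("chr%02d:%d:A>T", 1 + (0:56) %% 16, 1000 + 137 * (0:56))
  snp_strain <- f2[1 + (0:56) %% 39]
  var_f2_snp <- tibble::tibble(strain_id = snp_strain, kind = "snp_indel",
                               key = snp_key)
  var_f1_snp <- tibble::tibble(
    strain_id = p1[match(snp_strain[1:39], f2)],
    kind = "snp_indel", key = snp_key[1:39])

  # 30 aneuploidy events in 21 F2 strains; chrV in 16; 25 inherited
  an_strain <- c(f2[1:16], f2[17:21], f2[1:9])
  an_chrom <- c(rep("chrV", 16), rep("chrII", 5), rep("chrXII", 9))
  inherited_an <- seq_len(30) <= 25
  var_f2_an <- tibble::tibble(strain_id = an_strain, kind = "aneuploidy",
                              key = an_chrom)
  var_f1_an <- tibble::tibble(
    strain_id = p1[match(an_strain[inherited_an], f2)],
    kind = "aneuploidy", key = an_chrom[inherited_an])

  variants <- dplyr::distinct(dplyr::bind_rows(var_f2_snp, var_f1_snp,
                                               var_f2_an, var_f1_an))
  list(variants = variants, pedigree = pedigree)
}
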