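test_that("a 9-gene panel yields 36 pairs and 45 genotypes", {
  set.seed(61)
  panel <- make_strain_panel(sim_config())
  pairs <- unique(stats::na.omit(panel$genotypes$pair))
  expect_length(pairs, choose(9, 2))
  singles <- unique(panel$genotypes$gene[panel$genotypes$type == "single"])
  expect_equal(length(pairs) + length(singles), 45L)
  expect_equal(sum(panel$genotypes$type == "control"), 8L)
  # barcode pairs unique; strains per genotype within the configured ranges
  expect_false(anyDuplicated(paste(panel$map$entries$bc5,
                                   panel$map$entries$bc3)) > 0)
  n_per_pair <- table(panel$genotypes$pair[panel$genotypes$type == "double"])
  expect_true(all(n_per_pair >= 4 & n_per_pair <= 8))
  n_per_single <- table(panel$genotypes$gene[panel$genotypes$type ==
                                               "single"])
  expect_true(all(n_per_single >= 12 & n_per_single <= 16))
})

test_that("true double fitness is multiplicative plus eps and jitter", {
  set.seed(63)
  panel <- make_strain_panel(sim_config(sigma_b = 0))
  tr <- dplyr::inner_join(panel$truth[panel$truth$type == "double", ],
                          panel$truth_pairs, by = "pair")
  expect_equal(tr$fitness_true,
               tr$fitness_a * tr$fitness_b + tr$eps_true)
  # sigma_b = 0: all strains of one genotype share the true fitness
  spread <- tapply(tr$fitness_true, tr$pair, function(x) diff(range(x)))
  expect_equal(as.numeric(spread), rep(0, 36))
})

test_that("simulation is deterministic under a seed and conserves totals", {
  run <- function() {
    set.seed(65)
    panel <- small_panel(seed = 65)
    simulate_pool(panel, n_replicates = 2)
  }
  a <- run()
  b <- run()
  expect_identical(a$counts, b$counts)
  # sequencing totals: reads_per_strain * n_strains per sample
  n_strains <- length(unique(a$counts$strain_id))
  totals <- tapply(a$counts$count,
                   paste(a$counts$replicate, a$counts$time_point), sum)
  expect_true(all(totals == 100 * n_strains))
})

test_that("a neutral pool stays flat and estimates center on 1", {
  set.seed(67)
  genes <- sprintf("GENE%d", 1:4)
  prs <- utils::combn(genes, 2)
  cfg <- sim_config(
    n_genes = 4, pop_size = 1e6, reads_per_strain = 500, sigma_b = 0,
    single_fitness = stats::setNames(rep(1, 4), genes),
    epsilon_true = stats::setNames(rep(0, 6),
                                   paste(prs[1, ], prs[2, ], sep = ":")))
  panel <- make_strain_panel(cfg)
  counts <- simulate_pool(panel, n_replicates = 2)
  ctrl <- panel$genotypes$strain_id[panel$genotypes$type == "control"]
  fit <- pool_fitness(counts, ctrl)
  m <- mean(fit$fitness, na.rm = TRUE)
  se <- stats::sd(fit$fitness, na.rm = TRUE) /
    sqrt(sum(!is.na(fit$fitness)))
  expect_lt(abs(m - 1), 3 * se + 1e-3)
})

test_that("the estimator inverts the analytic infinite-depth trajectories", {
  set.seed(69)
  panel <- make_strain_panel(sim_config(sigma_b = 0.02))
  freqs <- analytic_frequencies(panel)
  ctrl <- panel$genotypes$strain_id[panel$genotypes$type == "control"]
  fit <- estimate_fitness(normalize_to_wt(freqs, ctrl))
  cmp <- dplyr::inner_join(fit, panel$truth, by = "strain_id")
  expect_lt(max(abs(cmp$fitness - cmp$fitness_true)), 1e-6)
})

test_that("sigma_b > 0 reproduces the genotype > barcode variance ordering", {
  set.seed(71)
  panel <- make_strain_panel(sim_config(pop_size = 1e6,
                                        reads_per_strain = 300,
                                        sigma_b = 0.05))
  counts <- simulate_pool(panel, n_replicates = 3)
  ctrl <- panel$genotypes$strain_id[panel$genotypes$type == "control"]
  fit <- pool_fitness(counts, ctrl)
  fit <- fit[!fit$censored, ]
  g <- panel$genotypes
  lab <- ifelse(is.na(g$pair), paste0(g$gene_a, ":", g$gene_b), g$pair)
  tbl <- tibble::tibble(strain_id = fit$strain_id,
                        replicate = fit$replicate, value = fit$fitness,
                        genotype = lab[match(fit$strain_id, g$strain_id)])
  s <- summarize_reproducibility(tbl)
  expect_gt(s$median_sd_same_genotype, s$median_sd_same_barcode)
})

test_that("emitted FASTQ loses reads at the binomial rate under errors", {
  set.seed(73)
  counts <- tiny_counts()
  counts$count <- counts$count * 20L
  map <- tiny_map()
  layout <- tiny_layout()
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts, map, layout, r1, r2, error_rate = 0.01)
  got <- count_double_barcodes(r1, r2, map, layout, max_mismatch = 2)
  total <- sum(counts$count)
  recovered <- sum(got$counts$count)
  # a pair is lost when either 8-mer barcode carries >= 3 errors, or the
  # 3-nt tag is hit at all (tags match exactly); bound the loss loosely
  p_tag <- 1 - 0.99^6
  expect_gt(recovered, total * (1 - p_tag) * 0.97)
  expect_lte(recovered, total)
})

test_that("OD simulation: doubling halves when r doubles; flat when K = od0", {
  r <- log(2) / 100
  c1 <- simulate_od_curve(0.005, 0.6, r)
  c2 <- simulate_od_curve(0.005, 0.6, 2 * r)
  f1 <- doubling_time(c1$time, c1$od)
  f2 <- doubling_time(c2$time, c2$od)
  expect_equal(f2$doubling_time / f1$doubling_time, 0.5, tolerance = 0.02)
  flat <- simulate_od_curve(0.3, 0.3, r)
  expect_true(doubling_time(flat$time, flat$od)$no_growth)
})
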