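test_that("epsilon is the deviation from the multiplicative expectation", {
  expect_equal(epsilon(0.72, 0.9, 0.8), 0)
  expect_equal(epsilon(0.60, 0.9, 0.8), -0.12)
  expect_equal(epsilon(1, 1, 1), 0)
  expect_true(is.na(epsilon(NA, 0.9, 0.8)))   # censored propagates
})

test_that("per-strain scores use proxy means and respect gene order", {
  geno <- genotype_map(
    tibble::tibble(strain_id = c("i1", "i2", "j1", "d1", "d2", "c1"),
                   gene_a = c("geneI", "DUBX", "geneJ", "geneI", "geneJ",
                              "DUBX"),
                   gene_b = c("DUBX", "geneI", "DUBY", "geneJ", "geneI",
                              "DUBY")),
    dubious = c("DUBX", "DUBY"))
  expect_equal(geno$type, c("single", "single", "single", "double",
                            "double", "control"))
  fit <- tibble::tibble(
    strain_id = c("i1", "i2", "j1", "d1", "d2", "c1"),
    condition = "c", replicate = "1",
    fitness = c(0.88, 0.92, 0.8, 0.60, 0.72, 1),
    censored = FALSE)
  eps <- strain_interaction_scores(fit, geno)
  # fhat_i = mean(0.88, 0.92) = 0.90; 0.60 - 0.90*0.80 = -0.12
  expect_equal(eps$eps[eps$strain_id == "d1"], -0.12)
  # d2 lists the genes in the opposite order; same pair, eps = 0
  expect_equal(eps$eps[eps$strain_id == "d2"], 0)
  expect_equal(unique(eps$pair), "GENEI:GENEJ")
})

test_that("a gene with no usable proxies leaves eps undefined, with a message", {
  geno <- genotype_map(
    tibble::tibble(strain_id = c("i1", "d1"),
                   gene_a = c("geneI", "geneI"),
                   gene_b = c("DUBX", "geneJ")),
    dubious = "DUBX")
  fit <- tibble::tibble(strain_id = c("i1", "d1"), condition = "c",
                        replicate = "1", fitness = c(0.9, 0.7),
                        censored = FALSE)
  expect_message(eps <- strain_interaction_scores(fit, geno), "undefined")
  expect_true(is.na(eps$eps))
})

test_that("t-based CI around the strain mean drives sign calls", {
  # zero variance: CI collapses to the mean
  r <- ci_mean(rep(0.1, 4))
  expect_equal(c(r$ci_low, r$ci_high), c(0.1, 0.1))
  expect_equal(r$sign_call, "positive")
  # symmetric about zero
  r2 <- ci_mean(c(-0.1, 0.1, -0.1, 0.1))
  expect_equal(r2$mean, 0)
  expect_equal(r2$ci_low, -r2$ci_high)
  expect_equal(r2$sign_call, "none")
  # hand-derived t interval: mean 0.065, sd 0.012910, t(0.975, 3) = 3.1824
  r3 <- ci_mean(c(0.05, 0.07, 0.06, 0.08))
  expect_equal(r3$mean, 0.065)
  expect_equal(r3$ci_low, 0.065 - 3.182446 * 0.01290994 / 2, tolerance = 1e-6)
  expect_equal(r3$ci_high, 0.065 + 3.182446 * 0.01290994 / 2, tolerance = 1e-6)
  expect_equal(r3$sign_call, "positive")
  # n < 2: undefined CI, never an exception
  r4 <- ci_mean(0.3)
  expect_true(is.na(r4$ci_low))
  expect_equal(r4$sign_call, "none")
})

test_that("aggregation invariants: ci_low <= mean <= ci_high; call iff 0 outside", {
  set.seed(9)
  eps <- tidyr::crossing(
    tibble::tibble(strain_id = sprintf("s%d", 1:6)),
    tibble::tibble(replicate = as.character(1:3))) |>
    dplyr::mutate(pair = "A:B", gene_a = "A", gene_b = "B",
                  condition = "c", eps = stats::rnorm(18, 0.02, 0.05))
  for (i in 1:20) {
    eps$eps <- stats::rnorm(18, stats::runif(1, -0.1, 0.1), 0.05)
    agg <- aggregate_interactions(eps)
    expect_lte(agg$ci_low, agg$mean_eps)
    expect_gte(agg$ci_high, agg$mean_eps)
    outside <- agg$ci_low > 0 || agg$ci_high < 0
    expect_identical(agg$sign_call != "none", outside)
  }
})

test_that("exact rank-sum p matches enumeration for all n <= 6", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    m <- sample(3:6, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(m)
    expect_equal(rank_sum_p(x, y), enumerate_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("complete separation at 8 vs 8 gives exact p = 2/12870", {
  p <- rank_sum_p(1:8, 101:108)
  expect_equal(p, 2 / 12870, tolerance = 1e-12)
})

test_that("BH step matches hand-computed thresholds and is order-invariant", {
  # thresholds at q = 0.10 for 3 tests: 0.0333, 0.0667, 0.1
  p <- c(0.001, 0.5, 0.9)
  expect_equal(stats::p.adjust(p, "BH") <= 0.10, c(TRUE, FALSE, FALSE))

  set.seed(17)
  eps <- tidyr::crossing(
    tibble::tibble(pair = sprintf("G%d:G%d", 1:6, 7:12)),
    tibble::tibble(strain_id = sprintf("s%d", 1:6),
                   replicate = "1"),
    tibble::tibble(condition = c("A", "B"))) |>
    dplyr::mutate(eps = stats::rnorm(dplyr::n()) +
                    ifelse(pair == "G1:G7" & condition == "B", 3, 0))
  d1 <- differential_interactions(eps, "A", "B")
  d2 <- differential_interactions(eps[sample(nrow(eps)), ], "A", "B")
  expect_equal(d1[order(d1$pair), ], d2[order(d2$pair), ])
  # identical value multisets in both conditions are never significant
  same <- eps
  v <- stats::rnorm(6)
  same$eps <- v[match(same$strain_id, sprintf("s%d", 1:6))]
  dsame <- differential_interactions(same, "A", "B")
  expect_true(all(!dsame$q_significant))
})

test_that("pairs with too few scores in a condition are skipped with a message", {
  eps <- tibble::tibble(
    pair = "A:B", strain_id = sprintf("s%d", 1:4), replicate = "1",
    condition = c("A", "A", "A", "B"),
    eps = c(0.1, 0.2, 0.3, 0.4))
  expect_message(d <- differential_interactions(eps, "A", "B"), "skipped")
  expect_equal(nrow(d), 0L)
})

test_that("reproducibility summary recovers known variance ordering", {
  # identical replicate vectors -> rho 1; SD of {1.0, 1.1, 1.2} = 0.1
  tbl <- tibble::tibble(strain_id = rep(c("a", "b", "c"), 2),
                        replicate = rep(c("1", "2"), each = 3),
                        value = rep(c(1.0, 1.1, 1.2), 2))
  s <- summarize_reproducibility(tbl)
  expect_equal(s$replicate_rho$rho, 1)
  expect_equal(s$median_sd_same_barcode, 0)
  expect_equal(stats::sd(c(1.0, 1.1, 1.2)), 0.1)

  # genotype-level spread sigma_b > within-barcode spread sigma_w
  set.seed(23)
  genos <- sprintf("g%d", 1:30)
  strains <- tidyr::crossing(genotype = genos,
                             bc = sprintf("bc%d", 1:6)) |>
    dplyr::mutate(strain_id = paste(genotype, bc, sep = "_"),
                  strain_mu = stats::rnorm(dplyr::n(), 0, 0.08))
  tbl2 <- tidyr::crossing(strains, replicate = as.character(1:3)) |>
    dplyr::mutate(value = strain_mu + stats::rnorm(dplyr::n(), 0, 0.01))
  s2 <- summarize_reproducibility(
    tbl2[, c("strain_id", "replicate", "value", "genotype")])
  expect_gt(s2$median_sd_same_genotype, s2$median_sd_same_barcode)
  expect_lt(s2$sd_comparison_p, 0.01)
  # single replicate: correlation section omitted
  s3 <- summarize_reproducibility(tbl[tbl$replicate == "1", ])
  expect_null(s3$replicate_rho)
})
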