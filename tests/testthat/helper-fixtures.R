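# Small in-code fixtures shared across test files.

# three strains x one condition x one replicate x 2 time points
tiny_counts <- function() {
  tibble::tibble(
    strain_id = rep(c("wt1", "mutA", "mutB"), each = 2),
    condition = "YPD", replicate = "1",
    time_point = rep(0:1, 3),
    count = c(50L, 50L, 30L, 15L, 20L, 5L))
}

tiny_map <- function() {
  barcode_map(
    tibble::tibble(strain_id = c("wt1", "mutA", "mutB"),
                   bc5 = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                   bc3 = c("TTTTTTTT", "ACACACAC", "GTGTGTGT")),
    tibble::tibble(tag = c("AAA", "CCC"), condition = "YPD",
                   replicate = "1", time_point = 0:1))
}

tiny_layout <- function() {
  read_layout(tag = c(1, 0, 3), bc5 = c(1, 3, 8), bc3 = c(2, 0, 8))
}

# brute-force two-sided rank-sum p by enumerating all rank assignments
enumerate_rank_sum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  obs <- sum(rank(c(x, y))[seq_len(n)])
  combs <- utils::combn(n + m, n)
  sums <- colSums(matrix(seq_len(n + m)[combs], nrow = n))
  mu <- n * (n + m + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

small_panel <- function(seed = 11, n_genes = 4, ...) {
  set.seed(seed)
  make_strain_panel(sim_config(n_genes = n_genes, pop_size = 1e5,
                               reads_per_strain = 100, ...))
}
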