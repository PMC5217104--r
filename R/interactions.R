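#' Build a genotype map from gene-pair annotations
#'
#' Each strain maps to an unordered gene pair; dubious-ORF placeholder
#' deletions mark single-deletion proxies (one real gene + one dubious
#' ORF) and double-dubious strains are wild-type controls. Gene names are
#' case-normalized to upper case and the pair label is order-independent.
#'
#' @param strains Data frame with columns `strain_id`, `gene_a`, `gene_b`.
#' @param dubious Character vector of dubious-ORF gene names.
#' @return Tibble adding `type` (`"control"`, `"single"`, `"double"`),
#'   `gene` (the real gene of a single proxy, else `NA`) and `pair`
#'   (canonical `"A:B"` label for doubles, else `NA`).
#' @export
genotype_map <- function(strains, dubious) {
  g <- tibble::as_tibble(strains)[, c("strain_id", "gene_a", "gene_b")]
  g$gene_a <- toupper(g$gene_a)
  g$gene_b <- toupper(g$gene_b)
  dubious <- toupper(dubious)
  dub_a <- g$gene_a %in% dubious
  dub_b <- g$gene_b %in% dubious
  g$type <- ifelse(dub_a & dub_b, "control",
                   ifelse(dub_a | dub_b, "single", "double"))
  g$gene <- dplyr::case_when(
    g$type == "single" & dub_a ~ g$gene_b,
    g$type == "single" & !dub_a ~ g$gene_a,
    TRUE ~ NA_character_)
  g$pair <- ifelse(g$type == "double",
                   paste(pmin(g$gene_a, g$gene_b),
                         pmax(g$gene_a, g$gene_b), sep = ":"),
                   NA_character_)
  g
}

#' Multiplicative-model genetic interaction score
#'
#' `epsilon = f_ij - f_i * f_j`: the deviation of the observed
#' double-mutant fitness from the product of the two single-mutant
#' fitnesses. Negative scores indicate synthetic sickness, positive
#' scores suppression. `NA` (censored) fitness propagates to `NA`.
#'
#' @param f_ij Double-mutant fitness.
#' @param f_i,f_j Single-mutant fitnesses.
#' @return `f_ij - f_i * f_j`, vectorized.
#' @export
epsilon <- function(f_ij, f_i, f_j) {
  f_ij - f_i * f_j
}

#' Per-strain interaction scores from a fitness table
#'
#' For each double-mutant strain, replicate culture and condition,
#' computes `epsilon = f_ij - fhat_i * fhat_j`, where `fhat_i` is the
#' mean fitness over all uncensored single-mutant proxy strains for gene
#' i in that replicate and condition (all proxy barcodes enter
#' symmetrically). A gene with no usable proxy in a replicate leaves
#' epsilon `NA` there, with a message.
#'
#' @param fitness Fitness tibble from [estimate_fitness()] /
#'   [pool_fitness()].
#' @param genotypes A [genotype_map()] tibble.
#' @return Tibble `strain_id`, `pair`, `gene_a`, `gene_b`, `condition`,
#'   `replicate`, `eps`.
#' @export
strain_interaction_scores <- function(fitness, genotypes) {
  fit <- dplyr::inner_join(fitness, genotypes, by = "strain_id")
  singles <- fit[fit$type == "single" & !fit$censored & !is.na(fit$fitness), ]
  proxy <- dplyr::summarise(
    dplyr::group_by(singles, .data$gene, .data$condition, .data$replicate),
    fhat = mean(.data$fitness), .groups = "drop")
  doubles <- fit[fit$type == "double", ]
  doubles$ga <- pmin(doubles$gene_a, doubles$gene_b)
  doubles$gb <- pmax(doubles$gene_a, doubles$gene_b)
  out <- dplyr::left_join(
    doubles, dplyr::rename(proxy, ga = "gene", fhat_a = "fhat"),
    by = c("ga", "condition", "replicate"))
  out <- dplyr::left_join(
    out, dplyr::rename(proxy, gb = "gene", fhat_b = "fhat"),
    by = c("gb", "condition", "replicate"))
  out$eps <- epsilon(out$fitness, out$fhat_a, out$fhat_b)
  n_na <- sum(is.na(out$eps))
  if (n_na > 0) {
    message(sprintf(
      "%d of %d double-strain scores undefined (censored fitness or missing proxies)",
      n_na, nrow(out)))
  }
  out <- out[, c("strain_id", "pair", "ga", "gb", "condition", "replicate",
                 "eps")]
  dplyr::rename(out, gene_a = "ga", gene_b = "gb")
}

#' Mean and Student-t confidence interval for a set of scores
#'
#' @param values Numeric scores (NAs dropped).
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return List `n`, `mean`, `sd`, `ci_low`, `ci_high`, `sign_call`
#'   (`"positive"` if the interval lies above 0, `"negative"` below 0,
#'   else `"none"`; `"none"` with an undefined CI when n < 2).
#' @export
ci_mean <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    return(list(n = n, mean = if (n) mean(values) else NA_real_,
                sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                sign_call = "none"))
  }
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  sign_call <- if (m - half > 0) "positive" else if (m + half < 0) "negative"
               else "none"
  list(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half,
       sign_call = sign_call)
}

#' Aggregate interaction scores over replicate strains
#'
#' Per-strain scores are first averaged over growth replicates (one value
#' per strain), then a 95% confidence interval is computed around the
#' mean across the strains carrying the same gene-deletion pair; a pair
#' is called significantly positive or negative when the interval
#' excludes zero.
#'
#' @param eps_strain Output of [strain_interaction_scores()].
#' @param alpha Two-sided level for the CI (default 0.05).
#' @return Tibble per pair x condition: `pair`, `gene_a`, `gene_b`,
#'   `condition`, `n_strains`, `mean_eps`, `ci_low`, `ci_high`,
#'   `sign_call`.
#' @export
aggregate_interactions <- function(eps_strain, alpha = 0.05) {
  per_strain <- dplyr::summarise(
    dplyr::group_by(eps_strain, .data$pair, .data$gene_a, .data$gene_b,
                    .data$condition, .data$strain_id),
    eps = mean(.data$eps, na.rm = TRUE), .groups = "drop")
  per_strain$eps[is.nan(per_strain$eps)] <- NA_real_
  agg <- dplyr::summarise(
    dplyr::group_by(per_strain, .data$pair, .data$gene_a, .data$gene_b,
                    .data$condition),
    res = list(ci_mean(.data$eps, alpha = alpha)), .groups = "drop")
  agg$n_strains <- vapply(agg$res, `[[`, numeric(1), "n")
  agg$mean_eps <- vapply(agg$res, `[[`, numeric(1), "mean")
  agg$ci_low <- vapply(agg$res, `[[`, numeric(1), "ci_low")
  agg$ci_high <- vapply(agg$res, `[[`, numeric(1), "ci_high")
  agg$sign_call <- vapply(agg$res, `[[`, character(1), "sign_call")
  agg$res <- NULL
  agg
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum p-value
#'
#' Exact when both samples have at most `exact_max` observations and no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group n for the exact null (default 8).
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(x, y, exact_max = 8L) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Call environment-dependent (differential) interactions
#'
#' For every gene pair observed in both conditions with at least
#' `min_n` replicate-strain scores per condition, tests whether the
#' per-strain scores (averaged over growth replicates) differ between
#' conditions by a two-sided rank-sum test, then applies
#' Benjamini-Hochberg correction across all tested pairs at rate `fdr`.
#'
#' @param eps_strain Output of [strain_interaction_scores()], covering
#'   both conditions.
#' @param condition_a,condition_b The two conditions to contrast.
#' @param fdr False discovery rate for the BH step (default 0.10).
#' @param min_n Minimum strains per condition per pair (default 3).
#' @return Tibble `pair`, `condition_a`, `condition_b`, `n_a`, `n_b`,
#'   `p_value`, `p_adjust`, `q_significant`.
#' @export
differential_interactions <- function(eps_strain, condition_a, condition_b,
                                      fdr = 0.10, min_n = 3L) {
  per_strain <- dplyr::summarise(
    dplyr::group_by(eps_strain, .data$pair, .data$condition,
                    .data$strain_id),
    eps = mean(.data$eps, na.rm = TRUE), .groups = "drop")
  per_strain <- per_strain[is.finite(per_strain$eps), ]
  pairs <- sort(unique(per_strain$pair))
  rows <- lapply(pairs, function(p) {
    a <- per_strain$eps[per_strain$pair == p &
                          per_strain$condition == condition_a]
    b <- per_strain$eps[per_strain$pair == p &
                          per_strain$condition == condition_b]
    if (length(a) < min_n || length(b) < min_n) {
      message(sprintf("pair %s skipped (n = %d vs %d)", p,
                      length(a), length(b)))
      return(NULL)
    }
    tibble::tibble(pair = p, condition_a = condition_a,
                   condition_b = condition_b, n_a = length(a),
                   n_b = length(b), p_value = rank_sum_p(a, b))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out$q_significant <- out$p_adjust <= fdr
  }
  out
}

#' Reproducibility of per-strain measurements across replicates
#'
#' Summarizes a per-strain, per-replicate measurement (fitness or
#' interaction score): Spearman correlation between every replicate
#' pair; the median across strains of the SD across replicate cultures
#' of the same double barcode; and, when a `genotype` grouping is given,
#' the median across genotypes of the SD across strains'
#' replicate-averaged values, with a rank-sum comparison of the two SD
#' distributions (different barcodes of one genotype vary more than one
#' barcode across cultures when between-strain variation is real).
#'
#' @param tbl Tibble with columns `strain_id`, `replicate`, `value` and
#'   optionally `genotype`.
#' @return List `replicate_rho` (tibble of pairwise Spearman rho, `NULL`
#'   with a single replicate), `median_sd_same_barcode`, and — with
#'   genotypes — `median_sd_same_genotype` plus `sd_comparison_p`.
#' @export
summarize_reproducibility <- function(tbl) {
  stopifnot(all(c("strain_id", "replicate", "value") %in% names(tbl)))
  reps <- sort(unique(tbl$replicate))
  wide <- tidyr::pivot_wider(tbl[, c("strain_id", "replicate", "value")],
                             names_from = "replicate",
                             values_from = "value")
  rho <- NULL
  if (length(reps) >= 2) {
    cmb <- utils::combn(as.character(reps), 2)
    rho <- tibble::tibble(
      rep_a = cmb[1, ], rep_b = cmb[2, ],
      rho = apply(cmb, 2, function(pr) {
        stats::cor(wide[[pr[1]]], wide[[pr[2]]], method = "spearman",
                   use = "pairwise.complete.obs")
      }))
  }
  per_strain_sd <- dplyr::summarise(
    dplyr::group_by(tbl, .data$strain_id),
    sd = stats::sd(.data$value, na.rm = TRUE),
    mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  out <- list(replicate_rho = rho,
              median_sd_same_barcode =
                stats::median(per_strain_sd$sd, na.rm = TRUE))
  if ("genotype" %in% names(tbl)) {
    geno <- dplyr::distinct(tbl[, c("strain_id", "genotype")])
    per_strain_sd <- dplyr::left_join(per_strain_sd, geno, by = "strain_id")
    per_geno_sd <- dplyr::summarise(
      dplyr::group_by(per_strain_sd, .data$genotype),
      sd = stats::sd(.data$mean, na.rm = TRUE), .groups = "drop")
    out$median_sd_same_genotype <- stats::median(per_geno_sd$sd,
                                                 na.rm = TRUE)
    out$sd_comparison_p <- rank_sum_p(
      per_geno_sd$sd[!is.na(per_geno_sd$sd)],
      per_strain_sd$sd[!is.na(per_strain_sd$sd)])
  }
  out
}
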