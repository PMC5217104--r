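#' Classify variants as inherited or de novo against a pedigree
#'
#' An event observed in a child strain is `inherited` when the identical
#' key (chrom+pos+alt for SNPs/indels, chromosome for whole-chromosome
#' aneuploidies) occurs in either sequenced parent; `de_novo` when both
#' parents are sequenced and neither carries it; otherwise
#' `unclassifiable` — an unsequenced parent never yields a de novo call.
#'
#' @param variants Tibble `strain_id`, `kind` (`"snp_indel"` or
#'   `"aneuploidy"`), `key`.
#' @param pedigree Tibble `child`, `parent1`, `parent2`, `generation`;
#'   `NA` parent means unknown.
#' @param sequenced Character vector of strains with sequence data
#'   (default: every child in the pedigree).
#' @return `variants` with a `provenance` column.
#' @export
classify_provenance <- function(variants, pedigree,
                                sequenced = pedigree$child) {
  variants <- tibble::as_tibble(variants)
  ped_idx <- match(variants$strain_id, pedigree$child)
  orphan <- is.na(ped_idx)
  if (any(orphan)) {
    warning(sprintf("%d variant(s) in strains absent from the pedigree",
                    sum(orphan)))
  }
  carried <- paste(variants$strain_id, variants$kind, variants$key)
  in_strain <- function(strain, kind, key) {
    !is.na(strain) & paste(strain, kind, key) %in% carried
  }
  p1 <- pedigree$parent1[ped_idx]
  p2 <- pedigree$parent2[ped_idx]
  p1_seq <- !is.na(p1) & p1 %in% sequenced
  p2_seq <- !is.na(p2) & p2 %in% sequenced
  inh <- (p1_seq & in_strain(p1, variants$kind, variants$key)) |
         (p2_seq & in_strain(p2, variants$kind, variants$key))
  variants$provenance <- dplyr::case_when(
    orphan ~ "unclassifiable",
    inh ~ "inherited",
    p1_seq & p2_seq ~ "de_novo",
    TRUE ~ "unclassifiable")
  variants
}

#' Tabulate inherited / de novo event summaries for a cohort
#'
#' Counts unique events (deduplicated by kind + key; an event shared by
#' several strains counts once, and is labelled inherited if any carrier
#' inherited it) and total strain-level events, per-strain event counts,
#' the chromosome frequency table for aneuploidies, and the percentage
#' of strains carrying at least one aneuploidy (rounded to the nearest
#' integer, as reported).
#'
#' @param classified Output of [classify_provenance()].
#' @param pedigree The pedigree used for classification.
#' @param generation Optional generation label (e.g. `"F2"`) restricting
#'   the cohort; strains of other generations are dropped.
#' @return List `n_strains`, `unique_events` (kind x provenance tibble),
#'   `total_events`, `per_strain` (events per strain by kind),
#'   `aneuploid_chrom_freq`, `pct_strains_aneuploid`,
#'   `pct_inherited_snp` (inherited share of unique classified
#'   SNPs/indels, percent).
#' @export
tabulate_events <- function(classified, pedigree, generation = NULL) {
  cohort <- pedigree$child
  if (!is.null(generation)) {
    cohort <- pedigree$child[pedigree$generation %in% generation]
  }
  ev <- classified[classified$strain_id %in% cohort, ]
  lvl <- c("inherited", "de_novo", "unclassifiable")
  uniq <- if (nrow(ev)) {
    dplyr::summarise(
      dplyr::group_by(ev, .data$kind, .data$key),
      provenance = lvl[min(match(.data$provenance, lvl))],
      .groups = "drop")
  } else {
    ev[, c("kind", "key", "provenance")]
  }
  unique_events <- dplyr::count(uniq, .data$kind, .data$provenance,
                                name = "n_unique")
  total_events <- dplyr::count(ev, .data$kind, .data$provenance,
                               name = "n_events")
  per_strain <- dplyr::count(ev, .data$strain_id, .data$kind, name = "n")
  an <- ev[ev$kind == "aneuploidy", ]
  chrom_freq <- dplyr::count(an, chrom = .data$key, name = "n_strains",
                             sort = TRUE)
  snps <- uniq[uniq$kind == "snp_indel" & uniq$provenance != "unclassifiable", ]
  list(
    n_strains = length(unique(cohort)),
    unique_events = unique_events,
    total_events = total_events,
    per_strain = per_strain,
    aneuploid_chrom_freq = chrom_freq,
    pct_strains_aneuploid =
      round(100 * length(unique(an$strain_id)) / length(unique(cohort))),
    pct_inherited_snp = if (nrow(snps))
      round(100 * mean(snps$provenance == "inherited")) else NA_real_)
}
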