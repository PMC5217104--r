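#' Extract tag and barcode fields from read pairs
#'
#' Pulls the configured substrings out of each read pair. Reads too short
#' to carry a span yield `NA` for that field (the failure token); no
#' quality filtering is applied.
#'
#' @param r1,r2 Character vectors of read sequences (mates 1 and 2, same
#'   length and order).
#' @param layout An [read_layout()] object.
#' @return Tibble with columns `tag`, `bc5`, `bc3` (`NA` where the read
#'   was shorter than the span).
#' @export
extract_fields <- function(r1, r2, layout) {
  stopifnot(inherits(layout, "iseq_read_layout"),
            length(r1) == length(r2))
  pull <- function(sp) {
    seqs <- if (sp[1] == 1L) r1 else r2
    out <- substr(seqs, sp[2] + 1L, sp[2] + sp[3])
    out[nchar(seqs) < sp[2] + sp[3]] <- NA_character_
    out
  }
  tibble::tibble(tag = pull(layout$tag), bc5 = pull(layout$bc5),
                 bc3 = pull(layout$bc3))
}

#' Match observed barcodes against references by Hamming distance
#'
#' Returns, for each observed string, the index of the unique reference
#' within `max_mismatch` substitutions, or `NA` if none is close enough or
#' two references tie at the minimal distance (ambiguous reads are never
#' assigned).
#'
#' @param observed Character vector; each element must have the reference
#'   length (`NA` allowed, propagates).
#' @param references Character vector of equal-length reference barcodes.
#' @param max_mismatch Maximum Hamming distance (0-2 typical; default 0).
#' @return Integer vector of reference indices, `NA` for no-match.
#' @export
match_barcode <- function(observed, references, max_mismatch = 0L) {
  L <- unique(nchar(references))
  if (length(L) != 1L) stop("references must share one length")
  bad <- !is.na(observed) & nchar(observed) != L
  if (any(bad)) {
    stop(sprintf("observed barcode length != reference length (%d) at %d read(s)",
                 L, sum(bad)))
  }
  idx <- match(observed, references)   # exact hits, the common case
  if (max_mismatch > 0L && anyNA(idx)) {
    todo <- which(is.na(idx) & !is.na(observed))
    if (length(todo)) {
      ref_raw <- lapply(references, charToRaw)
      uniq <- unique(observed[todo])
      resolved <- vapply(uniq, function(obs) {
        d <- vapply(ref_raw, function(r) sum(r != charToRaw(obs)), integer(1))
        dmin <- min(d)
        if (dmin > max_mismatch || sum(d == dmin) > 1L) NA_integer_
        else which.min(d)
      }, integer(1))
      idx[todo] <- resolved[match(observed[todo], uniq)]
    }
  }
  idx
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count known double barcodes in paired-end amplicon reads
#'
#' Demultiplexes read pairs on their multiplex tag (matched exactly) and
#' tallies pairs whose bc5 and bc3 both match a reference barcode and
#' whose combination exists in the map. Pairs whose halves are valid but
#' whose pairing is unknown (chimeras) are counted as unmatched, never
#' assigned. Pairs with an unknown tag go to the reserved `untagged`
#' bucket.
#'
#' @param r1_path,r2_path Paired FASTQ files (plain or gzip).
#' @param map An [barcode_map()] object.
#' @param layout An [read_layout()] object; barcode span lengths must
#'   match the map's barcode lengths.
#' @param max_mismatch Hamming tolerance for bc5/bc3 matching (default 0).
#' @return An `iseq_counts` object: `$counts` — long tibble `strain_id`,
#'   `condition`, `replicate`, `time_point`, `count` (complete over
#'   strains x samples); `$unmatched` — per-sample unmatched read pairs;
#'   `$untagged` — pairs whose tag matched no sample.
#' @export
count_double_barcodes <- function(r1_path, r2_path, map, layout,
                                  max_mismatch = 0L) {
  stopifnot(inherits(map, "iseq_barcode_map"),
            inherits(layout, "iseq_read_layout"))
  if (layout$bc5[3] != nchar(map$entries$bc5[1]) ||
      layout$bc3[3] != nchar(map$entries$bc3[1])) {
    stop("layout barcode span lengths do not match the barcode map")
  }
  r1 <- read_fastq_seqs(r1_path)
  r2 <- read_fastq_seqs(r2_path)
  if (length(r1) != length(r2)) {
    stop(sprintf("R1 has %d records but R2 has %d", length(r1), length(r2)))
  }

  samples <- map$tag_map
  empty <- tidyr::crossing(
    tibble::tibble(strain_id = map$entries$strain_id),
    samples[, c("condition", "replicate", "time_point")])
  empty$count <- 0L
  unmatched0 <- samples[, c("condition", "replicate", "time_point")]
  unmatched0$unmatched <- 0L

  if (length(r1) == 0L) {
    return(structure(list(counts = empty, unmatched = unmatched0,
                          untagged = 0L), class = "iseq_counts"))
  }

  fields <- extract_fields(r1, r2, layout)
  sample_idx <- match(fields$tag, samples$tag)       # tags matched exactly
  untagged <- sum(is.na(sample_idx))

  i5 <- match_barcode(fields$bc5, unique(map$entries$bc5), max_mismatch)
  i3 <- match_barcode(fields$bc3, unique(map$entries$bc3), max_mismatch)
  u5 <- unique(map$entries$bc5)
  u3 <- unique(map$entries$bc3)
  pair_key <- paste(u5[i5], u3[i3])
  strain_idx <- match(pair_key, paste(map$entries$bc5, map$entries$bc3))
  strain_idx[is.na(i5) | is.na(i3)] <- NA_integer_

  tagged <- !is.na(sample_idx)
  hit <- tagged & !is.na(strain_idx)
  counts <- empty
  if (any(hit)) {
    tal <- table(strain = map$entries$strain_id[strain_idx[hit]],
                 sample = sample_idx[hit])
    hits <- as.data.frame(tal, stringsAsFactors = FALSE)
    hits <- hits[hits$Freq > 0L, ]
    si <- as.integer(hits$sample)
    key_hit <- paste(hits$strain, samples$condition[si],
                     samples$replicate[si], samples$time_point[si])
    key_all <- paste(counts$strain_id, counts$condition, counts$replicate,
                     counts$time_point)
    counts$count[match(key_hit, key_all)] <- as.integer(hits$Freq)
  }
  miss <- tagged & is.na(strain_idx)
  unmatched <- unmatched0
  if (any(miss)) {
    tal <- tabulate(sample_idx[miss], nbins = nrow(samples))
    unmatched$unmatched <- as.integer(tal)
  }
  structure(list(counts = counts, unmatched = unmatched,
                 untagged = as.integer(untagged)),
            class = "iseq_counts")
}

#' @export
print.iseq_counts <- function(x, ...) {
  cat(sprintf(
    "<iseq_counts> %d strains x %d samples; %d matched, %d unmatched, %d untagged read pairs\n",
    length(unique(x$counts$strain_id)),
    nrow(unique(x$counts[, c("condition", "replicate", "time_point")])),
    sum(x$counts$count), sum(x$unmatched$unmatched), x$untagged))
  invisible(x)
}

#' Read / write a long-format count table
#'
#' Columns `strain_id condition replicate time_point count`.
#'
#' @param x Count tibble (or `iseq_counts`, whose `$counts` is written).
#' @param path TSV path.
#' @name count_table_io
#' @export
write_count_table <- function(x, path) {
  if (inherits(x, "iseq_counts")) x <- x$counts
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname count_table_io
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    strain_id = "c", condition = "c", replicate = "c",
                    time_point = "i", count = "d"))
}
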