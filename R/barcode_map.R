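#' Construct a double-barcode map
#'
#' Associates each strain with its (bc5, bc3) double barcode and each
#' multiplex tag with the pooled sample (condition, replicate, time point)
#' it demultiplexes to. All bc5 barcodes must share one length, all bc3
#' barcodes another, and (bc5, bc3) pairs must be unique so that a read
#' pair identifies at most one strain.
#'
#' @param entries Data frame with columns `strain_id`, `bc5`, `bc3`
#'   (DNA strings, one fixed length per column).
#' @param tag_map Data frame with columns `tag`, `condition`, `replicate`,
#'   `time_point`; tags must be unique and of one length.
#' @return An object of class `iseq_barcode_map`.
#' @export
barcode_map <- function(entries, tag_map) {
  entries <- tibble::as_tibble(entries)[, c("strain_id", "bc5", "bc3")]
  tag_map <- tibble::as_tibble(tag_map)[, c("tag", "condition", "replicate",
                                            "time_point")]
  stopifnot(!anyDuplicated(entries$strain_id))
  if (length(unique(nchar(entries$bc5))) != 1L ||
      length(unique(nchar(entries$bc3))) != 1L) {
    stop("all bc5 (and all bc3) barcodes must have the same length")
  }
  if (anyDuplicated(paste(entries$bc5, entries$bc3))) {
    stop("(bc5, bc3) pairs must be unique")
  }
  if (anyDuplicated(tag_map$tag) ||
      length(unique(nchar(tag_map$tag))) != 1L) {
    stop("multiplex tags must be unique and of equal length")
  }
  structure(list(entries = entries, tag_map = tag_map),
            class = "iseq_barcode_map")
}

#' @export
print.iseq_barcode_map <- function(x, ...) {
  cat(sprintf(
    "<iseq_barcode_map> %d strains (bc5 %d nt, bc3 %d nt), %d samples\n",
    nrow(x$entries), nchar(x$entries$bc5[1]), nchar(x$entries$bc3[1]),
    nrow(x$tag_map)))
  invisible(x)
}

#' Read a barcode map and tag map from TSV
#'
#' `strain_id<TAB>bc5<TAB>bc3` and `tag<TAB>condition<TAB>replicate<TAB>time_point`.
#'
#' @param barcode_path,tag_path Paths to the two TSV files (with headers).
#' @return An `iseq_barcode_map`.
#' @export
read_barcode_map <- function(barcode_path, tag_path) {
  entries <- readr::read_tsv(barcode_path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  tags <- readr::read_tsv(tag_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            tag = "c", condition = "c", replicate = "c",
                            time_point = "i"))
  barcode_map(entries, tags)
}

#' Describe where tag and barcodes sit within a read pair
#'
#' The amplicon architecture is configuration: each field is a span
#' `c(mate, start, length)` with `mate` 1 or 2 and `start` a 0-based
#' offset within that mate. Spans on the same mate must not overlap.
#'
#' @param tag,bc5,bc3 Integer vectors `c(mate, start, length)`.
#' @return An object of class `iseq_read_layout`.
#' @examples
#' read_layout(tag = c(1, 0, 6), bc5 = c(1, 6, 20), bc3 = c(2, 0, 20))
#' @export
read_layout <- function(tag, bc5, bc3) {
  spans <- list(tag = tag, bc5 = bc5, bc3 = bc3)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 3L || !sp[1] %in% c(1L, 2L) || sp[2] < 0 || sp[3] < 1) {
      stop(sprintf("span '%s' must be c(mate in 1:2, start >= 0, length >= 1)",
                   nm))
    }
  }
  for (m in 1:2) {
    on_mate <- Filter(function(sp) sp[1] == m, spans)
    if (length(on_mate) > 1L) {
      iv <- t(vapply(on_mate, function(sp) c(sp[2], sp[2] + sp[3]),
                     numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
        stop(sprintf("spans overlap on mate %d", m))
      }
    }
  }
  structure(spans, class = "iseq_read_layout")
}
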