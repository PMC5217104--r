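test_that("extract_fields pulls configured spans and flags short reads", {
  layout <- tiny_layout()
  f <- extract_fields("AAACCCGGGTTT", "GTGTGTGTAA", layout)
  expect_equal(f$tag, "AAA")
  expect_equal(f$bc5, "CCCGGGTT")
  expect_equal(f$bc3, "GTGTGTGT")

  # mate-2 spans read from the second read of the pair
  lay2 <- read_layout(tag = c(2, 0, 3), bc5 = c(1, 0, 8), bc3 = c(2, 3, 8))
  f2 <- extract_fields("CCCCCCCCXX", "TTTACACACAC", lay2)
  expect_equal(f2$tag, "TTT")
  expect_equal(f2$bc3, "ACACACAC")

  # read shorter than a span yields the failure token
  short <- extract_fields("AAACC", "GTGTGTGT", layout)
  expect_true(is.na(short$bc5))
  expect_equal(short$tag, "AAA")
})

test_that("match_barcode resolves unique nearest hits and rejects ties", {
  refs <- c("AAAAAAAA", "CCCCCCCC", "AAAATTTT")
  expect_equal(match_barcode("CCCCCCCC", refs, 0), 2L)
  # 1 mismatch from ref 1, far from others, within tolerance
  expect_equal(match_barcode("AAAAAAAT", refs, 2), 1L)
  # equidistant (distance 2) from refs 1 and 3 -> ambiguous, no match
  expect_true(is.na(match_barcode("AAAAATTA", refs, 2)))
  # beyond tolerance
  expect_true(is.na(match_barcode("GGGGAAAA", refs, 2)))
  # length mismatch is an input error
  expect_error(match_barcode("AAAA", refs, 0), "length")
})

test_that("match_barcode agrees with brute-force Hamming enumeration", {
  set.seed(21)
  refs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
    character(1))
  obs <- vapply(1:60, function(i) {
    r <- sample(refs, 1)
    pos <- sample(10, sample(0:3, 1))
    ch <- strsplit(r, "")[[1]]
    ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
    paste(ch, collapse = "")
  }, character(1))
  hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  for (mm in 0:3) {
    expected <- vapply(obs, function(o) {
      d <- vapply(refs, hamming, integer(1), a = o)
      if (min(d) > mm || sum(d == min(d)) > 1) NA_integer_ else which.min(d)
    }, integer(1), USE.NAMES = FALSE)
    expect_equal(match_barcode(obs, refs, mm), expected)
  }
})

test_that("counting round-trips a simulated table exactly at zero error", {
  counts <- tiny_counts()
  map <- tiny_map()
  layout <- tiny_layout()
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts, map, layout, r1, r2, error_rate = 0)
  got <- count_double_barcodes(r1, r2, map, layout, max_mismatch = 0)
  expect_equal(
    dplyr::arrange(got$counts, strain_id, time_point)$count,
    dplyr::arrange(counts, strain_id, time_point)$count)
  expect_equal(sum(got$unmatched$unmatched), 0L)
  expect_equal(got$untagged, 0L)
})

test_that("read pairs are conserved across matched/unmatched/untagged", {
  map <- tiny_map()
  layout <- tiny_layout()
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  # matched; chimera (valid halves, pairing absent); unknown tag
  writeLines(c("@1", "AAACCCCCCCC", "+", "IIIIIIIIIII",
               "@2", "AAACCCCCCCC", "+", "IIIIIIIIIII",
               "@3", "GGGCCCCCCCC", "+", "IIIIIIIIIII"), r1)
  writeLines(c("@1", "ACACACAC", "+", "IIIIIIII",
               "@2", "GTGTGTGT", "+", "IIIIIIII",
               "@3", "ACACACAC", "+", "IIIIIIII"), r2)
  got <- count_double_barcodes(r1, r2, map, layout)
  expect_equal(sum(got$counts$count), 1L)          # read 1 -> mutA
  expect_equal(got$counts$count[got$counts$strain_id == "mutA" &
                                  got$counts$time_point == 0], 1L)
  expect_equal(sum(got$unmatched$unmatched), 1L)   # chimera never assigned
  expect_equal(got$untagged, 1L)
  expect_equal(sum(got$counts$count) + sum(got$unmatched$unmatched) +
                 got$untagged, 3L)
})

test_that("raising max_mismatch never decreases counts; empty input ok", {
  counts <- tiny_counts()
  map <- tiny_map()
  layout <- tiny_layout()
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  set.seed(31)
  emit_fastq(counts, map, layout, r1, r2, error_rate = 0.02)
  prev <- -1L
  for (mm in 0:2) {
    got <- count_double_barcodes(r1, r2, map, layout, max_mismatch = mm)
    expect_gte(sum(got$counts$count), prev)
    prev <- sum(got$counts$count)
  }

  empty1 <- withr::local_tempfile(fileext = ".fastq")
  empty2 <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty1, empty2)
  got <- count_double_barcodes(empty1, empty2, map, layout)
  expect_equal(sum(got$counts$count), 0L)
  expect_equal(got$untagged, 0L)
})

test_that("gzip FASTQ input is accepted", {
  counts <- tiny_counts()
  map <- tiny_map()
  layout <- tiny_layout()
  r1 <- withr::local_tempfile(fileext = ".fastq.gz")
  r2 <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(counts, map, layout, r1, r2)
  got <- count_double_barcodes(r1, r2, map, layout)
  expect_equal(sum(got$counts$count), sum(counts$count))
})
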