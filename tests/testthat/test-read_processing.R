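q_of <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

test_that("trailing N bases are removed from both ends", {
  reads <- data.frame(read_id = "r1", sequence = "NACGTACGTACGTACGTACGTANN",
                      quality = q_of(30, 24), stringsAsFactors = FALSE)
  out <- trim_reads(reads, trim_config(min_length = 4L))
  expect_identical(out$sequence, "ACGTACGTACGTACGTACGTA")
  expect_identical(nchar(out$quality), nchar(out$sequence))
})

test_that("low-quality 3' bases below the floor are removed greedily", {
  seq <- "ACGTACGTACGTACGTACGTACGTA"
  qual <- paste0(q_of(30, 20), q_of(2, 5))
  out <- trim_reads(data.frame(read_id = "r1", sequence = seq, quality = qual,
                               stringsAsFactors = FALSE),
                    trim_config(quality_floor = 3L, min_length = 4L))
  expect_identical(out$sequence, substr(seq, 1, 20))
  # phred64 encoding shifts the same rule
  qual64 <- paste0(q_of(64 - 33 + 30, 20), q_of(64 - 33 + 2, 5))
  out64 <- trim_reads(data.frame(read_id = "r1", sequence = seq,
                                 quality = qual64, stringsAsFactors = FALSE),
                      trim_config(quality_floor = 3L,
                                  quality_encoding = "phred64",
                                  min_length = 4L))
  expect_identical(out64$sequence, substr(seq, 1, 20))
})

test_that("a clean read passes through unchanged", {
  seq <- "ACGTACGTACGTACGTACGTACGTC"
  out <- trim_reads(data.frame(read_id = "r1", sequence = seq,
                               quality = q_of(30, nchar(seq)),
                               stringsAsFactors = FALSE), trim_config())
  expect_identical(out$sequence, seq)
  expect_equal(nrow(out), 1L)
})

test_that("adapter trimming needs at least three overlapping bases", {
  adapter <- "AGATCGGAAGAGC"
  genomic <- "CCATTCCATTCCATTCCATTCCATT"
  mk <- function(s) data.frame(read_id = "r1", sequence = s,
                               quality = q_of(30, nchar(s)),
                               stringsAsFactors = FALSE)
  cfg <- trim_config(min_length = 4L)
  # full adapter occurrence cuts the read there
  out <- trim_reads(mk(paste0(genomic, adapter)), cfg)
  expect_identical(out$sequence, genomic)
  # 5-base adapter prefix at the 3' end is removed
  out5 <- trim_reads(mk(paste0(genomic, substr(adapter, 1, 5))), cfg)
  expect_identical(out5$sequence, genomic)
  # 2-base overlap is below the minimum and stays
  out2 <- trim_reads(mk(paste0(genomic, substr(adapter, 1, 2))), cfg)
  expect_identical(out2$sequence, paste0(genomic, "AG"))
})

test_that("reads shorter than the minimum after trimming are discarded", {
  reads <- data.frame(read_id = c("keep", "drop"),
                      sequence = c(strrep("ACGT", 10),
                                   paste0(strrep("AT", 8), strrep("N", 10))),
                      quality = c(q_of(30, 40), q_of(30, 26)),
                      stringsAsFactors = FALSE)
  out <- trim_reads(reads, trim_config())
  expect_identical(out$read_id, "keep")
  expect_equal(attr(out, "n_input"), 2L)
  expect_error(trim_reads(data.frame(read_id = "r", sequence = "ACGT",
                                     quality = "##", stringsAsFactors = FALSE)),
               "length")
})

test_that("a bisulfite T against a reference C is not a mismatch", {
  # 24 bp fragment, distinct decoy; the read converts two unmethylated C's
  frag <- "ACGGATTACCTGATCGATACCGAT"
  decoy <- "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"
  fr <- data.frame(fragment_id = 1:2, chrom = "chr1", start = c(0L, 100L),
                   end = c(24L, 140L), length = c(24L, 40L),
                   sequence = c(frag, decoy), stringsAsFactors = FALSE)
  idx <- build_converted_indices(fr)
  read <- chartr("C", "T", frag) # fully converted, fully unmethylated
  aln <- align_reads(data.frame(read_id = "r1", sequence = read,
                                stringsAsFactors = FALSE), idx)
  expect_identical(aln$status, "unique")
  expect_identical(aln$strand_mode, "OT")
  expect_equal(aln$counted_mismatches, 0L)
  expect_equal(aln$offset, 0L)
})

test_that("a read-A against a fragment-G counts as a mismatch in OT mode", {
  frag <- "ACGGATTACCTGATCGATACCGAT"
  fr <- data.frame(fragment_id = 1L, chrom = "chr1", start = 0L, end = 24L,
                   length = 24L, sequence = frag, stringsAsFactors = FALSE)
  idx <- build_converted_indices(fr)
  read <- frag
  substr(read, 3, 3) <- "A" # G -> A at position 2 (0-based)
  aln <- align_reads(data.frame(read_id = "r1", sequence = read,
                                stringsAsFactors = FALSE), idx)
  expect_identical(aln$status, "unique")
  expect_equal(aln$counted_mismatches, 1L)
})

test_that("a best/second-best gap below 2 is ambiguous", {
  fragA <- "ACGGATTACCTGATCGATACCGAT"
  fragB <- fragA
  substr(fragB, 7, 7) <- "A" # one T -> A difference
  fr <- data.frame(fragment_id = 1:2, chrom = "chr1", start = c(0L, 100L),
                   end = c(24L, 124L), length = 24L,
                   sequence = c(fragA, fragB), stringsAsFactors = FALSE)
  idx <- build_converted_indices(fr)
  aln <- align_reads(data.frame(read_id = "r1", sequence = fragA,
                                stringsAsFactors = FALSE), idx)
  expect_identical(aln$status, "ambiguous")
  expect_equal(aln$second_best_mismatches - aln$counted_mismatches, 1L)
})

test_that("reads from identical planted fragments are never unique", {
  frag <- "ACGGATTACCTGATCGATACCGATACGGATTACCTGATCG"
  fr <- data.frame(fragment_id = 1:2, chrom = "chr1", start = c(0L, 100L),
                   end = c(40L, 140L), length = 40L, sequence = frag,
                   stringsAsFactors = FALSE)
  idx <- build_converted_indices(fr)
  aln <- align_reads(data.frame(read_id = "r1",
                                sequence = chartr("C", "T", frag),
                                stringsAsFactors = FALSE), idx)
  expect_identical(aln$status, "ambiguous")
})

test_that("reads beyond the mismatch budget are unmapped", {
  frag <- "ACGGATTACCTGATCGATACCGAT"
  fr <- data.frame(fragment_id = 1L, chrom = "chr1", start = 0L, end = 24L,
                   length = 24L, sequence = frag, stringsAsFactors = FALSE)
  idx <- build_converted_indices(fr)
  read <- frag
  substr(read, 2, 2) <- "G"; substr(read, 6, 6) <- "G"
  substr(read, 11, 11) <- "A" # three counted mismatches
  aln <- align_reads(data.frame(read_id = "r1", sequence = read,
                                stringsAsFactors = FALSE), idx)
  expect_identical(aln$status, "unmapped")
  expect_identical(align_reads(data.frame(read_id = "r1", sequence = read,
                                          stringsAsFactors = FALSE),
                               idx, max_mismatches = 3L)$status, "unique")
})

test_that("error-free simulated reads realign to their origin", {
  fx <- fx_clean_run()
  rt <- roundtrip_accuracy(fx$alignments, fx$truth)
  expect_gte(rt$accuracy, 0.99)
  expect_true(all(fx$alignments$counted_mismatches == 0L))
  uniq <- fx$alignments$status == "unique"
  expect_true(all(fx$alignments$second_best_mismatches[uniq] -
                    fx$alignments$counted_mismatches[uniq] >= 2L |
                    is.na(fx$alignments$second_best_mismatches[uniq])))
})

test_that("SAM and alignment-table writers emit the records", {
  fx <- fx_clean_run()
  tsv <- tempfile(fileext = ".tsv")
  write_alignments(fx$alignments, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(fx$alignments))
  sam <- tempfile(fileext = ".sam")
  write_sam(fx$alignments, fx$genome, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), sum(fx$alignments$status == "unique"))
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_true(all(flags %in% c(0L, 16L)))
})
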