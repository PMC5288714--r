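#' Trimming configuration
#'
#' @param adapter Adapter sequence removed from the 3' end (longest
#'   prefix-overlap, minimum 3 bases).
#' @param quality_floor Phred score below which 3' bases are removed
#'   (default 3, the Illumina-1.5 "Q < 67 in ASCII-64" rule expressed in
#'   Phred units).
#' @param quality_encoding `"phred33"` or `"phred64"`.
#' @param min_length Reads shorter than this after trimming are discarded.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(adapter = DEFAULT_ADAPTER, quality_floor = 3L,
                        quality_encoding = c("phred33", "phred64"),
                        min_length = 20L) {
  quality_encoding <- match.arg(quality_encoding)
  if (quality_floor < 0) stopf("quality_floor must be non-negative")
  structure(list(adapter = toupper(adapter),
                 quality_floor = as.integer(quality_floor),
                 quality_encoding = quality_encoding,
                 min_length = as.integer(min_length)),
            class = "trim_config")
}

#' Trim reads: adapter, low-quality 3' bases, terminal ambiguous bases
#'
#' In order: (1) the longest 3'-end overlap with the adapter prefix
#' (full internal occurrences cut the read there; minimum overlap 3),
#' (2) greedy removal of 3' bases below the quality floor, (3) removal of
#' leading and trailing `N` runs. Reads shorter than `cfg$min_length`
#' afterwards are discarded.
#'
#' @param reads Data.frame with `read_id`, `sequence`, `quality`.
#' @param cfg A [trim_config()].
#' @return The trimmed subset of `reads`, with a `n_input` attribute.
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stopf("sequence and quality strings differ in length")
  offset <- if (cfg$quality_encoding == "phred33") 33L else 64L
  res <- .cpp_trim_reads(reads$sequence, reads$quality, cfg$adapter,
                         cfg$quality_floor, offset, cfg$min_length)
  out <- data.frame(read_id = reads$read_id[res$keep],
                    sequence = res$sequence[res$keep],
                    quality = res$quality[res$keep],
                    stringsAsFactors = FALSE)
  rrbs_log("info", sprintf("trim: %d of %d reads retained (%d discarded < %d nt)",
                           nrow(out), nrow(reads), sum(!res$keep),
                           cfg$min_length))
  attr(out, "n_input") <- nrow(reads)
  out
}

#' Bisulfite-aware ungapped alignment to the fragment indices
#'
#' Every ungapped placement of the read in every fragment is a candidate, in
#' both strand interpretations: the C-to-T-converted read against the
#' C-to-T index (OT) and the reverse complement against the G-to-A index
#' (OB). For each candidate, mismatches are counted between the original
#' read and the original fragment, ignoring read-T/fragment-C positions (OT)
#' and read-A/fragment-G positions (OB). The best placement is reported
#' `unique` only when the second-best has at least 2 more counted
#' mismatches; a smaller gap gives `ambiguous`; no placement within
#' `max_mismatches` gives `unmapped`.
#'
#' @param reads Data.frame with `read_id`, `sequence` (length >= 20).
#' @param index Converted indices from [build_converted_indices()].
#' @param max_mismatches Maximum counted mismatches for a reported hit.
#' @return Data.frame: `read_id`, `status` (`unique`/`ambiguous`/`unmapped`),
#'   `fragment_id`, `chrom`, `genome_start` (0-based), `offset`,
#'   `strand_mode` (`OT`/`OB`), `counted_mismatches`,
#'   `second_best_mismatches`, plus the read `sequence` carried along for
#'   methylation calling.
#' @export
align_reads <- function(reads, index, max_mismatches = 2L) {
  frags <- index$fragments
  res <- .cpp_align_reads(reads$sequence, frags$sequence,
                          as.integer(max_mismatches))
  status <- c("unique", "ambiguous", "unmapped")[res$status + 1L]
  out <- data.frame(
    read_id = reads$read_id,
    status = status,
    fragment_id = frags$fragment_id[res$fragment],
    chrom = frags$chrom[res$fragment],
    genome_start = frags$start[res$fragment] + res$offset,
    offset = res$offset,
    strand_mode = c("OT", "OB")[res$strand_mode + 1L],
    counted_mismatches = res$counted_mismatches,
    second_best_mismatches = res$second_best_mismatches,
    sequence = reads$sequence,
    stringsAsFactors = FALSE)
  tab <- table(factor(status, levels = c("unique", "ambiguous", "unmapped")))
  rrbs_log("info", sprintf("align: %d unique, %d ambiguous, %d unmapped",
                           tab[["unique"]], tab[["ambiguous"]],
                           tab[["unmapped"]]))
  out
}

#' Fraction of reads realigning to their simulated origin
#'
#' Compares alignments against the simulator truth table, adjusting the
#' expected fragment offset for 3' trimming: an OB read sequenced from the
#' fragment 3' end loses its leftmost fragment positions when its 3' tail is
#' trimmed, so the expected offset grows by the number of trimmed bases.
#' Reads absent from the alignment table are ignored.
#'
#' @param alignments Output of [align_reads()].
#' @param truth Truth table from [simulate_reads()].
#' @return List: `n`, `n_correct`, `accuracy` (fraction of aligned reads
#'   reported `unique` at the trim-adjusted true origin).
#' @export
roundtrip_accuracy <- function(alignments, truth) {
  tru <- truth[match(alignments$read_id, truth$read_id), , drop = FALSE]
  if (anyNA(tru$fragment_id)) stopf("alignments contain unknown read ids")
  trimmed <- tru$read_length - nchar(alignments$sequence)
  expected_off <- tru$offset + ifelse(tru$strand_mode == "OB", trimmed, 0L)
  ok <- alignments$status == "unique" &
    alignments$fragment_id == tru$fragment_id &
    alignments$offset == expected_off &
    alignments$strand_mode == tru$strand_mode
  list(n = nrow(alignments), n_correct = sum(ok), accuracy = mean(ok))
}

#' Write an alignment table as TSV
#'
#' @param alignments Output of [align_reads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  cols <- c("read_id", "status", "fragment_id", "chrom", "genome_start",
            "strand_mode", "counted_mismatches")
  write.table(alignments[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write unique alignments as SAM
#'
#' Emits minimal single-end records: flag 0 for OT and 16 for OB (the
#' sequenced strand maps to the reverse complement in fragment space), with
#' custom tags `XS` (strand mode) and `XM` (counted mismatches). Positions
#' are 1-based genome coordinates.
#'
#' @param alignments Output of [align_reads()].
#' @param genome Named character vector (for header lengths).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     genome_lengths(genome)), con)
  a <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(a)) {
    seqs <- ifelse(a$strand_mode == "OB", revcomp(a$sequence), a$sequence)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXS:A:%s\tXM:i:%d",
                       a$read_id, ifelse(a$strand_mode == "OB", 16L, 0L),
                       a$chrom, a$genome_start + 1L, nchar(a$sequence),
                       seqs, substr(a$strand_mode, 2, 2),
                       a$counted_mismatches), con)
  }
  invisible(path)
}
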