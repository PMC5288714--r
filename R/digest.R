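#' Restriction enzyme specification
#'
#' @param name Enzyme name.
#' @param recognition Recognition site over `{A,C,G,T}`.
#' @param cut_offset Bases 5' of the cut within the site (0..site length).
#' @return A list of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition))
    stopf("recognition site must be over {A,C,G,T}")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stopf("cut_offset must lie within the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme_spec")
}

#' Built-in enzymes for reduced-representation digestion
#'
#' MspI (C^CGG) and TaqI (T^CGA); both sites are palindromic so a
#' forward-strand scan covers both strands.
#'
#' @return A list of `enzyme_spec` objects.
#' @export
rrbs_enzymes <- function() {
  list(mspI = enzyme_spec("MspI", "CCGG", 1L),
       taqI = enzyme_spec("TaqI", "TCGA", 1L))
}

#' In-silico double digestion into the reduced-representation fragment set
#'
#' Cuts at every recognition site of every enzyme (union of cut positions;
#' complete digestion is order-independent) and keeps the maximal runs
#' between consecutive cuts whose length falls within the size-selection
#' window. Recognition sites containing `N` in the genome never match.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param enzymes List of [enzyme_spec()] objects (default MspI + TaqI).
#' @param min_len,max_len Size-selection window in bp (defaults 40 and 350).
#' @return A data.frame with columns `fragment_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `sequence`, ordered by (chrom, start).
#' @export
digest_genome <- function(genome, enzymes = rrbs_enzymes(),
                          min_len = 40L, max_len = 350L) {
  validate_genome(genome)
  if (length(enzymes) == 0) stopf("at least one enzyme required")
  if (min_len < 1L || max_len < min_len) stopf("invalid size-selection window")
  res <- vector("list", length(genome))
  n_dropped <- 0L
  for (ci in seq_along(genome)) {
    seq <- genome[[ci]]
    L <- nchar(seq)
    cuts <- integer(0)
    for (e in enzymes) {
      hits <- gregexpr(e$recognition, seq, fixed = TRUE)[[1]]
      if (hits[1] != -1L) cuts <- c(cuts, hits - 1L + e$cut_offset)
    }
    cuts <- sort(unique(c(0L, cuts, L)))
    start <- cuts[-length(cuts)]
    end <- cuts[-1]
    len <- end - start
    ok <- len >= min_len & len <= max_len & len > 0L
    n_dropped <- n_dropped + sum(!ok & len > 0L)
    if (!any(ok)) next
    res[[ci]] <- data.frame(chrom = names(genome)[ci],
                            start = start[ok], end = end[ok],
                            length = len[ok],
                            sequence = substring(seq, start[ok] + 1L, end[ok]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, names(genome)), out$start), , drop = FALSE]
  out <- cbind(fragment_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  rrbs_log("info", sprintf(
    "digest: %d fragments retained in [%d, %d] bp, %d outside window dropped",
    nrow(out), min_len, max_len, n_dropped))
  out
}

#' Build the two bisulfite-converted fragment indices
#'
#' One index has all C converted to T (original-top strand space), the other
#' all G converted to A (original-bottom strand space). `N` is preserved.
#' Original sequences are retained for bisulfite-aware mismatch re-counting.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @return A list with elements `c_to_t`, `g_to_a` (named character vectors
#'   keyed by fragment id) and `fragments` (the input table).
#' @export
build_converted_indices <- function(fragments) {
  if (nrow(fragments) == 0) stopf("no fragments to index")
  ids <- as.character(fragments$fragment_id)
  list(c_to_t = setNames(chartr("C", "T", fragments$sequence), ids),
       g_to_a = setNames(chartr("G", "A", fragments$sequence), ids),
       fragments = fragments)
}

#' Write the fragment table as TSV
#'
#' Coordinates remain 0-based half-open and are documented in a leading
#' `#` header line.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# fragment_id\tchrom\tstart\tend\tlength",
                   "(0-based, half-open)"), con)
  write.table(fragments[, c("fragment_id", "chrom", "start", "end", "length")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED3 (0-based half-open)
#'
#' @param intervals Data.frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  write.table(intervals[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
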