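#' Read a reference genome from FASTA
#'
#' Sequences are case-folded to upper case; any character outside
#' `{A,C,G,T,N}` is replaced by `N`. Multi-record and wrapped files (and
#' gzipped input) are handled by [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A genome: named character vector of upper-case sequences, one
#'   element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  validate_genome(seqs)
}

#' Validate a genome object
#'
#' @param genome Named character vector of chromosome sequences.
#' @return The genome, invisibly checked.
#' @export
validate_genome <- function(genome) {
  if (length(genome) == 0) stopf("empty genome")
  if (is.null(names(genome)) || anyDuplicated(names(genome)) ||
      any(!nzchar(names(genome))))
    stopf("chromosome names must be unique and non-empty")
  if (any(nchar(genome) == 0)) stopf("empty chromosome sequence")
  genome
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @return Named integer vector of base counts.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}
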