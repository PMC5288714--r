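#' Classify the sequence context of a cytosine
#'
#' The context (CpG, CHG or CHH, with H = A, C or T) is read from the two
#' bases downstream of the cytosine on its own strand: positions `pos + 1`,
#' `pos + 2` on the plus strand, and the complements of `pos - 1`, `pos - 2`
#' on the minus strand. Contexts that run off the chromosome or contain `N`
#' are `"undefined"`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s); the base there must be a cytosine on the
#'   requested strand (C on `+`, G on `-`).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Character vector in `{"CpG","CHG","CHH","undefined"}`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  lens <- genome_lengths(genome)
  out <- character(n)
  for (s in c("+", "-")) {
    idx <- which(strand == s)
    if (!length(idx)) next
    ch <- chrom[idx]; p <- pos[idx]
    base <- substring(genome[ch], p + 1L, p + 1L)
    want <- if (s == "+") "C" else "G"
    if (any(base != want))
      stopf("position is not a cytosine on the %s strand", s)
    if (s == "+") {
      b1 <- substring(genome[ch], p + 2L, p + 2L)
      b2 <- substring(genome[ch], p + 3L, p + 3L)
      off <- p + 2L > lens[ch]
      off2 <- p + 3L > lens[ch]
    } else {
      b1 <- chartr("ACGT", "TGCA", substring(genome[ch], p, p))
      b2 <- chartr("ACGT", "TGCA", substring(genome[ch], p - 1L, p - 1L))
      off <- p - 1L < 0L
      off2 <- p - 2L < 0L
    }
    ctx <- rep("undefined", length(idx))
    def1 <- !off & b1 %in% c("A", "C", "G", "T")
    cpg <- def1 & b1 == "G"
    ctx[cpg] <- "CpG"
    h1 <- def1 & b1 != "G"
    def2 <- h1 & !off2 & b2 %in% c("A", "C", "G", "T")
    ctx[def2 & b2 == "G"] <- "CHG"
    ctx[def2 & b2 != "G"] <- "CHH"
    out[idx] <- ctx
  }
  out
}

#' Detect CpG islands by sliding-window GC and observed/expected CpG
#'
#' Classic composition criteria: windows of `min_len` bp (1-bp step) qualify
#' when GC fraction is at least `min_gc` and the observed/expected CpG ratio
#' `n_CpG * L / (n_C * n_G)` is at least `min_oe`; overlapping qualifying
#' windows are merged into maximal islands.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param min_len Window (and minimum island) length in bp, default 200.
#' @param min_gc Minimum GC fraction, default 0.5.
#' @param min_oe Minimum observed/expected CpG ratio, default 0.6.
#' @return Data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `label = "CGI"`.
#' @export
detect_cpg_islands <- function(genome, min_len = 200L, min_gc = 0.5,
                               min_oe = 0.6) {
  if (min_gc <= 0 || min_gc > 1 || min_oe <= 0) stopf("invalid thresholds")
  res <- list()
  for (ci in seq_along(genome)) {
    seq <- genome[[ci]]
    L <- nchar(seq)
    if (L < min_len) next
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    isC <- b == "C"; isG <- b == "G"
    cpg <- isC & c(isG[-1], FALSE)
    cumC <- cumsum(isC); cumG <- cumsum(isG); cumCpG <- cumsum(cpg)
    w <- min_len
    starts <- seq_len(L - w + 1L)           # 1-based window starts
    nC <- cumC[starts + w - 1L] - c(0, cumC)[starts]
    nG <- cumG[starts + w - 1L] - c(0, cumG)[starts]
    # a CpG dinucleotide counts if it starts inside the window
    nCpG <- cumCpG[starts + w - 2L] - c(0, cumCpG)[starts]
    gc <- (nC + nG) / w
    oe <- ifelse(nC > 0 & nG > 0, nCpG * w / (nC * nG), 0)
    ok <- gc >= min_gc & oe >= min_oe
    if (!any(ok)) next
    r <- rle(ok)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    runs <- which(r$values)
    res[[length(res) + 1L]] <- data.frame(
      chrom = names(genome)[ci],
      start = starts_r[runs] - 1L,
      end = ends_r[runs] - 1L + w,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  out$label <- rep("CGI", nrow(out))
  rownames(out) <- NULL
  out
}
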