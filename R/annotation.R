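#' Construct a gene-models object
#'
#' @param genes Data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open gene span), `tss` (0-based; span start on `+`,
#'   span end - 1 on `-`). A missing `tss` column is derived.
#' @param exons Data.frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open, non-overlapping within a gene).
#' @return A list of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  ord <- order(exons$gene_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  ov <- unlist(lapply(split(seq_len(nrow(exons)), exons$gene_id), function(i)
    if (length(i) > 1) exons$start[i][-1] < exons$end[i][-length(i)] else
      logical(0)))
  if (any(ov)) stopf("overlapping exons within a gene")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from BED12 or GTF
#'
#' BED12 blocks become exons; GTF requires `exon` features carrying a
#' `gene_id` attribute. All coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
      else "bed12"
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(gene_id = gr$name,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    blocks <- gr$blocks
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(gene_id = gr$name[i], chrom = genes$chrom[i],
                 start = genes$start[i] + IRanges::start(b) - 1L,
                 end = genes$start[i] + IRanges::end(b),
                 stringsAsFactors = FALSE)
    }))
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (!length(ex)) stopf("no exon features in %s", path)
    exons <- data.frame(gene_id = ex$gene_id,
                        chrom = as.character(GenomicRanges::seqnames(ex)),
                        start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex),
                        stringsAsFactors = FALSE)
    genes <- do.call(rbind, lapply(split(seq_len(nrow(exons)),
                                         exons$gene_id), function(i)
      data.frame(gene_id = exons$gene_id[i[1]], chrom = exons$chrom[i[1]],
                 strand = as.character(GenomicRanges::strand(ex[i[1]])),
                 start = min(exons$start[i]), end = max(exons$end[i]),
                 stringsAsFactors = FALSE)))
    rownames(genes) <- NULL
  }
  if (any(!genes$strand %in% c("+", "-")))
    stopf("gene models must be stranded")
  gene_models(genes, exons)
}

#' Write gene models as BED12
#'
#' @param gm A [gene_models()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models_bed12 <- function(gm, path) {
  g <- gm$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- gm$exons[gm$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom[i], g$start[i], g$end[i], g$gene_id[i], g$strand[i],
            g$start[i], g$end[i], nrow(e),
            paste0(e$end - e$start, collapse = ","),
            paste0(e$start - g$start[i], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.promoter_windows <- function(gm, flank) {
  data.frame(chrom = gm$genes$chrom,
             start = pmax(0L, gm$genes$tss - flank),
             end = gm$genes$tss + flank + 1L,
             gene_id = gm$genes$gene_id,
             stringsAsFactors = FALSE)
}

.overlaps_any <- function(intervals, targets) {
  if (is.null(targets) || nrow(targets) == 0)
    return(logical(nrow(intervals)))
  q <- .to_granges(intervals)
  s <- .to_granges(targets)
  IRanges::overlapsAny(q, s)
}

#' Assign genomic intervals to promoter/exon/intron/intergenic
#'
#' Any-overlap tests with precedence promoter > exon > intron; promoter
#' windows span +/- `promoter_flank` around the strand-aware TSS (inclusive
#' of the TSS base); intron means overlapping a gene span but no exon.
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param gm A [gene_models()] object.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @return Character vector in
#'   `{"promoter","exon","intron","intergenic"}`.
#' @export
assign_category <- function(intervals, gm, promoter_flank = 1000L) {
  out <- rep("intergenic", nrow(intervals))
  in_span <- .overlaps_any(intervals, gm$genes)
  out[in_span] <- "intron"
  out[.overlaps_any(intervals, gm$exons)] <- "exon"
  out[.overlaps_any(intervals, .promoter_windows(gm, promoter_flank))] <-
    "promoter"
  out
}

#' Category distribution of DMRs (promoter / genic / intergenic)
#'
#' Exon and intron assignments collapse into "genic". Fractions are reported
#' over all DMRs and separately for hyper- and hypomethylated subsets when a
#' `direction` column is present.
#'
#' @param dmrs Data.frame of regions (`chrom`, `start`, `end`, optionally
#'   `direction`).
#' @param gm A [gene_models()] object.
#' @param promoter_flank Promoter half-width in bp.
#' @return List with `counts`, `fractions` (named over promoter/genic/
#'   intergenic) and `by_direction` (same shape per direction).
#' @export
category_distribution <- function(dmrs, gm, promoter_flank = 1000L) {
  if (nrow(dmrs) == 0) stopf("no DMRs to classify")
  cat4 <- assign_category(dmrs, gm, promoter_flank)
  cat3 <- ifelse(cat4 %in% c("exon", "intron"), "genic", cat4)
  lv <- c("promoter", "genic", "intergenic")
  tab <- function(x) {
    cnt <- table(factor(x, levels = lv))
    list(counts = as.integer(cnt), fractions = as.numeric(cnt) / sum(cnt))
  }
  all <- tab(cat3)
  names(all$counts) <- names(all$fractions) <- lv
  by_dir <- NULL
  if (!is.null(dmrs$direction)) {
    by_dir <- lapply(split(cat3, dmrs$direction), function(x) {
      t <- tab(x)
      names(t$counts) <- names(t$fractions) <- lv
      t
    })
  }
  list(counts = all$counts, fractions = all$fractions,
       by_direction = by_dir)
}

#' Map DMRs to genes by promoter-window or gene-span overlap
#'
#' A DMR associates with every gene whose promoter window or span it
#' overlaps; intergenic DMRs get no association.
#'
#' @param dmrs Data.frame of regions (`chrom`, `start`, `end`).
#' @param gm A [gene_models()] object.
#' @param promoter_flank Promoter half-width in bp.
#' @return Data.frame: `dmr` (row index into `dmrs`), `gene_id`, `where`
#'   (`promoter` or `body`).
#' @export
map_dmrs_to_genes <- function(dmrs, gm, promoter_flank = 1000L) {
  if (nrow(dmrs) == 0)
    return(data.frame(dmr = integer(0), gene_id = character(0),
                      where = character(0)))
  q <- .to_granges(dmrs)
  hit <- function(targets, label) {
    s <- .to_granges(targets)
    ov <- GenomicRanges::findOverlaps(q, s)
    data.frame(dmr = S4Vectors::queryHits(ov),
               gene_id = targets$gene_id[S4Vectors::subjectHits(ov)],
               where = rep(label, length(ov)), stringsAsFactors = FALSE)
  }
  out <- rbind(hit(.promoter_windows(gm, promoter_flank), "promoter"),
               hit(gm$genes, "body"))
  out <- out[!duplicated(out[, c("dmr", "gene_id")]), , drop = FALSE]
  out <- out[order(out$dmr, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-list overlap with a hypergeometric enrichment p-value
#'
#' @param query_genes Character vector (e.g. DMR-associated genes).
#' @param reference_genes Character vector (e.g. differentially expressed
#'   genes).
#' @param universe_size Size of the gene universe; must be at least
#'   `|query U reference|`.
#' @return List: `n_query`, `n_reference`, `n_overlap`, `fraction`
#'   (of query), `universe_size`, `p` (upper tail, P(X >= n_overlap)).
#' @export
overlap_stats <- function(query_genes, reference_genes, universe_size) {
  q <- unique(query_genes); r <- unique(reference_genes)
  if (universe_size < length(union(q, r)))
    stopf("universe smaller than the union of the gene sets")
  k <- length(intersect(q, r))
  p <- phyper(k - 1, length(r), universe_size - length(r), length(q),
              lower.tail = FALSE)
  list(n_query = length(q), n_reference = length(r), n_overlap = k,
       fraction = if (length(q)) k / length(q) else NA_real_,
       universe_size = universe_size, p = p)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path Input path.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
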