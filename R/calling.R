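#' Call per-cytosine methylation from unique alignments
#'
#' OT reads inform plus-strand cytosines (read base C = methylated,
#' T = unmethylated); OB reads inform minus-strand cytosines at reference G
#' positions (G = methylated, A = unmethylated after reverse complementing).
#' Other read bases at a cytosine (sequencing errors) are ignored. The level
#' is meth / (meth + unmeth); sites with fewer than `min_coverage`
#' informative reads are removed. Sites whose context is undefined (N or
#' chromosome edge) are excluded.
#'
#' @param alignments Output of [align_reads()]; only `unique` records are
#'   used.
#' @param fragments Fragment table the alignments refer to.
#' @param genome Named character vector of chromosome sequences.
#' @param min_coverage Minimum informative reads per retained site
#'   (default 5).
#' @param sample_id Sample label stored on the result.
#' @param merge_cpg If `TRUE`, combine the two strand-specific cytosines of
#'   each symmetric CpG dyad into one plus-strand record before filtering.
#' @return A `sample_methylome`: data.frame with `chrom`, `pos` (0-based),
#'   `strand`, `context`, `meth_count`, `unmeth_count`, `level`, ordered by
#'   position, with attributes `sample_id` and `n_observations` (informative
#'   read observations before the coverage filter).
#' @export
call_sites <- function(alignments, fragments, genome, min_coverage = 5L,
                       sample_id = "sample", merge_cpg = FALSE) {
  a <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(a) && !all(a$fragment_id %in% fragments$fragment_id))
    stopf("alignment references an unknown fragment")
  fidx <- match(a$fragment_id, fragments$fragment_id)
  cpos <- gregexpr("C", fragments$sequence, fixed = TRUE)
  gpos <- gregexpr("G", fragments$sequence, fixed = TRUE)
  grab <- function(h) lapply(h, function(x) if (x[1] == -1L) integer(0)
                             else as.integer(x) - 1L)
  tal <- .cpp_call_sites(fidx, a$offset,
                         as.integer(a$strand_mode == "OB"), a$sequence,
                         grab(cpos), grab(gpos))
  n_obs <- sum(tal$meth + tal$unmeth)
  out <- data.frame(
    chrom = fragments$chrom[tal$fragment],
    pos = fragments$start[tal$fragment] + tal$pos,
    strand = c("+", "-")[tal$strand + 1L],
    meth_count = tal$meth, unmeth_count = tal$unmeth,
    stringsAsFactors = FALSE)
  out$context <- classify_context(genome, out$chrom, out$pos, out$strand)
  out <- out[out$context != "undefined", , drop = FALSE]
  if (merge_cpg) {
    minus_cpg <- out$context == "CpG" & out$strand == "-"
    out$pos[minus_cpg] <- out$pos[minus_cpg] - 1L
    out$strand[out$context == "CpG"] <- "+"
    key <- paste(out$chrom, out$pos, out$strand)
    agg <- rowsum(cbind(out$meth_count, out$unmeth_count), key)
    base <- out[!duplicated(key), , drop = FALSE]
    m <- match(key[!duplicated(key)], rownames(agg))
    base$meth_count <- agg[m, 1]
    base$unmeth_count <- agg[m, 2]
    out <- base
  }
  keep <- (out$meth_count + out$unmeth_count) >= min_coverage
  rrbs_log("info", sprintf(
    "call: %d sites observed, %d retained at >=%d reads", nrow(out),
    sum(keep), min_coverage))
  out <- out[keep, , drop = FALSE]
  out$level <- out$meth_count / (out$meth_count + out$unmeth_count)
  out <- out[order(match(out$chrom, names(genome)), out$pos, out$strand),
             c("chrom", "pos", "strand", "context", "meth_count",
               "unmeth_count", "level")]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  attr(out, "n_observations") <- n_obs
  class(out) <- c("sample_methylome", "data.frame")
  out
}

#' @export
print.sample_methylome <- function(x, ...) {
  cat(sprintf("sample_methylome '%s': %d sites (%s)\n",
              attr(x, "sample_id"), nrow(x),
              paste(names(table(x$context)), table(x$context),
                    sep = "=", collapse = ", ")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

.site_key <- function(m) paste(m$chrom, m$pos, m$strand)

#' Estimate the bisulfite conversion rate from non-CpG cytosines
#'
#' Assuming near-zero true methylation outside CpG context, the fraction of
#' unmethylated calls at non-CpG cytosines estimates the conversion rate:
#' rate = sum(unmeth) / sum(meth + unmeth), with a Wilson 95% CI.
#'
#' @param methylome A `sample_methylome`.
#' @param contexts Contexts used (default CHH).
#' @param min_informative Minimum read observations for a defined estimate.
#' @return List with `rate`, `n_informative`, `ci_low`, `ci_high`,
#'   `defined`, `warn_all_methylated`.
#' @export
estimate_conversion_rate <- function(methylome, contexts = "CHH",
                                     min_informative = 100L) {
  m <- methylome[methylome$context %in% contexts, , drop = FALSE]
  n <- sum(m$meth_count + m$unmeth_count)
  if (n < min_informative) {
    rrbs_log("warn", sprintf(
      "conversion estimate undefined: %d informative observations (< %d)",
      n, min_informative))
    return(list(rate = NA_real_, n_informative = n, ci_low = NA_real_,
                ci_high = NA_real_, defined = FALSE,
                warn_all_methylated = FALSE))
  }
  x <- sum(m$unmeth_count)
  rate <- x / n
  z <- qnorm(0.975)
  centre <- (rate + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(rate * (1 - rate) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  warn <- rate == 0
  if (warn) rrbs_log("warn", "all non-CpG observations methylated; conversion rate 0")
  list(rate = rate, n_informative = n,
       ci_low = max(0, centre - half), ci_high = min(1, centre + half),
       defined = TRUE, warn_all_methylated = warn)
}

#' Pearson correlation of methylation levels between two samples
#'
#' @param a,b `sample_methylome` objects on the same reference.
#' @param context Context of compared sites (default CpG).
#' @return List with `r`, `n_shared`, `defined`.
#' @export
methylation_correlation <- function(a, b, context = "CpG") {
  a <- a[a$context == context, , drop = FALSE]
  b <- b[b$context == context, , drop = FALSE]
  i <- match(.site_key(a), .site_key(b))
  la <- a$level[!is.na(i)]
  lb <- b$level[i[!is.na(i)]]
  if (length(la) < 2 || var(la) == 0 || var(lb) == 0) {
    rrbs_log("warn", "correlation undefined: <2 shared sites or zero variance")
    return(list(r = NA_real_, n_shared = length(la), defined = FALSE))
  }
  list(r = cor(la, lb), n_shared = length(la), defined = TRUE)
}

#' Per-chromosome mean methylation and treated/control fold change
#'
#' @param methylomes Named list of `sample_methylome` objects.
#' @param conditions Named character vector: sample id -> condition.
#' @param treated,control Condition labels.
#' @param context Context of profiled sites.
#' @return Data.frame: one row per chromosome with per-sample mean levels
#'   and `fold_change` = treated mean / control mean (replicate-averaged).
#' @export
chromosome_profile <- function(methylomes, conditions, treated = "T",
                               control = "NT", context = "CpG") {
  stopifnot(!is.null(names(methylomes)))
  chroms <- unique(unlist(lapply(methylomes, function(m) unique(m$chrom))))
  means <- sapply(methylomes, function(m) {
    m <- m[m$context == context, , drop = FALSE]
    v <- tapply(m$level, factor(m$chrom, levels = chroms), mean)
    as.numeric(v)
  })
  means <- matrix(means, nrow = length(chroms),
                  dimnames = list(chroms, names(methylomes)))
  empty <- apply(means, 1, function(r) all(is.na(r)))
  if (any(empty)) {
    rrbs_log("warn", sprintf("chromosomes with no retained sites omitted: %s",
                             paste(chroms[empty], collapse = ", ")))
    means <- means[!empty, , drop = FALSE]
  }
  t_cols <- names(conditions)[conditions == treated]
  c_cols <- names(conditions)[conditions == control]
  fc <- rowMeans(means[, t_cols, drop = FALSE], na.rm = TRUE) /
    rowMeans(means[, c_cols, drop = FALSE], na.rm = TRUE)
  out <- data.frame(chrom = rownames(means), means, fold_change = fc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean methylation level per feature class
#'
#' Classes are promoter (+/- `promoter_flank` around the TSS), CGI, exon and
#' intron; a site may contribute to several classes. Empty classes are
#' omitted with a warning.
#'
#' @param methylome A `sample_methylome`.
#' @param gene_models A [gene_models()] object, or `NULL`.
#' @param islands CGI intervals (data.frame `chrom`,`start`,`end`), or `NULL`.
#' @param promoter_flank Promoter half-width in bp.
#' @param context Context of averaged sites.
#' @return Data.frame with `feature`, `mean_level`, `n_sites`.
#' @export
feature_average <- function(methylome, gene_models = NULL, islands = NULL,
                            promoter_flank = 1000L, context = "CpG") {
  m <- methylome[methylome$context == context, , drop = FALSE]
  classes <- list()
  if (!is.null(islands) && nrow(islands))
    classes$CGI <- islands[, c("chrom", "start", "end")]
  if (!is.null(gene_models)) {
    g <- gene_models$genes
    classes$promoter <- data.frame(chrom = g$chrom,
                                   start = pmax(0L, g$tss - promoter_flank),
                                   end = g$tss + promoter_flank + 1L)
    classes$exon <- gene_models$exons[, c("chrom", "start", "end")]
    ex <- GenomicRanges::reduce(.to_granges(gene_models$exons))
    sp <- .to_granges(g)
    introns <- GenomicRanges::setdiff(sp, ex)
    classes$intron <- .from_granges(introns)
  }
  res <- lapply(names(classes), function(cl) {
    inside <- .in_intervals(m$chrom, m$pos, classes[[cl]])
    if (!any(inside)) {
      rrbs_log("warn", sprintf("feature class '%s' has no sites; omitted", cl))
      return(NULL)
    }
    data.frame(feature = cl, mean_level = mean(m$level[inside]),
               n_sites = sum(inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(feature = character(0),
                                      mean_level = numeric(0),
                                      n_sites = integer(0))
  rownames(out) <- NULL
  out
}

.to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write the per-cytosine report (1-based positions) as TSV
#'
#' @param methylome A `sample_methylome`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cytosine_report <- function(methylome, path) {
  out <- as.data.frame(methylome)
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write bedGraph level tracks, one file per context
#'
#' @param methylome A `sample_methylome`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_bedgraph <- function(methylome, dir = ".", prefix = "sample") {
  paths <- character(0)
  for (ctx in unique(methylome$context)) {
    m <- methylome[methylome$context == ctx, , drop = FALSE]
    p <- file.path(dir, sprintf("%s.%s.bedGraph", prefix, ctx))
    con <- file(p, "w")
    writeLines(sprintf('track type=bedGraph name="%s %s"', prefix, ctx), con)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", m$chrom, m$pos, m$pos + 1L,
                       m$level), con)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Sample-level QC summary
#'
#' Reports the estimated bisulfite conversion rate and the mean coverage of
#' retained CpG sites, with pass flags at the conventional QC bounds
#' (conversion >= 98%, coverage >= 6x).
#'
#' @param methylome A `sample_methylome`.
#' @param min_conversion,min_coverage QC bounds.
#' @return List with `conversion`, `mean_cpg_coverage`, `pass`.
#' @export
qc_summary <- function(methylome, min_conversion = 0.98, min_coverage = 6) {
  conv <- estimate_conversion_rate(methylome)
  cpg <- methylome[methylome$context == "CpG", , drop = FALSE]
  cov <- mean(cpg$meth_count + cpg$unmeth_count)
  list(conversion = conv,
       mean_cpg_coverage = cov,
       pass = isTRUE(conv$rate >= min_conversion) && isTRUE(cov >= min_coverage))
}
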