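#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric point probabilities, with all
#' margins fixed, over every table whose point probability does not exceed
#' that of the observed table (relative tolerance 1e-7 for floating-point
#' ties). A table with a zero margin carries no information and returns 1.
#'
#' @param a,b Methylated/unmethylated counts in group A (or a 2x2 matrix as
#'   `a`, rows = groups, columns = meth/unmeth).
#' @param c,d Methylated/unmethylated counts in group B.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  fisher_p_vec(a, b, c, d)[1]
}

#' Vectorized two-sided Fisher p-values for 2x2 tables
#'
#' @param a,b,c,d Integer vectors of cell counts (rows = groups,
#'   columns = meth/unmeth).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (any(c(a[i], b[i], c[i], d[i]) < 0)) stopf("negative cell count")
    if (m1 == 0 || m2 == 0 || k == 0 || b[i] + d[i] == 0) { p[i] <- 1; next }
    lo <- max(0L, k - m2); hi <- min(k, m1)
    dens <- dhyper(lo:hi, m1, m2, k)
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of p_(j) * m / j on the sorted p-values, mapped
#' back to the input order and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Per-site differential methylation between two samples
#'
#' At every shared retained site, a 2x2 table of (meth, unmeth) counts gives
#' a two-sided Fisher p; Benjamini-Hochberg q-values are computed across all
#' tested sites of each context. A site is `strong` when
#' |delta| > `strong_threshold` and p < 0.05 and q < `q_threshold`.
#'
#' @param a,b `sample_methylome` objects (deltas are level(b) - level(a)).
#' @param strong_threshold Absolute level change defining strong sites
#'   (default 1/3).
#' @param q_threshold FDR threshold for strong sites (default 0.01).
#' @return Data.frame with site key columns, `level_a`, `level_b`, `delta`,
#'   `p`, `q`, `strong`.
#' @export
site_differential <- function(a, b, strong_threshold = 1/3,
                              q_threshold = 0.01) {
  i <- match(.site_key(a), .site_key(b))
  sa <- a[!is.na(i), , drop = FALSE]
  sb <- b[i[!is.na(i)], , drop = FALSE]
  if (nrow(sa) == 0) stopf("no shared retained sites")
  out <- data.frame(chrom = sa$chrom, pos = sa$pos, strand = sa$strand,
                    context = sa$context,
                    level_a = sa$level, level_b = sb$level,
                    delta = sb$level - sa$level,
                    stringsAsFactors = FALSE)
  out$p <- fisher_p_vec(sa$meth_count, sa$unmeth_count,
                        sb$meth_count, sb$unmeth_count)
  out$q <- NA_real_
  for (ctx in unique(out$context)) {
    sel <- out$context == ctx
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  out$strong <- abs(out$delta) > strong_threshold & out$p < 0.05 &
    out$q < q_threshold
  out
}

#' Windowed DMR detection between two samples
#'
#' The genome is tiled into non-overlapping windows of `window` bp anchored
#' at each chromosome origin; windows with fewer than `min_sites` shared
#' retained sites are discarded. In the default `pooled` mode each window's
#' counts are summed into one 2x2 table per window (Fisher p), with
#' Benjamini-Hochberg correction across all tested windows genome-wide. The
#' `per_site` mode tests each site and corrects within each window
#' separately, requiring the minimum within-window q below `q_threshold` in
#' addition to the pooled p and delta criteria. A window is a DMR when
#' p < `p_threshold`, q < `q_threshold` and |pooled delta| >= `min_delta`.
#'
#' @param a,b `sample_methylome` objects; deltas are b minus a (call with
#'   the control sample as `a` so `hyper` means higher in `b`).
#' @param window Window size in bp (default 200).
#' @param min_sites Minimum shared sites per tested window (default 3).
#' @param min_delta Minimum absolute pooled level change (default 0.25).
#' @param p_threshold,q_threshold Significance thresholds (0.05 and 0.01).
#' @param mode `"pooled"` or `"per_site"`.
#' @param context Context of sites entering windows (default CpG).
#' @return An object of class `dmr_result`: list with `dmrs` (the windows
#'   passing all criteria), `windows` (all tested windows with statistics)
#'   and `params`.
#' @export
detect_dmrs <- function(a, b, window = 200L, min_sites = 3L,
                        min_delta = 0.25, p_threshold = 0.05,
                        q_threshold = 0.01, mode = c("pooled", "per_site"),
                        context = "CpG") {
  mode <- match.arg(mode)
  sa <- a[a$context %in% context, , drop = FALSE]
  sb <- b[b$context %in% context, , drop = FALSE]
  i <- match(.site_key(sa), .site_key(sb))
  sa <- sa[!is.na(i), , drop = FALSE]
  sb <- sb[i[!is.na(i)], , drop = FALSE]
  win <- sa$pos %/% window
  key <- paste(sa$chrom, win)
  cnt <- table(key)
  tested_keys <- names(cnt)[cnt >= min_sites]
  sel <- key %in% tested_keys
  sa <- sa[sel, , drop = FALSE]; sb <- sb[sel, , drop = FALSE]
  key <- key[sel]
  if (!length(key)) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), n_sites = integer(0),
                        meth_a = integer(0), unmeth_a = integer(0),
                        meth_b = integer(0), unmeth_b = integer(0),
                        level_a = numeric(0), level_b = numeric(0),
                        delta = numeric(0), p = numeric(0), q = numeric(0),
                        direction = character(0))
    return(structure(list(dmrs = empty, windows = empty,
                          params = list(window = window, mode = mode)),
                     class = "dmr_result"))
  }
  f <- factor(key, levels = unique(key))
  pooled <- rowsum(cbind(sa$meth_count, sa$unmeth_count,
                         sb$meth_count, sb$unmeth_count),
                   f, reorder = FALSE)
  kk <- strsplit(levels(f), " ", fixed = TRUE)
  wdf <- data.frame(
    chrom = vapply(kk, `[`, "", 1),
    start = as.integer(vapply(kk, `[`, "", 2)) * window,
    stringsAsFactors = FALSE)
  wdf$end <- wdf$start + window
  wdf$n_sites <- as.integer(table(f))
  wdf$meth_a <- pooled[, 1]; wdf$unmeth_a <- pooled[, 2]
  wdf$meth_b <- pooled[, 3]; wdf$unmeth_b <- pooled[, 4]
  wdf$level_a <- wdf$meth_a / (wdf$meth_a + wdf$unmeth_a)
  wdf$level_b <- wdf$meth_b / (wdf$meth_b + wdf$unmeth_b)
  wdf$delta <- wdf$level_b - wdf$level_a
  wdf$p <- fisher_p_vec(wdf$meth_a, wdf$unmeth_a, wdf$meth_b, wdf$unmeth_b)
  if (mode == "pooled") {
    wdf$q <- bh_fdr(wdf$p)
  } else {
    site_p <- fisher_p_vec(sa$meth_count, sa$unmeth_count,
                           sb$meth_count, sb$unmeth_count)
    minq <- vapply(split(site_p, f), function(p) min(bh_fdr(p)), 0)
    wdf$q <- as.numeric(minq)
  }
  wdf$direction <- ifelse(wdf$delta >= 0, "hyper", "hypo")
  wdf <- wdf[order(match(wdf$chrom, unique(wdf$chrom)), wdf$start), ,
             drop = FALSE]
  rownames(wdf) <- NULL
  dmr <- wdf[wdf$p < p_threshold & wdf$q < q_threshold &
               abs(wdf$delta) >= min_delta, , drop = FALSE]
  rownames(dmr) <- NULL
  rrbs_log("info", sprintf("dmr: %d windows tested, %d DMRs (%s mode)",
                           nrow(wdf), nrow(dmr), mode))
  structure(list(dmrs = dmr, windows = wdf,
                 params = list(window = window, min_sites = min_sites,
                               min_delta = min_delta,
                               p_threshold = p_threshold,
                               q_threshold = q_threshold, mode = mode)),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("dmr_result: %d/%d tested %d-bp windows pass (mode %s)\n",
              nrow(x$dmrs), nrow(x$windows), x$params$window, x$params$mode))
  invisible(x)
}

#' Intersect pairwise DMR sets and merge into consensus regions
#'
#' Keeps windows called (same interval, same direction) in every pairwise
#' comparison, then merges book-ended or overlapping kept windows of the
#' same direction into maximal consensus regions.
#'
#' @param dmr_sets List of `dmr_result` objects (or DMR data.frames) from
#'   pairwise comparisons, all on the same window grid.
#' @return Data.frame: `chrom`, `start`, `end`, `direction`, `n_windows`,
#'   `q` (worst member-window q across comparisons), `delta` (mean member
#'   delta across comparisons).
#' @export
intersect_and_merge <- function(dmr_sets) {
  if (!length(dmr_sets)) stopf("at least one comparison required")
  grids <- unique(vapply(dmr_sets, function(d)
    if (inherits(d, "dmr_result")) d$params$window else NA_integer_,
    0L))
  grids <- grids[!is.na(grids)]
  if (length(grids) > 1) stopf("inconsistent window grids")
  window <- if (length(grids)) grids else NA_integer_
  tabs <- lapply(dmr_sets, function(d)
    if (inherits(d, "dmr_result")) d$dmrs else d)
  if (!is.na(window) &&
      any(vapply(tabs, function(t) any(t$start %% window != 0), FALSE)))
    stopf("inconsistent window grids")
  keys <- lapply(tabs, function(t) paste(t$chrom, t$start, t$direction))
  common <- Reduce(intersect, keys)
  if (!length(common))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_windows = integer(0), q = numeric(0),
                      delta = numeric(0)))
  rows <- lapply(seq_along(tabs), function(j)
    tabs[[j]][match(common, keys[[j]]), c("chrom", "start", "end",
                                          "direction", "q", "delta")])
  w <- rows[[1]]
  w$q <- do.call(pmax, lapply(rows, `[[`, "q"))
  w$delta <- rowMeans(do.call(cbind, lapply(rows, `[[`, "delta")))
  w <- w[order(match(w$chrom, unique(w$chrom)), w$start), , drop = FALSE]
  grp <- cumsum(!(c(FALSE, w$chrom[-1] == w$chrom[-nrow(w)] &
                      w$start[-1] <= w$end[-nrow(w)] &
                      w$direction[-1] == w$direction[-nrow(w)])))
  out <- do.call(rbind, lapply(split(w, grp), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               direction = g$direction[1], n_windows = nrow(g),
               q = min(g$q), delta = g$delta[which.max(abs(g$delta))],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "window") <- window
  out
}

#' Per-sample pooled levels of the top-ranked consensus DMRs
#'
#' DMRs are ranked by ascending q, then descending |delta|, then coordinate;
#' matrix entries are the pooled level (sum meth / sum total) of each DMR's
#' sites in each sample.
#'
#' @param consensus Output of [intersect_and_merge()].
#' @param methylomes Named list of `sample_methylome` objects (all samples).
#' @param n Number of top DMRs (default 100).
#' @param context Context of pooled sites.
#' @return Numeric matrix, rows = DMR ids, columns = sample ids.
#' @export
top_dmr_matrix <- function(consensus, methylomes, n = 100L,
                           context = "CpG") {
  if (nrow(consensus) == 0) stopf("no consensus DMRs")
  if (n > nrow(consensus))
    rrbs_log("info", sprintf("only %d consensus DMRs available (n = %d)",
                             nrow(consensus), n))
  ord <- order(consensus$q, -abs(consensus$delta),
               match(consensus$chrom, unique(consensus$chrom)),
               consensus$start)
  top <- consensus[ord[seq_len(min(n, nrow(consensus)))], , drop = FALSE]
  mat <- matrix(NA_real_, nrow(top), length(methylomes),
                dimnames = list(sprintf("%s:%d-%d", top$chrom, top$start,
                                        top$end),
                                names(methylomes)))
  for (j in seq_along(methylomes)) {
    m <- methylomes[[j]]
    m <- m[m$context %in% context, , drop = FALSE]
    for (i in seq_len(nrow(top))) {
      sel <- m$chrom == top$chrom[i] & m$pos >= top$start[i] &
        m$pos < top$end[i]
      tot <- sum(m$meth_count[sel] + m$unmeth_count[sel])
      if (tot > 0) mat[i, j] <- sum(m$meth_count[sel]) / tot
    }
  }
  mat
}

#' Write DMRs as BED6+ TSV
#'
#' Columns: chrom, start, end, name, score = -10*log10(q) capped at 1000,
#' strand ".", then n_sites, level_a, level_b, delta, p, q, direction, mode.
#'
#' @param dmr A `dmr_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dmrs <- function(dmr, path) {
  d <- dmr$dmrs
  score <- ifelse(d$q <= 0, 1000, pmin(1000, round(-10 * log10(d$q), 1)))
  out <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                    name = sprintf("DMR_%04d", seq_len(nrow(d))),
                    score = score, strand = rep(".", nrow(d)),
                    n_sites = d$n_sites, level_a = d$level_a,
                    level_b = d$level_b, delta = d$delta, p = d$p, q = d$q,
                    direction = d$direction,
                    mode = rep(dmr$params$mode, nrow(d)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
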