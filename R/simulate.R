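#' Simulation configuration for a synthetic RRBS study
#'
#' Defaults emulate the statistical structure of a two-condition,
#' two-replicate mammalian RRBS experiment: ~6x CpG coverage, >98% bisulfite
#' conversion, a CpG-island-bearing genome with hypomethylated islands
#' (mean 0.10) over a hypermethylated background (mean 0.75), near-zero
#' non-CpG methylation, and single-end 75 bp directional reads.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param island_count Total CpG islands planted across the genome.
#' @param island_length Island length (bp).
#' @param n_genes Total gene models placed.
#' @param mu_island Mean true CpG methylation inside islands.
#' @param mu_background Mean true CpG methylation outside islands.
#' @param mu_noncpg Mean true CHG/CHH methylation.
#' @param kappa Beta concentration of site baselines.
#' @param replicate_kappa_factor Replicate-level probabilities are redrawn
#'   around the site baseline with concentration `kappa * replicate_kappa_factor`.
#' @param conditions Named integer vector of replicate counts per condition.
#' @param treated,control Condition labels; planted shifts apply to `treated`.
#' @param coverage Mean reads per fragment per strand mode (Poisson).
#' @param read_length Read length (bp).
#' @param conversion_rate Probability an unmethylated C converts to T.
#' @param error_rate Per-base uniform substitution error probability.
#' @param lowq_frac Fraction of reads given a low-quality (Q2) 3' tail.
#' @param lowq_tail Length of the planted low-quality tail (bp).
#' @param base_quality Phred quality of ordinary bases.
#' @param adapter Adapter sequence planted by 3' read-through on fragments
#'   shorter than the read length.
#' @param adapter_readthrough Whether short fragments read into the adapter.
#' @param bg_gc,island_gc GC fraction of background and island sequence.
#' @param bg_cpg_oe Background CpG observed/expected ratio (CpG depletion).
#' @param min_len,max_len Fragment size-selection window (bp).
#' @param dmr_plan Planted-DMR table (`chrom`, `start`, `end`, `delta`,
#'   `scope`), or `NULL` for none.
#' @param seed Master integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 500000L,
                       island_count = 120L, island_length = 600L,
                       n_genes = 60L,
                       mu_island = 0.10, mu_background = 0.75,
                       mu_noncpg = 0.01, kappa = 20,
                       replicate_kappa_factor = 5,
                       conditions = c(NT = 2L, T = 2L),
                       treated = "T", control = "NT",
                       coverage = 6, read_length = 75L,
                       conversion_rate = 0.99, error_rate = 0.001,
                       lowq_frac = 0.05, lowq_tail = 8L,
                       base_quality = 30L,
                       adapter = DEFAULT_ADAPTER,
                       adapter_readthrough = TRUE,
                       bg_gc = 0.40, island_gc = 0.60, bg_cpg_oe = 0.20,
                       min_len = 40L, max_len = 350L,
                       dmr_plan = NULL, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(mu_island, mu_background, mu_noncpg, conversion_rate,
             error_rate, lowq_frac, bg_gc, island_gc)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (coverage <= 0) stopf("coverage must be positive")
  if (!all(c(treated, control) %in% names(conditions)))
    stopf("treated/control labels must name entries of `conditions`")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "RRBS simulation config: %d x %s bp chromosomes, %d islands, %d genes\n",
    x$n_chroms, format(x$chrom_length, big.mark = ","), x$island_count,
    x$n_genes))
  cat(sprintf("  conditions: %s; coverage %gx; %d bp reads; conversion %.3f\n",
              paste(names(x$conditions), x$conditions, sep = "x",
                    collapse = ", "),
              x$coverage, x$read_length, x$conversion_rate))
  cat(sprintf("  planted DMRs: %d; seed %d\n",
              if (is.null(x$dmr_plan)) 0L else nrow(x$dmr_plan), x$seed))
  invisible(x)
}

# sample one chromosome: CpG-depleted background with planted island sequence
.sim_chrom <- function(L, islands_local, cfg) {
  pC <- cfg$bg_gc / 2
  b <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c((1 - cfg$bg_gc) / 2, pC, pC, (1 - cfg$bg_gc) / 2))
  cg <- which(b[-L] == "C" & b[-1] == "G")
  if (length(cg)) {
    drop <- cg[runif(length(cg)) > cfg$bg_cpg_oe]
    if (length(drop))
      b[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
  }
  pCi <- cfg$island_gc / 2
  for (k in seq_len(nrow(islands_local))) {
    s <- islands_local$start[k]; e <- islands_local$end[k]
    b[(s + 1L):e] <- sample(c("A", "C", "G", "T"), e - s, replace = TRUE,
                            prob = c((1 - cfg$island_gc) / 2, pCi, pCi,
                                     (1 - cfg$island_gc) / 2))
  }
  paste0(b, collapse = "")
}

# place n non-overlapping intervals of length w uniformly on [0, L)
.place_intervals <- function(n, w, L, occupied = NULL, tries = 200L) {
  starts <- integer(0)
  occ_s <- if (is.null(occupied)) integer(0) else occupied$start
  occ_e <- if (is.null(occupied)) integer(0) else occupied$end
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(tries)) {
      s <- sample.int(L - w, 1L) - 1L
      if (!any(s < c(occ_e, starts + w) & s + w > c(occ_s, starts))) {
        starts <- c(starts, s); placed <- TRUE; break
      }
    }
    if (!placed) stopf("could not place %d intervals of %d bp in %d bp", n, w, L)
  }
  sort(starts)
}

#' Generate a synthetic genome with CpG islands and gene models
#'
#' The background is CpG-depleted (human-like observed/expected ratio), with
#' `island_count` CpG-dense islands and `n_genes` gene models (2--6 exons)
#' placed uniformly without overlap. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector), `genes`
#'   (a [gene_models()] object) and `islands` (BED-like data.frame).
#' @export
generate_genome <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$island_count,
                              length.out = config$n_chroms + 1L)))
  islands <- list(); seqs <- character(config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    st <- .place_intervals(per_chrom[ci], config$island_length,
                           config$chrom_length)
    isl <- data.frame(chrom = rep(chroms[ci], length(st)), start = st,
                      end = st + config$island_length,
                      stringsAsFactors = FALSE)
    islands[[ci]] <- isl
    seqs[ci] <- .sim_chrom(config$chrom_length, isl, config)
  }
  genome <- setNames(seqs, chroms)
  islands <- do.call(rbind, islands)
  islands$label <- rep("CGI", nrow(islands))

  genes_per <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    spans <- NULL
    for (g in seq_len(genes_per[ci])) {
      gid <- gid + 1L
      ne <- sample(2:6, 1L)
      elen <- sample(100:300, ne, replace = TRUE)
      ilen <- if (ne > 1) sample(200:1000, ne - 1L, replace = TRUE) else integer(0)
      glen <- sum(elen) + sum(ilen)
      st <- .place_intervals(1L, glen, config$chrom_length, occupied = spans)
      spans <- rbind(spans, data.frame(start = st, end = st + glen))
      es <- st + cumsum(c(0L, elen[-ne] + ilen))
      strand <- sample(c("+", "-"), 1L)
      id <- sprintf("gene%04d", gid)
      genes[[gid]] <- data.frame(
        gene_id = id, chrom = chroms[ci], strand = strand,
        start = st, end = st + glen,
        tss = if (strand == "+") st else st + glen - 1L,
        stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                 start = es, end = es + elen,
                                 stringsAsFactors = FALSE)
    }
  }
  gm <- gene_models(do.call(rbind, genes), do.call(rbind, exons))
  list(genome = genome, genes = gm, islands = islands)
}

#' Enumerate reference cytosines within retained fragments
#'
#' Both strands of every fragment are scanned: plus-strand cytosines are C's
#' of the fragment sequence, minus-strand cytosines sit opposite G's. The
#' `coverable` flag marks sites reachable by directional reads of
#' `read_length` (plus strand from the fragment 5' end, minus strand from
#' the 3' end).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param fragments Fragment table from [digest_genome()].
#' @param read_length Read length used for the `coverable` flag.
#' @return Data.frame: `chrom`, `pos` (0-based genome), `strand`, `context`,
#'   `frag` (row index into `fragments`), `pos_in_frag`, `coverable`.
#' @export
sites_from_fragments <- function(genome, fragments, read_length = 75L) {
  cpos <- gregexpr("C", fragments$sequence, fixed = TRUE)
  gpos <- gregexpr("G", fragments$sequence, fixed = TRUE)
  grab <- function(hits) lapply(hits, function(h) if (h[1] == -1L) integer(0)
                                else as.integer(h) - 1L)
  cpos <- grab(cpos); gpos <- grab(gpos)
  nc <- lengths(cpos); ng <- lengths(gpos)
  frag <- c(rep(seq_len(nrow(fragments)), nc),
            rep(seq_len(nrow(fragments)), ng))
  pif <- c(unlist(cpos), unlist(gpos))
  strand <- rep(c("+", "-"), c(sum(nc), sum(ng)))
  chrom <- fragments$chrom[frag]
  pos <- fragments$start[frag] + pif
  ctx <- classify_context(genome, chrom, pos, strand)
  flen <- fragments$length[frag]
  coverable <- ifelse(strand == "+", pif < read_length,
                      pif >= flen - read_length)
  out <- data.frame(chrom = chrom, pos = pos, strand = strand, context = ctx,
                    frag = frag, pos_in_frag = pif, coverable = coverable,
                    stringsAsFactors = FALSE)
  out[order(out$frag, out$pos_in_frag), , drop = FALSE]
}

# membership of positions in a set of intervals (same chrom space)
.in_intervals <- function(chrom, pos, intervals) {
  inside <- logical(length(pos))
  if (is.null(intervals) || nrow(intervals) == 0) return(inside)
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!length(idx)) next
    iv <- iv[order(iv$start), , drop = FALSE]
    j <- findInterval(pos[idx], iv$start)
    inside[idx] <- j >= 1L & pos[idx] < iv$end[pmax(j, 1L)]
  }
  inside
}

.rbeta_mean <- function(n, mu, kappa) {
  out <- numeric(n)
  zero <- mu <= 0; one <- mu >= 1
  mid <- !(zero | one)
  if (any(mid)) out[mid] <- rbeta(sum(mid), mu[mid] * kappa,
                                  (1 - mu[mid]) * kappa)
  out[one] <- 1
  out
}

#' Generate the ground-truth methylome over fragment cytosines
#'
#' Each site draws a baseline level from Beta(mu*kappa, (1-mu)*kappa) with mu
#' set by context and island membership; every replicate then redraws its
#' level around the (condition-shifted) baseline with concentration
#' `kappa * replicate_kappa_factor`. Planted DMRs shift the treated-condition
#' baseline by `delta`, clipped to the unit interval.
#'
#' @param genome,fragments,islands Outputs of [generate_genome()] /
#'   [digest_genome()].
#' @param dmr_plan Planted-DMR table or `NULL` (overrides `config$dmr_plan`).
#' @param config A [sim_config()].
#' @return An object of class `true_methylome`: list with `sites`,
#'   `baseline`, `levels` (site x sample matrix), `samples`, `config`.
#' @export
generate_methylome <- function(genome, fragments, islands, dmr_plan = NULL,
                               config = sim_config()) {
  if (is.null(dmr_plan)) dmr_plan <- config$dmr_plan
  set.seed(stage_seed(config$seed, "methylome"))
  sites <- sites_from_fragments(genome, fragments, config$read_length)
  sites$island <- .in_intervals(sites$chrom, sites$pos, islands)
  mu <- ifelse(sites$context == "CpG",
               ifelse(sites$island, config$mu_island, config$mu_background),
               config$mu_noncpg)
  baseline <- .rbeta_mean(nrow(sites), mu, config$kappa)

  sites$planted <- FALSE
  shift <- numeric(nrow(sites))
  if (!is.null(dmr_plan) && nrow(dmr_plan) > 0) {
    if (is.null(dmr_plan$scope)) dmr_plan$scope <- "CpG"
    for (k in seq_len(nrow(dmr_plan))) {
      hit <- sites$chrom == dmr_plan$chrom[k] &
        sites$pos >= dmr_plan$start[k] & sites$pos < dmr_plan$end[k]
      if (dmr_plan$scope[k] == "CpG") hit <- hit & sites$context == "CpG"
      conflict <- hit & sites$planted & shift != dmr_plan$delta[k]
      if (any(conflict))
        stopf("overlapping planted DMRs with conflicting deltas at %s:%d",
              dmr_plan$chrom[k], dmr_plan$start[k])
      shift[hit] <- dmr_plan$delta[k]
      sites$planted <- sites$planted | hit
      n_cpg <- sum(hit & sites$context == "CpG")
      if (n_cpg < 3L)
        warning(sprintf("planted DMR %s:%d-%d overlaps only %d CpG sites",
                        dmr_plan$chrom[k], dmr_plan$start[k],
                        dmr_plan$end[k], n_cpg))
    }
  }

  samples <- data.frame(
    sample_id = unlist(lapply(names(config$conditions), function(cn)
      sprintf("%s_%d", cn, seq_len(config$conditions[[cn]])))),
    condition = rep(names(config$conditions), config$conditions),
    replicate = unlist(lapply(config$conditions, seq_len)),
    stringsAsFactors = FALSE)

  k2 <- config$kappa * config$replicate_kappa_factor
  levels <- matrix(0, nrow(sites), nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    base <- baseline
    if (samples$condition[j] == config$treated)
      base <- pmin(pmax(base + shift, 0), 1)
    levels[, j] <- .rbeta_mean(nrow(sites), base, k2)
  }
  structure(list(sites = sites, baseline = baseline, levels = levels,
                 samples = samples, config = config),
            class = "true_methylome")
}

#' @export
print.true_methylome <- function(x, ...) {
  cat(sprintf("true_methylome: %d sites x %d samples (%d planted-DMR sites)\n",
              nrow(x$sites), nrow(x$samples), sum(x$sites$planted)))
  invisible(x)
}

#' Plan planted DMRs on covered, grid-aligned windows
#'
#' Selects 200-bp windows (aligned to the chromosome origin) that contain at
#' least `min_cpg` coverable CpG sites; hypermethylation shifts are planted
#' inside CpG islands (low baseline, so `+delta` does not clip) and
#' hypomethylation shifts outside them.
#'
#' @param methylome A [generate_methylome()] object (its sites define
#'   coverage), or a sites table from [sites_from_fragments()].
#' @param islands Island intervals.
#' @param n_hyper,n_hypo Numbers of planted hyper-/hypomethylated regions.
#' @param delta Absolute level shift.
#' @param window Window size in bp.
#' @param min_cpg Minimum coverable CpG sites per chosen window.
#' @return A `dmr_plan` data.frame (`chrom`, `start`, `end`, `delta`, `scope`).
#' @export
plan_dmrs <- function(methylome, islands, n_hyper, n_hypo, delta = 0.5,
                      window = 200L, min_cpg = 3L) {
  sites <- if (inherits(methylome, "true_methylome")) methylome$sites else
    methylome
  s <- sites[sites$context == "CpG" & sites$coverable, , drop = FALSE]
  s$island <- .in_intervals(s$chrom, s$pos, islands)
  win <- paste(s$chrom, s$pos %/% window)
  tab <- table(win, factor(s$island, levels = c(FALSE, TRUE)))
  key <- do.call(rbind, strsplit(rownames(tab), " ", fixed = TRUE))
  wdf <- data.frame(chrom = key[, 1],
                    start = as.integer(key[, 2]) * window,
                    n_isl = as.integer(tab[, "TRUE"]),
                    n_bg = as.integer(tab[, "FALSE"]),
                    stringsAsFactors = FALSE)
  hyper_cand <- wdf[wdf$n_isl >= min_cpg & wdf$n_bg == 0L, , drop = FALSE]
  hypo_cand <- wdf[wdf$n_bg >= min_cpg & wdf$n_isl == 0L, , drop = FALSE]
  if (nrow(hyper_cand) < n_hyper || nrow(hypo_cand) < n_hypo)
    stopf("not enough covered windows to plant %d hyper + %d hypo DMRs (%d/%d available)",
          n_hyper, n_hypo, nrow(hyper_cand), nrow(hypo_cand))
  pick <- function(cand, n) cand[sample.int(nrow(cand), n), , drop = FALSE]
  hy <- pick(hyper_cand, n_hyper); ho <- pick(hypo_cand, n_hypo)
  plan <- rbind(
    data.frame(chrom = hy$chrom, start = hy$start, end = hy$start + window,
               delta = rep(abs(delta), nrow(hy)), stringsAsFactors = FALSE),
    data.frame(chrom = ho$chrom, start = ho$start, end = ho$start + window,
               delta = rep(-abs(delta), nrow(ho)), stringsAsFactors = FALSE))
  plan$scope <- rep("CpG", nrow(plan))
  plan <- plan[order(plan$chrom, plan$start), , drop = FALSE]
  rownames(plan) <- NULL
  plan
}

#' Simulate directional bisulfite reads for one sample
#'
#' For each fragment, Poisson(`coverage`) reads per strand mode (OT from the
#' fragment 5' end, OB from the 3' end as reverse complement). Per cytosine a
#' methylation state is drawn from its true level; unmethylated cytosines
#' convert to T with probability `conversion_rate`; uniform substitution
#' errors are applied afterwards. Every draw is recorded in the truth table.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param methylome A `true_methylome`.
#' @param sample_id One of the methylome's sample ids.
#' @param config Optional [sim_config()] override (defaults to the
#'   methylome's config).
#' @return List with `reads` (`read_id`, `sequence`, `quality`) and `truth`
#'   (`read_id`, `fragment_id`, `strand_mode`, `offset`, `read_length`,
#'   `n_meth_draws`, `n_unmeth_draws`, `truncated`).
#' @export
simulate_reads <- function(fragments, methylome, sample_id, config = NULL) {
  if (is.null(config)) config <- methylome$config
  if (!sample_id %in% methylome$samples$sample_id)
    stopf("unknown sample '%s'", sample_id)
  set.seed(stage_seed(config$seed, paste0("reads:", sample_id)))
  nf <- nrow(fragments)
  s <- methylome$sites
  lev <- methylome$levels[, sample_id]
  fidx <- factor(s$frag, levels = seq_len(nf))
  plus <- s$strand == "+"
  c_pos <- split(s$pos_in_frag[plus], fidx[plus])
  c_lev <- split(lev[plus], fidx[plus])
  g_pos <- split(s$pos_in_frag[!plus], fidx[!plus])
  g_lev <- split(lev[!plus], fidx[!plus])
  raw <- .cpp_simulate_reads(fragments$sequence, c_pos, c_lev, g_pos, g_lev,
                             config$coverage, as.integer(config$read_length),
                             config$conversion_rate, config$error_rate,
                             config$lowq_frac, as.integer(config$lowq_tail),
                             as.integer(config$base_quality),
                             if (config$adapter_readthrough) config$adapter
                             else "",
                             isTRUE(config$adapter_readthrough))
  n <- length(raw$sequence)
  if (any(raw$truncated == 1L))
    rrbs_log("debug", sprintf("%s: %d reads truncated to fragment length",
                              sample_id, sum(raw$truncated == 1L)))
  flen <- fragments$length[raw$fragment]
  rl <- pmin(config$read_length, flen)
  reads <- data.frame(read_id = sprintf("%s_%07d", sample_id, seq_len(n)),
                      sequence = raw$sequence, quality = raw$quality,
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$read_id,
                      fragment_id = fragments$fragment_id[raw$fragment],
                      strand_mode = c("OT", "OB")[raw$strand_mode + 1L],
                      offset = ifelse(raw$strand_mode == 0L, 0L, flen - rl),
                      read_length = rl,
                      n_meth_draws = raw$n_meth_draws,
                      n_unmeth_draws = raw$n_unmeth_draws,
                      truncated = raw$truncated == 1L,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads Data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a (possibly gzipped) FASTQ file.
#' @return Data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(dss)),
             sequence = as.character(dss),
             quality = as.character(S4Vectors::mcols(dss)$qualities),
             stringsAsFactors = FALSE)
}

#' Write simulator truth tables as TSV
#'
#' @param methylome A `true_methylome`.
#' @param truth Read-level truth from [simulate_reads()] (optional).
#' @param dir Output directory.
#' @param sample_id Sample id used in file names for `truth`.
#' @return Invisibly, the written paths.
#' @export
write_truth_tables <- function(methylome, truth = NULL, dir = ".",
                               sample_id = NULL) {
  paths <- character(0)
  sites <- methylome$sites
  long <- do.call(rbind, lapply(methylome$samples$sample_id, function(sm)
    data.frame(sample = sm, chrom = sites$chrom, pos = sites$pos,
               strand = sites$strand, context = sites$context,
               true_level = methylome$levels[, sm], planted = sites$planted,
               stringsAsFactors = FALSE)))
  p <- file.path(dir, "truth_sites.tsv")
  write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(truth)) {
    p <- file.path(dir, sprintf("truth_reads_%s.tsv", sample_id))
    write.table(truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
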