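# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

# a mid-size error-free simulation: genome, fragments, truth, reads,
# alignments and called methylome for one sample
fx_clean_run <- function() {
  if (!is.null(.fx$clean)) return(.fx$clean)
  old <- options(rrbspipe.log_level = "warn")
  on.exit(options(old))
  cfg <- sim_config(n_chroms = 1L, chrom_length = 200000L,
                    island_count = 24L, n_genes = 12L,
                    error_rate = 0, seed = 3L)
  gen <- generate_genome(cfg)
  fragments <- digest_genome(gen$genome, rrbs_enzymes(),
                             cfg$min_len, cfg$max_len)
  methylome <- generate_methylome(gen$genome, fragments, gen$islands,
                                  NULL, cfg)
  sim <- simulate_reads(fragments, methylome, "NT_1", cfg)
  trimmed <- trim_reads(sim$reads, trim_config())
  index <- build_converted_indices(fragments)
  alignments <- align_reads(trimmed, index, max_mismatches = 2L)
  called <- call_sites(alignments, fragments, gen$genome, 5L, "NT_1")
  .fx$clean <- list(cfg = cfg, genome = gen$genome, genes = gen$genes,
                    islands = gen$islands, fragments = fragments,
                    methylome = methylome, reads = sim$reads,
                    truth = sim$truth, trimmed = trimmed, index = index,
                    alignments = alignments, called = called)
  .fx$clean
}

# a four-sample run with planted DMRs at high coverage, plus the four
# pairwise comparisons and the consensus set
fx_planted_run <- function() {
  if (!is.null(.fx$planted)) return(.fx$planted)
  old <- options(rrbspipe.log_level = "warn")
  on.exit(options(old))
  seed <- 11L
  cfg <- sim_config(n_chroms = 2L, chrom_length = 500000L,
                    island_count = 120L, n_genes = 40L,
                    coverage = 30, seed = seed)
  gen <- generate_genome(cfg)
  fragments <- digest_genome(gen$genome, rrbs_enzymes(),
                             cfg$min_len, cfg$max_len)
  sites <- sites_from_fragments(gen$genome, fragments, cfg$read_length)
  set.seed(stage_seed(seed, "plan"))
  plan <- plan_dmrs(sites, gen$islands, 25L, 25L, delta = 0.5)
  methylome <- suppressWarnings(
    generate_methylome(gen$genome, fragments, gen$islands, plan, cfg))
  index <- build_converted_indices(fragments)
  ids <- c("NT_1", "NT_2", "T_1", "T_2")
  methylomes <- lapply(setNames(ids, ids), function(sm) {
    sim <- simulate_reads(fragments, methylome, sm, cfg)
    al <- align_reads(trim_reads(sim$reads), index)
    call_sites(al, fragments, gen$genome, 5L, sm)
  })
  comparisons <- list()
  for (ci in c("NT_1", "NT_2")) for (ti in c("T_1", "T_2"))
    comparisons[[paste(ci, ti, sep = "_vs_")]] <-
      detect_dmrs(methylomes[[ci]], methylomes[[ti]])
  consensus <- intersect_and_merge(comparisons)
  .fx$planted <- list(cfg = cfg, genome = gen$genome, genes = gen$genes,
                      islands = gen$islands, fragments = fragments,
                      plan = plan, methylome = methylome,
                      methylomes = methylomes, comparisons = comparisons,
                      consensus = consensus)
  .fx$planted
}

# hand-rolled two-sided Fisher p by enumeration over binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0L, k - m2):min(k, m1)
  dens <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  min(1, sum(dens[dens <= dens[xs == a] * (1 + 1e-7)]))
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# a minimal sample_methylome from explicit site rows
make_methylome <- function(chrom, pos, strand, context, meth, unmeth,
                           sample_id = "s") {
  out <- data.frame(chrom = chrom, pos = pos, strand = strand,
                    context = context, meth_count = meth,
                    unmeth_count = unmeth,
                    level = meth / (meth + unmeth),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "n_observations") <- sum(meth + unmeth)
  class(out) <- c("sample_methylome", "data.frame")
  out
}

# a single-fragment reference (genome + fragment table) from a raw sequence
make_single_fragment <- function(sequence, chrom = "chr1") {
  genome <- setNames(sequence, chrom)
  fragments <- data.frame(fragment_id = 1L, chrom = chrom, start = 0L,
                          end = nchar(sequence), length = nchar(sequence),
                          sequence = sequence, stringsAsFactors = FALSE)
  list(genome = genome, fragments = fragments)
}

# alignment rows in the shape align_reads() emits
make_alignments <- function(sequences, offsets = 0L, strand_mode = "OT",
                            fragment_id = 1L, status = "unique") {
  n <- length(sequences)
  data.frame(read_id = sprintf("r%03d", seq_len(n)), status = status,
             fragment_id = fragment_id, chrom = "chr1",
             genome_start = offsets, offset = offsets,
             strand_mode = strand_mode, counted_mismatches = 0L,
             second_best_mismatches = NA_integer_, sequence = sequences,
             stringsAsFactors = FALSE)
}
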