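# a 30 bp reference whose position 1 is a CHH cytosine (C,A,T downstream)
.ref <- make_single_fragment("ACATTAGGATTAGGATTAGGATTAGGATTA")

test_that("the level is meth / (meth + unmeth) with the <5-read filter", {
  reads <- c("ACATT", "ACATT", "ACATT", "ATATT", "ATATT")
  m <- call_sites(make_alignments(reads), .ref$fragments, .ref$genome,
                  min_coverage = 5L, sample_id = "s1")
  site <- m[m$pos == 1L, ]
  expect_equal(site$meth_count, 3L)
  expect_equal(site$unmeth_count, 2L)
  expect_equal(site$level, 0.6)
  expect_identical(site$context, "CHH")
  # four covering reads fall below the filter
  m4 <- call_sites(make_alignments(reads[1:4]), .ref$fragments, .ref$genome,
                   min_coverage = 5L)
  expect_equal(nrow(m4[m4$pos == 1L, ]), 0L)
})

test_that("an all-T locus has level zero and error bases are ignored", {
  reads <- c(rep("ATATT", 7), "AGATT") # 7 informative T's, one G error
  m <- call_sites(make_alignments(reads), .ref$fragments, .ref$genome,
                  min_coverage = 5L)
  site <- m[m$pos == 1L, ]
  expect_equal(site$level, 0)
  expect_equal(site$meth_count + site$unmeth_count, 7L)
})

test_that("OB reads inform minus-strand cytosines", {
  # reference GT at positions 3-4: the G at pos 4 is a minus-strand C
  ref <- make_single_fragment("ATTGTTAATTAATTAATTAATTAATTAAGG")
  # an OB read is the reverse complement of a fragment slice; in fragment
  # space its bases at reference G positions read G (meth) or A (unmeth)
  ob <- rrbspipe:::revcomp("ATTGTTAATTAATTAATTAATTAATTAAGG")
  aln <- make_alignments(rep(ob, 5), strand_mode = "OB")
  m <- call_sites(aln, ref$fragments, ref$genome, min_coverage = 5L)
  g_site <- m[m$pos == 3L & m$strand == "-", ]
  expect_equal(g_site$meth_count, 5L)
  expect_identical(g_site$context, "CHH")
  expect_error(call_sites(make_alignments("ACATT", fragment_id = 9L),
                          .ref$fragments, .ref$genome), "fragment")
})

test_that("merge_cpg combines the symmetric dyad onto the plus strand", {
  ref <- make_single_fragment("ACGTTAATTAATTAATTAATTAATTAATTA")
  aln <- rbind(make_alignments(rep("ACGTT", 6), strand_mode = "OT"),
               make_alignments(rep(rrbspipe:::revcomp("ACGTT"), 6),
                               strand_mode = "OB"))
  merged <- call_sites(aln, ref$fragments, ref$genome, min_coverage = 5L,
                       merge_cpg = TRUE)
  dyad <- merged[merged$pos == 1L, ]
  expect_equal(nrow(dyad), 1L)
  expect_identical(dyad$strand, "+")
  expect_equal(dyad$meth_count, 12L)
  plain <- call_sites(aln, ref$fragments, ref$genome, min_coverage = 5L)
  expect_equal(sum(plain$pos %in% c(1L, 2L)), 2L)
})

test_that("informative observations are conserved through calling", {
  fx <- fx_clean_run()
  m <- fx$called
  expect_gte(attr(m, "n_observations"), sum(m$meth_count + m$unmeth_count))
  # oracle on a small constructed case: 5 reads x 8 covered cytosines
  reads <- rep("ACATTAGGATT", 5)
  mm <- call_sites(make_alignments(reads), .ref$fragments, .ref$genome,
                   min_coverage = 1L)
  b <- strsplit(substr(.ref$fragments$sequence, 1, 11), "")[[1]]
  n_plus <- sum(b == "C") # every read base at a C here is C or T
  n_minus <- 0            # no OB reads; plus G positions get no OT calls
  expect_equal(attr(mm, "n_observations"), 5L * (n_plus + n_minus))
})

test_that("conversion-rate estimation follows the non-CpG formula", {
  m <- make_methylome(chrom = "chr1", pos = 1:20, strand = "+",
                      context = "CHH", meth = rep(1L, 20),
                      unmeth = rep(9L, 20))
  est <- estimate_conversion_rate(m)
  expect_true(est$defined)
  expect_equal(est$rate, 0.9)
  expect_equal(est$n_informative, 200L)
  expect_true(est$ci_low < 0.9 && 0.9 < est$ci_high)
  # fully converted data estimates exactly 1
  m1 <- make_methylome("chr1", 1:20, "+", "CHH", rep(0L, 20), rep(10L, 20))
  expect_equal(estimate_conversion_rate(m1)$rate, 1)
  # all-methylated non-CpG data flags the degenerate rate 0
  m0 <- make_methylome("chr1", 1:20, "+", "CHH", rep(10L, 20), rep(0L, 20))
  est0 <- suppressMessages(estimate_conversion_rate(m0))
  expect_equal(est0$rate, 0)
  expect_true(est0$warn_all_methylated)
  # fewer than 100 informative observations is undefined
  few <- make_methylome("chr1", 1:5, "+", "CHH", rep(1L, 5), rep(9L, 5))
  expect_false(suppressMessages(estimate_conversion_rate(few))$defined)
})

test_that("Pearson correlation over shared CpG sites", {
  mk <- function(levels, id) make_methylome("chr1", seq_along(levels) * 10L,
                                            "+", "CpG",
                                            as.integer(levels * 10),
                                            as.integer((1 - levels) * 10),
                                            id)
  a <- mk(c(0, 0.5, 1), "a")
  expect_equal(methylation_correlation(a, mk(c(0, 0.5, 1), "b"))$r, 1)
  expect_equal(methylation_correlation(a, mk(c(1, 0.5, 0), "b"))$r, -1)
  expect_equal(methylation_correlation(mk(c(0, 0, 1), "a"),
                                       mk(c(0, 1, 1), "b"))$r, 0.5)
  flat <- suppressMessages(
    methylation_correlation(mk(c(0.5, 0.5, 0.5), "a"), a))
  expect_false(flat$defined)
})

test_that("chromosome profile fold change is treated over control", {
  mk <- function(levels, id) make_methylome(rep(c("chr1", "chr2"), each = 3),
                                            rep(1:3 * 10L, 2), "+", "CpG",
                                            as.integer(round(levels * 100)),
                                            as.integer(round((1 - levels) *
                                                               100)), id)
  base <- c(0.2, 0.4, 0.6, 0.8, 0.6, 0.4)
  ms <- list(NT_1 = mk(base, "NT_1"), T_1 = mk(base, "T_1"))
  cond <- c(NT_1 = "NT", T_1 = "T")
  prof <- chromosome_profile(ms, cond)
  expect_equal(prof$fold_change, c(1, 1))
  ms2 <- list(NT_1 = mk(base, "NT_1"), T_1 = mk(base * 0.5, "T_1"))
  expect_equal(chromosome_profile(ms2, cond)$fold_change, c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("feature averages follow the site field", {
  fx <- fx_clean_run()
  m <- fx$called
  flat <- m
  flat$level <- 0.5
  fa <- feature_average(flat, fx$genes, fx$islands)
  expect_true(all(abs(fa$mean_level - 0.5) < 1e-12))
  expect_setequal(fa$feature, c("CGI", "promoter", "exon", "intron"))
  # the simulated pattern: islands hypomethylated, background high
  real <- feature_average(m, fx$genes, fx$islands)
  cgi <- real$mean_level[real$feature == "CGI"]
  cpg <- m[m$context == "CpG", ]
  bg <- !rrbspipe:::.in_intervals(cpg$chrom, cpg$pos, fx$islands)
  expect_lt(cgi, mean(cpg$level[bg]))
  # no gene models: only the CGI class remains
  only_cgi <- feature_average(m, NULL, fx$islands)
  expect_identical(only_cgi$feature, "CGI")
})

test_that("called levels recover the truth at high coverage", {
  old <- options(rrbspipe.log_level = "warn"); on.exit(options(old))
  cfg <- sim_config(n_chroms = 1L, chrom_length = 150000L,
                    island_count = 18L, n_genes = 8L, coverage = 30,
                    conversion_rate = 1, error_rate = 0, seed = 21L)
  g <- generate_genome(cfg)
  fr <- digest_genome(g$genome, rrbs_enzymes(), cfg$min_len, cfg$max_len)
  me <- generate_methylome(g$genome, fr, g$islands, NULL, cfg)
  sim <- simulate_reads(fr, me, "NT_1", cfg)
  al <- align_reads(trim_reads(sim$reads), build_converted_indices(fr))
  called <- call_sites(al, fr, g$genome, 5L, "NT_1")
  cpg <- called[called$context == "CpG", ]
  key_true <- paste(me$sites$chrom, me$sites$pos, me$sites$strand)
  idx <- match(paste(cpg$chrom, cpg$pos, cpg$strand), key_true)
  true_lev <- me$levels[idx, "NT_1"]
  expect_lte(mean(abs(cpg$level - true_lev)), 0.1)
  expect_gte(cor(cpg$level, true_lev), 0.95)
})

test_that("cytosine report and bedGraph writers emit consistent records", {
  fx <- fx_clean_run()
  path <- tempfile(fileext = ".tsv")
  write_cytosine_report(fx$called, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(fx$called))
  expect_equal(back$pos, fx$called$pos + 1L)
  dir <- tempfile(); dir.create(dir)
  paths <- write_bedgraph(fx$called, dir, "s")
  expect_true(all(file.exists(file.path(
    dir, sprintf("s.%s.bedGraph", unique(fx$called$context))))))
})
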