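test_that("Fisher worked examples match the enumeration values", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(9, 1, 1, 9), 202 / 184756)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / 184756)
  expect_equal(fisher_exact_2x2(matrix(c(9, 1, 1, 9), 2, byrow = TRUE)),
               202 / 184756)
  # zero margins carry no information
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "negative")
})

test_that("Fisher agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:50) {
    t <- matrix(rpois(4, 20), 2)
    expect_equal(fisher_exact_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("BH worked examples match the step-up formula", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.05, 1)), c(0.10, 1))
  expect_equal(bh_fdr(c(0.03, 0.01)), c(0.03, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches a hand-rolled oracle and its invariants", {
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("site differential applies the strong-site rule", {
  mk <- function(meth, unmeth, id)
    make_methylome("chr1", seq_along(meth) * 50L, "+", "CpG",
                   meth, unmeth, id)
  a <- mk(c(40L, 20L, 8000L, 10L), c(10L, 20L, 2000L, 10L), "a")
  b <- mk(c(10L, 20L, 6000L, 10L), c(40L, 20L, 4000L, 10L), "b")
  sd <- site_differential(a, b)
  expect_equal(sd$delta, c(-0.6, 0, -0.2, 0))
  expect_equal(sd$p[1], oracle_fisher(40, 10, 10, 40))
  expect_equal(sd$p[c(2, 4)], c(1, 1))
  # |delta| 0.6 with tiny q: strong; tiny p at |delta| 0.2: not strong
  expect_true(sd$strong[1])
  expect_lt(sd$p[3], 1e-6)
  expect_false(sd$strong[3])
  expect_false(any(sd$strong[c(2, 4)]))
})

test_that("windows need min_sites shared sites and a identical to b is null", {
  mk <- function(meth, id) make_methylome(
    "chr1", c(10L, 50L, 210L, 250L, 290L), "+", "CpG",
    meth, 50L - meth, id)
  a <- mk(c(40L, 40L, 40L, 40L, 40L), "a")
  b <- mk(c(10L, 10L, 10L, 10L, 10L), "b")
  dd <- detect_dmrs(a, b)
  # the [0,200) window holds 2 sites and is discarded before testing
  expect_equal(dd$windows$start, 200L)
  expect_equal(dd$windows$n_sites, 3L)
  null <- detect_dmrs(a, a)
  expect_equal(nrow(null$dmrs), 0L)
  expect_equal(null$windows$p, rep(1, nrow(null$windows)),
               tolerance = 1e-9)
  expect_error(detect_dmrs(a, b, mode = "nonsense"))
})

test_that("a pooled window with strong counts is called with direction", {
  mk <- function(meth, id) make_methylome(
    "chr1", c(210L, 250L, 290L, 410L, 450L, 490L), "+", "CpG",
    meth, 60L - meth, id)
  a <- mk(c(48L, 48L, 48L, 30L, 30L, 30L), "a")
  b <- mk(c(12L, 12L, 12L, 30L, 30L, 30L), "b")
  for (mode in c("pooled", "per_site")) {
    dd <- detect_dmrs(a, b, mode = mode)
    expect_equal(nrow(dd$dmrs), 1L)
    expect_equal(dd$dmrs$start, 200L)
    expect_equal(dd$dmrs$delta, -0.6)
    expect_identical(dd$dmrs$direction, "hypo")
    expect_equal(dd$dmrs$p,
                 oracle_fisher(3L * 48L, 3L * 12L, 3L * 12L, 3L * 48L))
  }
})

test_that("consensus keeps only windows present in every comparison", {
  w <- function(chrom, start, direction, q = 1e-4, delta = 0.5)
    data.frame(chrom = chrom, start = start, end = start + 200L,
               direction = direction, q = q, delta = delta,
               stringsAsFactors = FALSE)
  c1 <- rbind(w("chr1", 0L, "hyper"), w("chr1", 200L, "hyper", q = 1e-3),
              w("chr1", 600L, "hypo"))
  c2 <- rbind(w("chr1", 0L, "hyper", q = 1e-5), w("chr1", 200L, "hyper"),
              w("chr2", 0L, "hyper"))
  cons <- intersect_and_merge(list(c1, c2))
  # chr1:600 (absent in c2) and chr2:0 (absent in c1) are excluded;
  # the two book-ended kept windows merge
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 0L)
  expect_equal(cons$end, 400L)
  expect_identical(cons$direction, "hyper")
  expect_equal(cons$n_windows, 2L)
  # per window the worst q across comparisons, then the best window of the
  # merged region: min(max(1e-4, 1e-5), max(1e-3, 1e-4))
  expect_equal(cons$q, 1e-4)
  # a window with the same interval but opposite direction does not match
  c3 <- rbind(w("chr1", 0L, "hypo"), w("chr1", 200L, "hyper"))
  cons3 <- intersect_and_merge(list(c1, c3))
  expect_equal(cons3$start, 200L)
  # single-comparison input is idempotent up to merging
  solo <- intersect_and_merge(list(c1))
  expect_equal(nrow(solo), 2L)
  expect_equal(solo$end[1], 400L)
})

test_that("inconsistent window grids are rejected", {
  off_grid <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                         direction = "hyper", q = 1e-4, delta = 0.5,
                         stringsAsFactors = FALSE)
  fx <- fx_planted_run()
  expect_error(intersect_and_merge(c(fx$comparisons[1], list(off_grid))),
               "grid")
  other <- fx$comparisons[[1]]
  other$params$window <- 100L
  expect_error(intersect_and_merge(list(fx$comparisons[[1]], other)),
               "grid")
})

test_that("the top-DMR matrix ranks by q then effect size", {
  fx <- fx_planted_run()
  cons <- fx$consensus
  mat <- top_dmr_matrix(cons, fx$methylomes, n = 100L)
  expect_equal(nrow(mat), min(100L, nrow(cons)))
  expect_equal(ncol(mat), 4L)
  expect_true(all(mat >= 0 & mat <= 1, na.rm = TRUE))
  mat5 <- top_dmr_matrix(cons, fx$methylomes, n = 5L)
  expect_equal(nrow(mat5), 5L)
  ord <- order(cons$q, -abs(cons$delta))
  expect_identical(rownames(mat5)[1],
                   sprintf("%s:%d-%d", cons$chrom[ord[1]],
                           cons$start[ord[1]], cons$end[ord[1]]))
  expect_error(top_dmr_matrix(cons[0, ], fx$methylomes), "consensus")
})

test_that("planted DMRs separate conditions in the matrix", {
  fx <- fx_planted_run()
  mat <- top_dmr_matrix(fx$consensus, fx$methylomes, n = 20L)
  gap <- rowMeans(mat[, c("T_1", "T_2")]) - rowMeans(mat[, c("NT_1", "NT_2")])
  expect_true(all(abs(gap) > 0.25, na.rm = TRUE))
})

test_that("DMR thresholds act monotonically", {
  fx <- fx_planted_run()
  key <- function(d) paste(d$dmrs$chrom, d$dmrs$start, d$dmrs$direction)
  a <- fx$methylomes$NT_1; b <- fx$methylomes$T_1
  loose <- detect_dmrs(a, b, min_delta = 0.25, q_threshold = 0.05)
  tight_delta <- detect_dmrs(a, b, min_delta = 1/3, q_threshold = 0.05)
  tight_q <- detect_dmrs(a, b, min_delta = 0.25, q_threshold = 0.01)
  expect_true(all(key(tight_delta) %in% key(loose)))
  expect_true(all(key(tight_q) %in% key(loose)))
})

test_that("DMR BED6+ output round-trips", {
  fx <- fx_planted_run()
  path <- tempfile(fileext = ".tsv")
  write_dmrs(fx$comparisons[[1]], path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(fx$comparisons[[1]]$dmrs))
  expect_true(all(back$score <= 1000))
  expect_identical(unique(back$mode), "pooled")
})
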