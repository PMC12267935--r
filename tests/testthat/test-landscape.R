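# Landscape statistics: Fisher-tested bins, correlations, metaprofiles,
# SNP density, inter-SNP distances, span classes.

mids <- function(pos, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(pos)), midpoint = pos,
             stringsAsFactors = FALSE)
}

test_that("identical call sets produce no flagged bins and unit correlation", {
  set.seed(3)
  a <- mids(sample.int(3e6, 300))
  bt <- binned_comparison(a, a, c(chr1 = 3e6), bin = 1e5)
  expect_true(all(abs(bt$p - 1) < 1e-7))
  expect_false(any(bt$flagged))
  expect_equal(sum(bt$freq_a), 1)
  expect_equal(sum(bt$freq_b), 1)
  expect_equal(correlate_bins(a, a, c(chr1 = 3e6), bin = 1e5)$r, 1)
})

test_that("per-bin Fisher P equals exhaustive hypergeometric enumeration", {
  # one bin holding (10 of 100) vs (50 of 100): P by enumerating all tables
  a <- mids(c(runif(10, 0, 1e5), runif(90, 1e5, 1e6)))
  b <- mids(c(runif(50, 0, 1e5), runif(50, 1e5, 1e6)))
  bt <- binned_comparison(a, b, c(chr1 = 1e6), bin = 1e5)
  # exhaustive two-sided P: sum of probabilities of tables at least as
  # extreme, margins fixed (row = 100/100, col = 60/140)
  enum_p <- function(x, m, n, k) {
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(x, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(bt$p[1], enum_p(10, 100, 100, 60), tolerance = 1e-9)
  # a few random margins <= 200
  set.seed(5)
  for (i in 1:20) {
    m <- sample(20:100, 1); n <- sample(20:100, 1)
    k <- sample(5:(m + n - 5), 1)
    x <- sample(max(0, k - n):min(k, m), 1)
    ft <- fisher.test(matrix(c(x, m - x, k - x, n - k + x), 2))$p.value
    expect_equal(ft, enum_p(x, m, n, k), tolerance = 1e-9)
  }
})

test_that("null landscapes are rarely flagged and BH is threshold-monotone", {
  set.seed(8)
  flagged <- integer(50)
  for (r in 1:50) {
    a <- mids(runif(200, 1, 3e6))
    b <- mids(runif(200, 1, 3e6))
    bt <- binned_comparison(a, b, c(chr1 = 3e6), bin = 1e5)
    flagged[r] <- sum(bt$flagged)
  }
  expect_lte(sum(flagged), 10)  # ~0 per replicate under the null
  # lowering the FDR threshold never flags more bins
  a <- mids(c(runif(150, 0, 3e5), runif(50, 3e5, 3e6)))
  b <- mids(runif(200, 1, 3e6))
  bt <- binned_comparison(a, b, c(chr1 = 3e6), bin = 1e5)
  n_flag <- vapply(c(0.2, 0.1, 0.05, 0.01), function(t) sum(bt$q < t),
                   integer(1))
  expect_true(all(diff(n_flag) <= 0))
})

test_that("binned comparison respects masks and errors on empty datasets", {
  a <- mids(c(5e4, 15e4, 25e4))
  b <- mids(c(5e4, 15e4, 25e4))
  mask <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  bt <- binned_comparison(a, b, c(chr1 = 3e5), bin = 1e5, masks = mask)
  expect_equal(bt$count_a, c(0L, 1L, 1L))
  expect_error(binned_comparison(mids(numeric()), b, c(chr1 = 3e5)),
               "must contain")
})

test_that("metaprofiles are strand-aware and flat under uniform midpoints", {
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 30000),
                        strand = c("+", "-"))
  # midpoints exactly at the anchors: single central spike
  mp <- metaprofile(mids(c(10000, 30000)), anchors, half_width = 2000,
                    binwidth = 100)
  expect_equal(sum(mp$rate > 0), 1)
  expect_equal(mp$offsets[which(mp$rate > 0)], 50)  # bin just right of 0
  # minus-strand anchor: a midpoint 100 bp left of it maps to offset +100
  mp2 <- metaprofile(mids(29900), anchors, half_width = 2000, binwidth = 100)
  expect_equal(mp2$offsets[which(mp2$rate > 0)], 150)  # bin (100, 200]
  # plus-strand: 100 bp left is upstream; bins are left-closed, so the
  # offset -100 falls in the [-100, 0) bin centred at -50
  mp3 <- metaprofile(mids(9900), anchors, half_width = 2000, binwidth = 100)
  expect_equal(mp3$offsets[which(mp3$rate > 0)], -50)
  expect_error(metaprofile(mids(1), anchors[0, ], half_width = 2000),
               "non-empty")

  # uniform midpoints: flat within sampling error (chi-square GOF);
  # anchors spaced so windows cannot overlap (no double counting)
  set.seed(12)
  pvals <- vapply(1:20, function(r) {
    anch <- data.frame(chrom = "chr1",
                       pos = sample(seq(10000, 2.99e6, by = 5000), 30) +
                         sample(0:499, 30, TRUE),
                       strand = sample(c("+", "-"), 30, TRUE))
    m <- metaprofile(mids(runif(3000, 1, 3e6)), anch, half_width = 2000,
                     binwidth = 400)
    counts <- m$rate * nrow(anch)
    suppressWarnings(chisq.test(counts)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("SNP density profile is flat for uniform catalogs, peaked by construction", {
  cat <- snp_catalog("chr1", seq(100, 99900, by = 100),
                     rep("A", 999), rep("G", 999))
  prof <- snp_density_around(mids(seq(20000, 80000, by = 5000)), cat,
                             window = 4000, binwidth = 10)
  expect_length(prof$density, 400)
  expect_equal(mean(prof$density), 0.1, tolerance = 1e-6)
  # at a bin width matching the spacing, every bin holds exactly one SNP
  prof100 <- snp_density_around(mids(seq(20000, 80000, by = 5000)), cat,
                                window = 4000, binwidth = 100)
  expect_true(all(prof100$density == 1))

  # empty catalog over the windows -> all-zero profile
  cat2 <- snp_catalog("chr1", c(1, 2), c("A", "C"), c("G", "T"))
  prof2 <- snp_density_around(mids(50000), cat2, chrom_lengths = c(chr1 = 1e5))
  expect_true(all(prof2$density == 0))

  # midpoints placed exactly at SNPs: central bins denser than flanks
  sparse <- snp_catalog("chr1", seq(500, 99500, by = 1000),
                        rep("A", 100), rep("G", 100))
  prof3 <- snp_density_around(mids(seq(10500, 90500, by = 1000)), sparse,
                              window = 4000, binwidth = 10)
  central <- mean(prof3$density[199:202])
  flank <- mean(prof3$density[c(1:50, 351:400)])
  expect_gt(central, flank)
  expect_error(snp_density_around(mids(numeric()), sparse), "no crossover")
})

test_that("inter-SNP distances at crossover sites and rank comparison", {
  cat <- snp_catalog("chr1", c(1000, 1500, 3000, 3100),
                     rep("A", 4), rep("G", 4))
  bp <- data.frame(read_id = c("a", "b"), chrom = "chr1",
                   bp_start = c(1000, 3000), bp_end = c(1500, 3100),
                   midpoint = c(1250, 3050), left_parent = "C",
                   right_parent = "L", type = "SCO", stringsAsFactors = FALSE)
  d <- inter_snp_distance_at_sites(bp, cat)
  expect_equal(d$distances, c(500, 100))
  expect_equal(d$median, 300)
  # identical call sets compare with P = 1
  dd <- inter_snp_distance_at_sites(bp, cat, other = bp)
  expect_equal(dd$p, 1)
  # breakpoint not bounded by catalog SNPs is skipped with a warning
  bad <- bp; bad$bp_start[2] <- 2999
  expect_warning(db <- inter_snp_distance_at_sites(bad, cat), "skipped")
  expect_equal(db$distances, 500)

  # shifted distributions are detected by the rank test
  set.seed(23)
  hits <- vapply(1:40, function(r) {
    pos <- cumsum(c(1000, sample(c(300, 700), 400, TRUE)))
    catx <- snp_catalog("chr1", pos, rep("A", 401), rep("G", 401))
    gaps <- diff(pos)
    short <- which(gaps == 300); long <- which(gaps == 700)
    mkbp <- function(idx, n) {
      i <- sample(idx, n, replace = TRUE)
      data.frame(read_id = sprintf("r%d", seq_len(n)), chrom = "chr1",
                 bp_start = pos[i], bp_end = pos[i + 1],
                 midpoint = (pos[i] + pos[i + 1]) / 2, left_parent = "C",
                 right_parent = "L", type = "SCO", stringsAsFactors = FALSE)
    }
    # one set drawn mostly from short gaps, the other mostly from long
    s1 <- mkbp(c(short, sample(long, 20)), 60)
    s2 <- mkbp(c(long, sample(short, 20)), 60)
    inter_snp_distance_at_sites(s1, catx, other = s2)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("crossovers are classified by the span class of their midpoint", {
  pos <- c(seq(1000, 1700, 100),            # dense: span 700
           seq(100000, 135000, 5000),       # medium: span 35000? -> >10000
           seq(500000, 503500, 500))        # span 3500
  cat <- snp_catalog("chr1", pos, rep("A", length(pos)),
                     rep("G", length(pos)))
  tr <- snp_span_track(cat, k = 8)
  calls <- mids(c(1350, 117500, 501750))
  tab <- classify_by_span(calls, tr, breaks = c(4000, 10000))
  expect_equal(as.integer(tab),
               c(2L, 0L, 1L, 0L))  # <=4000 x2, >10000 x1
  # empty call set -> all-zero counts
  expect_equal(sum(classify_by_span(mids(numeric()), tr)), 0)
  # midpoint outside the track -> unassigned
  tab2 <- classify_by_span(mids(10), tr, breaks = c(4000, 10000))
  expect_equal(as.integer(tab2[["unassigned"]]), 1L)
})

test_that("gene anchors load from GFF3 and BED6 with strand semantics", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", "1000", "2000", ".", "+", ".",
                     "ID=g1", sep = "\t"),
               paste("chr1", "src", "gene", "5000", "6000", ".", "-", ".",
                     "ID=g2", sep = "\t"),
               paste("chr1", "src", "mRNA", "1000", "2000", ".", "+", ".",
                     "ID=t1", sep = "\t")), gff)
  tss <- read_anchors(gff, "TSS")
  expect_equal(tss$pos, c(1000L, 6000L))  # minus-strand TSS is the right end
  tes <- read_anchors(gff, "TES")
  expect_equal(tes$pos, c(2000L, 5000L))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tg1\t0\t+", "chr1\t4999\t6000\tg2\t0\t-"),
             bed)
  expect_equal(read_anchors(bed, "TSS")$pos, c(1000L, 6000L))
})
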