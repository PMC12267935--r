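# SNP catalog loading, curation against F2 segregation data, span track.

write_snp_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("#CHROM\tPOS\tALLELE_COL\tALLELE_LER", rows), path)
  path
}

test_that("a well-formed SNP table loads sorted and deduplicated", {
  p <- write_snp_tsv(c("chr1\t500\tA\tG", "chr1\t100\tC\tT",
                       "chr1\t300\tG\tA", "chr1\t300\tG\tA"))
  cat <- read_snp_table(p)
  expect_s3_class(cat, "snp_catalog")
  expect_equal(cat$pos, c(100L, 300L, 500L))
  expect_equal(cat$allele_a, c("C", "G", "A"))
  # sort invariance: already-sorted input gives the identical catalog
  p2 <- write_snp_tsv(c("chr1\t100\tC\tT", "chr1\t300\tG\tA",
                        "chr1\t500\tA\tG"))
  expect_identical(cat, read_snp_table(p2))
})

test_that("invalid SNP rows are rejected with the offending line", {
  p <- write_snp_tsv(c("chr1\t100\tC\tT", "chr1\t200\tA\tA"))
  expect_error(read_snp_table(p), "allele_a == allele_b.*line 3")
  p <- write_snp_tsv(c("chr1\t100\tC\tT", "chr1\tnotanumber\tA\tG"))
  expect_error(read_snp_table(p), "line 3")
  p <- write_snp_tsv(c("chr1\t100\tC\tT", "chr1\t100\tC\tG"))
  expect_error(read_snp_table(p), "conflicting alleles")
  p <- write_snp_tsv("chr1\t100\tC")
  expect_error(read_snp_table(p), "malformed")
})

test_that("catalog merge is a union with conflict rejection", {
  a <- snp_catalog("chr1", c(100, 300), c("A", "C"), c("G", "T"))
  b <- snp_catalog("chr1", c(200, 300), c("T", "C"), c("A", "T"))
  m <- merge_snp_catalogs(a, b)
  expect_equal(m$pos, c(100L, 200L, 300L))
  conflicting <- snp_catalog("chr1", 300, "C", "G")
  expect_error(merge_snp_catalogs(a, conflicting), "conflicting")
})

test_that("curation applies the three criteria with inclusive AF bounds", {
  # perfect 1:2:1 over 2160 plants: chi-square statistic 0, P = 1
  m <- matrix(c(rep(0L, 540), rep(1L, 1080), rep(2L, 540)), ncol = 1)
  res <- curate_snp_candidates(m)
  expect_true(res$kept)
  expect_equal(res$seg_p, 1)
  expect_equal(res$af, 0.5)

  # genotyped in only 39 plants -> removed for the genotyping-count criterion
  m39 <- matrix(c(rep(0L, 10), rep(1L, 20), rep(2L, 9), rep(NA, 100)),
                ncol = 1)
  res39 <- curate_snp_candidates(m39)
  expect_false(res39$kept)
  expect_equal(res39$reason, "min_genotyped")

  # (100, 0, 100): segregation P from the independent chi-square CDF
  mseg <- matrix(c(rep(0L, 100), rep(2L, 100)), ncol = 1)
  res_seg <- curate_snp_candidates(mseg)
  expect_false(res_seg$kept)
  expect_equal(res_seg$reason, "segregation")
  oracle <- suppressWarnings(
    chisq.test(c(100, 0, 100), p = c(0.25, 0.5, 0.25)))
  expect_equal(res_seg$seg_p, oracle$p.value)

  # boundary AF 0.4 passes (inclusive bounds); het counts as half an allele
  maf <- matrix(c(rep(0L, 60), rep(1L, 80), rep(2L, 20)), ncol = 1)
  res_af <- curate_snp_candidates(maf, seg_p = 0)  # isolate the AF criterion
  expect_equal(res_af$af, 0.375)
  expect_equal(res_af$reason, "allele_frequency")
  maf2 <- matrix(c(rep(0L, 48), rep(1L, 64), rep(2L, 16)), ncol = 1)
  expect_equal(curate_snp_candidates(maf2, seg_p = 0)$af, 0.375)

  # all-missing column is a removal reason, not an exception
  res_na <- curate_snp_candidates(matrix(NA_integer_, nrow = 5, ncol = 1))
  expect_equal(res_na$reason, "insufficient genotyping")
})

test_that("curation is row/column order independent and filter-monotone", {
  set.seed(42)
  n <- 60
  m <- matrix(sample(c(0:2, NA), n * 20, replace = TRUE,
                     prob = c(0.22, 0.45, 0.22, 0.11)), nrow = n)
  colnames(m) <- paste0("s", 1:20)
  base <- curate_snp_candidates(m, min_genotyped = 40)
  perm <- curate_snp_candidates(m[sample(n), sample(20)], min_genotyped = 40)
  expect_equal(base$kept[match(perm$snp, base$snp)], perm$kept)
  # loosening every threshold can only keep more SNPs
  loose <- curate_snp_candidates(m, min_genotyped = 30, af_low = 0.3,
                                 af_high = 0.7, seg_p = 0.01)
  expect_true(all(loose$kept[base$kept]))
})

test_that("under true 1:2:1 segregation ~seg_p of SNPs fail criterion 3", {
  set.seed(7)
  n_snp <- 400
  m <- matrix(sample(0:2, 2160 * n_snp, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), nrow = 2160)
  res <- curate_snp_candidates(m, min_genotyped = 0, af_low = 0, af_high = 1)
  frac_fail <- mean(res$reason == "segregation")
  # binomial sampling band around 0.1 (3 sigma for n = 400)
  expect_lt(abs(frac_fail - 0.1), 3 * sqrt(0.1 * 0.9 / n_snp))
})

test_that("span track arithmetic and gap masks follow the definitions", {
  cat <- snp_catalog("chr1", seq(1000, 8000, by = 1000),
                     rep("A", 8), rep("G", 8))
  tr <- snp_span_track(cat, k = 8)
  expect_equal(nrow(tr$spans), 1L)
  expect_equal(tr$spans$span, 7000)
  expect_equal(nrow(tr$mask), 0L)

  # a 5001-bp gap (> 4000) masks the half-open interval between the SNPs
  cat2 <- snp_catalog("chr1", c(seq(100, 1000, by = 100), 6001),
                      rep("A", 11), rep("G", 11))
  tr2 <- snp_span_track(cat2, k = 8)
  expect_equal(tr2$mask,
               data.frame(chrom = "chr1", start = 1000L, end = 6001L))

  # equally spaced SNPs every 100 bp: empty mask
  cat3 <- snp_catalog("chr1", seq(100, 5000, by = 100),
                      rep("A", 50), rep("G", 50))
  expect_equal(nrow(snp_span_track(cat3, k = 8)$mask), 0L)

  # chromosome with < k SNPs is skipped with a message
  cat4 <- snp_catalog(rep(c("chr1", "chr2"), c(10, 3)),
                      c(seq(100, 1000, 100), c(50, 80, 120)),
                      rep("A", 13), rep("G", 13))
  expect_message(tr4 <- snp_span_track(cat4, k = 8), "chr2")
  expect_equal(tr4$skipped, "chr2")
  expect_true(all(tr4$spans$chrom == "chr1"))
})

# membership of 1-based points in a 0-based half-open mask
overlaps_any_test <- function(points, mask) {
  vapply(points, function(x)
    any(mask$start < x & x <= mask$end), logical(1))
}

test_that("span/mask computation matches a brute-force pairwise scan", {
  set.seed(11)
  for (rep in 1:5) {
    pos <- sort(sample.int(2e5, 300))
    pos <- pos[!duplicated(pos)]
    cat <- snp_catalog("chr1", pos, rep("A", length(pos)),
                       rep("G", length(pos)))
    k <- 8; thr <- 4000
    tr <- snp_span_track(cat, max_inter_snp = thr, k = k)
    # brute force spans
    exp_span <- vapply(seq_len(length(pos) - k + 1),
                       function(i) pos[i + k - 1] - pos[i], numeric(1))
    expect_equal(tr$spans$span, exp_span)
    # brute force mask membership per bp sample
    probe <- sort(sample.int(max(pos), 200))
    in_mask_bf <- vapply(probe, function(x) {
      any(vapply(seq_len(length(pos) - 1), function(i)
        pos[i + 1] - pos[i] > thr && x > pos[i] && x <= pos[i + 1],
        logical(1)))
    }, logical(1))
    in_mask <- overlaps_any_test(probe, tr$mask)
    expect_equal(in_mask, in_mask_bf)
  }
})

test_that("span_at returns the minimum covering-window span", {
  pos <- c(100, 200, 300, 400, 2000, 2100, 2200, 2300)
  cat <- snp_catalog("chr1", pos, rep("A", 8), rep("G", 8))
  tr <- snp_span_track(cat, k = 4)
  # windows: (100-400, span 300), (200-2000, 1800), (300-2100, 1800),
  # (400-2200, 1800), (2000-2300, 300)
  expect_equal(span_at(tr, "chr1", 150), 300)
  expect_equal(span_at(tr, "chr1", 1000), 1800)  # mid-gap: only wide windows
  expect_equal(span_at(tr, "chr1", 2250), 300)
  expect_true(is.na(span_at(tr, "chr1", 50)))
})
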