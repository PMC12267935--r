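# Alignment filtering, quality masking, and read-to-genotype-string
# conversion, including the SAM path with indel-containing CIGARs.

write_sam <- function(records, chrom_len = 100000,
                      path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:chr1\tLN:", chrom_len),
               records), path)
  path
}

sam_record <- function(qname, pos, cigar, seq, qual = NULL, flag = 0,
                       mapq = 60) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40
  paste(qname, flag, "chr1", pos, mapq, cigar, "*", 0, 0, seq, qual,
        sep = "\t")
}

test_that("alignment filter applies the unique-alignment criteria", {
  res <- filter_alignment(
    flag = c(0L, 0L, 0L, 4L, 1024L, 256L, 2048L, 0L),
    mapq = c(29, 60, 60, 60, 60, 60, 60, NA),
    seq_length = c(15000, 99, 10000, 10000, 10000, 10000, 10000, 10000))
  expect_equal(res$keep,
               c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$reason,
               c("mapq", "length", "", "unmapped", "duplicate", "secondary",
                 "supplementary", "no mapping quality"))
})

test_that("quality masking is strict at the threshold", {
  # Phred+33: quality 13 = '.', 14 = '/', 40 = 'I'
  expect_equal(mask_low_quality("ACGT", "I.I/"), "ANGT")
  expect_equal(mask_low_quality("ACGT", "////"), "ACGT")  # exactly 14: kept
  expect_equal(mask_low_quality("ACGT", "IIII"), "ACGT")
  expect_error(mask_low_quality("ACGT", "*"), "differ in length|qualities")
  expect_error(mask_low_quality("ACGT", NA_character_), "qualities")
})

test_that("genotype_read emits C/L calls and drops uninformative sites", {
  cat <- snp_catalog("chr1", seq(100, 1000, by = 100),
                     rep("A", 10), rep("G", 10))
  # error-free parent-A read spanning all 10 SNPs
  r <- masked_read("r1", "chr1", 50:1050, rep("A", 1001))
  gs <- genotype_read(r, cat)
  expect_equal(gs$string, "CCCCCCCCCC")
  expect_equal(gs$positions[[1]], seq(100L, 1000L, by = 100L))
  expect_equal(gs$n_overlap, 10L)

  # 4th SNP masked to N: 9 characters, overlapped still 10
  bases <- rep("A", 1001); bases[400 - 49] <- "N"
  gs_n <- genotype_read(masked_read("r2", "chr1", 50:1050, bases), cat)
  expect_equal(nchar(gs_n$string), 9L)
  expect_equal(gs_n$n_overlap, 10L)
  expect_false(400 %in% gs_n$positions[[1]])

  # base equal to neither allele: dropped the same way
  bases2 <- rep("A", 1001); bases2[400 - 49] <- "T"
  gs_t <- genotype_read(masked_read("r3", "chr1", 50:1050, bases2), cat)
  expect_equal(nchar(gs_t$string), 9L)
  expect_equal(gs_t$n_overlap, 10L)

  # parent-B read
  basesL <- rep("A", 1001); basesL[seq(100, 1000, 100) - 49] <- "G"
  expect_equal(genotype_read(masked_read("r4", "chr1", 50:1050, basesL),
                             cat)$string, "LLLLLLLLLL")

  # read overlapping zero catalog SNPs: empty string, valid
  gs0 <- genotype_read(masked_read("r5", "chr1", 2000:2100,
                                   rep("A", 101)), cat)
  expect_equal(gs0$string, "")
  expect_equal(gs0$n_overlap, 0L)
})

test_that("SAM genotyping handles filtering, masking, and indel CIGARs", {
  cat <- snp_catalog("chr1", c(120, 140, 160, 180), rep("A", 4), rep("G", 4))
  mk_seq <- function(n, at = integer(), base = "G") {
    s <- rep("A", n); s[at] <- base; paste(s, collapse = "")
  }
  recs <- c(
    # r1: plain match, parent A at all 4 SNPs (pos 101, 100M -> covers 101-200)
    sam_record("r1", 101, "100M", mk_seq(100)),
    # r2: parent B at all SNPs (offsets 20, 40, 60, 80 in the read)
    sam_record("r2", 101, "100M", mk_seq(100, c(20, 40, 60, 80))),
    # r3: 30M10D70M at pos 101: ref 101-130 (query 1-30), del ref 131-140,
    #     ref 141-210 (query 31-100) -> SNP 140 falls in the deletion
    sam_record("r3", 101, "30M10D70M", mk_seq(100)),
    # r4: insertion before the SNPs shifts query coordinates
    #     20M5I80M at pos 101: ref 101-120 (q 1-20), ins q 21-25,
    #     ref 121-200 (q 26-105); SNP 140 -> query 45
    sam_record("r4", 101, "20M5I80M", mk_seq(105, 45)),
    # r5: low MAPQ -> dropped
    sam_record("r5", 101, "100M", mk_seq(100), mapq = 10),
    # r6: quality 13 at SNP 120 (query 20) -> masked, dropped from string
    sam_record("r6", 101, "100M", mk_seq(100),
               qual = paste0(strrep("I", 19), ".", strrep("I", 80)))
  )
  gs <- genotype_sam(write_sam(recs), cat)
  stats <- attr(gs, "filter_stats")
  expect_equal(stats[["input"]], 6L)
  expect_equal(stats[["kept"]], 5L)
  expect_equal(stats[["dropped_mapq"]], 1L)

  g <- function(id) gs[gs$read_id == id, ]
  expect_equal(g("r1")$string, "CCCC")
  expect_equal(g("r2")$string, "LLLL")
  # deletion: SNP 140 uninformative but overlapped
  expect_equal(g("r3")$string, "CCC")
  expect_equal(g("r3")$n_overlap, 4L)
  expect_equal(g("r3")$positions[[1]], c(120L, 160L, 180L))
  # insertion does not disturb genotyping of downstream SNPs
  expect_equal(g("r4")$string, "CLCC")
  # masked base dropped, counted as overlapped
  expect_equal(g("r6")$string, "CCC")
  expect_equal(g("r6")$n_overlap, 4L)
})

test_that("string positions are a subsequence of catalog positions", {
  pool <- quick_pool(seed = 3)
  gs <- genotype_pool(pool)
  pos_by_chrom <- split(pool$catalog$pos, pool$catalog$chrom)
  for (i in seq_len(nrow(gs))) {
    p <- gs$positions[[i]]
    if (length(p) == 0) next
    expect_false(is.unsorted(p, strictly = TRUE))
    expect_true(all(p %in% pos_by_chrom[[gs$chrom[i]]]))
  }
})

test_that("error-free strings equal the haplotype labels over covered SNPs", {
  pool <- quick_pool(seed = 5, error_rate = 0, chimera_rate = 0,
                     base_lowq_frac = 0)
  gs <- genotype_pool(pool)
  for (i in seq_len(nrow(gs))) {
    rd <- pool$reads[i, ]
    p <- pool$catalog$pos[pool$catalog$chrom == rd$chrom]
    covered <- p[p >= rd$start & p <= rd$start + rd$len - 1]
    # oracle: parent of the generating mosaic at each covered SNP
    parent <- longco:::mosaic_parent(pool$genomes[[rd$genome]], rd$chrom,
                                     covered)
    expect_equal(gs$string[i],
                 paste(c("C", "L")[parent + 1], collapse = ""))
    expect_equal(gs$positions[[i]], as.integer(covered))
  }
})

test_that("masking more bases only shortens strings, never flips calls", {
  pool <- quick_pool(seed = 9, error_rate = 0.02, error_lowq_frac = 0,
                     base_lowq_frac = 0, chimera_rate = 0)
  gs1 <- genotype_pool(pool)
  pool2 <- pool
  # mask an extra random 10% of each read
  set.seed(1)
  pool2$lowq <- lapply(seq_len(nrow(pool$reads)), function(i)
    sort(unique(c(pool$lowq[[i]],
                  sample.int(pool$reads$len[i],
                             ceiling(pool$reads$len[i] * 0.1))))))
  gs2 <- genotype_pool(pool2)
  for (i in seq_len(nrow(gs1))) {
    p1 <- gs1$positions[[i]]; p2 <- gs2$positions[[i]]
    expect_true(all(p2 %in% p1))
    c1 <- strsplit(gs1$string[i], "")[[1]]
    c2 <- strsplit(gs2$string[i], "")[[1]]
    expect_equal(c2, c1[match(p2, p1)])
  }
})
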