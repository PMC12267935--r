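## Alignment filtering, base-quality masking, and conversion of aligned reads
## into parental-genotype strings over the SNP catalog.

#' Filter alignment records
#'
#' Keeps uniquely aligned primary records: mapped, not duplicate, not
#' secondary/supplementary, mapping quality at least `min_mapq` and query
#' length at least `min_len`. Secondary/supplementary records are dropped so
#' that each sequenced molecule contributes at most one genotype string;
#' split alignments would otherwise fabricate chimeric strings.
#'
#' @param flag SAM FLAG values.
#' @param mapq Mapping qualities (NA when absent).
#' @param seq_length Query sequence lengths.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param min_len Minimum query length in bp (default 100).
#' @return data.frame with logical `keep` and `reason` (first failing check:
#'   `"unmapped"`, `"duplicate"`, `"secondary"`, `"supplementary"`,
#'   `"no mapping quality"`, `"mapq"`, `"length"`; `""` when kept).
#' @export
filter_alignment <- function(flag, mapq, seq_length,
                             min_mapq = 30, min_len = 100) {
  n <- max(length(flag), length(mapq), length(seq_length))
  flag <- rep_len(as.integer(flag), n)
  mapq <- rep_len(as.numeric(mapq), n)
  seq_length <- rep_len(as.numeric(seq_length), n)
  reason <- character(n)
  reason[seq_length < min_len] <- "length"
  reason[!is.na(mapq) & mapq < min_mapq] <- "mapq"
  reason[is.na(mapq)] <- "no mapping quality"
  reason[bitwAnd(flag, 2048L) != 0L] <- "supplementary"
  reason[bitwAnd(flag, 256L) != 0L] <- "secondary"
  reason[bitwAnd(flag, 1024L) != 0L] <- "duplicate"
  reason[bitwAnd(flag, 4L) != 0L] <- "unmapped"
  data.frame(keep = reason == "", reason = reason, stringsAsFactors = FALSE)
}

#' Mask low-quality bases
#'
#' Replaces every base whose Phred quality is strictly below `min_baseq` with
#' `N`. At the default threshold Q = 14 this masks bases with an error
#' probability above ~3.98%, which suppresses genotyping errors caused by
#' sequencing errors.
#'
#' @param seq Character vector of read sequences.
#' @param qual Parallel character vector of Phred+33 quality strings.
#' @param min_baseq Masking threshold (default 14); bases with quality
#'   `< min_baseq` become `N`, bases at exactly `min_baseq` are kept.
#' @return Character vector of masked sequences.
#' @export
mask_low_quality <- function(seq, qual, min_baseq = 14) {
  if (length(seq) != length(qual))
    stop("seq and qual must have equal length")
  if (any(is.na(qual)) || any(qual == "*"))
    stop("base qualities are required for masking")
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality strings differ in length")
  vapply(seq_along(seq), function(i) {
    r <- charToRaw(seq[[i]])
    q <- as.integer(charToRaw(qual[[i]])) - 33L
    r[q < min_baseq] <- charToRaw("N")
    rawToChar(r)
  }, character(1))
}

#' Construct a masked read
#'
#' A minimal representation of one filtered, quality-masked alignment: the
#' aligned (match/mismatch) reference positions and the read base at each.
#'
#' @param read_id Read identifier.
#' @param chrom Chromosome name.
#' @param ref_pos Strictly increasing 1-based reference positions of aligned
#'   bases.
#' @param base Read base at each position (A/C/G/T/N; N for masked).
#' @param read_length Total read length (defaults to `length(ref_pos)`).
#' @return Object of class `masked_read`.
#' @export
masked_read <- function(read_id, chrom, ref_pos, base,
                        read_length = length(ref_pos)) {
  ref_pos <- as.integer(ref_pos)
  base <- toupper(as.character(base))
  stopifnot(length(ref_pos) == length(base))
  if (is.unsorted(ref_pos, strictly = TRUE))
    stop("ref_pos must be strictly increasing")
  if (!all(base %in% c("A", "C", "G", "T", "N")))
    stop("bases must be in {A,C,G,T,N}")
  structure(list(read_id = as.character(read_id), chrom = as.character(chrom),
                 ref_pos = ref_pos, base = base,
                 read_length = as.integer(read_length)),
            class = "masked_read")
}

#' Genotype one masked read against the SNP catalog
#'
#' For each catalog SNP covered by an aligned base of the read, emits `C`
#' when the base equals the parent-A allele and `L` when it equals the
#' parent-B allele. Sites where the base is `N`, equals neither allele, or
#' falls in a deletion of the read contribute no character but are counted in
#' the overlapped-SNP total.
#'
#' @param read A [masked_read()].
#' @param catalog A [snp_catalog].
#' @return One-row [genotype_strings] data.frame (empty string if the read
#'   overlaps no catalog SNP or genotypes none confidently).
#' @export
genotype_read <- function(read, catalog) {
  stopifnot(inherits(read, "masked_read"), inherits(catalog, "snp_catalog"))
  cat_ch <- catalog[catalog$chrom == read$chrom, , drop = FALSE]
  if (length(read$ref_pos) == 0L || nrow(cat_ch) == 0L)
    return(genotype_strings(read$read_id, read$chrom, "", list(integer()),
                            n_overlap = 0L, read_length = read$read_length))
  span <- range(read$ref_pos)
  overlapped <- cat_ch$pos >= span[1L] & cat_ch$pos <= span[2L]
  idx <- match(cat_ch$pos[overlapped], read$ref_pos)
  base <- ifelse(is.na(idx), "N", read$base[idx])  # deletion -> uninformative
  chars <- ifelse(base == cat_ch$allele_a[overlapped], "C",
                  ifelse(base == cat_ch$allele_b[overlapped], "L", NA))
  keep <- !is.na(chars)
  genotype_strings(read$read_id, read$chrom,
                   paste(chars[keep], collapse = ""),
                   list(cat_ch$pos[overlapped][keep]),
                   n_overlap = sum(overlapped),
                   read_length = read$read_length)
}

#' Genotype aligned reads from a SAM/BAM file
#'
#' Reads a coordinate-sorted SAM or BAM file, applies the alignment filter
#' ([filter_alignment]), masks bases below the quality threshold
#' ([mask_low_quality]) and converts every kept read into a genotype string
#' over the catalog.
#'
#' @param path SAM (plain text) or BAM file with SEQ and QUAL present.
#' @param catalog A [snp_catalog].
#' @param min_mapq,min_len,min_baseq Filtering/masking thresholds
#'   (defaults 30, 100, 14).
#' @return A [genotype_strings] data.frame with attribute `filter_stats`: a
#'   named vector of input/kept/dropped-by-reason counts.
#' @export
genotype_sam <- function(path, catalog, min_mapq = 30, min_len = 100,
                         min_baseq = 14) {
  stopifnot(inherits(catalog, "snp_catalog"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  n_in <- length(rec$qname)
  if (n_in == 0L)
    return(structure(genotype_strings(character(), character(), character(),
                                      list()),
                     filter_stats = c(input = 0L, kept = 0L)))
  qlen <- nchar(as.character(rec$seq))
  filt <- filter_alignment(rec$flag, rec$mapq, qlen,
                           min_mapq = min_mapq, min_len = min_len)
  keep <- filt$keep
  stats <- c(input = n_in, kept = sum(keep))
  if (any(!keep)) {
    tab <- table(filt$reason[!keep])
    stats <- c(stats, setNames(as.integer(tab), paste0("dropped_", names(tab))))
  }
  if (!any(keep)) {
    out <- genotype_strings(character(), character(), character(), list())
    attr(out, "filter_stats") <- stats
    return(out)
  }
  qname <- rec$qname[keep]; chrom <- as.character(rec$rname[keep])
  pos <- rec$pos[keep]; cigar <- rec$cigar[keep]
  seqs <- as.character(rec$seq)[keep]
  quals <- as.character(rec$qual)[keep]
  if (any(quals == "*" | nchar(quals) != nchar(seqs)))
    stop("base qualities missing in ", path, "; cannot genotype safely")
  seqs <- mask_low_quality(seqs, quals, min_baseq = min_baseq)

  # aligned (M/=/X) blocks in reference and query space, element-matched
  ops <- c("M", "=", "X")
  ref_blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = ops)
  qry_blocks <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cigar, ops = ops)

  out <- vector("list", length(qname))
  for (i in seq_along(qname)) {
    cat_ch <- catalog[catalog$chrom == chrom[i], , drop = FALSE]
    rl <- nchar(seqs[i])
    if (nrow(cat_ch) == 0L) {
      out[[i]] <- genotype_strings(qname[i], chrom[i], "", list(integer()),
                                   0L, rl)
      next
    }
    rb <- ref_blocks[[i]]; qb <- qry_blocks[[i]]
    rs <- BiocGenerics::start(rb); re <- BiocGenerics::end(rb)
    qs <- BiocGenerics::start(qb)
    aln_span <- c(min(rs), max(re))
    p <- cat_ch$pos
    overlapped <- p >= aln_span[1L] & p <= aln_span[2L]
    pov <- p[overlapped]
    # block index per SNP; 0/outside-block -> deletion (uninformative)
    bi <- findInterval(pov, rs)
    in_block <- bi >= 1L & pov <= re[pmax(bi, 1L)]
    off <- ifelse(in_block, qs[pmax(bi, 1L)] + (pov - rs[pmax(bi, 1L)]), NA)
    base <- rep("N", length(pov))
    if (any(in_block))
      base[in_block] <- substring(seqs[i], off[in_block], off[in_block])
    chars <- ifelse(base == cat_ch$allele_a[overlapped], "C",
                    ifelse(base == cat_ch$allele_b[overlapped], "L", NA))
    sel <- !is.na(chars)
    out[[i]] <- genotype_strings(qname[i], chrom[i],
                                 paste(chars[sel], collapse = ""),
                                 list(pov[sel]), sum(overlapped), rl)
  }
  res <- do.call(rbind, out)
  class(res) <- c("genotype_strings", "data.frame")
  attr(res, "filter_stats") <- stats
  res
}

#' Genotype an in-memory simulated pool
#'
#' The hermetic path from the simulator straight to genotype strings: the
#' simulator's alignments are exact (all-match, known coordinates), so
#' genotyping needs no alignment file round-trip. Bases recorded as
#' low-quality in the pool are treated as masked (`N`), exactly as
#' [genotype_sam()] would after quality masking.
#'
#' @param pool A `sim_pool` from [simulate_pool()].
#' @param catalog A [snp_catalog]; defaults to the pool's own catalog.
#' @return A [genotype_strings] data.frame.
#' @export
genotype_pool <- function(pool, catalog = pool$catalog) {
  stopifnot(inherits(pool, "sim_pool"), inherits(catalog, "snp_catalog"))
  reads <- pool$reads
  n <- nrow(reads)
  str_out <- character(n); pos_out <- vector("list", n)
  nov_out <- integer(n)
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    cat_ch <- catalog[catalog$chrom == ch, , drop = FALSE]
    if (nrow(cat_ch) == 0L) {
      str_out[ri] <- ""; pos_out[ri] <- list(integer())
      next
    }
    p <- cat_ch$pos; aa <- cat_ch$allele_a; ab <- cat_ch$allele_b
    starts <- reads$start[ri]; ends <- starts + reads$len[ri] - 1L
    i_lo <- findInterval(starts - 1L, p) + 1L
    i_hi <- findInterval(ends, p)
    cnt <- pmax(0L, i_hi - i_lo + 1L)
    nov_out[ri] <- cnt
    if (sum(cnt) == 0L) { str_out[ri] <- ""; pos_out[ri] <- list(integer()); next }
    rr <- rep(seq_along(ri), cnt)           # local read index per pair
    si <- sequence(cnt, from = i_lo)        # catalog index per pair
    off <- p[si] - starts[rr] + 1L
    base <- substring(pool$seq[ri][rr], off, off)
    # low-quality (masked) bases are uninformative
    low <- logical(length(rr))
    lowq <- pool$lowq[ri]
    has_low <- which(lengths(lowq) > 0L)
    if (length(has_low)) {
      pair_by_read <- split(seq_along(rr), rr)
      for (j in has_low) {
        pj <- pair_by_read[[as.character(j)]]
        if (!is.null(pj)) low[pj] <- off[pj] %in% lowq[[j]]
      }
    }
    isC <- !low & base == aa[si]
    isL <- !low & base == ab[si]
    keep <- isC | isL
    chars <- ifelse(isC, "C", "L")
    f <- factor(rr[keep], levels = seq_along(ri))
    str_out[ri] <- vapply(split(chars[keep], f), paste, character(1),
                          collapse = "")
    pos_out[ri] <- split(as.integer(p[si][keep]), f)
  }
  genotype_strings(reads$read_id, reads$chrom, str_out, pos_out,
                   n_overlap = nov_out, read_length = reads$len)
}
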