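## SNP catalog: the ordered set of biallelic parental SNPs that forms the
## coordinate backbone of read genotyping. Parent A ("Col-like") alleles are
## reported as 'C' characters downstream, parent B ("Ler-like") as 'L'.

new_snp_catalog <- function(df) {
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("snp_catalog", "data.frame")
  df
}

validate_snp_catalog <- function(df, line = NULL) {
  bases <- c("A", "C", "G", "T")
  bad <- which(!(df$allele_a %in% bases) | !(df$allele_b %in% bases))
  if (length(bad))
    stop("invalid allele at line ", line_label(bad, line),
         ": alleles must be one of A/C/G/T")
  same <- which(df$allele_a == df$allele_b)
  if (length(same))
    stop("allele_a == allele_b at line ", line_label(same, line),
         ": catalog SNPs must be biallelic")
  if (any(df$pos < 1L))
    stop("SNP positions must be >= 1 (1-based coordinates)")
  key <- paste(df$chrom, df$pos)
  dupd <- duplicated(key)
  if (any(dupd)) {
    # duplicates are tolerated when they agree; conflicting alleles are an error
    for (k in unique(key[dupd])) {
      rows <- df[key == k, c("allele_a", "allele_b")]
      if (nrow(unique(rows)) > 1L)
        stop("conflicting alleles for duplicated SNP at ", k)
    }
    df <- df[!dupd, , drop = FALSE]
  }
  df
}

line_label <- function(rows, line) {
  if (is.null(line)) paste(rows, collapse = ", ")
  else paste(line[rows], collapse = ", ")
}

#' Load a biallelic SNP table
#'
#' Reads a tab-separated SNP table (columns chromosome, 1-based position,
#' parent-A allele, parent-B allele), validates it and returns a sorted,
#' deduplicated catalog. Duplicated (chrom, pos) rows with identical alleles
#' are collapsed; conflicting duplicates are rejected.
#'
#' @param path TSV file. Header lines starting with `#` are skipped.
#' @param columns Integer or character vector of length 4 naming/locating the
#'   CHROM, POS, ALLELE_A, ALLELE_B columns (default first four columns).
#' @return A `snp_catalog`: data.frame with columns `chrom`, `pos`,
#'   `allele_a`, `allele_b`, sorted by (chrom, pos).
#' @seealso [curate_snp_candidates()], [snp_span_track()]
#' @export
read_snp_table <- function(path, columns = 1:4) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty SNP table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < max(if (is.numeric(columns)) columns else 4L))
  if (length(short))
    stop("malformed SNP table row at line ", lineno[short[1L]],
         " of ", path, " (need >= 4 tab-separated columns)")
  get_col <- function(i) vapply(parts, `[[`, "", i)
  if (is.character(columns)) {
    hdr <- parts[[1L]]
    idx <- match(columns, hdr)
    if (anyNA(idx)) stop("columns not found in header: ",
                         paste(columns[is.na(idx)], collapse = ", "))
    parts <- parts[-1L]; lineno <- lineno[-1L]
    columns <- idx
  }
  pos <- suppressWarnings(as.integer(get_col(columns[2L])))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("non-numeric position at line ", lineno[bad[1L]], " of ", path)
  df <- data.frame(
    chrom = get_col(columns[1L]),
    pos = pos,
    allele_a = toupper(get_col(columns[3L])),
    allele_b = toupper(get_col(columns[4L])),
    stringsAsFactors = FALSE
  )
  df <- validate_snp_catalog(df, line = lineno)
  new_snp_catalog(df)
}

#' Build a SNP catalog from vectors
#'
#' Programmatic constructor used by the simulator and in tests.
#'
#' @param chrom,pos,allele_a,allele_b Parallel vectors of chromosome, 1-based
#'   position and the two parental alleles.
#' @return A `snp_catalog`.
#' @export
snp_catalog <- function(chrom, pos, allele_a, allele_b) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   allele_a = toupper(allele_a), allele_b = toupper(allele_b),
                   stringsAsFactors = FALSE)
  new_snp_catalog(validate_snp_catalog(df))
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat("SNP catalog:", nrow(x), "SNPs on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (nrow(x)) {
    per <- table(x$chrom)
    cat(paste0("  ", names(per), ": ", as.integer(per), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Merge two SNP catalogs
#'
#' Set-union of two catalogs; a position present in both with different
#' alleles is a conflict and is rejected.
#'
#' @param a,b `snp_catalog` objects.
#' @return Merged `snp_catalog`.
#' @export
merge_snp_catalogs <- function(a, b) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  new_snp_catalog(validate_snp_catalog(df))
}

#' Read an F2 genotype matrix
#'
#' Rows are individuals, columns candidate SNPs; cells are 0 (homozygous
#' parent A), 1 (heterozygous), 2 (homozygous parent B) or NA (missing).
#'
#' @param path TSV with individual IDs in the first column and a header row of
#'   SNP identifiers.
#' @return Integer matrix with individual rownames and SNP colnames.
#' @export
read_genotype_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, row.names = 1L,
                   check.names = FALSE, na.strings = c("NA", "."))
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  bad <- m[!is.na(m) & !(m %in% 0:2)]
  if (length(bad)) stop("genotype matrix cells must be 0/1/2/NA")
  m
}

#' Curate candidate SNPs against F2 segregation data
#'
#' A candidate SNP is retained when (1) it has genotype calls in at least
#' `min_genotyped` individuals, (2) its B-allele frequency (heterozygotes
#' counted as 1/2) lies within `[af_low, af_high]` inclusive, and (3) the
#' (homA, het, homB) counts are compatible with 1:2:1 Mendelian segregation
#' by a Pearson chi-square goodness-of-fit test (2 df, no continuity
#' correction) at `P > seg_p`.
#'
#' @param matrix Genotype matrix as from [read_genotype_matrix()]: individuals
#'   in rows, SNPs in columns, cells 0/1/2/NA.
#' @param min_genotyped Minimum number of non-missing calls (default 40).
#' @param af_low,af_high Inclusive allele-frequency bounds (default 0.4, 0.6).
#' @param seg_p Segregation P-value threshold: SNPs with P <= `seg_p` are
#'   removed (default 0.1).
#' @return data.frame, one row per SNP column: `snp`, `n_genotyped`, `af`,
#'   `seg_p`, `kept`, `reason` (`""` when kept; otherwise the first failing
#'   criterion among `"min_genotyped"`, `"allele_frequency"`,
#'   `"segregation"`).
#' @export
curate_snp_candidates <- function(matrix, min_genotyped = 40,
                                  af_low = 0.4, af_high = 0.6, seg_p = 0.1) {
  if (!is.matrix(matrix) || ncol(matrix) == 0L)
    stop("genotype matrix must be a non-empty matrix")
  stopifnot(min_genotyped >= 0, af_low <= af_high, seg_p >= 0, seg_p <= 1)
  n0 <- colSums(matrix == 0L, na.rm = TRUE)
  n1 <- colSums(matrix == 1L, na.rm = TRUE)
  n2 <- colSums(matrix == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  af <- ifelse(n > 0, (n1 / 2 + n2) / n, NA_real_)
  exp_p <- c(0.25, 0.5, 0.25)
  stat <- vapply(seq_len(ncol(matrix)), function(j) {
    if (n[j] == 0L) return(NA_real_)
    obs <- c(n0[j], n1[j], n2[j])
    sum((obs - n[j] * exp_p)^2 / (n[j] * exp_p))
  }, numeric(1))
  pval <- pchisq(stat, df = 2L, lower.tail = FALSE)
  reason <- character(ncol(matrix))
  reason[!is.na(pval) & pval <= seg_p] <- "segregation"
  reason[is.na(af) | af < af_low | af > af_high] <- "allele_frequency"
  reason[n < min_genotyped] <- "min_genotyped"
  reason[n == 0L] <- "insufficient genotyping"
  data.frame(
    snp = colnames(matrix) %||% as.character(seq_len(ncol(matrix))),
    n_genotyped = as.integer(n),
    af = af,
    seg_p = pval,
    kept = reason == "",
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-SNP span track and low-density masks
#'
#' Computes, for each window of `k` consecutive catalog SNPs, the genomic span
#' `pos(i+k-1) - pos(i)` (the "8-SNP span" for the default `k = 8`): a local
#' SNP-density measure that governs caller sensitivity. Also emits the mask of
#' genomic intervals where the distance between consecutive SNPs exceeds
#' `max_inter_snp` (these regions are excluded from landscape analyses).
#'
#' @param catalog A [snp_catalog].
#' @param max_inter_snp Gap threshold in bp (default 4000).
#' @param k Window size in SNPs (default 8).
#' @return List of class `span_track` with elements
#'   \describe{
#'     \item{spans}{data.frame `chrom`, `start`, `end` (1-based SNP positions
#'       bounding the window) and `span` (bp).}
#'     \item{mask}{data.frame of 0-based half-open intervals covering every
#'       inter-SNP gap larger than `max_inter_snp`.}
#'     \item{skipped}{chromosomes with fewer than `k` SNPs (no spans there).}
#'   }
#' @export
snp_span_track <- function(catalog, max_inter_snp = 4000, k = 8) {
  stopifnot(inherits(catalog, "snp_catalog"), k >= 2, max_inter_snp > 0)
  spans <- list(); masks <- list(); skipped <- character()
  for (ch in unique(catalog$chrom)) {
    pos <- catalog$pos[catalog$chrom == ch]
    gaps <- diff(pos)
    big <- which(gaps > max_inter_snp)
    if (length(big)) {
      # half-open genomic interval between the two flanking SNPs: (p1, p2]
      masks[[ch]] <- data.frame(chrom = ch, start = pos[big],
                                end = pos[big + 1L],
                                stringsAsFactors = FALSE)
    }
    if (length(pos) < k) {
      skipped <- c(skipped, ch)
      message("span track: chromosome ", ch, " has fewer than ", k,
              " SNPs; spans undefined there")
      next
    }
    i <- seq_len(length(pos) - k + 1L)
    spans[[ch]] <- data.frame(chrom = ch, start = pos[i],
                              end = pos[i + k - 1L],
                              span = pos[i + k - 1L] - pos[i],
                              stringsAsFactors = FALSE)
  }
  spans <- if (length(spans)) do.call(rbind, spans) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               span = integer())
  mask <- if (length(masks)) reduce_intervals(do.call(rbind, masks)) else
    empty_intervals()
  rownames(spans) <- NULL
  structure(list(spans = spans, mask = mask, k = k,
                 max_inter_snp = max_inter_snp, skipped = skipped),
            class = "span_track")
}

#' @export
print.span_track <- function(x, ...) {
  cat("SNP span track: k =", x$k, "|", nrow(x$spans), "windows |",
      nrow(x$mask), "masked gap(s) >", x$max_inter_snp, "bp\n")
  invisible(x)
}

#' Span class of genomic loci
#'
#' The span value of a locus is the minimum span of any k-SNP window that
#' contains it; loci covered by no window get NA.
#'
#' @param track A [snp_span_track()] result.
#' @param chrom,pos Parallel vectors of loci (1-based).
#' @return Numeric vector of span values (bp).
#' @export
span_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  sp <- track$spans
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    sd <- sp[sp$chrom == ch, , drop = FALSE]
    if (nrow(sd) == 0L) next
    q <- IRanges::IRanges(start = pos[qi], width = 1L)
    s <- IRanges::IRanges(start = sd$start, end = sd$end)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    mins <- tapply(sd$span[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), min)
    out[qi[as.integer(names(mins))]] <- as.numeric(mins)
  }
  out
}
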