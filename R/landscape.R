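## Genome- and gene-scale crossover statistics: binned relative rates with
## per-bin Fisher tests and FDR, TSS/TES metaprofiles, SNP-density profiles
## around crossover midpoints, inter-SNP distances at crossover sites, and
## SNP-span region classes.

## Extract crossover midpoints (chrom, midpoint) from calls or a data.frame.
co_midpoints <- function(calls) {
  if (inherits(calls, "read_calls"))
    return(calls$breakpoints[, c("chrom", "midpoint")])
  if (inherits(calls, "crossover_events")) {
    ev <- calls$events
    return(data.frame(chrom = ev$chrom, midpoint = (ev$start + ev$end) / 2))
  }
  stopifnot(is.data.frame(calls), all(c("chrom", "midpoint") %in% names(calls)))
  calls[, c("chrom", "midpoint")]
}

## Remove midpoints falling inside any mask interval (0-based half-open).
apply_masks <- function(mid, masks) {
  if (is.null(masks)) return(mid)
  if (inherits(masks, "span_track")) masks <- masks$mask
  if (is.list(masks) && !is.data.frame(masks))
    masks <- do.call(rbind, lapply(masks, function(m)
      as.data.frame(if (inherits(m, "span_track")) m$mask else m)[,
        c("chrom", "start", "end")]))
  if (nrow(masks) == 0L) return(mid)
  hit <- overlaps_any(data.frame(chrom = mid$chrom,
                                 start = floor(mid$midpoint) - 1,
                                 end = floor(mid$midpoint)),
                      masks)
  mid[!hit, , drop = FALSE]
}

#' Binned comparison of two crossover landscapes
#'
#' Tiles the genome into fixed-width bins, counts crossover midpoints of the
#' two datasets per bin, and tests each bin's 2x2 table (in-bin vs elsewhere,
#' dataset A vs B) with a two-sided Fisher's exact test. P-values are
#' corrected across bins by Benjamini-Hochberg; bins with FDR `q < fdr` are
#' flagged. Relative frequencies (count / dataset total) are reported per
#' bin.
#'
#' @param calls_a,calls_b `read_calls` objects (or data.frames with `chrom`
#'   and `midpoint`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin Bin width in bp (default 100000).
#' @param masks Optional mask intervals (blacklist, span-track mask, or a
#'   list of both): midpoints inside masked regions are dropped before
#'   counting.
#' @param fdr FDR threshold for flagging (default 0.05).
#' @return data.frame of class `bin_table`: per bin `chrom`, `start`, `end`,
#'   `count_a`, `count_b`, `freq_a`, `freq_b`, `p`, `q`, `flagged`.
#' @export
binned_comparison <- function(calls_a, calls_b, chrom_lengths, bin = 100000,
                              masks = NULL, fdr = 0.05) {
  a <- apply_masks(co_midpoints(calls_a), masks)
  b <- apply_masks(co_midpoints(calls_b), masks)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both datasets must contain crossovers after masking")
  bins <- tile_genome(chrom_lengths, bin)
  bins$count_a <- count_in_bins(a, bins, bin)
  bins$count_b <- count_in_bins(b, bins, bin)
  tot_a <- sum(bins$count_a); tot_b <- sum(bins$count_b)
  bins$freq_a <- bins$count_a / tot_a
  bins$freq_b <- bins$count_b / tot_b
  bins$p <- vapply(seq_len(nrow(bins)), function(i) {
    m <- matrix(c(bins$count_a[i], tot_a - bins$count_a[i],
                  bins$count_b[i], tot_b - bins$count_b[i]), nrow = 2L)
    fisher.test(m)$p.value
  }, numeric(1))
  bins$q <- p.adjust(bins$p, method = "BH")
  bins$flagged <- bins$q < fdr
  class(bins) <- c("bin_table", "data.frame")
  bins
}

tile_genome <- function(chrom_lengths, bin) {
  stopifnot(!is.null(names(chrom_lengths)), bin > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    nb <- ceiling(L / bin)
    data.frame(chrom = ch, start = (seq_len(nb) - 1L) * bin,
               end = pmin(seq_len(nb) * bin, L), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

count_in_bins <- function(mid, bins, bin) {
  cnt <- integer(nrow(bins))
  for (ch in unique(mid$chrom)) {
    bi <- which(bins$chrom == ch)
    if (!length(bi)) next
    idx <- floor((mid$midpoint[mid$chrom == ch] - 1) / bin) + 1L
    idx <- idx[idx >= 1L & idx <= length(bi)]
    t <- tabulate(idx, nbins = length(bi))
    cnt[bi] <- cnt[bi] + t
  }
  cnt
}

#' Correlation between two binned crossover landscapes
#'
#' Pearson correlation between per-bin crossover counts of two datasets, with
#' the standard t-based test.
#'
#' @inheritParams binned_comparison
#' @param bin Bin width in bp (default 1e6).
#' @return List with `r`, `p`, `n_bins`, and the per-bin counts.
#' @export
correlate_bins <- function(calls_a, calls_b, chrom_lengths, bin = 1e6,
                           masks = NULL) {
  a <- apply_masks(co_midpoints(calls_a), masks)
  b <- apply_masks(co_midpoints(calls_b), masks)
  bins <- tile_genome(chrom_lengths, bin)
  if (nrow(bins) < 3L) stop("need at least 3 bins")
  ca <- count_in_bins(a, bins, bin)
  cb <- count_in_bins(b, bins, bin)
  if (sd(ca) == 0 || sd(cb) == 0)
    stop("zero variance in binned counts; correlation undefined")
  ct <- cor.test(ca, cb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = nrow(bins),
       count_a = ca, count_b = cb)
}

#' Metaprofile of crossover midpoints around gene anchors
#'
#' Assigns each crossover midpoint to its strand-oriented offset from every
#' anchor (TSS or TES) within `half_width` bp, bins the offsets, and
#' normalizes per anchor. For minus-strand anchors the offset sign is flipped
#' so that negative offsets are always biologically upstream. Optionally
#' computes a matched profile from an equal number of uniform random
#' positions on the analyzed genome.
#'
#' @param calls `read_calls` (or data.frame with `chrom`, `midpoint`).
#' @param anchors data.frame with `chrom`, `pos` (1-based anchor position)
#'   and `strand` (`"+"`/`"-"`).
#' @param half_width Window half-width in bp (default 2000).
#' @param binwidth Bin width in bp (default 100).
#' @param chrom_lengths Named chromosome lengths; required when
#'   `random_matched = TRUE`.
#' @param random_matched Also compute a random-site baseline profile?
#' @param seed Seed for the random baseline (recorded in the result).
#' @return List of class `metaprofile`: `offsets` (bin centers), `rate`
#'   (per-bin midpoint count / number of anchors), `random_rate` (or NULL),
#'   `n_anchors`, `n_sites`, `seed`.
#' @export
metaprofile <- function(calls, anchors, half_width = 2000, binwidth = 100,
                        chrom_lengths = NULL, random_matched = FALSE,
                        seed = 1L) {
  if (nrow(anchors) == 0L) stop("anchors must be non-empty")
  stopifnot(all(c("chrom", "pos", "strand") %in% names(anchors)),
            all(anchors$strand %in% c("+", "-")))
  mid <- co_midpoints(calls)
  nb <- ceiling(2 * half_width / binwidth)
  profile_of <- function(mid) {
    counts <- numeric(nb)
    for (ch in unique(anchors$chrom)) {
      ai <- which(anchors$chrom == ch)
      mp <- mid$midpoint[mid$chrom == ch]
      if (!length(mp)) next
      q <- IRanges::IRanges(start = anchors$pos[ai] - half_width,
                            end = anchors$pos[ai] + half_width)
      s <- IRanges::IRanges(start = as.integer(floor(mp)), width = 1L)
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      a_idx <- ai[S4Vectors::queryHits(hits)]
      off <- mp[S4Vectors::subjectHits(hits)] - anchors$pos[a_idx]
      off <- ifelse(anchors$strand[a_idx] == "-", -off, off)
      k <- floor((off + half_width) / binwidth) + 1L
      k[k > nb] <- nb
      k <- k[k >= 1L]
      counts <- counts + tabulate(k, nbins = nb)
    }
    counts / nrow(anchors)
  }
  rate <- profile_of(mid)
  random_rate <- NULL
  if (random_matched) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths required for the random baseline")
    rnd <- with_seed(seed, random_sites(nrow(mid), chrom_lengths))
    random_rate <- profile_of(rnd)
  }
  offsets <- -half_width + (seq_len(nb) - 0.5) * binwidth
  structure(list(offsets = offsets, rate = rate, random_rate = random_rate,
                 n_anchors = nrow(anchors), n_sites = nrow(mid), seed = seed),
            class = "metaprofile")
}

random_sites <- function(n, chrom_lengths, masks = NULL) {
  ch <- sample(names(chrom_lengths), n, replace = TRUE,
               prob = as.numeric(chrom_lengths))
  pos <- floor(runif(n, min = 1, max = as.numeric(chrom_lengths[ch]) + 1))
  df <- data.frame(chrom = ch, midpoint = pos, stringsAsFactors = FALSE)
  if (!is.null(masks)) df <- apply_masks(df, masks)
  df
}

#' SNP density around crossover midpoints
#'
#' Counts catalog SNPs in fixed-width bins within a window centered on each
#' crossover midpoint and reports the mean per-bin SNP count across windows.
#' A companion profile at an equal number of uniform random positions is
#' computed, and SNP density is compared between crossover and random windows
#' by a two-sided Wilcoxon rank-sum test in coarser test bins.
#'
#' @param calls `read_calls` (or data.frame with `chrom`, `midpoint`).
#' @param catalog A [snp_catalog].
#' @param window Window width in bp (default 4000, i.e. +/- 2 kb).
#' @param binwidth Profile bin width in bp (default 10).
#' @param test_binwidth Bin width for the per-bin Wilcoxon tests (default
#'   40).
#' @param chrom_lengths Named chromosome lengths for the random baseline;
#'   when NULL, random positions are drawn from the span of the catalog.
#' @param seed Seed for the random baseline.
#' @return List of class `snp_density_profile`: `offsets`, `density` (mean
#'   SNPs per bin), `random_density`, `test` (data.frame of test-bin offsets
#'   and Wilcoxon P-values), `n_windows`.
#' @export
snp_density_around <- function(calls, catalog, window = 4000, binwidth = 10,
                               test_binwidth = 40, chrom_lengths = NULL,
                               seed = 1L) {
  mid <- co_midpoints(calls)
  if (nrow(mid) == 0L) stop("no crossover midpoints")
  stopifnot(inherits(catalog, "snp_catalog"))
  half <- window / 2
  nb <- ceiling(window / binwidth)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(catalog$pos, catalog$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  window_matrix <- function(mid) {
    m <- matrix(0L, nrow = nrow(mid), ncol = nb)
    for (ch in unique(mid$chrom)) {
      wi <- which(mid$chrom == ch)
      p <- catalog$pos[catalog$chrom == ch]
      if (!length(p)) next
      for (w in wi) {
        lo <- mid$midpoint[w] - half
        sel <- p > lo & p <= lo + window
        if (!any(sel)) next
        k <- ceiling((p[sel] - lo) / binwidth)
        k[k < 1L] <- 1L; k[k > nb] <- nb
        m[w, ] <- m[w, ] + tabulate(k, nbins = nb)
      }
    }
    m
  }
  mat <- window_matrix(mid)
  rnd <- with_seed(seed, random_sites(nrow(mid), chrom_lengths))
  rmat <- window_matrix(rnd)
  # coarser bins for testing
  fold <- max(1L, as.integer(test_binwidth / binwidth))
  grp <- (seq_len(nb) - 1L) %/% fold
  coarse <- function(m) t(apply(m, 1L, function(r) tapply(r, grp, sum)))
  cm <- coarse(mat); crm <- coarse(rmat)
  pvals <- vapply(seq_len(ncol(cm)), function(j) {
    if (all(cm[, j] == crm[, j])) return(1)
    suppressWarnings(wilcox.test(cm[, j], crm[, j])$p.value)
  }, numeric(1))
  offsets <- -half + (seq_len(nb) - 0.5) * binwidth
  test_off <- tapply(offsets, grp, mean)
  structure(list(offsets = offsets, density = colMeans(mat),
                 random_density = colMeans(rmat),
                 test = data.frame(offset = as.numeric(test_off), p = pvals),
                 n_windows = nrow(mid), seed = seed),
            class = "snp_density_profile")
}

#' Inter-SNP distance at crossover sites
#'
#' For each crossover read, the distance between the two catalog SNPs
#' flanking its breakpoint: the physical resolution of that crossover call.
#' Optionally compares two call sets by a two-sided Wilcoxon rank-sum test.
#'
#' @param calls A `read_calls` object.
#' @param catalog A [snp_catalog]; breakpoints whose bounds are not catalog
#'   positions are skipped with a warning.
#' @param other Optional second `read_calls` for comparison.
#' @return List of class `inter_snp_distance`: `distances`, `median`, and
#'   when `other` is given `distances_other`, `median_other`, `p` (Wilcoxon).
#' @export
inter_snp_distance_at_sites <- function(calls, catalog, other = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  dist_of <- function(x) {
    bp <- if (inherits(x, "read_calls")) x$breakpoints else x
    if (nrow(bp) == 0L) return(numeric())
    ok <- vapply(seq_len(nrow(bp)), function(i) {
      p <- catalog$pos[catalog$chrom == bp$chrom[i]]
      bp$bp_start[i] %in% p && bp$bp_end[i] %in% p
    }, logical(1))
    if (any(!ok))
      warning(sum(!ok), " breakpoint(s) not bounded by catalog SNPs; skipped")
    bp$bp_end[ok] - bp$bp_start[ok]
  }
  d1 <- dist_of(calls)
  out <- list(distances = d1, median = median(d1))
  if (!is.null(other)) {
    d2 <- dist_of(other)
    out$distances_other <- d2
    out$median_other <- median(d2)
    out$p <- if (length(d1) && length(d2))
      suppressWarnings(wilcox.test(d1, d2)$p.value) else NA_real_
  }
  structure(out, class = "inter_snp_distance")
}

#' Classify crossovers by local SNP-density (span) class
#'
#' Assigns each crossover midpoint the span class of its locus (minimum
#' k-SNP window span covering it; see [snp_span_track()]) and tabulates the
#' counts per class.
#'
#' @param calls `read_calls` (or data.frame with `chrom`, `midpoint`).
#' @param span_track A [snp_span_track()].
#' @param breaks Span-class boundaries in bp (default `c(4000, 10000)`).
#' @return Table of counts per span class (including `"unassigned"` for
#'   midpoints outside the span track).
#' @export
classify_by_span <- function(calls, span_track, breaks = c(4000, 10000)) {
  mid <- co_midpoints(calls)
  labels <- c(paste0("<=", breaks[1L]),
              if (length(breaks) > 1L)
                paste0(breaks[-length(breaks)] + 1L, "-", breaks[-1L]),
              paste0(">", breaks[length(breaks)]))
  if (nrow(mid) == 0L)
    return(table(factor(character(), levels = c(labels, "unassigned"))))
  sp <- span_at(span_track, mid$chrom, round(mid$midpoint))
  cls <- as.character(cut(sp, breaks = c(0, breaks, Inf), labels = labels))
  cls[is.na(cls)] <- "unassigned"
  table(factor(cls, levels = c(labels, "unassigned")))
}

#' Read gene anchors (TSS/TES) from GFF3 or BED6
#'
#' @param path GFF3 (`gene` features used) or BED6 file; strand required.
#' @param anchor `"TSS"` or `"TES"`.
#' @return data.frame with `chrom`, `pos` (1-based anchor), `strand`.
#' @export
read_anchors <- function(path, anchor = c("TSS", "TES")) {
  anchor <- match.arg(anchor)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (all(nc >= 9L)) {        # GFF3: 1-based inclusive, strand col 7
    type <- vapply(parts, `[[`, "", 3L)
    parts <- parts[type == "gene"]
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- as.integer(vapply(parts, `[[`, "", 4L))
    end <- as.integer(vapply(parts, `[[`, "", 5L))
    strand <- vapply(parts, `[[`, "", 7L)
  } else if (all(nc >= 6L)) { # BED6: 0-based half-open, strand col 6
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- as.integer(vapply(parts, `[[`, "", 2L)) + 1L
    end <- as.integer(vapply(parts, `[[`, "", 3L))
    strand <- vapply(parts, `[[`, "", 6L)
  } else stop("anchors must be GFF3 (9 cols) or BED6 (6 cols)")
  if (!all(strand %in% c("+", "-"))) stop("strand required for anchors")
  pos <- if (anchor == "TSS") ifelse(strand == "+", start, end)
         else ifelse(strand == "+", end, start)
  data.frame(chrom = chrom, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}
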