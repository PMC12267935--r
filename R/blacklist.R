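## Exclusion regions: depth outliers (collapsed repeats, organellar inserts)
## and loci that repeatedly produce crossover calls in a somatic negative
## control, where no meiotic crossovers can exist.

new_blacklist <- function(df) {
  if (nrow(df) == 0L) {
    df <- empty_intervals("source")
  } else {
    parts <- lapply(split(df, df$source), function(d) {
      r <- reduce_intervals(d)
      r$source <- d$source[1L]
      r
    })
    df <- do.call(rbind, parts)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("blacklist", "data.frame")
  df
}

#' Construct a blacklist from intervals
#'
#' @param chrom,start,end Interval vectors, 0-based half-open.
#' @param source Source tag per interval: `"depth"`, `"negative_control"` or
#'   `"user"`.
#' @return A `blacklist` data.frame, sorted with overlapping intervals of the
#'   same source merged.
#' @export
blacklist <- function(chrom = character(), start = integer(),
                      end = integer(), source = "user") {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   source = rep_len(as.character(source), length(chrom)),
                   stringsAsFactors = FALSE)
  new_blacklist(df)
}

#' Combine blacklists
#'
#' @param ... `blacklist` objects.
#' @return Combined `blacklist` (intervals merged within each source tag).
#' @export
merge_blacklists <- function(...) {
  new_blacklist(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Binned read-depth profile
#'
#' Per-base coverage aggregated in fixed-width bins; the bin mean is used for
#' depth-outlier detection. Bins rather than single bases are used because
#' depth excursions of interest (collapsed repeats, organellar insertions)
#' extend over kilobases.
#'
#' @param chrom,start,len Aligned read coordinates (1-based start) and
#'   lengths.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param binwidth Bin width in bp (default 10000).
#' @return data.frame of class `depth_profile`: `chrom`, `start`, `end`
#'   (0-based half-open bins), `depth` (mean per-base coverage in bin), with
#'   attribute `mean_depth` (genome-wide mean over analyzed bins).
#' @export
compute_depth <- function(chrom, start, len, chrom_lengths, binwidth = 10000) {
  stopifnot(length(chrom) == length(start), length(start) == length(len),
            !is.null(names(chrom_lengths)))
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    nb <- ceiling(L / binwidth)
    cov_bp <- numeric(nb)
    ri <- which(chrom == ch)
    if (length(ri)) {
      s <- pmax(start[ri], 1L); e <- pmin(start[ri] + len[ri] - 1L, L)
      # distribute each read's bases over the bins it spans
      for (i in seq_along(ri)) {
        b1 <- (s[i] - 1L) %/% binwidth; b2 <- (e[i] - 1L) %/% binwidth
        if (b1 == b2) {
          cov_bp[b1 + 1L] <- cov_bp[b1 + 1L] + (e[i] - s[i] + 1L)
        } else {
          bins <- b1:b2
          lo <- pmax(s[i], bins * binwidth + 1L)
          hi <- pmin(e[i], (bins + 1L) * binwidth)
          cov_bp[bins + 1L] <- cov_bp[bins + 1L] + (hi - lo + 1L)
        }
      }
    }
    width <- pmin(seq_len(nb) * binwidth, L) - (seq_len(nb) - 1L) * binwidth
    out[[ch]] <- data.frame(chrom = ch,
                            start = (seq_len(nb) - 1L) * binwidth,
                            end = pmin(seq_len(nb) * binwidth, L),
                            depth = cov_bp / width,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "mean_depth") <- mean(df$depth)
  class(df) <- c("depth_profile", "data.frame")
  df
}

#' Depth-outlier blacklist
#'
#' Flags bins whose depth exceeds `fold` times the genome-wide mean depth and
#' merges adjacent flagged bins into intervals.
#'
#' @param profile A [compute_depth()] result (or data.frame with `chrom`,
#'   `start`, `end`, `depth`).
#' @param fold Multiplier over the genome mean (default 3).
#' @return A `blacklist` with source `"depth"`.
#' @export
depth_blacklist <- function(profile, fold = 3) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0L)
  mean_depth <- attr(profile, "mean_depth") %||% mean(profile$depth)
  if (mean_depth == 0) stop("no coverage in depth profile")
  hot <- profile[profile$depth > fold * mean_depth, , drop = FALSE]
  if (nrow(hot) == 0L) return(blacklist(source = "depth"))
  bl <- reduce_intervals(hot[, c("chrom", "start", "end")])
  blacklist(bl$chrom, bl$start, bl$end, source = "depth")
}

#' Negative-control false-positive blacklist
#'
#' In a somatic (e.g. hybrid leaf) control pool, meiotic crossovers cannot
#' exist, so clustered crossover calls mark artifact-prone loci. Breakpoint
#' intervals within `merge_window` bp of each other are clustered; clusters
#' supported by at least `min_fp` control calls become blacklist intervals.
#' A single isolated control call is not blacklisted: it is indistinguishable
#' from rare mitotic recombination.
#'
#' @param control_calls A `read_calls` object from the control pool (or its
#'   breakpoints data.frame).
#' @param min_fp Minimum clustered control calls (default 2).
#' @param merge_window Clustering window in bp (default 2000).
#' @return A `blacklist` with source `"negative_control"`.
#' @export
negative_control_blacklist <- function(control_calls, min_fp = 2,
                                       merge_window = 2000) {
  bp <- if (inherits(control_calls, "read_calls")) control_calls$breakpoints
        else control_calls
  if (is.null(bp) || nrow(bp) == 0L)
    return(blacklist(source = "negative_control"))
  out <- list()
  for (ch in unique(bp$chrom)) {
    d <- bp[bp$chrom == ch, , drop = FALSE]
    d <- d[order(d$bp_start), , drop = FALSE]
    # cluster breakpoints whose windows (expanded by merge_window/2) overlap
    half <- merge_window / 2
    s <- d$bp_start - half; e <- d$bp_end + half
    cummax_e <- cummax(e)
    cluster <- cumsum(c(TRUE, s[-1L] > cummax_e[-length(e)]))
    for (cl in split(seq_len(nrow(d)), cluster)) {
      if (length(cl) < min_fp) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(d$bp_start[cl]), end = max(d$bp_end[cl]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(blacklist(source = "negative_control"))
  df <- do.call(rbind, out)
  blacklist(df$chrom, df$start, df$end, source = "negative_control")
}

#' Read a blacklist from BED
#'
#' @param path BED file (0-based half-open); column 4, when present, is the
#'   source tag.
#' @return A `blacklist`.
#' @export
read_blacklist <- function(path) {
  df <- read_bed(path)
  src <- df$name %||% "user"
  if (nrow(df) == 0L) return(blacklist())
  blacklist(df$chrom, df$start, df$end, source = src)
}

#' Write a blacklist as BED
#'
#' @param x A `blacklist`.
#' @param path Output path (columns chrom, start, end, source).
#' @return `path`, invisibly.
#' @export
write_blacklist <- function(x, path) {
  write_bed(as.data.frame(x)[, c("chrom", "start", "end", "source")], path)
}
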