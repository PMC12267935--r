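## Genotype-string classification: the crossover-calling rule family.
##
## A genotype string is the ordered sequence of parental calls ('C'/'L') at
## catalog SNPs covered by one read. Classification works on the run-length
## structure of the string:
##   * too short (< min_snps characters)                     -> excluded
##   * both end runs >= end_run and both ends same parent    -> parental
##   * ends differ, exactly one switch, both runs >= flank   -> SCO
##   * ends differ, >= 2 switches, outer runs >= flank and
##     interior tracts >= complex_min_tract (complex models) -> CCO
##   * anything else                                         -> excluded

#' Construct a genotype-string set
#'
#' @param read_id,chrom Per-read identifiers.
#' @param string Character vector of genotype strings over `{C, L}`.
#' @param positions List of integer vectors: the 1-based genomic positions of
#'   the string characters (parallel to `string`).
#' @param n_overlap Number of catalog SNPs overlapped by the read, including
#'   sites dropped as N/ambiguous (defaults to `nchar(string)`).
#' @param read_length Aligned read length in bases.
#' @return data.frame of class `genotype_strings`.
#' @export
genotype_strings <- function(read_id, chrom, string, positions,
                             n_overlap = nchar(string),
                             read_length = NA_integer_) {
  stopifnot(length(read_id) == length(string),
            length(positions) == length(string))
  chrom <- rep_len(as.character(chrom), length(string))
  read_length <- rep_len(as.integer(read_length), length(string))
  n_overlap <- rep_len(as.integer(n_overlap), length(string))
  ok <- !grepl("[^CL]", string)
  if (!all(ok))
    stop("genotype strings may contain only 'C' and 'L' characters")
  if (any(nchar(string) != lengths(positions)))
    stop("string length and position count differ")
  df <- data.frame(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   string = as.character(string),
                   n_overlap = as.integer(n_overlap),
                   read_length = as.integer(read_length),
                   stringsAsFactors = FALSE)
  df$positions <- lapply(positions, as.integer)
  class(df) <- c("genotype_strings", "data.frame")
  df
}

## Classify one string given its run-length encoding.
## Returns list(class, reason, cuts) where cuts are the character indices
## after which a reported switch occurs.
classify_runs <- function(lens, first_char, model) {
  n <- sum(lens)
  if (n < model$min_snps)
    return(list(class = "excluded", reason = "too_few_snps", cuts = integer()))
  k <- length(lens)
  if (lens[1L] < model$end_run || lens[k] < model$end_run)
    return(list(class = "excluded", reason = "ambiguous", cuts = integer()))
  ends_same <- (k %% 2L) == 1L   # odd number of runs: both ends same parent
  if (ends_same) {
    if (model$ends_same_cco && k >= 3L &&
        lens[1L] >= model$flank_run && lens[k] >= model$flank_run &&
        all(lens[2:(k - 1L)] >= model$complex_min_tract) &&
        (k - 1L) <= model$complex_max_switches)
      return(list(class = "CCO", reason = "", cuts = cumsum(lens)[-k]))
    cls <- if (first_char == "C") "parental_C" else "parental_L"
    return(list(class = cls, reason = "", cuts = integer()))
  }
  # ends differ: crossover candidate
  if (k == 2L) {
    if (lens[1L] >= model$flank_run && lens[2L] >= model$flank_run)
      return(list(class = "SCO", reason = "", cuts = lens[1L]))
    return(list(class = "excluded", reason = "ambiguous", cuts = integer()))
  }
  if (model$allow_complex &&
      lens[1L] >= model$flank_run && lens[k] >= model$flank_run &&
      all(lens[2:(k - 1L)] >= model$complex_min_tract) &&
      (k - 1L) <= model$complex_max_switches)
    return(list(class = "CCO", reason = "", cuts = cumsum(lens)[-k]))
  list(class = "excluded", reason = "ambiguous", cuts = integer())
}

#' Classify a single genotype string
#'
#' @param string A genotype string over `{C, L}`.
#' @param model A [model_spec] (or shipped model name).
#' @param positions Optional integer vector of SNP genomic positions; when
#'   given, breakpoint intervals are reported.
#' @return List with `class` (`parental_C`, `parental_L`, `SCO`, `CCO` or
#'   `excluded`), `reason` (non-empty for exclusions), and `breakpoints`: a
#'   data.frame with one row per switch giving `bp_start`/`bp_end` (positions
#'   of the SNPs flanking the switch; the crossover lies in the half-open
#'   interval `(bp_start, bp_end]`) and `midpoint`.
#' @examples
#' classify_read("CCCCLLLL", shipped_models("8-CO"))$class   # "SCO"
#' classify_read("LLLLLLLL", shipped_models("8-CO"))$class   # "parental_L"
#' @export
classify_read <- function(string, model, positions = NULL) {
  if (is.character(model)) model <- shipped_models(model)
  stopifnot(inherits(model, "model_spec"))
  if (grepl("[^CL]", string))
    stop("genotype string may contain only 'C' and 'L'")
  chars <- strsplit(string, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L)
    return(list(class = "excluded", reason = "too_few_snps",
                breakpoints = empty_breakpoints()))
  r <- rle(chars)
  res <- classify_runs(r$lengths, chars[1L], model)
  bp <- empty_breakpoints()
  if (length(res$cuts) && !is.null(positions)) {
    stopifnot(length(positions) == length(chars))
    bp <- data.frame(bp_start = positions[res$cuts],
                     bp_end = positions[res$cuts + 1L])
    bp$midpoint <- (bp$bp_start + bp$bp_end) / 2
    bp$left_parent <- chars[res$cuts]
    bp$right_parent <- chars[res$cuts + 1L]
  }
  list(class = res$class, reason = res$reason, breakpoints = bp)
}

empty_breakpoints <- function() {
  data.frame(bp_start = integer(), bp_end = integer(), midpoint = numeric(),
             left_parent = character(), right_parent = character(),
             stringsAsFactors = FALSE)
}

#' Classify a pool of genotype strings
#'
#' Applies a calling model to every string, reclassifies crossover reads whose
#' breakpoint intervals overlap a blacklist, and computes pool-level summary
#' counts.
#'
#' @param strings A [genotype_strings] data.frame.
#' @param model A [model_spec] or shipped model name (default `"8-CO"`).
#' @param blacklist Optional blacklist (data.frame with `chrom`, `start`,
#'   `end`, 0-based half-open, e.g. from [depth_blacklist()]); a crossover
#'   read with any breakpoint interval overlapping it is excluded with reason
#'   `"blacklisted"`. Parental reads are unaffected.
#' @return Object of class `read_calls`: list with
#'   \describe{
#'     \item{calls}{data.frame: `read_id`, `chrom`, `class`, `reason`,
#'       `n_breakpoints`, `n_snps`, `n_overlap`, `read_length`, `string`.}
#'     \item{breakpoints}{data.frame of per-switch intervals for crossover
#'       reads: `read_id`, `chrom`, `bp_start`, `bp_end`, `midpoint`,
#'       `left_parent`, `right_parent`, `type`.}
#'     \item{summary}{list of class counts, exclusion reasons, crossover reads
#'       per million classified reads, and per-class read-length stats.}
#'     \item{model}{the model used.}
#'   }
#' @export
call_pool <- function(strings, model = "8-CO", blacklist = NULL) {
  if (is.character(model)) model <- shipped_models(model)
  stopifnot(inherits(strings, "genotype_strings") ||
              is.data.frame(strings))
  n <- nrow(strings)
  cls <- character(n); reason <- character(n)
  bp_list <- vector("list", n)
  chars_all <- strsplit(strings$string, "", fixed = TRUE)
  for (i in seq_len(n)) {
    chars <- chars_all[[i]]
    if (length(chars) == 0L) {
      cls[i] <- "excluded"; reason[i] <- "too_few_snps"
      next
    }
    r <- rle(chars)
    res <- classify_runs(r$lengths, chars[1L], model)
    cls[i] <- res$class; reason[i] <- res$reason
    if (length(res$cuts)) {
      pos <- strings$positions[[i]]
      bp_list[[i]] <- data.frame(
        read_id = strings$read_id[i], chrom = strings$chrom[i],
        bp_start = pos[res$cuts], bp_end = pos[res$cuts + 1L],
        midpoint = (pos[res$cuts] + pos[res$cuts + 1L]) / 2,
        left_parent = chars[res$cuts], right_parent = chars[res$cuts + 1L],
        type = res$class, stringsAsFactors = FALSE)
    }
  }
  breakpoints <- if (any(!vapply(bp_list, is.null, logical(1))))
    do.call(rbind, bp_list[!vapply(bp_list, is.null, logical(1))])
  else data.frame(read_id = character(), chrom = character(),
                  bp_start = integer(), bp_end = integer(),
                  midpoint = numeric(), left_parent = character(),
                  right_parent = character(), type = character(),
                  stringsAsFactors = FALSE)
  rownames(breakpoints) <- NULL

  # blacklist applies to breakpoint intervals, not whole reads
  if (!is.null(blacklist) && nrow(breakpoints)) {
    bl <- as.data.frame(blacklist)
    # breakpoint (bp_start, bp_end] in 1-based == [bp_start, bp_end) 0-based
    hit <- overlaps_any(
      data.frame(chrom = breakpoints$chrom,
                 start = breakpoints$bp_start, end = breakpoints$bp_end),
      bl)
    bad_reads <- unique(breakpoints$read_id[hit])
    if (length(bad_reads)) {
      sel <- strings$read_id %in% bad_reads & cls %in% c("SCO", "CCO")
      cls[sel] <- "excluded"; reason[sel] <- "blacklisted"
      breakpoints <- breakpoints[!breakpoints$read_id %in% bad_reads, ,
                                 drop = FALSE]
      rownames(breakpoints) <- NULL
    }
  }

  nbp <- integer(n)
  if (nrow(breakpoints)) {
    tab <- table(breakpoints$read_id)
    idx <- match(strings$read_id, names(tab))
    nbp[!is.na(idx)] <- as.integer(tab)[idx[!is.na(idx)]]
  }
  calls <- data.frame(
    read_id = strings$read_id, chrom = strings$chrom,
    class = cls, reason = reason,
    n_breakpoints = nbp,
    n_snps = nchar(strings$string),
    n_overlap = strings$n_overlap,
    read_length = strings$read_length,
    string = strings$string,
    stringsAsFactors = FALSE)

  out <- structure(list(calls = calls, breakpoints = breakpoints,
                        model = model), class = "read_calls")
  out$summary <- summarize_calls(out)
  out
}

summarize_calls <- function(x) {
  calls <- x$calls
  n <- nrow(calls)
  class_counts <- c(parental_C = sum(calls$class == "parental_C"),
                    parental_L = sum(calls$class == "parental_L"),
                    SCO = sum(calls$class == "SCO"),
                    CCO = sum(calls$class == "CCO"),
                    excluded = sum(calls$class == "excluded"))
  n_crossover <- class_counts[["SCO"]] + class_counts[["CCO"]]
  excl <- calls$reason[calls$class == "excluded"]
  len_stats <- lapply(split(calls$read_length, calls$class), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(mean = NA_real_, median = NA_real_)
    else c(mean = mean(v), median = median(v))
  })
  list(n_reads = n,
       class_counts = class_counts,
       excluded_by_reason = if (length(excl)) table(excl) else table(character()),
       n_crossover_reads = n_crossover,
       crossovers_per_million = if (n > 0) n_crossover / n * 1e6 else 0,
       read_length = len_stats)
}

#' @export
print.read_calls <- function(x, ...) {
  s <- x$summary
  cat("read calls (model ", x$model$name, "): ", s$n_reads, " reads\n",
      sep = "")
  cat("  parental C/L: ", s$class_counts[["parental_C"]], "/",
      s$class_counts[["parental_L"]],
      " | SCO: ", s$class_counts[["SCO"]],
      " | CCO: ", s$class_counts[["CCO"]],
      " | excluded: ", s$class_counts[["excluded"]], "\n", sep = "")
  cat(sprintf("  crossover reads per million: %.2f\n",
              s$crossovers_per_million))
  invisible(x)
}

#' Cluster crossover reads into unique events
#'
#' Breakpoint intervals on the same chromosome that overlap, transitively, are
#' merged into one crossover event. The event interval is the intersection of
#' the member intervals when non-empty, otherwise their union; reads detecting
#' the same crossover at slightly different SNP resolution therefore collapse
#' to the tightest consistent locus.
#'
#' @param calls A `read_calls` object (or a breakpoints data.frame with
#'   `chrom`, `bp_start`, `bp_end`, `read_id`, `type`).
#' @return List of class `crossover_events`:
#'   \describe{
#'     \item{events}{data.frame `chrom`, `start`, `end` (interval in the same
#'       `(start, end]` convention as breakpoints), `support` (number of
#'       reads), `type` (`SCO-only` or `contains-CCO`), `read_ids`
#'       (comma-separated).}
#'     \item{n_crossover_reads}{number of distinct crossover reads.}
#'     \item{proportion_nonoverlapping}{events / crossover reads.}
#'   }
#' @export
cluster_events <- function(calls) {
  bp <- if (inherits(calls, "read_calls")) calls$breakpoints else calls
  if (nrow(bp) == 0L)
    return(structure(list(
      events = data.frame(chrom = character(), start = integer(),
                          end = integer(), support = integer(),
                          type = character(), read_ids = character(),
                          stringsAsFactors = FALSE),
      n_crossover_reads = 0L, proportion_nonoverlapping = NA_real_),
      class = "crossover_events"))
  out <- list()
  for (ch in unique(bp$chrom)) {
    d <- bp[bp$chrom == ch, , drop = FALSE]
    d <- d[order(d$bp_start, d$bp_end), , drop = FALSE]
    # sweep: a new cluster starts when the interval (start, end] does not
    # overlap the running maximum end of the current cluster
    cummax_end <- cummax(d$bp_end)
    new_cluster <- c(TRUE, d$bp_start[-1L] >= cummax_end[-nrow(d)])
    cluster_id <- cumsum(new_cluster)
    for (cl in split(seq_len(nrow(d)), cluster_id)) {
      s_int <- max(d$bp_start[cl]); e_int <- min(d$bp_end[cl])
      if (s_int < e_int) { s <- s_int; e <- e_int }
      else { s <- min(d$bp_start[cl]); e <- max(d$bp_end[cl]) }
      ids <- unique(d$read_id[cl])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, support = length(ids),
        type = if (any(d$type[cl] == "CCO")) "contains-CCO" else "SCO-only",
        read_ids = paste(ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, out)
  events <- events[order(events$chrom, events$start), , drop = FALSE]
  rownames(events) <- NULL
  n_reads <- length(unique(bp$read_id))
  structure(list(events = events, n_crossover_reads = n_reads,
                 proportion_nonoverlapping = nrow(events) / n_reads),
            class = "crossover_events")
}

#' @export
print.crossover_events <- function(x, ...) {
  cat("crossover events:", nrow(x$events), "unique event(s) from",
      x$n_crossover_reads, "crossover read(s)\n")
  if (!is.na(x$proportion_nonoverlapping))
    cat(sprintf("  proportion nonoverlapping: %.4f\n",
                x$proportion_nonoverlapping))
  invisible(x)
}

#' Write per-crossover-read CSV
#'
#' One row per crossover read: its first/last breakpoint bounds, midpoint of
#' the first breakpoint, type, parents on each side of the first switch, and
#' the genotype string.
#'
#' @param x A `read_calls` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crossover_csv <- function(x, path) {
  stopifnot(inherits(x, "read_calls"))
  bp <- x$breakpoints
  if (nrow(bp) == 0L) {
    df <- data.frame(read_id = character(), chrom = character(),
                     bp_start = integer(), bp_end = integer(),
                     midpoint = numeric(), type = character(),
                     n_breakpoints = integer(), left_parent = character(),
                     right_parent = character(), n_snps_in_string = integer(),
                     read_length = integer(), genotype_string = character())
  } else {
    first <- bp[!duplicated(bp$read_id), , drop = FALSE]
    last <- bp[!duplicated(bp$read_id, fromLast = TRUE), , drop = FALSE]
    idx <- match(first$read_id, x$calls$read_id)
    df <- data.frame(read_id = first$read_id, chrom = first$chrom,
                     bp_start = first$bp_start,
                     bp_end = last$bp_end[match(first$read_id, last$read_id)],
                     midpoint = first$midpoint, type = first$type,
                     n_breakpoints = x$calls$n_breakpoints[idx],
                     left_parent = first$left_parent,
                     right_parent = first$right_parent,
                     n_snps_in_string = x$calls$n_snps[idx],
                     read_length = x$calls$read_length[idx],
                     genotype_string = x$calls$string[idx],
                     stringsAsFactors = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pool summary CSV
#'
#' @param x A `read_calls` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "read_calls"))
  s <- x$summary
  excl_names <- if (length(s$excluded_by_reason))
    paste0("excluded_", names(s$excluded_by_reason)) else character()
  rows <- data.frame(
    metric = c("n_reads", paste0("n_", names(s$class_counts)),
               "n_crossover_reads", "crossovers_per_million", excl_names),
    value = c(s$n_reads, as.numeric(s$class_counts), s$n_crossover_reads,
              s$crossovers_per_million,
              if (length(excl_names)) as.numeric(s$excluded_by_reason)
              else numeric()),
    stringsAsFactors = FALSE)
  for (cl in names(s$read_length)) {
    rows <- rbind(rows, data.frame(
      metric = paste0("read_length_", c("mean_", "median_"), cl),
      value = as.numeric(s$read_length[[cl]])))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
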