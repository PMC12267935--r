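## Validation against an orthogonal truth set, per-genome crossover-rate
## normalization by read subsampling, and the log-linear saturation model
## used for pool-size design.

#' Read a crossover truth set
#'
#' @param path BED-like TSV: CHROM, START, END (0-based half-open), optional
#'   INDIVIDUAL and SOURCE columns. `#` comment lines are skipped.
#' @return data.frame of class `truth_set` with columns `chrom`, `start`,
#'   `end`, `individual`, `source`.
#' @export
read_truth_set <- function(path) {
  df <- read_bed(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  truth_set(df$chrom, df$start, df$end,
            individual = if (min(lengths(parts)) >= 4L)
              vapply(parts, `[[`, "", 4L) else NA_character_,
            source = if (min(lengths(parts)) >= 5L)
              vapply(parts, `[[`, "", 5L) else NA_character_)
}

#' Construct a truth set
#'
#' @param chrom,start,end Truth crossover intervals (0-based half-open).
#' @param individual,source Optional per-crossover annotations.
#' @return data.frame of class `truth_set`.
#' @export
truth_set <- function(chrom, start, end, individual = NA_character_,
                      source = NA_character_) {
  stopifnot(all(end > start))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   individual = rep_len(as.character(individual),
                                        length(chrom)),
                   source = rep_len(as.character(source), length(chrom)),
                   stringsAsFactors = FALSE)
  class(df) <- c("truth_set", "data.frame")
  df
}

#' Score crossover calls against a truth set
#'
#' A crossover read is a true positive (TP) when its breakpoint interval,
#' expanded by `slack` bp on each side, overlaps any truth interval;
#' otherwise it is a false positive (FP). Precision = TP / (TP + FP) at read
#' level (multiple reads supporting one truth crossover each count as TP). A
#' truth crossover is detected when at least one TP read overlaps it;
#' undetected truth crossovers are tabulated by the local SNP-density (span)
#' class of their midpoint when a span track is supplied.
#'
#' @param calls A `read_calls` object.
#' @param truth A [truth_set()].
#' @param slack Interval expansion in bp (default 0).
#' @param span_track Optional [snp_span_track()] for the false-negative
#'   span-class table.
#' @param span_breaks Span-class boundaries in bp (default
#'   `c(4000, 10000)`).
#' @return List of class `validation_report`: `tp`, `fp`, `precision`,
#'   `truth_detected` (logical per truth row), `truth_support` (TP reads per
#'   truth row), `undetected_by_span` (table or NULL).
#' @export
score_against_truth <- function(calls, truth, slack = 0,
                                span_track = NULL,
                                span_breaks = c(4000, 10000)) {
  stopifnot(inherits(calls, "read_calls"), inherits(truth, "truth_set"))
  bp <- calls$breakpoints
  reads <- unique(bp$read_id)
  if (length(reads) == 0L) {
    warning("no crossover reads; precision undefined")
    return(structure(list(tp = 0L, fp = 0L, precision = NaN,
                          truth_detected = rep(FALSE, nrow(truth)),
                          truth_support = rep(0L, nrow(truth)),
                          undetected_by_span = NULL),
                     class = "validation_report"))
  }
  # per-breakpoint truth overlap; a read is TP if any of its breakpoints hits
  read_tp <- setNames(rep(FALSE, length(reads)), reads)
  truth_support_reads <- vector("list", nrow(truth))
  for (ch in unique(bp$chrom)) {
    bi <- which(bp$chrom == ch)
    ti <- which(truth$chrom == ch)
    if (!length(ti)) next
    q <- IRanges::IRanges(start = bp$bp_start[bi] + 1L - slack,
                          end = bp$bp_end[bi] + slack)
    s <- IRanges::IRanges(start = truth$start[ti] + 1L, end = truth$end[ti])
    hits <- IRanges::findOverlaps(q, s)
    if (!length(hits)) next
    hit_reads <- bp$read_id[bi[S4Vectors::queryHits(hits)]]
    read_tp[unique(hit_reads)] <- TRUE
    for (k in seq_along(hits)) {
      t_row <- ti[S4Vectors::subjectHits(hits)[k]]
      truth_support_reads[[t_row]] <-
        union(truth_support_reads[[t_row]], hit_reads[k])
    }
  }
  tp <- sum(read_tp); fp <- length(reads) - tp
  support <- lengths(truth_support_reads)
  detected <- support > 0L
  undet_tab <- NULL
  if (!is.null(span_track) && any(!detected)) {
    mid <- (truth$start + truth$end) / 2
    sp <- span_at(span_track, truth$chrom, round(mid))
    cls <- cut(sp, breaks = c(0, span_breaks, Inf), include.lowest = TRUE)
    undet_tab <- table(span_class = cls[!detected], useNA = "ifany")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 precision = tp / (tp + fp),
                 truth_detected = detected,
                 truth_support = as.integer(support),
                 undetected_by_span = undet_tab),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation: TP =", x$tp, "| FP =", x$fp,
      sprintf("| precision = %.4f\n", x$precision))
  cat("  truth crossovers detected:", sum(x$truth_detected), "/",
      length(x$truth_detected), "\n")
  if (!is.null(x$undetected_by_span)) {
    cat("  undetected by span class:\n")
    print(x$undetected_by_span)
  }
  invisible(x)
}

#' Crossovers per genome from read subsampling
#'
#' Repeatedly samples a fixed number of classified reads without replacement,
#' counts crossover reads in the sample, and divides by the number of genome
#' equivalents sampled (total aligned bases / genome size). Aligned bases
#' rather than read count x mean length are used so the estimate is robust to
#' read-length heterogeneity.
#'
#' @param calls A `read_calls` object (all classified reads, with read
#'   lengths).
#' @param genome_size Genome size in bp (default 119e6, the nuclear genome
#'   assayed in the original application).
#' @param reads_per_sample Reads per subsample (default 1e6).
#' @param replicates Number of subsamples (default 10).
#' @param seed Master seed; each replicate draws from an independently
#'   derived sub-seed, so results are reproducible.
#' @return List of class `co_per_genome`: `mean`, `sd`, `values` (per
#'   replicate), `reads_per_sample`, `replicates`.
#' @export
crossovers_per_genome <- function(calls, genome_size = 119e6,
                                  reads_per_sample = 1e6, replicates = 10,
                                  seed = 1L) {
  stopifnot(inherits(calls, "read_calls"))
  df <- calls$calls
  n <- nrow(df)
  is_co <- df$class %in% c("SCO", "CCO")
  if (n < reads_per_sample) {
    warning("pool (", n, " reads) smaller than reads_per_sample (",
            reads_per_sample, "); single exhaustive estimate")
    ge <- sum(df$read_length, na.rm = TRUE) / genome_size
    val <- sum(is_co) / ge
    return(structure(list(mean = val, sd = 0, values = val,
                          reads_per_sample = n, replicates = 1L),
                     class = "co_per_genome"))
  }
  seeds <- derive_seeds(seed, replicates)
  vals <- vapply(seq_len(replicates), function(r) {
    idx <- with_seed(seeds[r], sample.int(n, reads_per_sample))
    ge <- sum(df$read_length[idx], na.rm = TRUE) / genome_size
    sum(is_co[idx]) / ge
  }, numeric(1))
  structure(list(mean = mean(vals), sd = sd(vals), values = vals,
                 reads_per_sample = as.integer(reads_per_sample),
                 replicates = as.integer(replicates)),
            class = "co_per_genome")
}

#' @export
print.co_per_genome <- function(x, ...) {
  cat(sprintf("crossovers per genome: %.3f +/- %.3f (%d replicate(s) of %d reads)\n",
              x$mean, x$sd, x$replicates, x$reads_per_sample))
  invisible(x)
}

#' Fit the pool-size saturation model
#'
#' Least-squares fit of `y = a * ln(x) + b`, where `x` is per-individual
#' sequencing coverage and `y` the fraction of detected crossovers that are
#' nonoverlapping (unique). As per-individual coverage falls (more
#' individuals pooled at fixed depth), repeated sampling of the same
#' crossover molecule becomes rarer and `y` rises; the fitted curve is used
#' to choose a pool size that makes most detected crossovers unique.
#'
#' @param x Per-individual coverage values (> 0).
#' @param y Nonoverlapping fractions.
#' @return Object of class `saturation_fit` with elements `slope`,
#'   `intercept`, `fit` (the underlying `lm`), `x`, `y`.
#' @examples
#' f <- fit_saturation(c(0.25, 0.5, 1, 2, 4),
#'                     -0.196 * log(c(0.25, 0.5, 1, 2, 4)) + 0.873)
#' coef(f)   # slope -0.196, intercept 0.873
#' @export
fit_saturation <- function(x, y) {
  if (any(x <= 0)) stop("coverage values must be > 0")
  if (length(unique(x)) < 2L) stop("need at least 2 distinct coverage values")
  stopifnot(length(x) == length(y))
  fit <- lm(y ~ log(x))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 fit = fit, x = x, y = y),
            class = "saturation_fit")
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @rdname fit_saturation
#' @param object A `saturation_fit`.
#' @param newdata Coverage values at which to predict (`x > 0`).
#' @param ... Unused.
#' @return For `predict`: predicted nonoverlapping fractions, clamped to
#'   `[0, 1]` with a warning when the raw prediction falls outside.
#' @export
predict.saturation_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  if (any(x <= 0)) stop("coverage values must be > 0")
  y <- object$slope * log(x) + object$intercept
  if (any(y < 0 | y > 1)) {
    warning("prediction outside [0, 1]; clamped")
    y <- pmin(pmax(y, 0), 1)
  }
  y
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation fit: y = %.4f * ln(x) + %.4f  (n = %d)\n",
              x$slope, x$intercept, length(x$x)))
  invisible(x)
}
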