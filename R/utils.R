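#' Per-base error probability for a Phred quality score
#'
#' Phred quality Q encodes a base-call error probability of `10^(-Q/10)`.
#' The default base-quality masking threshold used throughout the pipeline is
#' Q = 14, i.e. bases with an error probability above ~3.98% are masked to `N`
#' before genotyping.
#'
#' @param q Phred quality score(s).
#' @return Error probability in `[0, 1]`.
#' @examples
#' phred_error_rate(14)   # ~0.0398
#' @export
phred_error_rate <- function(q) 10^(-q / 10)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive independent sub-seeds from a master seed, each < 2^31.
#' @noRd
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Run code with a locally-set RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

## Genomic intervals are handled as data.frames with columns
## chrom, start, end in 0-based half-open (BED) convention.
#' @noRd
empty_intervals <- function(extra = character()) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  for (col in extra) df[[col]] <- character()
  df
}

## Merge overlapping/adjacent half-open intervals per chromosome.
#' @noRd
reduce_intervals <- function(df) {
  if (nrow(df) == 0L) return(empty_intervals())
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1L],
               start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

## TRUE for each query interval that overlaps any subject interval
## (both 0-based half-open data.frames).
#' @noRd
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sd <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sd) == 0L) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = sd$start + 1L, end = sd$end)
    hit[qi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Read a BED file of intervals
#'
#' @param path BED file (0-based half-open); at least 3 columns, optional
#'   4th name/source column. Lines starting with `#` or `track` are skipped.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3L) stop("BED file needs at least 3 columns: ", path)
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (ncol_min >= 4L) df$name <- vapply(parts, `[[`, "", 4L)
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally further columns, written in order as BED columns 4+.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(df), c("chrom", "start", "end")))
  mat <- do.call(cbind, lapply(df[cols], as.character))
  lines <- if (nrow(df)) apply(mat, 1L, paste, collapse = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}
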