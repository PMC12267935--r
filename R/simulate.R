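## Synthetic pooled-gamete long-read simulator with a per-read truth ledger.
##
## Two parental haplotypes differ exactly at catalog SNP positions; each
## pooled genome is a haplotype mosaic with planted crossovers (optionally
## carrying short gene-conversion-like complex tracts); reads are sampled
## from the mosaics with log-normal lengths, then corrupted with i.i.d.
## substitution errors, two-valued base qualities, and coordinate-continuous
## chimeric joins between molecules. Alignments are exact by construction
## (the simulator knows the true coordinates), so genotyping and calling can
## be tested hermetically, without an external aligner.

BASES <- c("A", "C", "G", "T")

## sample one element of x (safe for length-1 x, unlike sample())
resample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulator configuration
#'
#' Defaults emulate the pooled-pollen study conditions: ~524 bp mean
#' inter-SNP distance, ~11.1 kb mean read length, 3.98% per-base substitution
#' errors (Phred Q = 14), and a few crossovers per gamete genome.
#'
#' @param chrom_lengths Named vector of chromosome lengths (default one 5-Mb
#'   chromosome, a desk-scale stand-in for a genome arm).
#' @param snp_spacing Mean inter-SNP distance in bp (default 524).
#' @param snp_placement `"poisson"` (exponential gaps, the default) or
#'   `"uniform"` (regular spacing).
#' @param n_genomes Number of pooled recombinant genomes (default 50).
#' @param co_per_genome Mean planted crossovers per genome (Poisson;
#'   default 4.5, a typical count per gamete for this cross).
#' @param complex_frac Fraction of crossovers planted with an adjacent
#'   complex (gene-conversion-like) tract (default 0.08).
#' @param complex_tract_snps Range of interior-tract lengths in SNPs
#'   (default `c(2, 4)`).
#' @param co_window Optional `c(lo, hi)` restricting crossover placement on
#'   every chromosome (bp); NULL = whole chromosome.
#' @param co_min_sep Minimum separation in bp between crossovers planted in
#'   the same genome (default 0). Crossovers closer than about one read
#'   length produce double-switch molecules that the ends-keyed parental rule
#'   cannot call; a positive separation plants isolated, callable crossovers.
#' @param n_reads Number of reads to sample (default 5000).
#' @param read_length_mean Mean read length in bp (log-normal; default
#'   11100).
#' @param read_length_sdlog Log-sd of the read-length distribution
#'   (default 0.6).
#' @param read_length_min Minimum read length (default 200).
#' @param error_rate Per-base substitution error rate (default
#'   `phred_error_rate(14)` = 0.0398).
#' @param error_lowq_frac Fraction of error bases whose quality falls below
#'   the masking threshold (default 0.5: base callers flag roughly half of
#'   their miscalls with low confidence).
#' @param base_lowq_frac Fraction of correct bases below the masking
#'   threshold (default 0.05).
#' @param chimera_rate Fraction of reads replaced by a chimeric join of two
#'   molecules (default 0.002).
#' @param q_high,q_low The two emitted quality values (default 40 and 10,
#'   straddling the Q14 masking threshold).
#' @param seed Master seed; all stages derive their own sub-seeds from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6),
                       snp_spacing = 524,
                       snp_placement = c("poisson", "uniform"),
                       n_genomes = 50,
                       co_per_genome = 4.5,
                       complex_frac = 0.08,
                       complex_tract_snps = c(2, 4),
                       co_window = NULL,
                       co_min_sep = 0,
                       n_reads = 5000,
                       read_length_mean = 11100,
                       read_length_sdlog = 0.6,
                       read_length_min = 200,
                       error_rate = phred_error_rate(14),
                       error_lowq_frac = 0.5,
                       base_lowq_frac = 0.05,
                       chimera_rate = 0.002,
                       q_high = 40, q_low = 10,
                       seed = 1L) {
  snp_placement <- match.arg(snp_placement)
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            snp_spacing > 0, n_genomes >= 1, co_per_genome >= 0,
            complex_frac >= 0, complex_frac <= 1,
            n_reads >= 1, read_length_mean > 0,
            error_rate >= 0, error_lowq_frac >= 0, error_lowq_frac <= 1,
            base_lowq_frac >= 0, base_lowq_frac <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            q_low < 14, q_high >= 14)
  if (error_rate > 0.5) stop("error_rate > 0.5 is nonsensical")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulator config:",
      sum(x$chrom_lengths) / 1e6, "Mb genome |",
      x$n_genomes, "genomes |", x$n_reads, "reads |",
      "CO/genome", x$co_per_genome, "|",
      sprintf("error %.4f", x$error_rate), "| seed", x$seed, "\n")
  invisible(x)
}

## parent index (0 = A, 1 = B) of genome g at bp positions pos on chrom ch
mosaic_parent <- function(genome, ch, pos) {
  sw <- genome$switches[[ch]]
  (genome$start_parent[[ch]] + findInterval(pos, sw)) %% 2L
}

## sequence of genome g on chrom ch over [s, e], from the haplotype strings
mosaic_seq <- function(genome, ch, s, e, hapA, hapB) {
  sw <- genome$switches[[ch]]
  cuts <- sw[sw >= s & sw < e]          # switch at x: bases > x are new parent
  bounds <- c(s, cuts + 1L, e + 1L)
  pieces <- character(length(bounds) - 1L)
  for (i in seq_along(pieces)) {
    p <- mosaic_parent(genome, ch, bounds[i])
    hap <- if (p == 0L) hapA[[ch]] else hapB[[ch]]
    pieces[i] <- substr(hap, bounds[i], bounds[i + 1L] - 1L)
  }
  paste(pieces, collapse = "")
}

#' Simulate a pooled-gamete long-read dataset
#'
#' Generates the reference and alternate haplotypes, the SNP catalog, a pool
#' of recombinant mosaic genomes with planted crossovers, and sampled reads
#' with exact alignments. When the configured error or chimera rate is
#' positive, [inject_errors()] is applied automatically. Deterministic given
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_pool`:
#'   \describe{
#'     \item{catalog}{the [snp_catalog] of planted SNPs.}
#'     \item{reads}{data.frame `read_id`, `genome`, `chrom`, `start` (1-based
#'       alignment start), `len`.}
#'     \item{seq}{character vector of read sequences (errors applied).}
#'     \item{lowq}{list of integer positions (1-based in the read) with
#'       below-threshold base quality.}
#'     \item{truth}{list: `crossovers` (per planted crossover: genome, chrom,
#'       `pos`, `type`, flanking catalog SNPs, `detectable`), `reads`
#'       (per-read ledger: spanned crossovers, chimera flag and junction,
#'       error count/positions).}
#'     \item{hapA,hapB,chrom_lengths,config}{generation internals.}
#'   }
#' @export
simulate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 5L)
  chrom_lengths <- config$chrom_lengths
  chroms <- names(chrom_lengths)

  ## 1. reference haplotype A and SNP catalog, haplotype B
  gen <- with_seed(seeds[1L], {
    hapA <- list(); hapB <- list(); snp <- list()
    for (ch in chroms) {
      L <- as.integer(chrom_lengths[[ch]])
      idx <- sample.int(4L, L, replace = TRUE)
      hapA[[ch]] <- intToUtf8(utf8ToInt("ACGT")[idx])
      if (config$snp_placement == "poisson") {
        n_guess <- ceiling(L / config$snp_spacing * 1.5)
        gaps <- ceiling(stats::rexp(n_guess, rate = 1 / config$snp_spacing))
        pos <- cumsum(pmax(gaps, 1))
        pos <- pos[pos <= L - 1L]
      } else {
        pos <- seq(from = config$snp_spacing, to = L - 1L,
                   by = config$snp_spacing)
      }
      pos <- as.integer(pos)
      ref_base <- BASES[idx[pos]]
      alt_base <- vapply(ref_base, function(b)
        sample(setdiff(BASES, b), 1L), character(1), USE.NAMES = FALSE)
      r <- charToRaw(hapA[[ch]])
      r[pos] <- charToRaw(paste(alt_base, collapse = ""))
      hapB[[ch]] <- rawToChar(r)
      snp[[ch]] <- data.frame(chrom = ch, pos = pos, allele_a = ref_base,
                              allele_b = alt_base, stringsAsFactors = FALSE)
    }
    list(hapA = hapA, hapB = hapB, snp = do.call(rbind, snp))
  })
  catalog <- new_snp_catalog(validate_snp_catalog(gen$snp))

  ## 2. pooled genomes: haplotype mosaics with planted crossovers
  genomes_truth <- with_seed(seeds[2L], {
    genomes <- vector("list", config$n_genomes)
    co_rows <- list()
    total_len <- sum(chrom_lengths)
    for (g in seq_len(config$n_genomes)) {
      genome <- list(switches = list(), start_parent = list())
      for (ch in chroms) {
        L <- chrom_lengths[[ch]]
        genome$start_parent[[ch]] <- sample(0:1, 1L)
        n_co <- rpois(1L, config$co_per_genome * L / total_len)
        win <- config$co_window %||% c(1, L - 1)
        sw <- integer()
        p <- catalog$pos[catalog$chrom == ch]
        xs <- sort(floor(runif(n_co, win[1L], win[2L])))
        if (config$co_min_sep > 0 && n_co > 1L) {
          # rejection resampling until all same-genome crossovers are isolated
          for (tries in 1:100) {
            if (all(diff(xs) >= config$co_min_sep)) break
            xs <- sort(floor(runif(n_co, win[1L], win[2L])))
          }
          xs <- xs[c(TRUE, diff(xs) >= config$co_min_sep)]
        }
        if (n_co > 0L) for (x in xs) {
          x <- as.integer(x)
          i_left <- findInterval(x, p)        # SNPs <= x
          left_snp <- if (i_left >= 1L) p[i_left] else NA_integer_
          right_snp <- if (i_left < length(p)) p[i_left + 1L] else NA_integer_
          complex <- runif(1) < config$complex_frac
          this_sw <- x
          type <- "simple"
          if (complex) {
            tract_range <- config$complex_tract_snps[1L]:
              config$complex_tract_snps[2L]
            t1 <- resample1(tract_range)
            t2 <- resample1(tract_range)
            j <- i_left
            if (j + t1 + t2 + 1L <= length(p)) {
              y1 <- as.integer(floor((p[j + t1] + p[j + t1 + 1L]) / 2))
              y2 <- as.integer(floor((p[j + t1 + t2] + p[j + t1 + t2 + 1L]) / 2))
              this_sw <- c(x, y1, y2)
              type <- "complex"
            }
          }
          sw <- c(sw, this_sw)
          co_rows[[length(co_rows) + 1L]] <- data.frame(
            genome = g, chrom = ch, pos = x, type = type,
            left_snp = left_snp, right_snp = right_snp,
            detectable = !is.na(left_snp) && !is.na(right_snp),
            n_switches = length(this_sw), stringsAsFactors = FALSE)
        }
        genome$switches[[ch]] <- sort(unique(sw))
      }
      genomes[[g]] <- genome
    }
    crossovers <- if (length(co_rows)) do.call(rbind, co_rows) else
      data.frame(genome = integer(), chrom = character(), pos = integer(),
                 type = character(), left_snp = integer(),
                 right_snp = integer(), detectable = logical(),
                 n_switches = integer(), stringsAsFactors = FALSE)
    list(genomes = genomes, crossovers = crossovers)
  })
  genomes <- genomes_truth$genomes
  crossovers <- genomes_truth$crossovers

  ## 3. read sampling from the mosaics
  pool <- with_seed(seeds[3L], {
    n <- config$n_reads
    g_idx <- sample.int(config$n_genomes, n, replace = TRUE)
    ch_idx <- sample(chroms, n, replace = TRUE,
                     prob = as.numeric(chrom_lengths))
    meanlog <- log(config$read_length_mean) - config$read_length_sdlog^2 / 2
    len <- pmax(config$read_length_min,
                round(rlnorm(n, meanlog, config$read_length_sdlog)))
    len <- pmin(len, as.numeric(chrom_lengths[ch_idx]))
    start <- floor(runif(n, 1, as.numeric(chrom_lengths[ch_idx]) - len + 2))
    reads <- data.frame(read_id = sprintf("read%06d", seq_len(n)),
                        genome = g_idx, chrom = ch_idx,
                        start = as.integer(start), len = as.integer(len),
                        stringsAsFactors = FALSE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- mosaic_seq(genomes[[g_idx[i]]], ch_idx[i],
                            reads$start[i], reads$start[i] + len[i] - 1L,
                            gen$hapA, gen$hapB)
    }
    list(reads = reads, seq = seqs)
  })

  ## per-read spanned crossovers (ledger)
  reads <- pool$reads
  n <- nrow(reads)
  co_count <- integer(n); co_ids <- character(n)
  if (nrow(crossovers)) {
    for (i in seq_len(n)) {
      sel <- which(crossovers$genome == reads$genome[i] &
                     crossovers$chrom == reads$chrom[i] &
                     crossovers$pos >= reads$start[i] &
                     crossovers$pos < reads$start[i] + reads$len[i])
      co_count[i] <- length(sel)
      co_ids[i] <- paste(sel, collapse = ",")
    }
  }
  truth_reads <- data.frame(read_id = reads$read_id, genome = reads$genome,
                            chrom = reads$chrom, start = reads$start,
                            end = reads$start + reads$len - 1L,
                            n_crossovers = co_count, crossover_ids = co_ids,
                            chimera = FALSE,
                            chimera_junction = NA_integer_,
                            chimera_genome = NA_integer_,
                            n_errors = 0L, stringsAsFactors = FALSE)

  out <- structure(list(config = config, catalog = catalog,
                        chrom_lengths = chrom_lengths,
                        hapA = gen$hapA, hapB = gen$hapB,
                        genomes = genomes,
                        reads = reads, seq = pool$seq,
                        lowq = rep(list(integer()), n),
                        truth = list(crossovers = crossovers,
                                     reads = truth_reads),
                        error_positions = rep(list(integer()), n)),
                   class = "sim_pool")
  if (config$error_rate > 0 || config$chimera_rate > 0 ||
      config$base_lowq_frac > 0)
    out <- inject_errors(out, seed = seeds[4L])
  out
}

#' @export
print.sim_pool <- function(x, ...) {
  cat("simulated pool:", nrow(x$reads), "reads |", nrow(x$catalog), "SNPs |",
      x$config$n_genomes, "genomes |",
      nrow(x$truth$crossovers), "planted crossover(s)\n")
  invisible(x)
}

#' Inject sequencing artifacts into a simulated pool
#'
#' Applies, in order: chimeric joins (a read's tail replaced by the
#' coordinate-continuous sequence of a different pooled genome, emulating
#' ligation chimeras between co-located molecules -- the dominant
#' false-positive source for strict callers), i.i.d. substitution errors at
#' `error_rate`, and two-valued base qualities (a configurable fraction of
#' error bases, and a background fraction of correct bases, fall below the
#' masking threshold). All events are recorded in the truth ledger.
#'
#' @param pool A `sim_pool` (normally error-free, fresh from
#'   [simulate_pool()]).
#' @param error_rate,error_lowq_frac,base_lowq_frac,chimera_rate Override the
#'   pool config values.
#' @param seed Seed (default derived from the pool config seed).
#' @return The corrupted `sim_pool` with updated ledger.
#' @export
inject_errors <- function(pool,
                          error_rate = pool$config$error_rate,
                          error_lowq_frac = pool$config$error_lowq_frac,
                          base_lowq_frac = pool$config$base_lowq_frac,
                          chimera_rate = pool$config$chimera_rate,
                          seed = derive_seeds(pool$config$seed, 5L)[4L]) {
  stopifnot(inherits(pool, "sim_pool"))
  if (error_rate > 0.5) stop("error_rate > 0.5 is nonsensical")
  n <- nrow(pool$reads)
  with_seed(seed, {
    ## chimeras: tail continues from a different genome at the same locus
    if (chimera_rate > 0 && pool$config$n_genomes > 1L) {
      chim <- which(runif(n) < chimera_rate)
      for (i in chim) {
        g2 <- resample1(setdiff(seq_along(pool$genomes), pool$reads$genome[i]))
        len <- pool$reads$len[i]
        k <- floor(runif(1, 0.25, 0.75) * len)  # junction inside the read
        s <- pool$reads$start[i]; ch <- pool$reads$chrom[i]
        tail_seq <- mosaic_seq(pool$genomes[[g2]], ch, s + k, s + len - 1L,
                               pool$hapA, pool$hapB)
        pool$seq[i] <- paste0(substr(pool$seq[i], 1L, k), tail_seq)
        pool$truth$reads$chimera[i] <- TRUE
        pool$truth$reads$chimera_junction[i] <- as.integer(s + k - 1L)
        pool$truth$reads$chimera_genome[i] <- g2
      }
    }
    ## substitution errors + two-valued qualities
    base_codes <- vapply(BASES, function(b) charToRaw(b), raw(1))
    for (i in seq_len(n)) {
      len <- pool$reads$len[i]
      lowq <- integer()
      if (error_rate > 0) {
        n_err <- rbinom(1L, len, error_rate)
        if (n_err > 0L) {
          epos <- sample.int(len, n_err)
          r <- charToRaw(pool$seq[i])
          cur <- match(r[epos], base_codes)
          shift <- sample.int(3L, n_err, replace = TRUE)
          r[epos] <- base_codes[((cur - 1L + shift) %% 4L) + 1L]
          pool$seq[i] <- rawToChar(r)
          pool$error_positions[[i]] <- sort(epos)
          pool$truth$reads$n_errors[i] <- n_err
          if (error_lowq_frac > 0)
            lowq <- epos[runif(n_err) < error_lowq_frac]
        }
      }
      if (base_lowq_frac > 0) {
        n_low <- rbinom(1L, len, base_lowq_frac)
        if (n_low > 0L) lowq <- c(lowq, sample.int(len, n_low))
      }
      pool$lowq[[i]] <- sort(unique(as.integer(lowq)))
    }
  })
  pool
}

#' Write a simulated pool as pipeline-ready fixture files
#'
#' Writes the reference FASTA (haplotype A), the SNP table (TSV), reads as
#' FASTQ and as a coordinate-sorted SAM with exact all-match alignments, the
#' truth ledgers (TSV), and the config as YAML (seed included). Re-running
#' with the same config reproduces identical files.
#'
#' @param pool A `sim_pool`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory? (default FALSE: refuse).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(pool, out_dir, force = FALSE) {
  stopifnot(inherits(pool, "sim_pool"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(reference = file.path(out_dir, "reference.fasta"),
             snps = file.path(out_dir, "snps.tsv"),
             fastq = file.path(out_dir, "reads.fastq"),
             sam = file.path(out_dir, "reads.sam"),
             truth_reads = file.path(out_dir, "truth_reads.tsv"),
             truth_crossovers = file.path(out_dir, "truth_crossovers.tsv"),
             config = file.path(out_dir, "config.yaml"))

  ref <- Biostrings::DNAStringSet(unlist(pool$hapA))
  names(ref) <- names(pool$hapA)
  Biostrings::writeXStringSet(ref, files[["reference"]])

  snp <- as.data.frame(pool$catalog)
  writeLines(c("#CHROM\tPOS\tALLELE_COL\tALLELE_LER",
               paste(snp$chrom, snp$pos, snp$allele_a, snp$allele_b,
                     sep = "\t")), files[["snps"]])

  qual_of <- function(i) {
    q <- rep(charToRaw(rawToChar(as.raw(pool$config$q_high + 33L))),
             pool$reads$len[i])
    if (length(pool$lowq[[i]]))
      q[pool$lowq[[i]]] <- charToRaw(rawToChar(as.raw(pool$config$q_low + 33L)))
    rawToChar(q)
  }
  quals <- vapply(seq_len(nrow(pool$reads)), qual_of, character(1))

  fq <- character(4L * nrow(pool$reads))
  fq[seq(1L, length(fq), 4L)] <- paste0("@", pool$reads$read_id)
  fq[seq(2L, length(fq), 4L)] <- pool$seq
  fq[seq(3L, length(fq), 4L)] <- "+"
  fq[seq(4L, length(fq), 4L)] <- quals
  writeLines(fq, files[["fastq"]])

  ord <- order(pool$reads$chrom, pool$reads$start)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(pool$chrom_lengths),
                  "\tLN:", as.integer(pool$chrom_lengths)),
           paste0("@PG\tID:longco-sim\tPN:longco-sim\tCL:seed=",
                  pool$config$seed))
  body <- paste(pool$reads$read_id[ord], 0L, pool$reads$chrom[ord],
                pool$reads$start[ord], 60L,
                paste0(pool$reads$len[ord], "M"), "*", 0L, 0L,
                pool$seq[ord], quals[ord], sep = "\t")
  writeLines(c(hdr, body), files[["sam"]])

  tr <- pool$truth$reads
  write.table(tr, files[["truth_reads"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pool$truth$crossovers, files[["truth_crossovers"]],
              sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- pool$config
  class(cfg) <- NULL
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(cfg, files[["config"]])
  invisible(files)
}

#' Truth intervals of planted crossovers as a truth set
#'
#' Converts the simulator's crossover ledger into a [truth_set()] of
#' flanking-SNP intervals (the resolution at which a caller can localize
#' them). Crossovers without SNPs on both sides are undetectable at any
#' setting and are dropped.
#'
#' @param pool A `sim_pool`.
#' @return A [truth_set()] (0-based half-open `(left_snp, right_snp]`
#'   intervals).
#' @export
sim_truth_set <- function(pool) {
  co <- pool$truth$crossovers
  co <- co[co$detectable, , drop = FALSE]
  if (nrow(co) == 0L)
    return(truth_set(character(), integer(), integer()))
  truth_set(co$chrom, co$left_snp, co$right_snp,
            individual = as.character(co$genome), source = "simulated")
}
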