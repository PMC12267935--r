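# Independent oracles and small fixture builders shared across tests.

# Brute-force transcription of the classification rules, written as a direct
# positional scan (independent of the run-length-encoding implementation).
oracle_classify <- function(s, model) {
  n <- nchar(s)
  if (n == 0) return("excluded")
  ch <- strsplit(s, "")[[1]]
  if (n < model$min_snps) return("excluded")
  er <- model$end_run
  if (length(unique(ch[1:er])) != 1 ||
      length(unique(ch[(n - er + 1):n])) != 1) return("excluded")
  if (ch[1] == ch[n]) return(paste0("parental_", ch[1]))
  sw <- which(ch[-n] != ch[-1])            # switch after position i
  fl <- model$flank_run
  if (length(sw) == 1) {
    i <- sw
    left_ok <- i >= fl && length(unique(ch[(i - fl + 1):i])) == 1
    right_ok <- (n - i) >= fl && length(unique(ch[(i + 1):(i + fl)])) == 1
    return(if (left_ok && right_ok) "SCO" else "excluded")
  }
  if (model$allow_complex) {
    tracts <- diff(c(0, sw, n))            # tract lengths between switches
    k <- length(tracts)
    if (tracts[1] >= fl && tracts[k] >= fl &&
        all(tracts[-c(1, k)] >= model$complex_min_tract) &&
        length(sw) <= model$complex_max_switches) return("CCO")
  }
  "excluded"
}

# All genotype strings over {C, L} with lengths 1..max_len (8190 for 12).
all_strings <- function(max_len = 12) {
  unlist(lapply(seq_len(max_len), function(n) {
    g <- expand.grid(rep(list(c("C", "L")), n), stringsAsFactors = FALSE)
    apply(g, 1, paste, collapse = "")
  }))
}

# Brute-force transitive overlap clustering of half-open intervals (s, e].
oracle_cluster <- function(chrom, s, e) {
  n <- length(s)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & s[i] < e[j] & s[j] < e[i])
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

# genotype_strings fixture from bare strings at regular SNP spacing
gs_fixture <- function(strings, chrom = "chr1", spacing = 100,
                       read_length = 10000) {
  positions <- lapply(strings, function(s) seq_len(nchar(s)) * spacing)
  genotype_strings(read_id = sprintf("r%03d", seq_along(strings)),
                   chrom = chrom, string = strings, positions = positions,
                   read_length = read_length)
}

# small, fast simulated pool for integration-style tests
quick_pool <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(chrom_lengths = c(chr1 = 5e5), n_reads = 400,
                   n_genomes = 10, co_per_genome = 3, seed = seed,
                   read_length_mean = 8000)
  simulate_pool(do.call(sim_config, utils::modifyList(defaults, args)))
}
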