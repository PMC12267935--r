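---
title: "Calling meiotic crossovers in pooled long reads: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling meiotic crossovers in pooled long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longco)
```

## The model

A hybrid between two inbred accessions carries two haplotypes that differ at
a dense catalog of biallelic SNPs (~one per 524 bp in the motivating Col ×
L*er* cross). During meiosis, crossovers exchange the haplotypes, so a DNA
molecule sampled from pooled gametes (pollen) or pooled recombinant progeny
is a mosaic of the two. A long sequencing read that spans a crossover
breakpoint shows, read 5′→3′, a run of one parent's alleles followed by a run
of the other's. `longco` reduces each aligned read to that signal — a
*genotype string* over `{C, L}` — and classifies the string.

The obstacle is the per-base error rate of long reads. At Phred Q = 14 the
error probability is $10^{-14/10} \approx 3.98\%$; roughly a third of
substitution errors at a SNP site convert one parental allele into the other,
so a single miscalled SNP looks exactly like a genotype switch. The calling
rules therefore demand *runs* of consistent calls:

* **parental** — at least `end_run` (2) identical calls at *each* end of the
  string, both ends the same parent (`CC…CC`, `LL…LL`);
* **SCO** (simple crossover) — ends of opposite parent, exactly one switch,
  with at least `flank_run` (4) identical calls immediately on each side
  (`CCCC–LLLL`);
* **CCO** (complex crossover) — ends of opposite parent, two or more
  switches, outer runs of at least `flank_run` and every interior tract of at
  least `complex_min_tract` (2) calls. These capture crossovers accompanied
  by gene-conversion tracts, which appear as short interior runs of the other
  parent;
* **excluded** — strings with fewer than `min_snps` (8) characters, or any
  other configuration (reason `"ambiguous"`).

A false SCO on a parental molecule requires a terminal run of ≥ `flank_run`
consecutive allele-flipping errors: with a per-SNP flip probability of
~`0.0398/3 ≈ 0.013`, that is ~$2p^2 \approx 3.5\times10^{-4}$ per read for a
flank of 2 but ~$2p^4 \approx 6\times10^{-8}$ for a flank of 4. That is the
entire design rationale of the model family: the shipped `4-SCO`, `6-SCO`,
`8-SCO` models (flanks 2, 3, 4; single switch) and `6-CO`, `7-CO`, `8-CO`
(complex switches admitted) trade sensitivity in SNP-sparse regions against
this error floor, and the acceptance suite verifies the predicted ordering of
false-call rates on simulated parental-only pools.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_mapq` | 30 | Phred | unique alignment; discards multi-mappers |
| `min_len` | 100 | bp | floor on usable read length |
| `min_baseq` | 14 | Phred | masks bases with error probability > 3.98% to `N` |
| `min_snps` | 8 | SNPs | minimum confidently genotyped sites per read |
| `flank_run` | 4 | SNPs | run required on each side of a switch |
| `end_run` | 2 | SNPs | run required at each string end |
| `complex_min_tract` | 2 | SNPs | minimum interior tract of a CCO |
| `fold` (depth blacklist) | 3 | × mean | flags collapsed repeats/organellar inserts |
| `min_fp`, `merge_window` | 2, 2000 | calls, bp | negative-control blacklist clustering |
| `max_inter_snp` | 4000 | bp | masks SNP deserts from landscape analyses |
| `genome_size` | 119e6 | bp | genome equivalents for per-genome rates |

All are exposed and recorded in run output (`run_config.yaml` from the CLI).

Decisions worth making explicit, where the rule text alone underdetermines
the implementation:

* **Ends-same strings with interior switches** (`CCCCLLLLCCCC`) are
  *parental*: the parental rule keys on the two string ends only. A
  double-crossover read is thus deliberately not called by default
  (`ends_same_cco = TRUE` in [model_spec()] enables it). Consequence: two
  crossovers closer together than a read length are structurally hard to
  call; the simulator exposes `co_min_sep` to plant isolated, callable
  crossovers when a test needs recall to be interpretable.
* **Uninformative SNP sites** (masked `N`, base matching neither allele, site
  deleted in the read) contribute *no* character rather than a third symbol.
  The `min_snps` threshold therefore counts confident calls only. Masking can
  shorten a string but can never flip a call — a property the test suite
  checks.
* **Secondary/supplementary alignments are dropped** so each molecule yields
  at most one string; split alignments of a chimeric molecule would otherwise
  fabricate crossover-like strings.
* **Allele-frequency bounds in SNP curation are inclusive** (`[0.4, 0.6]`)
  and heterozygotes count ½ toward the B-allele frequency — the standard
  F2 convention. The segregation check is a plain Pearson chi-square
  goodness-of-fit against 1:2:1 with 2 df, no continuity correction.
* **Breakpoints** are reported as the half-open interval between the last SNP
  of one tract and the first SNP of the next, `(left, right]`; the midpoint
  serves as the point estimate for profile analyses. Unique events merge
  transitively overlapping breakpoint intervals; the event interval is the
  intersection when non-empty (the tightest locus consistent with all
  supporting reads), otherwise the union.
* **Blacklists apply to breakpoints, not reads**: a parental read overlapping
  a blacklisted region still counts as parental; only crossover calls whose
  breakpoint falls in the region are excluded.
* **Fisher tests** on 100-kb bins are two-sided, with Benjamini–Hochberg FDR
  across bins (the standard FDR procedure); the per-bin 2×2 table is in-bin
  vs elsewhere × dataset A vs B.

## The simulator: what it emulates, and what it does not

`simulate_pool()` generates two haplotypes differing exactly at catalog SNPs
(Poisson-process placement, 524 bp mean spacing), a pool of recombinant
mosaic genomes (Poisson crossovers per genome, default 4.5 — a typical count
per gamete in this cross — with an 8% fraction carrying an adjacent
gene-conversion-like tract of 2–4 SNPs), and reads with log-normal lengths
(mean 11.1 kb). Artifacts are injected in the ledger-tracked order:

* **chimeras** (default 0.2% of reads): a read's tail is replaced by the
  coordinate-continuous sequence of a *different* pooled genome, emulating
  ligation chimeras between co-located molecules. These produce clean
  parental switches and are the dominant false-positive source for strict
  models;
* **substitution errors**: i.i.d. at `10^(-Q/10)` with Q = 14 by default;
* **two-valued base qualities**: half of the error bases (configurable) and
  5% of correct bases fall below the masking threshold. Only the threshold
  matters to the pipeline contract, so a continuous quality model would add
  nothing testable.

Alignments are emitted exactly (the simulator knows the true coordinates), so
genotyping is tested independently of an external aligner; a FASTQ is written
for users who want to run one. Deliberately *not* modeled: indel errors and
homopolymer artifacts (substitution-only suffices to exercise the
masking/genotyping contracts), realistic quality distributions, structural
variation between the parents, and the pericentromeric SNP deserts of a real
genome (the `>4000 bp` inter-SNP mask is exercised on constructed catalogs
instead). Passing tests on simulated pools therefore demonstrate the
*logic* of the pipeline — not performance on real nanopore data, where error
clustering and reference bias add failure modes the simulator does not
reproduce.

## Numerical and scale choices

Test and acceptance runs use desk-scale problem sizes chosen so the full
suite completes in minutes on one CPU while keeping the statistics
interpretable: the parental-only false-call comparison uses a 5-Mb
chromosome, ~10,000 SNPs and 50,000 reads (≈ 110 genome equivalents, enough
to see the `4-SCO` error floor of a few hundred calls per million while the
`8-*` models stay at zero); hermetic precision/recall uses ~100 isolated
crossovers in a SNP-dense 1-Mb genome at ~15× per-genome coverage, where the
probability that any planted crossover lacks a well-flanked spanning read is
~10⁻⁴; rate recovery uses 20 replicate pools of 4,000 reads. The recovery
target is the *planted* rate; the estimator has a small (~4–7%) downward bias
because crossovers within `flank_run` SNPs of a read end are structurally
uncallable on that read — well inside the replicate sampling spread at these
sizes.

Degenerate inputs are defined, not exceptional: an empty pool summarizes to
zeros; a read overlapping no catalog SNP yields an empty string (excluded
downstream); precision with no crossover reads is `NaN` with a warning; a
chromosome with fewer than `k` SNPs has no span track and is skipped with a
message. Saturation-model predictions are clamped to `[0, 1]` with a warning,
since the log-linear form is unbounded. All randomness in the package flows
through explicit seeds; stage seeds are derived from one master seed so that
every simulator output and subsampling replicate is exactly reproducible.

## Known limitations

* Double crossovers on one molecule (closer than a read length) are not
  called by default — an intrinsic cost of the ends-keyed parental rule.
* Precision on real data depends on error *clustering* that the i.i.d. error
  model understates; the negative-control blacklist exists precisely because
  real artifact loci recur.
* The per-genome rate estimator uses aligned bases over genome size;
  contamination or organellar reads inflate the denominator unless filtered.
* `crossovers_per_genome` subsamples reads without replacement, so pools
  smaller than the subsample size fall back to a single exhaustive estimate.
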