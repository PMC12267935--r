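#' Crossover-calling model specification
#'
#' A model in the rule family is defined by the minimum number of genotyped
#' SNPs a string must carry, the length of the homogeneous run required at
#' each string end for the string to be interpretable at all, the length of
#' the homogeneous run required on each side of a switch for a simple
#' crossover (SCO), and whether (and how) multi-switch complex crossovers
#' (CCOs) are admitted.
#'
#' The shipped models (see [shipped_models()]) are `4-SCO`, `6-SCO`, `8-SCO`
#' (single-switch only) and `6-CO`, `7-CO`, `8-CO` (complex switches allowed).
#' The `8-CO` model -- at least 8 genotyped SNPs, runs of 4 consistent calls on
#' both sides of the crossover (the `CCCC--LLLL` rule), two consistent calls at
#' each string end -- is the default production model.
#'
#' @param name Model label.
#' @param min_snps Minimum characters (confidently genotyped SNPs) required.
#' @param flank_run Identical characters required on each side of a switch.
#' @param end_run Identical characters required at each string end (default 2).
#' @param allow_complex Admit strings with two or more switches as CCO?
#' @param complex_min_tract Minimum length of each interior tract of a CCO
#'   (default 2).
#' @param complex_max_switches Maximum number of switches for a CCO
#'   (default `Inf`).
#' @param ends_same_cco Classify ends-same strings with interior switches as
#'   CCO instead of parental? Off by default: the parental rule keys on the
#'   two string ends only.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, min_snps, flank_run, end_run = 2,
                       allow_complex = FALSE, complex_min_tract = 2,
                       complex_max_switches = Inf, ends_same_cco = FALSE) {
  stopifnot(min_snps >= 2 * flank_run, end_run <= flank_run,
            min_snps >= 2, flank_run >= 1, end_run >= 1,
            complex_min_tract >= 1)
  structure(list(name = name, min_snps = as.integer(min_snps),
                 flank_run = as.integer(flank_run),
                 end_run = as.integer(end_run),
                 allow_complex = isTRUE(allow_complex),
                 complex_min_tract = as.integer(complex_min_tract),
                 complex_max_switches = complex_max_switches,
                 ends_same_cco = isTRUE(ends_same_cco)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "model %s: min_snps=%d, flank_run=%d, end_run=%d, complex=%s%s\n",
    x$name, x$min_snps, x$flank_run, x$end_run,
    if (x$allow_complex)
      sprintf("yes (min tract %d, max switches %s)",
              x$complex_min_tract, format(x$complex_max_switches))
    else "no",
    if (x$ends_same_cco) ", ends-same CCO on" else ""))
  invisible(x)
}

#' The shipped crossover-calling models
#'
#' Three single-switch models (`4-SCO`, `6-SCO`, `8-SCO`) and three models
#' that also admit complex multi-switch crossovers (`6-CO`, `7-CO`, `8-CO`).
#' All use an end run of 2 and, for the complex models, a minimum interior
#' tract of 2. Flank runs are half the SNP minimum (rounded down).
#'
#' @param name Optional single model name; when given, that `model_spec` is
#'   returned instead of the full list.
#' @return Named list of [model_spec] objects, or a single `model_spec`.
#' @export
shipped_models <- function(name = NULL) {
  models <- list(
    "4-SCO" = model_spec("4-SCO", min_snps = 4, flank_run = 2),
    "6-SCO" = model_spec("6-SCO", min_snps = 6, flank_run = 3),
    "8-SCO" = model_spec("8-SCO", min_snps = 8, flank_run = 4),
    "6-CO"  = model_spec("6-CO", min_snps = 6, flank_run = 3,
                         allow_complex = TRUE),
    "7-CO"  = model_spec("7-CO", min_snps = 7, flank_run = 3,
                         allow_complex = TRUE),
    "8-CO"  = model_spec("8-CO", min_snps = 8, flank_run = 4,
                         allow_complex = TRUE)
  )
  if (is.null(name)) return(models)
  if (!name %in% names(models))
    stop("unknown model '", name, "'; shipped models: ",
         paste(names(models), collapse = ", "))
  models[[name]]
}
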