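#' Pipeline configuration
#'
#' Collects all tunable constants of the discovery pipeline with their
#' defaults. Any value can be overridden by name.
#'
#' @param min_len,max_len retained read length range in nt after trimming.
#' @param max_hits maximum number of perfect genomic hits for a read to be
#'   placed; reads above this go to the multimap pool.
#' @param min_span,max_span allowed span (nt) from the outermost 5' end to
#'   the outermost 3' end of the guide/passenger predominant reads; the
#'   default 46-80 nt is the canonical pre-miRNA hairpin size. Long-hairpin
#'   runs override `max_span` (e.g. 160).
#' @param min_loop minimum unpaired separation (nt) between guide and
#'   passenger reads so a terminal loop can form.
#' @param flank nt of genomic context added on each side of the precursor
#'   interval before structure scoring.
#' @param duplex_mfe_gate maximum duplex folding energy (kcal/mol) for a
#'   guide/passenger pair to be kept as a candidate.
#' @param fold_backend `"auto"`, `"vienna"` or `"builtin"`.
#' @param fpr_target calibration stops at the first cutoff level whose
#'   estimated false-positive rate is at or below this value.
#' @param step increment of the relative cutoff level per iteration.
#' @param max_level last relative cutoff level tried before giving up.
#' @param min_annotated minimum number of annotated loci detected among the
#'   candidates for calibration to be attempted.
#' @param group_heterogeneity treat 5p/3p 5'-heterogeneity as a single
#'   joint parameter in the expected-count product (eight independent
#'   parameters instead of nine).
#' @param tailing_na_pass whether candidates without any tailing evidence
#'   (no unmapped reads aligning) pass the tailing cutoff.
#' @param adapter optional adapter sequence for read trimming.
#' @param min_overlap minimum 3'-anchored adapter prefix length accepted as
#'   trimming evidence.
#' @param require_adapter reject reads without adapter evidence.
#' @return a named list of settings (class `mirscout_config`).
#' @export
pipeline_config <- function(min_len = 18L, max_len = 26L,
                            max_hits = 4L,
                            min_span = 46L, max_span = 80L,
                            min_loop = 3L, flank = 10L,
                            duplex_mfe_gate = -14,
                            fold_backend = "auto",
                            fpr_target = 0.01, step = 0.01,
                            max_level = 0.99, min_annotated = 20L,
                            group_heterogeneity = FALSE,
                            tailing_na_pass = TRUE,
                            adapter = NULL, min_overlap = 5L,
                            require_adapter = FALSE) {
  cfg <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
              max_hits = as.integer(max_hits),
              min_span = as.integer(min_span),
              max_span = as.integer(max_span),
              min_loop = as.integer(min_loop), flank = as.integer(flank),
              duplex_mfe_gate = duplex_mfe_gate,
              fold_backend = fold_backend,
              fpr_target = fpr_target, step = step,
              max_level = max_level,
              min_annotated = as.integer(min_annotated),
              group_heterogeneity = isTRUE(group_heterogeneity),
              tailing_na_pass = isTRUE(tailing_na_pass),
              adapter = adapter, min_overlap = as.integer(min_overlap),
              require_adapter = isTRUE(require_adapter))
  if (cfg$min_span >= cfg$max_span)
    stop("min_span must be smaller than max_span")
  if (cfg$step <= 0 || cfg$step > 0.5) stop("step must be in (0, 0.5]")
  if (cfg$fpr_target <= 0 || cfg$fpr_target >= 1)
    stop("fpr_target must be in (0, 1)")
  class(cfg) <- "mirscout_config"
  cfg
}
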