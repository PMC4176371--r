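PARAM_NAMES <- c("het_5p", "het_3p", "overhang", "mfe_duplex", "mfe_flank",
                 "entropy_nt", "entropy_struct", "tailing", "multimap")

# adverse direction per parameter: "high" = large values are miRNA-unlike
PARAM_DIRECTIONS <- c(het_5p = "high", het_3p = "high", overhang = "high",
                      mfe_duplex = "high", mfe_flank = "high",
                      entropy_nt = "low", entropy_struct = "high",
                      tailing = "low", multimap = "high")

# parameter value matrix used by the cutoff machinery; the two overhangs
# are collapsed into one deviation-from-+2 parameter so that the nine
# entries behave independently
param_matrix <- function(params) {
  dev <- pmax(abs(params$overhang_a - 2), abs(params$overhang_b - 2))
  cbind(het_5p = params$het_5p, het_3p = params$het_3p, overhang = dev,
        mfe_duplex = params$duplex_mfe, mfe_flank = params$mfe_flank,
        entropy_nt = params$entropy_nt,
        entropy_struct = params$entropy_struct,
        tailing = params$tailing, multimap = params$multimap)
}

#' Label candidate loci against a known-miRNA annotation
#'
#' A candidate is `annotated` when its guide read interval overlaps an
#' annotation feature on the same strand by at least `min_frac` of the
#' guide read length, `antisense` when only an opposite-strand overlap
#' exists, and `candidate` otherwise.
#'
#' @param candidates candidate data.frame (scored or not).
#' @param annotation a GFF3/BED file path, a `GRanges`, or a data.frame
#'   with `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @param min_frac minimum overlap fraction of the guide read (default
#'   0.5).
#' @param index optional `genome_index` used to sanity-check that
#'   annotation coordinates fit the assembly.
#' @return the candidate data.frame with a `label` column.
#' @export
label_candidates <- function(candidates, annotation, min_frac = 0.5,
                             index = NULL) {
  ann <- as_annotation_granges(annotation)
  if (!is.null(index)) {
    lens <- index$lengths[as.character(GenomicRanges::seqnames(ann))]
    if (anyNA(lens) || any(GenomicRanges::end(ann) > lens))
      stop("annotation coordinates exceed the assembly: wrong genome?")
  }
  n <- nrow(candidates)
  candidates$label <- rep("candidate", n)
  if (n == 0L || length(ann) == 0L) return(candidates)
  guide <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$guide_start + 1L, candidates$guide_end),
    strand = candidates$strand)
  for (same_strand in c(TRUE, FALSE)) {
    hits <- GenomicRanges::findOverlaps(
      guide, ann,
      ignore.strand = TRUE)
    qs <- S4Vectors::queryHits(hits); ss <- S4Vectors::subjectHits(hits)
    strand_match <- as.character(GenomicRanges::strand(guide))[qs] ==
      as.character(GenomicRanges::strand(ann))[ss]
    keep <- if (same_strand) strand_match else !strand_match
    qs <- qs[keep]; ss <- ss[keep]
    if (length(qs) == 0L) next
    ow <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(guide)[qs], IRanges::ranges(ann)[ss]))
    good <- unique(qs[ow >= min_frac * IRanges::width(IRanges::ranges(guide))[qs]])
    lab <- if (same_strand) "annotated" else "antisense"
    upgrade <- candidates$label[good] == "candidate" |
      (lab == "annotated")
    candidates$label[good[upgrade]] <- lab
  }
  candidates
}

as_annotation_granges <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    ann <- rtracklayer::import(annotation)
  } else if (is(annotation, "GRanges")) {
    ann <- annotation
  } else if (is.data.frame(annotation)) {
    ann <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(annotation$start + 1L, annotation$end),
      strand = annotation$strand)
  } else stop("unsupported annotation type")
  if (!is.null(ann$type) && any(ann$type == "miRNA"))
    ann <- ann[ann$type %in% c("miRNA", "miRNA_primary_transcript")]
  ann
}

#' Per-parameter cutoffs at a relative cutoff level
#'
#' For each of the nine independent parameters, the cutoff is the value
#' beyond which the worst `ceiling(level * n)` annotated miRNAs lie in
#' the adverse direction (high heterogeneity, overhangs deviating from
#' +2, high folding energies, low nucleotide entropy, high structural
#' entropy, low tailing, high multimapping). Concretely the cutoff is the
#' `(k+1)`-th worst annotated value with `k = ceiling(level * n)`, and a
#' value fails when strictly beyond the cutoff, so with distinct values
#' exactly the worst k annotated loci fail each parameter; ties can only
#' reduce the failing fraction (discrete slack `<= level + 1/n`).
#'
#' @param annotated_params data.frame of scored annotated loci.
#' @param level relative cutoff in `[0, 1)`.
#' @param min_annotated minimal number of annotated exemplars required.
#' @return a `cutoff_table` data.frame: `parameter`, `direction`,
#'   `cutoff`.
#' @export
cutoffs_at_level <- function(annotated_params, level,
                             min_annotated = 20L) {
  if (nrow(annotated_params) < min_annotated)
    stop(sprintf(paste0("only %d annotated loci detected (need >= %d): ",
                        "calibration against annotation is not possible; ",
                        "provide deeper libraries or a richer annotation"),
                 nrow(annotated_params), min_annotated))
  vals <- param_matrix(annotated_params)
  cuts <- vapply(PARAM_NAMES, function(p) {
    v <- vals[, p]
    v <- v[!is.na(v)]
    n <- length(v)
    k <- ceiling(level * n)
    if (PARAM_DIRECTIONS[[p]] == "high") {
      sv <- sort(v, decreasing = TRUE)
      if (k + 1L > n) -Inf else sv[k + 1L]
    } else {
      sv <- sort(v)
      if (k + 1L > n) Inf else sv[k + 1L]
    }
  }, numeric(1))
  structure(data.frame(parameter = PARAM_NAMES,
                       direction = unname(PARAM_DIRECTIONS[PARAM_NAMES]),
                       cutoff = unname(cuts), stringsAsFactors = FALSE),
            class = c("cutoff_table", "data.frame"), level = level)
}

#' Apply a cutoff table to scored loci
#'
#' @param params data.frame of scored loci.
#' @param cutoffs a `cutoff_table`.
#' @param na_pass whether an `NA` parameter value (tailing without
#'   evidence) passes its cutoff.
#' @return logical matrix, one column per parameter, plus a `pass_all`
#'   attribute-free final column named `all`.
#' @export
apply_cutoffs <- function(params, cutoffs, na_pass = TRUE) {
  vals <- param_matrix(params)
  pass <- matrix(TRUE, nrow(vals), length(PARAM_NAMES),
                 dimnames = list(NULL, PARAM_NAMES))
  for (i in seq_len(nrow(cutoffs))) {
    p <- cutoffs$parameter[i]
    v <- vals[, p]
    ok <- if (cutoffs$direction[i] == "high") v <= cutoffs$cutoff[i]
          else v >= cutoffs$cutoff[i]
    ok[is.na(v)] <- na_pass
    pass[, p] <- ok
  }
  cbind(pass, all = rowSums(!pass) == 0L)
}

#' Per-parameter strengths
#'
#' The strength of a parameter at a cutoff level is the fraction of all
#' (non-annotated) candidates eliminated by its cutoff. The two overhang
#' scores enter as one joint parameter, so nine strengths describe the
#' nine independent parameters (eight when 5' heterogeneity is grouped).
#'
#' @param candidate_params scored non-annotated candidates.
#' @param cutoffs a `cutoff_table`.
#' @param na_pass see [apply_cutoffs()].
#' @param group_heterogeneity merge het_5p/het_3p into one joint
#'   strength.
#' @return named numeric vector of strengths in `[0, 1]`.
#' @export
strengths <- function(candidate_params, cutoffs, na_pass = TRUE,
                      group_heterogeneity = FALSE) {
  pass <- apply_cutoffs(candidate_params, cutoffs, na_pass = na_pass)
  s <- colMeans(!pass[, PARAM_NAMES, drop = FALSE])
  if (group_heterogeneity) {
    joint <- mean(!(pass[, "het_5p"] & pass[, "het_3p"]))
    s <- c(het = joint, s[setdiff(PARAM_NAMES, c("het_5p", "het_3p"))])
  }
  s
}

#' Expected number of candidates passing all cutoffs by chance
#'
#' Under the approximation that the parameters eliminate candidates
#' independently, `Expected = N * prod(1 - strength_i)` over the nine
#' independent strengths.
#'
#' @param s named strengths vector.
#' @param N total number of (non-annotated) candidates considered.
#' @return expected count (float).
#' @export
expected_count <- function(s, N) {
  stopifnot(all(s >= 0 & s <= 1))
  N * prod(1 - s)
}

#' Estimated false-positive rate
#'
#' `FPR = Expected / Observed`, where Observed is the number of
#' candidates passing all cutoffs.
#'
#' @param expected expected chance passers, see [expected_count()].
#' @param observed observed passers.
#' @return the ratio; `NA` when `observed` is 0 (no candidates left).
#' @export
fpr_estimate <- function(expected, observed) {
  if (observed == 0L) return(NA_real_)
  expected / observed
}

#' Recall of annotated miRNAs
#'
#' @param detected number of annotated miRNAs detected as candidates.
#' @param passing number of those passing all cutoffs.
#' @return percentage, rounded to the nearest integer.
#' @export
recall_pct <- function(detected, passing) {
  if (detected <= 0L) stop("no annotated miRNAs detected")
  stopifnot(passing >= 0L, detected >= passing)
  round(100 * passing / detected)
}

#' Calibrate cutoffs against annotated miRNAs until the FPR target is met
#'
#' Starting from the smallest relative cutoff level, the per-parameter
#' cutoffs (from the annotated loci), the strengths, the expected chance
#' passers and the observed passers are recomputed at each level; the
#' loop stops at the first level whose FPR is at or below `fpr_target`.
#' Annotated loci are excluded from the strengths, from N and from
#' Observed; they are still pushed through the cutoffs to report recall
#' (the trace also carries the passing count including annotated loci).
#'
#' @param labeled scored + labeled candidate data.frame (see
#'   [label_candidates()]).
#' @param config a [pipeline_config()] (uses `fpr_target`, `step`,
#'   `max_level`, `min_annotated`, `group_heterogeneity`,
#'   `tailing_na_pass`).
#' @return a `mirna_prediction` list: `novel`, `antisense`,
#'   `annotated_passing` (data.frames), `fpr_result` (list `N`,
#'   `expected`, `observed`, `fpr`, `level`), `cutoffs`, `trace`
#'   (one row per level), `converged`, and `candidate_fpr` (per
#'   candidate, the FPR at the strictest traced level it still passes).
#' @export
calibrate <- function(labeled, config = pipeline_config()) {
  stopifnot("label" %in% names(labeled))
  ann <- labeled[labeled$label == "annotated", , drop = FALSE]
  cand <- labeled[labeled$label != "annotated", , drop = FALSE]
  if (nrow(ann) < config$min_annotated)
    stop(sprintf(paste0("only %d annotated loci detected (need >= %d): ",
                        "cannot calibrate cutoffs"),
                 nrow(ann), config$min_annotated))
  N <- nrow(cand)
  levels <- seq(config$step, config$max_level, by = config$step)
  trace <- NULL
  best <- NULL
  last_pass_level <- rep(NA_real_, nrow(labeled))
  last_pass_fpr <- rep(NA_real_, nrow(labeled))
  for (level in levels) {
    ct <- cutoffs_at_level(ann, level, min_annotated = config$min_annotated)
    s <- strengths(cand, ct, na_pass = config$tailing_na_pass,
                   group_heterogeneity = config$group_heterogeneity)
    pass_cand <- apply_cutoffs(cand, ct, na_pass = config$tailing_na_pass)
    pass_ann <- apply_cutoffs(ann, ct, na_pass = config$tailing_na_pass)
    observed <- sum(pass_cand[, "all"])
    expected <- expected_count(s, N)
    fpr <- fpr_estimate(expected, observed)
    ann_passing <- sum(pass_ann[, "all"])
    trace <- rbind(trace, data.frame(
      level = level, expected = expected, observed = observed,
      fpr = fpr, annotated_passing = ann_passing,
      observed_with_annotated = observed + ann_passing,
      t(setNames(s, paste0("strength_", names(s)))),
      t(setNames(ct$cutoff, paste0("cutoff_", ct$parameter)))))
    all_pass_full <- logical(nrow(labeled))
    all_pass_full[labeled$label != "annotated"] <- pass_cand[, "all"]
    all_pass_full[labeled$label == "annotated"] <- pass_ann[, "all"]
    if (!is.na(fpr)) {
      last_pass_level[all_pass_full] <- level
      last_pass_fpr[all_pass_full] <- fpr
    }
    if (observed == 0L) {
      return(prediction_set(labeled, cand, ann, pass_cand, pass_ann, ct,
                            trace, N, expected, observed, fpr, level,
                            converged = FALSE, last_pass_level,
                            last_pass_fpr,
                            diagnostic = "no candidates left"))
    }
    if (fpr <= config$fpr_target) {
      return(prediction_set(labeled, cand, ann, pass_cand, pass_ann, ct,
                            trace, N, expected, observed, fpr, level,
                            converged = TRUE, last_pass_level,
                            last_pass_fpr))
    }
  }
  prediction_set(labeled, cand, ann, NULL, NULL, NULL, trace, N,
                 NA_real_, NA_integer_, NA_real_, NA_real_,
                 converged = FALSE, last_pass_level, last_pass_fpr,
                 diagnostic = "FPR target not reached at max_level")
}

prediction_set <- function(labeled, cand, ann, pass_cand, pass_ann, ct,
                           trace, N, expected, observed, fpr, level,
                           converged, last_pass_level, last_pass_fpr,
                           diagnostic = NULL) {
  drop_cols <- c("duplex", "stack_5p", "stack_3p")
  strip <- function(df) df[, setdiff(names(df), drop_cols), drop = FALSE]
  if (converged) {
    passing <- cand[pass_cand[, "all"], , drop = FALSE]
    novel <- passing[passing$label == "candidate", , drop = FALSE]
    anti <- passing[passing$label == "antisense", , drop = FALSE]
    ann_pass <- ann[pass_ann[, "all"], , drop = FALSE]
  } else {
    novel <- anti <- ann_pass <- cand[0L, , drop = FALSE]
  }
  structure(list(
    novel = strip(novel), antisense = strip(anti),
    annotated_passing = strip(ann_pass),
    fpr_result = list(N = N, expected = expected, observed = observed,
                      fpr = fpr, level = level),
    cutoffs = ct, trace = trace, converged = converged,
    candidate_fpr = data.frame(locus_id = labeled$locus_id,
                               label = labeled$label,
                               last_pass_level = last_pass_level,
                               fpr = last_pass_fpr),
    n_annotated_detected = nrow(ann),
    recall = if (nrow(ann) > 0L && converged)
      recall_pct(nrow(ann), nrow(ann_pass)) else NA_integer_,
    diagnostic = diagnostic), class = "mirna_prediction")
}

#' @export
print.mirna_prediction <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(paste0("mirna_prediction: converged at level %.2f ",
                       "(FPR %.4f)\n  novel %d, antisense %d, annotated ",
                       "passing %d / %d detected (recall %d%%)\n"),
                x$fpr_result$level, x$fpr_result$fpr, nrow(x$novel),
                nrow(x$antisense), nrow(x$annotated_passing),
                x$n_annotated_detected, x$recall))
  } else {
    cat(sprintf("mirna_prediction: not converged (%s)\n",
                x$diagnostic %||% "?"))
  }
  invisible(x)
}

#' Strength-calibrated cutoffs for long-hairpin prediction
#'
#' When too few annotated exemplars exist in a size range (e.g. 81-160 nt
#' precursors), cutoffs cannot be derived from annotated percentiles.
#' Instead the per-parameter strengths from a completed standard
#' calibration are fixed: each cutoff is placed at the candidate-
#' distribution quantile that eliminates the reference strength fraction,
#' and the whole strength vector is scaled by a common multiplier >= 1,
#' raised stepwise until the FPR meets the target.
#'
#' @param labeled scored + labeled candidates of the alternative size
#'   range.
#' @param reference_strengths named strengths vector from [calibrate()]
#'   (`strength_*` columns of the trace row at the final level).
#' @param config a [pipeline_config()].
#' @param multiplier_step increment of the common multiplier.
#' @return a `mirna_prediction` (trace rows are indexed by multiplier).
#' @export
calibrate_by_strength <- function(labeled, reference_strengths,
                                  config = pipeline_config(),
                                  multiplier_step = 0.05) {
  stopifnot("label" %in% names(labeled))
  cand <- labeled[labeled$label != "annotated", , drop = FALSE]
  ann <- labeled[labeled$label == "annotated", , drop = FALSE]
  N <- nrow(cand)
  if (N == 0L) stop("no candidates to calibrate")
  vals <- param_matrix(cand)
  ref <- reference_strengths[PARAM_NAMES]
  trace <- NULL
  last_pass_level <- rep(NA_real_, nrow(labeled))
  last_pass_fpr <- rep(NA_real_, nrow(labeled))
  mult <- 1
  repeat {
    target_s <- pmin(ref * mult, 1)
    cuts <- vapply(PARAM_NAMES, function(p) {
      v <- vals[, p]; v <- v[!is.na(v)]; n <- length(v)
      k <- ceiling(target_s[[p]] * n)
      if (PARAM_DIRECTIONS[[p]] == "high") {
        sv <- sort(v, decreasing = TRUE)
        if (k + 1L > n) -Inf else sv[k + 1L]
      } else {
        sv <- sort(v)
        if (k + 1L > n) Inf else sv[k + 1L]
      }
    }, numeric(1))
    ct <- structure(data.frame(parameter = PARAM_NAMES,
                               direction = unname(PARAM_DIRECTIONS[PARAM_NAMES]),
                               cutoff = unname(cuts),
                               stringsAsFactors = FALSE),
                    class = c("cutoff_table", "data.frame"),
                    level = mult)
    s <- strengths(cand, ct, na_pass = config$tailing_na_pass,
                   group_heterogeneity = config$group_heterogeneity)
    pass_cand <- apply_cutoffs(cand, ct, na_pass = config$tailing_na_pass)
    pass_ann <- if (nrow(ann)) apply_cutoffs(ann, ct,
                                             na_pass = config$tailing_na_pass)
                else matrix(logical(), 0, length(PARAM_NAMES) + 1L,
                            dimnames = list(NULL, c(PARAM_NAMES, "all")))
    observed <- sum(pass_cand[, "all"])
    expected <- expected_count(s, N)
    fpr <- fpr_estimate(expected, observed)
    trace <- rbind(trace, data.frame(
      level = mult, expected = expected, observed = observed, fpr = fpr,
      annotated_passing = sum(pass_ann[, "all"]),
      observed_with_annotated = observed + sum(pass_ann[, "all"]),
      t(setNames(s, paste0("strength_", names(s)))),
      t(setNames(ct$cutoff, paste0("cutoff_", ct$parameter)))))
    if (!is.na(fpr)) {
      allp <- logical(nrow(labeled))
      allp[labeled$label != "annotated"] <- pass_cand[, "all"]
      if (nrow(ann)) allp[labeled$label == "annotated"] <- pass_ann[, "all"]
      last_pass_level[allp] <- mult
      last_pass_fpr[allp] <- fpr
    }
    done_ok <- !is.na(fpr) && fpr <= config$fpr_target
    # parameters with zero reference strength can never be scaled up, so
    # the loop is exhausted once every positive strength has reached 1
    exhausted <- observed == 0L || all(ref <= 0) ||
      all(target_s[ref > 0] >= 1)
    if (done_ok || exhausted) {
      return(prediction_set(labeled, cand, ann, pass_cand, pass_ann, ct,
                            trace, N, expected, observed, fpr, mult,
                            converged = done_ok, last_pass_level,
                            last_pass_fpr,
                            diagnostic = if (!done_ok)
                              "no candidates left under scaled strengths"))
    }
    mult <- mult + multiplier_step
  }
}
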