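#' Run the full miRNA discovery pipeline
#'
#' reads -> exact mapping -> hairpin discovery -> ten-parameter scoring
#' -> annotation labeling -> FPR-calibrated prediction. All stages use
#' the constants in `config`; outputs are deterministic for identical
#' inputs and config.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param libraries read input(s): FASTA/FASTQ/TSV paths, data.frames or
#'   a prebuilt `read_library` (see [build_read_library()]).
#' @param annotation known-miRNA annotation (GFF3/BED path, `GRanges` or
#'   data.frame), see [label_candidates()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the standard reports
#'   (predictions GFF3, per-candidate parameter TSV, calibration trace
#'   TSV, run log).
#' @return list with `prediction` (a `mirna_prediction`), `candidates`
#'   (scored + labeled data.frame), `mapped` counts summary, `library`
#'   summary and `config`.
#' @export
run_pipeline <- function(genome, libraries, annotation,
                         config = pipeline_config(), out_dir = NULL) {
  index <- if (is(genome, "genome_index")) genome else build_index(genome)
  library <- if (is(libraries, "read_library")) libraries
             else build_read_library(libraries, adapter = config$adapter,
                                     min_overlap = config$min_overlap,
                                     require_adapter = config$require_adapter,
                                     min_len = config$min_len,
                                     max_len = config$max_len)
  mapped <- map_reads(library, index, max_hits = config$max_hits)
  candidates <- discover_candidates(mapped, index, config)
  candidates <- score_candidates(candidates, mapped, config)
  candidates <- label_candidates(candidates, annotation, index = index)
  prediction <- calibrate(candidates, config)

  funnel <- c(unique_reads = nrow(library$reads),
              total_count = library$total_count,
              placed_alignments = nrow(mapped$placed),
              multimapped_reads = nrow(mapped$multimap_pool),
              unmapped_reads = nrow(mapped$unmapped),
              candidate_loci = nrow(candidates),
              annotated_detected = sum(candidates$label == "annotated"),
              observed_passing = prediction$fpr_result$observed %||% NA)
  res <- list(prediction = prediction, candidates = candidates,
              funnel = funnel, config = config)
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

write_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_parameter_tsv(res$candidates, res$prediction,
                      file.path(out_dir, "parameters.tsv"))
  if (!is.null(res$prediction$trace))
    write.table(res$prediction$trace, file.path(out_dir, "trace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_predictions_gff3(res$prediction,
                         file.path(out_dir, "predictions.gff3"))
  log <- c(sprintf("mirscout %s", as.character(utils::packageVersion("mirscout"))),
           sprintf("folding backend: %s",
                   fold_backend(res$config$fold_backend)),
           sprintf("config: %s",
                   paste(names(unlist(res$config)), unlist(res$config),
                         sep = "=", collapse = " ")),
           paste(names(res$funnel), res$funnel, sep = "=", collapse = " "))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Write the per-candidate parameter report
#'
#' One row per candidate locus with coordinates, label, the ten
#' parameter values, the duplex structure summary and, when a
#' calibration result is supplied, per-parameter pass/fail at the final
#' cutoffs and the per-candidate FPR level.
#'
#' @param candidates scored + labeled candidates.
#' @param prediction optional `mirna_prediction`.
#' @param file output TSV path.
#' @return the path, invisibly.
#' @export
write_parameter_tsv <- function(candidates, prediction = NULL, file) {
  cols <- c("locus_id", "chrom", "strand", "pre_start", "pre_end",
            "guide_start", "guide_end", "guide_seq", "guide_count",
            "pass_start", "pass_end", "pass_seq", "pass_count",
            "guide_arm", "label", "het_5p", "het_3p", "overhang_a",
            "overhang_b", "duplex_mfe", "mfe_flank", "entropy_nt",
            "entropy_struct", "tailing", "multimap", "structure")
  out <- candidates[, intersect(cols, names(candidates)), drop = FALSE]
  if (!is.null(prediction) && !is.null(prediction$cutoffs)) {
    pass <- apply_cutoffs(candidates, prediction$cutoffs)
    colnames(pass) <- paste0("pass_", colnames(pass))
    out <- cbind(out, pass)
    out$fpr <- prediction$candidate_fpr$fpr[
      match(out$locus_id, prediction$candidate_fpr$locus_id)]
  }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write predicted miRNAs as GFF3
#'
#' Novel, antisense and annotated passing loci are emitted as
#' `miRNA_primary_transcript` features with two mature `miRNA` children
#' (1-based coordinates, strand-correct).
#'
#' @param prediction a `mirna_prediction`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_predictions_gff3 <- function(prediction, file) {
  sets <- list(novel = prediction$novel, antisense = prediction$antisense,
               annotated = prediction$annotated_passing)
  rows <- list()
  for (nm in names(sets)) {
    df <- sets[[nm]]
    if (is.null(df) || nrow(df) == 0L) next
    for (i in seq_len(nrow(df))) {
      x <- df[i, ]
      s5 <- if (x$guide_arm == "5p") c(x$guide_start, x$guide_end)
            else c(x$pass_start, x$pass_end)
      s3 <- if (x$guide_arm == "5p") c(x$pass_start, x$pass_end)
            else c(x$guide_start, x$guide_end)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = x$chrom, start = x$pre_start, end = x$pre_end,
        strand = x$strand, type = "miRNA_primary_transcript",
        ID = x$locus_id, Name = paste0(nm, "_", x$locus_id),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = x$chrom, start = s5[1L], end = s5[2L], strand = x$strand,
        type = "miRNA", ID = paste0(x$locus_id, "_5p"),
        Name = paste0(nm, "_", x$locus_id, "_5p"),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = x$chrom, start = s3[1L], end = s3[2L], strand = x$strand,
        type = "miRNA", ID = paste0(x$locus_id, "_3p"),
        Name = paste0(nm, "_", x$locus_id, "_3p"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", file)
    return(invisible(file))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$type <- df$type; gr$ID <- df$ID; gr$Name <- df$Name
  rtracklayer::export(gr, file, format = "GFF3")
  invisible(file)
}
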