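#' Cluster placed alignments into candidate hairpin windows
#'
#' Same-chromosome, same-strand alignments are grouped transitively:
#' two read stacks are linked whenever their combined interval fits within
#' `max_span` nt, i.e. the two stacks could sit on the arms of one
#' precursor hairpin. Clusters are maximal under this linkage.
#'
#' @param mapped a `mapped_read_set` (or its `placed` data.frame).
#' @param max_span maximal precursor span in nt (default 80).
#' @return list of data.frames of alignments, ordered by chromosome,
#'   strand and start.
#' @export
cluster_loci <- function(mapped, max_span = 80L) {
  placed <- if (is.data.frame(mapped)) mapped else mapped$placed
  if (nrow(placed) == 0L) return(list())
  placed <- placed[order(placed$chrom, placed$strand, placed$start,
                         placed$end), , drop = FALSE]
  key <- paste(placed$chrom, placed$strand)
  out <- list()
  for (k in unique(key)) {
    p <- placed[key == k, , drop = FALSE]
    cl_id <- integer(nrow(p)); cur <- 1L; cl_id[1L] <- 1L
    starts <- p$start; ends <- p$end
    mem <- 1L
    for (i in seq_len(nrow(p))[-1L]) {
      # sorted by start, so the combined interval starts at starts[mem]
      linked <- any(pmax(ends[mem], ends[i]) - starts[mem] <= max_span)
      if (!linked) { cur <- cur + 1L; mem <- integer() }
      cl_id[i] <- cur
      mem <- c(mem, i)
    }
    out <- c(out, split(p, cl_id))
  }
  names(out) <- NULL
  out[order(vapply(out, function(x) x$chrom[1L], character(1)),
            vapply(out, function(x) min(x$start), numeric(1)),
            vapply(out, function(x) x$strand[1L], character(1)))]
}

# valid passenger rows for a given guide row: non-overlapping, separated
# by at least min_loop nt, joint span within [min_span, max_span]
passenger_candidates <- function(cl, g, min_span, max_span, min_loop) {
  sep_ok <- cl$start >= cl$end[g] + min_loop | cl$end + min_loop <= cl$start[g]
  span <- pmax(cl$end, cl$end[g]) - pmin(cl$start, cl$start[g])
  which(sep_ok & span >= min_span & span <= max_span &
          seq_len(nrow(cl)) != g)
}

#' Assign guide and passenger strands within a read cluster
#'
#' The most abundant read stack becomes the guide; the most abundant
#' stack that can form a hairpin with it (non-overlapping, separated by a
#' minimal terminal loop, joint span within the precursor window) becomes
#' the passenger. Count ties are broken towards the lower duplex MFE and
#' then the smaller genomic start. Arms are labelled 5p/3p by transcript
#' orientation.
#'
#' @param cluster data.frame of alignments from [cluster_loci()].
#' @param min_span,max_span,min_loop window constraints (nt).
#' @param backend folding backend for tie-breaking duplexes.
#' @return a one-row candidate data.frame (without duplex/extension yet),
#'   or `NULL` when no valid pairing exists.
#' @export
assign_guide_passenger <- function(cluster, min_span = 46L, max_span = 80L,
                                   min_loop = 3L, backend = NULL) {
  cl <- cluster[order(-cluster$count, cluster$start), , drop = FALSE]
  if (nrow(cl) < 2L) return(NULL)
  g <- 1L
  cand <- passenger_candidates(cl, g, min_span, max_span, min_loop)
  if (length(cand) == 0L) return(NULL)
  top <- cand[cl$count[cand] == max(cl$count[cand])]
  if (length(top) > 1L) {
    # tie: prefer the thermodynamically supported pairing
    folds <- fold_duplex(rep(cl$sequence[g], length(top)),
                         cl$sequence[top], backend = backend)
    mfe <- vapply(folds, `[[`, numeric(1), "mfe")
    top <- top[order(mfe, cl$start[top])]
  }
  p <- top[1L]
  strand <- cl$strand[1L]
  # 5p arm is the arm nearer the transcript 5' end
  g_is_5p <- if (strand == "+") cl$start[g] < cl$start[p]
             else cl$start[g] > cl$start[p]
  data.frame(chrom = cl$chrom[1L], strand = strand,
             guide_start = cl$start[g], guide_end = cl$end[g],
             guide_seq = cl$sequence[g], guide_count = cl$count[g],
             pass_start = cl$start[p], pass_end = cl$end[p],
             pass_seq = cl$sequence[p], pass_count = cl$count[p],
             guide_arm = if (g_is_5p) "5p" else "3p",
             pre_start = min(cl$start[c(g, p)]),
             pre_end = max(cl$end[c(g, p)]),
             stringsAsFactors = FALSE)
}

#' Duplex energy gate
#' @param mfe duplex MFE (kcal/mol).
#' @param gate inclusive threshold (default -14).
#' @return logical: `TRUE` when the duplex passes (`mfe <= gate`).
#' @export
gate_duplex <- function(mfe, gate = -14) mfe <= gate

#' Extend a candidate locus with flanking genomic context
#'
#' Widens `pre_start`/`pre_end` by `flank` nt on each side (clipped at
#' the chromosome bounds; a `clipped` flag records truncation) and
#' refreshes `pre_sequence` from the genome on the locus strand.
#'
#' @param locus one-row candidate data.frame.
#' @param index a `genome_index`.
#' @param flank nt of context on each side (default 10).
#' @return the locus with `pre_start`, `pre_end`, `pre_sequence`,
#'   `clipped` updated.
#' @export
extend_locus <- function(locus, index, flank = 10L) {
  clen <- index$lengths[[locus$chrom]]
  s <- max(0L, locus$pre_start - flank)
  e <- min(clen, locus$pre_end + flank)
  locus$clipped <- (s != locus$pre_start - flank) ||
    (e != locus$pre_end + flank)
  locus$pre_start <- s
  locus$pre_end <- e
  locus$pre_sequence <- genome_seq(index, locus$chrom, s, e, locus$strand)
  locus
}

#' Discover candidate precursor loci from mapped reads
#'
#' Runs clustering, guide/passenger assignment, duplex folding and gating,
#' and flank extension; one candidate at most per cluster. Also attaches
#' the per-arm read stacks used later by the heterogeneity score: each
#' cluster alignment is assigned to the arm whose predominant read 5' end
#' is nearer.
#'
#' @param mapped a `mapped_read_set`.
#' @param index a `genome_index`.
#' @param config a [pipeline_config()].
#' @return data.frame of candidate loci (sorted by chrom, start, strand)
#'   with list columns `duplex` (a `duplex_fold` per row), `stack_5p`,
#'   `stack_3p` (alignment data.frames per arm).
#' @export
discover_candidates <- function(mapped, index, config = pipeline_config()) {
  clusters <- cluster_loci(mapped, max_span = config$max_span)
  rows <- lapply(clusters, assign_guide_passenger,
                 min_span = config$min_span, max_span = config$max_span,
                 min_loop = config$min_loop,
                 backend = config$fold_backend)
  keep <- !vapply(rows, is.null, logical(1))
  rows <- rows[keep]; clusters <- clusters[keep]
  if (length(rows) == 0L) return(empty_candidates())
  cand <- do.call(rbind, rows)

  seq5p <- ifelse(cand$guide_arm == "5p", cand$guide_seq, cand$pass_seq)
  seq3p <- ifelse(cand$guide_arm == "5p", cand$pass_seq, cand$guide_seq)
  duplexes <- fold_duplex(seq5p, seq3p, backend = config$fold_backend)
  cand$duplex_mfe <- vapply(duplexes, `[[`, numeric(1), "mfe")

  pass <- gate_duplex(cand$duplex_mfe, config$duplex_mfe_gate)
  cand <- cand[pass, , drop = FALSE]
  duplexes <- duplexes[pass]; clusters <- clusters[pass]
  if (nrow(cand) == 0L) return(empty_candidates())

  cand$pre_sequence <- NA_character_
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand)))
    out[[i]] <- extend_locus(cand[i, , drop = FALSE], index, config$flank)
  cand <- do.call(rbind, out)

  # per-arm read stacks (nearest predominant 5' end wins)
  stacks <- mapply(function(cl, i) {
    fp <- five_prime_pos(cl$start, cl$end, cl$strand)
    g5 <- five_prime_pos(cand$guide_start[i], cand$guide_end[i],
                         cand$strand[i])
    p5 <- five_prime_pos(cand$pass_start[i], cand$pass_end[i],
                         cand$strand[i])
    to_guide <- abs(fp - g5) <= abs(fp - p5)
    list(guide = cl[to_guide, , drop = FALSE],
         pass = cl[!to_guide, , drop = FALSE])
  }, clusters, seq_len(nrow(cand)), SIMPLIFY = FALSE)

  g_stacks <- lapply(stacks, `[[`, "guide")
  p_stacks <- lapply(stacks, `[[`, "pass")
  sel5p <- cand$guide_arm == "5p"
  stack_5p <- g_stacks; stack_5p[!sel5p] <- p_stacks[!sel5p]
  stack_3p <- p_stacks; stack_3p[!sel5p] <- g_stacks[!sel5p]
  cand$duplex <- I(duplexes)
  cand$stack_5p <- I(stack_5p)
  cand$stack_3p <- I(stack_3p)
  ord <- order(cand$chrom, cand$pre_start, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand$locus_id <- sprintf("locus_%04d", seq_len(nrow(cand)))
  cand
}

empty_candidates <- function() {
  data.frame(chrom = character(), strand = character(),
             guide_start = integer(), guide_end = integer(),
             guide_seq = character(), guide_count = integer(),
             pass_start = integer(), pass_end = integer(),
             pass_seq = character(), pass_count = integer(),
             guide_arm = character(), pre_start = integer(),
             pre_end = integer(), duplex_mfe = numeric(),
             pre_sequence = character(), clipped = logical(),
             locus_id = character(), stringsAsFactors = FALSE)
}
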