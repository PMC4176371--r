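#' 5' end heterogeneity of an arm read stack
#'
#' Count-weighted mean distance of read 5' ends from the predominant
#' read's 5' end: `H = sum(count * |off5' - off5'(predominant)|) /
#' sum(count)`. Precise RNase III processing leaves the 5' end of genuine
#' miRNAs sharp, so low values indicate miRNA-like stacks.
#'
#' @param stack data.frame of alignments (`start`, `end`, `strand`,
#'   `count`) on one arm.
#' @return non-negative heterogeneity score (nt, count-weighted).
#' @export
score_heterogeneity <- function(stack) {
  if (is.null(stack) || nrow(stack) == 0L) stop("empty arm stack")
  fp <- five_prime_pos(stack$start, stack$end, stack$strand)
  pred <- fp[which.max(stack$count)]
  sum(stack$count * abs(fp - pred)) / sum(stack$count)
}

#' Duplex terminus overhangs
#'
#' From the guide/passenger duplex fold, computes the signed overhang at
#' the two duplex termini: positive values are 3' protrusions, negative
#' values 5' protrusions. Terminus A is the 5p-5'/3p-3' end, terminus B
#' the 5p-3'/3p-5' end (strand A of the fold must be the 5p arm).
#' Drosha/Dicer processing leaves +2/+2.
#'
#' @param duplex a `duplex_fold` with the 5p arm as strand A.
#' @return named integer vector `c(a = ..., b = ...)`; `NA` when the
#'   duplex has no pairs.
#' @export
score_overhangs <- function(duplex) {
  if (nrow(duplex$pairs) == 0L) return(c(a = NA_integer_, b = NA_integer_))
  u <- duplex$unpaired
  c(a = unname(u["b3"] - u["a5"]), b = unname(u["a3"] - u["b5"]))
}

#' Nucleotide entropy of the precursor sequence
#'
#' Shannon entropy (bits) of overlapping k-nucleotide frequencies
#' (default dinucleotides) of the extended precursor sequence. Simple
#' repeats score low; genuine miRNA precursors tend to score high.
#'
#' @param pre_sequence precursor sequence (with flanks).
#' @param k word size (default 2).
#' @return entropy in bits.
#' @export
score_entropy_nt <- function(pre_sequence, k = 2L) {
  kmer_entropy(pre_sequence, k)
}

#' Structural entropy of the precursor fold
#'
#' Shannon entropy (bits) of overlapping k-character windows (default
#' triplets) of the dot-bracket string of the precursor MFE structure.
#' Clean stem-loops use few distinct structural words and score low.
#'
#' @param structure dot-bracket string.
#' @param k window size (default 3).
#' @return entropy in bits.
#' @export
score_entropy_struct <- function(structure, k = 3L) {
  kmer_entropy(structure, k)
}

#' Non-templated 3' tailing score of candidate loci
#'
#' Genome-unmapped reads are aligned to each candidate's precursor
#' sequence allowing mismatches. A read is TAILED when its only
#' mismatches form a contiguous 3'-terminal run of at most `max_tail` nt
#' consisting solely of A/T (U): the signature of post-transcriptional
#' adenylation/uridylation. A read aligning with 1..`max_other`
#' mismatches elsewhere counts as OTHER. The score is
#' `TAILED / (TAILED + OTHER)` (read counts), `NA` when there is no
#' evidence either way.
#'
#' @param pre_sequences character vector of precursor sequences.
#' @param unmapped data.frame (`sequence`, `count`) of genome-unmapped
#'   reads.
#' @param max_tail maximal tail length (default 3).
#' @param max_other maximal non-tail mismatches (default 2).
#' @return data.frame with `tailed`, `other` (read counts) and `tailing`
#'   (proportion or `NA`).
#' @export
score_tailing <- function(pre_sequences, unmapped, max_tail = 3L,
                          max_other = 2L) {
  n <- length(pre_sequences)
  res <- data.frame(tailed = numeric(n), other = numeric(n),
                    tailing = rep(NA_real_, n))
  if (n == 0L || is.null(unmapped) || nrow(unmapped) == 0L) return(res)
  # seed heuristic: reads are >= 18 nt, so three disjoint 6-mers cover
  # positions 1-18; <= 2 scattered mismatches or a <= 3 nt terminal tail
  # can corrupt at most two of them, hence a qualifying read always has
  # one seed occurring exactly in the precursor sequence
  sw <- 6L
  reads <- unmapped$sequence
  ok <- nchar(reads) >= 3L * sw
  reads <- reads[ok]; cnt <- unmapped$count[ok]
  if (length(reads) == 0L) return(res)
  seeds <- rbind(substr(reads, 1L, sw),
                 substr(reads, sw + 1L, 2L * sw),
                 substr(reads, 2L * sw + 1L, 3L * sw))
  useeds <- unique(as.vector(seeds))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))
  subj <- Biostrings::DNAStringSet(pre_sequences)
  hits <- Biostrings::vwhichPDict(pd, subj)
  seed_of_read <- matrix(match(seeds, useeds), nrow = 3L)
  for (i in seq_len(n)) {
    present <- hits[[i]]
    if (length(present) == 0L) next
    cand_reads <- which(colSums(matrix(seed_of_read %in% present,
                                       nrow = 3L)) > 0L)
    if (length(cand_reads) == 0L) next
    tailed <- 0; other <- 0
    for (r in cand_reads) {
      cls <- classify_unmapped_cpp(reads[r], pre_sequences[i],
                                   max_tail, max_other)
      if (cls == 2L) tailed <- tailed + cnt[r]
      else if (cls == 1L) other <- other + cnt[r]
    }
    res$tailed[i] <- tailed; res$other[i] <- other
    if (tailed + other > 0) res$tailing[i] <- tailed / (tailed + other)
  }
  res
}

#' Multimapping contamination score of candidate loci
#'
#' Reads discarded at mapping time for exceeding the genomic hit limit
#' are matched back (exact match) onto each precursor sequence; the score
#' is `m / (m + s)` where `m` is their summed count on the locus and `s`
#' the summed count of placed reads on the locus. High values flag loci
#' whose read evidence is ambiguous.
#'
#' @param pre_sequences character vector of precursor sequences.
#' @param placed_counts numeric vector: summed placed read count per
#'   locus.
#' @param multimap_pool data.frame (`sequence`, `count`).
#' @return numeric vector of proportions in `[0, 1]`.
#' @export
score_multimap <- function(pre_sequences, placed_counts, multimap_pool) {
  n <- length(pre_sequences)
  m <- numeric(n)
  if (!is.null(multimap_pool) && nrow(multimap_pool) > 0L) {
    subj <- Biostrings::DNAStringSet(pre_sequences)
    widths <- nchar(multimap_pool$sequence)
    for (w in unique(widths)) {
      idx <- which(widths == w)
      pd <- Biostrings::PDict(
        Biostrings::DNAStringSet(multimap_pool$sequence[idx]))
      cnts <- Biostrings::vcountPDict(pd, subj)
      m <- m + as.vector(crossprod(cnts > 0L, multimap_pool$count[idx]))
    }
  }
  m / (m + placed_counts)
}

#' Score candidate loci on the ten biogenesis-signature parameters
#'
#' Adds to the candidate table: `het_5p`, `het_3p` (5' heterogeneity per
#' arm), `overhang_a`, `overhang_b` (duplex terminus overhangs, +2/+2 for
#' canonical processing), `mfe_duplex`, `mfe_flank` (folding energy of
#' duplex and of the full extended precursor), `entropy_nt`,
#' `entropy_struct`, `tailing` and `multimap`, plus the precursor
#' dot-bracket `structure`.
#'
#' @param candidates data.frame from [discover_candidates()].
#' @param mapped the `mapped_read_set` the candidates came from.
#' @param config a [pipeline_config()].
#' @return the candidate data.frame with parameter columns appended.
#' @export
score_candidates <- function(candidates, mapped,
                             config = pipeline_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates$het_5p <- vapply(candidates$stack_5p, score_heterogeneity,
                              numeric(1))
  candidates$het_3p <- vapply(candidates$stack_3p, score_heterogeneity,
                              numeric(1))
  ov <- t(vapply(candidates$duplex, score_overhangs, integer(2)))
  candidates$overhang_a <- ov[, "a"]
  candidates$overhang_b <- ov[, "b"]
  # duplex MFE was computed at gating time
  hp <- fold_hairpin(candidates$pre_sequence,
                     backend = config$fold_backend)
  candidates$mfe_flank <- hp$mfe
  candidates$structure <- hp$structure
  candidates$entropy_nt <- vapply(candidates$pre_sequence,
                                  score_entropy_nt, numeric(1),
                                  USE.NAMES = FALSE)
  candidates$entropy_struct <- vapply(candidates$structure,
                                      score_entropy_struct, numeric(1),
                                      USE.NAMES = FALSE)
  tl <- score_tailing(candidates$pre_sequence, mapped$unmapped)
  candidates$tailing <- tl$tailing
  placed_counts <- vapply(seq_len(nrow(candidates)), function(i) {
    sum(candidates$stack_5p[[i]]$count) +
      sum(candidates$stack_3p[[i]]$count)
  }, numeric(1))
  candidates$multimap <- score_multimap(candidates$pre_sequence,
                                        placed_counts,
                                        mapped$multimap_pool)
  candidates
}
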