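#' Build an exact-match genome index
#'
#' Wraps the genome as a [Biostrings::DNAStringSet] ready for exact
#' pattern matching on both strands; the actual k-mer preprocessing is
#' done per query batch by [Biostrings::PDict()], so the "index" mainly
#' validates and normalises the reference.
#'
#' @param genome path to a FASTA file or a `DNAStringSet`.
#' @return a `genome_index` (list with `seqs` and `lengths`).
#' @export
build_index <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(is(genome, "DNAStringSet"))
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must have unique names")
  structure(list(seqs = genome,
                 lengths = setNames(Biostrings::width(genome),
                                    names(genome))),
            class = "genome_index")
}

#' Extract genomic sequence of a 0-based half-open interval
#'
#' @param index a `genome_index`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval on the plus strand.
#' @param strand returned sequence is reverse-complemented for `"-"`.
#' @return character sequence.
#' @export
genome_seq <- function(index, chrom, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(index$seqs[[chrom]],
                                       start = start + 1L, end = end))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Map collapsed reads to the genome with zero mismatches
#'
#' Every perfect occurrence of every read is enumerated on both strands.
#' Reads with 1..`max_hits` occurrences are "placed" (all occurrences
#' listed); reads with more hits go to the multimap pool (alignments
#' dropped, counts kept for the multimapping score); reads with no
#' perfect hit are retained for the tailing score.
#'
#' Coordinates are 0-based half-open on the plus strand; for minus-strand
#' alignments the biological 5' end is `end - 1` (see
#' [five_prime_pos()]).
#'
#' @param library a `read_library` (or data.frame with `sequence`,
#'   `count`).
#' @param index a `genome_index` from [build_index()].
#' @param max_hits maximum genomic hit count for placement (default 4).
#' @return a `mapped_read_set`: list with data.frames `placed`
#'   (`sequence`, `count`, `chrom`, `start`, `end`, `strand`, `n_hits`),
#'   `multimap_pool` (`sequence`, `count`, `n_hits`) and `unmapped`
#'   (`sequence`, `count`).
#' @export
map_reads <- function(library, index, max_hits = 4L) {
  tab <- if (is.data.frame(library)) library else library$reads
  empty_placed <- data.frame(sequence = character(), count = integer(),
                             chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             n_hits = integer(), stringsAsFactors = FALSE)
  pool <- data.frame(sequence = character(), count = integer(),
                     n_hits = integer(), stringsAsFactors = FALSE)
  unmapped <- data.frame(sequence = character(), count = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    return(structure(list(placed = empty_placed, multimap_pool = pool,
                          unmapped = unmapped), class = "mapped_read_set"))

  hits <- vector("list", nrow(tab))
  widths <- nchar(tab$sequence)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(tab$sequence[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (chrom in names(index$seqs)) {
      subject <- index$seqs[[chrom]]
      if (length(subject) < w) next
      mf <- Biostrings::matchPDict(pd_f, subject)
      mr <- Biostrings::matchPDict(pd_r, subject)
      for (k in seq_along(idx)) {
        sf <- Biostrings::startIndex(mf)[[k]]
        sr <- Biostrings::startIndex(mr)[[k]]
        add <- NULL
        if (length(sf))
          add <- data.frame(chrom = chrom, start = sf - 1L,
                            end = sf - 1L + w, strand = "+",
                            stringsAsFactors = FALSE)
        if (length(sr))
          add <- rbind(add,
                       data.frame(chrom = chrom, start = sr - 1L,
                                  end = sr - 1L + w, strand = "-",
                                  stringsAsFactors = FALSE))
        if (!is.null(add)) hits[[idx[k]]] <- rbind(hits[[idx[k]]], add)
      }
    }
  }

  n_hits <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h),
                   integer(1))
  placed_idx <- which(n_hits >= 1L & n_hits <= max_hits)
  placed <- empty_placed
  if (length(placed_idx)) {
    placed <- do.call(rbind, lapply(placed_idx, function(i) {
      h <- hits[[i]]
      data.frame(sequence = tab$sequence[i], count = tab$count[i],
                 chrom = h$chrom, start = h$start, end = h$end,
                 strand = h$strand, n_hits = n_hits[i],
                 stringsAsFactors = FALSE)
    }))
    placed <- placed[order(placed$chrom, placed$start, placed$strand,
                           placed$sequence), , drop = FALSE]
    rownames(placed) <- NULL
  }
  mm <- which(n_hits > max_hits)
  if (length(mm))
    pool <- data.frame(sequence = tab$sequence[mm], count = tab$count[mm],
                       n_hits = n_hits[mm], stringsAsFactors = FALSE)
  um <- which(n_hits == 0L)
  if (length(um))
    unmapped <- data.frame(sequence = tab$sequence[um],
                           count = tab$count[um], stringsAsFactors = FALSE)
  structure(list(placed = placed, multimap_pool = pool,
                 unmapped = unmapped), class = "mapped_read_set")
}

#' @export
print.mapped_read_set <- function(x, ...) {
  cat(sprintf(paste0("mapped_read_set: %d placed alignments, ",
                     "%d multimapped reads, %d unmapped reads\n"),
              nrow(x$placed), nrow(x$multimap_pool), nrow(x$unmapped)))
  invisible(x)
}

#' Write placed alignments as BED
#' @param mapped a `mapped_read_set`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_alignments_bed <- function(mapped, file) {
  p <- mapped$placed
  bed <- data.frame(p$chrom, p$start, p$end, p$sequence, p$count, p$strand)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
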