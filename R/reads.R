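#' Trim a 3' sequencing adapter from reads
#'
#' Exact matching only, consistent with the zero-mismatch mapping regime
#' downstream: a read is trimmed at the leftmost full occurrence of the
#' adapter, or at a 3'-anchored exact prefix of the adapter of at least
#' `min_overlap` nt. Reads without adapter evidence are returned untrimmed,
#' or rejected (`NA`) when `require_adapter` is set.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param adapter adapter sequence.
#' @param min_overlap minimum 3'-anchored adapter prefix length.
#' @param require_adapter reject reads without adapter evidence.
#' @return character vector of trimmed reads; `NA` marks rejected reads.
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACTGGAATTC", "TGGAATTC")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L,
                         require_adapter = FALSE) {
  if (is.null(adapter) || !nzchar(adapter)) stop("adapter must be non-empty")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  reads <- check_dna(reads, allow_n = TRUE, what = "read")
  adapter <- check_dna(adapter, allow_n = FALSE, what = "adapter")

  out <- character(length(reads))
  alen <- nchar(adapter)
  hit <- regexpr(adapter, reads, fixed = TRUE)
  for (i in seq_along(reads)) {
    r <- reads[i]
    if (hit[i] > 0L) {
      out[i] <- substr(r, 1L, hit[i] - 1L)
      next
    }
    L <- nchar(r)
    found <- FALSE
    for (k in seq(min(alen - 1L, L), min_overlap)) {
      if (substr(r, L - k + 1L, L) == substr(adapter, 1L, k)) {
        out[i] <- substr(r, 1L, L - k)
        found <- TRUE
        break
      }
    }
    if (!found) out[i] <- if (require_adapter) NA_character_ else r
  }
  out
}

#' Collapse trimmed reads into a unique-sequence library
#'
#' Unique sequences are counted (optionally weighted by pre-existing
#' counts), reads outside `[min_len, max_len]` and reads containing N are
#' dropped. The 18-26 nt default window retains mature miRNA-sized reads.
#'
#' @param reads character vector of trimmed read sequences (`NA` entries,
#'   e.g. adapter rejects, are dropped).
#' @param counts optional integer vector of per-read counts (default 1).
#' @param min_len,max_len retained length range.
#' @param n_libraries provenance: how many libraries were pooled.
#' @return a `read_library`: list with `reads` (data.frame of `sequence`,
#'   `count`, sorted by sequence), `total_count` and `n_libraries`.
#' @export
collapse_and_filter <- function(reads, counts = NULL, min_len = 18L,
                                max_len = 26L, n_libraries = 1L) {
  if (is.null(counts)) counts <- rep(1L, length(reads))
  stopifnot(length(counts) == length(reads))
  keep <- !is.na(reads)
  reads <- toupper(reads[keep]); counts <- counts[keep]
  check_dna(reads, allow_n = TRUE, what = "read")
  len <- nchar(reads)
  keep <- len >= min_len & len <= max_len & !grepl("N", reads, fixed = TRUE)
  reads <- reads[keep]; counts <- counts[keep]
  if (length(reads) == 0L) {
    warning("read library is empty after filtering")
    tab <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    agg <- rowsum(as.numeric(counts), group = reads)
    tab <- data.frame(sequence = rownames(agg),
                      count = as.integer(agg[, 1L]),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$sequence), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(reads = tab, total_count = sum(tab$count),
                 n_libraries = as.integer(n_libraries)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library: %d unique sequences, %d reads (%d libraries)\n",
              nrow(x$reads), x$total_count, x$n_libraries))
  invisible(x)
}

read_one_library <- function(file) {
  lf <- tolower(file)
  if (grepl("\\.(tsv|txt|tab)$", lf)) {
    tab <- read.table(file, sep = "\t", header = FALSE,
                      col.names = c("sequence", "count"),
                      colClasses = c("character", "integer"))
    return(tab)
  }
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", lf)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(file, format = fmt)
  data.frame(sequence = as.character(seqs), count = 1L,
             stringsAsFactors = FALSE)
}

#' Read, trim and collapse small RNA libraries
#'
#' Accepts FASTA/FASTQ files, pre-collapsed two-column
#' `sequence<TAB>count` tables, data.frames with `sequence`/`count`
#' columns, or plain character vectors of reads. Counts are pooled across
#' all inputs before collapsing, so recurrent sequences accumulate evidence
#' across libraries. Pre-collapsed tables bypass adapter trimming.
#'
#' @param inputs a file path vector, a data.frame, a character vector of
#'   reads, or a list mixing these.
#' @param adapter optional adapter to trim from raw (non-collapsed) reads.
#' @param min_overlap,require_adapter see [trim_adapter()].
#' @param min_len,max_len retained length range.
#' @return a `read_library` (see [collapse_and_filter()]).
#' @export
build_read_library <- function(inputs, adapter = NULL, min_overlap = 5L,
                               require_adapter = FALSE, min_len = 18L,
                               max_len = 26L) {
  if (!is.list(inputs) || is.data.frame(inputs)) inputs <- list(inputs)
  seqs <- character(); cnts <- integer(); n_lib <- 0L
  for (inp in inputs) {
    if (is.character(inp) && length(inp) == 1L && file.exists(inp)) {
      inp <- read_one_library(inp)
    }
    if (is.data.frame(inp)) {
      tab <- data.frame(sequence = toupper(inp$sequence),
                        count = if ("count" %in% names(inp)) inp$count else 1L,
                        stringsAsFactors = FALSE)
      precollapsed <- any(tab$count != 1L)
    } else if (is.character(inp)) {
      tab <- data.frame(sequence = toupper(inp), count = 1L,
                        stringsAsFactors = FALSE)
      precollapsed <- FALSE
    } else {
      stop("unsupported input type for read library")
    }
    if (!is.null(adapter) && !precollapsed) {
      tab$sequence <- trim_adapter(tab$sequence, adapter, min_overlap,
                                   require_adapter)
    }
    seqs <- c(seqs, tab$sequence); cnts <- c(cnts, tab$count)
    n_lib <- n_lib + 1L
  }
  collapse_and_filter(seqs, cnts, min_len = min_len, max_len = max_len,
                      n_libraries = n_lib)
}

#' Write / read a collapsed sequence-count table
#' @param library a `read_library`.
#' @param file path of the two-column TSV.
#' @return `read_collapsed_tsv` returns a `read_library`.
#' @export
write_collapsed_tsv <- function(library, file) {
  write.table(library$reads, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_collapsed_tsv
#' @export
read_collapsed_tsv <- function(file) {
  tab <- read_one_library(file)
  collapse_and_filter(tab$sequence, tab$count, min_len = 1L,
                      max_len = .Machine$integer.max)
}
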