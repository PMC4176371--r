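COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA character vectors
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s characters (first offender: '%s')",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 x[which(bad)[1]]), call. = FALSE)
  }
  toupper(x)
}

#' Strand-aware 5' end coordinate
#'
#' For 0-based half-open intervals, the biological 5' end of a read on the
#' plus strand is `start`; on the minus strand it is `end - 1`.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of "+"/"-".
#' @return integer vector of 5'-end genomic positions.
#' @export
five_prime_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

#' Strand-aware 3' end coordinate
#' @inheritParams five_prime_pos
#' @return integer vector of 3'-end genomic positions.
#' @export
three_prime_pos <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

# Shannon entropy (bits) of overlapping k-mer frequencies of a string.
kmer_entropy <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(0)
  kmers <- substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  p <- table(kmers) / length(kmers)
  -sum(p * log2(p))
}
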