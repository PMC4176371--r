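# Independent oracles and small fixture builders used across tests.

# brute-force exact mapping: O(n*m) sliding window over both strands
naive_map_read <- function(read, genome_chars) {
  hits <- NULL
  w <- nchar(read)
  rc <- revcomp(read)
  for (chrom in names(genome_chars)) {
    g <- genome_chars[[chrom]]
    L <- nchar(g)
    if (L < w) next
    windows <- substring(g, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
    for (s in which(windows == read))
      hits <- rbind(hits, data.frame(chrom = chrom, start = s - 1L,
                                     end = s - 1L + w, strand = "+"))
    for (s in which(windows == rc))
      hits <- rbind(hits, data.frame(chrom = chrom, start = s - 1L,
                                     end = s - 1L + w, strand = "-"))
  }
  hits
}

# direct k-mer entropy from first principles (independent of kmer_entropy)
oracle_entropy <- function(x, k) {
  n <- nchar(x)
  words <- character(0)
  for (i in seq_len(n - k + 1L)) words <- c(words, substr(x, i, i + k - 1L))
  tab <- table(words)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log2(p))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# an alignment stack data.frame on the plus strand from 5' offsets/counts
stack_from_offsets <- function(offsets, counts, width = 22L,
                               strand = "+", base = 1000L) {
  if (strand == "+") {
    start <- base + offsets
  } else {
    # 5' end of a minus-strand read is end-1
    start <- base - offsets - width + 1L
  }
  data.frame(chrom = "chr1", start = start, end = start + width,
             strand = strand, count = counts,
             sequence = vapply(seq_along(offsets), function(i)
               rand_seq(width), character(1)),
             stringsAsFactors = FALSE)
}

# small simulation shared by discovery/pipeline tests
small_sim <- function(seed = 5L) {
  cfg <- sim_config(seed = seed, genome_length = 40000L, n_chrom = 1L,
                    n_mirnas = 6L, n_annotated = 3L, n_marginal = 1L,
                    n_decoys = 12L, read_depth = 60)
  list(cfg = cfg, sim = simulate_dataset(cfg))
}

small_config <- function(...) pipeline_config(min_annotated = 3L, ...)
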