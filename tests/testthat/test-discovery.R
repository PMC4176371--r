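mk_placed <- function(starts, counts, width = 22L, chrom = "chr1",
                      strand = "+") {
  data.frame(chrom = chrom, start = starts, end = starts + width,
             strand = strand, count = counts,
             sequence = vapply(starts, function(s) rand_seq(width),
                               character(1)),
             n_hits = 1L, stringsAsFactors = FALSE)
}

test_that("clustering links stacks that fit one precursor window", {
  set.seed(31)
  # two stacks 30 nt apart fit an 80 nt window -> one cluster
  cl <- cluster_loci(mk_placed(c(0L, 30L), c(10L, 5L)), max_span = 80L)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 2L)
  # 200 nt apart -> two clusters
  cl <- cluster_loci(mk_placed(c(0L, 200L), c(10L, 5L)), max_span = 80L)
  expect_length(cl, 2L)
  # chain 0/40/90: 0-40 fits (span 62), 40-90 does not (span 72+?); with
  # width 22 span(40,90) = 112-40 = 72 <= 80 so all three chain; with
  # width 35 span(40,90) = 125-40 = 85 > 80 and span(0,40) = 75 <= 80
  cl <- cluster_loci(mk_placed(c(0L, 40L, 90L), c(9L, 8L, 7L),
                               width = 35L), max_span = 80L)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, nrow, integer(1)), c(2L, 1L))
  # opposite strands never cluster together
  both <- rbind(mk_placed(0L, 5L), mk_placed(10L, 5L, strand = "-"))
  expect_length(cluster_loci(both, max_span = 80L), 2L)
})

test_that("guide/passenger assignment follows abundance and the span window", {
  set.seed(32)
  cl <- mk_placed(c(0L, 40L), c(100L, 20L))
  res <- assign_guide_passenger(cl, min_span = 46L, max_span = 80L)
  expect_equal(res$guide_start, 0L)
  expect_equal(res$guide_count, 100L)
  expect_equal(res$pass_start, 40L)
  expect_equal(res$pre_end - res$pre_start, 62L)   # joint span 62
  expect_equal(res$guide_arm, "5p")                # + strand, leftmost
  # guide on the right of a minus-strand cluster is the 5p arm
  clm <- mk_placed(c(0L, 40L), c(100L, 20L), strand = "-")
  expect_equal(assign_guide_passenger(clm)$guide_arm, "3p")
  # single stack: no pairing possible
  expect_null(assign_guide_passenger(mk_placed(0L, 50L)))
  # overlapping stacks cannot be guide and passenger
  expect_null(assign_guide_passenger(mk_placed(c(0L, 10L), c(9L, 5L))))
  # count tie: smaller genomic start becomes the guide
  tie <- assign_guide_passenger(mk_placed(c(0L, 40L), c(100L, 100L)))
  expect_equal(tie$guide_start, 0L)
})

test_that("the duplex gate is inclusive at the threshold", {
  expect_true(gate_duplex(-14.0, gate = -14))
  expect_true(gate_duplex(-20, gate = -14))
  expect_false(gate_duplex(-13.9, gate = -14))
})

test_that("locus extension adds clipped flanks and refreshes the sequence", {
  set.seed(33)
  g <- rand_seq(300)
  idx <- build_index(Biostrings::DNAStringSet(c(chr1 = g)))
  locus <- data.frame(chrom = "chr1", strand = "+", pre_start = 100L,
                      pre_end = 162L, stringsAsFactors = FALSE)
  ext <- extend_locus(locus, idx, flank = 10L)
  expect_equal(c(ext$pre_start, ext$pre_end), c(90L, 172L))
  expect_false(ext$clipped)
  expect_equal(ext$pre_sequence, substr(g, 91, 172))
  # clipping at the chromosome start
  lo <- extend_locus(data.frame(chrom = "chr1", strand = "+",
                                pre_start = 4L, pre_end = 60L), idx, 10L)
  expect_equal(lo$pre_start, 0L)
  expect_true(lo$clipped)
  # flank = 0 keeps the guide/passenger span
  id <- extend_locus(locus, idx, flank = 0L)
  expect_equal(c(id$pre_start, id$pre_end), c(100L, 162L))
  # minus strand sequences are reverse complemented
  lm <- extend_locus(data.frame(chrom = "chr1", strand = "-",
                                pre_start = 100L, pre_end = 162L), idx, 0L)
  expect_equal(lm$pre_sequence, revcomp(substr(g, 101, 162)))
})

test_that("discovery finds every planted miRNA whose reads map", {
  ss <- small_sim()
  pc <- small_config()
  lib <- build_read_library(ss$sim$reads)
  idx <- build_index(ss$sim$genome)
  mapped <- map_reads(lib, idx)
  cand <- discover_candidates(mapped, idx, pc)
  tr <- ss$sim$truth
  mir <- tr[grepl("mirna", tr$class), ]
  for (i in seq_len(nrow(mir))) {
    t <- mir[i, ]
    hit <- cand$chrom == t$chrom & cand$strand == t$strand &
      cand$pre_start < t$pre_end & cand$pre_end > t$pre_start
    expect_true(any(hit), label = paste("planted", t$locus_id, "found"))
    j <- which(hit)[1]
    expect_equal(cand$guide_start[j], t$guide_start)
    expect_equal(cand$pass_start[j], t$pass_start)
  }
  # every candidate satisfies the locus invariants
  expect_true(all(cand$guide_count >= cand$pass_count))
  expect_true(all(cand$duplex_mfe <= pc$duplex_mfe_gate))
  span <- pmax(cand$guide_end, cand$pass_end) -
    pmin(cand$guide_start, cand$pass_start)
  expect_true(all(span >= pc$min_span & span <= pc$max_span))
  ovl <- pmin(cand$guide_end, cand$pass_end) -
    pmax(cand$guide_start, cand$pass_start)
  expect_true(all(ovl < 0))
  # determinism: a second run is identical
  cand2 <- discover_candidates(mapped, idx, pc)
  expect_identical(cand[, !vapply(cand, is.list, logical(1))],
                   cand2[, !vapply(cand2, is.list, logical(1))])
})
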