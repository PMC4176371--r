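test_that("the generator is deterministic for a fixed seed and config", {
  cfg <- sim_config(seed = 9L, genome_length = 30000L, n_chrom = 1L,
                    n_mirnas = 4L, n_annotated = 2L, n_marginal = 1L,
                    n_decoys = 8L, read_depth = 30)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  # a different seed changes the genome
  c <- simulate_dataset(sim_config(seed = 10L, genome_length = 30000L,
                                   n_chrom = 1L, n_mirnas = 4L,
                                   n_annotated = 2L, n_marginal = 1L,
                                   n_decoys = 8L, read_depth = 30))
  expect_false(identical(as.character(a$genome),
                         as.character(c$genome)))
})

test_that("planted cassettes encode the designed duplex geometry", {
  set.seed(71)
  for (i in 1:3) {
    sp <- plant_mirna(sim_config())
    a5 <- substr(sp$cassette, sp$arm5p[1] + 1, sp$arm5p[2])
    a3 <- substr(sp$cassette, sp$arm3p[1] + 1, sp$arm3p[2])
    d <- fold_duplex(a5, a3)[[1]]
    expect_lte(d$mfe, -14)
    expect_equal(score_overhangs(d), c(a = 2L, b = 2L))
  }
  # marginal exemplars sit between clean miRNAs and decoys: gate-passing
  # but weaker duplex, shifted register
  set.seed(72)
  mg <- plant_mirna(sim_config(), marginal = TRUE,
                    loop_seq = strrep("CTA", 7) |> substr(1, 20))
  a5 <- substr(mg$cassette, mg$arm5p[1] + 1, mg$arm5p[2])
  a3 <- substr(mg$cassette, mg$arm3p[1] + 1, mg$arm3p[2])
  dm <- fold_duplex(a5, a3)[[1]]
  expect_lte(dm$mfe, -14)
  expect_gte(dm$mfe, -26)
})

test_that("planted truth intervals contain the sequences reads come from", {
  ss <- small_sim(seed = 6L)
  sim <- ss$sim
  idx <- build_index(sim$genome)
  tr <- sim$truth
  mir <- tr[tr$class == "mirna_clean", ]
  for (i in seq_len(nrow(mir))) {
    t <- mir[i, ]
    gseq <- genome_seq(idx, t$chrom, t$guide_start, t$guide_end, t$strand)
    # the predominant guide read is among the simulated reads with a
    # dominant count (sharp 5' ends)
    j <- match(gseq, sim$reads$sequence)
    expect_false(is.na(j), label = paste("guide read of", t$locus_id))
    near <- sim$reads$count[j]
    expect_gte(near, 0.5 * ss$cfg$read_depth)
  }
})

test_that("simulated tailing matches the configured rate", {
  cfg <- sim_config(seed = 13L, genome_length = 30000L, n_chrom = 1L,
                    n_mirnas = 5L, n_annotated = 2L, n_marginal = 0L,
                    n_decoys = 0L, read_depth = 100, tail_prob = 0.5)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$genome)
  tr <- sim$truth[sim$truth$class == "mirna_clean", ]
  ratios <- vapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i, ]
    gseq <- genome_seq(idx, t$chrom, t$guide_start, t$guide_end, t$strand)
    tails <- grepl(paste0("^", gseq, "[AT]{1,3}$"), sim$reads$sequence)
    n_guide <- sim$reads$count[match(gseq, sim$reads$sequence)]
    sum(sim$reads$count[tails]) / n_guide
  }, numeric(1))
  # binomial tolerance around 0.5 at depth ~100 per locus
  expect_true(all(ratios > 0.3 & ratios < 0.7))
  # tails must be non-templated: the tailed read never maps perfectly
  lib <- build_read_library(sim$reads)
  mapped <- map_reads(lib, idx)
  tail_reads <- sim$reads$sequence[grepl("[AT]{1}$", sim$reads$sequence) &
                                     nchar(sim$reads$sequence) > 22]
  expect_true(all(tail_reads %in% mapped$unmapped$sequence))
})

test_that("the toy annotation round-trips through GFF3", {
  ss <- small_sim(seed = 8L)
  dir <- tempfile()
  out <- simulate_dataset(ss$cfg, dir = dir)
  expect_true(all(file.exists(unlist(out$files))))
  ann <- rtracklayer::import(out$files$annotation)
  pri <- ann[ann$type == "miRNA_primary_transcript"]
  tr <- out$truth[out$truth$annotated, ]
  expect_equal(length(pri), nrow(tr))
  ord <- order(GenomicRanges::start(pri))
  tro <- tr[order(tr$pre_start), ]
  expect_equal(GenomicRanges::start(pri)[ord], tro$pre_start + 1L)
  expect_equal(GenomicRanges::end(pri)[ord], tro$pre_end)
  # genome file reproduces the in-memory genome
  g2 <- Biostrings::readDNAStringSet(out$files$genome)
  expect_equal(as.character(g2), as.character(out$genome),
               ignore_attr = TRUE)
})

test_that("an overcrowded genome is rejected", {
  cfg <- sim_config(seed = 1L, genome_length = 5000L, n_mirnas = 10L,
                    n_decoys = 50L)
  expect_error(make_genome(cfg), "overcrowded|too small")
})
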