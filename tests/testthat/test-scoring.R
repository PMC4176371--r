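test_that("5' heterogeneity matches hand-computed stack values", {
  set.seed(41)
  # single stack: distance to the predominant read is zero
  expect_equal(score_heterogeneity(stack_from_offsets(0L, 50L)), 0)
  # (90*0 + 10*1) / 100
  expect_equal(score_heterogeneity(
    stack_from_offsets(c(0L, 1L), c(90L, 10L))), 0.1)
  # (50*0 + 25*2 + 25*2) / 100
  expect_equal(score_heterogeneity(
    stack_from_offsets(c(0L, 2L, -2L), c(50L, 25L, 25L))), 1.0)
  # strand-aware: same offsets on the minus strand give the same score
  expect_equal(score_heterogeneity(
    stack_from_offsets(c(0L, 2L, -2L), c(50L, 25L, 25L), strand = "-")),
    1.0)
  # invariance under uniform translation of all alignments
  st <- stack_from_offsets(c(0L, 1L, 3L), c(60L, 30L, 10L))
  sh <- st; sh$start <- sh$start + 500L; sh$end <- sh$end + 500L
  expect_equal(score_heterogeneity(st), score_heterogeneity(sh))
  expect_error(score_heterogeneity(st[0, ]), "empty")
})

test_that("duplex overhangs are read off the pairing termini", {
  # synthetic fold objects: pairs between 22-mers, unpaired counted
  # outside the outermost pair
  mk <- function(pairs, la = 22L, lb = 22L)
    structure(list(mfe = -30, pairs = pairs,
                   unpaired = c(a5 = min(pairs[, 1]) - 1L,
                                a3 = la - max(pairs[, 1]),
                                b5 = min(pairs[, 2]) - 1L,
                                b3 = lb - max(pairs[, 2]))),
              class = "duplex_fold")
  # canonical Drosha/Dicer geometry: A1..20 paired to B20..1, two free
  # 3' nt on each strand -> +2/+2
  can <- mk(cbind(1:20, 20:1))
  expect_equal(score_overhangs(can), c(a = 2L, b = 2L))
  # blunt duplex
  blunt <- mk(cbind(1:22, 22:1))
  expect_equal(score_overhangs(blunt), c(a = 0L, b = 0L))
  # 3 unpaired nt at the A 5' end: a 5' overhang, negative sign
  neg <- mk(cbind(4:22, 22:4))
  expect_equal(score_overhangs(neg)[["a"]], -3L)
  # built end-to-end from sequences: passenger shifted +2 at both ends
  a <- "GCAGTACGGTACGTTAGCATCG"
  b <- paste0(revcomp(substr(a, 1, 20)), "TT")
  expect_equal(score_overhangs(fold_duplex(a, b)[[1]]),
               c(a = 2L, b = 2L))
})

test_that("sequence and structure entropies match direct computation", {
  # odd-length alternating repeat: exactly two equally frequent
  # dinucleotides -> 1 bit
  expect_equal(score_entropy_nt("ACACACACA"), 1.0)
  expect_equal(score_entropy_nt(strrep("A", 40)), 0)
  set.seed(42)
  r <- rand_seq(64)
  expect_equal(score_entropy_nt(r), oracle_entropy(r, 2))
  expect_gt(score_entropy_nt(r), score_entropy_nt(strrep("AC", 32)))
  expect_lt(abs(score_entropy_nt(r) - 4), 0.7)
  # reversal + complementation leaves dinucleotide entropy unchanged
  expect_equal(score_entropy_nt(r), score_entropy_nt(revcomp(r)))
  # structure entropy on dot-bracket strings
  expect_equal(score_entropy_struct(strrep(".", 30)), 0)
  # a long clean stem uses few distinct triplets; alternating unit
  # structures use more
  stem <- paste0(strrep("(", 60), "....", strrep(")", 60))
  alt <- strrep("().", 40)
  expect_equal(score_entropy_struct(stem), oracle_entropy(stem, 3))
  expect_gt(score_entropy_struct(alt), score_entropy_struct(stem))
})

test_that("tailing classifies terminal A/U runs against other mismatches", {
  set.seed(43)
  pre <- rand_seq(80)
  guide <- substr(pre, 21, 42)
  tail_read <- paste0(guide, if (substr(pre, 43, 43) == "A") "T" else "A")
  mm <- guide
  p <- 10L
  substr(mm, p, p) <- setdiff(c("A", "C", "G", "T"),
                              substr(guide, p, p))[1]
  # all unmapped evidence is tailed -> 1.0
  res <- score_tailing(pre, data.frame(sequence = tail_read, count = 10L))
  expect_equal(res$tailing, 1.0)
  # internal mismatch only -> 0.0
  res <- score_tailing(pre, data.frame(sequence = mm, count = 10L))
  expect_equal(res$tailing, 0.0)
  # 6 tailed + 4 other -> 0.6 (count-weighted)
  res <- score_tailing(pre, data.frame(sequence = c(tail_read, mm),
                                       count = c(6L, 4L)))
  expect_equal(res$tailing, 0.6)
  expect_equal(res$tailed, 6)
  expect_equal(res$other, 4)
  # no evidence -> NA, not zero
  res <- score_tailing(pre, data.frame(sequence = rand_seq(22), count = 5L))
  expect_true(is.na(res$tailing))
  # a 2-nt A/T tail with both bases non-templated also counts
  t1 <- if (substr(pre, 41, 41) == "A") "T" else "A"
  t2 <- if (substr(pre, 42, 42) == "T") "A" else "T"
  at2 <- paste0(substr(guide, 1, 20), t1, t2)
  res <- score_tailing(pre, data.frame(sequence = at2, count = 3L))
  expect_equal(res$tailed, 3)
})

test_that("multimap score is the pooled fraction of locus evidence", {
  set.seed(44)
  pre <- rand_seq(80)
  inner <- substr(pre, 30, 49)
  # m = 400, s = 100 -> 0.8
  expect_equal(score_multimap(pre, 100,
                              data.frame(sequence = inner, count = 400L)),
               0.8)
  # m = 100, s = 100 -> 0.5
  expect_equal(score_multimap(pre, 100,
                              data.frame(sequence = inner, count = 100L)),
               0.5)
  # no pool read occurs in the locus -> 0
  expect_equal(score_multimap(pre, 100,
                              data.frame(sequence = rand_seq(20),
                                         count = 400L)),
               0)
})

test_that("scored planted loci carry the designed signature values", {
  ss <- small_sim()
  pc <- small_config()
  lib <- build_read_library(ss$sim$reads)
  idx <- build_index(ss$sim$genome)
  mapped <- map_reads(lib, idx)
  cand <- score_candidates(discover_candidates(mapped, idx, pc),
                           mapped, pc)
  tr <- ss$sim$truth
  clean <- tr[tr$class == "mirna_clean", ]
  hit <- vapply(seq_len(nrow(cand)), function(i)
    any(clean$chrom == cand$chrom[i] & clean$strand == cand$strand[i] &
          clean$pre_start < cand$pre_end[i] &
          clean$pre_end > cand$pre_start[i]), logical(1))
  expect_gte(sum(hit), nrow(clean) - 1L)
  cc <- cand[hit, ]
  expect_true(all(cc$overhang_a == 2L & cc$overhang_b == 2L))
  expect_true(all(cc$het_5p <= 0.25 & cc$het_3p <= 0.25))
  expect_true(all(cc$duplex_mfe <= -14))
  expect_true(all(cc$multimap == 0))
  expect_true(all(is.na(cc$tailing) | cc$tailing >= 0.4))
  # all ten parameters populated (tailing NA allowed only when no
  # unmapped evidence)
  for (p in c("het_5p", "het_3p", "overhang_a", "overhang_b",
              "duplex_mfe", "mfe_flank", "entropy_nt", "entropy_struct",
              "multimap"))
    expect_false(anyNA(cand[[p]]), label = p)
})
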