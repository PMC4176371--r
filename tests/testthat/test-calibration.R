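# scored-parameter frame generator used by the cutoff/strength tests
mk_params <- function(n, seed = NULL, mirna_like = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (mirna_like) {
    data.frame(
      het_5p = abs(rnorm(n, 0.2, 0.2)), het_3p = abs(rnorm(n, 0.2, 0.2)),
      overhang_a = 2L + sample(-1:1, n, TRUE, c(.1, .8, .1)),
      overhang_b = 2L + sample(-1:1, n, TRUE, c(.1, .8, .1)),
      duplex_mfe = rnorm(n, -30, 3), mfe_flank = rnorm(n, -40, 4),
      entropy_nt = rnorm(n, 3.8, 0.08),
      entropy_struct = rnorm(n, 2.6, 0.15),
      tailing = pmin(1, pmax(0, rnorm(n, 0.8, 0.15))),
      multimap = pmin(1, abs(rnorm(n, 0.02, 0.03))))
  } else {
    data.frame(
      het_5p = abs(rnorm(n, 2, 1)), het_3p = abs(rnorm(n, 2, 1)),
      overhang_a = sample(-6:8, n, TRUE),
      overhang_b = sample(-6:8, n, TRUE),
      duplex_mfe = rnorm(n, -18, 3), mfe_flank = rnorm(n, -22, 5),
      entropy_nt = rnorm(n, 3.3, 0.25),
      entropy_struct = rnorm(n, 3.1, 0.3),
      tailing = pmin(1, pmax(0, rnorm(n, 0.15, 0.1))),
      multimap = pmin(1, abs(rnorm(n, 0.3, 0.15))))
  }
}

test_that("labeling distinguishes annotated, antisense and novel loci", {
  cand <- data.frame(chrom = "chr1", strand = c("+", "-", "+"),
                     guide_start = c(100L, 100L, 500L),
                     guide_end = c(122L, 122L, 522L),
                     locus_id = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", start = 100L, end = 122L,
                    strand = "+")
  lab <- label_candidates(cand, ann)
  expect_equal(lab$label, c("annotated", "antisense", "candidate"))
  # a sub-50% overlap does not count as annotated
  ann2 <- data.frame(chrom = "chr1", start = 112L, end = 134L,
                     strand = "+")
  expect_equal(label_candidates(cand, ann2)$label[1], "candidate")
  # coordinates beyond the assembly are caught
  idx <- build_index(Biostrings::DNAStringSet(c(chr1 = strrep("A", 200))))
  expect_error(label_candidates(cand, data.frame(chrom = "chr1",
                                                 start = 100L, end = 900L,
                                                 strand = "+"),
                                index = idx), "assembly")
})

test_that("cutoffs exclude exactly the worst annotated tail", {
  # 99 zeros and one outlier: at 1% only the outlier is excluded
  ann <- mk_params(100, seed = 51)
  ann$het_5p <- c(rep(0, 99), 10)
  ct <- cutoffs_at_level(ann, 0.01)
  pass <- apply_cutoffs(ann, ct)
  expect_equal(sum(!pass[, "het_5p"]), 1L)
  expect_false(pass[100, "het_5p"])
  # level 0: cutoffs sit at the extreme annotated values, all pass
  ct0 <- cutoffs_at_level(ann, 0)
  expect_true(all(apply_cutoffs(ann, ct0)[, seq_len(9)]))
  # discrete slack: failing fraction per parameter <= level + 1/n
  ann2 <- mk_params(200, seed = 52)
  for (level in c(0.01, 0.05, 0.2)) {
    ct <- cutoffs_at_level(ann2, level)
    frac <- colMeans(!apply_cutoffs(ann2, ct)[, seq_len(9)])
    expect_true(all(frac <= level + 1 / 200 + 1e-12),
                label = paste("slack at level", level))
  }
  expect_error(cutoffs_at_level(mk_params(5), 0.01), "annotated")
})

test_that("strengths count eliminated candidates, overhangs jointly", {
  ann <- mk_params(200, seed = 53)
  cand <- mk_params(100, seed = 54)
  ct <- cutoffs_at_level(ann, 0.01)
  # force a known failure pattern on one parameter
  ct$cutoff[ct$parameter == "het_5p"] <- Inf
  cand$het_5p <- 0
  cand$het_5p[1:13] <- Inf
  ct$cutoff[ct$parameter == "het_5p"] <- 1
  s <- strengths(cand, ct)
  expect_equal(unname(s["het_5p"]), 0.13)
  # overhang union: a fails at terminus A on 30, terminus B on 30 with
  # overlap 15 -> union 45 of 100
  cand2 <- mk_params(100, seed = 55)
  cand2$overhang_a <- 2L; cand2$overhang_b <- 2L
  cand2$overhang_a[1:30] <- 9L
  cand2$overhang_b[16:45] <- 9L
  ct2 <- ct; ct2$cutoff[ct2$parameter == "overhang"] <- 1
  expect_equal(unname(strengths(cand2, ct2)["overhang"]), 0.45)
  # nothing fails -> strength 0
  ct3 <- cutoffs_at_level(ann, 0)
  cand3 <- ann
  expect_equal(unname(strengths(cand3, ct3)["multimap"]), 0)
  # grouped heterogeneity: eight independent strengths
  sg <- strengths(cand, ct, group_heterogeneity = TRUE)
  expect_length(sg, 8L)
  expect_true("het" %in% names(sg))
})

test_that("the expected-count model and FPR ratio follow their formulas", {
  expect_equal(expected_count(setNames(rep(0, 9), PARAM <- paste0("p", 1:9)),
                              100), 100)
  expect_equal(expected_count(c(0.5, 0.5, rep(0, 7)), 100), 25)
  expect_equal(expected_count(c(1, rep(0.3, 8)), 1000), 0)
  expect_error(expected_count(c(-0.1, rep(0, 8)), 10))
  expect_equal(fpr_estimate(25, 50), 0.5)
  expect_equal(fpr_estimate(0, 50), 0)
  expect_true(is.na(fpr_estimate(10, 0)))
})

test_that("recall arithmetic rounds to whole percent", {
  expect_equal(recall_pct(10, 10), 100)
  expect_equal(recall_pct(200, 37), 18)
  expect_error(recall_pct(0, 0), "detected")
  expect_error(recall_pct(10, 11))
})

test_that("calibration converges on separable data and reports a trace", {
  ann <- mk_params(60, seed = 61)
  good <- mk_params(15, seed = 62)
  bad <- mk_params(300, seed = 63, mirna_like = FALSE)
  labeled <- rbind(cbind(ann, label = "annotated"),
                   cbind(good, label = "candidate"),
                   cbind(bad, label = "candidate"))
  labeled$locus_id <- sprintf("L%03d", seq_len(nrow(labeled)))
  pred <- calibrate(labeled, pipeline_config())
  expect_true(pred$converged)
  expect_lte(pred$fpr_result$fpr, 0.01)
  # conservation: observed = novel + antisense at the final level
  expect_equal(pred$fpr_result$observed,
               nrow(pred$novel) + nrow(pred$antisense))
  expect_equal(pred$fpr_result$N, 315L)
  # most planted good candidates survive, decoys are mostly rejected
  expect_gte(nrow(pred$novel), 10L)
  # per-candidate FPR annotation exists for passers
  cf <- pred$candidate_fpr
  expect_true(all(!is.na(cf$fpr[cf$locus_id %in% pred$novel$locus_id])))
  # the trace is monotone: strengths up, expected down, observed down
  tr <- pred$trace
  sc <- grep("^strength_", names(tr), value = TRUE)
  if (nrow(tr) > 1L) {
    for (cn in sc) expect_true(all(diff(tr[[cn]]) >= -1e-12), label = cn)
    expect_true(all(diff(tr$expected) <= 1e-9))
    expect_true(all(diff(tr$observed) <= 0L))
  }
})

test_that("calibration reports non-convergence when no signal exists", {
  ann <- mk_params(80, seed = 64)
  cand <- mk_params(400, seed = 65)   # same distribution as annotated
  labeled <- rbind(cbind(ann, label = "annotated"),
                   cbind(cand, label = "candidate"))
  labeled$locus_id <- sprintf("L%03d", seq_len(nrow(labeled)))
  pred <- calibrate(labeled, pipeline_config(max_level = 0.3))
  expect_false(pred$converged)
  expect_equal(nrow(pred$novel), 0L)
  expect_type(pred$diagnostic, "character")
  expect_error(calibrate(labeled[labeled$label != "annotated", ],
                         pipeline_config()), "annotated")
})

test_that("strength-calibrated cutoffs hit the reference quantiles", {
  cand <- mk_params(100, seed = 66)
  cand$het_5p <- seq_len(100) / 10     # distinct, ordered values
  labeled <- cbind(cand, label = "candidate",
                   locus_id = sprintf("L%03d", 1:100))
  ref <- setNames(rep(0, 9), c("het_5p", "het_3p", "overhang",
                               "mfe_duplex", "mfe_flank", "entropy_nt",
                               "entropy_struct", "tailing", "multimap"))
  # reference strength 0 -> cutoffs at the extremes, everything passes
  pred0 <- calibrate_by_strength(labeled, ref, pipeline_config())
  expect_equal(pred0$fpr_result$observed, 100L)
  # reference strength 0.6 on het_5p eliminates the worst 60; a second
  # parameter failing a subset of the same loci makes expected < observed
  ref2 <- ref; ref2["het_5p"] <- 0.6; ref2["multimap"] <- 0.2
  cand$multimap <- 0; cand$multimap[61:80] <- 0.9
  labeled <- cbind(cand, label = "candidate",
                   locus_id = sprintf("L%03d", 1:100))
  pred <- calibrate_by_strength(labeled, ref2,
                                pipeline_config(fpr_target = 0.9))
  expect_equal(pred$fpr_result$observed, 40L)
  expect_equal(pred$cutoffs$cutoff[pred$cutoffs$parameter == "het_5p"],
               4.0)   # the 40th-best value: 40 pass, the worst 60 fail
})
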