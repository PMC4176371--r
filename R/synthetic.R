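#' Configuration of the synthetic benchmark generator
#'
#' The generator inverts the biogenesis signatures the scorer assumes
#' into a generative model: planted miRNA loci are hairpins with sharp
#' 5' ends, +2/+2 duplex overhangs, a partially paired lower stem in the
#' flanks, frequent non-templated A/U tails and complex (uniform-random)
#' sequence; decoy loci corrupt one or more of these signatures
#' (positional jitter, simple repeats, multimapping repeat elements,
#' shifted duplex registers, biased base composition, unpaired flanks,
#' few tails). A designated subset of planted miRNAs forms the toy
#' annotation; it deliberately includes a couple of "marginal" exemplars
#' (weaker duplex, jittered ends, modest tailing, mild multimapping)
#' mirroring the known heterogeneity of curated miRNA registries --
#' these marginal entries are exactly what percentile-based cutoff
#' calibration sacrifices first.
#'
#' @param seed integer RNG seed; the same seed and config reproduce the
#'   dataset byte for byte.
#' @param genome_length total genome size (nt) over all chromosomes.
#' @param n_chrom number of chromosomes.
#' @param n_mirnas planted miRNA loci.
#' @param n_annotated how many planted miRNAs enter the toy annotation
#'   (includes the marginal exemplars).
#' @param n_marginal marginal annotated exemplars.
#' @param n_decoys planted decoy loci, split evenly across
#'   `decoy_classes`.
#' @param decoy_classes subset of `degradation`, `simple_repeat`,
#'   `multimap_repeat`, `shifted_overhang`.
#' @param read_depth mean reads on a planted guide arm (Poisson).
#' @param guide_passenger_ratio guide arm depth relative to passenger.
#' @param het_sd 5' positional jitter SD (nt) for degradation decoys.
#' @param tail_prob probability that a planted-miRNA guide read carries a
#'   1-3 nt non-templated A/U tail.
#' @param arm_len mature arm length (nt).
#' @param motif_len length of the multimapping repeat elements.
#' @param n_motif_families distinct repeat element families embedded in
#'   decoy loops.
#' @param motif_read_count pooled read count per decoy repeat family.
#' @param marginal_motif_count pooled read count of the low-level repeat
#'   family contaminating the marginal annotated exemplars.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, n_chrom = 2L,
                       n_mirnas = 20L, n_annotated = 10L, n_marginal = 2L,
                       n_decoys = 200L,
                       decoy_classes = c("degradation", "simple_repeat",
                                         "multimap_repeat",
                                         "shifted_overhang"),
                       read_depth = 100, guide_passenger_ratio = 5,
                       het_sd = 3, tail_prob = 0.35,
                       arm_len = 22L, motif_len = 20L,
                       n_motif_families = 4L, motif_read_count = 80L,
                       marginal_motif_count = 15L) {
  decoy_classes <- match.arg(decoy_classes,
                             c("degradation", "simple_repeat",
                               "multimap_repeat", "shifted_overhang"),
                             several.ok = TRUE)
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_chrom = as.integer(n_chrom),
              n_mirnas = as.integer(n_mirnas),
              n_annotated = as.integer(n_annotated),
              n_marginal = as.integer(n_marginal),
              n_decoys = as.integer(n_decoys),
              decoy_classes = decoy_classes,
              read_depth = read_depth,
              guide_passenger_ratio = guide_passenger_ratio,
              het_sd = het_sd, tail_prob = tail_prob,
              arm_len = as.integer(arm_len),
              motif_len = as.integer(motif_len),
              n_motif_families = as.integer(n_motif_families),
              motif_read_count = as.integer(motif_read_count),
              marginal_motif_count = as.integer(marginal_motif_count),
              # signature knobs (per locus class)
              clean_jitter_prob = 0.03, clean_other_prob = 0.02,
              marginal_tail_prob = 0.06, marginal_other_prob = 0.2,
              decoy_tail_prob = 0.01, decoy_other_prob = 0.12,
              clean_bias = c(A = .25, C = .25, G = .25, T = .25),
              marginal_bias = c(A = .5, C = .25, G = .15, T = .10),
              decoy_bias = c(A = .45, C = .25, G = .17, T = .13))
  stopifnot(cfg$n_marginal <= cfg$n_annotated,
            cfg$n_annotated <= cfg$n_mirnas,
            cfg$n_mirnas >= 0L, cfg$n_decoys >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n, bias = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(bias), n, TRUE, prob = bias), collapse = "")
}

# bases that neither Watson-Crick- nor wobble-pair with `partner`
nonpairing_bases <- function(partner) {
  bad <- c(unname(COMP[partner]),
           switch(partner, G = "T", T = "G", NULL))
  setdiff(c("A", "C", "G", "T"), bad)
}

#' Construct one planted miRNA hairpin cassette
#'
#' Layout: `[flank5 10][5p arm][loop][3p arm - 2][3' overhang 2][flank3 8]`
#' with the 3p arm built as the reverse complement of the 5p arm so the
#' mature reads form a duplex with 2-nt 3' overhangs at both termini.
#' Clean cassettes carry one non-pairing mismatch plus up to two G:U
#' wobbles in the stem and a lower stem pairing the flanks; marginal
#' cassettes carry four mismatches, a shifted passenger, biased base
#' composition, unpaired flanks and a low-level repeat element as loop.
#'
#' Planted cassettes are drawn by rejection sampling: a candidate
#' cassette is kept only when its duplex energy, whole-precursor folding
#' energy, dinucleotide entropy and structural entropy fall in the band
#' designed for its quality class (clean bands strictly better than
#' marginal bands, which in turn border the decoy bulk). This makes the
#' planted signatures a property of the dataset by construction rather
#' than a distributional tendency. After `max_tries` draws the attempt
#' satisfying most conditions is kept.
#'
#' @param cfg a [sim_config()].
#' @param marginal build a marginal exemplar instead of a clean one.
#' @param loop_seq optional fixed loop sequence (e.g. a repeat element).
#' @param backend folding backend used to verify the bands.
#' @param max_tries rejection-sampling budget.
#' @return list with `cassette` (character), relative 0-based intervals
#'   `arm5p`, `arm3p` (the mature read windows) and `hairpin` (arm
#'   extremities), and `guide_arm`.
#' @export
plant_mirna <- function(cfg = sim_config(), marginal = FALSE,
                        loop_seq = NULL, backend = NULL,
                        max_tries = 120L) {
  best <- NULL; best_ok <- -1L
  for (try in seq_len(max_tries)) {
    sp <- plant_mirna_once(cfg, marginal, loop_seq)
    a5 <- substr(sp$cassette, sp$arm5p[1L] + 1L, sp$arm5p[2L])
    a3 <- substr(sp$cassette, sp$arm3p[1L] + 1L, sp$arm3p[2L])
    dup <- fold_duplex(a5, a3, backend = backend)[[1L]]$mfe
    hp <- fold_hairpin(sp$cassette, backend = backend)
    ent <- score_entropy_nt(sp$cassette)
    stru <- score_entropy_struct(hp$structure[1L])
    conds <- if (marginal) {
      c(dup >= -25.5, dup <= -15.5, hp$mfe[1L] >= -32, hp$mfe[1L] <= -16,
        ent >= 3.42, ent <= 3.65, stru >= 3.05)
    } else {
      c(dup >= -40, dup <= -26.5, hp$mfe[1L] <= -36,
        ent >= 3.70, stru <= 2.80)
    }
    if (all(conds)) return(sp)
    if (sum(conds) > best_ok) { best <- sp; best_ok <- sum(conds) }
  }
  best
}

plant_mirna_once <- function(cfg, marginal, loop_seq) {
  bias <- if (marginal) cfg$marginal_bias else cfg$clean_bias
  alen <- cfg$arm_len
  # arm with balanced GC among the paired 20 nt keeps duplex energies in
  # a narrow band
  paired <- alen - 2L
  gc <- paired %/% 2L
  if (marginal) {
    # marginal exemplars carry a (G/C,A) dinucleotide run through most of
    # the arm: GC balance (and hence the duplex energy band) is kept, but
    # sequence complexity drops well below uniform-random arms
    # a (G/C,A) run lowers complexity; the random tail of the arm breaks
    # the periodicity so the duplex register stays unambiguous
    s <- sample(c("G", "C"), 1L)
    rest_n <- paired - 14L
    rest <- paste(sample(c(sample(c("G", "C"), rest_n - 1L, TRUE), "A")),
                  collapse = "")
    A <- paste0(strrep(paste0(s, "A"), 7L), rest,
                paste(sample(c("A", "C", "G"), 2L, TRUE), collapse = ""))
  } else {
    A <- paste(c(sample(c(sample(c("G", "C"), gc, TRUE),
                         sample(c("A", "T"), paired - gc, TRUE))),
                 sample(c("A", "C", "G", "T"), 2L, TRUE)), collapse = "")
  }
  Achars <- strsplit(A, "")[[1]]
  B <- strsplit(revcomp(substr(A, 1L, paired)), "")[[1]]
  partners <- Achars[paired:1L]          # partner of B[p] is A[paired+1-p]
  n_mm <- if (marginal) 4L else 1L
  mm_pos <- sort(sample(4L:(paired - 3L), n_mm))
  if (marginal) {
    # spread the mismatches so the duplex energy band stays narrow
    repeat {
      if (min(diff(mm_pos)) >= 3L) break
      mm_pos <- sort(sample(4L:(paired - 3L), n_mm))
    }
  }
  for (p in mm_pos) B[p] <- sample(nonpairing_bases(partners[p]), 1L)
  if (!marginal) {
    # up to two wobbles where the 5p partner is G or T
    wob <- setdiff(which(partners %in% c("G", "T")), mm_pos)
    wob <- utils::head(wob[sample.int(length(wob))], sample(0:2, 1L))
    for (p in wob) B[p] <- if (partners[p] == "G") "T" else "G"
  }
  B <- paste(B, collapse = "")
  # marginal loops carry a self-folding GC insert: the precursor then
  # folds as a multiloop (high structural entropy) while adding almost
  # no sequence complexity
  loop <- if (!is.null(loop_seq)) {
    if (marginal) paste0(loop_seq, "GCGCGAAACGCGC") else loop_seq
  } else rand_dna(sample(12:16, 1L), bias)
  ov2 <- rand_dna(2L, bias)
  # marginal flanks: unpaired (no lower stem), 5' one low-complexity
  f5 <- if (marginal) strrep("CA", 5L) else rand_dna(10L, bias)
  f3 <- if (marginal) rand_dna(8L, bias) else revcomp(substr(f5, 3L, 10L))
  cassette <- paste0(f5, A, loop, B, ov2, f3)
  off3 <- 10L + alen + nchar(loop)       # start of the 3p read window
  shift <- if (marginal) 1L else 0L      # marginal passenger is off by 1
  list(cassette = cassette,
       arm5p = c(10L, 10L + alen),
       arm3p = c(off3 + shift, off3 + alen + shift),
       hairpin = c(10L, off3 + alen),
       guide_arm = sample(c("5p", "3p"), 1L),
       marginal = marginal)
}

# decoy cassette builders ---------------------------------------------

plant_decoy <- function(class, cfg, motif) {
  bias <- cfg$decoy_bias
  alen <- cfg$arm_len
  paired <- alen - 2L
  if (class == "simple_repeat") {
    # AT-leaning repeat units: weak-ish stems and low sequence entropy
    unit <- rand_dna(sample(3:5, 1L), c(A = .4, C = .12, G = .08, T = .4))
    A <- paste0(strrep(unit, ceiling(alen / nchar(unit))))
    A <- substr(A, 1L, alen)
  } else {
    # degradation stems are weaker (lower GC) than genuine miRNA duplexes
    gc <- switch(class, degradation = 7L, multimap_repeat = 8L,
                 paired %/% 2L)
    A <- paste(c(sample(c(sample(c("G", "C"), gc, TRUE),
                         sample(names(bias), paired - gc, TRUE,
                                prob = bias))),
                 sample(names(bias), 2L, TRUE, prob = bias)),
               collapse = "")
  }
  Achars <- strsplit(A, "")[[1]]
  B <- strsplit(revcomp(substr(A, 1L, paired)), "")[[1]]
  partners <- Achars[paired:1L]
  n_mm <- switch(class, degradation = sample(3:5, 1L),
                 simple_repeat = sample(2:4, 1L),
                 shifted_overhang = sample(2:3, 1L),
                 multimap_repeat = sample(2:3, 1L))
  for (p in sort(sample(4L:(paired - 3L), n_mm)))
    B[p] <- sample(nonpairing_bases(partners[p]), 1L)
  B <- paste(B, collapse = "")
  loop <- if (class == "multimap_repeat") rand_dna(11L, bias) else motif
  ov2 <- rand_dna(2L, bias)
  f5 <- rand_dna(10L, bias)
  f3 <- rand_dna(8L, bias)
  cassette <- paste0(f5, A, loop, B, ov2, f3)
  off3 <- 10L + alen + nchar(loop)
  # decoy duplex registers are clearly off the +2/+2 geometry
  shift <- switch(class,
                  shifted_overhang = sample(c(-4L, -3L, 3L, 4L), 1L),
                  degradation = sample(c(-4L, -3L, -2L, 2L, 3L, 4L), 1L),
                  0L)
  list(cassette = cassette,
       arm5p = c(10L, 10L + alen),
       arm3p = c(off3 + shift, off3 + alen + shift),
       hairpin = c(10L, off3 + alen),
       guide_arm = sample(c("5p", "3p"), 1L),
       marginal = FALSE)
}

#' Generate the synthetic genome and its truth table
#'
#' Plants the requested miRNA and decoy cassettes (plus standalone
#' copies of the repeat elements that need extra genomic occurrences) at
#' non-overlapping positions separated by random background gaps, half
#' of them on the minus strand, across `n_chrom` chromosomes of
#' uniform-random background. Seeds the RNG with `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a `DNAStringSet`), `truth` (data.frame:
#'   one row per planted locus with 0-based genomic intervals) and
#'   `motifs` (data.frame of repeat families and read counts).
#' @export
make_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  # repeat element families: index 1 is the low-level family touching the
  # marginal annotated exemplars, the rest contaminate decoy loops
  fam <- data.frame(
    family = seq_len(cfg$n_motif_families + 1L),
    motif = vapply(seq_len(cfg$n_motif_families + 1L), function(i) {
      if (i == 1L) {
        # the family touching the marginal annotated exemplars is a
        # periodic (simple-repeat-like) element
        substr(strrep(rand_dna(6L, cfg$decoy_bias),
                      ceiling(cfg$motif_len / 6L) + 1L),
               1L, cfg$motif_len)
      } else rand_dna(cfg$motif_len, cfg$decoy_bias)
    }, character(1)),
    count = c(cfg$marginal_motif_count,
              rep(cfg$motif_read_count, cfg$n_motif_families)),
    stringsAsFactors = FALSE)

  specs <- list()
  n_marg <- cfg$n_marginal
  for (i in seq_len(cfg$n_mirnas)) {
    marginal <- i > cfg$n_mirnas - n_marg
    loop_seq <- if (marginal) fam$motif[1L] else NULL
    sp <- plant_mirna(cfg, marginal = marginal, loop_seq = loop_seq)
    sp$class <- if (marginal) "mirna_marginal" else "mirna_clean"
    sp$family <- if (marginal) 1L else NA_integer_
    specs[[length(specs) + 1L]] <- sp
  }
  classes <- cfg$decoy_classes
  per <- if (length(classes)) cfg$n_decoys %/% length(classes) else 0L
  decoy_fams <- if (cfg$n_motif_families > 0L)
    1L + seq_len(cfg$n_motif_families) else integer()
  mm_templates <- list()
  for (cl in classes) {
    n_cl <- per + if (cl == classes[length(classes)])
      cfg$n_decoys - per * length(classes) else 0L
    if (cl == "multimap_repeat") {
      n_templates <- max(1L, n_cl %/% 7L)
      for (t in seq_len(n_templates)) {
        sp <- plant_decoy(cl, cfg, motif = NULL)
        sp$class <- cl; sp$family <- NA_integer_
        copies <- if (t == n_templates)
          n_cl - (n_templates - 1L) * (n_cl %/% n_templates)
          else n_cl %/% n_templates
        for (cp in seq_len(copies)) {
          spc <- sp; spc$template <- t
          specs[[length(specs) + 1L]] <- spc
        }
      }
    } else {
      for (i in seq_len(n_cl)) {
        f <- if (length(decoy_fams)) sample(decoy_fams, 1L) else NA_integer_
        sp <- plant_decoy(cl, cfg,
                          motif = if (is.na(f)) rand_dna(cfg$motif_len)
                                  else fam$motif[f])
        sp$class <- cl; sp$family <- f
        specs[[length(specs) + 1L]] <- sp
      }
    }
  }
  # standalone copies so the marginal-locus repeat family exceeds the
  # multimap hit limit
  n_standalone <- if (n_marg > 0L) max(0L, 5L - n_marg) + 1L else 0L
  for (i in seq_len(n_standalone)) {
    specs[[length(specs) + 1L]] <- list(cassette = fam$motif[1L],
                                        class = "motif_standalone",
                                        family = 1L, marginal = FALSE)
  }

  specs <- specs[sample(length(specs))]
  lens <- vapply(specs, function(s) nchar(s$cassette), integer(1))
  gaps <- 120L + floor(runif(length(specs) + cfg$n_chrom) * 120)
  need <- sum(lens) + sum(gaps)
  if (need > cfg$genome_length)
    stop(sprintf(paste0("genome too small: %d planted nt + gaps need ",
                        "~%d nt but genome_length is %d (overcrowded)"),
                 sum(lens), need, cfg$genome_length))

  chrom_len <- cfg$genome_length %/% cfg$n_chrom
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))
  seqs <- setNames(vector("list", cfg$n_chrom), chrom_names)
  truth <- NULL
  ci <- 1L; cursor <- 0L; parts <- list(); gi <- 1L
  flush_chrom <- function(parts, cursor) {
    if (cursor < chrom_len)
      parts[[length(parts) + 1L]] <- rand_dna(chrom_len - cursor)
    paste(unlist(parts), collapse = "")
  }
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    L <- nchar(sp$cassette)
    gap <- gaps[gi]; gi <- gi + 1L
    if (cursor + gap + L + 60L > chrom_len && ci < cfg$n_chrom) {
      seqs[[ci]] <- flush_chrom(parts, cursor)
      ci <- ci + 1L; cursor <- 0L; parts <- list()
    }
    if (cursor + gap + L + 60L > chrom_len)
      stop("genome too small while planting (overcrowded)")
    parts[[length(parts) + 1L]] <- rand_dna(gap)
    strand <- if (runif(1) < 0.5) "+" else "-"
    planted <- if (strand == "+") sp$cassette else revcomp(sp$cassette)
    parts[[length(parts) + 1L]] <- planted
    start <- cursor + gap
    if (!is.null(sp$arm5p)) {
      rel2abs <- function(iv) {
        if (strand == "+") start + iv
        else c(start + L - iv[2L], start + L - iv[1L])
      }
      a5 <- rel2abs(sp$arm5p); a3 <- rel2abs(sp$arm3p)
      hp <- rel2abs(sp$hairpin)
      g5p <- sp$guide_arm == "5p"
      truth <- rbind(truth, data.frame(
        class = sp$class, chrom = chrom_names[ci], strand = strand,
        pre_start = hp[1L], pre_end = hp[2L],
        arm5p_start = a5[1L], arm5p_end = a5[2L],
        arm3p_start = a3[1L], arm3p_end = a3[2L],
        guide_arm = sp$guide_arm,
        guide_start = if (g5p) a5[1L] else a3[1L],
        guide_end = if (g5p) a5[2L] else a3[2L],
        pass_start = if (g5p) a3[1L] else a5[1L],
        pass_end = if (g5p) a3[2L] else a5[2L],
        family = sp$family,
        template = if (is.null(sp$template)) NA_integer_ else sp$template,
        stringsAsFactors = FALSE))
    } else {
      truth <- rbind(truth, data.frame(
        class = sp$class, chrom = chrom_names[ci], strand = strand,
        pre_start = start, pre_end = start + L,
        arm5p_start = NA_integer_, arm5p_end = NA_integer_,
        arm3p_start = NA_integer_, arm3p_end = NA_integer_,
        guide_arm = NA_character_,
        guide_start = NA_integer_, guide_end = NA_integer_,
        pass_start = NA_integer_, pass_end = NA_integer_,
        family = sp$family, template = NA_integer_,
        stringsAsFactors = FALSE))
    }
    cursor <- start + L
  }
  seqs[[ci]] <- flush_chrom(parts, cursor)
  for (j in seq_len(cfg$n_chrom)) {
    if (is.null(seqs[[j]])) seqs[[j]] <- rand_dna(chrom_len)
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chrom_names

  # designate the annotated subset: all marginal exemplars plus the
  # first clean miRNAs
  truth$locus_id <- sprintf("sim_%03d", seq_len(nrow(truth)))
  truth$annotated <- FALSE
  marg <- which(truth$class == "mirna_marginal")
  clean <- which(truth$class == "mirna_clean")
  truth$annotated[c(marg,
                    utils::head(clean, cfg$n_annotated - length(marg)))] <- TRUE
  list(genome = genome, truth = truth, motifs = fam)
}

templated_base_after <- function(genome, chrom, start, end, strand) {
  chr <- genome[[chrom]]
  if (strand == "+") {
    if (end >= length(chr)) return(NA_character_)
    as.character(Biostrings::subseq(chr, end + 1L, end + 1L))
  } else {
    if (start <= 0L) return(NA_character_)
    revcomp(as.character(Biostrings::subseq(chr, start, start)))
  }
}

#' Simulate pooled small RNA reads from a synthetic truth table
#'
#' Per planted locus, guide and passenger arm read counts are Poisson
#' around `read_depth` (passenger `read_depth / guide_passenger_ratio`);
#' read 5' ends jitter according to the locus class (sharp for clean
#' miRNAs, N(0, `het_sd`) for degradation decoys); planted-miRNA guide
#' reads additionally yield non-templated 1-3 nt A/U-tailed copies
#' (first tail base verified against the genome so the tail cannot be
#' templated) and all classes yield a class-specific level of
#' internal-mismatch reads that will not map. Repeat-family reads are
#' added with their configured pooled counts. Seeds the RNG with
#' `cfg$seed + 1`.
#'
#' @param sim output of [make_genome()].
#' @param cfg the same [sim_config()].
#' @return data.frame (`sequence`, `count`) of pooled collapsed reads.
#' @export
simulate_reads <- function(sim, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  genome <- sim$genome
  truth <- sim$truth
  idx <- structure(list(seqs = genome,
                        lengths = setNames(Biostrings::width(genome),
                                           names(genome))),
                   class = "genome_index")
  seqs <- character(); cnts <- integer()
  emit <- function(s, n = 1L) {
    seqs[[length(seqs) + 1L]] <<- s
    cnts[[length(cnts) + 1L]] <<- as.integer(n)
  }
  jitter_offsets <- function(n, class) {
    switch(class,
           mirna_clean = sample(c(-1L, 0L, 1L), n, TRUE,
                                prob = c(cfg$clean_jitter_prob / 2,
                                         1 - cfg$clean_jitter_prob,
                                         cfg$clean_jitter_prob / 2)),
           mirna_marginal = sample(c(-1L, 0L, 1L, 2L), n, TRUE,
                                   prob = c(.15, .55, .2, .1)),
           degradation = pmax(-6L, pmin(6L,
                                        as.integer(round(rnorm(n, 0, cfg$het_sd))))),
           simple_repeat = pmax(-5L, pmin(5L,
                                          as.integer(round(rnorm(n, 0, 2.5))))),
           multimap_repeat = pmax(-3L, pmin(3L,
                                            as.integer(round(rnorm(n, 0, 1))))),
           shifted_overhang = sample(c(-1L, 0L, 1L), n, TRUE,
                                     prob = c(.05, .9, .05)))
  }
  class_probs <- function(class) {
    switch(class,
           mirna_clean = c(tail = cfg$tail_prob,
                           other = cfg$clean_other_prob),
           mirna_marginal = c(tail = cfg$marginal_tail_prob,
                              other = cfg$marginal_other_prob),
           c(tail = cfg$decoy_tail_prob, other = cfg$decoy_other_prob))
  }
  done_templates <- integer()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$class == "motif_standalone") next
    if (tr$class == "multimap_repeat") {
      # identical cassette copies: simulate reads once per template
      if (tr$template %in% done_templates) next
      done_templates <- c(done_templates, tr$template)
    }
    clen <- idx$lengths[[tr$chrom]]
    for (arm in c("guide", "pass")) {
      depth <- if (arm == "guide") cfg$read_depth
               else cfg$read_depth / cfg$guide_passenger_ratio
      n <- max(1L, rpois(1L, depth))
      s0 <- tr[[paste0(arm, "_start")]]; e0 <- tr[[paste0(arm, "_end")]]
      off <- jitter_offsets(n, tr$class)
      # jitter shifts the whole read window; on the minus strand a +1
      # 5'-end shift moves the window left
      off_g <- if (tr$strand == "+") off else -off
      tab <- table(off_g)
      for (o in names(tab)) {
        oo <- as.integer(o)
        s <- max(0L, s0 + oo); e <- min(clen, e0 + oo)
        if (e - s < 18L) next
        emit(genome_seq(idx, tr$chrom, s, e, tr$strand), tab[[o]])
      }
      if (arm == "guide") {
        pr <- class_probs(tr$class)
        gseq <- genome_seq(idx, tr$chrom, s0, e0, tr$strand)
        n_tail <- rbinom(1L, n, pr[["tail"]])
        if (n_tail > 0L) {
          tmpl <- templated_base_after(genome, tr$chrom, s0, e0, tr$strand)
          pool <- setdiff(c("A", "T"), tmpl)
          for (t in seq_len(n_tail)) {
            tl <- sample(1:3, 1L)
            tail_seq <- paste(c(sample(pool, 1L),
                                sample(c("A", "T"), tl - 1L, TRUE)),
                              collapse = "")
            emit(paste0(gseq, tail_seq), 1L)
          }
        }
        n_other <- rbinom(1L, n, pr[["other"]])
        for (t in seq_len(n_other)) {
          p <- sample(7:(nchar(gseq) - 6L), 1L)
          ch <- substr(gseq, p, p)
          sub <- sample(setdiff(c("A", "C", "G", "T"), ch), 1L)
          emit(paste0(substr(gseq, 1L, p - 1L), sub,
                      substr(gseq, p + 1L, nchar(gseq))), 1L)
        }
      }
    }
  }
  for (f in seq_len(nrow(sim$motifs))) {
    used <- any(!is.na(truth$family) & truth$family == sim$motifs$family[f])
    if (used) emit(sim$motifs$motif[f], sim$motifs$count[f])
  }
  agg <- rowsum(as.numeric(cnts), group = seqs)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1L]),
             stringsAsFactors = FALSE)
}

#' Toy annotation of the designated annotated subset
#'
#' @param truth truth table from [make_genome()].
#' @return a `GRanges` with miRNA_primary_transcript and mature miRNA
#'   features (1-based), suitable for [label_candidates()] or GFF3
#'   export.
#' @export
truth_annotation <- function(truth) {
  ann <- truth[isTRUE_vec(truth$annotated), , drop = FALSE]
  if (nrow(ann) == 0L)
    return(GenomicRanges::GRanges())
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = a$chrom, start = a$pre_start, end = a$pre_end,
      strand = a$strand, type = "miRNA_primary_transcript",
      ID = a$locus_id, Name = paste0("sim-mir-", i))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = a$chrom, start = a$arm5p_start, end = a$arm5p_end,
      strand = a$strand, type = "miRNA", ID = paste0(a$locus_id, "_5p"),
      Name = paste0("sim-mir-", i, "-5p"))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = a$chrom, start = a$arm3p_start, end = a$arm3p_end,
      strand = a$strand, type = "miRNA", ID = paste0(a$locus_id, "_3p"),
      Name = paste0("sim-mir-", i, "-3p"))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$type <- df$type; gr$ID <- df$ID; gr$Name <- df$Name
  gr
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: genome + truth ([make_genome()]), pooled reads
#' ([simulate_reads()]) and the toy annotation ([truth_annotation()]);
#' optionally writes `genome.fa`, `reads.fastq`, `reads.tsv`,
#' `annotation.gff3`, `truth.tsv` and a config echo to `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return list with `genome`, `truth`, `reads`, `annotation`, `motifs`,
#'   `config` (and `files` when `dir` is given).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  sim <- make_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  ann <- truth_annotation(sim$truth)
  out <- list(genome = sim$genome, truth = sim$truth, reads = reads,
              annotation = ann, motifs = sim$motifs, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(genome = file.path(dir, "genome.fa"),
                  reads_fastq = file.path(dir, "reads.fastq"),
                  reads_tsv = file.path(dir, "reads.tsv"),
                  annotation = file.path(dir, "annotation.gff3"),
                  truth = file.path(dir, "truth.tsv"),
                  config = file.path(dir, "sim_config.txt"))
    Biostrings::writeXStringSet(sim$genome, files$genome)
    write_sim_fastq(reads, files$reads_fastq)
    write.table(reads, files$reads_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    rtracklayer::export(ann, files$annotation, format = "GFF3")
    write.table(sim$truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(paste(names(unlist(cfg)), unlist(cfg), sep = "="),
               files$config)
    out$files <- files
  }
  out
}

#' Expand a collapsed read table into a constant-quality FASTQ file
#' @param reads data.frame (`sequence`, `count`).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_sim_fastq <- function(reads, file) {
  seqs <- rep(reads$sequence, reads$count)
  ids <- sprintf("read_%06d", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  qual <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(n) strrep("I", n), character(1)))
  qdss <- Biostrings::QualityScaledDNAStringSet(dss, qual)
  Biostrings::writeQualityScaledXStringSet(qdss, file)
  invisible(file)
}
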