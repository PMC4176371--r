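---
title: "Stringent miRNA discovery: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stringent miRNA discovery: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Canonical miRNA biogenesis constrains what a genuine miRNA locus looks
like in deep small RNA sequencing data: a 46–80 nt precursor hairpin
whose two arms are both sequenced (guide more deeply than passenger),
read 5′ ends sharpened by RNase III cleavage, a guide/passenger duplex
with 2-nt 3′ overhangs at both termini, a thermodynamically stable
duplex and flanking stem, non-repetitive sequence, a simple stem-loop
structure, frequent non-templated 3′ A/U tailing, and unambiguous
(non-multimapping) read evidence. `mirscout` turns each of these into a
score, derives per-parameter cutoffs from the behaviour of *annotated*
miRNAs, and raises the stringency until the estimated false-positive
rate (FPR) of the prediction reaches a target.

The FPR model treats the parameters as independent filters. If
parameter *i* eliminates a fraction *sᵢ* (its *strength*) of the *N*
non-annotated candidates, a structureless candidate passes all filters
with probability Π(1 − sᵢ), so

> Expected = N · Π(1 − sᵢ),  FPR = Expected / Observed.

The two overhang scores are strongly interdependent (one duplex
geometry determines both), so they enter the product as one joint
parameter — nine independent strengths. A config switch
(`group_heterogeneity`) also merges the two 5′-heterogeneity strengths
into one for sensitivity analyses, giving eight.

Annotated loci are excluded from N, from the strengths and from
Observed; they are still pushed through the cutoffs to report recall,
and the trace records the passing count with annotated loci included,
since either bookkeeping convention is defensible.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `min_len`/`max_len` | 18/26 nt | retained read lengths after trimming |
| `max_hits` | 4 | perfect genomic hits above which a read is pooled as multimapping |
| `min_span`/`max_span` | 46/80 nt | precursor span between outermost read ends; long-hairpin runs raise `max_span` (e.g. 160) |
| `min_loop` | 3 nt | minimal guide/passenger separation; the physical minimum terminal loop |
| `flank` | 10 nt | genomic context added per side before structure scoring |
| `duplex_mfe_gate` | −14 kcal/mol | inclusive duplex gate; backend-dependent scale, hence a config value |
| `fpr_target`, `step` | 0.01, 0.01 | calibration target and level increment |
| `min_annotated` | 20 | annotated loci required before percentile calibration is attempted |
| `tailing_na_pass` | TRUE | loci with no unmapped-read evidence pass the tailing cutoff |

The ±10 nt extension is *not* counted against the 46–80 nt window: the
window bounds the duplex-bearing hairpin, the extension only serves
structure and overhang assessment.

## Numerical and procedural choices

**Quantile convention.** At level *q* with *n* annotated loci, the
cutoff for a parameter is the (k+1)-th worst annotated value,
k = ⌈q·n⌉, and a value fails only when strictly beyond the cutoff. With
distinct values exactly the worst k annotated loci fail; ties can only
reduce the failing fraction (at most q + 1/n fail — the testable
discrete-slack bound). An equally defensible convention (fail at ≥ the
k-th worst value) breaks down when a parameter is degenerate (e.g. all
annotated overhang deviations are 0), which is why it was not used.

**Directions.** High heterogeneity, |overhang − 2|, folding energies,
structural entropy and multimapping are adverse; low nucleotide entropy
and low tailing are adverse. The overhang pass criterion is
max(|a−2|, |b−2|) ≤ c at both termini, anchoring the +2/+2 geometry
rather than the marginal distributions.

**Entropy definitions.** Sequence complexity is the Shannon entropy of
overlapping dinucleotides of the extended precursor; structural
complexity is the Shannon entropy of overlapping dot-bracket triplets.
Any fixed k works with percentile calibration (cutoffs are invariant to
monotone rescaling within a parameter); both k are config arguments of
the scoring functions.

**Tailing.** The score is TAILED/(TAILED+OTHER), bounded in [0,1],
rather than the raw TAILED/OTHER ratio — monotone-equivalent for
percentile cutoffs and defined when OTHER is 0. A read is TAILED when
its only mismatches against the precursor form a contiguous 3′-terminal
run of ≤ 3 nt consisting solely of A/T; OTHER when it aligns with 1–2
mismatches elsewhere. Loci with no evidence get NA and, by default,
pass the tailing cutoff: absence of evidence at a shallow locus should
not by itself reject it. This is a deviation risk worth knowing about:
with `tailing_na_pass = FALSE` such loci would be rejected instead.
Tailing is scored per locus (not genome-wide), and the unmapped-read
alignment is seeded with three disjoint 6-mers so that any read with a
qualifying mismatch pattern is guaranteed to be examined.

**Ties.** Guide ties break to the smaller genomic start; passenger ties
prefer the lower duplex MFE, then the smaller start. One candidate per
cluster (the best pairing). Antisense duplicates on opposite strands
are both retained and disambiguated at labeling.

**Degenerate inputs.** Observed = 0 ends calibration with an empty
prediction (reported, not an error); too few annotated loci is an error
with guidance; an overcrowded synthetic genome is an error.

**Folding backends.** ViennaRNA (`RNAduplex`/`RNAfold`, 37 °C
nearest-neighbour parameters, T→U applied internally) when available;
otherwise a bundled stacking-aware duplex alignment DP and weighted
Nussinov fold, calibrated so a ≥16-bp near-perfect duplex scores well
below −14 kcal/mol and unpairable sequence scores ≈ 0. Absolute
energies differ between backends; the percentile machinery absorbs
this, and the duplex gate is a config value for the same reason.

## What the synthetic generator emulates

`simulate_dataset()` inverts the scorer's assumptions into a generative
model. Planted miRNA cassettes are
`[flank 10][arm 22][loop][arm 22 − 2][overhang 2][flank 8]` hairpins:
arms GC-balanced and mutually complementary up to one non-pairing
mismatch and up to two G:U wobbles, +2/+2 overhang geometry encoded in
the read windows, a lower stem pairing the flanks, sharp 5′ ends,
guide ≈ 5× passenger depth (Poisson), 1–3 nt non-templated A/U tails at
`tail_prob` (the first tail base is checked against the genome so the
tail cannot be templated). Decoy classes each corrupt targeted
signatures: *degradation* (jittered 5′ ends at `het_sd`, 3–5 stem
mismatches, weaker AT-leaning stems, random flanks, shifted duplex
registers), *simple repeats* (periodic AT-leaning arms, low sequence
entropy), *multimapping repeats* (identical cassette copies exceeding
the hit limit), *shifted overhangs* (clean hairpins with the passenger
window displaced ±3–4 nt). Decoy loops additionally embed shared repeat
elements whose reads exceed the hit limit, feeding the multimap score.

Two generator design points deserve emphasis because they are easy to
get wrong:

1. **The toy annotation contains marginal exemplars.** Percentile
   calibration *presupposes* a quality tail among annotated miRNAs —
   the worst q-fraction is sacrificed at each level. If all annotated
   exemplars were pristine and iid with the novel loci, the worst-k
   order statistics would fall inside the clean distribution and clip
   genuine novel loci (for any continuous score, a new draw beats the
   2nd-worst of n iid draws with probability 2/(n+1), regardless of
   scale). Curated registries do contain questionable entries; the
   generator models this with `n_marginal` exemplars whose duplex,
   flanks, 5′ precision, tailing, complexity and multimap contamination
   all sit between the clean miRNAs and the decoys, anchoring every
   cutoff in that corridor.
2. **Signature bands are enforced, not hoped for.** Each planted
   cassette is accepted only when its duplex MFE, precursor MFE,
   dinucleotide entropy and structural entropy fall within the band
   defined for its quality class (rejection sampling, ≤120 draws,
   best-effort fallback). The bands are the definition of the classes;
   without enforcement, rare draws (e.g. a marginal duplex above the
   −14 gate) silently change the study conditions of a run.

A single RNG stream per stage (`seed` for the genome, `seed + 1` for
reads), drawn in documented order, makes outputs byte-identical for a
fixed seed and config.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: sequencing error models and quality
scores, expression dynamics across tissues and libraries, conservation,
isomiR biology beyond simple 5′ jitter and A/U tails, mirtrons and
other non-canonical biogenesis, genome-scale repeat families, and the
sheer candidate volume of a mammalian genome (the benchmark runs at
~130–160 candidates, not ~30 000). Results on synthetic data
demonstrate the machinery's correctness and calibration behaviour, not
field performance.

## Problem sizes used in the checks

The standard benchmark is a 100 kb genome, 20 planted miRNAs (10
annotated, of which 2 marginal), 200 decoys and mean arm depth 100;
unit fixtures are 2–40 kb genomes with handfuls of loci. These sizes
make every property of interest measurable (order-of-minutes full
suite) while keeping the calibration non-trivial — the choice is the
package's own.

## Known limitations

- The expected-count model assumes parameter independence; correlated
  parameters (both overhangs; to a lesser degree the heterogeneities)
  must be grouped, and residual correlations bias the FPR estimate
  optimistically.
- Percentile calibration needs enough annotated exemplars
  (`min_annotated`); with 10 toy exemplars the discrete levels are
  coarse, and with degenerate parameters cutoffs can only exclude by
  strict inequality.
- Zero-mismatch mapping makes detection sensitive to SNPs/editing; the
  tailing score partially compensates at the 3′ end only.
- The builtin folding backend is a deliberately simple energy model;
  absolute energies are not comparable to nearest-neighbour values.
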