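---
title: "Statistical detection of circular RNA junctions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical detection of circular RNA junctions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements: the
models, their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the method left room.

## The detection problem

A backsplice joins a splice donor to an *upstream* acceptor, producing a
circular RNA whose only sequence-level signature is the scrambled
exon–exon junction. Reads spanning scrambled junctions, however, also arise
from artifacts: many exons (ALU-derived in particular) are nearly identical,
and sequencing or polymerase errors can make a read from an ordinary linear
junction match a scrambled junction equally well or better. A read whose
mate lands *inside* the genomic span of the presumed circle is
indistinguishable from true circular evidence; a mate *outside* that span is
consistent with neither a linear nor a circular transcript and is called a
**decoy**. Decoys are not discarded here — they are the training data for
the artifact class.

## Junction database

Every pair of (deduplicated) exons on one chromosome and strand whose start
coordinates lie within `window` (default 1,000,000 nt) contributes a linear
and a scrambled junction; each exon also yields a scrambled self-junction
(single-exon circle). Sequences take `pad_side` (default 150) nt from each
side in transcript orientation; shorter exons are N-padded *away from the
boundary*, so every sequence is exactly `2 * pad_side` nt and the boundary
is always at position 150. Padding distal to the boundary keeps the offset
computation identical for all junctions; in alignment the reference `N`
matches any base (the near-zero N penalty), so short exons are not
penalized. Coordinates are 1-based closed throughout, the R/Bioconductor
convention; junction ids print the 1-based splice-site positions as
`chrom:pos5:pos3:strand`, with `pos5 > pos3` the backsplice signature.

The window is measured between exon *start* coordinates and pairing is not
restricted to genes: same-strand cross-gene pairs within the window are
included (homologous-gene artifacts are exactly such junctions) and flagged
by the `cross_gene` column.

## Read-pair classification

R1 and R2 align independently, as single-end reads, to the genome, the
linear index, and the scrambled index. The rules, in order:

* an R1 with a passing genome (or rRNA) alignment is discarded —
  non-diagnostic;
* an R1 aligning to both a linear and a scrambled junction anchors to the
  linear one only;
* the anchor must overlap the splice boundary by `min_overlap` (default 10)
  nt, where the offset is the smaller side of the overlap;
* R2 takes its best-scoring alignment, ties broken genome > linear >
  scrambled > de novo;
* linear anchors with a concordant mate (opposite orientation, downstream in
  fragment orientation, span at most `max_fragment` = 1000 nt) are
  **linear**; scrambled anchors are **circular** if the mate lies within the
  presumed circle — the full span between the junctional exons, since the
  circle may include or exclude anything in between — expanded by
  `buffer` = 15 nt (reverse-transcription slop; 50 nt for de novo junctions,
  matching the bin size, applied symmetrically on both ends), and **decoy**
  otherwise (outside, other chromosome, or same orientation).

One footprint subtlety: a mate mapped to a junction sequence is projected
back to genome coordinates through the junction's two exon sides, and a side
covered by fewer than `min_overlap` bases is dropped from the footprint. A
few overhanging bases carry no positional evidence — they tie across every
junction sharing the other side — and letting them define "outside the
circle" would miscall genuinely circular pairs as decoys.

The built-in matcher (20-nt exact seeds, mismatch-verified extension,
acceptance at four mismatches per 100 read bases, score −6 per mismatch,
MAPQ from the best/second-best gap per index, pseudo-random but
reproducible tie-breaking) replaces an external aligner for desk-scale
genomes; SAM and a plain-TSV alignment dialect are the ingestion paths for
real data.

## The two-step weighted logistic model

Linear reads are class 1 ("true alignment"), decoys class 2 ("artifact").
Three R1 features carry the signal: boundary offset, alignment score, and
mapping quality (R2's features are spent on categorization). Because the
labels themselves contain errors, fitting proceeds twice:

1. equal weights within a class, scaled so both classes sum to half the
   total read count — the larger linear class is downweighted to equal
   influence, and keeping the total at the sample size leaves Wald standard
   errors on the honest scale;
2. weights are multiplied by the step-1 predictions — `p_hat` for linear
   reads, `1 - p_hat` for decoys — renormalized to equal class totals, and
   the model is refit. Reads whose mate-based label conflicts with the
   model's view lose influence.

For scoring, each read takes the *conservative* end of the 95% Wald interval
on its linear predictor: the lower bound if the read is predicted class 1,
the upper bound otherwise. The interval end is truncated at 0.5: a wide
interval may neutralize a read's evidence but must never invert its
direction (with small decoy classes, saturated cells can make intervals very
wide; inverting would turn strong positive evidence into strong negative
evidence). Probabilities are clamped to `(1e-6, 1 - 1e-6)` before log-space
products.

Perfect or quasi-separation — detected as non-convergence, runaway
coefficients, or exploded coefficient standard errors (any SE above 5, the
signature of a saturated predictor cell with vanishing information) —
triggers a ridge-penalized IRLS fallback: a fixed penalty of 0.01 per unit
weight on standardized non-intercept coefficients, sandwich covariance,
mapped back to the raw scale. The fallback is exercised deliberately by the
test suite.

## Junction-level inference

The posterior that a junction is truly expressed aggregates its non-decoy
reads: `P = prod(p) / (prod(p) + prod(1 - p))`, computed in log space. One
read gives `P = p`; a junction whose reads split evenly between `q` and
`1 - q` gives exactly 0.5 — read count alone cannot inflate the posterior,
which is the property that decouples confidence from expression level.
Reported circles require `P >= 0.9` and at least `n_min` reads (default 2;
1 for very shallow libraries).

P-values:

* **linear junctions** — permutation null: with `l_i = log((1-p_i)/p_i)`,
  the junction sum `l_n` has null mean `n*mu` and variance `n*var1`, with
  `mu` and `var1` estimated once per dataset over all decoy and linear reads
  (per-read averaging). One-sided `p = pnorm(z)`: small when the posterior
  is higher than chance.
* **circular junctions** — the permutation null is over-conservative for
  reads the model never trained on, so a two-point artifact null is used:
  an artifact read has probability 0.1 with 95% chance and 0.9 with 5%
  chance; with the printed moments `mu = log(9)`, `var = n*log(9)^2` and the
  conservative per-read posterior 0.9, the z-score reduces to `-2*sqrt(n)`.
  (The printed `var` is the second moment, not the variance, of that
  two-point law; the printed form is implemented verbatim since it defines
  the reported numbers.) BH FDR is computed within the scrambled set.
* **naive mode** (single-end data, de novo screening) — all mismatches are
  sequencing error under `Poisson(0.01 * bases)`; the upper tail
  `P(X >= m)` is reported so that *low* p flags excess mismatches, the false
  positive signature. (The alternative lower-tail reading would flag the
  cleanest junctions as failures, contradicting how the test is used.)

## De novo discovery

Reads failing every index are split into 5' and 3' segments (length
`read_len - 65`, i.e. 35 nt for 100-nt reads), each required to map uniquely
with at most two mismatches, on one strand, in backsplice orientation.
Candidates are grouped by 50-nt genome bin pairs; a group needs three reads
with distinct offsets. Members stack by their split offsets; at every
position covered by more than one read, (non-consensus reads)/(covering
reads) adds to the score `S` — zero for a unanimous stack, with expectation
`sum(p)` over multiply covered positions under a per-base error rate `p`
(about 1 for 100 such positions at 1%). Groups with `S < 5` survive;
consensus ties break lexicographically; a group with two or more
well-supported conflicting columns (depth ≥ 3, minority fraction > 1/3) is
rejected as a multiple-breakpoint mixture — the formula-free screen the
method names, given a concrete rule here.

Breakpoints are refined by splitting the consensus at every position leaving
≥ 20 nt on both sides and matching the fragments within ±500 nt of their
bins (≤ 1 mismatch). Among mappable breakpoints, GT-AG flanks win (U2), then
the U12 signature (TATCCT one nucleotide downstream of the donor, or AT-AC
termini), then the first mappable split — resolving the `ag-GT`-style
ambiguity in favour of the canonical signal. Junctions within 1 kb of an
annotated gene take its name, otherwise `UNAN`. Finally all unaligned reads
are realigned to the consensus index; junctions pass with naive `p > 0.9`,
decoy/circle ratio `< 0.1`, and breakpoint separation `> 200` nt (read as
breakpoint distance, not minimum circle size; the knob is exposed), after
collapsing bins to unique breakpoints.

At a 1% error rate the observed mismatch count against the consensus sits at
its null expectation, so `naive p > 0.9` is a strict purity screen — only
near-error-free junctions pass. The de novo recovery guarantees are
therefore stated, and tested, for error-free reads; with errors the screen
deliberately trades recall for purity.

## Induction statistics

* **Exterior splicing.** Linear expression must be measured independently of
  the circle, so only linear junctions with at least one splice site outside
  every qualifying circle span (count ≥ `k_min`; 10 for deep data, 0 for
  shallow) are used; with several circles the exterior set is the
  intersection.
* **Normalization.** Per sample, counts divide by the median count among
  junctions exceeding five counts — junctional-depth normalization in the
  spirit of RPKM.
* **Age-weighted z.** With `x_i = r_i / c_i` and the age contrast `o`
  (centered to sum zero, then unit 2-norm — in that order), the statistic is
  `z = sum(o * (x - mean(x))) / sqrt(sum(o^2 * x / c))`. The variance is the
  `o^2`-weighted sum of the per-sample Poisson variance estimates
  `x_i / c_i`; a unit-norm shortcut that drops the `o^2` weighting inflates
  the variance roughly `n`-fold and deflates every z by about `sqrt(n)`,
  so the weighted form is the one that is actually N(0,1)-calibrated (the
  null simulation in the test suite checks mean ≈ 0 and sd within
  [0.9, 1.1]). z is maximal when counts rise linearly with age. Ages enter
  as raw values; duplicated ages contribute through the same contrast entry.
  Both the maximum and the median exterior-linear z are sensible gene-level
  comparators; the package emits per-junction z and leaves the summary to
  the caller.
* **JRPKM.** A junction is reachable by reads starting in a window of
  `2 * (read_len - min_overlap)` = 180 nt, so
  `JRPKM = count / (linear_mapped / ((180/1000) * 1e6))`.
* **Two-timepoint test.** The circle fraction `n_c / (n_c + n_l)` gets a 95%
  binomial CI per sample (Wilson score by default — better small-`n`
  coverage than Clopper–Pearson, which is available via `method`);
  non-overlap calls an increase or decrease. Because both counts share the
  sample's depth, the fraction is depth-free.
* **Outlier analysis.** Per gene across samples, the circle fraction is
  standardized against the pooled MLE (`z_n`) and against an unweighted OLS
  prediction from depth-normalized linear counts (`z_o`); each `z_o` is
  divided by the median across genes of the per-gene sd of `z_o` (Poisson
  overdispersion absorption; when every gene is exactly on trend that median
  is zero and the correction is skipped with a warning rather than dividing
  by zero), referred to `t(n - 2)`, BH-corrected, and flagged at FDR 0.001.
  OLS predictions outside (0, 1) are clamped with a warning.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 100-nt paired reads, fragments
260 ± 35 nt, a 1% per-base substitution error rate (substitution-only — the
pipeline accepts only ungapped alignments, so indels would be invisible),
six five-exon genes each expressing a circle over exons e2–e4, and in four
of them an ALU-like near-copy of the acceptor exon (two diverged bases, at
40 and 60 nt from the exon start) *inside* the circle. Reads from those
circles whose boundary overlap stops short of the first diverged base
cannot distinguish the true backsplice from the homolog-acceptor scrambled
junction: the resulting ties produce artifact junctions, false-positive
circular reads, and decoy reads — the exact taxonomy the classifier is
trained on. Coverage (1000 fragments per homolog circle) is set so the
expected decoy yield per sample (~20–30) comfortably exceeds the
classifier's 10-read class minimum; the direct route — sequencing errors
flipping a linear read to a scrambled junction — requires beating the
linear-preference rule by five mismatches and is astronomically rare at any
desk scale, so the homolog-tie route is the mechanism that matters.
Circular fragment sampling wraps modulo the circle length, so circles
shorter than a read produce doubly junctional reads. Un-annotated GT-AG
circles can be planted in intergenic space for de novo tests.

What the generator does **not** emulate: quality-score profiles (the error
rate is flat), PCR duplicates, reverse-transcription template switching
(reflected only through the decoy feature distributions of
`simulate_feature_table()`), intron retention, multi-chromosome genomes,
and minus-strand genes in the default layout (strand handling is exercised
by the index-construction tests instead). Passing tests therefore show the
statistical machinery behaves as designed under its own assumptions — not
that those assumptions exhaust real libraries.

Problem sizes used by the checked-in simulations: ~4,800 read pairs per
sample on an ~13-kb genome with ~900 junction sequences; 20 independent
seeds for the end-to-end recovery property; 10,000 junctions for the
permutation-null and induction calibrations; 100 replicates at 5,000 reads
per class for coefficient recovery; 10,000 depth-2 stacks for the consensus
score expectation.

## Numerical choices and degenerate inputs

* Posteriors, and all products of probabilities, are computed in log space
  with a two-term log-sum-exp; probabilities are clamped at `1e-6`.
* Empty annotation: empty junction set with a warning. Exon outside the
  genome: error naming the exon. Empty read input: empty reports, zero
  summary, success.
* All-zero count vectors give `z = NA` (reported missing); constant ages are
  an error (no contrast).
* Consensus ties: lexicographic, deterministic. Aligner ties: stable
  per-read hash, deterministic across runs and platforms (integer
  arithmetic only).
* The seed governs every stochastic step; generator outputs are
  byte-identical under a fixed seed.

## Known limitations

The built-in matcher is exhaustive-by-seeds and meant for toy genomes; real
data should come in as SAM/TSV from a production aligner. Junctions are
deduplicated by splice-site id, so alternative exon extents sharing both
splice sites collapse. The de novo stage assumes plus-strand-style stacking
per strand group and is validated on plus-strand plants. Posterior
calibration inherits whatever biases the decoy class carries; in very
shallow samples the ridge fallback keeps the classifier usable but its
intervals are regularized, not exact.
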