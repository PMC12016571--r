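---
title: "Methods: benchmarks, features and models for N-phosphosite prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarks, features and models for N-phosphosite prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific choices behind `npsite`: the model
and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where more than one defensible option existed.

## The window model

All feature extraction operates on a 31-residue peptide window centered on
a candidate histidine, lysine or arginine. The choice of 31 follows the
established observation that kinase recognition is governed by roughly the
14–15 residues either side of a phosphosite; windows that would extend
past a terminus are padded with the `-` character so every window has
exactly 31 positions and the center is always position 16. Coordinates
are 1-based and fully closed, matching UniProt site numbering.

Ambiguity letters (B, Z, X, U, O) are accepted on input so that real
UniProt sequences parse, but windows containing them are flagged and every
encoder treats them as pad-equivalent: they drop out of the AAC tally,
contribute a zero block to HQI8, and map to the BLOSUM62 "any" row. This
keeps the encoders total without inventing physicochemical values for
ambiguous letters.

## Feature encodings

- **AAC** (20 values) is the composition of the canonical residues of the
  window. Pads are excluded from numerator *and* denominator, so the
  vector always sums to 1 — a window is described by what is actually
  observed, not diluted by its padding.
- **HQI8** (248 values) assigns each window position the eight
  "high-quality" AAindex indices (accessions BLAM930101, BIOV880101,
  MAXF760101, TSAJ990101, NAKH920108, CEDJ970104, LIFS790101,
  MIYS990104) selected by fuzzy clustering of the AAindex property space;
  the values are read at run time from the AAindex copy shipped with
  `seqinr`, and a replacement table can be supplied as TSV. Values are
  used as published, without per-feature standardization; boosted trees
  are scale-invariant, so standardization would only matter for other
  learners plugged into the same interface.
- **BLOSUM62** (620 values) encodes each position by its row of the
  standard BLOSUM62 matrix. The pad/ambiguity row is the matrix's X
  ("any") row — the closest published semantics for a character that may
  stand for any residue — and can be overridden by supplying a matrix
  parsed from an NCBI-format file with `read_blosum()`.

Combinations concatenate in the fixed order AAC, HQI8, BLOSUM62,
position-major within the positional encoders, yielding the seven lengths
20, 248, 620, 268, 640, 868, 888. Encoding is deterministic and feature
names identify (encoder, position, channel) uniquely.

## Benchmark construction

Positives are the distinct windows around annotated sites; identical
peptides arising in different proteins collapse to one example per site
type, removing an easy source of train/test leakage.

The negative rule has four steps, each with a rationale:

1. candidates come only from proteins that carry at least one verified
   site, so positives and negatives share the same detectability bias;
2. candidates above the per-residue RSA ceiling (0.12 His, 0.30 Lys,
   0.20 Arg) are excluded — exposed residues are the ones most likely to
   be unobserved true sites, and the per-letter ceilings also balance the
   class ratio by amino acid;
3. windows are extracted exactly as for positives;
4. windows with ungapped end-to-end identity ≥ 30% to any positive of
   the same type are removed.

The identity filter is a direct all-pairs scan over equal-length 31-mers
(sparse one-hot cross-product; matching non-pad positions / 31) rather
than a wrapped clustering tool: at a 30% threshold word-based clustering
heuristics operate at or below their documented floor, while the exact
scan is cheap at benchmark scale and has a one-line definition that a
brute-force oracle can re-verify. Candidates lacking an RSA value are
dropped and counted, not imputed — the RSA constraint *is* the negative
rule. Negatives are deduplicated but not filtered against each other,
since the rule is defined relative to the positive set only.

## Training and evaluation

One GBDT classifier per site type (binary logistic objective, histogram
tree construction, single thread for determinism; defaults: 200 rounds,
depth 4, learning rate 0.1, no subsampling). The per-type default feature
combinations — AAC+HQI8 for pHis and pArg, all three for pLys — follow
the model-selection outcome for this problem family. A small documented
grid (rounds × depth × learning rate) can be searched by mean k-fold
cross-validated AUC; the learner sits behind a bundle interface so other
algorithms can be registered without touching the pipeline.

Evaluation uses repeated stratified 80/20 splits (default 5) and repeated
stratified 10-fold cross-validation (default 10), reporting mean ± sd of
sensitivity, specificity, precision, F1, accuracy, MCC and AUC. Two
printed-formula corrections are deliberate: specificity is computed as
TN/(TN+FP) and MCC with the standard Matthews denominator
√((TP+FP)(TP+FN)(TN+FP)(TN+FN)); the variants sometimes seen in print
(FN/(FP+TN); a denominator without the TN+FP factor) are inconsistent
with the quantities they are meant to measure. Ratios with a zero
denominator are reported as `NA`, never silently as 0. Hard calls use the
0.5 cutoff that also defines the reporting threshold of the predictor;
AUC is the rank (Mann–Whitney) statistic with average ranks for ties, so
it is invariant under monotone transforms of the scores. All randomness
flows from one top-level seed from which per-repeat and per-fold seeds
derive deterministically.

## Enrichment and motifs

`e_ratio()` computes (m·N)/(M·n) and compares cohorts with the
chi-squared test without continuity correction (the mainstream default at
these sample sizes; Yates is available as an option). Motif discovery is
the greedy motif-x scheme: repeatedly fix the (offset, residue) pair with
the smallest exact binomial upper-tail p-value of its foreground count
given the current background frequency, reduce both sets to matching
windows, and stop when no pair reaches the per-step cutoff (default
1e-4, the motif-x family convention) or the occurrence floor. A motif is
reported when its score Σ −log10(p) ≥ 5 with ≥ 10 foreground
occurrences. Exact tails rather than normal approximations keep small
counts honest; a zero background count is guarded by half a pseudo-count
so a p-value is always defined. Ties break by smaller offset magnitude,
then alphabetical residue, making the search fully deterministic.

## Prediction and grading

Every H/K/R residue of a query is windowed, scored by the type's bundle
and reported when the probability exceeds 0.50, graded high
(0.85 < p ≤ 1], middle (0.70 < p ≤ 0.85] or low (0.50 < p ≤ 0.70];
grades are assigned on the full-precision probability and only the
printed value is rounded to four decimals. Proteome scans default to the
0.85 high-confidence threshold and can exclude already-annotated
positions. Queries must be longer than 16 residues — one more than the
window half-width — and shorter inputs are rejected outright; for legal
lengths of 17–30 the window is padded, consistent with the pad character
being part of the encoding alphabet.

## The synthetic generator

The generator exists so every stage of the pipeline is testable without
any external corpus. It emulates, under one seed:

- i.i.d. background sequences (default uniform 1/20 — chosen so planted
  enrichments are analytically checkable; a Swiss-Prot-like composition
  preset is included);
- planted sites whose flank letters at the signal offsets are resampled
  with the residue weights multiplied by an effect size: K/E at offsets
  ±1..±7 of pHis, S/P at −8..−1 of pLys, S/P at ±1..±4 of pArg —
  the qualitative flank patterns reported for real sites. The default
  effect multiplier of 5 makes the Bayes-optimal AUC of the planted
  problem comfortably above 0.9, so a correct implementation has
  headroom against the 0.85 recovery bar while an effect of 1 is an
  exact null;
- default planted counts of 2000/4000/2800 (pHis/pLys/pArg) across 2600
  proteins of mean length 400 (~1M residues), proportioned like real
  curated benchmarks so that the RSA ceilings produce the familiar ~1:3
  class balance;
- per-residue RSA uniform on [0,1] with planted sites drawn from
  Beta(5,3) (mean 0.625, mostly "exposed"), so the negative rule's RSA
  filter genuinely removes candidates;
- structural labels drawn from a configurable background law, with an
  optional coil-enrichment multiplier for sites to exercise the
  propensity statistics.

It does **not** emulate residue autocorrelation, domain structure,
homologous protein families, detection noise, or species differences.
Passing tests therefore demonstrate that the pipeline recovers signals it
is pointed at and respects its own contracts — not that a given AUC will
transfer to real proteomes, where positives are scarcer and the
background is structured.

## Problem sizes used in the shipped checks

Unit tests run on a miniature scene (60 proteins, ~80–100 sites per
type). The end-to-end recovery check uses the study-scale defaults above
(~2000 positives / ~5900 negatives for the His-type benchmark), a single
80/20 split for the held-out AUC, a label-permutation null, and a
2-repeat 10-fold cross-validation for the consistency comparison — sizes
at which the quantities of interest are stable to well under the margins
being asserted. The motif null check uses 100 seeded draws of 200
foreground windows against a 2000-window background.

## Known limitations

- Published benchmark performance (AUC ≈ 0.90–0.92 on curated human
  datasets) is not re-derivable without those datasets and their splits;
  the synthetic recovery experiment is the substitute contract shipped
  here.
- The RSA ceilings are consumed as configuration; the balancing
  procedure that originally produced them is not re-derived.
- Negatives depend on annotation completeness: unannotated true sites
  that are buried enough to pass the RSA filter will contaminate the
  negative pool, a limitation shared by every predictor built this way.
- The homology filter is ungapped and window-local by design; it is not
  a general homology reduction across full-length proteins.
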