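---
title: "Methods: proteogenomic database construction, PSM rescoring and sORF selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic database construction, PSM rescoring and sORF selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfpep)
```

## The problem

Endogenous (enzyme-free) peptidomics asks which peptides are actually present
in a tissue — mature neuropeptides cleaved from precursor proteins, their
truncation ladders, and the translation products of small open reading frames
(sORFs, proteins of at most 100 amino acids) that often sit on genes annotated
as non-coding. Two things make this hard. First, without a digestion enzyme
the search space of candidate peptides explodes: every substring of every
protein in the database is a candidate, and a proteogenomics database that
adds hundreds of thousands of predicted sORF products multiplies it further.
Second, endogenous peptides mostly do not end on Lys/Arg, fragment less
predictably, and are often supported by a single spectrum, so the
identification statistics must be handled carefully.

`sorfpep` implements the computational core of such a workflow in four layers:

1. **Database construction** (`build_database()` and friends): merge a
   reference proteome, two styles of predicted-sORF sets and a contaminant
   set into one target–decoy FASTA, with redundancy rules and a composition
   report.
2. **Spectral arithmetic** (`monoisotopic_mass()`, `fragment_mz()`,
   `match_peaks()`, MGF I/O): the mass and b/y fragment layer that spectral
   features are built on.
3. **Validation** (`compute_qvalues()`, `pep_estimate()`,
   `semi_supervised_rescore()`): target–decoy false-discovery control and a
   cross-validated, semi-supervised linear rescorer over an expanded feature
   set.
4. **Interpretation** (`group_peptides()`, `annotate_neuropeptides()`,
   `filter_small()`, `noncoding_filter()`, `uniqueness_scan()`,
   `coverage()`, `summary_tables()`): peptide-level summaries, neuropeptide
   annotation and non-coding sORF candidate selection.

A fifth layer, the simulator (`simulate_*()`), generates synthetic inputs
with known ground truth for every other layer; it is first-class, tested
code, and the entire test suite runs from it.

## Database construction rules

The search database is assembled in a fixed stage order. Within each source,
identical sequences are collapsed first. For ribosome-profiling predictions
that carry genomic loci, two redundancy rules apply before anything else:

* **Longest per stop codon.** Predictions sharing a stop position are nested
  proposals of the same ORF; only the longest is kept. The key is
  `(chrom, strand, stop_coord)` where `stop_coord` is the strand-aware
  3'-most coding coordinate in 0-based half-open (BED-compatible)
  coordinates: the last block end − 1 on `+`, the first block start on `−`.
  Length ties are broken by lexicographically smallest sequence, then
  smallest id, so results are reproducible.
* **Single-exon coding overlaps.** A prediction whose locus has exactly one
  exon block and overlaps (≥ 1 nt, same chromosome and strand) an annotated
  protein-coding exon is discarded; these are dominated by out-of-frame
  shadows of the annotated protein. We considered the alternative reading —
  "fully contained within one coding exon" — and kept the structural
  (one-block-and-overlapping) reading as the default because it is the
  stricter filter and does not depend on exact exon boundaries.

Across sources, the two predicted sets are deduplicated against each other
(survivor precedence `reference > openprot > sorfs_org > contaminant`, then
smallest id), and predictions whose full sequence equals a reference protein
are removed. We interpret "identical" as exact full-sequence identity:
removing predictions merely *contained* in reference proteins would silently
delete genuinely distinct short proteoforms. A containment mode exists behind
`containment = TRUE` for users who want the aggressive behaviour.

Decoys are whole-sequence reversals, one per target, id-prefixed `DECOY_`.
Because the searches are enzyme-free, there is no reason to anchor C-terminal
residues the way tryptic decoy schemes do. Reversal is an involution, which
the tests exploit; palindromic decoys are legal and flagged.

The composition report classifies every distinct sequence into one of the
seven disjoint membership cells over the three sources and derives three
percentages (proteogenomics-only, reference-only, overlap). Percentages are
rounded half away from zero at one decimal — base R's `round()` rounds half
to even, which disagrees with the conventional presentation of such tables.
Composition is computed on the pre-decoy, pre-contaminant sets: decoys and
contaminants are search machinery, not search space.

## Masses, fragments and peak matching

Residue monoisotopic masses, the proton (1.00727646677 Da) and water
(18.0105646837 Da) are fixed in code. The supported variable modifications
are the endogenous-peptidomics set: C-terminal amidation (−0.984016 Da),
methionine oxidation (+15.994915 Da), and pyro-glutamate from N-terminal Gln
(−17.026549 Da) or Glu (−18.010565 Da). Amidation shifts only the y series,
pyro-glutamate only the b series, oxidation follows its residue; the
complementarity identity `b(n−1) + y(1) = M + 2·proton` therefore holds for
every admissible peptidoform and is property-tested on 1,000 random
peptidoforms.

Peak matching is nearest-within-tolerance at a symmetric 0.02 Da (the
conventional fragment mass error for TOF feature extraction), non-exclusive
(one observed peak may serve several theoretical ions) with equidistant ties
going to the higher intensity. We chose non-exclusive matching over greedy
assignment because it is deterministic, order-free and adequate at 0.02 Da;
a ppm-scaled tolerance was considered and rejected since the downstream
features are correlation-based and insensitive to the distinction at
peptide-fragment m/z ranges.

Spectral features compare predicted and observed fragment-intensity vectors
on the charge-1 b-then-y ladder. Both vectors are normalised to total ion
current and transformed `log2(x·1e4 + 1)` — stable at zero, scale-invariant
after TIC normalisation, and compressive enough that a few dominant ions do
not own the correlation. The Pearson correlation of a zero-variance vector
is defined as 0 (an unmatched spectrum is evidence of absence, not missing
data). Retention-time features are the absolute, signed and span-relative
errors; predicted RTs and intensities are *inputs* (in practice produced by
external predictors) — the package ships no trained models, and the
simulator's intensity models exist only to generate fixtures.

## Target–decoy statistics

`compute_qvalues()` ranks by decreasing score with score ties broken
decoy-first (the conservative choice), estimates FDR at each threshold as
`(D + plus_one) / max(T, 1)`, and monotonises by a running minimum from the
bottom. `plus_one = FALSE` is the default; the `+1` numerator variant used
by some tools is available and both are tested against a brute-force
threshold-enumeration oracle. `pep_estimate()` reports the local decoy
fraction in a sliding window over the ranking, made monotone by isotonic
regression; in the uninformative limit (all scores equal) every PSM gets
`D/(D+T)`, which is the estimator's fixed point by construction. PEP is
reported alongside q-values; neither is derived from the other.

## The semi-supervised rescorer

`semi_supervised_rescore()` mirrors the published semi-supervised
target–decoy scheme at desk scale:

* PSMs are split **spectrum-wise** into `folds = 3` disjoint folds via a
  seeded deterministic string hash of the spectrum id, so all PSMs of one
  spectrum share a fold and no peptidoform leaks across the train/test
  boundary through its spectrum.
* Per fold: positives are initialised as training-fold targets with
  base-score q ≤ 0.01; an L2-regularised (ridge) logistic classifier of
  positives versus all training decoys is fitted; training PSMs are
  rescored, positives reselected at q ≤ 0.01, and the loop repeats until the
  positive set is stable or `max_iter = 10`. Ridge strength is selected from
  a small grid by an inner 2-fold split of the training spectra, maximising
  accepted training targets.
* The held-out fold is scored with the trained weights and standardised
  using the mean and standard deviation of the *training* decoys under the
  same weights — a larger decoy sample than the held-out fold's own, and
  independent of the fold being scored, which measurably reduces cross-fold
  merge noise. Final q-values come from `compute_qvalues()` on the merged
  scores.
* A fold with no decoys or no initial positives falls back to the base
  score with a warning.

Rescoring never changes labels or the PSM set — only scores and q-values.
Two properties guard the loop against self-confirmation: with only the base
score available, the accepted set at q ≤ 0.01 tracks base-score acceptance
(mean relative difference ≤ 2% over seeded replicates at 8,000 PSMs; the
residual difference is cross-fold merge noise of order `1/sqrt(n_decoys)`);
and with permuted, uninformative features the mean true false-discovery
proportion among accepted PSMs stays within `[0, 0.03]` over 20 seeded
simulation replicates.

## Summarisation and sORF selection

Peptide grouping keeps target PSMs with q **strictly below** 0.01 (the
boundary PSM at exactly 0.01 is excluded) and groups by sequence plus
modifications. Both counting modes — with and without modifications in the
key — are exposed, because method-comparison counts are conventionally
modification-aware while precursor-level counts often are not; the package
does not resolve that convention, it parameterises it.

Neuropeptide annotation matches a peptide group to a reference entry when
either sequence contains the other. Bidirectional containment is the only
rule that captures both directions of the truncation ladders produced by
endogenous proteolysis (an identified peptide may extend or truncate the
catalogued mature form). Groups matching a supplied precursor protein but no
mature entry are flagged `precursor_only` rather than dropped.

sORF candidate selection: the small-protein filter is inclusive at 100 aa;
the non-coding filter excludes gene-level biotype `protein_coding` (gene
level, not transcript level, so that experimental evidence from overlapping
coding regions cannot masquerade as a non-coding hit), retains lncRNA / TEC
/ pseudogene and other biotypes, retains allowlisted curated genes
regardless, and retains-but-flags genes with no biotype annotation at all.
`uniqueness_scan()` is a gap-free windowed Hamming scan (exact substring
hits plus windows with at most `max_mismatches` mismatches); it stands in
for an alignment-based homology search, which is reasonable for short MS
sequence tags where gapped alignments of near-identical hits collapse to
the ungapped case. The mismatch bound plays the role of an e-value cutoff;
we document the analogy and do not claim equivalence. Tags shorter than 8
residues are refused. Coverage is the percentage of protein residues under
the union of all occurrences of all identified peptides, binned at the
conventional 10% and 30% break points. Every emitted overview table ends in
a totals row that is asserted equal to its column sums at construction.

## The simulator

The simulator emulates exactly the structures the pipeline consumes:

* `simulate_proteome()` plants the seven Venn cells over three sequence
  sets with distinct random sequences, so composition recovery can be
  checked exactly. Default lengths 20–80 aa keep the collision probability
  negligible while exercising the < 100 aa accounting.
* `simulate_sorf_predictions()` plants stop-sharing groups (known longest
  member) and single-exon coding overlaps (known removals) with valid BED
  coordinate arithmetic on both strands, and emits the exact expected
  survivor lists.
* `simulate_spectra()` places peaks at the theoretical charge-1 b/y m/z of
  random peptidoforms (lengths 8–50, charges 1–6, 80% non-tryptic
  C-termini by default, matching the enzyme-free regime where roughly four
  in five peptides do not end on K/R), with observed intensities built as a
  convex mixture in transformed-intensity space so the expected
  predicted–observed correlation is approximately the requested `rho`
  (`rho = 1` reproduces the prediction exactly), plus uniform noise peaks.
* `simulate_psm_scores()` draws correct-target scores from
  `Normal(mu_correct, sigma)` and incorrect-target and decoy scores from
  `Normal(mu_incorrect, sigma)` — the core target–decoy assumption that
  decoys model incorrect targets — with informative auxiliary features
  shifted only for correct PSMs, and returns the true labels. Defaults
  (1,500 targets, 1,500 decoys, 35% correct, 3σ separation, three
  informative features of effect 1.2) give a regime where the base score
  accepts a few hundred PSMs at 1% FDR and the auxiliary features carry
  real additional signal, comparable to a single peptidomics run after
  spectrum filtering.

Every generator is seed-deterministic and byte-stable, and restores the
caller's RNG state. What the simulator does **not** model: isotope
envelopes, ion-mobility physics, chimeric spectra, correlated noise between
features, heavy-tailed score distributions (a flag exists for the mixture
shape), or realistic retention-time error structure. Passing tests
therefore demonstrate the correctness and calibration of the *algorithms*
under the stated generative assumptions, not instrument-level performance
on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest sizes —
published-magnitude Venn cells scaled by 1,000 (545 sequences), PSM
collections of 1,400–8,000, 20 calibration replicates — which we consider
the right scale for exercising every code path and statistical property of
a desk-scale reimplementation; the arithmetic is size-independent and the
calibration properties are asserted as averages over seeded replicates.
Other fixed choices: decoy prefix `DECOY_`; fragment charges generated up
to a configurable maximum (2 is conventional for precursors of charge ≥ 2);
no neutral-loss ions (the feature model is b/y-based); median imputation
with indicator masks for missing features; percentages rounded half-up to
one decimal.

## Known limitations

* The uniqueness scan is gap-free; insertions/deletions in a homolog will
  hide it from the scan.
* The rescorer is linear; non-linear rescoring (gradient boosting and
  kernel variants exist in the wider literature) is out of scope.
* Frame logic for "out-of-frame predictions on coding genes" is not
  modelled; the gene-biotype exclusion is the implemented reading.
* mzIdentML ingestion and vendor raw formats are out of scope; PSMs enter
  through the TSV dialect and spectra through MGF.
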