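---
title: "cypscope: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cypscope: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypscope)
```

`cypscope` implements a survey pipeline for polymorphic cytochrome P450
(CYP) drug-metabolizing enzymes: literature mining of allele-frequency
statements, a curated star-allele catalog, cohort allele frequencies from
genotypes, and a tissue-expression body map. This vignette documents the
models, the tunable parameters and why their defaults are what they are,
what the synthetic generators do and do not emulate, and the places where
the design was genuinely open.

## 1. Relation mining

### Model

Abstracts are tokenized into word-level tokens with sentence indices;
star alleles (`CYP2D6*4`), rsIDs and percentages (`81.3%`) are atomic
tokens so that token distances mean word distances. Entities come from a
dictionary (ethnicities, effect words, negation cues, CYP synonyms) plus
two pattern rules: percentages parse to `FREQUENCY` mentions on the 0-100
scale, and `CYPnXm`-shaped tokens (with optional star suffix, or the word
`CYP` followed by a bare code) to `CYP` mentions.

Every (CYP, ethnicity, frequency) triple sharing a sentence becomes a
candidate scored by the distance rule: within thresholds
d_ce ≤ 7 (CYP-ethnicity) and d_fc ≤ 6 (frequency-CYP) and without
negation, the score is exactly 100. The thresholds are the published rule
of the original curation effort; scores of 100 were the ones accepted for
manual review there, which is why `min_score = 100` is the reference
operating point (the CLI default) while the R-level default returns all
candidates.

### Choices the rule statement left open

The source rule family names order, redundancy, distance, topic
segmentation and sentence breaking, but only quantifies distance. Our
choices:

* **Decay beyond thresholds**: linear, `decay_weight = 10` points per
  excess token per dimension, floored at zero. The simplest monotone
  rule; any decay that is monotone and reaches 0 within a sentence's
  length behaves equivalently at the `min_score = 100` operating point.
* **Negation**: multiplicative `negation_factor = 0.5` when a negation
  cue lies strictly between the closest of the two mention pairs.
  A multiplicative factor preserves the score ordering within the negated
  subset; the "closest pair" scoping keeps unrelated negations at
  sentence edges from flipping candidates.
* **Sentence scoping**: same-sentence windows by default ("sentence
  breaking for boundaries"); adjacent-sentence matching is available
  behind `cross_sentence = TRUE` with a score cap of 90, so cross-sentence
  hits can never outrank an in-sentence hit at the reference threshold.
* **Order / redundancy**: implemented as tie-breakers and deduplication,
  not score terms — candidates sort by (score, CYP position, ethnicity
  position) and `deduplicate()` collapses per
  (document, CYP, ethnicity, frequency value) keeping the best score.
* **Frequency parsing**: only numeric `%`/"percent" forms. The mined
  statements of interest are numeric frequency reports; spelled-out
  numbers are deliberately rejected rather than half-supported.
* **Output**: validated records export to TSV (not a SQL dump) because it
  is toolchain-neutral and round-trips losslessly with the bundled
  reader.

The validation workflow models the curation states only: `UNREVIEWED` →
`TRUE` | `FALSE` | `NOT_SURE`, and `NOT_SURE` → `TRUE` | `FALSE` (the
second reviewer). No GUI is provided.

## 2. Star-allele catalog

The packaged catalog transcribes a published 34-allele curation for
Caucasians verbatim, including a genotype-breakdown frequency cell for
CYP2C9\*2 ("19.0% \*1/\*2 1.6% \*2/\*2 1.8 % \*2/\*3"). The loader takes
the **first** percentage of such cells — the heterozygous carrier class —
as the scalar frequency and keeps the verbatim cell in a `_raw` column,
so summaries stay computable while the source ambiguity is preserved.
Activity strings map to a seven-member class set that deliberately keeps
expression/transcription-level effects (`DECREASE_EXPRESSION`,
`INCREASE_TRANSCRIPTION`, `HIGHER_INDUCIBILITY`) distinct from
enzyme-level `INCREASE`/`DECREASE`/`NO_ENZYME`/`NONFUNCTIONAL`: collapsing
them would be lossy and they are pharmacologically different mechanisms.

Where the curation's narrative and its table disagree (four known cells,
plus one allele counted in the text but not printed), the **table** wins
and the conflict is recorded in `inst/extdata/ERRATA.md` rather than
silently corrected.

`filter_polymorphic()` implements the ≥ 1% definition of a
pharmacogenetic polymorphism; the packaged catalog is already filtered at
1%, so the default threshold retains all 34 records — the filter matters
for user-supplied extended tables and for stricter cutoffs.

## 3. Cohort allele frequencies

`allele_frequencies()` uses standard AC/AN semantics: the denominator is
twice the number of *called* samples, missing genotypes (`./.`) are
excluded, phasing is ignored, and multi-allelic sites are split into one
record per alternate allele. The upstream survey did not state its
missing-data handling; AC/AN is the field convention and is what VCF
headers themselves report.

Consequence classes, amino-acid changes and damaging calls are **consumed
annotations** (a pipe-delimited INFO key, default `CSQ_CLASS`), never
computed — the original analysis likewise consumed effect predictions
rather than running them. cDNA strings such as `435G>T` are stored
verbatim and never arithmetically interpreted.

Star-allele calling (`call_star_alleles()`) is cohort-level
presence/absence: an allele is `PRESENT` when all of its defining
variants survive the non-synonymous ≥ 1% filter, `PARTIAL` when some do.
Per-sample diplotyping and phasing are explicit non-goals — the survey
reports population frequencies, not individual metabolizer phenotypes.
`flag_novel()` matches variants to definitions by positional key
(`pos:ref:alt`) when available, falling back to rsID; the packaged SNP
table carries rsIDs only, so rsID matching is what its tests exercise.

## 4. Expression body map

Probe sets are averaged per gene on the provided intensity scale (no log
transform by default — the upstream matrix normalization is unknown, and
fold-change calls are scale-dependent by design). Relative expression is
the z-score of a gene across tissues, mean and standard deviation
(denominator n − 1) taken over a configurable **baseline** tissue set:
all tissues by default, with `exclude = "liver"` available because the
dominant liver signal was treated separately in the original analysis.
Zero-variance genes get an all-zero z row and a degenerate flag instead
of NaNs.

`body_map_calls()` compares each (gene, tissue) intensity against the
mean of the *other* tissues: `UP` at fold ≥ k, `DOWN` at fold ≤ 1/k.
The default k = 2 follows the stated analysis criterion; k = 3 matches
the stricter highlighting used in the published figure — the sources
state both, so both are first-class values of one parameter rather than
two modes. Cells whose other-tissue mean is zero are suppressed with a
warning rather than emitting infinite folds.

## 5. Synthetic data and what a green test establishes

All generators take an integer seed, restore the caller's RNG state, and
are byte-identical across reruns. Each returns a ground-truth ledger
sufficient to score the downstream stage without inspecting generator
internals.

* **Abstracts**: planted documents embed exactly one tuple at requested
  token distances (defaults d_ce = 7, d_fc = 6 — the rule thresholds)
  inside filler text drawn from a fixed vocabulary disjoint from the
  lexicon, so distances are exact. Decoy documents carry a full triple at
  distances 6 tokens beyond each threshold (score 0 under default decay),
  and background documents mention a CYP only. The generator emulates
  co-occurrence geometry, **not** linguistic realism: recovery tests
  certify the window/scoring logic, not NER performance on real prose.
* **Genotypes**: per-sample alleles are two independent Bernoulli(f)
  draws — Hardy–Weinberg equilibrium with no population structure or
  linkage disequilibrium. Frequency-recovery tests use the exact binomial
  3-sigma band 3·√(f(1−f)/2n)·100 percentage points; cohort sizes 100 and
  1,000 bracket desk-scale versions of the 1,092-genome cohort.
* **Expression**: background intensities are log-normal around 100 with
  log-scale standard deviation 0.25 — a typical microarray
  replicate-level coefficient of variation (~25%); planted
  (gene, tissue, fold) cells multiply every probe of that gene. The
  default shape (84 probes, 40 CYP isoforms, 65 tissues, liver first)
  mirrors the original array design. At 6-fold plants and threshold 2 the
  expected recall is ≈ 1 and the per-cell false-call probability ≈ 0.4%,
  so the acceptance bands (recall ≥ 0.95, false-call rate ≤ 0.05 over
  non-planted cells) test correctness, not luck. Inter-tissue correlation
  and probe-affinity effects are not modeled.

These parameter values are modeling commitments stated once here; tests
consume them as given.

## 6. Numerical and degenerate-input conventions

* Scores clamp to [0, 100]; distances must be non-negative integers.
* Frequencies are percentages on 0-100 everywhere except generator
  `true_freq` (a probability in [0, 1], matching the binomial sampler).
* Frequency mentions outside [0, 100] are discarded with a warning, not
  errors — real abstracts contain "150% increase" phrasings.
* Ranking tie-breaks are lexicographic ((cyp, allele) in catalog
  rankings, rsID for per-gene maxima, key name in `coverage_stats()`),
  making every summary deterministic.
* Empty inputs: empty abstracts yield no mentions; an empty catalog
  cannot be summarized (error); all-zero count tables are an error; an
  all-missing VCF site is excluded with a warning.

## 7. Known limitations

* The relation extractor is dictionary + pattern based; it will miss
  entity surface forms absent from the lexicon and does not resolve
  anaphora ("this enzyme"). Scores other than the 100-point operating
  rule are a package convention, not a published calibration.
* Counts derived from external databases (per-CYP SNP totals, drug
  metabolism shares, the 199-SNP cohort-wide total) are **not**
  reproducible from the packaged fixtures; `coverage_stats()` is provided
  as a generic summarizer for user-supplied count tables instead.
* The packaged SNP table reproduces its source verbatim, including
  duplicate rsID rows; downstream counts treat rows, not unique rsIDs,
  as the unit.
* Star-allele presence calling ignores haplotype phase; an allele defined
  by two variants can be called `PRESENT` even if the variants never
  co-occur on one haplotype in any individual.
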