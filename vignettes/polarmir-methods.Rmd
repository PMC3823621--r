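---
title: "Integrated miRNA-mRNA correlation screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA-mRNA correlation screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarmir)
```

## The analysis problem

Microglia, the resident myeloid cells of the brain, shift between a
resting state (M0), a pro-inflammatory "classically activated" state
induced by LPS (M1) and an "alternatively activated" state induced by
IL-4 (M2a). MicroRNAs post-transcriptionally repress target mRNAs, and a
miRNA whose expression tracks a polarization state is a candidate
regulator of that state's transcriptional program. Given paired miRNA
and mRNA expression matrices from the same samples, polarmir screens for
candidate miRNA:mRNA regulatory pairs by combining three independent
lines of evidence: differential expression of the gene, strong
expression correlation between gene and miRNA, and prediction of the
pair by two independent target databases.

## The screening procedure

For a contrast of a treated condition against the resting control, the
stages are:

1. **Differential expression.** For each feature, a two-sided two-sample
   Student *t*-test (pooled variance) on the log2 expression values of
   the two groups. The log2 fold change is the difference of group means;
   the signed linear fold is $\pm 2^{|\Delta|}$ with the sign of
   $\Delta$. Benjamini–Hochberg q-values are computed across all tested
   features. Default significance thresholds: $p < 10^{-4}$ for genes,
   $p < 0.05$ for miRNAs, both strict inequalities and both
   configurable.
2. **miRNA shortlist.** Only abundant, differentially expressed miRNAs
   are screened: a miRNA is kept when it is significant and its mean
   linear expression, $\mathrm{mean}(2^{x})$ over all samples, strictly
   exceeds 50% of the mean of a user-named reference miRNA (the highest
   expressor on the platform). The comparison is made on the linear
   scale because "expression level" fractions are naturally linear-scale
   quantities; the choice is exposed through `min_fraction`.
3. **Correlation screen.** Each shortlisted miRNA is Pearson-correlated
   with every gene across the pooled samples of the contrast's two
   conditions (n = 6 in the default 3-replicate design). The screen is
   contrast-specific, so only the contrast's samples enter; correlating
   across the full design is available by passing all conditions.
   Candidates must satisfy $|r| > 0.5$ (strict) *and* the gene-level DE
   threshold.
4. **Triple intersection.** Candidates are intersected with the miRNA's
   predicted target sets from two databases (GMT format). Only genes
   present in *both* predictions survive — a gene predicted by a single
   database appears in the overlap statistics but never in the
   interactome.
5. **Direction classification.** Each surviving pair is classified
   `inversely_correlated` (r < 0; the canonical repression signature)
   or `positively_correlated` (r ≥ 0; compensatory or indirect
   regulation). Interactome rows are ordered positively correlated
   class first, then by descending $|\log_2 \mathrm{FC}|$, ties broken
   alphabetically by gene symbol.
6. **Enrichment.** The interactome genes of each miRNA are tested for
   over-representation in user-supplied annotation sets with a
   right-tailed hypergeometric test,
   $P(X \ge k) = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
   against the universe of all measured genes (only measured genes can
   enter a query, so the whole genome would be the wrong reference).
   Per-miRNA tables are pooled, ranked by $-\log_{10} p$, and annotated
   with the significance line $-\log_{10}(0.05) = 1.30$. Duplicate set
   names from different miRNAs stay as separate rows so each ranked
   entry keeps its originating miRNA. The test is a transparent,
   self-contained replacement for proprietary knowledge-base enrichment
   scores: the workflow shape and the 1.30 threshold convention carry
   over, absolute p-values from curated commercial databases do not.

### Assumptions

* Input matrices are already normalized, on log2 scale, with finite
  values; probe-to-gene collapsing happened upstream.
* Groups have approximately equal variance (pooled *t*); a Welch option
  (`var_equal = FALSE`) is available when that is doubtful.
* n = 3 per group is small: the correlation screen at $|r| > 0.5$ with
  6 samples retains roughly 31% of null genes (the Pearson null tail at
  df = 4), which is why the DE filter and the double database
  intersection are required before a pair is reported.

### Identifier conventions

Gene symbols are matched case-insensitively via a canonical upper-case
form, because array annotations and prediction databases disagree on
casing. miRNA ids are canonicalized by dropping the species prefix
(`mmu-miR-155` ≡ `miR-155`) and normalizing the `miR` stem casing;
star-form ids (`miR-191*`) stay distinct from their mates because
arrays report them separately.

## The synthetic data generator

`simulate_microglia()` emulates the study design every stage is tested
against: 3 conditions × 3 replicates, with planted truth recorded for
scoring.

* **Noise model.** Additive Gaussian on log2 scale (log-normal linear
  scale), default sd 0.2 log2 units. No error model is implied by array
  summaries themselves; 0.2 is chosen so that n = 3 *t*-tests at
  $p < 10^{-4}$ are attainable for large planted folds — the regime the
  screen is designed for.
* **Planted condition effects.** Defaults mirror the magnitudes such
  experiments report: a 425-fold M1 gene (`IL6LIKE`), a 38.85-fold M2a
  gene (`CHI3L3LIKE`), a 9.69-fold M1 miRNA (`miR-155like`) and a
  2.66-fold M2a miRNA (`miR-145like`). Planted marker features carry
  pure condition effects and never receive incoming edges, so the
  planted fold is exactly the expected recovered fold.
* **Regulatory edges.** Each planted miRNA represses 6 and activates 3
  filler genes (slopes ∓1.5 on log2 scale). A target gene receives
  `beta` times the regulating miRNA's *condition-level* deviation from
  its baseline, plus independent noise. Coupling to the condition-level
  (expected) deviation rather than the per-sample realized value is a
  deliberate modelling choice: propagating the miRNA's own sampling
  noise into the gene caps the gene's attainable *t*-statistic at
  $\mathrm{dev}/(\sigma\sqrt{2/3})$ regardless of $|\beta|$, which
  would make the modest M2a program (deviation 1.41 log2) permanently
  invisible to the $p < 10^{-4}$ gene filter. Under condition-level
  coupling the planted correlations still arise through the shared
  condition structure, and both planted programs are recoverable.
* **Databases and annotations.** Each true edge enters each prediction
  database independently with probability `db_sensitivity` (default
  0.9), plus `db_noise` (default 5) decoy predictions per regulator.
  The annotation collection holds one "network" set per regulator (its
  true targets) plus decoy sets size-matched to the true sets, so
  enrichment calibration is honest: a method that ranks decoys as well
  as true networks gains nothing from set-size artifacts.
* **Reference miRNA.** `miR-709like` is planted at the top of the
  baseline range (log2 = 14) with no condition effect; planted miRNAs
  sit just below it so the 50% shortlist rule keeps them, and filler
  miRNAs sit low enough to be excluded.

**What the generator does not emulate:** probe-level array physics,
batch and normalization artifacts, correlated gene-gene backgrounds,
heavy-tailed noise, and the tens of thousands of features of a real
array. Passing tests therefore demonstrate correctness of the screening
arithmetic and a calibrated recovery of planted structure under an
idealized noise model — not performance on raw array data.

## Numerical choices

* Zero-variance features never produce NaNs: a flat feature gets
  *t* = 0, p = 1; a feature with zero within-group variance but
  different means degenerates to p = 0 (the zero-noise limit). A gene
  with a constant profile gets r = 0 with a `degenerate` flag, so it is
  excluded by the strict correlation threshold instead of propagating
  an undefined correlation.
* All screen thresholds are strict inequalities (`>` for |r| and the
  expression fraction, `<` for p), so boundary values — a gene at
  r = 0.5 exactly, a miRNA at exactly 50% of the reference — are
  excluded.
* A significant feature with log2 fold change exactly 0 is counted
  neither up nor down, keeping the two-class partition of significant
  features exact.
* Interactome sorting breaks fold-change ties alphabetically by gene
  symbol. The packaged reference interactome
  (`table2_mir155.tsv`) contains one order inversion in its
  down-regulated class that traces to printed rounding
  (−0.9855 listed before −0.986); the sorter follows the stated rule
  rather than reproducing that artifact, and the tests assert the rule.
* BH adjustment is delegated to `stats::p.adjust(method = "BH")` and the
  hypergeometric tail to `stats::phyper`; the test suite checks both
  against independent brute-force implementations (explicit step-up on
  vectors up to length 20; exhaustive enumeration of all draws for
  universes up to 12).
* The q < 10⁻⁷ "heatmap" gene selection uses BH q-values; the threshold
  is configurable (`heatmap_q`).
* The `power` column of an interactome is the gene's differential-
  expression p-value. An alternative reading — the correlation's own
  significance — would be computable from r and n; the DE reading is
  used because every packaged reference row satisfies the DE filter,
  and the choice is documented here so it can be revisited.
* Correlations are computed on log2 expression. At the sample sizes
  involved the Pearson r of log2 values is the better-behaved choice
  (linear-scale values span orders of magnitude and a single
  high-expression sample would dominate).

## Problem sizes used by the tests

The unit suite runs on toy fixtures (≤ 50 features). Calibration and
recovery checks use generated datasets of 60–300 genes and 12–60
miRNAs; the planted-fold recovery check averages 200 independent
datasets of 60 genes × 12 miRNAs at noise sd 0.2, n = 3 per group —
enough that the Monte-Carlo standard error of each mean recovered fold
is well inside the 10% acceptance band. The same computation, from
scratch, is what `scripts/acceptance.R` reports.

## Known limitations

* No empirical-Bayes variance moderation (limma-style) — with n = 3 the
  per-feature pooled *t* is noisy; the package reproduces the classical
  screen rather than improving on it.
* Seed-based target prediction is out of scope: databases are inputs.
* Enrichment is over-representation only; no activation z-scores or
  causal network directionality.
* Paired designs and >2-group omnibus tests are not implemented; every
  contrast is a two-group comparison against the resting control.
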