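---
title: "Methods: splice-aware variant deleteriousness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-aware variant deleteriousness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caddsplice)
```

# The model

The scoring model is a logistic regression of a proxy label — derived
human alleles as proxy-benign (0) versus matched simulated variants as
proxy-deleterious (1) — on a fixed 1029-column feature expansion of each
variant:

* 222 annotation features: 90 numeric annotations plus one-hot encodings
  of 12 categorical annotations;
* 12 ordered base-substitution indicators (SNVs only);
* 189 amino-acid-exchange indicators;
* 14 missingness indicators, one per annotation group;
* 592 interaction features: the 16 consequence-category indicators
  crossed with a 37-member annotation set *D* that includes the four
  SpliceAI and five MMSplice features, so the model can learn
  consequence-specific splice coefficients.

The proxy-label design assumes deleterious variation is depleted among
alleles that survived recent human evolution, so a classifier separating
derived from simulated alleles ranks deleteriousness without ever seeing
curated pathogenic labels. The raw score is the fitted log-odds; ranking,
not calibration, is the target quantity.

## Schema conventions

The published feature totals fix the counts (222 annotation features, 16
consequence categories, |D| = 37, 14 indicators, 1029 in total) but not
every name, so the default schema adopts conventions where needed:

* The 16 consequence-category names follow the conventional coarse
  classes (stop-gained through intergenic). The count is forced by the
  592 = 16 × 37 identity; the names are presentation-level and
  configurable.
* The 12 categorical annotations and their level cardinalities are chosen
  so the one-hot block contributes exactly 132 columns (222 − 90).
  Annotations outside the splice block are opaque numeric or categorical
  columns here; their biological provenance is out of scope.
* Missing values are an explicit `NA` sentinel, distinct from 0, because
  the model's missingness treatment is imputation-to-zero *plus* an
  indicator, applied at encoding time.
* Coordinates are 1-based and VCF-style; alleles on the forward strand;
  InDels longer than 50 bp are rejected.

## The amino-acid-exchange enumeration

The 189 exchanges are generated by brute force: translate all 64 codons
and each of their nine single-base mutants, and collect ordered residue
pairs over the 21-symbol alphabet (20 residues + stop). Same-residue
pairs reachable through a synonymous codon change are included; there are
exactly 19 (every residue except single-codon Met and Trp, plus
stop-to-stop), and with them the enumeration reproduces the canonical
count of 189 — excluding them gives 170. Reachability by a single base
change is symmetric, which the test suite checks.

# Splice-score preprocessing

Four rules prepare the deep-learning splice scores:

* **Masking.** A predicted splice *gain* at an already-annotated site and
  a predicted *loss* where no site exists carry no class signal, so they
  are zeroed — independently for donor and acceptor. A site is
  "annotated" on an exact position-and-gene match against the supplied
  splice-site table.
* **Derived-allele swap.** Proxy-benign variants are scored with
  reference and alternative reversed (the model's reference must match
  the genome), so gain and loss are swapped within donor and within
  acceptor, and masking is applied *after* the swap.
* **MMSplice delta.** The reference score is subtracted from the
  alternative score (reversed for proxy-benign) and positive differences
  are clipped to 0, keeping only disruption-consistent signal.
* **Imputation.** Variants without splice annotation are imputed to 0,
  and the SpliceAI missingness indicator records the absence.

The clipped MMSplice features are kept non-positive exactly as stated by
the source rule, not negated: the regression absorbs the sign, fitting
negative coefficients so that stronger (more negative) deltas raise the
score. Whether the upstream implementation negated the stored feature
before fitting is not documented; the literal convention is used here and
the generator's truth weights follow it.

Splice blocks attach to a variant only when the score row's gene matches
the variant's gene (scores are restricted to the consequence's gene);
unmatched blocks are dropped before imputation.

## Splice-disruption calls from psi

A variant is splice-disrupting (sdv) when the percent-spliced-in of the
tested exon changes by more than 0.5 — strict inequality, absolute
change. Alternative thresholds (0.7, 0.3, 0.1) and the two-sided variant
(sdv: Δpsi > 0.5; no-sdv: Δpsi < 0.1; intermediates excluded) are
supported. Δpsi is treated as unsigned; the source data's published split
is the ground truth wherever that data set is used.

# Fitting

`fit_cadd()` fits an L2-penalized logistic regression (glmnet, alpha = 0)
with the penalty chosen by held-out grid search: a seed-controlled random
split (20% holdout by default), log-loss on the holdout across a
decreasing lambda grid (default `10^seq(0, -4)`), then a refit on all
rows at the selected lambda. Choices that matter:

* **Scaling.** Continuous columns (numeric annotations and interaction
  values) are divided by their training standard deviation; indicator
  columns enter raw. Columns are *not* centered: centering would
  destroy the sparsity of the interaction block, and with an unpenalized
  intercept it changes the ridge solution only marginally. The scaling
  vector is stored in the model artifact and reported coefficients are
  mapped back to the original feature scale, so scoring applies no
  further transform.
* **Convergence.** Optimizer tolerance defaults to `1e-7` with a 1e5
  iteration cap; failure to converge is an error, never a silent
  warning. Refits under an identical seed reproduce the model to within
  optimizer tolerance.
* **Class weighting.** None: the proxy classes are constructed matched,
  and the generator produces balanced labels by centering the generating
  linear predictor.

## Identifiability of the coefficients

The feature expansion contains exact linear dependencies by construction:
every *D*-member column equals the sum of its 16 consequence-cross
columns, and each complete one-hot group sums to a constant. Coefficients
inside such a set are identified only up to redistribution — the ridge
penalty resolves the split by shrinking toward the minimum-norm
representative, which spreads a generating weight across the set. This is
a property of the model family, not a defect of the fit; predictions are
unaffected. Consequently:

* the end-to-end regression test (generating weights on splice features
  and consequence indicators, `default_true_weights()`) checks the
  recovered *sign pattern* and the ranking performance, which are
  invariant under the redistribution;
* the quantitative parameter-recovery check (Pearson > 0.9 between
  estimated and generating coefficients at n = 50,000) places its truth
  on identifiable columns only — numeric annotations outside *D*
  (`recovery_true_weights()`). On those columns ridge shrinkage is
  essentially uniform after scaling, which leaves the correlation intact.

# Ranking statistics

* **PHRED-like scaling.** A raw score's rank against a reference
  distribution (descending; ties share the worst rank) maps to
  `-10 log10(rank / N)`: the top score of 100 gives 20, the median about
  3.01, an all-tied reference 0. The reference distribution is an
  explicit argument — no genome-wide reference set is bundled.
* **PR / ROC.** Curves are computed at every distinct threshold. The PR
  area is trapezoidal over recall, anchored at recall 0 with the first
  precision; the ROC area is the Mann–Whitney statistic with ties
  counted one half, so it is invariant under monotone transforms. Tests
  cross-check against a brute-force pairwise oracle and an independent
  ROC implementation.
* **Cross-predictor comparisons** either drop variants lacking any
  compared score or impute missing scores as benign (0); both policies
  are provided because they can change conclusions materially.
* **Frequency-bin enrichment.** Variants are binned as singleton
  (AC = 1), frequent (MAF > 0.001) or rare (the rest); a MAF of exactly
  0.001 is unassigned by the strict rule and goes to frequent so the
  bins partition deterministically. At a given percentile of the
  category's score distribution (linear-interpolation percentile), each
  bin's observed count strictly above the threshold is divided by its
  expected count under random drawing. Uncertainty is a percentile
  bootstrap over variants (default 1000 iterations, seed-controlled),
  re-deriving the threshold inside each resample; the 2.5/97.5
  percentiles form the interval. Bin-size-weighted ratios average to 1
  at any threshold (conservation of counts), which is a test invariant.

# The synthetic-data generator

The generator emulates the pipeline's inputs with known structure; it is
the package's test bed, not a biological simulator.

* **Training sets.** Annotations are Gaussian (logit-normal for bounded,
  probability-like columns), categoricals uniform, missingness
  missing-completely-at-random per indicator group. Splice features are
  laid out so every preprocessing rule is load-bearing: junk values are
  planted exactly where masking will zero them, proxy-benign blocks are
  stored swapped and allele-reversed, and positive MMSplice differences
  are planted where the clip rule must remove them. Labels are Bernoulli
  draws of the logistic model at known sparse weights, with the
  intercept auto-centered for class balance. Re-running the
  preprocessing on the raw tables reproduces the generating features
  exactly — the package's core round-trip test.
* **Reporter assay.** A latent disruption effect shifts the exon's psi
  on the logit scale (logit-normal psi, so values respect [0, 1] by
  construction) and, noisily, the splice submodel scores. The default
  disruption fraction (0.0493) solves
  `p0 · P(Δpsi > 0.5 | disrupted) = 1050 / 27733` under the generator's
  effect and noise distributions — matching the reference assay's sdv
  prevalence analytically rather than by trial.
* **Allele frequencies.** Allele counts follow a discrete Pareto tail
  capped at the sample size, giving a realistic singleton-heavy site
  frequency spectrum; optional coupling raises a variant's tail index
  with its standardized score, thinning the tail for deleterious
  variants. Zero coupling decouples score from frequency, the null used
  for calibration tests.

All generator randomness derives from a single integer seed with fixed
sub-stream offsets, so every output is bit-reproducible.

What the generator does *not* emulate: real annotation provenance and
inter-annotation correlation, sequence context, mutation-rate-aware
variant placement, ascertainment of assayed exons, and informative
missingness. Passing tests therefore demonstrate that the machinery
implements its rules and recovers known structure — not that the model
attains any particular performance on real data.

# Problem sizes and numerical tolerances

The test suite and acceptance script run at sizes where the checked
asymptotics have stabilized while keeping runtimes in minutes: parameter
recovery at n = 50,000; null auPRC at n = 10,000 over 100 replicates;
null enrichment at n = 20,000 per replicate over 100 replicates with 200
bootstrap iterations (the percentile bootstrap visibly under-covers for
bins with fewer than ~20 variants above threshold, a known small-count
property, so the coverage check uses a size where each bin is
comfortably populated); the simulated reporter assay at the reference
assay's full n = 27,733. The assay-scale sdv count is checked against
its calibrated expectation within binomial sampling tolerance.

# Known limitations

* Annotation columns other than the splice features are opaque; the
  schema reproduces the published feature-space structure, not the
  annotations' sources.
* The PHRED-scaling reference distribution is caller-supplied; no
  genome-wide precomputed reference ships with the package.
* Per-gene consequence matching uses exact position-and-gene joins;
  transcript-model edge cases (overlapping genes, strand-ambiguous
  sites) are not modeled.
* Benchmarks against the real reporter-assay, clinical-variant and
  population data sets require those external downloads and the real
  trained annotations; the package reproduces the statistics and rules,
  and its synthetic fixtures emulate the structure of those inputs.
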