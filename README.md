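# caddsplice

Genome-wide variant deleteriousness scoring with deep-learning-derived
splice features, in the style of CADD v1.6 (CADD-Splice).

## The problem

General-purpose variant effect predictors rank variants across all effect
classes — missense, nonsense, regulatory, splicing — but historically
under-perform on splice-altering variants, which specialized deep neural
networks (SpliceAI, MMSplice) predict far better from sequence alone. The
approach implemented here integrates those process-specific splice scores
as *features* of a genome-wide logistic model trained on proxy labels:
evolutionarily derived human alleles (proxy-benign) versus matched
simulated variants (proxy-deleterious). The package is aimed at method
developers and analysts who want the full scoring pipeline — splice-score
preprocessing, feature expansion, model fitting, PHRED-like scaling and
the associated benchmark statistics — exercisable end to end on synthetic
fixtures with known generating structure.

## The model

Each variant is expanded into 1029 features in five groups, and the score
is the linear predictor of an L2-regularized logistic regression:

```
eta = b0 + sum_i beta_i X_i                        (222 annotation features)
         + sum_{i != j} gamma_ij 1{ref=i, alt=j}   (12 base substitutions)
         + sum_i delta_i 1{aa exchange i}          (189 SNV-reachable exchanges)
         + sum_i tau_i W_i                         (14 missingness indicators)
         + sum_{c, d in D} alpha_cd 1{consequence=c} X_d   (16 x 37 = 592 crosses)
```

The 222 annotation features comprise 90 numeric annotations and one-hot
encodings of 12 categorical annotations. `D` is a fixed 37-member set of
annotations (conservation, position, mutation-density and the nine splice
features) crossed with the 16 consequence categories. The 189 amino-acid
exchanges are every ordered residue pair (21-symbol alphabet, stop
included) reachable by mutating one base of some codon — including the 19
same-residue pairs reachable through a synonymous change.

Splice submodel scores are preprocessed before entering the model:
SpliceAI gains are zeroed at annotated splice sites and losses zeroed
elsewhere ("masking"); proxy-benign variants, scored with alleles
reversed, have gain/loss swapped before masking; MMSplice alternative
minus reference differences (orientation reversed for proxy-benign) are
clipped at 0; unannotated variants are imputed to 0 with a missingness
indicator. Raw scores are converted to PHRED-like scaled scores,
`-10 * log10(rank / N)` against a reference score distribution.

## Worked example

```r
library(caddsplice)

cfg  <- sim_config(n_variants = 3000, seed = 42)
sim  <- simulate_training_set(cfg)

# raw inputs -> preprocessed splice features -> design matrix -> model
prepped <- prep_splice_features(sim$av_raw, sim$splice_scores, sim$splice_sites)
design  <- build_design_matrix(prepped, default_schema())
design
#> <cadd_design> 3000 variants x 1029 features
#>            X   base_pairs  aa_exchange            W interactions
#>          222           12          189           14          592

model  <- fit_cadd(design, sim$labels, seed = 1)
scored <- score_variants(model, prepped)
head(scored[c("chrom", "pos", "ref", "alt", "raw_score", "scaled_score")], 3)
#>   chrom      pos ref alt raw_score scaled_score
#> 1 chr20 84837605   G   A  -0.72060        1.995
#> 2 chr11 89285016   T   G  -0.10154        3.316
#> 3 chr20 66833684   G   C  -0.00595        3.569

roc_curve(scored$raw_score, sim$labels)$auroc
#> 0.909
round(model_weights(model)$beta[c("SpliceAI_donloss", "SpliceAI_accloss")], 3)
#> SpliceAI_donloss SpliceAI_accloss
#>            0.640            0.739
```

The raw score is the fitted log-odds of the proxy-deleterious class;
the scaled score is its PHRED-like percentile transform (here against the
scored set itself), so 3.3 means roughly the top 47% of the reference
distribution. The splice-loss coefficients come out positive: stronger
predicted splice disruption raises the deleteriousness score.

The reporter-assay generator drives splice scores and psi changes from a
shared latent disruption effect:

```r
mf <- simulate_mfass_like(cfg)
mean(mf$sdv)                                  # sdv prevalence
#> 0.036
pr_curve(mf$SpliceAI_max, mf$sdv)$auprc       # splice score vs sdv label
#> 0.76
```

A subcommand CLI over the same functions ships in `inst/cli/caddsplice`
(`simulate`, `prep-splice`, `build-matrix`, `train`, `score`,
`evaluate`).

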