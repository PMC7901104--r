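#' Synthetic data with known generating structure
#'
#' The generator emulates the inputs of the scoring pipeline so that every
#' stage is testable without external downloads: annotated variants drawn
#' under a known sparse weight vector (labels are Bernoulli draws of the
#' logistic model, so fitting can be checked against the truth), raw splice
#' submodel blocks laid out with class-dependent orientation so that the
#' masking/swap/delta rules are exercised end to end, reporter-assay style
#' psi pairs driven by a latent disruption effect, and heavy-tailed allele
#' frequencies with optional negative score-frequency coupling.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param n_variants Number of variants (>= 2).
#' @param seed Integer seed; all generator randomness derives from it.
#' @param schema Feature schema used for annotation layout.
#' @param true_weights Named numeric vector of generating weights over
#'   design-matrix columns (sparse; unnamed columns have weight 0).
#' @param intercept Generating intercept; `"auto"` (default) centers the
#'   linear predictor at zero so the two proxy classes come out balanced.
#' @param splice_effect_fraction Share of variants whose class signal flows
#'   through the splice features.
#' @param missing_rate Missing-completely-at-random rate applied per
#'   missingness-indicator group.
#' @param splice_missing_rate Fraction of variants with no splice
#'   annotation at all (imputed to zero downstream, with indicator set).
#' @param psi_noise_sd Logit-scale measurement noise of the psi assay.
#' @param sdv_threshold Delta-psi threshold used for the sdv call.
#' @param disruption_fraction Fraction of reporter-assay variants carrying
#'   a large latent disruption effect. The default solves
#'   `p0 * P(delta_psi > 0.5 | disrupted) = 1050/27733` for the generator's
#'   effect and noise distributions, matching the sdv prevalence of the
#'   reference reporter assay.
#' @param af_sample_size Number of diploid individuals behind the allele
#'   counts.
#' @param af_alpha Pareto tail index of the allele-count distribution.
#' @param af_coupling Strength of the negative coupling between
#'   deleteriousness score and allele frequency (0 = none).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 1000, seed = 1,
                       schema = default_schema(),
                       true_weights = default_true_weights(),
                       intercept = "auto",
                       splice_effect_fraction = 0.3,
                       missing_rate = 0.05,
                       splice_missing_rate = 0.2,
                       psi_noise_sd = 0.25,
                       sdv_threshold = 0.5,
                       disruption_fraction = 0.0493,
                       af_sample_size = 15708,
                       af_alpha = 1.0,
                       af_coupling = 0) {
  stopifnot(n_variants >= 2, length(seed) == 1, is.finite(seed))
  probs <- c(splice_effect_fraction, missing_rate, splice_missing_rate,
             disruption_fraction)
  if (any(probs < 0 | probs > 1)) stop("fractions must lie in [0, 1]")
  if (psi_noise_sd < 0) stop("psi_noise_sd must be non-negative")
  structure(list(
    n_variants = as.integer(n_variants), seed = as.integer(seed),
    schema = schema, true_weights = true_weights, intercept = intercept,
    splice_effect_fraction = splice_effect_fraction,
    missing_rate = missing_rate, splice_missing_rate = splice_missing_rate,
    psi_noise_sd = psi_noise_sd, sdv_threshold = sdv_threshold,
    disruption_fraction = disruption_fraction,
    af_sample_size = as.integer(af_sample_size),
    af_alpha = af_alpha, af_coupling = af_coupling),
    class = "sim_config")
}

#' Default sparse generating weights
#'
#' Nonzero weights on conservation-style annotations, the preprocessed
#' splice features, one base substitution, two consequence one-hots, the
#' SpliceAI missingness indicator and two consequence crosses. MMSplice
#' features are non-positive by construction, so their negative weights
#' make stronger (more negative) deltas more deleterious.
#'
#' @return Named numeric vector over design-matrix column names.
#' @export
default_true_weights <- function() {
  c(GerpN = 0.8, verPhyloP = 0.7, priPhCons = 0.6, bStatistic = -0.5,
    SIFTval = -0.6,
    SpliceAI_accloss = 2.0, SpliceAI_donloss = 2.0,
    SpliceAI_accgain = 1.5, SpliceAI_dongain = 1.5,
    MMSplice_exon = -1.2, MMSplice_donor = -1.0, MMSplice_acceptor = -1.0,
    "base:C>T" = 0.3,
    "Consequence=STOP_GAINED" = 2.0,
    "Consequence=CANONICAL_SPLICE" = 1.2,
    "ind:SpliceAI" = -0.3,
    "int:INTRONIC:verPhyloP" = 0.4,
    "int:CANONICAL_SPLICE:SpliceAI_donloss" = 0.8)
}

#' Generating weights restricted to identifiable columns
#'
#' The model's design matrix carries exact linear dependencies by
#' construction: each interaction-set annotation equals the sum of its 16
#' consequence-cross columns, and complete one-hot groups sum to a
#' constant. Coefficients inside such a set are only identified up to
#' redistribution (regularization resolves the split), so per-coefficient
#' recovery checks place the generating weight on columns outside every
#' exact dependency: numeric annotations that are not interaction-set
#' members. [default_true_weights()] remains the default generator truth;
#' this set exists for parameter-recovery simulations.
#'
#' @return Named numeric vector over design-matrix column names.
#' @export
recovery_true_weights <- function() {
  c(GC = 0.8, CpG = -0.6, SIFTval = -0.9, Grantham = 0.5,
    PolyPhenVal = 0.7, mirSVR_Score = -0.4, EncH3K27Ac = 0.6,
    dnaHelT = -0.5, targetScan = 0.45, dbscSNV_ada = 1.0,
    dbscSNV_rf = -0.8, fitCons = 0.9, TFBS = 0.35, mutIndex = -0.7)
}

LOGIT_NORMAL_ANNOS <- c("mamPhCons", "priPhCons", "verPhCons", "fitCons",
                        "dbscSNV_ada", "dbscSNV_rf")

default_consequence_probs <- function() {
  c(STOP_GAINED = 0.010, STOP_LOST = 0.003, CANONICAL_SPLICE = 0.020,
    SPLICE_SITE = 0.040, NON_SYNONYMOUS = 0.120, SYNONYMOUS = 0.090,
    FRAME_SHIFT = 0.007, INFRAME = 0.010, `5PRIME_UTR` = 0.030,
    `3PRIME_UTR` = 0.060, INTRONIC = 0.220, UPSTREAM = 0.070,
    DOWNSTREAM = 0.070, REGULATORY = 0.060, NONCODING_CHANGE = 0.050,
    INTERGENIC = 0.140)
}

sample_aa_pairs <- function(consequence) {
  ex <- enumerate_aa_exchanges()
  parts <- strsplit(ex, ">", fixed = TRUE)
  ref <- vapply(parts, `[`, "", 1L)
  alt <- vapply(parts, `[`, "", 2L)
  pool <- list(
    NON_SYNONYMOUS = which(ref != alt & ref != "*" & alt != "*"),
    SYNONYMOUS = which(ref == alt & ref != "*"),
    STOP_GAINED = which(alt == "*" & ref != "*"),
    STOP_LOST = which(ref == "*" & alt != "*"))
  n <- length(consequence)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  for (cc in names(pool)) {
    rows <- which(consequence == cc)
    if (length(rows) > 0) {
      pick <- pool[[cc]][sample.int(length(pool[[cc]]), length(rows),
                                    replace = TRUE)]
      aa_ref[rows] <- ref[pick]
      aa_alt[rows] <- alt[pick]
    }
  }
  list(aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Simulate a proxy-labeled training set
#'
#' Generates annotated variants, raw splice blocks and splice-site
#' annotation, computes the linear predictor of the generating model on the
#' preprocessed features, draws labels `Bernoulli(plogis(eta))`, and then
#' lays out the raw splice inputs in the orientation each class would have
#' been scored in (proxy-benign variants carry swapped gain/loss and
#' reversed MMSplice ref/alt), so running [prep_splice_features()] on the
#' raw tables reproduces the generating features.
#'
#' @param config A [sim_config()].
#' @return List of class `cadd_sim`: `av` (annotated variants with
#'   preprocessed splice features and `class_label`), `av_raw` (without
#'   splice features), `splice_scores` and `splice_sites` (raw input
#'   tables), `design` (a `cadd_design`), `labels` (0/1), `eta`,
#'   `true_weights`, `intercept` and `config`.
#' @export
simulate_training_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schema <- config$schema
  n <- config$n_variants
  set.seed(config$seed)

  n_genes <- max(2L, ceiling(n / 25))
  n_exons <- 8L                          # donor/acceptor pairs per gene
  gene_id <- sprintf("gene%05d", sample.int(n_genes, n, replace = TRUE))
  gene_chrom <- sprintf("chr%d", sample.int(22, n_genes, replace = TRUE))
  gene_start <- sample.int(1e8, n_genes)
  # per-gene site tables: n_exons donors and acceptors along the gene
  donor_pos <- outer(gene_start, (seq_len(n_exons) - 1) * 6000 + 1000, `+`)
  acceptor_pos <- donor_pos + 2500
  gid <- as.integer(sub("gene", "", gene_id))

  probs <- default_consequence_probs()[schema$consequence_categories]
  probs[is.na(probs)] <- 0.01
  consequence <- sample(schema$consequence_categories, n, replace = TRUE,
                        prob = probs)

  # alleles: SNVs except the frameshift/in-frame classes, which get InDels
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  is_fs <- consequence == "FRAME_SHIFT"
  is_if <- consequence == "INFRAME"
  alt[is_fs] <- paste0(ref[is_fs], "A")
  alt[is_if] <- paste0(ref[is_if], "AAA")

  # positions: splice-affected variants sit at (or near) their gene's sites
  splicy <- stats::runif(n) < config$splice_effect_fraction
  at_site <- splicy & stats::runif(n) < 0.5
  site_is_donor <- stats::runif(n) < 0.5
  exon_of <- sample.int(n_exons, n, replace = TRUE)
  pos <- sample.int(1e8, n, replace = TRUE)
  site_pos <- ifelse(site_is_donor,
                     donor_pos[cbind(gid, exon_of)],
                     acceptor_pos[cbind(gid, exon_of)])
  pos[at_site] <- site_pos[at_site]
  pos[splicy & !at_site] <- site_pos[splicy & !at_site] +
    sample(3:40, sum(splicy & !at_site), replace = TRUE)

  av <- data.frame(chrom = gene_chrom[gid], pos = pos, ref = ref, alt = alt,
                   gene_id = gene_id, consequence = consequence,
                   stringsAsFactors = FALSE)

  # variant keys must be unique (annotation joins are keyed on them);
  # resample the alt allele of colliding SNVs until the keys separate
  for (pass in 1:8) {
    key <- paste(av$chrom, av$pos, av$ref, av$alt, sep = ":")
    dup <- which(duplicated(key) & nchar(av$ref) == 1 & nchar(av$alt) == 1)
    if (length(dup) == 0) break
    av$alt[dup] <- vapply(av$ref[dup],
                          function(b) sample(setdiff(bases, b), 1), "")
  }
  alt <- av$alt
  if (anyDuplicated(paste(av$chrom, av$pos, av$ref, av$alt, sep = ":"))) {
    stop("could not generate unique variant keys; reduce n_variants")
  }
  aa <- sample_aa_pairs(consequence)
  av$aa_ref <- aa$aa_ref
  av$aa_alt <- aa$aa_alt

  for (nm in schema$numeric_annotations) {
    if (nm %in% c(SPLICEAI_COLS, MMSPLICE_COLS)) next
    av[[nm]] <- if (nm %in% LOGIT_NORMAL_ANNOS) {
      stats::plogis(stats::rnorm(n, 0, 1.5))
    } else {
      stats::rnorm(n)
    }
  }
  for (nm in setdiff(names(schema$categorical_annotations), "Consequence")) {
    av[[nm]] <- sample(schema$categorical_annotations[[nm]], n,
                       replace = TRUE)
  }
  av$Consequence <- consequence
  av$Type <- ifelse(is_fs | is_if, ifelse(nchar(alt) > nchar(ref),
                                          "INS", "DEL"), "SNV")

  # MCAR missingness per indicator group (annotation columns only)
  for (grp in schema$indicator_groups) {
    cols <- intersect(grp, names(av))
    if (length(cols) == 0) next
    drop <- stats::runif(n) < config$missing_rate
    for (cl in cols) av[[cl]][drop] <- NA
  }

  # generating splice features, already in scoring (masked) orientation
  feat <- matrix(0, nrow = n, ncol = 9,
                 dimnames = list(NULL, c(SPLICEAI_COLS, MMSPLICE_COLS)))
  loss_col <- ifelse(site_is_donor, "SpliceAI_donloss", "SpliceAI_accloss")
  gain_col <- ifelse(site_is_donor, "SpliceAI_dongain", "SpliceAI_accgain")
  for (i in which(splicy)) {
    feat[i, if (at_site[i]) loss_col[i] else gain_col[i]] <-
      stats::runif(1, 0.4, 1)
    feat[i, "MMSplice_exon"] <- -abs(stats::rnorm(1, 0.8, 0.4))
    feat[i, if (site_is_donor[i]) "MMSplice_donor" else
      "MMSplice_acceptor"] <- -abs(stats::rnorm(1, 0.6, 0.3))
  }
  bg <- !splicy
  feat[bg, "MMSplice_exon"] <- -abs(stats::rnorm(sum(bg), 0, 0.05))

  splice_missing <- stats::runif(n) < config$splice_missing_rate
  feat[splice_missing, ] <- 0
  for (cl in colnames(feat)) av[[cl]] <- feat[, cl]
  av$SpliceAI_missing <- splice_missing

  design <- build_design_matrix(av, schema)
  w <- rep(0, length(design$columns))
  names(w) <- design$columns
  known <- intersect(names(config$true_weights), design$columns)
  if (length(known) < length(config$true_weights)) {
    stop("true_weights name(s) not design columns: ",
         paste(setdiff(names(config$true_weights), design$columns),
               collapse = ", "))
  }
  w[known] <- config$true_weights[known]
  xw <- as.numeric(design$matrix %*% w)
  intercept <- if (identical(config$intercept, "auto")) -mean(xw) else
    config$intercept
  eta <- intercept + xw
  labels <- stats::rbinom(n, 1, stats::plogis(eta))
  av$class_label <- ifelse(labels == 1, "proxy_deleterious", "proxy_benign")

  # raw splice blocks in as-scored orientation: the proxy-benign class is
  # scored with alleles reversed, so its gains/losses and ref/alt are
  # flipped relative to the generating features
  block <- empty_splice_block(n)
  benign <- labels == 0
  junk <- function(k) stats::runif(k, 0, 0.35)
  observed <- which(!splice_missing)
  for (i in observed) {
    pre <- feat[i, SPLICEAI_COLS]
    # entries the mask will zero are filled with junk signal; masking acts
    # per side, so only the affected side's gain (and the other entries'
    # losses) are junkable
    if (at_site[i] && site_is_donor[i]) {
      pre[c("SpliceAI_dongain", "SpliceAI_accloss")] <- junk(2)
    } else if (at_site[i]) {
      pre[c("SpliceAI_accgain", "SpliceAI_donloss")] <- junk(2)
    } else {
      pre[c("SpliceAI_accloss", "SpliceAI_donloss")] <- junk(2)
    }
    if (benign[i]) {
      pre <- pre[c("SpliceAI_accloss", "SpliceAI_accgain",
                   "SpliceAI_donloss", "SpliceAI_dongain")]
    }
    block[i, SPLICEAI_COLS] <- as.numeric(pre)
  }
  m_ref <- matrix(stats::rnorm(n * 5), n, 5)
  delta <- feat[, MMSPLICE_COLS]
  # where the generating delta is 0, plant positive raw differences on a
  # subset so the clip-at-zero rule is exercised
  pos_diff <- delta == 0 & matrix(stats::runif(n * 5) < 0.3, n, 5)
  delta[pos_diff] <- stats::runif(sum(pos_diff), 0.05, 0.8)
  m_alt <- m_ref + sweep(delta, 1, ifelse(benign, -1, 1), `*`)
  block[observed, mmsplice_ref_cols()] <- m_ref[observed, ]
  block[observed, mmsplice_alt_cols()] <- m_alt[observed, ]
  block[splice_missing, c(SPLICEAI_COLS, mmsplice_ref_cols(),
                          mmsplice_alt_cols())] <- NA_real_

  splice_scores <- cbind(av[c("chrom", "pos", "ref", "alt", "gene_id")],
                         block[c(SPLICEAI_COLS, mmsplice_ref_cols(),
                                 mmsplice_alt_cols())])
  splice_scores <- splice_scores[!splice_missing, , drop = FALSE]

  splice_sites <- data.frame(
    chrom = rep(rep(gene_chrom, n_exons), 2),
    pos = c(as.vector(donor_pos), as.vector(acceptor_pos)),
    type = rep(c("donor", "acceptor"), each = n_genes * n_exons),
    gene_id = rep(rep(sprintf("gene%05d", seq_len(n_genes)), n_exons), 2),
    strand = "+", stringsAsFactors = FALSE)

  av_raw <- av[setdiff(names(av), c(SPLICEAI_COLS, MMSPLICE_COLS,
                                    "SpliceAI_missing"))]
  structure(list(av = av, av_raw = av_raw, splice_scores = splice_scores,
                 splice_sites = splice_sites, design = design,
                 labels = labels, eta = eta, true_weights = w,
                 intercept = intercept, config = config),
            class = "cadd_sim")
}

#' Simulate a reporter-assay (MFASS-like) data set
#'
#' A latent splice-disruption effect drives both the psi change of the
#' tested exon (through a logit-scale shift plus measurement noise) and the
#' splice submodel scores (noisily), so score-based predictors separate sdv
#' from no-sdv variants with an auPRC above prevalence but below 1. psi
#' values are logit-normal and therefore respect `[0, 1]` by construction.
#'
#' @param config A [sim_config()]; `disruption_fraction`, `psi_noise_sd`
#'   and `sdv_threshold` control the assay.
#' @return Data frame with variant identity, `psi_ref`, `psi_alt`,
#'   `delta_psi`, `sdv`, the latent effect, four SpliceAI submodel scores,
#'   `SpliceAI_max` and `MMSplice_delta_logit_psi`.
#' @export
simulate_mfass_like <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  set.seed(config$seed + 1L)

  disrupted <- stats::runif(n) < config$disruption_fraction
  effect <- ifelse(disrupted,
                   pmax(stats::rnorm(n, 4, 1.2), 0),
                   abs(stats::rnorm(n, 0, 0.35)))
  psi_ref <- stats::plogis(stats::rnorm(n, 2.0, 1.2))
  logit_alt <- stats::qlogis(psi_ref) - effect +
    stats::rnorm(n, 0, config$psi_noise_sd)
  psi_alt <- stats::plogis(logit_alt)
  meas <- classify_sdv(psi_ref, psi_alt, threshold = config$sdv_threshold)

  is_donor <- stats::runif(n) < 0.5
  score_noise <- function() stats::rnorm(n, 0, 1.3)
  active <- stats::plogis((effect - 2.5 + score_noise()) / 1.0)
  idle <- stats::plogis(stats::rnorm(n, -4, 0.8))
  sai <- data.frame(
    SpliceAI_accgain = stats::plogis(stats::rnorm(n, -4.5, 0.8)),
    SpliceAI_dongain = stats::plogis(stats::rnorm(n, -4.5, 0.8)),
    SpliceAI_accloss = ifelse(is_donor, idle, active),
    SpliceAI_donloss = ifelse(is_donor, active, idle))
  mms <- -(0.5 * effect + stats::rnorm(n, 0, 0.45))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  data.frame(
    chrom = sprintf("chr%d", sample.int(22, n, replace = TRUE)),
    pos = sample.int(1e8, n, replace = TRUE),
    ref = ref,
    alt = vapply(ref, function(b) sample(setdiff(bases, b), 1), ""),
    gene_id = sprintf("gene%05d", sample.int(max(2, n %/% 12), n,
                                             replace = TRUE)),
    psi_ref = meas$psi_ref, psi_alt = meas$psi_alt,
    delta_psi = meas$delta_psi, sdv = meas$sdv,
    latent_effect = effect,
    sai,
    SpliceAI_max = collapse_max(sai),
    MMSplice_delta_logit_psi = mms,
    stringsAsFactors = FALSE)
}

#' Simulate allele-frequency records
#'
#' Allele counts follow a discrete Pareto tail (`AC = floor(u^(-1/alpha))`
#' capped at the haploid sample size / 2), giving the heavy-tailed site
#' frequency spectrum population data show. With `af_coupling > 0`, a
#' variant's tail index increases with its (standardized) deleteriousness
#' score, thinning the tail and pushing high-scoring variants toward
#' singleton status; `af_coupling = 0` decouples frequency from score.
#'
#' @param config A [sim_config()].
#' @param scores Optional per-variant deleteriousness scores (length
#'   `n_variants`) that the coupling acts on; defaults to standard normal
#'   draws.
#' @return Data frame with variant index, `score`, `AC`, `MAF` and `bin`.
#' @export
simulate_frequencies <- function(config, scores = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  set.seed(config$seed + 2L)
  if (is.null(scores)) scores <- stats::rnorm(n)
  if (length(scores) != n) stop("scores must have length n_variants")
  z <- as.numeric(scale(scores))
  alpha <- pmax(config$af_alpha + config$af_coupling * z, 0.2)
  u <- stats::runif(n)
  ac <- pmin(floor(u ^ (-1 / alpha)), config$af_sample_size)
  maf <- ac / (2 * config$af_sample_size)
  data.frame(variant = seq_len(n), score = scores, AC = as.integer(ac),
             MAF = maf, bin = assign_bins(maf, ac))
}
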