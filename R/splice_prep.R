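#' Splice submodel score preprocessing
#'
#' SpliceAI provides four probabilities per variant (acceptor/donor x
#' gain/loss) and MMSplice provides reference and alternative scores for five
#' submodels (acceptor, acceptor intron, exon, donor, donor intron). Before
#' entering the model these are preprocessed:
#'
#' * *Masking*: predicted splice gain at an already annotated splice site and
#'   predicted splice loss away from annotated sites carry no class signal,
#'   so they are set to 0 (independently for donor and acceptor).
#' * *Derived-allele swap*: proxy-benign (human-derived) variants are scored
#'   with reference and alternative alleles reversed, so their gain and loss
#'   scores are swapped for donor and for acceptor, and masking is applied
#'   after the swap.
#' * *MMSplice delta*: the reference score is subtracted from the
#'   alternative score (reversed for the proxy-benign class) and positive
#'   differences are clipped to 0.
#' * *Imputation*: variants without SpliceAI or MMSplice annotation are
#'   imputed as 0, with the SpliceAI missingness indicator recording absent
#'   SpliceAI annotation.
#'
#' A splice block is a data frame with one row per variant and columns
#' `SpliceAI_accgain`, `SpliceAI_accloss`, `SpliceAI_dongain`,
#' `SpliceAI_donloss`, `MMSplice_<submodel>_ref` / `_alt` for the five
#' submodels, and logical site-context flags `at_annotated_acceptor`,
#' `at_annotated_donor`.
#'
#' @name splice-prep
NULL

SPLICEAI_COLS <- c("SpliceAI_accgain", "SpliceAI_accloss",
                   "SpliceAI_dongain", "SpliceAI_donloss")

MMSPLICE_SUBMODELS <- c("acceptor", "acceptorIntron", "exon",
                        "donor", "donorIntron")

MMSPLICE_COLS <- paste0("MMSplice_", MMSPLICE_SUBMODELS)

mmsplice_ref_cols <- function() paste0(MMSPLICE_COLS, "_ref")
mmsplice_alt_cols <- function() paste0(MMSPLICE_COLS, "_alt")

#' Construct an empty splice block
#'
#' @param n Number of rows; all scores `NA`, all site flags `FALSE`.
#' @return Splice-block data frame.
#' @export
empty_splice_block <- function(n) {
  cols <- c(SPLICEAI_COLS, mmsplice_ref_cols(), mmsplice_alt_cols())
  block <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(cols),
                                dimnames = list(NULL, cols)))
  block$at_annotated_acceptor <- rep(FALSE, n)
  block$at_annotated_donor <- rep(FALSE, n)
  block
}

check_splice_block <- function(block) {
  need <- c(SPLICEAI_COLS, mmsplice_ref_cols(), mmsplice_alt_cols(),
            "at_annotated_acceptor", "at_annotated_donor")
  miss <- setdiff(need, names(block))
  if (length(miss) > 0) {
    stop("splice block lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (cl in SPLICEAI_COLS) {
    x <- block[[cl]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop("SpliceAI scores must lie in [0, 1]: ", cl)
    }
  }
  invisible(block)
}

#' Mask SpliceAI scores by splice-site context
#'
#' For donor and acceptor independently: at an annotated site the gain score
#' is set to 0; away from annotated sites the loss score is set to 0.
#' Missing (`NA`) scores stay missing. Masking is idempotent.
#'
#' @param block Splice-block data frame.
#' @return The block with masked SpliceAI columns.
#' @export
mask_spliceai <- function(block) {
  check_splice_block(block)
  at_acc <- block$at_annotated_acceptor
  at_don <- block$at_annotated_donor
  mask0 <- function(x, where) ifelse(where & !is.na(x), 0, x)
  block$SpliceAI_accgain <- mask0(block$SpliceAI_accgain, at_acc)
  block$SpliceAI_accloss <- mask0(block$SpliceAI_accloss, !at_acc)
  block$SpliceAI_dongain <- mask0(block$SpliceAI_dongain, at_don)
  block$SpliceAI_donloss <- mask0(block$SpliceAI_donloss, !at_don)
  block
}

#' Swap gain/loss then mask (derived-allele recipe)
#'
#' Proxy-benign variants are scored with reference and alternative reversed,
#' so a predicted gain is really a loss and vice versa. Gain and loss are
#' swapped within donor and within acceptor, then [mask_spliceai()] is
#' applied to the swapped scores.
#'
#' @param block Splice-block data frame.
#' @return The block with swapped and masked SpliceAI columns.
#' @export
swap_then_mask_spliceai <- function(block) {
  check_splice_block(block)
  tmp <- block$SpliceAI_accgain
  block$SpliceAI_accgain <- block$SpliceAI_accloss
  block$SpliceAI_accloss <- tmp
  tmp <- block$SpliceAI_dongain
  block$SpliceAI_dongain <- block$SpliceAI_donloss
  block$SpliceAI_donloss <- tmp
  mask_spliceai(block)
}

#' Class-oriented, clipped MMSplice score differences
#'
#' For the proxy-deleterious class and ordinary scoring the reference score
#' is subtracted from the alternative score; for the proxy-benign class the
#' alternative score is subtracted from the reference score (the alleles
#' were scored reversed). Positive differences are set to 0. A missing ref
#' or alt score propagates `NA` for that submodel.
#'
#' @param block Splice-block data frame.
#' @param class_label Single value or per-row vector of
#'   `"proxy_benign"`, `"proxy_deleterious"` or `"unlabeled"`.
#' @return Data frame with the five clipped columns `MMSplice_acceptor`,
#'   `MMSplice_acceptorIntron`, `MMSplice_exon`, `MMSplice_donor`,
#'   `MMSplice_donorIntron`.
#' @export
mmsplice_delta <- function(block, class_label = "unlabeled") {
  check_splice_block(block)
  n <- nrow(block)
  class_label <- rep_len(as.character(class_label), n)
  if (!all(class_label %in% CLASS_LABELS)) {
    stop("class_label values must be one of: ",
         paste(CLASS_LABELS, collapse = ", "))
  }
  sign <- ifelse(class_label == "proxy_benign", -1, 1)
  out <- lapply(seq_along(MMSPLICE_COLS), function(i) {
    d <- sign * (block[[mmsplice_alt_cols()[i]]] -
                   block[[mmsplice_ref_cols()[i]]])
    pmin(d, 0)
  })
  names(out) <- MMSPLICE_COLS
  as.data.frame(out)
}

#' Impute missing splice features to zero
#'
#' Replaces every `NA` in the nine splice feature columns by 0 and adds a
#' logical `SpliceAI_missing` column that is `TRUE` when all four SpliceAI
#' scores were missing (the schema's `SpliceAI` missingness indicator).
#'
#' @param features Data frame containing the four SpliceAI columns and the
#'   five clipped MMSplice columns.
#' @return The data frame with zeros in place of `NA` plus
#'   `SpliceAI_missing`.
#' @export
impute_splice <- function(features) {
  need <- c(SPLICEAI_COLS, MMSPLICE_COLS)
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    stop("splice feature frame lacks column(s): ", paste(miss, collapse = ", "))
  }
  sai <- as.matrix(features[SPLICEAI_COLS])
  features$SpliceAI_missing <- rowSums(is.na(sai)) == length(SPLICEAI_COLS)
  for (cl in need) {
    x <- features[[cl]]
    x[is.na(x)] <- 0
    features[[cl]] <- x
  }
  features
}

#' Collapse submodel scores to their maximum
#'
#' The single-score summary of a multi-submodel predictor (e.g. the four
#' SpliceAI submodels) is the per-variant maximum.
#'
#' @param scores Numeric vector (one variant's submodel scores) or matrix /
#'   data frame (variants in rows).
#' @param na.rm Drop `NA` submodel scores before taking the maximum.
#' @return Numeric scalar (vector input) or vector (matrix input).
#' @export
collapse_max <- function(scores, na.rm = FALSE) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.matrix(scores)) {
    if (ncol(scores) == 0) stop("no submodel scores to collapse")
    return(apply(scores, 1, max, na.rm = na.rm))
  }
  if (length(scores) == 0) stop("no submodel scores to collapse")
  max(scores, na.rm = na.rm)
}

#' Combined MMSplice + SpliceAI score (MMAI / MMAIpsi)
#'
#' Equal-weight linear combination of MMSplice `delta_logit_psi` and the
#' SpliceAI submodel maximum, each divided by its standard deviation across
#' the benchmark variants; optionally the reference-allele percent
#' spliced-in, likewise normalized, is added (MMAIpsi). The default standard
#' deviations are the ones computed across the MFASS variants (MMSplice
#' 0.5291, SpliceAI 0.1206, psi 0.0622).
#'
#' @param mmsplice MMSplice `delta_logit_psi` score(s).
#' @param spliceai_max SpliceAI submodel maximum score(s).
#' @param sd_mm,sd_ai,sd_psi Positive normalizing standard deviations.
#' @param psi Optional reference-allele percent spliced-in.
#' @return Numeric combined score.
#' @export
combine_mmai <- function(mmsplice, spliceai_max,
                         sd_mm = 0.5291, sd_ai = 0.1206,
                         psi = NULL, sd_psi = 0.0622) {
  if (sd_mm <= 0 || sd_ai <= 0) stop("normalizing sd must be positive")
  out <- mmsplice / sd_mm + spliceai_max / sd_ai
  if (!is.null(psi)) {
    if (is.null(sd_psi) || sd_psi <= 0) stop("normalizing sd must be positive")
    out <- out + psi / sd_psi
  }
  out
}

#' Call splice-disrupting variants from percent spliced-in
#'
#' A variant is splice-disrupting (sdv) when the psi ratio of the tested
#' exon changes by more than `threshold` (strict inequality; default 0.5).
#' Alternative thresholds (0.7, 0.3, 0.1) are supported through `threshold`,
#' and the two-sided variant through `no_sdv_below`: with
#' `no_sdv_below = 0.1`, variants with `delta_psi < 0.1` are called no-sdv
#' and intermediate variants are excluded (`sdv = NA`).
#'
#' @param psi_ref,psi_alt Percent spliced-in of the reference and
#'   alternative allele, in `[0, 1]`.
#' @param threshold sdv threshold on `delta_psi` (strict `>`).
#' @param no_sdv_below Optional upper bound (strict `<`) below which a
#'   variant is called no-sdv; intermediates become `NA`.
#' @return Data frame with `psi_ref`, `psi_alt`, `delta_psi`
#'   (`|psi_alt - psi_ref|`) and logical `sdv`.
#' @export
classify_sdv <- function(psi_ref, psi_alt, threshold = 0.5,
                         no_sdv_below = NULL) {
  if (any(psi_ref < 0 | psi_ref > 1 | psi_alt < 0 | psi_alt > 1,
          na.rm = TRUE)) {
    stop("psi values must lie in [0, 1]")
  }
  delta_psi <- abs(psi_alt - psi_ref)
  if (is.null(no_sdv_below)) {
    sdv <- delta_psi > threshold
  } else {
    sdv <- ifelse(delta_psi > threshold, TRUE,
                  ifelse(delta_psi < no_sdv_below, FALSE, NA))
  }
  data.frame(psi_ref = psi_ref, psi_alt = psi_alt,
             delta_psi = delta_psi, sdv = sdv)
}

#' Attach and preprocess splice features for annotated variants
#'
#' Joins a splice-score table to a variant table by (chrom, pos, ref, alt),
#' keeping a score row only when its `gene_id` matches the variant's
#' (scores are restricted to the consequence's gene); flags variants at
#' annotated donor/acceptor positions by exact position and gene match
#' against a splice-site table; applies [mask_spliceai()] (or
#' [swap_then_mask_spliceai()] for proxy-benign variants), the class-aware
#' [mmsplice_delta()], and [impute_splice()].
#'
#' @param variants Annotated-variant data frame with at least chrom, pos,
#'   ref, alt; a `gene_id` column and a `class_label` column are used when
#'   present.
#' @param splice_scores Splice-score table as read by
#'   [read_splice_scores()]: variant key columns, `gene_id`, four SpliceAI
#'   columns, ten MMSplice ref/alt columns.
#' @param splice_sites Splice-site table as read by [read_splice_sites()]:
#'   `chrom`, `pos`, `type` (donor/acceptor), `gene_id`, `strand`.
#' @return `variants` with the nine imputed splice feature columns and the
#'   logical `SpliceAI_missing` indicator appended.
#' @export
prep_splice_features <- function(variants, splice_scores = NULL,
                                 splice_sites = NULL) {
  n <- nrow(variants)
  block <- empty_splice_block(n)
  vkey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                sep = ":")
  gene <- if ("gene_id" %in% names(variants)) variants$gene_id else
    rep(NA_character_, n)

  if (!is.null(splice_scores) && nrow(splice_scores) > 0) {
    skey <- paste(splice_scores$chrom, splice_scores$pos, splice_scores$ref,
                  splice_scores$alt, sep = ":")
    idx <- match(vkey, skey)
    matched <- !is.na(idx)
    if ("gene_id" %in% names(splice_scores)) {
      sg <- splice_scores$gene_id[idx]
      same_gene <- !is.na(sg) & !is.na(gene) & sg == gene
      matched <- matched & same_gene           # gene-mismatched blocks drop
    }
    score_cols <- c(SPLICEAI_COLS, mmsplice_ref_cols(), mmsplice_alt_cols())
    for (cl in intersect(score_cols, names(splice_scores))) {
      block[[cl]][matched] <- splice_scores[[cl]][idx[matched]]
    }
  }

  if (!is.null(splice_sites) && nrow(splice_sites) > 0) {
    site_key <- function(type) {
      s <- splice_sites[splice_sites$type == type, , drop = FALSE]
      paste(s$chrom, s$pos, s$gene_id, sep = ":")
    }
    here <- paste(variants$chrom, variants$pos, gene, sep = ":")
    block$at_annotated_acceptor <- here %in% site_key("acceptor")
    block$at_annotated_donor <- here %in% site_key("donor")
  }

  labels <- if ("class_label" %in% names(variants)) variants$class_label else
    rep("unlabeled", n)
  benign <- labels == "proxy_benign"
  masked <- mask_spliceai(block)
  if (any(benign)) {
    swapped <- swap_then_mask_spliceai(block[benign, , drop = FALSE])
    masked[benign, SPLICEAI_COLS] <- swapped[SPLICEAI_COLS]
  }

  feats <- masked[SPLICEAI_COLS]
  feats <- cbind(feats, mmsplice_delta(block, labels))
  feats <- impute_splice(feats)
  cbind(variants, feats)
}
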