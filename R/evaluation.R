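#' Benchmark statistics
#'
#' Precision-recall and ROC curves with areas, allele-frequency bin
#' enrichment with bootstrap confidence intervals, and rank correlations —
#' the statistics used to compare splice-aware variant scores against
#' experimental splice-disruption labels, curated pathogenic variants and
#' population allele frequencies.
#'
#' @name evaluation
NULL

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  keep <- !is.na(scores) & !is.na(labels)
  list(scores = scores[keep], labels = labels[keep])
}

#' Precision-recall curve and area
#'
#' Precision and recall at every distinct score threshold (higher score =
#' positive call); the area is trapezoidal over recall, anchored at
#' recall 0 with the precision of the strictest threshold.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 is the positive
#'   class.
#' @return List with `curve` (data frame: threshold, precision, recall) and
#'   `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  ord <- order(d$scores, decreasing = TRUE)
  s <- d$scores[ord]; y <- d$labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  n_pos <- sum(d$labels)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  r <- c(0, recall); p <- c(precision[1], precision)
  auprc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = data.frame(threshold = thr, precision = precision,
                          recall = recall),
       auprc = auprc)
}

#' ROC curve and area
#'
#' The area equals the probability that a random positive outranks a random
#' negative, with ties counted one half (Mann-Whitney); it is computed from
#' average ranks and is invariant under strictly monotone score transforms.
#'
#' @inheritParams pr_curve
#' @return List with `curve` (data frame: threshold, fpr, tpr) and `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  ord <- order(d$scores, decreasing = TRUE)
  s <- d$scores[ord]; y <- d$labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  n_pos <- sum(d$labels); n_neg <- length(d$labels) - n_pos
  r <- rank(d$scores)                      # average ranks handle ties as 1/2
  auroc <- (sum(r[d$labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(curve = data.frame(threshold = c(Inf, thr),
                          fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos)),
       auroc = auroc)
}

#' Assign allele-frequency bins
#'
#' Bins follow the population-frequency rule: `singleton` when the allele
#' count is 1; otherwise `frequent` when MAF exceeds 0.001 and `rare` below
#' it. A MAF of exactly 0.001 (unassigned by the strict rule) goes to
#' `frequent` so the bins partition all variants.
#'
#' @param maf Minor allele frequencies in `[0, 0.5]`.
#' @param ac Allele counts (>= 1).
#' @return Factor with levels `frequent`, `rare`, `singleton`.
#' @export
assign_bins <- function(maf, ac) {
  if (any(ac < 1, na.rm = TRUE)) stop("allele count must be >= 1")
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("MAF must lie in [0, 0.5]")
  }
  bin <- ifelse(ac == 1, "singleton",
                ifelse(maf >= 0.001, "frequent", "rare"))
  factor(bin, levels = c("frequent", "rare", "singleton"))
}

enrichment_point <- function(scores, bins, percentile) {
  threshold <- stats::quantile(scores, percentile / 100, names = FALSE,
                               type = 7)
  above <- scores > threshold
  frac_above <- mean(above)
  vapply(levels(bins), function(b) {
    in_bin <- bins == b
    if (!any(in_bin)) return(NA_real_)
    expected <- sum(in_bin) * frac_above
    if (expected == 0) return(NA_real_)
    sum(above & in_bin) / expected
  }, numeric(1))
}

#' Frequency-bin enrichment above a score percentile
#'
#' The score threshold is the given percentile of the category's score
#' distribution (linear-interpolation percentile). For each frequency bin
#' the observed number of variants strictly above the threshold is divided
#' by the number expected under random drawing (bin size times the overall
#' fraction above threshold). Uncertainty comes from a percentile bootstrap
#' over variants: resampling with replacement, recomputing threshold and
#' ratios each iteration, and taking the 2.5%/97.5% quantiles.
#'
#' @param scores Numeric scores for all variants of one category.
#' @param bins Factor from [assign_bins()], aligned with `scores`.
#' @param percentile Score percentile in (0, 100) defining the threshold.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with one row per bin: `bin`, `n`, `observed`,
#'   `expected`, `ratio`, `ci_low`, `ci_high` (empty bins report `NA`
#'   ratios).
#' @export
af_enrichment <- function(scores, bins, percentile = 90, n_boot = 1000,
                          seed = 1) {
  if (length(scores) != length(bins)) stop("scores and bins differ in length")
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)")
  }
  bins <- as.factor(bins)
  ratio <- enrichment_point(scores, bins, percentile)

  set.seed(seed)
  n <- length(scores)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = nlevels(bins))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- enrichment_point(scores[idx], bins[idx], percentile)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)

  threshold <- stats::quantile(scores, percentile / 100, names = FALSE)
  above <- scores > threshold
  data.frame(
    bin = levels(bins),
    n = as.integer(table(bins)),
    observed = as.integer(vapply(levels(bins),
                                 function(b) sum(above & bins == b),
                                 numeric(1))),
    expected = as.numeric(table(bins)) * mean(above),
    ratio = ratio,
    ci_low = ci[1, ],
    ci_high = ci[2, ],
    row.names = NULL)
}

#' Spearman rank correlation between two score vectors
#'
#' Average ranks are used for ties; incomplete pairs are removed.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2).
#' @return Spearman's rho.
#' @export
rank_correlation <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors differ in length")
  }
  if (length(scores_a) < 2) stop("need at least two paired scores")
  stats::cor(scores_a, scores_b, method = "spearman",
             use = "complete.obs")
}

#' Restrict a benchmark table to fully scored variants, or impute missing
#' scores as benign
#'
#' Cross-predictor comparisons either drop variants lacking any compared
#' score (`policy = "exclude"`, the default) or treat a missing score as a
#' benign call of 0 (`policy = "benign"`).
#'
#' @param benchmark Data frame with one column per predictor score.
#' @param score_cols Names of the score columns compared.
#' @param policy `"exclude"` or `"benign"`.
#' @return The filtered (or imputed) benchmark table.
#' @export
handle_missing_scores <- function(benchmark, score_cols,
                                  policy = c("exclude", "benign")) {
  policy <- match.arg(policy)
  miss <- setdiff(score_cols, names(benchmark))
  if (length(miss) > 0) {
    stop("benchmark lacks score column(s): ", paste(miss, collapse = ", "))
  }
  if (policy == "exclude") {
    keep <- stats::complete.cases(benchmark[score_cols])
    benchmark[keep, , drop = FALSE]
  } else {
    for (cl in score_cols) {
      x <- benchmark[[cl]]
      x[is.na(x)] <- 0
      benchmark[[cl]] <- x
    }
    benchmark
  }
}
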