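#' Model fitting and scoring
#'
#' The scoring model is an L2-regularized logistic regression of the
#' proxy-deleterious (1) versus proxy-benign (0) label on the full design
#' matrix. The regularization strength is chosen by held-out grid search
#' (log-loss on a random holdout split, seed-controlled), mirroring the
#' held-out hyperparameter selection used by earlier model versions.
#' Continuous columns are scaled to unit standard deviation on the training
#' data before fitting (without centering, which preserves sparsity and,
#' with an unpenalized intercept, leaves the fit essentially unchanged);
#' indicator columns enter raw. Reported coefficients are mapped back to
#' the original feature scale, so scoring applies no further transform.
#'
#' @name scorer
NULL

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("proxy_benign", "proxy_deleterious")
    if (any(bad)) stop("labels must be proxy_benign / proxy_deleterious")
    labels <- as.integer(labels == "proxy_deleterious")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  labels
}

log_loss <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the regularized logistic regression
#'
#' @param design A `cadd_design` (see [build_design_matrix()]).
#' @param labels Per-row labels: 0/1 or `"proxy_benign"` /
#'   `"proxy_deleterious"`.
#' @param lambda Decreasing grid of L2 penalty strengths searched; the
#'   default spans strong to effectively unpenalized.
#' @param holdout_frac Fraction of rows held out for penalty selection.
#' @param seed Integer seed controlling the holdout split.
#' @param thresh,maxit Optimizer convergence tolerance and iteration cap;
#'   failure to converge is an error.
#' @return A `cadd_model`: intercept and coefficients on the original
#'   feature scale, the scaling vector, the selected penalty, and training
#'   metadata.
#' @export
fit_cadd <- function(design, labels,
                     lambda = 10 ^ seq(0, -4, length.out = 9),
                     holdout_frac = 0.2, seed = 1,
                     thresh = 1e-7, maxit = 1e5) {
  stopifnot(inherits(design, "cadd_design"))
  y <- as_binary_labels(labels)
  x <- design$matrix
  if (length(y) != nrow(x)) stop("labels do not align with design rows")
  if (length(unique(y)) < 2) stop("both classes must be present")

  scales <- rep(1, ncol(x))
  sds <- sqrt(pmax(Matrix::colMeans(x ^ 2) - Matrix::colMeans(x) ^ 2, 0))
  scales[design$continuous & sds > 0] <- sds[design$continuous & sds > 0]
  xs <- x %*% Matrix::Diagonal(x = 1 / scales)
  colnames(xs) <- design$columns

  lambda <- sort(lambda, decreasing = TRUE)
  fit_glmnet <- function(x, y, lam) {
    withCallingHandlers(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE, intercept = TRUE,
                     thresh = thresh, maxit = maxit),
      warning = function(w) {
        if (grepl("converge|convergence", conditionMessage(w),
                  ignore.case = TRUE)) {
          stop("logistic regression did not converge: ",
               conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      })
  }

  lambda_best <- lambda[1]
  holdout_loss <- NULL
  if (length(lambda) > 1) {
    set.seed(seed)
    n <- nrow(xs)
    hold <- sample.int(n, max(1L, floor(n * holdout_frac)))
    if (length(unique(y[-hold])) < 2 || length(unique(y[hold])) < 2) {
      stop("holdout split left a single class; use more data or a smaller ",
           "holdout fraction")
    }
    path <- fit_glmnet(xs[-hold, , drop = FALSE], y[-hold], lambda)
    p_hold <- stats::predict(path, xs[hold, , drop = FALSE],
                             type = "response")
    holdout_loss <- apply(p_hold, 2, function(p) log_loss(y[hold], p))
    lambda_best <- path$lambda[which.min(holdout_loss)]
  }

  full <- fit_glmnet(xs, y, lambda)
  cf <- stats::coef(full, s = lambda_best)
  beta0 <- cf[1, 1]
  coef_scaled <- stats::setNames(cf[-1, 1], design$columns)

  structure(
    list(beta0 = beta0,
         coef = coef_scaled / scales,      # original feature scale
         coef_scaled = coef_scaled,
         scales = stats::setNames(scales, design$columns),
         columns = design$columns,
         groups = design$groups,
         schema = design$schema,
         lambda = lambda_best,
         lambda_grid = lambda,
         holdout_loss = holdout_loss,
         meta = list(n = nrow(x), n_deleterious = sum(y),
                     holdout_frac = holdout_frac, seed = seed,
                     thresh = thresh, maxit = maxit,
                     package_version =
                       as.character(utils::packageVersion("caddsplice")))),
    class = "cadd_model")
}

#' @export
print.cadd_model <- function(x, ...) {
  cat(sprintf("<cadd_model> %d features, lambda = %.3g, n = %d (%d/%d)\n",
              length(x$coef), x$lambda, x$meta$n,
              x$meta$n - x$meta$n_deleterious, x$meta$n_deleterious))
  invisible(x)
}

#' Grouped model weights
#'
#' Splits the flat coefficient vector into the model equation's groups:
#' intercept `beta0`, annotation coefficients `beta`, base-substitution
#' coefficients `gamma`, amino-acid-exchange coefficients `delta`,
#' missingness-indicator coefficients `tau`, and the consequence-by-D
#' interaction matrix `alpha`.
#'
#' @param model A `cadd_model`.
#' @return List with elements `beta0`, `beta`, `gamma`, `delta`, `tau`,
#'   `alpha` (matrix, consequence categories x interaction set).
#' @export
model_weights <- function(model) {
  stopifnot(inherits(model, "cadd_model"))
  g <- model$groups
  schema <- model$schema
  alpha <- matrix(model$coef[g == "interactions"],
                  nrow = length(schema$consequence_categories),
                  ncol = length(schema$interaction_set), byrow = TRUE,
                  dimnames = list(schema$consequence_categories,
                                  schema$interaction_set))
  list(beta0 = model$beta0,
       beta = model$coef[g == "X"],
       gamma = model$coef[g == "base_pairs"],
       delta = model$coef[g == "aa_exchange"],
       tau = model$coef[g == "W"],
       alpha = alpha)
}

#' Raw (log-odds) scores
#'
#' The linear predictor of the fitted model; higher means more
#' deleterious-like. Batch scoring is exactly row-wise scoring.
#'
#' @param model A `cadd_model`.
#' @param newdata A `cadd_design` or a numeric matrix/vector with the
#'   model's columns.
#' @return Numeric vector of raw scores.
#' @export
raw_score <- function(model, newdata) {
  stopifnot(inherits(model, "cadd_model"))
  x <- if (inherits(newdata, "cadd_design")) newdata$matrix else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$coef) ||
      (!is.null(colnames(x)) && !identical(colnames(x), model$columns))) {
    stop("feature columns do not match the model schema")
  }
  as.numeric(model$beta0 + x %*% model$coef)
}

#' PHRED-like scaling against a reference score distribution
#'
#' Each raw score is ranked against the reference distribution in
#' descending order (rank 1 = highest score; ties share the worst, i.e.
#' largest, rank) and scaled as `-10 * log10(rank / N)`. The top score out
#' of N = 100 maps to 20, the median to about 3.01, and the bottom (or an
#' all-tied reference) to 0.
#'
#' @param raw_scores Scores to scale.
#' @param reference Reference raw-score distribution (non-empty).
#' @return Numeric vector of scaled scores.
#' @export
phred_scale <- function(raw_scores, reference) {
  if (length(reference) == 0) stop("empty reference distribution")
  n <- length(reference)
  sorted <- sort(reference)
  # rank = number of reference scores >= s  (ties take the largest rank)
  rank <- n - findInterval(raw_scores, sorted, left.open = TRUE)
  -10 * log10(rank / n)
}

#' Percentile rank in a reference distribution
#'
#' Fraction of reference scores at or below each score; used when
#' comparing score versions on a common rank scale.
#'
#' @inheritParams phred_scale
#' @return Numeric vector in (0, 1].
#' @export
score_percentile <- function(raw_scores, reference) {
  if (length(reference) == 0) stop("empty reference distribution")
  findInterval(raw_scores, sort(reference)) / length(reference)
}

#' Score annotated variants end to end
#'
#' Builds the design matrix, applies the model and scales against a
#' reference distribution (by default the raw scores of the scored set
#' itself).
#'
#' @param model A `cadd_model`.
#' @param av Annotated-variant data frame with preprocessed splice columns.
#' @param reference Optional reference raw-score distribution for
#'   [phred_scale()].
#' @return Data frame with chrom, pos, ref, alt, `raw_score`,
#'   `scaled_score` and `percentile_rank`.
#' @export
score_variants <- function(model, av, reference = NULL) {
  design <- build_design_matrix(av, model$schema)
  raw <- raw_score(model, design)
  if (is.null(reference)) reference <- raw
  data.frame(chrom = av$chrom, pos = av$pos, ref = av$ref, alt = av$alt,
             raw_score = raw,
             scaled_score = phred_scale(raw, reference),
             percentile_rank = score_percentile(raw, reference))
}

#' Save / load a fitted model as a JSON artifact
#'
#' The artifact bundles the schema, scaling vector, coefficients, selected
#' penalty and training metadata, so a reloaded model scores identically.
#'
#' @param model A `cadd_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cadd_model"))
  payload <- unclass(model)
  payload$schema <- unclass(payload$schema)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  schema <- feature_schema(
    numeric_annotations = raw$schema$numeric_annotations,
    categorical_annotations = raw$schema$categorical_annotations,
    indicator_groups = raw$schema$indicator_groups,
    consequence_categories = raw$schema$consequence_categories,
    interaction_set = raw$schema$interaction_set,
    coding_consequences = raw$schema$coding_consequences,
    bases = raw$schema$bases,
    aa_alphabet = raw$schema$aa_alphabet)
  structure(
    list(beta0 = raw$beta0,
         coef = stats::setNames(unlist(raw$coef), raw$columns),
         coef_scaled = stats::setNames(unlist(raw$coef_scaled), raw$columns),
         scales = stats::setNames(unlist(raw$scales), raw$columns),
         columns = raw$columns, groups = raw$groups, schema = schema,
         lambda = raw$lambda, lambda_grid = raw$lambda_grid,
         holdout_loss = raw$holdout_loss, meta = raw$meta),
    class = "cadd_model")
}
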