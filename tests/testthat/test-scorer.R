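fit_small <- function(n = 400, seed = 3, ...) {
  set.seed(seed)
  av <- small_av(n)
  av$a <- rnorm(n); av$b <- rnorm(n); av$c <- rnorm(n)
  av$consequence <- sample(c("C1", "C2", "C3"), n, replace = TRUE)
  d <- build_design_matrix(av, small_schema())
  eta <- 1.5 * av$a - 1 * av$b
  y <- rbinom(n, 1, plogis(eta))
  list(design = d, labels = y, av = av)
}

test_that("fitting rejects degenerate inputs", {
  f <- fit_small()
  expect_error(fit_cadd(f$design, rep(1, nrow(f$design$matrix))),
               "both classes")
  expect_error(fit_cadd(f$design, f$labels[-1]), "align")
  expect_error(fit_cadd(f$design, rep(c("good", "bad"), 200)),
               "proxy_benign")
})

test_that("refitting with identical seed and data reproduces the model", {
  f <- fit_small()
  m1 <- fit_cadd(f$design, f$labels, seed = 9)
  m2 <- fit_cadd(f$design, f$labels, seed = 9)
  expect_identical(m1$lambda, m2$lambda)
  expect_equal(m1$coef, m2$coef)
  expect_equal(m1$beta0, m2$beta0)
})

test_that("with label-independent features and strong shrinkage the intercept approaches the prevalence log-odds", {
  set.seed(21)
  f <- fit_small(n = 2000)
  y <- rbinom(2000, 1, 0.3)          # independent of every feature
  m <- fit_cadd(f$design, y, lambda = 100)   # single strong penalty
  expect_lt(max(abs(m$coef_scaled)), 0.02)
  expect_equal(m$beta0, qlogis(mean(y)), tolerance = 0.05)
})

test_that("weaker regularization separates a separable training set further", {
  set.seed(4)
  n <- 300
  av <- small_av(n)
  av$a <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  y <- rep(c(0, 1), each = n / 2)
  d <- build_design_matrix(av, small_schema())
  auc <- vapply(c(10, 0.001), function(lam) {
    m <- fit_cadd(d, y, lambda = lam)
    roc_curve(raw_score(m, d), y)$auroc
  }, numeric(1))
  expect_gte(auc[2], auc[1])
  expect_gt(auc[2], 0.99)
})

test_that("raw scores are the linear predictor and batch equals row-wise", {
  f <- fit_small()
  m <- fit_cadd(f$design, f$labels, seed = 1)
  # zero row scores to the intercept
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1, length(m$coef)),
                               dimnames = list(NULL, m$columns))
  expect_equal(raw_score(m, zero), m$beta0)
  # unit vector on feature k adds exactly its coefficient
  k <- match("a", m$columns)
  unit <- zero; unit[1, k] <- 1
  expect_equal(raw_score(m, unit), m$beta0 + unname(m$coef["a"]))
  # batch equals row-wise
  batch <- raw_score(m, f$design)
  rows <- vapply(1:5, function(i) {
    raw_score(m, f$design$matrix[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(batch[1:5], rows)
})

test_that("scoring rejects mismatched feature spaces", {
  f <- fit_small()
  m <- fit_cadd(f$design, f$labels, seed = 1)
  wrong <- f$design$matrix[, -1]
  expect_error(raw_score(m, wrong), "match the model schema")
})

test_that("grouped weights carry the model equation's shapes", {
  f <- fit_small()
  m <- fit_cadd(f$design, f$labels, seed = 1)
  w <- model_weights(m)
  expect_length(w$beta, 5)            # 3 numeric + 2 one-hot
  expect_length(w$gamma, 12)
  expect_length(w$delta, 189)
  expect_length(w$tau, 1)
  expect_identical(dim(w$alpha), c(3L, 2L))
  expect_equal(length(w$beta) + length(w$gamma) + length(w$delta) +
                 length(w$tau) + length(w$alpha), length(m$coef))
  expect_equal(unname(w$alpha["C1", "a"]),
               unname(m$coef["int:C1:a"]))
})

test_that("PHRED scaling matches the -10*log10(rank/N) closed form", {
  ref <- 1:100
  expect_equal(phred_scale(100, ref), 20)                 # top of N = 100
  expect_equal(phred_scale(51, ref), -10 * log10(0.5), tolerance = 1e-10)
  expect_equal(phred_scale(1, ref), 0)                    # bottom rank N
  # ties share the worst rank
  expect_equal(phred_scale(5, rep(5, 10)), 0)
  expect_error(phred_scale(1, numeric(0)), "empty")
})

test_that("scaled scores are a strictly monotone transform of raw scores", {
  set.seed(8)
  raw <- rnorm(500)
  scaled <- phred_scale(raw, raw)
  expect_equal(rank_correlation(raw, scaled), 1)
  expect_identical(order(raw), order(scaled))
})

test_that("models round-trip through the JSON artifact", {
  f <- fit_small()
  m <- fit_cadd(f$design, f$labels, seed = 1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$coef, m$coef)
  expect_equal(m2$beta0, m$beta0)
  expect_identical(m2$schema, m$schema)
  expect_equal(raw_score(m2, f$design), raw_score(m, f$design))
})

test_that("score_variants emits the public score-file columns", {
  f <- fit_small(n = 50)
  m <- fit_cadd(f$design, f$labels, seed = 1)
  tab <- score_variants(m, f$av)
  expect_named(tab, c("chrom", "pos", "ref", "alt", "raw_score",
                      "scaled_score", "percentile_rank"))
  expect_equal(rank_correlation(tab$raw_score, tab$scaled_score), 1)
  expect_true(all(tab$percentile_rank > 0 & tab$percentile_rank <= 1))
})
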