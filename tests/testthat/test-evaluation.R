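test_that("perfect separation gives unit areas", {
  s <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(pr_curve(s, y)$auprc, 1)
  expect_equal(roc_curve(s, y)$auroc, 1)
})

test_that("a single top-ranked positive yields auPRC 1", {
  s <- c(5, 4:1)
  y <- c(1, 0, 0, 0, 0)
  expect_equal(pr_curve(s, y)$auprc, 1)
})

test_that("label-independent scores give auPRC near prevalence and auROC near half", {
  set.seed(31)
  n <- 10000
  prev <- 0.1
  reps <- replicate(20, {
    y <- rbinom(n, 1, prev)
    s <- rnorm(n)
    c(pr_curve(s, y)$auprc, roc_curve(s, y)$auroc)
  })
  expect_equal(mean(reps[1, ]), prev, tolerance = 0.02)
  expect_equal(mean(reps[2, ]), 0.5, tolerance = 0.02)
})

test_that("auROC equals the pairwise Mann-Whitney oracle, ties included", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(1:8, n, replace = TRUE)    # heavy ties
    expect_equal(roc_curve(s, y)$auroc, auroc_oracle(s, y))
  }
})

test_that("curve areas agree with an independent ROC implementation", {
  set.seed(17)
  y <- rbinom(300, 1, 0.3)
  s <- rnorm(300) + y
  expect_equal(roc_curve(s, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("areas are invariant under strictly monotone transforms", {
  set.seed(19)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + 0.8 * y
  expect_equal(roc_curve(exp(s), y)$auroc, roc_curve(s, y)$auroc)
  expect_equal(pr_curve(exp(s), y)$auprc, pr_curve(s, y)$auprc)
})

test_that("single-class labels are rejected", {
  expect_error(pr_curve(1:5, rep(1, 5)), "both classes")
  expect_error(roc_curve(1:5, rep(0, 5)), "both classes")
})

test_that("frequency bins follow the MAF/AC rules", {
  expect_equal(as.character(assign_bins(0.01, 100)), "frequent")
  expect_equal(as.character(assign_bins(0.3, 1)), "singleton")
  expect_equal(as.character(assign_bins(1e-4, 5)), "rare")
  # the boundary MAF goes to frequent so the bins partition
  expect_equal(as.character(assign_bins(0.001, 10)), "frequent")
  expect_error(assign_bins(0.01, 0), ">= 1")
  expect_error(assign_bins(0.7, 5), "0.5")
})

test_that("a bin occupying exactly the top q fraction is enriched 1/q", {
  n <- 1000
  q <- 0.1
  scores <- seq_len(n)
  bins <- factor(ifelse(scores > n * (1 - q), "singleton", "rare"),
                 levels = c("frequent", "rare", "singleton"))
  e <- af_enrichment(scores, bins, percentile = 100 * (1 - q),
                     n_boot = 50, seed = 1)
  expect_equal(e$ratio[e$bin == "singleton"], 1 / q, tolerance = 0.01)
  # empty bin reports missing, not zero
  expect_true(is.na(e$ratio[e$bin == "frequent"]))
})

test_that("a bin with nothing above threshold gets ratio 0 with CI floor 0", {
  n <- 500
  scores <- seq_len(n)
  bins <- factor(ifelse(scores <= 100, "rare", "singleton"),
                 levels = c("frequent", "rare", "singleton"))
  e <- af_enrichment(scores, bins, percentile = 80, n_boot = 100, seed = 2)
  expect_equal(e$ratio[e$bin == "rare"], 0)
  expect_equal(e$ci_low[e$bin == "rare"], 0)
})

test_that("bin-size-weighted enrichment ratios average to one", {
  set.seed(23)
  scores <- rnorm(2000)
  bins <- factor(sample(c("frequent", "rare", "singleton"), 2000, TRUE,
                        prob = c(0.1, 0.5, 0.4)),
                 levels = c("frequent", "rare", "singleton"))
  e <- af_enrichment(scores, bins, percentile = 95, n_boot = 10, seed = 1)
  expect_equal(sum(e$n * e$ratio) / sum(e$n), 1, tolerance = 1e-10)
})

test_that("the bootstrap is reproducible under a fixed seed", {
  set.seed(3)
  scores <- rnorm(300)
  bins <- assign_bins(runif(300, 0, 0.5), sample(c(1, 2, 50), 300, TRUE))
  e1 <- af_enrichment(scores, bins, 90, n_boot = 50, seed = 11)
  e2 <- af_enrichment(scores, bins, 90, n_boot = 50, seed = 11)
  expect_identical(e1, e2)
})

test_that("rank correlation matches the exact rank formula", {
  expect_equal(rank_correlation(1:10, 1:10), 1)
  expect_equal(rank_correlation(1:10, 10:1), -1)
  set.seed(29)
  a <- rnorm(10); b <- rnorm(10)
  d <- rank(a) - rank(b)
  expect_equal(rank_correlation(a, b), 1 - 6 * sum(d ^ 2) / (10 * 99))
  expect_error(rank_correlation(1:3, 1:4), "length")
  expect_error(rank_correlation(1, 1), "at least two")
})

test_that("missing-score policies exclude or call benign", {
  tab <- data.frame(s1 = c(1, NA, 3), s2 = c(0.5, 1, NA), label = c(1, 0, 1))
  kept <- handle_missing_scores(tab, c("s1", "s2"), "exclude")
  expect_equal(nrow(kept), 1)
  benign <- handle_missing_scores(tab, c("s1", "s2"), "benign")
  expect_equal(benign$s1, c(1, 0, 3))
  expect_equal(benign$s2, c(0.5, 1, 0))
  expect_error(handle_missing_scores(tab, "nope"), "nope")
})
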