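test_that("masking zeroes gain at annotated sites and loss elsewhere", {
  b <- one_block(dongain = 0.8, donloss = 0.3, at_don = TRUE)
  m <- mask_spliceai(b)
  expect_equal(m$SpliceAI_dongain, 0)
  expect_equal(m$SpliceAI_donloss, 0.3)

  b <- one_block(accgain = 0.5, accloss = 0.9, at_acc = FALSE)
  m <- mask_spliceai(b)
  expect_equal(m$SpliceAI_accgain, 0.5)
  expect_equal(m$SpliceAI_accloss, 0)

  b <- one_block(accgain = 0, accloss = 0, dongain = 0, donloss = 0)
  expect_equal(mask_spliceai(b), b)
})

test_that("masking acts on donor and acceptor independently", {
  b <- one_block(accgain = 0.4, accloss = 0.6, dongain = 0.7, donloss = 0.2,
                 at_acc = TRUE, at_don = FALSE)
  m <- mask_spliceai(b)
  expect_equal(
    as.numeric(m[c("SpliceAI_accgain", "SpliceAI_accloss",
                   "SpliceAI_dongain", "SpliceAI_donloss")]),
    c(0, 0.6, 0.7, 0))
})

test_that("masking is idempotent and preserves [0, 1]", {
  set.seed(42)
  for (i in 1:20) {
    b <- one_block(accgain = runif(1), accloss = runif(1),
                   dongain = runif(1), donloss = runif(1),
                   at_acc = runif(1) < 0.5, at_don = runif(1) < 0.5)
    m1 <- mask_spliceai(b)
    expect_equal(mask_spliceai(m1), m1)
    vals <- as.numeric(m1[SPLICEAI_COLS <- c("SpliceAI_accgain",
                                             "SpliceAI_accloss",
                                             "SpliceAI_dongain",
                                             "SpliceAI_donloss")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("the derived-allele recipe swaps gain/loss before masking", {
  b <- one_block(dongain = 0.7, donloss = 0.1, accgain = 0, accloss = 0,
                 at_don = FALSE)
  m <- swap_then_mask_spliceai(b)
  expect_equal(m$SpliceAI_dongain, 0.1)
  expect_equal(m$SpliceAI_donloss, 0)

  b <- one_block(dongain = 0.4, donloss = 0.4, accgain = 0, accloss = 0,
                 at_don = TRUE)
  m <- swap_then_mask_spliceai(b)
  expect_equal(m$SpliceAI_dongain, 0)
  expect_equal(m$SpliceAI_donloss, 0.4)

  zero <- one_block(accgain = 0, accloss = 0, dongain = 0, donloss = 0)
  expect_equal(swap_then_mask_spliceai(zero), zero)
})

test_that("swapping twice before masking restores the original scores", {
  set.seed(7)
  swap_only <- function(b) {
    tmp <- b$SpliceAI_accgain
    b$SpliceAI_accgain <- b$SpliceAI_accloss; b$SpliceAI_accloss <- tmp
    tmp <- b$SpliceAI_dongain
    b$SpliceAI_dongain <- b$SpliceAI_donloss; b$SpliceAI_donloss <- tmp
    b
  }
  for (i in 1:10) {
    b <- one_block(accgain = runif(1), accloss = runif(1),
                   dongain = runif(1), donloss = runif(1),
                   at_acc = runif(1) < 0.5, at_don = runif(1) < 0.5)
    expect_equal(mask_spliceai(swap_only(swap_only(b))), mask_spliceai(b))
  }
})

test_that("MMSplice deltas are class-oriented and clipped at zero", {
  mk <- function(ref, alt) one_block(mm_ref = rep(ref, 5),
                                     mm_alt = rep(alt, 5))
  d <- mmsplice_delta(mk(-1, -3), "proxy_deleterious")
  expect_equal(unique(as.numeric(d)), -2)
  d <- mmsplice_delta(mk(-3, -1), "proxy_benign")
  expect_equal(unique(as.numeric(d)), -2)
  # positive differences clip to 0 in every class
  for (cl in c("proxy_benign", "proxy_deleterious", "unlabeled")) {
    block <- if (cl == "proxy_benign") mk(0.5, 0) else mk(0, 0.5)
    expect_equal(unique(as.numeric(mmsplice_delta(block, cl))), 0)
  }
  expect_error(mmsplice_delta(mk(0, 0), "benign"), "class_label")
})

test_that("mmsplice_delta is never positive and symmetric classes negate", {
  set.seed(11)
  for (i in 1:20) {
    b <- one_block(mm_ref = rnorm(5), mm_alt = rnorm(5))
    del <- as.numeric(mmsplice_delta(b, "proxy_deleterious"))
    ben <- as.numeric(mmsplice_delta(b, "proxy_benign"))
    expect_true(all(del <= 0) && all(ben <= 0))
    # before clipping the two orientations are exact negatives: at most one
    # of the clipped values is nonzero per submodel
    expect_true(all(del == 0 | ben == 0))
  }
})

test_that("imputation zero-fills and sets the SpliceAI indicator", {
  full_missing <- cbind(one_block()[c("SpliceAI_accgain", "SpliceAI_accloss",
                                      "SpliceAI_dongain", "SpliceAI_donloss")],
                        mmsplice_delta(one_block(), "unlabeled"))
  out <- impute_splice(full_missing)
  expect_true(all(as.matrix(out[setdiff(names(out), "SpliceAI_missing")]) == 0))
  expect_true(out$SpliceAI_missing)

  present <- data.frame(SpliceAI_accgain = 0.1, SpliceAI_accloss = 0.2,
                        SpliceAI_dongain = 0.3, SpliceAI_donloss = 0.4,
                        MMSplice_acceptor = -1, MMSplice_acceptorIntron = 0,
                        MMSplice_exon = -2, MMSplice_donor = 0,
                        MMSplice_donorIntron = -0.5)
  out <- impute_splice(present)
  expect_false(out$SpliceAI_missing)
  expect_equal(out[names(present)], present)

  partial <- present
  partial$MMSplice_exon <- NA
  partial$SpliceAI_donloss <- NA
  out <- impute_splice(partial)
  expect_equal(out$MMSplice_exon, 0)
  expect_equal(out$SpliceAI_donloss, 0)
  expect_equal(out$SpliceAI_accgain, 0.1)
  expect_false(out$SpliceAI_missing)
})

test_that("submodel collapse takes the maximum and rejects empty input", {
  expect_equal(collapse_max(c(0.1, 0.9, 0.0, 0.3)), 0.9)
  expect_equal(collapse_max(0.5), 0.5)
  expect_equal(collapse_max(c(0, 0, 0, 0)), 0)
  expect_error(collapse_max(numeric(0)), "no submodel")
  m <- rbind(c(0.1, 0.9), c(0.5, 0.2))
  expect_equal(collapse_max(m), c(0.9, 0.5))
})

test_that("the combined splice score normalizes by the benchmark SDs", {
  expect_equal(combine_mmai(0, 0), 0)
  expect_equal(combine_mmai(0.5291, 0.1206), 2)
  expect_equal(combine_mmai(0.5291, 0.1206, psi = 0.0622), 3)
  expect_error(combine_mmai(1, 1, sd_mm = 0), "positive")
  expect_error(combine_mmai(1, 1, psi = 1, sd_psi = -1), "positive")
})

test_that("sdv calls use a strict delta-psi threshold", {
  m <- classify_sdv(0.9, 0.2)
  expect_equal(m$delta_psi, 0.7)
  expect_true(m$sdv)
  # a change of exactly 0.5 is not disrupting (strictly greater required)
  m <- classify_sdv(0.6, 0.1)
  expect_equal(m$delta_psi, 0.5)
  expect_false(m$sdv)
  expect_false(classify_sdv(0.4, 0.4)$sdv)
  expect_error(classify_sdv(1.2, 0.5), "\\[0, 1\\]")
  # alternative thresholds
  expect_true(classify_sdv(0.9, 0.5, threshold = 0.3)$sdv)
  expect_false(classify_sdv(0.9, 0.5, threshold = 0.7)$sdv)
})

test_that("two-sided sdv calling excludes intermediate variants", {
  m <- classify_sdv(c(0.9, 0.9, 0.9), c(0.1, 0.6, 0.85),
                    threshold = 0.5, no_sdv_below = 0.1)
  expect_equal(m$sdv, c(TRUE, NA, FALSE))
})

test_that("sdv calls are monotone in the psi change", {
  psi_ref <- 0.95
  deltas <- seq(0, 0.95, by = 0.05)
  calls <- classify_sdv(rep(psi_ref, length(deltas)), psi_ref - deltas)$sdv
  expect_false(is.unsorted(calls))   # FALSE...TRUE, never back
})

test_that("splice features attach by variant key and matching gene", {
  av <- data.frame(chrom = "chr1", pos = c(100, 200, 300), ref = "A",
                   alt = "G", gene_id = c("g1", "g1", "g2"),
                   class_label = c("proxy_deleterious", "proxy_benign",
                                   "unlabeled"),
                   stringsAsFactors = FALSE)
  scores <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A",
                       alt = "G", gene_id = c("g1", "g9"),
                       stringsAsFactors = FALSE)
  scores[c("SpliceAI_accgain", "SpliceAI_accloss", "SpliceAI_dongain",
           "SpliceAI_donloss")] <- list(0.2, 0.8, 0.1, 0.9)
  for (sub in c("acceptor", "acceptorIntron", "exon", "donor",
                "donorIntron")) {
    scores[[paste0("MMSplice_", sub, "_ref")]] <- -1
    scores[[paste0("MMSplice_", sub, "_alt")]] <- -1.5
  }
  sites <- data.frame(chrom = "chr1", pos = 100, type = "donor",
                      gene_id = "g1", strand = "+",
                      stringsAsFactors = FALSE)
  out <- prep_splice_features(av, scores, sites)
  # variant 1: annotated donor -> donor gain masked, loss kept
  expect_equal(out$SpliceAI_dongain[1], 0)
  expect_equal(out$SpliceAI_donloss[1], 0.9)
  expect_equal(out$MMSplice_exon[1], -0.5)
  expect_false(out$SpliceAI_missing[1])
  # variant 2: gene mismatch drops the block entirely -> imputed zeros
  expect_true(out$SpliceAI_missing[2])
  expect_true(all(out[2, c("SpliceAI_accgain", "SpliceAI_donloss",
                           "MMSplice_exon")] == 0))
  # variant 3: no score row at all
  expect_true(out$SpliceAI_missing[3])
})
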