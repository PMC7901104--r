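# Small schema for arithmetic-level tests: 3 numeric annotations (2 in D),
# one 2-level categorical, 1 indicator group, 3 consequence categories.
small_schema <- function() {
  feature_schema(
    numeric_annotations = c("a", "b", "c"),
    categorical_annotations = list(cat1 = c("L1", "L2")),
    indicator_groups = list(ia = "a"),
    consequence_categories = c("C1", "C2", "C3"),
    interaction_set = c("a", "b")
  )
}

small_av <- function(n = 4) {
  data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    consequence = rep_len(c("C1", "C2", "C3"), n),
    a = seq_len(n) / 2, b = -seq_len(n), c = 0.1,
    cat1 = rep_len(c("L1", "L2"), n),
    stringsAsFactors = FALSE
  )
}

# one-variant splice block with explicit values
one_block <- function(accgain = NA, accloss = NA, dongain = NA, donloss = NA,
                      at_acc = FALSE, at_don = FALSE,
                      mm_ref = rep(NA_real_, 5), mm_alt = rep(NA_real_, 5)) {
  block <- empty_splice_block(1)
  block$SpliceAI_accgain <- accgain
  block$SpliceAI_accloss <- accloss
  block$SpliceAI_dongain <- dongain
  block$SpliceAI_donloss <- donloss
  block[paste0("MMSplice_", c("acceptor", "acceptorIntron", "exon",
                              "donor", "donorIntron"), "_ref")] <-
    as.list(mm_ref)
  block[paste0("MMSplice_", c("acceptor", "acceptorIntron", "exon",
                              "donor", "donorIntron"), "_alt")] <-
    as.list(mm_alt)
  block$at_annotated_acceptor <- at_acc
  block$at_annotated_donor <- at_don
  block
}

# Pairwise Mann-Whitney oracle for the ROC area: ties count one half.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
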