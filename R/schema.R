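#' Feature schema for the combined annotation model
#'
#' A `cadd_schema` declares every feature the scoring model knows about:
#' numeric annotations, categorical annotations with their level sets,
#' missingness-indicator groups, the consequence categories used for one-hot
#' encoding and feature crosses, the interaction set `D`, the nucleotide
#' alphabet and the amino-acid alphabet. The design matrix, the fitted model
#' and all readers validate against the active schema, so a schema fully
#' determines the feature space.
#'
#' @param numeric_annotations Character vector of numeric annotation names.
#' @param categorical_annotations Named list; each element is the ordered
#'   character vector of levels for one categorical annotation.
#' @param indicator_groups Named list mapping each missingness indicator to
#'   the annotation names it covers. The reserved group name
#'   `"aa_exchange"` refers to the amino-acid substitution encoding rather
#'   than to an annotation column.
#' @param consequence_categories Ordered character vector of consequence
#'   categories.
#' @param interaction_set Character vector `D` of annotation names crossed
#'   with the consequence categories.
#' @param coding_consequences Subset of `consequence_categories` for which an
#'   amino-acid exchange may be present.
#' @param bases Nucleotide alphabet (fixed, exposed for completeness).
#' @param aa_alphabet Amino-acid alphabet; 20 residues plus the stop symbol.
#'
#' @return An object of class `cadd_schema`.
#' @seealso [default_schema()], [validate_schema()], [read_schema()]
#' @export
feature_schema <- function(numeric_annotations,
                           categorical_annotations,
                           indicator_groups,
                           consequence_categories,
                           interaction_set,
                           coding_consequences = character(0),
                           bases = c("A", "C", "G", "T"),
                           aa_alphabet = AA_ALPHABET_21) {
  schema <- structure(
    list(
      numeric_annotations = as.character(numeric_annotations),
      categorical_annotations = lapply(categorical_annotations, as.character),
      indicator_groups = lapply(indicator_groups, as.character),
      consequence_categories = as.character(consequence_categories),
      interaction_set = as.character(interaction_set),
      coding_consequences = as.character(coding_consequences),
      bases = as.character(bases),
      aa_alphabet = as.character(aa_alphabet)
    ),
    class = "cadd_schema"
  )
  schema
}

#' The 21-symbol amino-acid alphabet (20 residues + stop)
#' @export
AA_ALPHABET_21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Default feature schema (GRCh37-style, 1029 model features)
#'
#' The shipped default reproduces the structure of the GRCh37 v1.6 feature
#' space: 90 numeric annotations and 12 categorical annotations whose one-hot
#' encodings add 132 columns (222 annotation features in total), 14
#' missingness indicators, 16 consequence categories and a 37-member
#' interaction set `D`, for 222 + 12 + 189 + 14 + 592 = 1029 model features.
#' Annotation names follow the conventional CADD column names; annotations
#' outside the splice block are treated as opaque numeric/categorical
#' columns. The categorical level cardinalities (summing to 132) are a
#' documented convention of this package; the counts per group are fixed by
#' the published feature totals.
#'
#' @return A `cadd_schema`.
#' @export
default_schema <- function() {
  interaction_set <- c(
    "bStatistic", "cDNApos", "CDSpos", "Dst2Splice", "GerpN", "GerpS",
    "mamPhCons", "mamPhyloP", "minDistTSE", "minDistTSS", "priPhCons",
    "priPhyloP", "protPos", "relcDNApos", "relCDSpos", "relProtPos",
    "verPhCons", "verPhyloP", "Dist2Mutation",
    "freq100", "freq1000", "freq10000",
    "rare100", "rare1000", "rare10000",
    "sngl100", "sngl1000", "sngl10000",
    "SpliceAI_accgain", "SpliceAI_accloss", "SpliceAI_dongain",
    "SpliceAI_donloss",
    "MMSplice_acceptorIntron", "MMSplice_acceptor", "MMSplice_donorIntron",
    "MMSplice_donor", "MMSplice_exon"
  )

  other_numeric <- c(
    "GC", "CpG", "motifECount", "motifEScoreChng", "motifDist",
    "tOverlapMotifs", "SIFTval", "PolyPhenVal", "Grantham", "targetScan",
    "mirSVR_Score", "mirSVR_E", "mirSVR_Aln", "dbscSNV_ada", "dbscSNV_rf",
    "GerpRS", "GerpRSpval", "fitCons",
    "EncExp", "EncH3K27Ac", "EncH3K4Me1", "EncH3K4Me3", "EncH3K9Ac",
    "EncH3K27Me3", "EncH3K36Me3", "EncH3K9Me3", "EncH4K20Me1",
    "EncNucleo", "EncTotalRNA", "EncOCC",
    "EncOCCombPVal", "EncOCCombSig", "EncOCDNasePVal", "EncOCDNaseSig",
    "EncOCFairePVal", "EncOCFaireSig", "EncOCpolIIPVal", "EncOCpolIISig",
    "EncOCctcfPVal", "EncOCctcfSig", "EncOCmycPVal", "EncOCmycSig",
    "TFBS", "TFBSPeaks", "TFBSPeaksMax", "RemapOverlapTF", "RemapOverlapCL",
    "Length", "dnaHelT", "dnaMGW", "dnaProT", "dnaRoll", "mutIndex"
  )

  categorical <- list(
    Type = c("SNV", "INS", "DEL"),
    AnnoType = c("CodingTranscript", "Intergenic", "NonCodingTranscript",
                 "RegulatoryFeature"),
    Consequence = default_consequences(),
    Domain = c("ncoils", "sigp", "lcompl", "ndomain", "other"),
    Dst2SplType = c("ACCEPTOR", "DONOR"),
    SIFTcat = c("deleterious", "tolerated"),
    PolyPhenCat = c("benign", "possibly_damaging", "probably_damaging"),
    Segway = sprintf("seg%02d", 1:25),
    chromHMM = sprintf("state%02d", 1:25),
    EnsembleRegulatoryFeature = c("CTCF_binding_site", "enhancer",
                                  "open_chromatin_region", "promoter",
                                  "promoter_flanking_region",
                                  "TF_binding_site", "regulatory_region",
                                  "other"),
    motifEName = sprintf("motif%02d", 1:37),
    motifEHIPos = c("no", "yes")
  )

  indicator_groups <- list(
    cDNApos = c("cDNApos", "relcDNApos"),
    CDSpos = c("CDSpos", "relCDSpos"),
    protPos = c("protPos", "relProtPos"),
    aminoacid_substitution = "aa_exchange",
    targetScan = "targetScan",
    mirSVR = c("mirSVR_Score", "mirSVR_E", "mirSVR_Aln"),
    Grantham = "Grantham",
    PolyPhenVal = c("PolyPhenVal", "PolyPhenCat"),
    SIFTval = c("SIFTval", "SIFTcat"),
    Dist2Mutation = "Dist2Mutation",
    chromHMM = "chromHMM",
    dbscSNV_ada = "dbscSNV_ada",
    dbscSNV_rf = "dbscSNV_rf",
    SpliceAI = c("SpliceAI_accgain", "SpliceAI_accloss",
                 "SpliceAI_dongain", "SpliceAI_donloss")
  )

  feature_schema(
    numeric_annotations = sort(c(interaction_set, other_numeric)),
    categorical_annotations = categorical,
    indicator_groups = indicator_groups,
    consequence_categories = default_consequences(),
    interaction_set = interaction_set,
    coding_consequences = c("STOP_GAINED", "STOP_LOST", "NON_SYNONYMOUS",
                            "SYNONYMOUS")
  )
}

#' Default consequence categories (16 CADD-style classes)
#' @export
default_consequences <- function() {
  c("STOP_GAINED", "STOP_LOST", "CANONICAL_SPLICE", "SPLICE_SITE",
    "NON_SYNONYMOUS", "SYNONYMOUS", "FRAME_SHIFT", "INFRAME",
    "5PRIME_UTR", "3PRIME_UTR", "INTRONIC", "UPSTREAM", "DOWNSTREAM",
    "REGULATORY", "NONCODING_CHANGE", "INTERGENIC")
}

#' Validate a feature schema
#'
#' Checks uniqueness of names within each list, the subset relation of the
#' interaction set and the indicator groups, the nucleotide and amino-acid
#' alphabets, and the coding-consequence subset. Violations are returned, not
#' raised, so callers can report all problems at once.
#'
#' @param schema A `cadd_schema`.
#' @return Character vector of violations; empty when the schema is valid.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "cadd_schema"))
  v <- character(0)
  add <- function(cond, msg) if (cond) c(v, msg) else v

  dup <- function(x) unique(x[duplicated(x)])
  v <- add(anyDuplicated(schema$numeric_annotations) > 0,
           sprintf("numeric_annotations: duplicated name(s): %s",
                   paste(dup(schema$numeric_annotations), collapse = ", ")))
  v <- add(anyDuplicated(names(schema$categorical_annotations)) > 0,
           "categorical_annotations: duplicated annotation name(s)")
  for (nm in names(schema$categorical_annotations)) {
    v <- add(anyDuplicated(schema$categorical_annotations[[nm]]) > 0,
             sprintf("categorical_annotations: duplicated level(s) in '%s'", nm))
  }
  v <- add(any(schema$numeric_annotations %in%
                 names(schema$categorical_annotations)),
           "annotation name(s) both numeric and categorical")
  v <- add(anyDuplicated(schema$consequence_categories) > 0,
           "consequence_categories: duplicated name(s)")
  v <- add(anyDuplicated(schema$interaction_set) > 0,
           "interaction_set: duplicated name(s)")

  unknown_d <- setdiff(schema$interaction_set, schema$numeric_annotations)
  v <- add(length(unknown_d) > 0,
           sprintf("interaction_set: name(s) not numeric annotations: %s",
                   paste(unknown_d, collapse = ", ")))

  v <- add(anyDuplicated(names(schema$indicator_groups)) > 0,
           "indicator_groups: duplicated indicator name(s)")
  known <- c(schema$numeric_annotations,
             names(schema$categorical_annotations), "aa_exchange")
  for (nm in names(schema$indicator_groups)) {
    unknown <- setdiff(schema$indicator_groups[[nm]], known)
    v <- add(length(unknown) > 0,
             sprintf("indicator_groups: '%s' covers unknown name(s): %s",
                     nm, paste(unknown, collapse = ", ")))
  }

  v <- add(!setequal(schema$bases, c("A", "C", "G", "T")),
           "bases: must be the four nucleotides A, C, G, T")
  v <- add(length(schema$aa_alphabet) != 21 ||
             anyDuplicated(schema$aa_alphabet) > 0,
           "aa_alphabet: must be 21 unique symbols (20 residues + stop)")
  unknown_cc <- setdiff(schema$coding_consequences,
                        schema$consequence_categories)
  v <- add(length(unknown_cc) > 0,
           sprintf("coding_consequences: unknown categor(ies): %s",
                   paste(unknown_cc, collapse = ", ")))
  v
}

#' Number of model features implied by a schema
#'
#' @param schema A `cadd_schema`.
#' @return Named integer vector with elements `X`, `base_pairs`,
#'   `aa_exchange`, `W`, `interactions` and `total`.
#' @export
schema_feature_counts <- function(schema) {
  n_x <- length(schema$numeric_annotations) +
    sum(lengths(schema$categorical_annotations))
  n_bp <- length(enumerate_base_pairs())
  n_aa <- length(enumerate_aa_exchanges())
  n_w <- length(schema$indicator_groups)
  n_int <- length(schema$consequence_categories) *
    length(schema$interaction_set)
  c(X = n_x, base_pairs = n_bp, aa_exchange = n_aa, W = n_w,
    interactions = n_int,
    total = n_x + n_bp + n_aa + n_w + n_int)
}

#' @export
print.cadd_schema <- function(x, ...) {
  cnt <- schema_feature_counts(x)
  cat("<cadd_schema>\n")
  cat(sprintf("  numeric annotations:     %d\n",
              length(x$numeric_annotations)))
  cat(sprintf("  categorical annotations: %d (%d one-hot columns)\n",
              length(x$categorical_annotations),
              sum(lengths(x$categorical_annotations))))
  cat(sprintf("  missingness indicators:  %d\n", length(x$indicator_groups)))
  cat(sprintf("  consequence categories:  %d\n",
              length(x$consequence_categories)))
  cat(sprintf("  interaction set D:       %d\n", length(x$interaction_set)))
  cat(sprintf("  model features:          %d\n", cnt[["total"]]))
  invisible(x)
}

#' Read / write a schema as YAML
#'
#' The YAML layout mirrors the `cadd_schema` fields one-to-one, so
#' `read_schema(write_schema(s, f))` reproduces `s` exactly.
#'
#' @param schema A `cadd_schema`.
#' @param path File path.
#' @return `read_schema` returns a `cadd_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cadd_schema"))
  yaml::write_yaml(unclass(schema), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- feature_schema(
    numeric_annotations = raw$numeric_annotations,
    categorical_annotations = raw$categorical_annotations,
    indicator_groups = raw$indicator_groups,
    consequence_categories = raw$consequence_categories,
    interaction_set = raw$interaction_set,
    coding_consequences = raw$coding_consequences %||% character(0),
    bases = raw$bases,
    aa_alphabet = raw$aa_alphabet
  )
  bad <- validate_schema(schema)
  if (length(bad) > 0) {
    stop("invalid schema in '", path, "':\n  ", paste(bad, collapse = "\n  "))
  }
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a
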