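#' Variant tables
#'
#' Variants are plain data frames with columns `chrom`, `pos`, `ref`, `alt`
#' and optionally `gene_id`, one row per allele (VCF-style, 1-based, forward
#' strand). Annotated variants extend the same table with a `consequence`
#' column, an optional amino-acid exchange (`aa_ref`, `aa_alt`), a
#' `class_label` column (`"proxy_benign"`, `"proxy_deleterious"` or
#' `"unlabeled"`) and one column per annotation named in the active schema.
#' Missing annotation values are `NA` — an explicit sentinel distinct from 0,
#' because imputation-to-zero plus a missingness indicator is the model's
#' missingness treatment and happens only at encoding time.
#'
#' @name variant-tables
NULL

CLASS_LABELS <- c("proxy_benign", "proxy_deleterious", "unlabeled")

#' Validate a variant table
#'
#' Enforces the variant invariants: `ref != alt`, `pos >= 1`, SNV alleles
#' drawn from A/C/G/T, and InDel length (difference between allele lengths)
#' at most 50 bp.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return The input, invisibly, if valid; otherwise an error listing the
#'   first offending rows.
#' @export
validate_variants <- function(variants) {
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- function(idx, what) {
    if (any(idx)) {
      stop(sprintf("invalid variant(s) (%s) at row(s): %s", what,
                   paste(utils::head(which(idx), 5), collapse = ", ")))
    }
  }
  bad(variants$pos < 1, "pos < 1")
  bad(variants$ref == variants$alt, "ref == alt")
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  ok_base <- function(x) x %in% c("A", "C", "G", "T")
  bad(is_snv & !(ok_base(variants$ref) & ok_base(variants$alt)),
      "SNV allele outside A/C/G/T")
  bad(indel_length(variants$ref, variants$alt) > 50, "InDel longer than 50 bp")
  invisible(variants)
}

#' InDel length of an allele pair (0 for SNVs and balanced substitutions)
#' @param ref,alt Allele strings.
#' @return Integer vector of absolute length differences.
#' @export
indel_length <- function(ref, alt) {
  abs(nchar(ref) - nchar(alt))
}

#' Validate an annotated-variant table against a schema
#'
#' Checks that every annotation column is declared in the schema, that
#' categorical values are legal levels, that consequences and class labels
#' are legal, and that an amino-acid exchange is only present for coding
#' consequences.
#'
#' @param av Annotated-variant data frame.
#' @param schema A `cadd_schema`.
#' @return The input, invisibly, if valid.
#' @export
validate_annotated <- function(av, schema) {
  validate_variants(av)
  if (!"consequence" %in% names(av)) {
    stop("annotated variant table lacks a 'consequence' column")
  }
  reserved <- c("chrom", "pos", "ref", "alt", "gene_id", "consequence",
                "aa_ref", "aa_alt", "class_label")
  reserved <- c(reserved, names(av)[endsWith(names(av), "_missing")])
  anno_cols <- setdiff(names(av), reserved)
  known <- c(schema$numeric_annotations, names(schema$categorical_annotations))
  unknown <- setdiff(anno_cols, known)
  if (length(unknown) > 0) {
    stop("annotation column(s) absent from schema: ",
         paste(unknown, collapse = ", "))
  }
  bad_cons <- !av$consequence %in% schema$consequence_categories
  if (any(bad_cons)) {
    stop("unknown consequence value(s): ",
         paste(unique(av$consequence[bad_cons]), collapse = ", "))
  }
  if ("class_label" %in% names(av) &&
      !all(av$class_label %in% CLASS_LABELS)) {
    stop("class_label values must be one of: ",
         paste(CLASS_LABELS, collapse = ", "))
  }
  for (nm in intersect(names(schema$categorical_annotations), anno_cols)) {
    vals <- av[[nm]]
    bad <- !is.na(vals) & !vals %in% schema$categorical_annotations[[nm]]
    if (any(bad)) {
      stop(sprintf("illegal level(s) for categorical annotation '%s': %s",
                   nm, paste(unique(vals[bad]), collapse = ", ")))
    }
  }
  if (all(c("aa_ref", "aa_alt") %in% names(av))) {
    has_aa <- !is.na(av$aa_ref) | !is.na(av$aa_alt)
    noncoding <- !av$consequence %in% schema$coding_consequences
    if (any(has_aa & noncoding)) {
      stop("amino-acid exchange present on non-coding consequence at row(s): ",
           paste(utils::head(which(has_aa & noncoding), 5), collapse = ", "))
    }
    bad_aa <- (has_aa & (is.na(av$aa_ref) | is.na(av$aa_alt))) |
      (!is.na(av$aa_ref) & !av$aa_ref %in% schema$aa_alphabet) |
      (!is.na(av$aa_alt) & !av$aa_alt %in% schema$aa_alphabet)
    if (any(bad_aa)) {
      stop("malformed amino-acid exchange at row(s): ",
           paste(utils::head(which(bad_aa), 5), collapse = ", "))
    }
  }
  invisible(av)
}
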