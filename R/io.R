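#' Readers and writers
#'
#' Variants come from VCF (plain or gzipped); annotations, splice scores,
#' splice sites, allele frequencies and scored output travel as
#' tab-separated tables with empty fields for missing values. All writers
#' produce files their paired readers parse back to equal in-memory
#' objects.
#'
#' @name io
NULL

#' Read variants from a VCF file
#'
#' Multi-allelic records are split into one variant per alternative allele.
#' InDels longer than 50 bp are skipped; the number skipped is attached as
#' attribute `skipped_indels` and reported via a message.
#'
#' @param path VCF path (plain or gzipped).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, one row per
#'   allele, validated by [validate_variants()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
    attr(out, "skipped_indels") <- 0L
    return(out)
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  out <- data.frame(chrom = fix$CHROM[idx],
                    pos = as.integer(fix$POS[idx]),
                    ref = fix$REF[idx],
                    alt = unlist(alts),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pos))) {
    stop("malformed VCF record(s) at data line(s): ",
         paste(utils::head(unique(idx[is.na(out$pos)]), 5), collapse = ", "))
  }
  too_long <- indel_length(out$ref, out$alt) > 50
  if (any(too_long)) {
    message(sum(too_long), " InDel(s) longer than 50 bp skipped")
  }
  out <- out[!too_long, , drop = FALSE]
  rownames(out) <- NULL
  validate_variants(out)
  attr(out, "skipped_indels") <- sum(too_long)
  out
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "",
                                  colClasses = NULL, showProgress = FALSE))
}

write_tsv <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

variant_key <- function(tab) {
  paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
}

#' Read an annotation table and join it to variants
#'
#' The TSV carries the variant key columns (chrom, pos, ref, alt) plus
#' annotation columns named in the schema. Empty fields stay missing
#' (`NA`), never 0. Unknown columns and duplicate variant keys are errors;
#' variants absent from the table are returned in the `unmatched`
#' attribute.
#'
#' @param path Annotation TSV path.
#' @param schema A `cadd_schema`.
#' @param variants Optional variant table to join against (e.g. from
#'   [read_vcf()]); by default all table rows are returned.
#' @return Annotated-variant data frame (see [validate_annotated()]).
#' @export
read_annotations <- function(path, schema = default_schema(),
                             variants = NULL) {
  tab <- read_tsv(path)
  key <- variant_key(tab)
  if (anyDuplicated(key) > 0) {
    stop("duplicate variant key(s) in annotation table: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = ", "))
  }
  unmatched <- character(0)
  if (!is.null(variants)) {
    vkey <- variant_key(variants)
    unmatched <- vkey[!vkey %in% key]
    if (length(unmatched) > 0) {
      message(length(unmatched), " variant(s) missing from annotation table")
    }
    tab <- tab[match(vkey[vkey %in% key], key), , drop = FALSE]
    rownames(tab) <- NULL
  }
  validate_annotated(tab, schema)
  attr(tab, "unmatched") <- unmatched
  tab
}

#' @rdname read_annotations
#' @param av Annotated-variant table to write.
#' @export
write_annotations <- function(av, path) {
  write_tsv(av, path)
}

#' Read a splice-score table
#'
#' Columns: chrom, pos, ref, alt, gene_id, the four SpliceAI submodel
#' scores and the ten MMSplice ref/alt submodel scores; empty fields are
#' missing.
#'
#' @param path TSV path.
#' @return Data frame suitable for [prep_splice_features()].
#' @export
read_splice_scores <- function(path) {
  tab <- read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "gene_id",
            SPLICEAI_COLS, mmsplice_ref_cols(), mmsplice_alt_cols())
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("splice-score table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_splice_scores
#' @param scores Splice-score table to write.
#' @export
write_splice_scores <- function(scores, path) {
  write_tsv(scores, path)
}

#' Read a splice-site annotation table
#'
#' BED-like TSV with columns chrom, pos, type (`donor` / `acceptor`),
#' gene_id and strand.
#'
#' @param path TSV path.
#' @return Data frame of annotated splice-site positions.
#' @export
read_splice_sites <- function(path) {
  tab <- read_tsv(path)
  need <- c("chrom", "pos", "type", "gene_id", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("splice-site table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(tab$type %in% c("donor", "acceptor"))) {
    stop("splice-site type must be 'donor' or 'acceptor'")
  }
  tab
}

#' @rdname read_splice_sites
#' @param sites Splice-site table to write.
#' @export
write_splice_sites <- function(sites, path) {
  write_tsv(sites, path)
}

#' Read an allele-frequency table
#'
#' Columns: chrom, pos, ref, alt, `MAF`, `AC`; bins are (re)assigned with
#' [assign_bins()].
#'
#' @param path TSV path.
#' @return Data frame with a `bin` factor appended.
#' @export
read_frequencies <- function(path) {
  tab <- read_tsv(path)
  need <- c("MAF", "AC")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("frequency table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab$bin <- assign_bins(tab$MAF, tab$AC)
  tab
}

#' Write scored output
#'
#' Mirrors the public score-file layout: chrom, pos, ref, alt, raw score,
#' scaled score (plus percentile rank when present).
#'
#' @param scores Data frame from [score_variants()].
#' @param path Output TSV path.
#' @export
write_scores <- function(scores, path) {
  write_tsv(scores, path)
}
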