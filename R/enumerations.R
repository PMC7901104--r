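#' Base-substitution and amino-acid-exchange enumerations
#'
#' The model carries one indicator per ordered nucleotide substitution
#' (12 pairs) and one indicator per amino-acid exchange creatable with a
#' single nucleotide variant. The amino-acid enumeration is produced by
#' brute force over all 64 codons and their 9 single-base mutants under the
#' standard genetic code; an exchange `ref>alt` is included whenever some
#' codon pair one base apart translates to that ordered residue pair.
#' Same-residue exchanges reachable through a synonymous codon change are
#' included (19 of them: every residue except Met and Trp, which have
#' single codons, plus stop-to-stop), which is what brings the total to the
#' canonical 189.
#'
#' @name enumerations
NULL

#' Ordered nucleotide substitution pairs
#'
#' @return Character vector of the 12 ordered `"ref>alt"` pairs with
#'   `ref != alt`, in row-major A,C,G,T order.
#' @export
enumerate_base_pairs <- function() {
  b <- c("A", "C", "G", "T")
  pairs <- expand.grid(alt = b, ref = b, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, c("ref", "alt")]
  pairs <- pairs[order(match(pairs$ref, b), match(pairs$alt, b)), ]
  paste(pairs$ref, pairs$alt, sep = ">")
}

#' Amino-acid exchanges reachable by a single nucleotide variant
#'
#' @param genetic_code Named character vector mapping codons to one-letter
#'   residues (`"*"` = stop); defaults to the standard code.
#' @return Character vector of ordered `"ref>alt"` exchanges (189 under the
#'   standard code), sorted by ref then alt residue in [AA_ALPHABET_21]
#'   order.
#' @export
enumerate_aa_exchanges <- function(genetic_code = Biostrings::GENETIC_CODE) {
  bases <- c("A", "C", "G", "T")
  codons <- names(genetic_code)
  seen <- character(0)
  for (cd in codons) {
    for (i in 1:3) {
      for (b in setdiff(bases, substr(cd, i, i))) {
        mut <- cd
        substr(mut, i, i) <- b
        seen <- c(seen, paste(genetic_code[[cd]], genetic_code[[mut]],
                              sep = ">"))
      }
    }
  }
  seen <- unique(seen)
  parts <- strsplit(seen, ">", fixed = TRUE)
  ref <- vapply(parts, `[`, "", 1L)
  alt <- vapply(parts, `[`, "", 2L)
  seen[order(match(ref, AA_ALPHABET_21), match(alt, AA_ALPHABET_21))]
}
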