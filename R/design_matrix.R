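#' Design matrix construction
#'
#' Expands annotated variants into the model's feature matrix. With the
#' default schema a row has 1029 columns in five groups:
#'
#' * `X` (222): numeric annotations (missing imputed to 0) followed by
#'   one-hot encodings of the categorical annotations (missing level = all
#'   zeros);
#' * `base_pairs` (12): the ordered nucleotide substitution of an SNV;
#' * `aa_exchange` (189): the amino-acid exchange indicator for coding SNVs;
#' * `W` (14): missingness indicators, 1 when every annotation of the
#'   indicator's group is undefined for the variant;
#' * `interactions` (16 x 37 = 592): consequence-category indicator times
#'   the (imputed) value of each interaction-set annotation.
#'
#' Matrices are stored sparse (`Matrix::dgCMatrix`): the one-hot and
#' interaction blocks are almost entirely zeros.
#'
#' @name design-matrix
NULL

design_columns <- function(schema) {
  cat_names <- sort(names(schema$categorical_annotations))
  cat_cols <- unlist(lapply(cat_names, function(nm) {
    paste0(nm, "=", schema$categorical_annotations[[nm]])
  }), use.names = FALSE)
  x_cols <- c(schema$numeric_annotations, cat_cols)
  bp_cols <- paste0("base:", enumerate_base_pairs())
  aa_cols <- paste0("aa:", enumerate_aa_exchanges())
  w_cols <- paste0("ind:", names(schema$indicator_groups))
  int_cols <- unlist(lapply(schema$consequence_categories, function(cc) {
    paste0("int:", cc, ":", schema$interaction_set)
  }), use.names = FALSE)
  list(
    columns = c(x_cols, bp_cols, aa_cols, w_cols, int_cols),
    groups = rep(c("X", "base_pairs", "aa_exchange", "W", "interactions"),
                 c(length(x_cols), length(bp_cols), length(aa_cols),
                   length(w_cols), length(int_cols)))
  )
}

group_missing <- function(av, schema, members, indicator = NULL) {
  n <- nrow(av)
  # a precomputed flag (e.g. SpliceAI_missing, set during splice
  # preprocessing before zero-imputation) overrides NA-based detection
  if (!is.null(indicator)) {
    flag <- paste0(indicator, "_missing")
    if (flag %in% names(av)) return(as.logical(av[[flag]]))
  }
  miss <- rep(TRUE, n)
  for (m in members) {
    m_miss <- if (identical(m, "aa_exchange")) {
      if (all(c("aa_ref", "aa_alt") %in% names(av))) {
        is.na(av$aa_ref) | is.na(av$aa_alt)
      } else rep(TRUE, n)
    } else if (m %in% names(av)) {
      is.na(av[[m]])
    } else rep(TRUE, n)
    miss <- miss & m_miss
  }
  miss
}

#' Build the design matrix for a set of annotated variants
#'
#' @param av Annotated-variant data frame (see [validate_annotated()]);
#'   splice feature columns are expected to be preprocessed already (see
#'   [prep_splice_features()]).
#' @param schema A `cadd_schema`.
#' @return A `cadd_design`: list with `matrix` (sparse, rows in input
#'   order), `columns`, `groups` (column group of each column), `continuous`
#'   (logical; columns subject to scaling before fitting) and `schema`.
#' @export
build_design_matrix <- function(av, schema = default_schema()) {
  if (is.null(av) || nrow(av) == 0) stop("no variants to encode")
  validate_annotated(av, schema)
  n <- nrow(av)
  layout <- design_columns(schema)
  columns <- layout$columns
  col_at <- function(nm) match(nm, columns)

  ii <- vector("list", 0); jj <- vector("list", 0); xx <- vector("list", 0)
  push <- function(i, j, x) {
    keep <- !is.na(x) & x != 0
    ii[[length(ii) + 1L]] <<- i[keep]
    jj[[length(jj) + 1L]] <<- rep_len(j, length(i))[keep]
    xx[[length(xx) + 1L]] <<- x[keep]
  }

  # numeric annotations, imputed to 0 (NA contributes no triplet)
  num_imputed <- matrix(0, nrow = n,
                        ncol = length(schema$numeric_annotations),
                        dimnames = list(NULL, schema$numeric_annotations))
  for (nm in schema$numeric_annotations) {
    if (nm %in% names(av)) {
      vals <- as.numeric(av[[nm]])
      vals[is.na(vals)] <- 0
      num_imputed[, nm] <- vals
      push(seq_len(n), col_at(nm), vals)
    }
  }

  # categorical one-hots
  for (nm in sort(names(schema$categorical_annotations))) {
    if (!nm %in% names(av)) next
    levels <- schema$categorical_annotations[[nm]]
    hit <- match(av[[nm]], levels)          # NA level -> all-zero block
    obs <- which(!is.na(hit))
    if (length(obs) > 0) {
      j <- col_at(paste0(nm, "=", levels))[hit[obs]]
      ii[[length(ii) + 1L]] <- obs
      jj[[length(jj) + 1L]] <- j
      xx[[length(xx) + 1L]] <- rep(1, length(obs))
    }
  }

  # base-substitution indicator (SNVs only)
  is_snv <- nchar(av$ref) == 1 & nchar(av$alt) == 1
  if (any(is_snv)) {
    j <- col_at(paste0("base:", av$ref, ">", av$alt))[is_snv]
    ii[[length(ii) + 1L]] <- which(is_snv)
    jj[[length(jj) + 1L]] <- j
    xx[[length(xx) + 1L]] <- rep(1, sum(is_snv))
  }

  # amino-acid exchange indicator (pairs outside the SNV-reachable set are
  # silently unencodable, matching the fixed 189-column convention)
  if (all(c("aa_ref", "aa_alt") %in% names(av))) {
    has_aa <- !is.na(av$aa_ref) & !is.na(av$aa_alt)
    if (any(has_aa)) {
      j <- col_at(paste0("aa:", av$aa_ref, ">", av$aa_alt))[has_aa]
      obs <- which(has_aa)[!is.na(j)]
      if (length(obs) > 0) {
        ii[[length(ii) + 1L]] <- obs
        jj[[length(jj) + 1L]] <- j[!is.na(j)]
        xx[[length(xx) + 1L]] <- rep(1, length(obs))
      }
    }
  }

  # missingness indicators
  for (nm in names(schema$indicator_groups)) {
    miss <- group_missing(av, schema, schema$indicator_groups[[nm]], nm)
    push(seq_len(n), col_at(paste0("ind:", nm)), as.numeric(miss))
  }

  # consequence x interaction-set crosses: the D-vector copied into the
  # consequence's slice, zeros elsewhere
  cons <- av$consequence
  for (cc in schema$consequence_categories) {
    rows <- which(cons == cc)
    if (length(rows) == 0) next
    for (d in schema$interaction_set) {
      push(rows, col_at(paste0("int:", cc, ":", d)), num_imputed[rows, d])
    }
  }

  m <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, length(columns)), dimnames = list(NULL, columns)
  )
  structure(
    list(matrix = m, columns = columns, groups = layout$groups,
         continuous = layout$groups %in% c("X", "interactions") &
           !grepl("=", columns, fixed = TRUE),
         schema = schema),
    class = "cadd_design"
  )
}

#' Encode a single annotated variant
#'
#' Pure convenience wrapper around [build_design_matrix()] for one row.
#'
#' @param av_row One-row annotated-variant data frame.
#' @param schema A `cadd_schema`.
#' @return Named numeric feature vector.
#' @export
encode_variant <- function(av_row, schema = default_schema()) {
  if (nrow(av_row) != 1) stop("encode_variant expects exactly one row")
  d <- build_design_matrix(av_row, schema)
  stats::setNames(as.numeric(d$matrix[1, ]), d$columns)
}

#' @export
print.cadd_design <- function(x, ...) {
  cat(sprintf("<cadd_design> %d variants x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(factor(x$groups,
                     levels = c("X", "base_pairs", "aa_exchange", "W",
                                "interactions"))))
  invisible(x)
}

#' Export / import a design matrix
#'
#' The matrix is written as a gzipped TSV with a header row (dense, for
#' inspection and interchange) together with a JSON sidecar carrying the
#' column groups; `read_design_matrix` reverses the export.
#'
#' @param design A `cadd_design`.
#' @param path Output TSV path (".gz" is appended if absent).
#' @return `write_design_matrix` returns the TSV path invisibly.
#' @export
write_design_matrix <- function(design, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  tab <- as.data.frame(as.matrix(design$matrix))
  names(tab) <- design$columns
  data.table::fwrite(tab, path, sep = "\t", compress = "gzip")
  manifest <- jsonlite::toJSON(
    list(columns = design$columns, groups = design$groups),
    auto_unbox = FALSE)
  writeLines(manifest, paste0(sub("\\.gz$", "", path), ".manifest.json"))
  invisible(path)
}

#' @rdname write_design_matrix
#' @param schema Schema to attach on import.
#' @export
read_design_matrix <- function(path, schema = default_schema()) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.delim(con, check.names = FALSE)
  manifest_path <- paste0(sub("\\.gz$", "", path), ".manifest.json")
  manifest <- jsonlite::fromJSON(manifest_path)
  m <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  colnames(m) <- manifest$columns
  structure(
    list(matrix = m, columns = manifest$columns, groups = manifest$groups,
         continuous = manifest$groups %in% c("X", "interactions") &
           !grepl("=", manifest$columns, fixed = TRUE),
         schema = schema),
    class = "cadd_design")
}
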