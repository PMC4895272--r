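#' Read an expression matrix from delimited text
#'
#' Reads a features-by-samples expression table: the first row holds sample
#' IDs, the first column feature IDs, and the body is numeric (expression
#' levels, typically log scale; values are taken as given). Orientation is
#' never guessed: if your file is samples-by-features, transpose it yourself —
#' silent auto-transposition is a classic silent-corruption bug, so the
#' package refuses to do it.
#'
#' Missing or non-numeric cells are rejected rather than imputed; the method
#' expects fully pre-processed (e.g. differentially expressed) matrices.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @return A numeric matrix with feature IDs as row names and sample IDs as
#'   column names.
#' @section Errors:
#' Distinct condition classes are signalled for a missing file
#' (`mircore_file_error`), ragged rows (`mircore_ragged_error`), duplicate
#' feature or sample IDs (`mircore_duplicate_id_error`) and non-numeric cells
#' (`mircore_nonnumeric_error`).
#' @seealso [align_samples()], [write_expression()]
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_mircore(sprintf("expression file not found: %s", path),
                  class = "mircore_file_error")
  }
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"", comment.char = "")
  if (length(nf) < 2L) {
    abort_mircore(sprintf("expression file needs a header row and at least one feature row: %s", path),
                  class = "mircore_ragged_error")
  }
  body_nf <- nf[-1L]
  if (length(unique(body_nf)) != 1L) {
    bad <- which(body_nf != body_nf[1L])[1L] + 1L
    abort_mircore(sprintf("ragged row at line %d: expected %d fields, found %d",
                          bad, body_nf[1L], body_nf[bad - 1L]),
                  class = "mircore_ragged_error")
  }
  # Header may carry one fewer field than the body (R's row-name convention).
  if (!nf[1L] %in% c(body_nf[1L], body_nf[1L] - 1L)) {
    abort_mircore(sprintf("header has %d fields but data rows have %d", nf[1L], body_nf[1L]),
                  class = "mircore_ragged_error")
  }
  if (nf[1L] == body_nf[1L] - 1L) {
    # R row-name convention: header names only the sample columns.
    tab <- tryCatch(
      utils::read.table(path, sep = delimiter, header = TRUE,
                        check.names = FALSE, colClasses = "character",
                        comment.char = "", quote = "\"",
                        stringsAsFactors = FALSE),
      error = function(e) {
        if (grepl("row.names", conditionMessage(e), fixed = TRUE)) {
          abort_mircore(sprintf("duplicate feature IDs in %s", path),
                        class = "mircore_duplicate_id_error")
        }
        stop(e)
      }
    )
    feature_ids <- rownames(tab)
  } else {
    tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             comment.char = "", quote = "\"",
                             stringsAsFactors = FALSE, row.names = NULL)
    feature_ids <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
  }
  sample_ids <- colnames(tab)
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    abort_mircore(sprintf("duplicate feature IDs: %s", paste(dup, collapse = ", ")),
                  class = "mircore_duplicate_id_error")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort_mircore(sprintf("duplicate sample IDs: %s", paste(dup, collapse = ", ")),
                  class = "mircore_duplicate_id_error")
  }
  values <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  values <- matrix(as.numeric(values), nrow = nrow(tab), ncol = ncol(tab))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(matrix(values, nrow(tab))), arr.ind = TRUE)[1L, ]
    abort_mircore(
      sprintf("non-numeric or non-finite cell at feature '%s', sample '%s' (no silent imputation)",
              feature_ids[bad[1L]], sample_ids[bad[2L]]),
      class = "mircore_nonnumeric_error"
    )
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  validate_expression_matrix(values)
  values
}

# Internal invariant check shared by readers and the synthetic generator.
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort_mircore("expression data must be a numeric matrix", "mircore_type_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort_mircore("expression matrix must have feature row names and sample column names",
                  "mircore_type_error")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort_mircore("duplicate feature or sample IDs", "mircore_duplicate_id_error")
  }
  if (any(!is.finite(m))) {
    abort_mircore("expression matrix contains non-finite values", "mircore_nonnumeric_error")
  }
  invisible(m)
}

#' Write an expression matrix to delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces finite doubles bit-exactly.
#'
#' @param m Numeric matrix with feature row names and sample column names.
#' @param path Output file path.
#' @param delimiter Field separator (default tab).
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  validate_expression_matrix(m)
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  lines <- c(
    paste(c("feature_id", colnames(m)), collapse = delimiter),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], chr[i, ]), collapse = delimiter)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Align two expression matrices on their shared samples
#'
#' Restricts the miRNA and mRNA matrices to the samples (columns) they have
#' in common, in a single canonical order (the miRNA matrix's column order
#' restricted to the intersection). Sample matching is by exact string ID;
#' no fuzzy matching. At least 3 shared samples are required — correlation is
#' degenerate below that.
#'
#' @param mirna miRNA expression matrix (features x samples).
#' @param mrna mRNA expression matrix (features x samples).
#' @return A `matched_pair`: a list with elements `mirna` and `mrna` (column
#'   orders identical), plus `dropped_mirna` and `dropped_mrna` recording the
#'   sample IDs that were discarded from each input.
#' @export
align_samples <- function(mirna, mrna) {
  validate_expression_matrix(mirna)
  validate_expression_matrix(mrna)
  common <- colnames(mirna)[colnames(mirna) %in% colnames(mrna)]
  if (length(common) < 3L) {
    abort_mircore(
      sprintf("only %d shared sample IDs between the two matrices; need at least 3",
              length(common)),
      class = "mircore_overlap_error"
    )
  }
  dropped_mirna <- setdiff(colnames(mirna), common)
  dropped_mrna <- setdiff(colnames(mrna), common)
  if (length(dropped_mirna) || length(dropped_mrna)) {
    message(sprintf("align_samples: dropped %d miRNA and %d mRNA samples without a match",
                    length(dropped_mirna), length(dropped_mrna)))
  }
  structure(
    list(mirna = mirna[, common, drop = FALSE],
         mrna = mrna[, common, drop = FALSE],
         dropped_mirna = dropped_mirna,
         dropped_mrna = dropped_mrna),
    class = "matched_pair"
  )
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf("matched expression pair: %d miRNAs x %d mRNAs over %d shared samples\n",
              nrow(x$mirna), nrow(x$mrna), ncol(x$mirna)))
  invisible(x)
}

#' Read a reference table of confirmed miRNA-mRNA interactions
#'
#' Accepts either a two-column delimited file (miRNA ID, mRNA ID; an optional
#' header line is detected when the first token is a column label such as
#' `mirna` or `mirna_id` rather than a feature ID) or the JSON pair list the
#' pipeline itself writes. Duplicate pairs are collapsed silently with a
#' logged count.
#'
#' @param path Path to the reference file.
#' @param delimiter Field separator for the text form (default tab).
#' @return An `interaction_reference`: a data frame with character columns
#'   `mirna` and `mrna`, one row per unique pair.
#' @export
read_reference <- function(path, delimiter = "\t") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_mircore(sprintf("reference file not found: %s", path),
                  class = "mircore_file_error")
  }
  raw <- readLines(path, warn = FALSE)
  first_char <- sub("^\\s*", "", paste(raw, collapse = ""))
  if (nzchar(first_char) && substr(first_char, 1L, 1L) %in% c("[", "{")) {
    parsed <- jsonlite::fromJSON(path)
    if (is.data.frame(parsed) && all(c("mirna", "mrna") %in% names(parsed))) {
      return(new_interaction_reference(parsed$mirna, parsed$mrna))
    }
    abort_mircore("JSON reference must be an array of {mirna, mrna} objects",
                  class = "mircore_parse_error")
  }
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    return(new_interaction_reference(character(0), character(0)))
  }
  fields <- strsplit(raw, delimiter, fixed = TRUE)
  nfld <- lengths(fields)
  bad <- which(nfld != 2L)
  if (length(bad)) {
    abort_mircore(sprintf("reference line %d has %d columns; expected 2", bad[1L], nfld[bad[1L]]),
                  class = "mircore_parse_error")
  }
  header_tokens <- c("mirna", "mirna_id", "mir", "mir_id", "microrna", "source")
  if (tolower(trimws(fields[[1L]][1L])) %in% header_tokens) {
    fields <- fields[-1L]
  }
  mirna <- vapply(fields, `[[`, character(1), 1L)
  mrna <- vapply(fields, `[[`, character(1), 2L)
  new_interaction_reference(mirna, mrna)
}

new_interaction_reference <- function(mirna, mrna) {
  key <- paste(mirna, mrna, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("read_reference: collapsed %d duplicate pair(s)", sum(dup)))
  }
  structure(
    data.frame(mirna = mirna[!dup], mrna = mrna[!dup], stringsAsFactors = FALSE),
    class = c("interaction_reference", "data.frame")
  )
}
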