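#' Read a canonicalization pair file
#'
#' Each line holds one training pair in reaction-like format,
#' \code{source >> canonical}. Whitespace around the \code{>>} delimiter is
#' tolerated on read; lines with zero or more than one delimiter are an error.
#'
#' @param path Path to the text file.
#' @return A data.frame with character columns \code{source} and \code{target}.
#' @export
read_pair_file <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("pair file is empty: ", path, call. = FALSE)
  n_delim <- lengths(gregexpr(">>", lines, fixed = TRUE))
  n_delim[!grepl(">>", lines, fixed = TRUE)] <- 0L
  bad <- which(n_delim != 1L)
  if (length(bad)) {
    stop(sprintf("malformed pair line %d (expected exactly one '>>'): %s",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  parts <- strsplit(lines, ">>", fixed = TRUE)
  src <- trimws(vapply(parts, `[`, "", 1L))
  dst <- trimws(vapply(parts, `[`, "", 2L))
  if (any(!nzchar(src)) || any(!nzchar(dst)))
    stop("empty SMILES on one side of a pair", call. = FALSE)
  data.frame(source = src, target = dst, stringsAsFactors = FALSE)
}

#' Write canonicalization pairs
#'
#' Canonical serialized form is \code{"src >> dst"} with single spaces, one
#' pair per line; \code{read_pair_file(write_pair_file(x)) == x}.
#'
#' @param pairs data.frame with columns \code{source}, \code{target}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pair_file <- function(pairs, path) {
  stopifnot(all(c("source", "target") %in% names(pairs)))
  writeLines(paste(pairs$source, ">>", pairs$target), path)
  invisible(path)
}

#' Read a QSAR table from CSV
#'
#' Rows whose target is not a finite number or whose SMILES does not tokenize
#' under the vocabulary are dropped, with a message reporting the count.
#'
#' @param path CSV path.
#' @param smiles_col,y_col Column names for structure and endpoint.
#' @param id_col Optional id column; row numbers are used when absent.
#' @param vocab Vocabulary used to validate SMILES.
#' @return data.frame with columns \code{id}, \code{smiles}, \code{y}.
#' @export
read_qsar_csv <- function(path, smiles_col = "smiles", y_col = "y",
                          id_col = NULL, vocab = smiles_vocabulary()) {
  if (!file.exists(path)) stop("QSAR file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(smiles_col, y_col))
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  ids <- if (!is.null(id_col) && id_col %in% names(df)) as.character(df[[id_col]])
         else as.character(seq_len(nrow(df)))
  smiles <- normalize_smiles_text(as.character(df[[smiles_col]]))
  y <- suppressWarnings(as.numeric(df[[y_col]]))
  tokenizable <- vapply(smiles, function(s)
    !inherits(try(tokenize(s, vocab), silent = TRUE), "try-error"), TRUE)
  keep <- is.finite(y) & nzchar(smiles) & tokenizable
  if (any(!keep))
    message(sum(!keep), " row(s) dropped (unparsable target or SMILES)")
  out <- data.frame(id = ids[keep], smiles = smiles[keep], y = y[keep],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("no usable rows in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}
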