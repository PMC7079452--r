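#' Character vocabulary for SMILES models
#'
#' The fixed character set covers the diversity of drug-like SMILES:
#' organic-subset and bracket atoms, charges, stereo markers, ring closures
#' and branching. Tokenization is strictly character-level: two-letter
#' elements such as \code{Br} and \code{Cl} are deliberately kept as two
#' tokens, since more elaborate merging schemes do not improve accuracy for
#' canonicalization-style models. The caret \code{^} marks sequence start and
#' the dollar \code{$} sequence end. A distinct padding id (never a printable
#' symbol) completes the vocabulary at 66 entries.
#'
#' @return An object of class \code{smiles_vocabulary} with fields
#'   \code{symbols} (ordered character vector), \code{index} (named integer
#'   map symbol -> id), \code{start_id}, \code{end_id}, \code{pad_id} and
#'   \code{size} (number of ids including the pad).
#' @examples
#' v <- smiles_vocabulary()
#' v$size            # 66
#' tokenize("CCO", v)
#' @export
smiles_vocabulary <- function() {
  symbols <- c(
    "^", "#", "%", "(", ")", "+", "-", ".", "/",
    as.character(0:9), "=", "@",
    "A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "O",
    "P", "R", "S", "T", "V", "X", "Y", "Z",
    "[", "\\", "]",
    "a", "b", "c", "d", "e", "f", "g", "i", "l", "m", "n", "o", "p", "r",
    "s", "t", "u", "y",
    "$"
  )
  stopifnot(!anyDuplicated(symbols))
  index <- seq_along(symbols)
  names(index) <- symbols
  v <- list(
    symbols = symbols,
    index = index,
    start_marker = "^",
    end_marker = "$",
    start_id = unname(index[["^"]]),
    end_id = unname(index[["$"]]),
    pad_id = length(symbols) + 1L,
    size = length(symbols) + 1L
  )
  class(v) <- "smiles_vocabulary"
  v
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("SMILES character vocabulary:", length(x$symbols), "symbols + pad id",
      x$pad_id, "\n")
  invisible(x)
}

# En dash occasionally appears in typeset SMILES sources; SMILES itself only
# uses the ASCII hyphen.
normalize_smiles_text <- function(s) gsub("–", "-", s)

#' Tokenize a SMILES string
#'
#' Character-level encoding with start/end markers. Unknown characters are a
#' hard error (silently skipping them would corrupt the position-to-atom
#' alignment the relevance engine relies on).
#'
#' @param smiles SMILES string (single string).
#' @param vocab A \code{\link{smiles_vocabulary}}.
#' @return An object of class \code{token_sequence}: list with \code{ids}
#'   (integer vector, first is start marker, last end marker) and \code{text}.
#' @examples
#' ts <- tokenize("Brc1ccccc1", smiles_vocabulary())
#' length(ts$ids)  # 12: 'Br' stays two tokens
#' @export
tokenize <- function(smiles, vocab = smiles_vocabulary()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  smiles <- normalize_smiles_text(smiles)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  ids <- unname(vocab$index[chars])
  bad <- which(is.na(ids))
  if (length(bad)) {
    stop(sprintf("unknown character '%s' at position %d in SMILES '%s'",
                 chars[bad[1]], bad[1], smiles), call. = FALSE)
  }
  out <- list(ids = c(vocab$start_id, as.integer(ids), vocab$end_id),
              text = smiles)
  class(out) <- "token_sequence"
  out
}

#' Decode a token sequence back to its SMILES string
#'
#' @param seq A \code{token_sequence} or a bare integer id vector (markers
#'   included).
#' @param vocab A \code{\link{smiles_vocabulary}}.
#' @return The character string between the markers.
#' @export
detokenize <- function(seq, vocab = smiles_vocabulary()) {
  ids <- if (inherits(seq, "token_sequence")) seq$ids else as.integer(seq)
  if (length(ids) < 2L)
    stop("token sequence needs at least start and end markers", call. = FALSE)
  if (any(ids < 1L | ids > length(vocab$symbols)))
    stop("token id outside vocabulary: ",
         paste(ids[ids < 1L | ids > length(vocab$symbols)], collapse = ", "),
         call. = FALSE)
  if (ids[1] != vocab$start_id || ids[length(ids)] != vocab$end_id)
    stop("token sequence must start with '^' and end with '$'", call. = FALSE)
  body <- ids[-c(1L, length(ids))]
  if (any(body == vocab$start_id | body == vocab$end_id))
    stop("marker id inside the sequence body", call. = FALSE)
  paste(vocab$symbols[body], collapse = "")
}
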