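# Dynamic SMILES embeddings: the frozen encoder's per-position output.

#' Extract the dynamic embedding of one SMILES
#'
#' Runs the encoder only (no dropout, weights untouched) and returns the
#' positions-by-d_model matrix. Rows cover all tokens including the start
#' and end markers; the same character at different positions gets different
#' rows because the representation is contextual.
#'
#' @param model A \code{canonicalizer} (trained or freshly initialized).
#' @param smiles SMILES string.
#' @return Object of class \code{dynamic_embedding}: list with
#'   \code{matrix} ((n_char + 2) x d_model), \code{tokens} (the
#'   \code{token_sequence}) and \code{smiles}.
#' @export
extract_embedding <- function(model, smiles) {
  stopifnot(inherits(model, "canonicalizer"))
  ts <- tokenize(smiles, model$vocab)
  ids <- matrix(ts$ids, 1L)
  enc <- encoder_fwd(model, ids, matrix(TRUE, 1L, length(ts$ids)))
  out <- list(matrix = enc$H, tokens = ts, smiles = smiles)
  class(out) <- "dynamic_embedding"
  out
}

#' Batch embedding extraction
#'
#' Pads and masks a batch so that, up to floating tolerance, every returned
#' matrix equals the single-item extraction.
#'
#' @param model A \code{canonicalizer}.
#' @param smiles_list Character vector.
#' @param chunk Batch size per forward pass.
#' @return List of \code{dynamic_embedding}, in input order.
#' @export
batch_extract <- function(model, smiles_list, chunk = 64L) {
  stopifnot(length(smiles_list) >= 1L)
  vocab <- model$vocab
  out <- vector("list", length(smiles_list))
  for (start in seq(1L, length(smiles_list), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(smiles_list))
    toks <- lapply(smiles_list[idx], function(s) {
      r <- tryCatch(tokenize(s, vocab), error = function(e)
        stop("item ", which(smiles_list == s)[1], ": ", conditionMessage(e),
             call. = FALSE))
      r
    })
    ids_mat <- pad_batch(lapply(toks, `[[`, "ids"), vocab$pad_id)
    mask <- ids_mat != vocab$pad_id
    enc <- encoder_fwd(model, ids_mat, mask)
    L <- ncol(ids_mat)
    for (j in seq_along(idx)) {
      n <- length(toks[[j]]$ids)
      rows <- ((j - 1L) * L + 1L):((j - 1L) * L + n)
      e <- list(matrix = enc$H[rows, , drop = FALSE], tokens = toks[[j]],
                smiles = smiles_list[idx[j]])
      class(e) <- "dynamic_embedding"
      out[[idx[j]]] <- e
    }
  }
  out
}
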