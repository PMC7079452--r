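# Chemistry-toolkit oracle backed by RDKit, reached through the system
# Python. Each R-level call is one batched subprocess invocation; callers
# that need many molecules should pass vectors.

rdkit_call <- function(requests, python = Sys.which("python")) {
  if (!nzchar(python)) stop("no python interpreter on PATH", call. = FALSE)
  script <- system.file("python", "rdkit_oracle.py", package = "smiqsar")
  if (!nzchar(script)) script <- file.path("inst", "python", "rdkit_oracle.py")
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(requests, infile, auto_unbox = TRUE, null = "null")
  out <- suppressWarnings(
    system2(python, shQuote(script), stdout = TRUE, stderr = FALSE,
            stdin = infile))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("rdkit oracle subprocess failed (is rdkit installed?)",
         call. = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

#' RDKit-backed canonicalization oracle
#'
#' Same interface as \code{\link{grammar_oracle}} but delegating to RDKit
#' (via the system Python) for canonical SMILES, seeded atom-renumbering
#' variants, atom-rooted writings and heavy-atom counts. Handles general
#' SMILES including rings, aromaticity and stereochemistry.
#'
#' @param python Path to the Python interpreter with rdkit installed.
#' @return A \code{canon_oracle}.
#' @export
rdkit_oracle <- function(python = Sys.which("python")) {
  one <- function(op, smiles, arg = NULL) {
    res <- rdkit_call(list(list(op = op, smiles = smiles, arg = arg)),
                      python)[[1]]
    if (!is.null(res$error)) stop(res$error, call. = FALSE)
    res
  }
  o <- list(
    name = "rdkit",
    canonical = function(smiles) {
      res <- rdkit_call(lapply(smiles, function(s)
        list(op = "canonical", smiles = s, arg = NULL)), python)
      vapply(res, function(r) {
        if (!is.null(r$error)) stop(r$error, call. = FALSE)
        r$smiles
      }, "")
    },
    random_variant = function(smiles, seed)
      one("variant", smiles, as.integer(seed))$smiles,
    rooted_variant = function(smiles, atom_index) {
      # atom_index is 1-based on the R side
      res <- one("rooted", smiles, as.integer(atom_index) - 1L)
      structure(res$smiles,
                atom_order = vapply(res$order, function(i) i + 1L, 1L))
    },
    heavy_atom_count = function(smiles) {
      res <- rdkit_call(lapply(smiles, function(s)
        list(op = "natoms", smiles = s, arg = NULL)), python)
      vapply(res, function(r) {
        if (!is.null(r$error)) stop(r$error, call. = FALSE)
        as.integer(r$n)
      }, 1L)
    }
  )
  class(o) <- "canon_oracle"
  o
}
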