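#' Augmentation policy
#'
#' Ten-fold enumeration of alternative SMILES writings of each molecule,
#' plus the canonical form itself, is used during both training and
#' prediction; ten was found optimal in prior augmentation studies and is
#' the default here.
#'
#' @param n_augment Number of enumerated variants per molecule.
#' @param include_identity Include the canonical->canonical identity line in
#'   pair generation (so each molecule appears \code{n_augment + 1} times).
#' @param seed Base RNG seed for variant sampling.
#' @export
augmentation_policy <- function(n_augment = 10L, include_identity = TRUE,
                                seed = 1L) {
  stopifnot(n_augment >= 0L)
  structure(list(n_augment = as.integer(n_augment),
                 include_identity = isTRUE(include_identity),
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

#' Enumerate alternative SMILES for one molecule
#'
#' Variants are sampled with replacement (duplicates possible for small
#' molecules); every variant canonicalizes back to the input's canonical
#' form under the same oracle, and the sample is deterministic given the
#' seed.
#'
#' @param smiles Single SMILES string.
#' @param n Number of variants.
#' @param seed RNG seed.
#' @param oracle A \code{canon_oracle} (\code{\link{grammar_oracle}} or
#'   \code{\link{rdkit_oracle}}).
#' @return Character vector of length \code{n}.
#' @export
enumerate_smiles <- function(smiles, n, seed = 1L, oracle = grammar_oracle()) {
  stopifnot(length(smiles) == 1L, n >= 0L)
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(k)
    oracle$random_variant(smiles, derive_seed(seed, k)), "")
}

#' Build canonicalization training pairs
#'
#' Every molecule contributes \code{n_augment} (variant -> canonical) lines
#' plus, when \code{include_identity}, one canonical -> canonical line: 11
#' lines per molecule under the defaults.
#'
#' @param molecules Character vector of SMILES.
#' @param policy An \code{\link{augmentation_policy}}.
#' @param oracle A \code{canon_oracle}.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{parent}.
#' @export
make_canonicalization_pairs <- function(molecules,
                                        policy = augmentation_policy(),
                                        oracle = grammar_oracle()) {
  stopifnot(inherits(policy, "augmentation_policy"), length(molecules) >= 1L)
  out <- vector("list", length(molecules))
  for (i in seq_along(molecules)) {
    canon <- tryCatch(oracle$canonical(molecules[i]), error = function(e)
      stop("molecule ", i, " (", molecules[i], "): ", conditionMessage(e),
           call. = FALSE))
    vars <- enumerate_smiles(molecules[i], policy$n_augment,
                             derive_seed(policy$seed, i), oracle)
    src <- c(vars, if (policy$include_identity) canon)
    if (!length(src)) next
    out[[i]] <- data.frame(source = src, target = canon, parent = i,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Augment a QSAR dataset by SMILES enumeration
#'
#' Each record expands to its canonical SMILES plus \code{n_augment}
#' variants, all carrying the parent's endpoint value and id, so that
#' consensus grouping and leakage-safe (parent-level) splitting remain
#' possible downstream. Records the oracle cannot parse are dropped with a
#' message.
#'
#' @param records data.frame with columns \code{id}, \code{smiles}, \code{y}
#'   (as from \code{\link{read_qsar_csv}}).
#' @param policy An \code{\link{augmentation_policy}}.
#' @param oracle A \code{canon_oracle}.
#' @return data.frame with columns \code{id}, \code{smiles}, \code{y},
#'   \code{variant} (0 for the canonical row).
#' @export
augment_qsar_dataset <- function(records, policy = augmentation_policy(),
                                 oracle = grammar_oracle()) {
  stopifnot(all(c("id", "smiles", "y") %in% names(records)))
  out <- vector("list", nrow(records))
  dropped <- 0L
  for (i in seq_len(nrow(records))) {
    canon <- tryCatch(oracle$canonical(records$smiles[i]),
                      error = function(e) NA_character_)
    if (is.na(canon)) { dropped <- dropped + 1L; next }
    vars <- enumerate_smiles(records$smiles[i], policy$n_augment,
                             derive_seed(policy$seed, i), oracle)
    out[[i]] <- data.frame(id = records$id[i],
                           smiles = c(canon, vars),
                           y = records$y[i],
                           variant = seq_len(length(vars) + 1L) - 1L,
                           stringsAsFactors = FALSE)
  }
  if (dropped) message(dropped, " record(s) dropped (oracle parse failure)")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no augmentable records", call. = FALSE)
  rownames(res) <- NULL
  res
}
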