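# Synthetic molecule fixtures: acyclic toy molecules over a small element
# palette, a self-defined canonical (normal) form, seeded SMILES variants and
# planted-property QSAR datasets. Everything here is chemistry-toolkit-free
# so the full pipeline is testable offline; an RDKit-backed oracle with the
# same interface lives in oracle-rdkit.R.

SUBSET_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                    F = 1L, Cl = 1L, Br = 1L, I = 1L)
HALOGENS <- c("F", "Cl", "Br", "I")

# --- subset SMILES parser -------------------------------------------------
# Grammar: acyclic, single bonds only, elements from SUBSET_VALENCE
# (two-letter Cl/Br), branches with parentheses. Returns elements in order
# of appearance and an edge list.
parse_subset_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- character(0)
  edges <- matrix(integer(0), ncol = 2)
  pos <- 1L

  read_atom <- function() {
    two <- if (pos < n) paste0(chars[pos], chars[pos + 1L]) else ""
    el <- if (two %in% c("Cl", "Br")) two else chars[pos]
    if (!el %in% names(SUBSET_VALENCE))
      stop(sprintf("cannot parse '%s' at position %d of '%s'",
                   el, pos, smiles), call. = FALSE)
    pos <<- pos + nchar(el)
    elements[length(elements) + 1L] <<- el
    length(elements)
  }

  parse_chain <- function(parent) {
    last <- parent
    while (pos <= n) {
      ch <- chars[pos]
      if (ch == "(") {
        if (last == 0L) stop("branch before any atom in '", smiles, "'",
                             call. = FALSE)
        pos <<- pos + 1L
        parse_chain(last)
        if (pos > n || chars[pos] != ")")
          stop("unbalanced '(' in '", smiles, "'", call. = FALSE)
        pos <<- pos + 1L
      } else if (ch == ")") {
        return(invisible(NULL))
      } else {
        a <- read_atom()
        if (last != 0L) edges <<- rbind(edges, c(last, a))
        last <- a
      }
    }
    invisible(NULL)
  }

  parse_chain(0L)
  if (pos <= n) stop("unbalanced ')' in '", smiles, "'", call. = FALSE)
  if (!length(elements)) stop("empty SMILES", call. = FALSE)
  list(elements = elements, edges = edges)
}

mol_adjacency <- function(mol) {
  adj <- vector("list", length(mol$elements))
  if (nrow(mol$edges)) {
    for (k in seq_len(nrow(mol$edges))) {
      i <- mol$edges[k, 1]; j <- mol$edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Write the tree rooted at `root`. `orderer` permutes each child list; the
# last child in the returned order continues the chain, earlier ones are
# parenthesized branches. Returns the string and the atom output order.
write_subset_smiles <- function(mol, root, orderer = identity) {
  adj <- mol_adjacency(mol)
  order_out <- integer(0)
  rec <- function(a, parent) {
    order_out[length(order_out) + 1L] <<- a
    kids <- setdiff(adj[[a]], parent)
    if (!length(kids)) return(mol$elements[a])
    kids <- orderer(kids)
    parts <- character(length(kids))
    for (i in seq_along(kids)) parts[i] <- rec(kids[i], a)
    k <- length(parts)
    paste0(mol$elements[a],
           if (k > 1) paste0("(", parts[-k], ")", collapse = "") else "",
           parts[k])
  }
  s <- rec(root, 0L)
  list(smiles = s, order = order_out)
}

# Normal form: for every possible root write the tree with children ordered
# by their (recursively normalized) subtree strings, ascending in C-locale;
# the lexicographically smallest full string wins. Idempotent by
# construction since it only depends on the abstract labelled tree.
canonical_subset_smiles <- function(smiles) {
  mol <- if (is.character(smiles)) parse_subset_smiles(smiles) else smiles
  adj <- mol_adjacency(mol)
  sub <- function(a, parent) {
    kids <- setdiff(adj[[a]], parent)
    if (!length(kids)) return(mol$elements[a])
    parts <- sort(vapply(kids, sub, "", a), method = "radix")
    k <- length(parts)
    paste0(mol$elements[a],
           if (k > 1) paste0("(", parts[-k], ")", collapse = "") else "",
           parts[k])
  }
  cand <- vapply(seq_along(mol$elements), sub, "", 0L)
  cand[order(cand, method = "radix")[1]]
}

# Deterministic rooted writing with canonically ordered children; the atom
# output order (original indices, in order of appearance in the string) is
# attached as an attribute for attribution bookkeeping.
rooted_subset_smiles <- function(smiles, atom_index) {
  mol <- parse_subset_smiles(smiles)
  if (atom_index < 1L || atom_index > length(mol$elements))
    stop("atom index out of range", call. = FALSE)
  adj <- mol_adjacency(mol)
  sub_str <- function(a, parent) {
    kids <- setdiff(adj[[a]], parent)
    if (!length(kids)) return(mol$elements[a])
    parts <- sort(vapply(kids, sub_str, "", a), method = "radix")
    k <- length(parts)
    paste0(mol$elements[a],
           if (k > 1) paste0("(", parts[-k], ")", collapse = "") else "",
           parts[k])
  }
  canon_order <- function(kids, a) kids[order(vapply(kids, sub_str, "", a),
                                              method = "radix")]
  order_out <- integer(0)
  rec <- function(a, parent) {
    order_out[length(order_out) + 1L] <<- a
    kids <- setdiff(adj[[a]], parent)
    if (!length(kids)) return(mol$elements[a])
    kids <- canon_order(kids, a)
    parts <- character(length(kids))
    for (i in seq_along(kids)) parts[i] <- rec(kids[i], a)
    k <- length(parts)
    paste0(mol$elements[a],
           if (k > 1) paste0("(", parts[-k], ")", collapse = "") else "",
           parts[k])
  }
  s <- rec(atom_index, 0L)
  structure(s, atom_order = order_out)
}

random_subset_variant <- function(smiles, seed) {
  mol <- parse_subset_smiles(smiles)
  with_seed(seed, {
    root <- sample.int(length(mol$elements), 1L)
    write_subset_smiles(mol, root, orderer = function(k)
      if (length(k) > 1L) k[sample.int(length(k))] else k)$smiles
  })
}

#' Pure-grammar canonicalization oracle
#'
#' A chemistry-toolkit-free implementation of the canonicalization-oracle
#' interface for the acyclic toy subset of SMILES (elements C, N, O, S, P,
#' F, Cl, Br, I; single bonds; branches). The normal form is the
#' lexicographically smallest rooted writing with sorted branches. Useful to
#' exercise the whole pipeline (pair generation, seq2seq training, rooted
#' attribution) without RDKit.
#'
#' @return A \code{canon_oracle}: list of functions \code{canonical(smiles)},
#'   \code{random_variant(smiles, seed)}, \code{rooted_variant(smiles,
#'   atom_index)} (returns the string with an \code{atom_order} attribute
#'   mapping output order to input atom indices), and
#'   \code{heavy_atom_count(smiles)}.
#' @seealso \code{\link{rdkit_oracle}}
#' @export
grammar_oracle <- function() {
  o <- list(
    name = "grammar",
    canonical = function(smiles)
      vapply(smiles, canonical_subset_smiles, "", USE.NAMES = FALSE),
    random_variant = function(smiles, seed)
      random_subset_variant(smiles, seed),
    rooted_variant = function(smiles, atom_index)
      rooted_subset_smiles(smiles, atom_index),
    heavy_atom_count = function(smiles)
      vapply(smiles, function(s) length(parse_subset_smiles(s)$elements),
             1L, USE.NAMES = FALSE)
  )
  class(o) <- "canon_oracle"
  o
}

# --- toy libraries and planted properties ---------------------------------

#' Specification for a toy molecule library
#'
#' @param n_molecules Number of distinct molecules to generate.
#' @param max_heavy_atoms Largest tree size (heavy atoms).
#' @param palette Named probability weights over elements used when growing
#'   trees. Defaults to a mostly-carbon organic palette with ~25 percent
#'   heteroatoms/halogens, giving halogen counts that vary from 0 to about 3
#'   per molecule.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @export
toy_library_spec <- function(n_molecules = 300L, max_heavy_atoms = 9L,
                             palette = c(C = 0.55, N = 0.10, O = 0.14,
                                         F = 0.07, Cl = 0.07, Br = 0.07),
                             seed = 1L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 2L,
            all(names(palette) %in% names(SUBSET_VALENCE)))
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 palette = palette / sum(palette), seed = as.integer(seed)),
            class = "toy_library_spec")
}

grow_random_tree <- function(n_atoms, palette) {
  elements <- "C"  # carbon root guarantees the tree can grow
  free <- SUBSET_VALENCE[["C"]]
  edges <- matrix(integer(0), ncol = 2)
  while (length(elements) < n_atoms) {
    open <- which(free > 0L)
    if (!length(open)) break
    parent <- if (length(open) == 1L) open else
      sample(open, 1L, prob = free[open])
    el <- sample(names(palette), 1L, prob = palette)
    elements <- c(elements, el)
    a <- length(elements)
    edges <- rbind(edges, c(parent, a))
    free[parent] <- free[parent] - 1L
    free <- c(free, SUBSET_VALENCE[[el]] - 1L)
  }
  list(elements = elements, edges = edges)
}

#' Generate a toy molecule library
#'
#' Random acyclic molecules (alkane/amine/ether/halide-like trees) emitted
#' as normal-form SMILES, distinct within the library, deterministic under
#' the spec's seed.
#'
#' @param spec A \code{\link{toy_library_spec}}.
#' @return Character vector of \code{n_molecules} canonical (normal-form)
#'   SMILES.
#' @export
generate_toy_library <- function(spec = toy_library_spec()) {
  stopifnot(inherits(spec, "toy_library_spec"))
  with_seed(spec$seed, {
    seen <- character(0)
    tries <- 0L
    while (length(seen) < spec$n_molecules && tries < spec$n_molecules * 60L) {
      tries <- tries + 1L
      n_atoms <- sample(3:spec$max_heavy_atoms, 1L)
      mol <- grow_random_tree(n_atoms, spec$palette)
      s <- canonical_subset_smiles(mol)
      if (!s %in% seen) seen <- c(seen, s)
    }
    if (length(seen) < spec$n_molecules)
      stop("could not generate ", spec$n_molecules, " distinct molecules; ",
           "increase max_heavy_atoms", call. = FALSE)
    seen
  })
}

#' Canonicalization pairs from the grammar normal form
#'
#' Desk-scale stand-in for a large canonicalization corpus: for every library
#' molecule, \code{n_variants} seeded random rewritings paired with the
#' normal form, plus one identity line (canonical on both sides). With the
#' default \code{n_variants = 10} each molecule contributes 11 lines.
#'
#' @param library Character vector of SMILES (any subset-grammar writing).
#' @param n_variants Variants per molecule.
#' @param seed Seed for variant sampling.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{parent} (library index).
#' @export
grammar_canonical_pairs <- function(library, n_variants = 10L, seed = 1L) {
  oracle <- grammar_oracle()
  canon <- oracle$canonical(library)
  out <- vector("list", length(library))
  for (i in seq_along(library)) {
    vars <- if (n_variants > 0L)
      vapply(seq_len(n_variants), function(k)
        oracle$random_variant(library[i], derive_seed(seed, i * 1000L + k)),
        "")
    else character(0)
    out[[i]] <- data.frame(source = c(vars, canon[i]),
                           target = canon[i], parent = i,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Define a planted structure-property rule
#'
#' Ground truth for attribution experiments: a linear atom-count rule whose
#' per-atom contributions are known exactly.
#'
#' @param betas Named coefficients over atom classes; supported classes are
#'   \code{halogen}, \code{oxygen}, \code{nitrogen}. Default is the
#'   halogen-count rule y = 2 * n_halogen.
#' @param noise_sd Gaussian noise added to regression targets.
#' @param task \code{"regression"} or \code{"classification"}; classification
#'   labels molecules by presence of the first named atom class, planted at
#'   a controlled prevalence.
#' @param prevalence Positive-class fraction planted for classification.
#' @export
planted_property <- function(betas = c(halogen = 2), noise_sd = 0.1,
                             task = c("regression", "classification"),
                             prevalence = 0.5) {
  task <- match.arg(task)
  stopifnot(length(betas) >= 1L, !is.null(names(betas)),
            all(names(betas) %in% c("halogen", "oxygen", "nitrogen")),
            noise_sd >= 0, prevalence > 0, prevalence < 1)
  structure(list(betas = betas, noise_sd = noise_sd, task = task,
                 prevalence = prevalence), class = "planted_property")
}

atom_class_members <- function(cls) {
  switch(cls, halogen = HALOGENS, oxygen = "O", nitrogen = "N",
         stop("unknown atom class ", cls))
}

#' Build a planted-property QSAR dataset with atom-level ground truth
#'
#' Regression: y is the linear atom-count rule plus Gaussian noise, so the
#' true contribution of every atom is its class coefficient.
#' Classification: a \code{prevalence} fraction of molecules carries the
#' motif (first atom class of the rule); the generator plants or strips a
#' terminal atom of that class so the label is exact by construction.
#'
#' @param library Character vector of subset-grammar SMILES.
#' @param planted A \code{\link{planted_property}}.
#' @param seed RNG seed.
#' @return list with \code{records} (data.frame id, smiles, y) and
#'   \code{atom_truth}: per molecule, a numeric vector of true per-atom
#'   contributions aligned with atom appearance order in \code{smiles}.
#' @export
make_planted_dataset <- function(library, planted = planted_property(),
                                 seed = 1L) {
  stopifnot(inherits(planted, "planted_property"))
  with_seed(seed, {
    smiles <- library
    if (planted$task == "classification") {
      cls <- atom_class_members(names(planted$betas)[1])
      n_pos <- round(planted$prevalence * length(smiles))
      pos_idx <- sample.int(length(smiles), n_pos)
      smiles <- vapply(seq_along(smiles), function(i)
        plant_or_strip(smiles[i], cls, plant = i %in% pos_idx), "")
    }
    truth <- lapply(smiles, function(s) {
      mol <- parse_subset_smiles(s)
      contrib <- numeric(length(mol$elements))
      for (cls in names(planted$betas)) {
        hit <- mol$elements %in% atom_class_members(cls)
        contrib[hit] <- contrib[hit] + planted$betas[[cls]]
      }
      contrib
    })
    y <- if (planted$task == "regression") {
      vapply(truth, sum, 0) + stats::rnorm(length(truth), 0, planted$noise_sd)
    } else {
      as.numeric(vapply(truth, function(tr) any(tr != 0), TRUE))
    }
    list(records = data.frame(id = as.character(seq_along(smiles)),
                              smiles = smiles, y = y,
                              stringsAsFactors = FALSE),
         atom_truth = truth)
  })
}

# Plant (or remove) a terminal atom of the given class; used to control
# classification prevalence exactly.
plant_or_strip <- function(smiles, cls, plant) {
  mol <- parse_subset_smiles(smiles)
  has <- mol$elements %in% cls
  if (plant && !any(has)) {
    deg <- tabulate(c(mol$edges), nbins = length(mol$elements))
    term_c <- which(mol$elements == "C" & deg == 1L)
    if (length(term_c)) mol$elements[term_c[1]] <- cls[1]
    else {  # no terminal carbon: attach a fresh halogen to an open atom
      free <- SUBSET_VALENCE[mol$elements] - deg
      open <- which(free > 0L)
      mol$elements <- c(mol$elements, cls[1])
      mol$edges <- rbind(mol$edges, c(open[1], length(mol$elements)))
    }
  } else if (!plant && any(has)) {
    mol$elements[has] <- "C"
  }
  canonical_subset_smiles(mol)
}
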