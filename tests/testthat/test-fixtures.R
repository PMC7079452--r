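test_that("toy library generation is seed-deterministic and tokenizable", {
  spec <- toy_library_spec(n_molecules = 100L, seed = 7L)
  lib1 <- generate_toy_library(spec)
  lib2 <- generate_toy_library(spec)
  expect_identical(lib1, lib2)
  expect_equal(length(lib1), 100L)
  expect_false(anyDuplicated(lib1) > 0)
  v <- smiles_vocabulary()
  for (s in lib1) expect_silent(tokenize(s, v))
})

test_that("grammar normal form is idempotent and variant-invariant", {
  o <- grammar_oracle()
  lib <- small_library()
  canon <- o$canonical(lib)
  expect_identical(o$canonical(canon), canon)
  for (i in seq_along(lib)[1:40]) {
    for (k in 1:3) {
      var <- o$random_variant(lib[i], seed = 100L * i + k)
      expect_identical(o$canonical(var), canon[i])
    }
  }
})

test_that("rooted variants cover every atom and report the output order", {
  o <- grammar_oracle()
  s <- "CC(Cl)C(N)O"
  n <- o$heavy_atom_count(s)
  expect_equal(n, 6L)
  for (a in seq_len(n)) {
    r <- o$rooted_variant(s, a)
    ord <- attr(r, "atom_order")
    expect_equal(sort(ord), seq_len(n))
    expect_equal(ord[1], a)  # rooted at the requested atom
    expect_identical(o$canonical(as.character(r)), o$canonical(s))
  }
  expect_error(o$rooted_variant(s, 7L), "range")
})

test_that("grammar pair fixture: counts, normal-form targets, functionality", {
  lib <- small_library()[1:20]
  pairs <- grammar_canonical_pairs(lib, n_variants = 10L, seed = 1L)
  expect_equal(nrow(pairs), 20L * 11L)
  expect_equal(as.integer(table(pairs$parent)), rep(11L, 20L))
  o <- grammar_oracle()
  expect_identical(o$canonical(unique(pairs$target)), unique(pairs$target))
  # variant -> target mapping is a function: no source maps to two targets
  agg <- tapply(pairs$target, pairs$source, function(x) length(unique(x)))
  expect_true(all(agg == 1L))
  # each molecule carries an identity line (appended last per molecule;
  # random variants may additionally coincide with the canonical form)
  ident <- pairs$source == pairs$target
  expect_true(all(tapply(ident, pairs$parent, sum) >= 1L))
  last_per_parent <- cumsum(rep(11L, 20L))
  expect_identical(pairs$source[last_per_parent], pairs$target[last_per_parent])
})

test_that("planted regression dataset matches its rule exactly at zero noise", {
  lib <- small_library()[1:30]
  ds <- make_planted_dataset(lib, planted_property(betas = c(halogen = 2),
                                                   noise_sd = 0), seed = 1L)
  hal_count <- vapply(ds$atom_truth, function(tr) sum(tr != 0), 1L)
  expect_equal(ds$records$y, 2 * hal_count)
  # truth vectors align with atom counts
  o <- grammar_oracle()
  expect_equal(lengths(ds$atom_truth),
               unname(o$heavy_atom_count(ds$records$smiles)))
})

test_that("planted classification controls prevalence by construction", {
  lib <- small_library()
  pl <- planted_property(betas = c(halogen = 1), task = "classification",
                         prevalence = 0.5)
  ds <- make_planted_dataset(lib, pl, seed = 9L)
  expect_lt(abs(mean(ds$records$y) - 0.5), 0.05)
  # labels agree with halogen presence in the emitted structures
  has_hal <- grepl("F|Cl|Br|I", ds$records$smiles)
  expect_equal(as.numeric(has_hal), ds$records$y)
})

test_that("shuffling targets destroys the planted signal (negative control)", {
  ds <- make_planted_dataset(small_library(),
                             planted_property(noise_sd = 0.1), seed = 3L)
  y <- ds$records$y
  set.seed(11)
  y_shuf <- sample(y)
  # the shuffled targets carry no structure information at all
  expect_lt(abs(cor(y, y_shuf)), 0.35)
})

test_that("grammar oracle agrees with the chemistry toolkit on the toy set", {
  # one batched call into the RDKit-backed oracle
  o_tk <- rdkit_oracle()
  o_gr <- grammar_oracle()
  lib <- small_library()[1:30]
  ref <- o_tk$canonical(lib)  # all parse, or this errors
  expect_length(ref, 30L)
  # a grammar variant and its parent collapse to the same toolkit canonical
  vars <- vapply(seq_along(lib), function(i)
    o_gr$random_variant(lib[i], seed = i), "")
  expect_identical(o_tk$canonical(vars), ref)
  expect_equal(o_tk$heavy_atom_count(lib), o_gr$heavy_atom_count(lib))
})
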