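test_that("vocabulary has 66 ids, unique symbols and well-placed markers", {
  v <- smiles_vocabulary()
  expect_equal(v$size, 66L)
  expect_equal(length(v$symbols), 65L)
  expect_false(anyDuplicated(v$symbols) > 0)
  expect_identical(v$symbols[v$start_id], "^")
  expect_identical(v$symbols[v$end_id], "$")
  expect_false(v$pad_id %in% v$index)
  # index and symbol table are mutual inverses
  for (i in seq_along(v$symbols))
    expect_equal(unname(v$index[[v$symbols[i]]]), i)
})

test_that("tokenize is strictly character-level with markers", {
  v <- smiles_vocabulary()
  ts <- tokenize("Brc1ccccc1", v)
  expect_s3_class(ts, "token_sequence")
  expect_length(ts$ids, 12L)  # 'Br' stays two tokens
  expect_identical(v$symbols[ts$ids[2:3]], c("B", "r"))
  expect_equal(ts$ids[1], v$start_id)
  expect_equal(ts$ids[length(ts$ids)], v$end_id)

  expect_equal(tokenize("", v)$ids, c(v$start_id, v$end_id))

  err <- tryCatch(tokenize("CC?O", v), error = identity)
  expect_match(conditionMessage(err), "'\\?'")
  expect_match(conditionMessage(err), "position 3")
})

test_that("tokenize/detokenize are mutual inverses on 200+ SMILES", {
  v <- smiles_vocabulary()
  strings <- c(generate_toy_library(toy_library_spec(200L, seed = 3L)),
               drug_smiles)
  for (s in strings)
    expect_identical(detokenize(tokenize(s, v), v), s)
  # en dash normalizes to hyphen on the way in
  expect_identical(detokenize(tokenize("C/C=C–C", v), v), "C/C=C-C")
})

test_that("detokenize validates ids and markers", {
  v <- smiles_vocabulary()
  expect_identical(detokenize(c(v$start_id, v$index[["C"]], v$end_id), v), "C")
  expect_error(detokenize(c(v$start_id, 999L, v$end_id), v), "outside")
  expect_error(detokenize(c(v$index[["C"]], v$end_id), v), "start")
  expect_error(detokenize(c(v$start_id, v$start_id, v$end_id), v), "marker")
})

test_that("pair files parse, reject malformed lines, and round-trip", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("CC(O)C >> CC(C)O", "CCO>>CCO", "  CC  >>  CC  "), p)
  pairs <- read_pair_file(p)
  expect_equal(pairs$source, c("CC(O)C", "CCO", "CC"))
  expect_equal(pairs$target, c("CC(C)O", "CCO", "CC"))
  expect_identical(pairs$source[3], pairs$target[3])  # identity line

  writeLines(c("CCO >> CCO", "no delimiter here"), p)
  expect_error(read_pair_file(p), "line 2")
  writeLines(c("A >> B >> C"), p)
  expect_error(read_pair_file(p), "line 1")

  rnd <- grammar_canonical_pairs(small_library()[1:10], n_variants = 4L,
                                 seed = 2L)[, c("source", "target")]
  write_pair_file(rnd, p)
  expect_identical(read_pair_file(p), rnd)
})

test_that("read_qsar_csv drops bad rows with a message and validates columns", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCO", "CCN"), y = c(1.5, -2)), p,
            row.names = FALSE)
  recs <- read_qsar_csv(p)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$y, c(1.5, -2))

  write.csv(data.frame(smiles = c("CCO", "C?C", "CCC"),
                       y = c("1.0", "2.0", "NA")), p, row.names = FALSE)
  expect_message(recs <- read_qsar_csv(p), "2 row")
  expect_equal(recs$smiles, "CCO")

  expect_error(read_qsar_csv(p, y_col = "missing"), "missing column")

  lib <- small_library()
  write.csv(data.frame(smiles = lib, y = seq_along(lib)), p,
            row.names = FALSE)
  expect_equal(nrow(read_qsar_csv(p)), length(lib))
})
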