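test_that("pretraining schedule follows the warmup/decay formula with floor", {
  sched <- lr_schedule()  # factor 20, warmup 16000, floor 1e-4
  expect_equal(lr_at_step(16000, sched), 20 / 16000)          # peak 1.25e-3
  expect_equal(lr_at_step(400000, sched), 1e-4)               # 5e-5 floored
  expect_equal(lr_at_step(8000, sched), 20 * 0.5 / 16000)

  # peak sits exactly at warmup; floor respected everywhere (scaled grid)
  s <- lr_schedule(factor = 2, warmup = 100L, floor = 1e-4)
  grid <- 1:400
  lam <- lr_at_step(grid, s)
  expect_equal(grid[which.max(lam)], 100L)
  expect_true(all(lam >= s$floor))
  expect_true(all(diff(lam[1:100]) >= 0))    # warmup is nondecreasing
  expect_true(all(diff(lam[100:150]) <= 0))  # then decays
  expect_lt(max(abs(diff(lam))), 2.5e-4)     # no jumps (continuity proxy)
})

test_that("model forward has the contracted shapes", {
  m <- tiny_encoder()
  v <- m$vocab
  src <- lapply(c("CCO", "NC(C)O"), function(s) tokenize(s, v)$ids)
  tgt <- lapply(c("C(C)O", "C(C(C)N)O"), function(s) tokenize(s, v)$ids)
  res <- smiqsar:::canonicalizer_step(m, src, tgt, train = TRUE)
  expect_true(is.finite(res$loss))
  # grads exist for every parameter and match shapes
  expect_setequal(names(res$grads), names(m$params))
  for (nm in names(m$params))
    expect_equal(dim(res$grads[[nm]]), dim(m$params[[nm]]))
  # encoder output is (positions x d_model) per molecule
  e <- extract_embedding(m, "CCO")
  expect_equal(dim(e$matrix), c(5L, m$config$d_model))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(transformer_config(n_heads = 5L, d_model = 32L), "d_model")
  expect_error(transformer_config(dropout = 1), "dropout")
})

test_that("copy task reaches >99% char accuracy and loss stays finite", {
  lib <- generate_toy_library(toy_library_spec(n_molecules = 30L, seed = 7L))
  pairs <- data.frame(source = lib, target = lib)
  cfg <- transformer_config(n_layers = 1L, n_heads = 4L, d_model = 32L,
                            d_ff = 256L, dropout = 0, max_len = 40L,
                            label_smoothing = 0)
  m <- build_canonicalizer(cfg, seed = 3L)
  m <- train_canonicalizer(pairs, m, epochs = 100L, seed = 5L,
                           batch_size = 4L, lr = 2e-3)
  expect_true(all(is.finite(m$train_state$log$loss)))
  v <- m$vocab
  ids <- lapply(lib, function(s) tokenize(s, v)$ids)
  eval <- smiqsar:::canonicalizer_step(m, ids, ids, train = FALSE)
  expect_gt(eval$acc, 0.99)
  assign("copy_model", m, envir = .fixture_cache)
})

test_that("char accuracy increases over the first epochs on the grammar task", {
  lib <- small_library()[1:40]
  pairs <- grammar_canonical_pairs(lib, n_variants = 5L, seed = 2L)
  m <- build_canonicalizer(tiny_transformer_config(), seed = 2L)
  m <- train_canonicalizer(pairs, m, epochs = 3L, seed = 4L,
                           batch_size = 4L, lr = 2e-3)
  by_ep <- tapply(m$train_state$log$char_acc, m$train_state$log$epoch, mean)
  expect_gt(by_ep[[2]], by_ep[[1]])
  expect_gt(by_ep[[3]], by_ep[[1]])
})

test_that("greedy decoding terminates, is deterministic, and flags truncation", {
  m <- tiny_encoder()  # untrained
  d1 <- greedy_decode(m, "CC(Cl)C(N)O", max_len = 15L)
  d2 <- greedy_decode(m, "CC(Cl)C(N)O", max_len = 15L)
  expect_identical(as.character(d1), as.character(d2))
  expect_lte(nchar(d1), 15L)

  cp <- get("copy_model", envir = .fixture_cache)
  lib <- generate_toy_library(toy_library_spec(n_molecules = 30L, seed = 7L))
  dec <- vapply(lib[1:10], function(s) as.character(greedy_decode(cp, s)), "")
  expect_gt(mean(dec == lib[1:10]), 0.7)  # trained copy model mostly restores
})

test_that("canonicalization report counts subsets consistently", {
  m <- tiny_encoder()
  o <- grammar_oracle()
  inputs <- c(small_library()[1:8],
              vapply(small_library()[9:12], function(s)
                o$random_variant(s, 1L), ""))
  rep <- canonicalization_report(m, inputs, o)
  expect_equal(rep$all$n, 12L)
  expect_equal(rep$stereo$n, sum(grepl("@", inputs)))
  expect_equal(rep$cis_trans$n, sum(grepl("[/\\\\]", inputs)))
  expect_equal(rep$already_canonical,
               mean(inputs == o$canonical(inputs)))
  expect_true(rep$all$rate >= 0 && rep$all$rate <= 1)
  expect_length(rep$decoded, 12L)
})
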