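test_that("the published head geometry pools to width 1720", {
  cfg <- cnn_head_config()
  expect_equal(cfg$kernel_sizes, c(1:10, 15L, 20L))
  expect_equal(cfg$pooled_width, 1720L)  # 100 + 4*200 + 5*100 + 2*160
  head <- build_head(cfg, d_model = 16L)
  expect_equal(nrow(head$params$dense.W), 1720L)
  expect_equal(ncol(head$params$dense.W), 512L)
  expect_equal(ncol(head$params$`conv20.W`), 160L)
  expect_error(cnn_head_config(kernel_sizes = 1:3, filter_counts = 1:2),
               "length")
})

test_that("forward works on inputs shorter than the largest kernel", {
  head <- build_head(cnn_head_config(), d_model = 16L)
  Z <- matrix(rnorm(5 * 16), 5, 16)  # 5 positions vs kernel 20
  out <- smiqsar:::head_forward(head, Z)
  expect_true(is.finite(out$prediction))
})

test_that("classification head outputs a normalized 2-vector", {
  cfg <- cnn_head_config(kernel_sizes = 1:3, filter_counts = rep(4L, 3),
                         dense_width = 8L, task = "classification")
  head <- build_head(cfg, d_model = 8L)
  out <- smiqsar:::head_forward(head, matrix(rnorm(48), 6, 8))
  expect_length(out$prob, 2L)
  expect_equal(sum(out$prob), 1)
  expect_true(out$prediction >= 0 && out$prediction <= 1)
})

test_that("degenerate targets and tiny datasets are rejected", {
  enc <- tiny_encoder()
  lib <- small_library()[1:25]
  cfg <- cnn_head_config(kernel_sizes = 1:2, filter_counts = rep(4L, 2),
                         dense_width = 8L, max_epochs = 2L)
  const <- data.frame(id = as.character(1:25), smiles = lib, y = rep(1, 25))
  expect_error(train_qsar(const, enc, cfg), "zero-variance")
  few <- data.frame(id = as.character(1:5), smiles = lib[1:5], y = rnorm(5))
  expect_error(train_qsar(few, enc, cfg), "20 parent")
  onecls <- data.frame(id = as.character(1:25), smiles = lib, y = rep(1, 25))
  expect_error(train_qsar(onecls, enc,
                          cnn_head_config(kernel_sizes = 1:2,
                                          filter_counts = rep(4L, 2),
                                          dense_width = 8L,
                                          task = "classification")),
               "both classes")
})

test_that("training leaves the encoder byte-identical and restores best weights", {
  qm <- tiny_qsar()
  expect_identical(qm$encoder$params, tiny_encoder()$params)  # frozen
  expect_equal(qm$best_holdout_loss, min(qm$log$holdout_loss))
  expect_lte(qm$best_epoch, nrow(qm$log))
})

test_that("predictions are deterministic and pad-invariant", {
  qm <- tiny_qsar()
  s <- small_library()[1]
  expect_identical(predict_raw(qm, s), predict_raw(qm, s))
  # appending zero pad positions to the embedding does not change the output
  Z <- extract_embedding(qm$encoder, s)$matrix
  p1 <- smiqsar:::head_forward(qm$head, Z)$prediction
  p2 <- smiqsar:::head_forward(qm$head, rbind(Z, matrix(0, 7, ncol(Z))))$prediction
  expect_equal(p1, p2)
})

test_that("holdout split is at parent level (no augmentation leakage)", {
  qm <- tiny_qsar()
  expect_true(length(qm$holdout_parents) >= 1L)
  # holdout parents are full molecules, not augmented rows
  expect_true(all(qm$holdout_parents %in% as.character(1:40)))
})
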