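# TextCNN QSAR head over frozen dynamic embeddings: parallel 1D
# convolutions with global max-pooling, dropout, a dense layer, a highway
# block, and a one-neuron (regression) or two-neuron softmax
# (classification) output. The encoder is never updated.

#' CNN head configuration
#'
#' Defaults follow the published TextCNN head: kernels
#' (1,2,3,4,5,6,7,8,9,10,15,20) with (100,200,200,200,200,100,100,100,100,
#' 100,160,160) filters (pooled width 1720), dropout 0.25, dense width 512,
#' one highway block. Smaller kernel/filter lists are appropriate for
#' desk-scale experiments.
#'
#' @param kernel_sizes Integer vector of 1D kernel sizes.
#' @param filter_counts Filters per kernel; same length as
#'   \code{kernel_sizes}.
#' @param dropout Dropout rate on the pooled vector during training.
#' @param dense_width Width of the dense layer feeding the highway block.
#' @param task \code{"regression"} (MSE) or \code{"classification"}
#'   (two-neuron softmax with cross-entropy).
#' @param learning_rate Adam learning rate.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience (epochs without holdout
#'   improvement).
#' @param holdout_fraction Fraction of parent molecules held out for early
#'   stopping.
#' @param seed Seed for initialization, the holdout split and dropout.
#' @export
cnn_head_config <- function(kernel_sizes = c(1:10, 15L, 20L),
                            filter_counts = c(100L, 200L, 200L, 200L, 200L,
                                              100L, 100L, 100L, 100L, 100L,
                                              160L, 160L),
                            dropout = 0.25, dense_width = 512L,
                            task = c("regression", "classification"),
                            learning_rate = 1e-4, max_epochs = 100L,
                            patience = 10L, holdout_fraction = 0.10,
                            seed = 1L) {
  task <- match.arg(task)
  stopifnot(length(kernel_sizes) == length(filter_counts),
            all(kernel_sizes >= 1L), all(filter_counts >= 1L),
            dropout >= 0, dropout < 1, dense_width >= 1L,
            learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 filter_counts = as.integer(filter_counts),
                 pooled_width = sum(as.integer(filter_counts)),
                 dropout = dropout, dense_width = as.integer(dense_width),
                 task = task, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "cnn_head_config")
}

#' Build an untrained CNN head
#'
#' @param config A \code{\link{cnn_head_config}}.
#' @param d_model Embedding width of the frozen encoder.
#' @return Object of class \code{cnn_head} holding weights and config.
#' @export
build_head <- function(config = cnn_head_config(), d_model = 64L) {
  stopifnot(inherits(config, "cnn_head_config"))
  n_out <- if (config$task == "regression") 1L else 2L
  params <- list()
  with_seed(config$seed, {
    for (i in seq_along(config$kernel_sizes)) {
      k <- config$kernel_sizes[i]; f <- config$filter_counts[i]
      params[[sprintf("conv%d.W", k)]] <- init_mat(k * d_model, f)
      params[[sprintf("conv%d.b", k)]] <- numeric(f)
    }
    params$dense.W <- init_mat(config$pooled_width, config$dense_width)
    params$dense.b <- numeric(config$dense_width)
    params$hw.Wt <- init_mat(config$dense_width, config$dense_width)
    params$hw.bt <- rep(-1, config$dense_width)  # open carry gate at init
    params$hw.Wh <- init_mat(config$dense_width, config$dense_width)
    params$hw.bh <- numeric(config$dense_width)
    params$out.W <- init_mat(config$dense_width, n_out)
    params$out.b <- numeric(n_out)
  })
  structure(list(config = config, d_model = as.integer(d_model),
                 n_out = n_out, params = params),
            class = "cnn_head")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Zero-pad an embedding matrix at the bottom so every kernel sees at least
# one all-zero window; makes predictions invariant to extra trailing pads.
pad_embedding <- function(Z, max_kernel) {
  rbind(Z, matrix(0, max_kernel, ncol(Z)))
}

im2col <- function(Z, k) {
  n_win <- nrow(Z) - k + 1L
  d <- ncol(Z)
  out <- matrix(0, n_win, k * d)
  for (off in seq_len(k))
    out[, ((off - 1L) * d + 1L):(off * d)] <- Z[off:(off + n_win - 1L), ,
                                                drop = FALSE]
  out
}

# Forward pass for one embedding matrix. Caches everything the relevance
# engine and backward pass need.
head_forward <- function(head, Z, train = FALSE, need_cache = FALSE) {
  cfg <- head$config; P <- head$params
  maxk <- max(cfg$kernel_sizes)
  Zp <- pad_embedding(Z, maxk)
  pooled <- numeric(cfg$pooled_width)
  conv_cache <- if (need_cache) vector("list", length(cfg$kernel_sizes))
  off <- 0L
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]; f <- cfg$filter_counts[i]
    X <- im2col(Zp, k)
    C <- relu_fwd(linear_fwd(X, P[[sprintf("conv%d.W", k)]],
                             P[[sprintf("conv%d.b", k)]]))
    am <- max.col(t(C), ties.method = "first")  # argmax window per filter
    mx <- C[cbind(am, seq_len(f))]
    pooled[(off + 1L):(off + f)] <- mx
    if (need_cache)
      conv_cache[[i]] <- list(k = k, X = X, C = C, argmax = am)
    off <- off + f
  }
  v <- pooled
  dmask <- NULL
  if (train && cfg$dropout > 0) {
    dmask <- (stats::runif(length(v)) > cfg$dropout) / (1 - cfg$dropout)
    v <- v * dmask
  }
  zd <- as.vector(v %*% P$dense.W) + P$dense.b
  a <- pmax(zd, 0)
  zt <- as.vector(a %*% P$hw.Wt) + P$hw.bt
  tgate <- sigmoid(zt)
  zh <- as.vector(a %*% P$hw.Wh) + P$hw.bh
  h <- pmax(zh, 0)
  hw <- tgate * h + (1 - tgate) * a
  z_out <- as.vector(hw %*% P$out.W) + P$out.b
  if (head$config$task == "regression") {
    pred <- z_out[1]
    prob <- NULL
  } else {
    e <- exp(z_out - max(z_out))
    prob <- e / sum(e)
    pred <- prob[2]
  }
  res <- list(prediction = pred, prob = prob, z_out = z_out)
  if (need_cache)
    res$cache <- list(Zp = Zp, conv = conv_cache, pooled = pooled,
                      dmask = dmask, v = v, zd = zd, a = a, tgate = tgate,
                      zh = zh, h = h, hw = hw)
  res
}

# ---- batched training machinery ------------------------------------------
# The encoder is frozen, so embeddings and their im2col expansions are
# computed once; every epoch is then a handful of large GEMMs.

prepare_head_batch <- function(head, emb_list) {
  cfg <- head$config
  maxk <- max(cfg$kernel_sizes)
  L <- max(vapply(emb_list, function(e) nrow(e$matrix), 1L)) + maxk
  B <- length(emb_list)
  d <- head$d_model
  Zs <- lapply(emb_list, function(e)
    rbind(e$matrix, matrix(0, L - nrow(e$matrix), d)))
  Zall <- do.call(rbind, Zs)  # (B*L) x d, sequences stacked
  xk <- vector("list", length(cfg$kernel_sizes))
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]
    n_win <- L - k + 1L
    # windows within each sequence block
    Xi <- matrix(0, B * n_win, k * d)
    for (off in seq_len(k)) {
      rows <- as.vector(outer(seq_len(n_win) + off - 1L,
                              (seq_len(B) - 1L) * L, `+`))
      Xi[, ((off - 1L) * d + 1L):(off * d)] <- Zall[rows, , drop = FALSE]
    }
    xk[[i]] <- Xi
  }
  list(xk = xk, B = B, L = L, n_win = L - cfg$kernel_sizes + 1L)
}

# Restrict a prepared batch to a subset of sequences (one-off copy, so the
# per-epoch loop runs on contiguous matrices with no gathers).
subset_prep <- function(prep, rows) {
  xk <- vector("list", length(prep$xk))
  for (i in seq_along(prep$xk)) {
    n_win <- prep$n_win[i]
    ridx <- as.vector(outer(seq_len(n_win), (rows - 1L) * n_win, `+`))
    xk[[i]] <- prep$xk[[i]][ridx, , drop = FALSE]
  }
  list(xk = xk, B = length(rows), L = prep$L, n_win = prep$n_win)
}

# Batched forward over a prepared batch; returns pooled matrix (B x width)
# plus caches for backward.
head_batch_forward <- function(head, prep, train = FALSE, drop_seed = NULL) {
  cfg <- head$config; P <- head$params
  nb <- prep$B
  pooled <- matrix(0, nb, cfg$pooled_width)
  conv_cache <- vector("list", length(cfg$kernel_sizes))
  off <- 0L
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]; f <- cfg$filter_counts[i]
    n_win <- prep$n_win[i]
    X <- prep$xk[[i]]
    C <- relu_fwd(linear_fwd(X, P[[sprintf("conv%d.W", k)]],
                             P[[sprintf("conv%d.b", k)]]))
    # segment max over each sequence's n_win rows
    Ca <- array(C, dim = c(n_win, nb, f))
    mx <- Ca[1, , , drop = FALSE]
    am <- array(1L, dim = c(1, nb, f))
    if (n_win > 1) for (w in 2:n_win) {
      better <- Ca[w, , , drop = FALSE] > mx
      mx[better] <- Ca[w, , , drop = FALSE][better]
      am[better] <- w
    }
    pooled[, (off + 1L):(off + f)] <- matrix(mx, nb, f)
    conv_cache[[i]] <- list(k = k, f = f, n_win = n_win,
                            X = X, C = C, argmax = matrix(am, nb, f))
    off <- off + f
  }
  v <- pooled
  dmask <- NULL
  if (train && cfg$dropout > 0) {
    if (!is.null(drop_seed))
      dmask <- with_seed(drop_seed,
                         (matrix(stats::runif(length(v)), nb) > cfg$dropout) /
                           (1 - cfg$dropout))
    else
      dmask <- (matrix(stats::runif(length(v)), nb) > cfg$dropout) /
        (1 - cfg$dropout)
    v <- v * dmask
  }
  zd <- linear_fwd(v, P$dense.W, P$dense.b)
  a <- relu_fwd(zd)
  zt <- linear_fwd(a, P$hw.Wt, P$hw.bt)
  tg <- sigmoid(zt)
  zh <- linear_fwd(a, P$hw.Wh, P$hw.bh)
  h <- relu_fwd(zh)
  hw <- tg * h + (1 - tg) * a
  z_out <- linear_fwd(hw, P$out.W, P$out.b)
  list(z_out = z_out, conv = conv_cache, pooled = pooled, dmask = dmask,
       v = v, zd = zd, a = a, tg = tg, zh = zh, h = h, hw = hw)
}

head_batch_loss <- function(head, fwd, y) {
  if (head$config$task == "regression") {
    pred <- fwd$z_out[, 1]
    r <- pred - y
    list(loss = mean(r * r), dz = matrix(2 * r / length(y), ncol = 1),
         pred = pred)
  } else {
    Pm <- softmax_rows(fwd$z_out)
    n <- length(y)
    idx <- cbind(seq_len(n), y + 1L)
    loss <- -mean(log(Pm[idx] + 1e-12))
    dz <- Pm
    dz[idx] <- dz[idx] - 1
    list(loss = loss, dz = dz / n, pred = Pm[, 2])
  }
}

head_batch_backward <- function(head, fwd, dz) {
  cfg <- head$config; P <- head$params
  g <- list()
  lo <- linear_bwd(dz, fwd$hw, P$out.W)
  g$out.W <- lo$dW; g$out.b <- lo$db
  dhw <- lo$dX
  dtg <- dhw * (fwd$h - fwd$a)
  dh <- dhw * fwd$tg
  da <- dhw * (1 - fwd$tg)
  dzh <- dh * (fwd$zh > 0)
  lh <- linear_bwd(dzh, fwd$a, P$hw.Wh)
  g$hw.Wh <- lh$dW; g$hw.bh <- lh$db
  dzt <- dtg * fwd$tg * (1 - fwd$tg)
  lt <- linear_bwd(dzt, fwd$a, P$hw.Wt)
  g$hw.Wt <- lt$dW; g$hw.bt <- lt$db
  da <- da + lh$dX + lt$dX
  dzd <- da * (fwd$zd > 0)
  ld <- linear_bwd(dzd, fwd$v, P$dense.W)
  g$dense.W <- ld$dW; g$dense.b <- ld$db
  dv <- ld$dX
  if (!is.null(fwd$dmask)) dv <- dv * fwd$dmask
  off <- 0L
  nb <- nrow(dv)
  for (i in seq_along(cfg$kernel_sizes)) {
    cc <- fwd$conv[[i]]
    k <- cc$k; f <- cc$f; n_win <- cc$n_win
    dpool <- dv[, (off + 1L):(off + f), drop = FALSE]
    dC <- matrix(0, n_win * nb, f)
    # route gradient to the argmax window of each (sequence, filter)
    rows <- (rep(seq_len(nb), times = f) - 1L) * n_win + as.vector(cc$argmax)
    dC[cbind(rows, rep(seq_len(f), each = nb))] <- as.vector(dpool)
    dC <- dC * (cc$C > 0)
    lc <- linear_bwd(dC, cc$X, P[[sprintf("conv%d.W", k)]])
    g[[sprintf("conv%d.W", k)]] <- lc$dW
    g[[sprintf("conv%d.b", k)]] <- lc$db
    off <- off + f
  }
  g
}

#' Train the QSAR head on frozen embeddings
#'
#' Expands records by SMILES enumeration, extracts embeddings once through
#' the frozen encoder, and trains the CNN head with Adam (MSE or two-class
#' cross-entropy). A fraction of parent molecules -- not raw augmented rows,
#' to avoid augmentation leakage -- is held out; the weights with the best
#' holdout loss are restored at the end.
#'
#' @param records data.frame with \code{id}, \code{smiles}, \code{y}
#'   (classification targets must be 0/1).
#' @param encoder A \code{canonicalizer} whose encoder supplies embeddings;
#'   its weights are left byte-identical.
#' @param config A \code{\link{cnn_head_config}}.
#' @param policy An \code{\link{augmentation_policy}}.
#' @param oracle A \code{canon_oracle}.
#' @param verbose Print epoch summaries.
#' @return Object of class \code{qsar_model}: the frozen encoder reference,
#'   trained head, configs, training log and holdout parent ids.
#' @export
train_qsar <- function(records, encoder, config = cnn_head_config(),
                       policy = augmentation_policy(), oracle = grammar_oracle(),
                       verbose = FALSE) {
  stopifnot(inherits(encoder, "canonicalizer"),
            all(c("id", "smiles", "y") %in% names(records)))
  if (length(unique(records$id)) < 20L)
    stop("need at least 20 parent molecules", call. = FALSE)
  if (config$task == "regression") {
    if (stats::var(records$y) == 0)
      stop("zero-variance target", call. = FALSE)
  } else {
    if (!all(records$y %in% c(0, 1)) || length(unique(records$y)) < 2L)
      stop("classification target must contain both classes coded 0/1",
           call. = FALSE)
  }
  rows <- augment_qsar_dataset(records, policy, oracle)
  emb <- batch_extract(encoder, rows$smiles)
  head <- build_head(config, d_model = encoder$config$d_model)
  prep <- prepare_head_batch(head, emb)

  parents <- unique(rows$id)
  n_hold <- max(1L, round(config$holdout_fraction * length(parents)))
  hold_parents <- with_seed(config$seed,
                            sample(parents, n_hold))
  hold_rows <- which(rows$id %in% hold_parents)
  train_rows <- setdiff(seq_len(nrow(rows)), hold_rows)
  prep_train <- subset_prep(prep, train_rows)
  prep_hold <- subset_prep(prep, hold_rows)
  rm(prep)
  y <- rows$y
  if (config$task == "classification") y <- as.integer(y)

  opt <- adam_init(head$params)
  best <- list(loss = Inf, params = head$params, epoch = 0L)
  log_rows <- list()
  wait <- 0L
  for (ep in seq_len(config$max_epochs)) {
    fwd <- head_batch_forward(head, prep_train, train = TRUE,
                              drop_seed = derive_seed(config$seed, ep))
    tr <- head_batch_loss(head, fwd, y[train_rows])
    if (!is.finite(tr$loss)) stop("non-finite training loss", call. = FALSE)
    grads <- head_batch_backward(head, fwd, tr$dz)
    up <- adam_step(head$params, grads, opt, config$learning_rate)
    head$params <- up$params; opt <- up$state
    hf <- head_batch_forward(head, prep_hold)
    hl <- head_batch_loss(head, hf, y[hold_rows])
    log_rows[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                                 holdout_loss = hl$loss,
                                 lr = config$learning_rate)
    if (hl$loss < best$loss - 1e-9) {
      best <- list(loss = hl$loss, params = head$params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    if (verbose)
      message(sprintf("epoch %d: train %.4f holdout %.4f", ep, tr$loss,
                      hl$loss))
  }
  head$params <- best$params
  structure(list(encoder = encoder, head = head, config = config,
                 policy = policy, oracle_name = oracle$name,
                 log = do.call(rbind, log_rows),
                 best_epoch = best$epoch, best_holdout_loss = best$loss,
                 holdout_parents = hold_parents),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model (%s): %d kernels, pooled width %d, best epoch %d (holdout loss %.4f)\n",
              x$config$task, length(x$config$kernel_sizes),
              x$config$pooled_width, x$best_epoch, x$best_holdout_loss))
  invisible(x)
}

#' Single-SMILES prediction (no augmentation)
#'
#' Deterministic forward pass with dropout off: the regression value, or the
#' positive-class probability for classification.
#'
#' @param model A \code{qsar_model}.
#' @param smiles SMILES string.
#' @export
predict_raw <- function(model, smiles) {
  stopifnot(inherits(model, "qsar_model"))
  Z <- extract_embedding(model$encoder, smiles)$matrix
  head_forward(model$head, Z)$prediction
}
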