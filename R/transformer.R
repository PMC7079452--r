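# Sequence-to-sequence transformer for SMILES canonicalization.
# Pre-norm encoder/decoder blocks, sinusoidal positions, teacher-forced
# cross-entropy training, greedy decoding. The encoder's per-position output
# is the "dynamic SMILES embedding" consumed by the QSAR head.

#' Transformer configuration
#'
#' The published canonicalization model used a three-layer encoder/decoder
#' with multi-head self-attention; exact widths were not published, so all
#' sizes are configurable. \code{d_model} is the embedding width of the
#' per-position representation handed to the QSAR head.
#'
#' @param n_layers Encoder and decoder depth (same for both stacks).
#' @param n_heads Attention heads; must divide \code{d_model}.
#' @param d_model Model (embedding) width.
#' @param d_ff Position-wise feed-forward width.
#' @param dropout Dropout rate used during training.
#' @param max_len Maximum SMILES length in characters (sequences get two
#'   extra marker positions).
#' @param label_smoothing Cross-entropy label smoothing mass (0 disables);
#'   the canonical seq2seq recipe uses 0.1.
#' @param tie_output Share the output projection with the token embedding
#'   (transposed), as in the original seq2seq transformer.
#' @export
transformer_config <- function(n_layers = 3L, n_heads = 8L, d_model = 64L,
                               d_ff = 256L, dropout = 0.1, max_len = 110L,
                               label_smoothing = 0.1, tie_output = TRUE) {
  stopifnot(n_layers >= 1L, n_heads >= 1L, d_model %% n_heads == 0L,
            d_ff >= 1L, dropout >= 0, dropout < 1, max_len >= 4L,
            label_smoothing >= 0, label_smoothing < 1)
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 dropout = dropout, max_len = as.integer(max_len),
                 label_smoothing = label_smoothing,
                 tie_output = isTRUE(tie_output)),
            class = "transformer_config")
}

#' Learning-rate schedule for canonicalizer pretraining
#'
#' \code{lambda(step) = factor * min(1, step/warmup) / max(step, warmup)},
#' clamped from below at \code{floor}: linear warmup to
#' \code{factor/warmup}, then inverse-step decay.
#'
#' @param factor,warmup,floor Schedule constants (defaults 20, 16000, 1e-4).
#' @export
lr_schedule <- function(factor = 20, warmup = 16000L, floor = 1e-4) {
  stopifnot(factor > 0, warmup >= 1, floor > 0)
  structure(list(factor = factor, warmup = as.integer(warmup), floor = floor),
            class = "lr_schedule")
}

#' Evaluate the pretraining learning rate at a step
#'
#' @param step Training step (>= 1).
#' @param sched A \code{\link{lr_schedule}}.
#' @return The learning rate, never below \code{sched$floor}.
#' @examples
#' lr_at_step(16000, lr_schedule())  # 20/16000 = 1.25e-3, the peak
#' @export
lr_at_step <- function(step, sched = lr_schedule()) {
  stopifnot(all(step >= 1))
  lam <- sched$factor * pmin(1, step / sched$warmup) / pmax(step, sched$warmup)
  pmax(sched$floor, lam)
}

sinusoidal_positions <- function(max_pos, d) {
  pos <- matrix(0, max_pos, d)
  idx <- seq_len(ceiling(d / 2))
  freq <- 1 / 10000^((2 * (idx - 1)) / d)
  ang <- outer(seq_len(max_pos), freq)
  pos[, 2 * idx - 1] <- sin(ang)
  even <- 2 * idx
  even <- even[even <= d]
  pos[, even] <- cos(ang[, seq_along(even), drop = FALSE])
  pos
}

attn_param_names <- function(prefix) paste0(prefix, c("Wq", "Wk", "Wv", "Wo"))

attn_params <- function(params, prefix, n_heads) {
  p <- list(Wq = params[[paste0(prefix, "Wq")]],
            Wk = params[[paste0(prefix, "Wk")]],
            Wv = params[[paste0(prefix, "Wv")]],
            Wo = params[[paste0(prefix, "Wo")]])
  attr(p, "n_heads") <- n_heads
  p
}

#' Build an untrained canonicalization model
#'
#' Encoder: token embedding (scaled by sqrt(d_model)) + sinusoidal positions
#' followed by pre-norm blocks of multi-head self-attention and position-wise
#' feed-forward sublayers with residual connections; decoder mirrors the
#' encoder and adds cross-attention into the encoder output; a final linear
#' layer produces per-position scores over the vocabulary.
#'
#' @param config A \code{\link{transformer_config}}.
#' @param vocab A \code{\link{smiles_vocabulary}}.
#' @param seed Seed for weight initialization.
#' @return An object of class \code{canonicalizer}.
#' @export
build_canonicalizer <- function(config = transformer_config(),
                                vocab = smiles_vocabulary(), seed = 1L) {
  stopifnot(inherits(config, "transformer_config"))
  d <- config$d_model; V <- vocab$size; dff <- config$d_ff
  params <- list()
  with_seed(seed, {
    params$emb <- init_mat(V, d, scale = 1 / sqrt(d))
    add_attn <- function(prefix) {
      for (nm in attn_param_names(prefix)) params[[nm]] <<- init_mat(d, d)
    }
    add_ffn_ln <- function(prefix, ln_names) {
      params[[paste0(prefix, "W1")]] <<- init_mat(d, dff)
      params[[paste0(prefix, "b1")]] <<- numeric(dff)
      params[[paste0(prefix, "W2")]] <<- init_mat(dff, d)
      params[[paste0(prefix, "b2")]] <<- numeric(d)
      for (ln in ln_names) {
        params[[paste0(prefix, ln, "_g")]] <<- rep(1, d)
        params[[paste0(prefix, ln, "_b")]] <<- numeric(d)
      }
    }
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("enc%d.", l)
      add_attn(paste0(pre, "sa."))
      add_ffn_ln(pre, c("ln1", "ln2"))
    }
    params$enc_ln_g <- rep(1, d); params$enc_ln_b <- numeric(d)
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("dec%d.", l)
      add_attn(paste0(pre, "sa."))
      add_attn(paste0(pre, "ca."))
      add_ffn_ln(pre, c("ln1", "ln2", "ln3"))
    }
    params$dec_ln_g <- rep(1, d); params$dec_ln_b <- numeric(d)
    if (!config$tie_output) params$Wout <- init_mat(d, V)
    params$bout <- numeric(V)
  })
  m <- list(config = config, vocab = vocab, params = params,
            pos = sinusoidal_positions(config$max_len + 2L, d),
            train_state = NULL)
  class(m) <- "canonicalizer"
  m
}

#' @export
print.canonicalizer <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("SMILES canonicalizer: %d+%d layers, %d heads, ",
                     "d_model %d, d_ff %d (%s parameters)\n"),
              cfg$n_layers, cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$d_ff,
              format(n_par, big.mark = ",")))
  if (!is.null(x$train_state))
    cat(sprintf("  trained: %d steps, char accuracy %.3f\n",
                x$train_state$step, x$train_state$char_accuracy))
  invisible(x)
}

pad_batch <- function(id_list, pad_id) {
  L <- max(lengths(id_list))
  mat <- matrix(pad_id, length(id_list), L)
  for (i in seq_along(id_list)) mat[i, seq_along(id_list[[i]])] <- id_list[[i]]
  mat
}

embed_fwd <- function(model, ids_mat) {
  d <- model$config$d_model
  B <- nrow(ids_mat); L <- ncol(ids_mat)
  ids_flat <- as.integer(t(ids_mat))
  X <- model$params$emb[ids_flat, , drop = FALSE] * sqrt(d) +
    model$pos[rep(seq_len(L), B), , drop = FALSE]
  list(X = X, ids_flat = ids_flat, B = B, L = L)
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  (matrix(stats::runif(nr * nc), nr, nc) > rate) / (1 - rate)
}

apply_drop <- function(X, m) if (is.null(m)) X else X * m

# Encoder stack. Returns final hidden state H (B*L x d) and, when
# need_cache, everything the backward pass needs.
encoder_fwd <- function(model, ids_mat, mask, train = FALSE,
                        need_cache = FALSE) {
  cfg <- model$config; P <- model$params
  emb <- embed_fwd(model, ids_mat)
  X <- emb$X
  rate <- if (train) cfg$dropout else 0
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d.", l)
    c1 <- list()
    ln1 <- layernorm_fwd(X, P[[paste0(pre, "ln1_g")]], P[[paste0(pre, "ln1_b")]])
    ap <- attn_params(P, paste0(pre, "sa."), cfg$n_heads)
    att <- attention_fwd(ln1$Y, ln1$Y, ap, emb$B, emb$L, emb$L, mask)
    dm1 <- dropout_mask(nrow(X), ncol(X), rate)
    X1 <- X + apply_drop(att$Y, dm1)
    ln2 <- layernorm_fwd(X1, P[[paste0(pre, "ln2_g")]], P[[paste0(pre, "ln2_b")]])
    Z1 <- linear_fwd(ln2$Y, P[[paste0(pre, "W1")]], P[[paste0(pre, "b1")]])
    F1 <- relu_fwd(Z1)
    F2 <- linear_fwd(F1, P[[paste0(pre, "W2")]], P[[paste0(pre, "b2")]])
    dm2 <- dropout_mask(nrow(X), ncol(X), rate)
    Xout <- X1 + apply_drop(F2, dm2)
    if (need_cache)
      layers[[l]] <- list(X = X, ln1 = ln1, att = att, dm1 = dm1, X1 = X1,
                          ln2 = ln2, Z1 = Z1, F1 = F1, dm2 = dm2)
    X <- Xout
  }
  lnf <- layernorm_fwd(X, P$enc_ln_g, P$enc_ln_b)
  list(H = lnf$Y, emb = emb,
       cache = if (need_cache) list(layers = layers, Xfinal = X, lnf = lnf))
}

encoder_bwd <- function(model, dH, enc, mask, grads) {
  cfg <- model$config; P <- model$params
  lb <- layernorm_bwd(dH, enc$cache$lnf, P$enc_ln_g)
  grads$enc_ln_g <- grads$enc_ln_g + lb$dg
  grads$enc_ln_b <- grads$enc_ln_b + lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("enc%d.", l)
    cc <- enc$cache$layers[[l]]
    # FFN sublayer
    dF2 <- apply_drop(dX, cc$dm2)
    l2 <- linear_bwd(dF2, cc$F1, P[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- grads[[paste0(pre, "W2")]] + l2$dW
    grads[[paste0(pre, "b2")]] <- grads[[paste0(pre, "b2")]] + l2$db
    dZ1 <- l2$dX * (cc$Z1 > 0)
    l1 <- linear_bwd(dZ1, cc$ln2$Y, P[[paste0(pre, "W1")]])
    grads[[paste0(pre, "W1")]] <- grads[[paste0(pre, "W1")]] + l1$dW
    grads[[paste0(pre, "b1")]] <- grads[[paste0(pre, "b1")]] + l1$db
    lnb <- layernorm_bwd(l1$dX, cc$ln2, P[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- grads[[paste0(pre, "ln2_g")]] + lnb$dg
    grads[[paste0(pre, "ln2_b")]] <- grads[[paste0(pre, "ln2_b")]] + lnb$db
    dX1 <- dX + lnb$dX
    # attention sublayer
    datt <- apply_drop(dX1, cc$dm1)
    ap <- attn_params(P, paste0(pre, "sa."), cfg$n_heads)
    ab <- attention_bwd(datt, cc$att, cc$ln1$Y, cc$ln1$Y, ap)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      key <- paste0(pre, "sa.", nm)
      grads[[key]] <- grads[[key]] + ab[[paste0("d", nm)]]
    }
    lnb1 <- layernorm_bwd(ab$dXq + ab$dXkv, cc$ln1, P[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- grads[[paste0(pre, "ln1_g")]] + lnb1$dg
    grads[[paste0(pre, "ln1_b")]] <- grads[[paste0(pre, "ln1_b")]] + lnb1$db
    dX <- dX1 + lnb1$dX
  }
  # embedding
  d <- cfg$d_model
  agg <- rowsum(dX, enc$emb$ids_flat)
  rows <- as.integer(rownames(agg))
  grads$emb[rows, ] <- grads$emb[rows, ] + agg * sqrt(d)
  grads
}

decoder_fwd <- function(model, ids_mat, Henc, src_mask, tgt_mask,
                        train = FALSE, need_cache = FALSE, B_enc = NULL,
                        L_enc = NULL) {
  cfg <- model$config; P <- model$params
  emb <- embed_fwd(model, ids_mat)
  X <- emb$X
  rate <- if (train) cfg$dropout else 0
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("dec%d.", l)
    ln1 <- layernorm_fwd(X, P[[paste0(pre, "ln1_g")]], P[[paste0(pre, "ln1_b")]])
    ap1 <- attn_params(P, paste0(pre, "sa."), cfg$n_heads)
    sa <- attention_fwd(ln1$Y, ln1$Y, ap1, emb$B, emb$L, emb$L, tgt_mask,
                        causal = TRUE)
    dm1 <- dropout_mask(nrow(X), ncol(X), rate)
    X1 <- X + apply_drop(sa$Y, dm1)
    ln2 <- layernorm_fwd(X1, P[[paste0(pre, "ln2_g")]], P[[paste0(pre, "ln2_b")]])
    ap2 <- attn_params(P, paste0(pre, "ca."), cfg$n_heads)
    ca <- attention_fwd(ln2$Y, Henc, ap2, emb$B, emb$L, L_enc, src_mask)
    dm2 <- dropout_mask(nrow(X), ncol(X), rate)
    X2 <- X1 + apply_drop(ca$Y, dm2)
    ln3 <- layernorm_fwd(X2, P[[paste0(pre, "ln3_g")]], P[[paste0(pre, "ln3_b")]])
    Z1 <- linear_fwd(ln3$Y, P[[paste0(pre, "W1")]], P[[paste0(pre, "b1")]])
    F1 <- relu_fwd(Z1)
    F2 <- linear_fwd(F1, P[[paste0(pre, "W2")]], P[[paste0(pre, "b2")]])
    dm3 <- dropout_mask(nrow(X), ncol(X), rate)
    Xout <- X2 + apply_drop(F2, dm3)
    if (need_cache)
      layers[[l]] <- list(X = X, ln1 = ln1, sa = sa, dm1 = dm1, X1 = X1,
                          ln2 = ln2, ca = ca, dm2 = dm2, X2 = X2,
                          ln3 = ln3, Z1 = Z1, F1 = F1, dm3 = dm3)
    X <- Xout
  }
  lnf <- layernorm_fwd(X, P$dec_ln_g, P$dec_ln_b)
  Wout <- if (cfg$tie_output) t(P$emb) else P$Wout
  logits <- linear_fwd(lnf$Y, Wout, P$bout)
  list(logits = logits, emb = emb,
       cache = if (need_cache) list(layers = layers, lnf = lnf))
}

decoder_bwd <- function(model, dlogits, dec, Henc, grads) {
  cfg <- model$config; P <- model$params
  Wout <- if (cfg$tie_output) t(P$emb) else P$Wout
  lo <- linear_bwd(dlogits, dec$cache$lnf$Y, Wout)
  if (cfg$tie_output) grads$emb <- grads$emb + t(lo$dW)
  else grads$Wout <- grads$Wout + lo$dW
  grads$bout <- grads$bout + lo$db
  lb <- layernorm_bwd(lo$dX, dec$cache$lnf, P$dec_ln_g)
  grads$dec_ln_g <- grads$dec_ln_g + lb$dg
  grads$dec_ln_b <- grads$dec_ln_b + lb$db
  dX <- lb$dX
  dHenc <- matrix(0, nrow(Henc), ncol(Henc))
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("dec%d.", l)
    cc <- dec$cache$layers[[l]]
    dF2 <- apply_drop(dX, cc$dm3)
    l2 <- linear_bwd(dF2, cc$F1, P[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- grads[[paste0(pre, "W2")]] + l2$dW
    grads[[paste0(pre, "b2")]] <- grads[[paste0(pre, "b2")]] + l2$db
    dZ1 <- l2$dX * (cc$Z1 > 0)
    l1 <- linear_bwd(dZ1, cc$ln3$Y, P[[paste0(pre, "W1")]])
    grads[[paste0(pre, "W1")]] <- grads[[paste0(pre, "W1")]] + l1$dW
    grads[[paste0(pre, "b1")]] <- grads[[paste0(pre, "b1")]] + l1$db
    lnb3 <- layernorm_bwd(l1$dX, cc$ln3, P[[paste0(pre, "ln3_g")]])
    grads[[paste0(pre, "ln3_g")]] <- grads[[paste0(pre, "ln3_g")]] + lnb3$dg
    grads[[paste0(pre, "ln3_b")]] <- grads[[paste0(pre, "ln3_b")]] + lnb3$db
    dX2 <- dX + lnb3$dX
    # cross-attention
    dca <- apply_drop(dX2, cc$dm2)
    ap2 <- attn_params(P, paste0(pre, "ca."), cfg$n_heads)
    ab2 <- attention_bwd(dca, cc$ca, cc$ln2$Y, Henc, ap2)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      key <- paste0(pre, "ca.", nm)
      grads[[key]] <- grads[[key]] + ab2[[paste0("d", nm)]]
    }
    dHenc <- dHenc + ab2$dXkv
    lnb2 <- layernorm_bwd(ab2$dXq, cc$ln2, P[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- grads[[paste0(pre, "ln2_g")]] + lnb2$dg
    grads[[paste0(pre, "ln2_b")]] <- grads[[paste0(pre, "ln2_b")]] + lnb2$db
    dX1 <- dX2 + lnb2$dX
    # masked self-attention
    dsa <- apply_drop(dX1, cc$dm1)
    ap1 <- attn_params(P, paste0(pre, "sa."), cfg$n_heads)
    ab1 <- attention_bwd(dsa, cc$sa, cc$ln1$Y, cc$ln1$Y, ap1)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      key <- paste0(pre, "sa.", nm)
      grads[[key]] <- grads[[key]] + ab1[[paste0("d", nm)]]
    }
    lnb1 <- layernorm_bwd(ab1$dXq + ab1$dXkv, cc$ln1, P[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- grads[[paste0(pre, "ln1_g")]] + lnb1$dg
    grads[[paste0(pre, "ln1_b")]] <- grads[[paste0(pre, "ln1_b")]] + lnb1$db
    dX <- dX1 + lnb1$dX
  }
  d <- cfg$d_model
  agg <- rowsum(dX, dec$emb$ids_flat)
  rows <- as.integer(rownames(agg))
  grads$emb[rows, ] <- grads$emb[rows, ] + agg * sqrt(d)
  list(grads = grads, dHenc = dHenc)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# One teacher-forced training step on a batch of (source, target) token id
# lists. Returns loss, char accuracy, grads.
canonicalizer_step <- function(model, src_ids, tgt_ids, train = TRUE) {
  vocab <- model$vocab
  src_mat <- pad_batch(src_ids, vocab$pad_id)
  tin <- lapply(tgt_ids, function(x) x[-length(x)])
  tout <- lapply(tgt_ids, function(x) x[-1L])
  tin_mat <- pad_batch(tin, vocab$pad_id)
  tout_mat <- pad_batch(tout, vocab$pad_id)
  src_mask <- src_mat != vocab$pad_id
  tgt_mask <- tin_mat != vocab$pad_id
  B <- nrow(src_mat)

  enc <- encoder_fwd(model, src_mat, src_mask, train = train,
                     need_cache = train)
  dec <- decoder_fwd(model, tin_mat, enc$H, src_mask, tgt_mask,
                     train = train, need_cache = train,
                     L_enc = ncol(src_mat))
  tout_flat <- as.integer(t(tout_mat))
  valid <- tout_flat != vocab$pad_id
  Pm <- softmax_rows(dec$logits)
  n_valid <- sum(valid)
  smooth <- model$config$label_smoothing %||% 0
  V_sym <- vocab$size - 1L  # smoothing mass spread over real symbols only
  picked <- Pm[cbind(which(valid), tout_flat[valid])]
  logP <- log(Pm[valid, -vocab$pad_id, drop = FALSE] + 1e-12)
  loss <- if (smooth > 0)
    -( (1 - smooth) * sum(log(picked + 1e-12)) +
         smooth / V_sym * sum(logP) ) / n_valid
  else -sum(log(picked + 1e-12)) / n_valid
  pred <- max.col(dec$logits, ties.method = "first")
  acc <- mean(pred[valid] == tout_flat[valid])
  if (!train) return(list(loss = loss, acc = acc))

  dlogits <- Pm
  dlogits[cbind(which(valid), tout_flat[valid])] <-
    dlogits[cbind(which(valid), tout_flat[valid])] - (1 - smooth)
  if (smooth > 0)
    dlogits[valid, -vocab$pad_id] <- dlogits[valid, -vocab$pad_id] -
      smooth / V_sym
  dlogits[!valid, ] <- 0
  dlogits <- dlogits / n_valid
  grads <- zero_grads(model$params)
  db <- decoder_bwd(model, dlogits, dec, enc$H, grads)
  grads <- encoder_bwd(model, db$dHenc, enc, src_mask, db$grads)
  list(loss = loss, acc = acc, grads = grads)
}

#' Train the canonicalization model
#'
#' Teacher-forced next-token cross-entropy over canonicalization pairs, Adam
#' with either the warmup/decay pretraining schedule or a constant rate, and
#' per-step character-accuracy logging. No early stopping or weight
#' averaging is applied at this stage.
#'
#' @param pairs data.frame with columns \code{source}, \code{target} (e.g.
#'   from \code{\link{read_pair_file}} or
#'   \code{\link{make_canonicalization_pairs}}).
#' @param model A \code{\link{build_canonicalizer}} model.
#' @param epochs Number of passes over the pairs.
#' @param seed Seed controlling shuffling and dropout.
#' @param batch_size Sequences per step.
#' @param schedule Optional \code{\link{lr_schedule}}; when \code{NULL} a
#'   constant \code{lr} is used (appropriate for desk-scale runs far below
#'   the schedule's warmup horizon).
#' @param lr Constant learning rate used when \code{schedule} is NULL.
#' @param verbose Print per-epoch summaries.
#' @return The model with trained weights and a \code{train_state} list
#'   (step count, final char accuracy, per-step log).
#' @export
train_canonicalizer <- function(pairs, model, epochs = 5L, seed = 1L,
                                batch_size = 16L, schedule = NULL,
                                lr = 1e-3, verbose = FALSE) {
  stopifnot(nrow(pairs) >= 1L, all(c("source", "target") %in% names(pairs)))
  vocab <- model$vocab
  src_ids <- lapply(pairs$source, function(s) tokenize(s, vocab)$ids)
  tgt_ids <- lapply(pairs$target, function(s) tokenize(s, vocab)$ids)
  long <- max(c(lengths(src_ids), lengths(tgt_ids))) - 2L
  if (long > model$config$max_len)
    stop("sequence longer than config max_len (", long, " > ",
         model$config$max_len, ")", call. = FALSE)
  opt <- adam_init(model$params)
  step <- 0L
  log_rows <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(pairs))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0; ep_acc <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        res <- canonicalizer_step(model, src_ids[idx], tgt_ids[idx])
        if (!is.finite(res$loss))
          stop("non-finite loss at step ", step + 1L, call. = FALSE)
        step <- step + 1L
        lam <- if (is.null(schedule)) lr else lr_at_step(step, schedule)
        up <- adam_step(model$params, res$grads, opt, lam)
        model$params <- up$params
        opt <- up$state
        ep_loss <- ep_loss + res$loss; ep_acc <- ep_acc + res$acc
        log_rows[[step]] <- data.frame(epoch = ep, step = step,
                                       loss = res$loss, char_acc = res$acc,
                                       lr = lam)
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, char acc %.3f", ep,
                        ep_loss / length(batches), ep_acc / length(batches)))
    }
  })
  log <- do.call(rbind, log_rows)
  model$train_state <- list(step = step, epoch = as.integer(epochs),
                            char_accuracy = log$char_acc[nrow(log)],
                            log = log)
  model
}

#' Greedy decoding of the canonical SMILES
#'
#' Argmax decoding until the end marker or \code{max_len}; the result may be
#' chemically invalid for an undertrained model -- callers validate. A
#' \code{truncated} attribute flags decodes that hit the length cap.
#'
#' @param model A \code{canonicalizer}.
#' @param smiles Input SMILES string.
#' @param max_len Decode cap in characters (default: model config).
#' @return Decoded string.
#' @export
greedy_decode <- function(model, smiles, max_len = NULL) {
  vocab <- model$vocab
  max_len <- max_len %||% model$config$max_len
  src <- tokenize(smiles, vocab)$ids
  src_mat <- matrix(src, 1L)
  src_mask <- matrix(TRUE, 1L, length(src))
  enc <- encoder_fwd(model, src_mat, src_mask)
  ids <- vocab$start_id
  truncated <- TRUE
  for (i in seq_len(max_len)) {
    tin_mat <- matrix(ids, 1L)
    dec <- decoder_fwd(model, tin_mat, enc$H,
                       src_mask, matrix(TRUE, 1L, length(ids)),
                       L_enc = length(src))
    logit <- dec$logits[length(ids), ]
    logit[c(vocab$pad_id, vocab$start_id)] <- -Inf
    nxt <- which.max(logit)
    ids <- c(ids, nxt)
    if (nxt == vocab$end_id) { truncated <- FALSE; break }
  }
  if (truncated) ids <- c(ids, vocab$end_id)
  structure(detokenize(ids, vocab), truncated = truncated)
}

#' Exact-match canonicalization report
#'
#' Decodes every input and compares against the oracle's canonical string,
#' overall and on the stereo (\code{@}) and cis/trans (\code{/} or \code{\\})
#' subsets, mirroring the standard validation layout for canonicalization
#' models; also reports the fraction of inputs that were already canonical.
#'
#' @param model A trained \code{canonicalizer}.
#' @param smiles_list Character vector of input SMILES.
#' @param oracle A \code{canon_oracle} supplying reference canonical forms.
#' @param max_len Decode cap.
#' @return list of class \code{canonicalization_report} with per-category
#'   counts and rates.
#' @export
canonicalization_report <- function(model, smiles_list, oracle, max_len = NULL) {
  stopifnot(length(smiles_list) >= 1L)
  ref <- oracle$canonical(smiles_list)
  dec <- vapply(smiles_list, function(s)
    as.character(greedy_decode(model, s, max_len)), "")
  hit <- dec == ref
  subset_stats <- function(sel) list(n = sum(sel), correct = sum(hit & sel),
                                     rate = if (sum(sel)) mean(hit[sel]) else NA_real_)
  out <- list(
    all = subset_stats(rep(TRUE, length(hit))),
    stereo = subset_stats(grepl("@", smiles_list, fixed = TRUE)),
    cis_trans = subset_stats(grepl("[/\\\\]", smiles_list)),
    already_canonical = mean(smiles_list == ref),
    decoded = dec, reference = ref
  )
  class(out) <- "canonicalization_report"
  out
}

#' @export
print.canonicalization_report <- function(x, ...) {
  cat("Canonicalization validation\n")
  row <- function(nm, s) if (s$n > 0)
    cat(sprintf("  %-18s %6d / %6d (%.1f%%)\n", nm, s$correct, s$n,
                100 * s$rate))
  row("All", x$all); row("Stereo (@)", x$stereo)
  row("Cis/trans (/ \\)", x$cis_trans)
  cat(sprintf("  already canonical  %.1f%% of inputs\n",
              100 * x$already_canonical))
  invisible(x)
}
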