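# Layer-wise relevance propagation through the CNN head, down to the frozen
# encoder's per-position output (propagation deliberately stops there).
# Epsilon-rule for dense/conv layers, winner-take-all for the max-pool
# inversion, signal-take-all for the highway gate. Every step reports the
# relevance absorbed by bias terms; the ledger mirrors the
# layer / R(L+1) / R(L) / Delta / Bias% accounting used to judge whether an
# explanation can be trusted.

sign_eps <- function(z, eps) z + ifelse(z >= 0, eps, -eps)

#' Epsilon-rule relevance propagation through a dense layer
#'
#' \code{R_i = sum_j x_i w_ij / (z_j + sign(z_j) eps) R_j} with
#' \code{z_j = sum_i x_i w_ij + b_j}. The relevance share of the bias (and
#' the epsilon stabilizer) is returned explicitly so that
#' \code{sum(r_in) + bias_absorbed == sum(r_out)} up to floating error.
#'
#' @param r_out Relevance on the layer outputs (length ncol(weights)).
#' @param weights din x dout weight matrix.
#' @param bias Output bias vector (or NULL).
#' @param inputs Layer input activations (length din).
#' @param eps Stabilizer, tiny and sign-matched.
#' @return list(r_in, bias_absorbed).
#' @export
lrp_dense <- function(r_out, weights, bias, inputs, eps = 1e-9) {
  stopifnot(length(inputs) == nrow(weights),
            length(r_out) == ncol(weights), eps > 0)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  z <- as.vector(inputs %*% weights) + bias
  denom <- sign_eps(z, eps)
  share <- r_out / denom
  share[r_out == 0] <- 0  # avoid 0 * Inf pathologies on dead outputs
  r_in <- inputs * as.vector(weights %*% share)
  list(r_in = r_in,
       bias_absorbed = sum((bias + (denom - z)) * share))
}

#' Epsilon-rule relevance propagation through a 1D convolution
#'
#' The convolution is treated as a dense layer with tied weights applied to
#' each window; per-window relevance is redistributed with the same
#' epsilon rule and accumulated on the overlapping input positions.
#'
#' @param r_out n_windows x n_filters relevance on the conv output map.
#' @param kernel (k*d) x n_filters weight matrix (window rows concatenated
#'   position-major).
#' @param bias Filter bias vector.
#' @param inputs n_positions x d input matrix (n_windows = n_positions - k
#'   + 1).
#' @param eps Stabilizer.
#' @return list(r_in: n_positions x d matrix, bias_absorbed).
#' @export
lrp_conv <- function(r_out, kernel, bias, inputs, eps = 1e-9) {
  d <- ncol(inputs)
  k <- nrow(kernel) / d
  stopifnot(k == round(k))
  k <- as.integer(k)
  n_win <- nrow(inputs) - k + 1L
  stopifnot(nrow(r_out) == n_win, ncol(r_out) == ncol(kernel))
  if (is.null(bias)) bias <- numeric(ncol(kernel))
  r_in <- matrix(0, nrow(inputs), d)
  bias_abs <- 0
  for (p in seq_len(n_win)) {
    rp <- r_out[p, ]
    if (all(rp == 0)) next
    x_win <- as.vector(t(inputs[p:(p + k - 1L), , drop = FALSE]))
    res <- lrp_dense(rp, kernel, bias, x_win, eps)
    r_in[p:(p + k - 1L), ] <- r_in[p:(p + k - 1L), ] +
      matrix(res$r_in, k, d, byrow = TRUE)
    bias_abs <- bias_abs + res$bias_absorbed
  }
  list(r_in = r_in, bias_absorbed = bias_abs)
}

#' Winner-take-all inversion of a global max-pool
#'
#' Each filter's relevance is assigned entirely to the window that won the
#' pooling; ties break to the lowest index. Conservation is exact.
#'
#' @param r_out Relevance per filter (length n_filters).
#' @param inputs n_windows x n_filters pooled-over map.
#' @return n_windows x n_filters relevance matrix.
#' @export
lrp_maxpool <- function(r_out, inputs) {
  stopifnot(length(r_out) == ncol(inputs))
  am <- max.col(t(inputs), ties.method = "first")
  r_in <- matrix(0, nrow(inputs), ncol(inputs))
  r_in[cbind(am, seq_along(r_out))] <- r_out
  r_in
}

#' Signal-take-all relevance split through a highway gate
#'
#' The gate is treated as a constant receiving zero relevance; relevance
#' splits between the transform branch (gate * transformed) and the carry
#' branch ((1 - gate) * carry) in proportion to their contributions to the
#' output.
#'
#' @param r_out Relevance on the highway output.
#' @param gate Gate activations t in (0, 1).
#' @param transformed Transform-branch activations h.
#' @param carry Carry-branch activations x.
#' @param eps Stabilizer.
#' @return list(r_transform, r_carry).
#' @export
lrp_highway <- function(r_out, gate, transformed, carry, eps = 1e-9) {
  a <- gate * transformed
  cc <- (1 - gate) * carry
  denom <- sign_eps(a + cc, eps)
  share <- r_out / denom
  share[r_out == 0] <- 0
  list(r_transform = a * share, r_carry = cc * share)
}

ledger_row <- function(layer, r_upper, r_lower) {
  delta <- r_upper - r_lower
  data.frame(layer = layer, r_upper = r_upper, r_lower = r_lower,
             delta = delta,
             bias_pct = if (r_upper != 0) 100 * delta / r_upper else NA_real_,
             stringsAsFactors = FALSE)
}

#' Assemble a relevance-conservation ledger from layer sums
#'
#' Bookkeeping used throughout the relevance engine: for each layer,
#' \code{Delta = R(L+1) - R(L)} and \code{Bias\% = 100 * Delta / R(L+1)}.
#'
#' @param layers Character vector of layer names.
#' @param r_upper Incoming relevance sums R(L+1).
#' @param r_lower Outgoing relevance sums R(L).
#' @return data.frame ledger with columns layer, r_upper, r_lower, delta,
#'   bias_pct.
#' @export
relevance_ledger <- function(layers, r_upper, r_lower) {
  stopifnot(length(layers) == length(r_upper),
            length(layers) == length(r_lower))
  do.call(rbind, lapply(seq_along(layers), function(i)
    ledger_row(layers[i], r_upper[i], r_lower[i])))
}

#' Propagate relevance from the prediction to encoder positions
#'
#' Starts from the predicted value (regression) or the positive-class
#' pre-softmax score (classification) and walks back through the output
#' layer, highway block (signal-take-all), dense layer with max-pool
#' inversion, and each kernel's convolution, stopping at the frozen
#' encoder's output. Returns the per-position relevance (summed over
#' embedding features, aligned with the token sequence including markers)
#' and the conservation ledger.
#'
#' @param model A \code{qsar_model}.
#' @param smiles SMILES string.
#' @param eps Epsilon stabilizer for the propagation rules.
#' @return list of class \code{relevance_propagation}: \code{per_position},
#'   \code{tokens}, \code{ledger}, \code{prediction}, \code{relevance_matrix}
#'   (positions x d_model), \code{applicability}.
#' @export
propagate_relevance <- function(model, smiles, eps = 1e-9) {
  stopifnot(inherits(model, "qsar_model"))
  emb <- extract_embedding(model$encoder, smiles)
  Z <- emb$matrix
  head <- model$head
  cfg <- head$config
  P <- head$params
  fwd <- head_forward(head, Z, need_cache = TRUE)
  cache <- fwd$cache

  # output relevance: one propagated scalar
  if (cfg$task == "regression") {
    r_result <- fwd$z_out[1]
    r_out_vec <- r_result
  } else {
    r_result <- fwd$z_out[2]           # positive-class pre-softmax score
    r_out_vec <- c(0, r_result)
  }

  # output dense layer -> highway output
  st1 <- lrp_dense(r_out_vec, P$out.W, P$out.b, cache$hw, eps)
  r_hw <- st1$r_in

  # highway block (signal-take-all; gate gets nothing) -> highway input
  sp <- lrp_highway(r_hw, cache$tgate, cache$h, cache$a, eps)
  st2 <- lrp_dense(sp$r_transform, P$hw.Wh, P$hw.bh, cache$a, eps)
  r_a <- sp$r_carry + st2$r_in

  # dense layer -> pooled vector, then invert the max-pool
  st3 <- lrp_dense(r_a, P$dense.W, P$dense.b, cache$v, eps)
  r_pooled <- st3$r_in

  # per-kernel: de-pool then conv back onto the (padded) embedding
  r_Z <- matrix(0, nrow(cache$Zp), ncol(cache$Zp))
  conv_rows <- list()
  off <- 0L
  for (i in seq_along(cfg$kernel_sizes)) {
    cc <- cache$conv[[i]]
    f <- ncol(cc$C)
    rp <- r_pooled[(off + 1L):(off + f)]
    r_map <- lrp_maxpool(rp, cc$C)
    res <- lrp_conv(r_map, P[[sprintf("conv%d.W", cc$k)]],
                    P[[sprintf("conv%d.b", cc$k)]], cache$Zp, eps)
    r_Z <- r_Z + res$r_in
    conv_rows[[i]] <- ledger_row(sprintf("Conv%d", cc$k), sum(rp),
                                 sum(res$r_in))
    off <- off + f
  }

  n_tok <- nrow(Z)
  r_Z_real <- r_Z[seq_len(n_tok), , drop = FALSE]
  per_position <- rowSums(r_Z_real)

  ledger <- rbind(
    ledger_row("Result", r_result, NA_real_),
    ledger_row("HighWay Output", r_result, sum(r_hw)),
    ledger_row("HighWay Input", sum(r_hw), sum(r_a)),
    ledger_row("DeMaxPool", sum(r_a), sum(r_pooled)),
    do.call(rbind, conv_rows),
    ledger_row("Total", r_result, sum(per_position))
  )
  ledger$delta[1] <- NA_real_; ledger$bias_pct[1] <- NA_real_

  out <- list(per_position = per_position, tokens = emb$tokens,
              ledger = ledger, prediction = fwd$prediction,
              relevance_matrix = r_Z_real,
              applicability = applicability_flag(ledger))
  class(out) <- "relevance_propagation"
  out
}

#' Applicability warning from a conservation ledger
#'
#' If less than half of the output relevance survives to the input
#' positions, the explanation (and possibly the prediction) should be
#' questioned -- an applicability-domain or propagation problem. Exactly
#' 50 percent propagated is still "ok".
#'
#' @param ledger A ledger data.frame with a \code{"Total"} row.
#' @return \code{"ok"} or \code{"warning"}.
#' @export
applicability_flag <- function(ledger) {
  tot <- ledger[ledger$layer == "Total", ]
  if (!nrow(tot)) stop("ledger has no Total row", call. = FALSE)
  frac <- tot$r_lower[1] / tot$r_upper[1]
  if (is.na(frac) || frac < 0.5) "warning" else "ok"
}

#' @export
print.relevance_propagation <- function(x, ...) {
  cat(sprintf("prediction %.4f; propagated %.1f%% (%s)\n", x$prediction,
              100 * x$ledger$r_lower[nrow(x$ledger)] /
                x$ledger$r_upper[nrow(x$ledger)],
              x$applicability))
  df <- x$ledger
  df$r_upper <- signif(df$r_upper, 5); df$r_lower <- signif(df$r_lower, 5)
  df$delta <- signif(df$delta, 4); df$bias_pct <- signif(df$bias_pct, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# --- character-to-atom mapping --------------------------------------------

ORGANIC_UPPER <- c("B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_LOWER <- c("b", "c", "n", "o", "p", "s")

#' Map SMILES characters to heavy atoms
#'
#' Two-letter elements (Cl, Br) span both characters; a bracket atom owns
#' everything from \code{[} to \code{]}; ring-closure digits, bond symbols
#' and branch parentheses fold into the nearest preceding atom. Characters
#' before the first atom go to a separate prefix bucket (markers are not
#' part of the input here). The spans partition the character positions.
#'
#' @param smiles SMILES string (no markers).
#' @return list of class \code{char_atom_map}: \code{spans} (per heavy atom,
#'   integer character indices), \code{elements} (per-atom element symbol),
#'   \code{prefix} (indices before the first atom, normally empty).
#' @export
map_chars_to_atoms <- function(smiles) {
  chars <- strsplit(normalize_smiles_text(smiles), "", fixed = TRUE)[[1]]
  n <- length(chars)
  spans <- list()
  elements <- character(0)
  prefix <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed '[' in '", smiles, "'", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      el <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      spans[[length(spans) + 1L]] <- i:j
      elements <- c(elements, if (length(el)) el else body)
      i <- j + 1L
    } else if (i < n && ch %in% c("C", "B") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      spans[[length(spans) + 1L]] <- c(i, i + 1L)
      elements <- c(elements, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% ORGANIC_UPPER || ch %in% AROMATIC_LOWER) {
      spans[[length(spans) + 1L]] <- i
      elements <- c(elements, ch)
      i <- i + 1L
    } else {
      if (length(spans)) {
        spans[[length(spans)]] <- c(spans[[length(spans)]], i)
      } else {
        prefix <- c(prefix, i)
      }
      i <- i + 1L
    }
  }
  structure(list(spans = spans, elements = elements, prefix = prefix),
            class = "char_atom_map")
}

#' Per-atom attribution by atom-rooted SMILES averaging
#'
#' For every heavy atom the oracle writes a SMILES rooted at that atom;
#' relevance is propagated for each rooted string, summed over the
#' characters each atom owns, mapped back to the original atom numbering,
#' and averaged over all rooted variants. The prediction is likewise the
#' average of the per-variant predictions.
#'
#' @param model A \code{qsar_model}.
#' @param smiles SMILES string.
#' @param oracle A \code{canon_oracle} whose \code{rooted_variant} reports
#'   the atom output order.
#' @param eps Propagation stabilizer.
#' @return list of class \code{atom_attribution}: \code{contributions}
#'   (per original heavy atom), \code{elements}, \code{prediction},
#'   \code{n_rooted}, \code{mean_bias_pct}, \code{applicability}.
#' @export
atom_attribution <- function(model, smiles, oracle = grammar_oracle(),
                             eps = 1e-9) {
  n <- oracle$heavy_atom_count(smiles)
  contributions <- numeric(n)
  preds <- numeric(n)
  biases <- numeric(n)
  warns <- 0L
  elements <- character(n)
  for (a in seq_len(n)) {
    rooted <- oracle$rooted_variant(smiles, a)
    ord <- attr(rooted, "atom_order")
    prop <- propagate_relevance(model, as.character(rooted), eps)
    cam <- map_chars_to_atoms(as.character(rooted))
    if (length(cam$spans) != n)
      stop("rooted SMILES atom count mismatch for '", rooted, "'",
           call. = FALSE)
    if (is.null(ord)) ord <- seq_len(n)
    elements[ord] <- cam$elements
    for (kk in seq_len(n)) {
      # character index -> token position: +1 for the start marker
      val <- sum(prop$per_position[cam$spans[[kk]] + 1L])
      contributions[ord[kk]] <- contributions[ord[kk]] + val
    }
    preds[a] <- prop$prediction
    tot <- prop$ledger[prop$ledger$layer == "Total", ]
    biases[a] <- tot$bias_pct[1]
    if (prop$applicability != "ok") warns <- warns + 1L
  }
  out <- list(contributions = contributions / n, elements = elements,
              prediction = mean(preds), n_rooted = n,
              mean_bias_pct = mean(biases),
              applicability = if (warns > n / 2) "warning" else "ok")
  class(out) <- "atom_attribution"
  out
}

#' @export
print.atom_attribution <- function(x, ...) {
  cat(sprintf("prediction %.4f over %d rooted SMILES (mean bias %.1f%%, %s)\n",
              x$prediction, x$n_rooted, x$mean_bias_pct, x$applicability))
  print(data.frame(atom = seq_along(x$contributions), element = x$elements,
                   contribution = signif(x$contributions, 4)),
        row.names = FALSE)
  invisible(x)
}
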