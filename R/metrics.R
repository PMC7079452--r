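# Consensus inference over augmented SMILES and the evaluation statistics.

#' Consensus prediction over enumerated SMILES
#'
#' Predicts on the canonical SMILES plus \code{n_augment} enumerated
#' variants and averages; the spread over the batch serves as a confidence
#' measure. For classification the per-variant positive-class probabilities
#' are averaged.
#'
#' @param model A \code{qsar_model}.
#' @param smiles SMILES string.
#' @param n_augment Variants in addition to the canonical form.
#' @param seed Enumeration seed.
#' @param oracle A \code{canon_oracle}.
#' @return list of class \code{consensus_prediction}: \code{mean},
#'   \code{std}, \code{n_variants}, \code{per_variant}.
#' @export
predict_consensus <- function(model, smiles, n_augment = 10L, seed = 1L,
                              oracle = grammar_oracle()) {
  stopifnot(inherits(model, "qsar_model"))
  canon <- oracle$canonical(smiles)
  variants <- c(canon, enumerate_smiles(smiles, n_augment, seed, oracle))
  per <- vapply(variants, function(s) predict_raw(model, s), 0,
                USE.NAMES = FALSE)
  out <- list(mean = mean(per),
              std = if (length(per) > 1L) stats::sd(per) else 0,
              n_variants = length(per), per_variant = per,
              smiles = variants)
  class(out) <- "consensus_prediction"
  out
}

#' @export
print.consensus_prediction <- function(x, ...) {
  cat(sprintf("consensus over %d SMILES: %.4f +- %.4f\n", x$n_variants,
              x$mean, x$std))
  invisible(x)
}

#' Coefficient of determination
#'
#' \code{r2 = 1 - SS_res/SS_tot} where \code{SS_tot} is the total variance
#' of the observations and \code{SS_res} the residual variance; may be
#' negative for predictors worse than the mean.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L,
            all(is.finite(y)), all(is.finite(y_hat)))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance observations", call. = FALSE)
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half; computed from rank sums (Wilcoxon form), which equals
#' the exhaustive pairwise count.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher means more positive.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap standard error of a metric
#'
#' Standard deviation of the metric over \code{B} resamples (with
#' replacement) of the (y, y_hat) pairs. Resamples on which the metric is
#' undefined (zero variance, single class) are dropped.
#'
#' @param y,y_hat Observation/prediction pairs.
#' @param metric Function of (y, y_hat), e.g. \code{\link{r_squared}} or
#'   \code{function(y, s) auc(y, s)}.
#' @param B Number of resamples (>= 100).
#' @param seed RNG seed.
#' @export
bootstrap_sem <- function(y, y_hat, metric = r_squared, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L, length(y) == length(y_hat))
  n <- length(y)
  with_seed(seed, {
    vals <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric(y[idx], y_hat[idx]), error = function(e) NA_real_)
    }, 0)
    stats::sd(vals[is.finite(vals)])
  })
}
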