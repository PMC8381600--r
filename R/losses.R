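#' Adversarial domain-discrimination loss
#'
#' Cross-entropy of one source batch and one target batch against their
#' one-hot domain labels (source = class 1, target = class 2), summed over
#' the batch, natural log. Probabilities are floored at 1e-12 before the log.
#'
#' @param p_src softmax output matrix `2 x K` for the source batch.
#' @param p_tgt softmax output matrix `2 x K` for the target batch.
#' @return non-negative scalar loss.
#' @export
domain_adv_loss <- function(p_src, p_tgt) {
  -sum(log(clamp_prob(p_src[1L, ]))) - sum(log(clamp_prob(p_tgt[2L, ])))
}

#' Category cross-entropy on a labeled source batch
#'
#' One-hot cross-entropy (natural log, summed over the batch) of classifier
#' outputs against the true deviant/standard labels.
#'
#' @param p softmax output matrix `2 x K` (row 2 = P(deviant)).
#' @param y binary labels, length K (1 = deviant).
#' @return non-negative scalar loss.
#' @export
source_class_loss <- function(p, y) {
  if (ncol(p) != length(y)) stop("batch size mismatch between probs and labels")
  -sum(log(clamp_prob(p[cbind(as.integer(y) + 1L, seq_along(y))])))
}

#' Category cross-entropy against target pseudo labels
#'
#' Same form as [source_class_loss()] but the labels are the binarized
#' ensemble predictions (pseudo labels) of the unlabeled target batch, which
#' are treated as constants during backpropagation.
#'
#' @param p softmax output matrix `2 x K`.
#' @param pseudo binary pseudo labels, length K.
#' @return non-negative scalar loss.
#' @export
target_pseudo_loss <- function(p, pseudo) source_class_loss(p, pseudo)

#' Per-source perplexity scores and classifier weights
#'
#' The perplexity score of source j is the batch mean of
#' `-log(1 - D_j(F(x_t)))` over target samples (D_j = probability the j-th
#' discriminator assigns the sample to the target domain) plus the mean
#' discriminator loss `l_j` accumulated for that source. A source whose
#' discriminator is confused about the target (D near 0.5 or above) scores
#' high and its classifier earns more weight.
#'
#' @param d_target list (length N) of numeric vectors: per-sample D_j values
#'   on the target batch.
#' @param l_s numeric vector (length N) of mean discriminator losses.
#' @return a `perplexity_weights` object: list with `p_s` (scores), `l_s`,
#'   and `w` (normalized weights, see [classifier_weights()]).
#' @export
perplexity_scores <- function(d_target, l_s) {
  if (length(d_target) != length(l_s))
    stop("need one mean discriminator loss per source")
  p_s <- vapply(seq_along(d_target), function(j) {
    mean(-log(clamp_prob(1 - d_target[[j]]))) + l_s[[j]]
  }, numeric(1))
  structure(list(p_s = p_s, l_s = as.numeric(l_s), w = classifier_weights(p_s)),
            class = "perplexity_weights")
}

#' Normalize perplexity scores into ensemble weights
#'
#' `w_j = p_j / sum(p)`. If every score is zero the weights fall back to
#' uniform `1/N` (with a message).
#'
#' @param p_s numeric vector of non-negative perplexity scores (or a
#'   `perplexity_weights` object).
#' @return numeric weights on the simplex: `w >= 0`, `sum(w) = 1`.
#' @export
classifier_weights <- function(p_s) {
  if (inherits(p_s, "perplexity_weights")) p_s <- p_s$p_s
  if (any(p_s < 0)) stop("perplexity scores must be non-negative")
  tot <- sum(p_s)
  if (tot <= 0) {
    message("all perplexity scores are zero; falling back to uniform weights")
    return(rep(1 / length(p_s), length(p_s)))
  }
  p_s / tot
}

#' Weighted ensemble prediction over target samples
#'
#' Combines the per-source classifier probabilities with the perplexity
#' weights. The stored `p_hat` is the literal `(1/N) * sum_j w_j p_j`;
#' ranking and the pseudo-label threshold use the weighted mean
#' `sum_j w_j p_j` (the same quantity rescaled by N), which lies in `[0, 1]`
#' so that the conventional 0.5 cutoff is meaningful for any N. Ranking is
#' by descending probability with ties broken toward the original order.
#'
#' @param w weights (length N, from [classifier_weights()]).
#' @param probs matrix `N x n` of per-classifier P(deviant) for each target
#'   sample (a plain vector is taken as N = 1).
#' @return a `prediction_state`: list with `p_hat`, `weighted` (the
#'   N-rescaled probability used for thresholding), `pseudo_labels`,
#'   `ranking`.
#' @export
ensemble_predict <- function(w, probs) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  N <- nrow(probs)
  if (length(w) != N) stop("one weight per classifier required")
  weighted <- as.numeric(crossprod(w, probs))   # sum_j w_j p_j, in [0, 1]
  p_hat <- weighted / N
  structure(list(p_hat = p_hat, weighted = weighted,
                 pseudo_labels = as.integer(weighted > 0.5),
                 ranking = order(-p_hat, seq_along(p_hat))),
            class = "prediction_state")
}

#' Ranked target-sample pool
#'
#' Returns the indices of the top `ceiling(Q * n)` target samples by
#' descending ensemble probability; these form the target training pool of
#' the next epoch. Invariant under any strictly increasing transform of the
#' probabilities; all-equal probabilities yield the first samples in original
#' order.
#'
#' @param state a `prediction_state`.
#' @param Q retained fraction in (0, 1].
#' @return integer index vector of length `ceiling(Q * n)`.
#' @export
select_target_pool <- function(state, Q) {
  if (Q <= 0 || Q > 1) stop("Q must be in (0, 1]")
  n <- length(state$p_hat)
  state$ranking[seq_len(ceiling(Q * n))]
}

#' Class-balanced source resample
#'
#' Keeps every deviant trial and a uniformly drawn standard subset of equal
#' size (all standards, with a message, if they are the minority). Performed
#' once per training epoch so the rare deviant class is never swamped.
#'
#' @param epochs an `epoch_set`.
#' @param seed optional seed; NULL uses the current RNG stream.
#' @return a balanced `epoch_set`.
#' @export
balanced_source_sample <- function(epochs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dev <- which(epochs$labels == 1L)
  std <- which(epochs$labels == 0L)
  if (length(dev) == 0L || length(std) == 0L)
    stop("balanced resampling needs both classes")
  if (length(std) < length(dev)) {
    message("fewer standards than deviants; keeping all standards")
    keep_std <- std
  } else {
    keep_std <- std[sample.int(length(std), length(dev))]
  }
  subset_epochs(epochs, sort(c(dev, keep_std)), require_both_classes = TRUE)
}

#' Total adversarial training objective
#'
#' `alpha * sum_j L_adv_j + gamma * sum_j L_src_j + lambda * sum_j L_tgt_j`.
#'
#' @param bundle list with numeric vectors `L_adv`, `L_cls_src`, `L_cls_tgt`
#'   (one entry per source).
#' @param tcfg a [train_config()] (supplies `alpha`, `gamma`, `lambda`).
#' @return scalar total loss.
#' @export
total_loss <- function(bundle, tcfg) {
  tcfg$alpha * sum(bundle$L_adv) + tcfg$gamma * sum(bundle$L_cls_src) +
    tcfg$lambda * sum(bundle$L_cls_tgt)
}
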