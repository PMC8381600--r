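#' @keywords internal
"_PACKAGE"

# Probability floor used inside every log(); keeps cross-entropy finite when a
# softmax saturates.
PROB_EPS <- 1e-12

clamp_prob <- function(p) pmax(p, PROB_EPS)

#' Column-wise softmax
#'
#' Numerically stable softmax over the rows of each column of a logit matrix.
#'
#' @param logits numeric matrix (classes x batch).
#' @return matrix of the same shape; every column is non-negative and sums to 1.
#' @keywords internal
softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Derive a child seed from a master seed and a small integer tag, staying
# within the 32-bit signed range R requires for set.seed().
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 7919 + tag * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
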