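#' Model architecture configuration
#'
#' Geometry of the compact convolutional feature extractor. The first
#' temporal convolution uses kernels of length `fs/2 + 1` (about 2 Hz
#' frequency resolution), the spatial convolution collapses all channels, and
#' after two average-pooling stages (factors 2 and 5) the flattened feature
#' has length `F2 * T / 10`, which is also the input width of every
#' fully connected domain discriminator and category classifier.
#'
#' @param F1 number of temporal filters.
#' @param F2 number of spatial filters (= feature maps thereafter).
#' @param p_dropout dropout probability on the final feature maps (training
#'   only), in `[0, 1)`.
#' @param ch input channel count.
#' @param T samples per trial; must be divisible by 10.
#' @param fs sampling rate in Hz; `fs/2 + 1` and `fs/5 + 1` must be odd
#'   integers no longer than the signal they convolve (so `fs` must be a
#'   multiple of 20).
#' @return an object of class `model_config`.
#' @export
model_config <- function(F1 = 4L, F2 = 8L, p_dropout = 0.2, ch = 61L,
                         T = 100L, fs = 100) {
  if (T %% 10 != 0) stop("T must be divisible by 10")
  if (fs %% 20 != 0)
    stop("fs must be a multiple of 20 so both kernels fs/2+1 and fs/5+1 are odd")
  k1 <- fs / 2 + 1; k3 <- fs / 5 + 1
  if (k1 > T) stop("temporal kernel fs/2+1 exceeds trial length")
  if (k3 > T / 2) stop("second temporal kernel fs/5+1 exceeds pooled length T/2")
  if (p_dropout < 0 || p_dropout >= 1) stop("p_dropout must be in [0, 1)")
  structure(list(F1 = as.integer(F1), F2 = as.integer(F2),
                 p_dropout = p_dropout, ch = as.integer(ch), T = as.integer(T),
                 fs = fs, k1 = as.integer(k1), k3 = as.integer(k3)),
            class = "model_config")
}

#' Flattened feature dimension of a configuration
#'
#' @param mcfg a [model_config()].
#' @return integer, `F2 * T / 10`.
#' @export
feature_dim <- function(mcfg) as.integer(mcfg$F2 * mcfg$T / 10)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

runif_init <- function(dims, fan_in) {
  a <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -a, a), dim = dims)
}

#' Initialize all network parameters
#'
#' Feature extractor plus `n_sources` domain discriminators and category
#' classifiers, with the standard uniform fan-in scheme. Draws from the
#' current R random stream.
#'
#' @param mcfg a [model_config()].
#' @param n_sources number of source domains N.
#' @return list with `params` (trainable arrays) and `state` (batch-norm
#'   running statistics, not trained).
#' @export
init_network <- function(mcfg, n_sources) {
  d <- feature_dim(mcfg)
  p <- list(
    W1 = runif_init(c(mcfg$F1, mcfg$k1), mcfg$k1),
    b1 = as.numeric(runif_init(mcfg$F1, mcfg$k1)),
    bn1_gamma = rep(1, mcfg$F1), bn1_beta = rep(0, mcfg$F1),
    W2 = runif_init(c(mcfg$ch * mcfg$F1, mcfg$F2), mcfg$ch * mcfg$F1),
    b2 = as.numeric(runif_init(mcfg$F2, mcfg$ch * mcfg$F1)),
    bn2_gamma = rep(1, mcfg$F2), bn2_beta = rep(0, mcfg$F2),
    W3 = runif_init(c(mcfg$F2 * mcfg$k3, mcfg$F2), mcfg$F2 * mcfg$k3),
    b3 = as.numeric(runif_init(mcfg$F2, mcfg$F2 * mcfg$k3)),
    bn3_gamma = rep(1, mcfg$F2), bn3_beta = rep(0, mcfg$F2)
  )
  for (j in seq_len(n_sources)) {
    p[[paste0("disc_W", j)]] <- runif_init(c(2L, d), d)
    p[[paste0("disc_b", j)]] <- as.numeric(runif_init(2L, d))
    p[[paste0("clf_W", j)]] <- runif_init(c(2L, d), d)
    p[[paste0("clf_b", j)]] <- as.numeric(runif_init(2L, d))
  }
  state <- list(
    bn1_mean = rep(0, mcfg$F1), bn1_var = rep(1, mcfg$F1),
    bn2_mean = rep(0, mcfg$F2), bn2_var = rep(1, mcfg$F2),
    bn3_mean = rep(0, mcfg$F2), bn3_var = rep(1, mcfg$F2))
  list(params = p, state = state)
}

# ---- batch norm over the columns of a (samples x maps) matrix -------------

bn_forward <- function(Z, gamma, beta, run_mean, run_var, train) {
  if (train) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    v <- pmax(v, 0)
    new_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    new_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(Z, 2, mu, "-"), 2, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(Y = Y, xhat = xhat, inv_sd = inv_sd,
       new_mean = new_mean, new_var = new_var)
}

bn_backward <- function(dY, xhat, inv_sd, gamma) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dZ <- sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"),
              2, inv_sd, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Same-padded 1-d convolutions are evaluated as banded-matrix products:
# out[t] = sum_k w[k] * xpad[t + k - 1] is B %*% xpad with B[t, t+k-1] = w[k].
# The band indices depend only on the geometry, so they are precomputed once
# per forward/backward pair; filling the band and the GEMM are the only
# per-step costs.

.band_cache <- new.env(parent = emptyenv())

band_memo <- function(key, builder) {
  if (is.null(.band_cache[[key]])) .band_cache[[key]] <- builder()
  .band_cache[[key]]
}

# linear indices of the band entries of the stacked (nf*T x Tpad) matrix,
# ordered (t, k, f): entry for filter block f at row (f-1)*T + t,
# column t + k - 1
band_index_1 <- function(T, k, nf) {
  t <- seq_len(T)
  idx <- array(0L, dim = c(T, k, nf))
  for (f in seq_len(nf)) for (kk in seq_len(k))
    idx[, kk, f] <- ((f - 1L) * T + t) + (nf * T) * (t + kk - 2L)
  as.vector(idx)
}

# as above for the blocked conv3: output block g, input block f, entry at
# row (g-1)*T + t, column (f-1)*Tpad + t + k - 1; ordered (t, k, g, f)
band_index_3 <- function(T, Tpad, k, nf_out, nf_in) {
  t <- seq_len(T)
  idx <- array(0L, dim = c(T, k, nf_out, nf_in))
  nr <- nf_out * T
  for (f in seq_len(nf_in)) for (g in seq_len(nf_out)) for (kk in seq_len(k))
    idx[, kk, g, f] <- ((g - 1L) * T + t) +
      nr * ((f - 1L) * Tpad + t + kk - 2L)
  as.vector(idx)
}

#' Feature extractor forward pass
#'
#' Runs the three-convolution pipeline on a batch of trials. Training mode
#' uses batch statistics for the batch-norm layers (updating the running
#' averages) and applies feature-map dropout from the current R random
#' stream; evaluation mode uses the running averages and no dropout.
#'
#' @param mcfg a [model_config()].
#' @param params,state from [init_network()].
#' @param X array `T x ch x batch` (note time-major layout) or a single
#'   `ch x T` trial matrix.
#' @param train logical.
#' @param keep_cache keep intermediates for [feature_backward()].
#' @return list with `feats` (matrix `feature_dim x batch`), `state` (updated
#'   running statistics) and, if requested, `cache`.
#' @export
feature_forward <- function(mcfg, params, state, X, train = FALSE,
                            keep_cache = FALSE) {
  if (is.matrix(X)) {  # single ch x T trial
    if (nrow(X) != mcfg$ch || ncol(X) != mcfg$T)
      stop("input trial must be ch x T (", mcfg$ch, " x ", mcfg$T, ")")
    X <- array(t(X), dim = c(mcfg$T, mcfg$ch, 1L))
  }
  dX <- dim(X)
  if (length(dX) != 3L || dX[1L] != mcfg$T || dX[2L] != mcfg$ch)
    stop("input must be a T x ch x batch array")
  T <- mcfg$T; ch <- mcfg$ch; b <- dX[3L]
  F1 <- mcfg$F1; F2 <- mcfg$F2; k1 <- mcfg$k1; k3 <- mcfg$k3
  T2 <- T %/% 2L; T10 <- T %/% 10L
  pad1 <- (k1 - 1L) %/% 2L; pad3 <- (k3 - 1L) %/% 2L

  # conv 1: temporal, per channel, same padding, as a banded GEMM
  Tp1 <- T + k1 - 1L
  Xp <- matrix(0, Tp1, ch * b)
  Xp[pad1 + seq_len(T), ] <- X                   # (Tp1, ch*b)
  idx1 <- band_memo(sprintf("b1_%d_%d_%d", T, k1, F1),
                    function() band_index_1(T, k1, F1))
  B1 <- matrix(0, F1 * T, Tp1)
  B1[idx1] <- rep(as.vector(t(params$W1)), each = T)
  O1 <- B1 %*% Xp                                # (F1*T, ch*b), t within f
  Z1 <- matrix(0, T * ch * b, F1)
  for (f in seq_len(F1))
    Z1[, f] <- as.vector(O1[(f - 1L) * T + seq_len(T), ])
  Z1 <- sweep(Z1, 2, params$b1, "+")
  bn1 <- bn_forward(Z1, params$bn1_gamma, params$bn1_beta,
                    state$bn1_mean, state$bn1_var, train)

  # conv 2: spatial, collapses channels
  A1 <- array(bn1$Y, dim = c(T, ch, b, F1))
  M1 <- aperm(A1, c(1L, 3L, 2L, 4L))             # (T, b, ch, F1)
  dim(M1) <- c(T * b, ch * F1)
  Z2 <- M1 %*% params$W2
  Z2 <- sweep(Z2, 2, params$b2, "+")             # (T*b, F2)
  bn2 <- bn_forward(Z2, params$bn2_gamma, params$bn2_beta,
                    state$bn2_mean, state$bn2_var, train)
  mask2 <- bn2$Y > 0
  R2 <- bn2$Y * mask2
  P2 <- colMeans(array(R2, dim = c(2L, T2, b, F2)), dims = 1L)  # (T2, b, F2)

  # conv 3: temporal summary across feature maps, same padding, blocked GEMM
  Tp3 <- T2 + k3 - 1L
  Ppad <- array(0, dim = c(Tp3, b, F2))
  Ppad[pad3 + seq_len(T2), , ] <- P2
  Pstack <- aperm(Ppad, c(1L, 3L, 2L))           # (Tp3, F2, b)
  dim(Pstack) <- c(Tp3 * F2, b)
  idx3 <- band_memo(sprintf("b3_%d_%d_%d_%d", T2, Tp3, k3, F2),
                    function() band_index_3(T2, Tp3, k3, F2, F2))
  B3 <- matrix(0, F2 * T2, F2 * Tp3)
  W3arr <- array(params$W3, dim = c(F2, k3, F2)) # (f_in, k, g)
  B3[idx3] <- rep(as.vector(aperm(W3arr, c(2L, 3L, 1L))), each = T2)
  O3 <- B3 %*% Pstack                            # (F2*T2, b), t within g
  Z3 <- aperm(array(O3, dim = c(T2, F2, b)), c(1L, 3L, 2L))
  dim(Z3) <- c(T2 * b, F2)
  Z3 <- sweep(Z3, 2, params$b3, "+")             # (T2*b, F2)
  bn3 <- bn_forward(Z3, params$bn3_gamma, params$bn3_beta,
                    state$bn3_mean, state$bn3_var, train)
  mask3 <- bn3$Y > 0
  R3 <- bn3$Y * mask3
  P5 <- colMeans(array(R3, dim = c(5L, T10, b, F2)), dims = 1L) # (T10, b, F2)

  # feature-map dropout (whole map per sample), training only
  if (train && mcfg$p_dropout > 0) {
    keep <- matrix(stats::rbinom(b * F2, 1L, 1 - mcfg$p_dropout), b, F2)
    dropmask <- keep / (1 - mcfg$p_dropout)
  } else {
    dropmask <- matrix(1, b, F2)
  }
  P5d <- P5 * array(rep(dropmask, each = T10), dim = c(T10, b, F2))

  Fm <- aperm(P5d, c(1L, 3L, 2L))                # (T10, F2, b)
  dim(Fm) <- c(T10 * F2, b)

  new_state <- list(bn1_mean = bn1$new_mean, bn1_var = bn1$new_var,
                    bn2_mean = bn2$new_mean, bn2_var = bn2$new_var,
                    bn3_mean = bn3$new_mean, bn3_var = bn3$new_var)
  cache <- NULL
  if (keep_cache)
    cache <- list(Xp = Xp, idx1 = idx1, bn1 = bn1, M1 = M1, bn2 = bn2,
                  mask2 = mask2, bn3 = bn3, mask3 = mask3, Pstack = Pstack,
                  B3 = B3, idx3 = idx3, dropmask = dropmask, b = b)
  list(feats = Fm, state = new_state, cache = cache)
}

#' Feature extractor backward pass
#'
#' Backpropagates a gradient with respect to the flattened features through
#' the pipeline cached by [feature_forward()] (training mode), returning
#' gradients for every feature-extractor parameter. The gradient with respect
#' to the raw input is not formed (it is never needed).
#'
#' @param mcfg a [model_config()].
#' @param params trainable parameters.
#' @param cache cache from `feature_forward(..., keep_cache = TRUE)`.
#' @param dF gradient matrix `feature_dim x batch`.
#' @return named list of gradients matching the feature-extractor entries of
#'   `params`.
#' @export
feature_backward <- function(mcfg, params, cache, dF) {
  T <- mcfg$T; ch <- mcfg$ch; b <- cache$b
  F1 <- mcfg$F1; F2 <- mcfg$F2; k3 <- mcfg$k3
  T2 <- T %/% 2L; T10 <- T %/% 10L
  pad3 <- (k3 - 1L) %/% 2L

  G <- array(dF, dim = c(T10, F2, b))
  dP5d <- aperm(G, c(1L, 3L, 2L))                # (T10, b, F2)
  dP5 <- dP5d * array(rep(cache$dropmask, each = T10), dim = c(T10, b, F2))
  # pool5 backward: spread each pooled value over its 5 inputs
  dR3 <- array(rep(as.vector(dP5) / 5, each = 5L), dim = c(5L, T10, b, F2))
  dR3 <- matrix(dR3, T2 * b, F2)
  dA3 <- dR3 * cache$mask3
  bn3b <- bn_backward(dA3, cache$bn3$xhat, cache$bn3$inv_sd, params$bn3_gamma)
  dZ3 <- bn3b$dZ
  db3 <- colSums(dZ3)
  dO3 <- aperm(array(dZ3, dim = c(T2, b, F2)), c(1L, 3L, 2L))
  dim(dO3) <- c(T2 * F2, b)                      # (F2*T2, b), t within g
  dB3 <- tcrossprod(dO3, cache$Pstack)           # (F2*T2, F2*Tp3)
  dW3v <- colSums(matrix(dB3[cache$idx3], T2))   # ordered (k, g, f_in)
  dW3 <- array(dW3v, dim = c(k3, F2, F2))        # (k, g, f_in)
  dW3 <- aperm(dW3, c(3L, 1L, 2L))               # (f_in, k, g)
  dim(dW3) <- c(F2 * k3, F2)
  dPstack <- crossprod(cache$B3, dO3)            # (F2*Tp3, b), t within f
  dPpad <- aperm(array(dPstack, dim = c(T2 + k3 - 1L, F2, b)), c(1L, 3L, 2L))
  dP2 <- dPpad[pad3 + seq_len(T2), , , drop = FALSE]
  dim(dP2) <- c(T2, b, F2)
  dR2 <- array(rep(as.vector(dP2) / 2, each = 2L), dim = c(2L, T2, b, F2))
  dR2 <- matrix(dR2, T * b, F2)
  dA2 <- dR2 * cache$mask2
  bn2b <- bn_backward(dA2, cache$bn2$xhat, cache$bn2$inv_sd, params$bn2_gamma)
  dZ2 <- bn2b$dZ
  dW2 <- crossprod(cache$M1, dZ2)
  db2 <- colSums(dZ2)
  dM1 <- dZ2 %*% t(params$W2)                    # (T*b, ch*F1)
  dA1 <- aperm(array(dM1, dim = c(T, b, ch, F1)), c(1L, 3L, 2L, 4L))
  dim(dA1) <- c(T * ch * b, F1)
  bn1b <- bn_backward(dA1, cache$bn1$xhat, cache$bn1$inv_sd, params$bn1_gamma)
  dZ1 <- bn1b$dZ
  db1 <- colSums(dZ1)
  k1 <- mcfg$k1
  dO1 <- matrix(0, F1 * T, ch * b)               # t within f
  for (f in seq_len(F1))
    dO1[(f - 1L) * T + seq_len(T), ] <- matrix(dZ1[, f], T, ch * b)
  dB1 <- tcrossprod(dO1, cache$Xp)               # (F1*T, Tp1)
  dW1v <- colSums(matrix(dB1[cache$idx1], T))    # ordered (k, f)
  dW1 <- t(matrix(dW1v, k1, F1))                 # (F1, k1)

  list(W1 = dW1, b1 = db1,
       bn1_gamma = bn1b$dgamma, bn1_beta = bn1b$dbeta,
       W2 = dW2, b2 = db2,
       bn2_gamma = bn2b$dgamma, bn2_beta = bn2b$dbeta,
       W3 = dW3, b3 = db3,
       bn3_gamma = bn3b$dgamma, bn3_beta = bn3b$dbeta)
}

#' Fully connected softmax head
#'
#' One affine layer to 2 logits followed by a softmax; used for every domain
#' discriminator and category classifier. Output convention: row 1 is
#' "source domain" / "standard", row 2 is "target domain" / "deviant".
#'
#' @param W weight matrix `2 x feature_dim`; `b` length-2 bias.
#' @param feats feature matrix `feature_dim x batch`.
#' @return list with `probs` (2 x batch, columns sum to 1) and `logits`.
#' @export
head_forward <- function(W, b, feats) {
  if (nrow(feats) != ncol(W))
    stop("feature length ", nrow(feats), " does not match head input width ",
         ncol(W))
  logits <- W %*% feats + b
  list(probs = softmax_cols(logits), logits = logits)
}

# gradient of a scaled cross-entropy through softmax: dlogits = s*(p - y)
head_backward <- function(W, feats, dlogits) {
  list(dW = dlogits %*% t(feats), db = rowSums(dlogits),
       dfeats = t(W) %*% dlogits)
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; during backpropagation the gradient flowing
#' from a domain discriminator back into the feature extractor is negated
#' ([grad_reverse_backward()]), so minimizing the discriminator loss in the
#' head simultaneously maximizes it in the features — the adversarial
#' confusion objective.
#'
#' @param x any numeric input.
#' @return `grad_reverse()` returns `x` unchanged; `grad_reverse_backward()`
#'   returns the negated gradient.
#' @export
grad_reverse <- function(x) x

#' @rdname grad_reverse
#' @param grad gradient with respect to the layer output.
#' @export
grad_reverse_backward <- function(grad) -grad

# ---- Adam optimizer over a named list of arrays ---------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
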