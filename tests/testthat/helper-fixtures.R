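# Shared fixtures and independent oracles, all generated in code.

# tiny geometry that satisfies the architecture constraints
# (T divisible by 10, kernels fs/2+1 and fs/5+1 odd and short enough)
tiny_mcfg <- function(ch = 3L, p_dropout = 0) {
  model_config(F1 = 2L, F2 = 3L, p_dropout = p_dropout, ch = ch,
               T = 20L, fs = 20)
}

tiny_synth_cfg <- function(seed = 1L, channels = 3L, n_trials = 64L) {
  synth_config(channels = channels, fs = 20, trial_len = 20,
               imbalance_ratio = 3, n_trials = n_trials, seed = seed,
               noise_sd = 8)
}

tiny_subject <- function(id = "s", gain = 2, seed = 1L, channels = 3L,
                         n_trials = 64L, ...) {
  cfg <- tiny_synth_cfg(seed, channels, n_trials)
  simulate_subject(subject_profile(id, "strong", p3_gain = gain, ...),
                   cfg, seed = seed)
}

# hand-built epoch set with constant-valued trials (one value per trial)
const_epochs <- function(values, labels, ch = 2L, T = 4L, fs = 20) {
  n <- length(values)
  trials <- array(rep(values, times = ch * T), dim = c(n, ch, T))
  epoch_set(trials, labels, fs, require_both_classes = FALSE)
}

# --- independent naive forward pass (direct nested loops) -------------------
# Recomputes the feature extractor from its layer definitions without any of
# the banded-GEMM machinery; used as the forward-pass oracle.
naive_feature_forward <- function(mcfg, params, state, X, train = FALSE) {
  T <- mcfg$T; ch <- mcfg$ch; b <- dim(X)[3L]
  F1 <- mcfg$F1; F2 <- mcfg$F2; k1 <- mcfg$k1; k3 <- mcfg$k3
  T2 <- T / 2; T10 <- T / 10
  pad1 <- (k1 - 1) / 2; pad3 <- (k3 - 1) / 2
  eps <- 1e-5
  bn <- function(Z, gamma, beta, rmean, rvar) {
    if (train) { mu <- colMeans(Z); v <- colMeans(Z^2) - mu^2 }
    else { mu <- rmean; v <- rvar }
    sweep(sweep(sweep(sweep(Z, 2, mu, "-"), 2, sqrt(v + eps), "/"),
                2, gamma, "*"), 2, beta, "+")
  }
  # conv1
  Xpad <- array(0, c(T + k1 - 1, ch, b))
  Xpad[pad1 + seq_len(T), , ] <- X
  Z1 <- matrix(0, T * ch * b, F1)  # rows ordered t fastest, then c, then b
  for (f in seq_len(F1)) {
    o <- array(0, c(T, ch, b))
    for (bb in seq_len(b)) for (cc in seq_len(ch)) for (tt in seq_len(T))
      o[tt, cc, bb] <- sum(params$W1[f, ] * Xpad[tt:(tt + k1 - 1), cc, bb]) +
        params$b1[f]
    Z1[, f] <- as.vector(o)
  }
  A1 <- bn(Z1, params$bn1_gamma, params$bn1_beta, state$bn1_mean, state$bn1_var)
  A1 <- array(A1, c(T, ch, b, F1))
  # conv2 (spatial): W2 rows ordered channel-fastest within filter
  Z2 <- matrix(0, T * b, F2)
  for (g in seq_len(F2)) {
    o <- array(0, c(T, b))
    for (bb in seq_len(b)) for (tt in seq_len(T)) {
      acc <- params$b2[g]
      for (f in seq_len(F1)) for (cc in seq_len(ch))
        acc <- acc + params$W2[cc + ch * (f - 1), g] * A1[tt, cc, bb, f]
      o[tt, bb] <- acc
    }
    Z2[, g] <- as.vector(o)
  }
  A2 <- bn(Z2, params$bn2_gamma, params$bn2_beta, state$bn2_mean, state$bn2_var)
  R2 <- pmax(A2, 0)
  P2 <- array(0, c(T2, b, F2))
  R2a <- array(R2, c(T, b, F2))
  for (tt in seq_len(T2))
    P2[tt, , ] <- (R2a[2 * tt - 1, , ] + R2a[2 * tt, , ]) / 2
  # conv3: W3 rows ordered map-fastest within kernel offset
  Ppad <- array(0, c(T2 + k3 - 1, b, F2))
  Ppad[pad3 + seq_len(T2), , ] <- P2
  Z3 <- matrix(0, T2 * b, F2)
  for (g in seq_len(F2)) {
    o <- array(0, c(T2, b))
    for (bb in seq_len(b)) for (tt in seq_len(T2)) {
      acc <- params$b3[g]
      for (f in seq_len(F2)) for (kk in seq_len(k3))
        acc <- acc + params$W3[f + F2 * (kk - 1), g] * Ppad[tt + kk - 1, bb, f]
      o[tt, bb] <- acc
    }
    Z3[, g] <- as.vector(o)
  }
  A3 <- bn(Z3, params$bn3_gamma, params$bn3_beta, state$bn3_mean, state$bn3_var)
  R3 <- array(pmax(A3, 0), c(T2, b, F2))
  P5 <- array(0, c(T10, b, F2))
  for (tt in seq_len(T10))
    P5[tt, , ] <- apply(R3[(5 * tt - 4):(5 * tt), , , drop = FALSE], c(2, 3), mean)
  Fm <- aperm(P5, c(1, 3, 2))
  dim(Fm) <- c(T10 * F2, b)
  Fm
}

# random 2-class probability columns
rand_probs <- function(K) {
  p <- matrix(stats::runif(2 * K, 0.01, 1), 2, K)
  sweep(p, 2, colSums(p), "/")
}

# --- scalar-loop cross-entropy oracle ---------------------------------------
# Independent elementwise implementation of the three losses.
loop_ce <- function(p, y_index) {
  # p: 2 x K probs; y_index: 1-based true class per column
  tot <- 0
  for (k in seq_len(ncol(p))) {
    pk <- max(p[y_index[k], k], 1e-12)
    tot <- tot - log(pk)
  }
  tot
}

# --- composite loss harness for gradient checks -----------------------------
# Mirrors one training step's objective (N = 1 source) using the exported
# primitives; deterministic given fixed inputs (dropout must be 0).
composite_loss <- function(mcfg, params, state, Xs, ys, Xt, pseudo, tcfg) {
  b_s <- dim(Xs)[3L]; b_t <- dim(Xt)[3L]
  X <- array(0, dim = c(mcfg$T, mcfg$ch, b_s + b_t))
  X[, , seq_len(b_s)] <- Xs
  X[, , b_s + seq_len(b_t)] <- Xt
  fw <- feature_forward(mcfg, params, state, X, train = TRUE, keep_cache = TRUE)
  fs <- fw$feats[, seq_len(b_s), drop = FALSE]
  ft <- fw$feats[, b_s + seq_len(b_t), drop = FALSE]
  hd <- head_forward(params$disc_W1, params$disc_b1, cbind(fs, ft))
  L_adv <- domain_adv_loss(hd$probs[, seq_len(b_s), drop = FALSE],
                           hd$probs[, b_s + seq_len(b_t), drop = FALSE])
  hc <- head_forward(params$clf_W1, params$clf_b1, fs)
  L_src <- source_class_loss(hc$probs, ys)
  ht <- head_forward(params$clf_W1, params$clf_b1, ft)
  L_tgt <- target_pseudo_loss(ht$probs, pseudo)
  total <- total_loss(list(L_adv = L_adv, L_cls_src = L_src, L_cls_tgt = L_tgt),
                      tcfg)
  list(total = total, fw = fw, fs = fs, ft = ft, hd = hd, hc = hc, ht = ht)
}

# analytic gradients for composite_loss, using the same backward machinery
# the trainer uses (gradient reversal on the discriminator path)
composite_grads <- function(mcfg, params, state, Xs, ys, Xt, pseudo, tcfg) {
  cl <- composite_loss(mcfg, params, state, Xs, ys, Xt, pseudo, tcfg)
  b_s <- length(ys); b_t <- length(pseudo)
  onehot <- function(y) rbind(1 - y, y)
  Ydom <- cbind(matrix(c(1, 0), 2, b_s), matrix(c(0, 1), 2, b_t))
  d <- feature_dim(mcfg)
  dfeat <- matrix(0, d, b_s + b_t)
  hb <- head_backward(params$disc_W1, cbind(cl$fs, cl$ft),
                      tcfg$alpha * (cl$hd$probs - Ydom))
  rev <- grad_reverse_backward(hb$dfeats)
  dfeat <- dfeat + rev
  cb <- head_backward(params$clf_W1, cl$fs,
                      tcfg$gamma * (cl$hc$probs - onehot(ys)))
  dfeat[, seq_len(b_s)] <- dfeat[, seq_len(b_s)] + cb$dfeats
  tb <- head_backward(params$clf_W1, cl$ft,
                      tcfg$lambda * (cl$ht$probs - onehot(pseudo)))
  dfeat[, b_s + seq_len(b_t)] <- dfeat[, b_s + seq_len(b_t)] + tb$dfeats
  fg <- feature_backward(mcfg, params, cl$fw$cache, dfeat)
  c(fg, list(disc_W1 = hb$dW, disc_b1 = hb$db,
             clf_W1 = cb$dW + tb$dW, clf_b1 = cb$db + tb$db))
}

# scaled-down adaptation scenario: two strong-response source subjects and
# one target whose P3 is weaker, later (+40 ms), spatially rotated by one
# channel and noisier -- a plausible cross-subject shift
adaptation_scenario <- function(seed) {
  cfg <- synth_config(channels = 8, n_trials = 300, seed = seed, noise_sd = 10)
  comps <- default_erp_components(8)
  ds <- function(tag) p3msda:::derive_seed(seed, tag)
  list(
    s1 = simulate_subject(
      subject_profile("s1", "strong", p3_gain = 3.0, noise_sd = 10),
      cfg, comps, seed = ds(1)),
    s2 = simulate_subject(
      subject_profile("s2", "strong", p3_gain = 2.7, noise_sd = 11,
                      latency_shift = 10),
      cfg, comps, seed = ds(2)),
    weak1 = simulate_subject(
      subject_profile("w1", "weak", p3_gain = 0.5, noise_sd = 10),
      cfg, comps, seed = ds(4)),
    weak2 = simulate_subject(
      subject_profile("w2", "weak", p3_gain = 0.55, noise_sd = 11,
                      latency_shift = 10),
      cfg, comps, seed = ds(5)),
    target = simulate_subject(
      subject_profile("t", "medium", p3_gain = 1.5, noise_sd = 12,
                      latency_shift = 40, focus_offset = 1,
                      jitter_scale = 1.2),
      cfg, comps, seed = ds(3)))
}
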