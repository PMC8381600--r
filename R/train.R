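#' Training configuration
#'
#' @param alpha weight of the adversarial domain losses.
#' @param gamma weight of the supervised source category losses.
#' @param lambda weight of the target pseudo-label losses.
#' @param K batch size per domain; must be even (each source batch holds K/2
#'   deviants and K/2 standards) and at least 2.
#' @param Q fraction of ranked target samples retained as the next epoch's
#'   training pool, in (0, 1].
#' @param lr Adam learning rate.
#' @param epochs number of training epochs.
#' @param seed master seed controlling initialization, resampling, batch
#'   shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(alpha = 0.2, gamma = 0.8, lambda = 0.2, K = 20L,
                         Q = 0.8, lr = 3e-4, epochs = 300L, seed = 1L) {
  if (alpha < 0 || gamma < 0 || lambda < 0)
    stop("loss weights must be non-negative")
  if (K < 2L || K %% 2L != 0L) stop("K must be even and >= 2")
  if (Q <= 0 || Q > 1) stop("Q must be in (0, 1]")
  structure(list(alpha = alpha, gamma = gamma, lambda = lambda,
                 K = as.integer(K), Q = Q, lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

onehot2 <- function(y) rbind(1 - y, y)

# trials (n x ch x T) -> time-major array (T x ch x n)
time_major <- function(trials) aperm(trials, c(3L, 2L, 1L))

# evaluation-mode scoring of a target array against every head
score_target <- function(mcfg, params, state, Xt, n_sources, chunk = 512L) {
  n <- dim(Xt)[3L]
  d <- feature_dim(mcfg)
  disc <- matrix(0, n_sources, n)
  clf <- matrix(0, n_sources, n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    fw <- feature_forward(mcfg, params, state, Xt[, , idx, drop = FALSE],
                          train = FALSE)
    for (j in seq_len(n_sources)) {
      disc[j, idx] <- head_forward(params[[paste0("disc_W", j)]],
                                   params[[paste0("disc_b", j)]],
                                   fw$feats)$probs[2L, ]
      clf[j, idx] <- head_forward(params[[paste0("clf_W", j)]],
                                  params[[paste0("clf_b", j)]],
                                  fw$feats)$probs[2L, ]
    }
    at <- at + chunk
  }
  list(disc = disc, clf = clf)
}

#' Fit a multi-source adversarial domain-adaptation model
#'
#' Trains the shared convolutional feature extractor, one domain
#' discriminator and one category classifier per source domain, on labeled
#' source subjects plus the *unlabeled* trials of a target subject (any
#' labels present in `target` are ignored). Each epoch: every source is
#' class-rebalanced (all deviants + an equal random standard subset), the
#' target training pool is the top-Q fraction of target samples ranked by the
#' current ensemble probability (initially all of them), and `m` joint
#' batches of K samples per domain are stepped with Adam on the combined
#' objective `alpha * adversarial + gamma * source category + lambda * target
#' pseudo-label`. Discriminator gradients reach the feature extractor through
#' the gradient reversal layer; classifier weights are refreshed every batch
#' from the perplexity scores. After each epoch the full target set is
#' re-scored in evaluation mode and re-ranked.
#'
#' @param sources list of labeled `epoch_set` objects, one per source domain.
#' @param target `epoch_set` of the target subject; only its trials are used.
#' @param mcfg a [model_config()]; defaults to the data geometry with the
#'   standard filter counts.
#' @param tcfg a [train_config()].
#' @param verbose print a progress line every 10 epochs.
#' @return an object of class `p3msda` with components `params`, `bn_state`,
#'   `weights` (final ensemble weights), `perplexity`, `prediction` (final
#'   `prediction_state` on the target set), `history` (per-epoch losses) and
#'   the configurations. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @export
p3msda <- function(sources, target, mcfg = NULL, tcfg = train_config(),
                   verbose = FALSE) {
  if (inherits(sources, "epoch_set")) sources <- list(sources)
  N <- length(sources)
  if (N < 1L) stop("at least one source domain is required")
  stopifnot(inherits(target, "epoch_set"))
  if (is.null(mcfg))
    mcfg <- model_config(ch = n_channels(target), T = n_samples(target),
                         fs = target$fs)
  for (s in sources) {
    if (n_channels(s) != mcfg$ch || n_samples(s) != mcfg$T)
      stop("source geometry does not match the model configuration")
  }
  if (n_channels(target) != mcfg$ch || n_samples(target) != mcfg$T)
    stop("target geometry does not match the model configuration")

  K <- tcfg$K; half <- K %/% 2L
  d <- feature_dim(mcfg)
  set.seed(tcfg$seed)
  net <- init_network(mcfg, N)
  params <- net$params; state <- net$state
  opt <- adam_init(params)

  Xs <- lapply(sources, function(s) time_major(s$trials))
  ys <- lapply(sources, `[[`, "labels")
  Xt <- time_major(target$trials)   # labels (if any) are never read
  n_t <- dim(Xt)[3L]
  pool <- seq_len(n_t)

  hist_rows <- vector("list", tcfg$epochs)
  tgt_cols <- N * K + seq_len(K)
  w <- rep(1 / N, N)
  pw <- NULL; pred_state <- NULL

  for (epoch in seq_len(tcfg$epochs)) {
    # per-epoch balanced resample of every source (all deviants + matched
    # standard subset), then per-class shuffles for batch construction
    dev_ord <- std_ord <- vector("list", N)
    m <- floor(length(pool) / K)
    for (j in seq_len(N)) {
      dev <- which(ys[[j]] == 1L)
      std <- which(ys[[j]] == 0L)
      nbal <- min(length(dev), length(std))
      if (nbal < half)
        stop("source ", j, " has too few trials per class for batch size K = ", K)
      dev_ord[[j]] <- sample(dev)[seq_len(nbal)]
      std_ord[[j]] <- std[sample.int(length(std), nbal)]
      m <- min(m, floor(nbal / half))
    }
    if (m < 1L)
      stop("not enough samples to form a single batch (K = ", K, ")")
    pool_ord <- sample(pool)

    l_run <- rep(0, N); nb <- 0L
    ep_adv <- ep_src <- ep_tgt <- rep(0, N); ep_total <- 0
    for (bt in seq_len(m)) {
      tgt_idx <- pool_ord[(bt - 1L) * K + seq_len(K)]
      batch_idx <- vector("list", N)
      ybatch <- vector("list", N)
      X <- array(0, dim = c(mcfg$T, mcfg$ch, N * K + K))
      for (j in seq_len(N)) {
        sl <- (bt - 1L) * half + seq_len(half)
        bi <- c(dev_ord[[j]][sl], std_ord[[j]][sl])
        batch_idx[[j]] <- bi
        ybatch[[j]] <- ys[[j]][bi]
        X[, , (j - 1L) * K + seq_len(K)] <- Xs[[j]][, , bi]
      }
      X[, , tgt_cols] <- Xt[, , tgt_idx]

      fw <- feature_forward(mcfg, params, state, X, train = TRUE,
                            keep_cache = TRUE)
      state <- fw$state
      feats <- fw$feats
      dfeat <- matrix(0, d, N * K + K)
      hgrads <- list()
      L_adv <- L_src <- L_tgt <- numeric(N)
      d_tgt <- vector("list", N)
      clf_tgt <- vector("list", N)
      clf_tgt_probs <- matrix(0, N, K)
      ft <- feats[, tgt_cols, drop = FALSE]

      for (j in seq_len(N)) {
        scols <- (j - 1L) * K + seq_len(K)
        fs_j <- feats[, scols, drop = FALSE]
        dW <- params[[paste0("disc_W", j)]]
        db <- params[[paste0("disc_b", j)]]
        hd <- head_forward(dW, db, cbind(fs_j, ft))
        ps <- hd$probs[, seq_len(K), drop = FALSE]
        pt <- hd$probs[, K + seq_len(K), drop = FALSE]
        L_adv[j] <- domain_adv_loss(ps, pt)
        l_run[j] <- l_run[j] + mean(-log(clamp_prob(ps[1L, ])))
        d_tgt[[j]] <- pt[2L, ]
        Ydom <- cbind(matrix(c(1, 0), 2L, K), matrix(c(0, 1), 2L, K))
        hb <- head_backward(dW, cbind(fs_j, ft),
                            tcfg$alpha * (hd$probs - Ydom))
        hgrads[[paste0("disc_W", j)]] <- hb$dW
        hgrads[[paste0("disc_b", j)]] <- hb$db
        # adversarial path: gradient reversal into the feature extractor
        rev <- grad_reverse_backward(hb$dfeats)
        dfeat[, scols] <- dfeat[, scols] + rev[, seq_len(K), drop = FALSE]
        dfeat[, tgt_cols] <- dfeat[, tgt_cols] + rev[, K + seq_len(K), drop = FALSE]

        cW <- params[[paste0("clf_W", j)]]
        cb <- params[[paste0("clf_b", j)]]
        hc <- head_forward(cW, cb, fs_j)
        L_src[j] <- source_class_loss(hc$probs, ybatch[[j]])
        cb_back <- head_backward(cW, fs_j,
                                 tcfg$gamma * (hc$probs - onehot2(ybatch[[j]])))
        hgrads[[paste0("clf_W", j)]] <- cb_back$dW
        hgrads[[paste0("clf_b", j)]] <- cb_back$db
        dfeat[, scols] <- dfeat[, scols] + cb_back$dfeats

        clf_tgt[[j]] <- head_forward(cW, cb, ft)
        clf_tgt_probs[j, ] <- clf_tgt[[j]]$probs[2L, ]
      }

      nb <- nb + 1L
      pw <- perplexity_scores(d_tgt, l_run / nb)
      w <- pw$w
      bstate <- ensemble_predict(w, clf_tgt_probs)
      pseudo <- bstate$pseudo_labels
      if (tcfg$lambda > 0) {
        for (j in seq_len(N)) {
          cW <- params[[paste0("clf_W", j)]]
          L_tgt[j] <- target_pseudo_loss(clf_tgt[[j]]$probs, pseudo)
          tb <- head_backward(cW, ft,
                              tcfg$lambda * (clf_tgt[[j]]$probs - onehot2(pseudo)))
          hgrads[[paste0("clf_W", j)]] <-
            hgrads[[paste0("clf_W", j)]] + tb$dW
          hgrads[[paste0("clf_b", j)]] <-
            hgrads[[paste0("clf_b", j)]] + tb$db
          dfeat[, tgt_cols] <- dfeat[, tgt_cols] + tb$dfeats
        }
      } else {
        for (j in seq_len(N))
          L_tgt[j] <- target_pseudo_loss(clf_tgt[[j]]$probs, pseudo)
      }

      bundle <- list(L_adv = L_adv, L_cls_src = L_src, L_cls_tgt = L_tgt)
      total <- total_loss(bundle, tcfg)
      if (!is.finite(total))
        stop(sprintf(
          "non-finite training loss at epoch %d batch %d (adv %s; src %s; tgt %s)",
          epoch, bt, paste(signif(L_adv, 3), collapse = ","),
          paste(signif(L_src, 3), collapse = ","),
          paste(signif(L_tgt, 3), collapse = ",")))

      fgrads <- feature_backward(mcfg, params, fw$cache, dfeat)
      stepped <- adam_step(params, c(fgrads, hgrads), opt, tcfg$lr)
      params <- stepped$params; opt <- stepped$opt

      ep_adv <- ep_adv + L_adv; ep_src <- ep_src + L_src; ep_tgt <- ep_tgt + L_tgt
      ep_total <- ep_total + total
    }

    # epoch-end: re-score and re-rank the full target set in eval mode
    sc <- score_target(mcfg, params, state, Xt, N)
    pw <- perplexity_scores(asplit(sc$disc, 1L), l_run / nb)
    w <- pw$w
    pred_state <- ensemble_predict(w, sc$clf)
    pool <- select_target_pool(pred_state, tcfg$Q)

    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, batches = m,
      loss_total = ep_total / m,
      loss_adv = sum(ep_adv) / m,
      loss_src = sum(ep_src) / m,
      loss_tgt = sum(ep_tgt) / m,
      pool_size = length(pool),
      positive_rate = mean(pred_state$pseudo_labels))
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      cat(sprintf("epoch %3d  loss %.3f  (adv %.3f, src %.3f, tgt %.3f)  pool %d\n",
                  epoch, ep_total / m, sum(ep_adv) / m, sum(ep_src) / m,
                  sum(ep_tgt) / m, length(pool)))
  }

  structure(list(
    params = params, bn_state = state, mcfg = mcfg, tcfg = tcfg,
    n_sources = N,
    source_ids = vapply(sources, `[[`, "", "subject_id"),
    target_id = target$subject_id,
    weights = w, perplexity = pw, prediction = pred_state,
    history = do.call(rbind, hist_rows), call = match.call()),
    class = "p3msda")
}

#' @export
print.p3msda <- function(x, ...) {
  cat(sprintf("<p3msda> %d source domain(s) [%s] -> target '%s'\n",
              x$n_sources, paste(x$source_ids, collapse = ", "), x$target_id))
  cat(sprintf("  feature dim %d | epochs %d | final loss %.3f\n",
              feature_dim(x$mcfg), x$tcfg$epochs,
              utils::tail(x$history$loss_total, 1L)))
  cat("  ensemble weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.p3msda <- function(object, ...) {
  h <- utils::tail(object$history, 1L)
  cat("Multi-source adversarial domain adaptation fit\n")
  print(object)
  cat(sprintf("  perplexity scores: %s\n",
              paste(signif(object$perplexity$p_s, 3), collapse = ", ")))
  cat(sprintf("  target pool size: %d of %d | predicted deviant rate %.3f\n",
              h$pool_size, length(object$prediction$p_hat), h$positive_rate))
  invisible(object)
}

#' @export
coef.p3msda <- function(object, ...) {
  stats::setNames(object$weights, object$source_ids)
}

#' @export
plot.p3msda <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss_total, h$loss_adv, h$loss_src, h$loss_tgt),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "steelblue", "darkgreen"),
                    xlab = "epoch", ylab = "mean batch loss", ...)
  graphics::legend("topright",
                   c("total", "adversarial", "source category", "target pseudo"),
                   lty = 1, lwd = 2,
                   col = c("black", "firebrick", "steelblue", "darkgreen"),
                   bty = "n")
  invisible(h)
}

#' Predict target labels with a trained model
#'
#' Scores trials in evaluation mode with every category classifier, combines
#' them with the stored final ensemble weights, and thresholds the weighted
#' probability at 0.5. On the trials the model was trained on this reproduces
#' the final training `prediction_state`.
#'
#' @param object a fitted `p3msda` model.
#' @param newdata an `epoch_set` (default: not allowed, pass explicitly).
#' @param type "response" for weighted probabilities, "label" for binary
#'   labels, "state" for the full `prediction_state`.
#' @param ... unused.
#' @export
predict.p3msda <- function(object, newdata,
                           type = c("response", "label", "state"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "epoch_set"))
  Xt <- time_major(newdata$trials)
  sc <- score_target(object$mcfg, object$params, object$bn_state, Xt,
                     object$n_sources)
  st <- ensemble_predict(object$weights, sc$clf)
  switch(type,
         response = st$weighted,
         label = st$pseudo_labels,
         state = st)
}

#' Source-only convolutional baseline
#'
#' The no-adaptation reference: the same feature extractor plus a single
#' softmax classifier, trained on class-balanced batches of pooled labeled
#' source trials only. Target data are never touched during training, so any
#' gain of [p3msda()] over this baseline is attributable to adaptation.
#'
#' @param source pooled labeled `epoch_set`.
#' @param mcfg a [model_config()] (default from data geometry).
#' @param tcfg a [train_config()]; only `K`, `lr`, `epochs` and `seed` are
#'   used (the loss is plain cross-entropy).
#' @return an object of class `eegnet_baseline` with a `predict` method.
#' @export
eegnet_fit <- function(source, mcfg = NULL, tcfg = train_config()) {
  stopifnot(inherits(source, "epoch_set"))
  if (is.null(mcfg))
    mcfg <- model_config(ch = n_channels(source), T = n_samples(source),
                         fs = source$fs)
  K <- tcfg$K; half <- K %/% 2L
  set.seed(tcfg$seed)
  net <- init_network(mcfg, 1L)
  params <- net$params; state <- net$state
  opt <- adam_init(params)
  Xs <- time_major(source$trials)
  y <- source$labels
  for (epoch in seq_len(tcfg$epochs)) {
    dev <- which(y == 1L); std <- which(y == 0L)
    nbal <- min(length(dev), length(std))
    if (nbal < half) stop("too few trials per class for batch size K = ", K)
    dev_ord <- sample(dev)[seq_len(nbal)]
    std_ord <- std[sample.int(length(std), nbal)]
    m <- floor(nbal / half)
    for (bt in seq_len(m)) {
      sl <- (bt - 1L) * half + seq_len(half)
      bi <- c(dev_ord[sl], std_ord[sl])
      fw <- feature_forward(mcfg, params, state, Xs[, , bi, drop = FALSE],
                            train = TRUE, keep_cache = TRUE)
      state <- fw$state
      hc <- head_forward(params$clf_W1, params$clf_b1, fw$feats)
      loss <- source_class_loss(hc$probs, y[bi])
      if (!is.finite(loss))
        stop("non-finite baseline loss at epoch ", epoch)
      hb <- head_backward(params$clf_W1, fw$feats, hc$probs - onehot2(y[bi]))
      fgrads <- feature_backward(mcfg, params, fw$cache, hb$dfeats)
      grads <- c(fgrads, list(clf_W1 = hb$dW, clf_b1 = hb$db))
      stepped <- adam_step(params, grads, opt, tcfg$lr)
      params <- stepped$params; opt <- stepped$opt
    }
  }
  structure(list(params = params, bn_state = state, mcfg = mcfg, tcfg = tcfg),
            class = "eegnet_baseline")
}

#' @export
predict.eegnet_baseline <- function(object, newdata,
                                    type = c("response", "label"), ...) {
  type <- match.arg(type)
  Xt <- time_major(newdata$trials)
  sc <- score_target(object$mcfg, object$params, object$bn_state, Xt, 1L)
  p <- sc$clf[1L, ]
  if (type == "response") p else as.integer(p > 0.5)
}
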