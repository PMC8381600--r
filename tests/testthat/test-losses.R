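test_that("the three cross-entropy losses match a scalar-loop oracle", {
  set.seed(5)
  for (rep in 1:25) {
    K <- sample(2:12, 1)
    ps <- rand_probs(K); pt <- rand_probs(K)
    y <- sample(0:1, K, replace = TRUE)
    # domain loss: sources are class 1, targets class 2
    expect_equal(domain_adv_loss(ps, pt),
                 loop_ce(ps, rep(1L, K)) + loop_ce(pt, rep(2L, K)),
                 tolerance = 1e-9)
    expect_equal(source_class_loss(ps, y), loop_ce(ps, y + 1L),
                 tolerance = 1e-9)
    expect_equal(target_pseudo_loss(pt, y), loop_ce(pt, y + 1L),
                 tolerance = 1e-9)
  }
})

test_that("uniform and certain predictions hit the closed forms", {
  K <- 7
  u <- matrix(0.5, 2, K)
  expect_equal(domain_adv_loss(u[, 1, drop = FALSE], u[, 1, drop = FALSE]),
               2 * log(2), tolerance = 1e-12)
  expect_equal(domain_adv_loss(u, u), 2 * K * log(2), tolerance = 1e-12)
  expect_equal(source_class_loss(matrix(0.5, 2, 20), rep(1L, 20)),
               20 * log(2), tolerance = 1e-12)
  # single sample with probability 1/4 on the true class
  expect_equal(source_class_loss(matrix(c(0.75, 0.25), 2, 1), 1L), log(4),
               tolerance = 1e-12)
  # certain & correct predictions: loss at the clamping floor
  sure_s <- rbind(rep(1, K), rep(0, K))
  sure_t <- rbind(rep(0, K), rep(1, K))
  expect_lt(domain_adv_loss(sure_s, sure_t), 1e-10)
  expect_lt(source_class_loss(sure_t, rep(1L, K)), 1e-10)
  # pseudo labels all one class, uniform predictions
  expect_equal(target_pseudo_loss(matrix(0.5, 2, 20), rep(1L, 20)),
               20 * log(2), tolerance = 1e-12)
})

test_that("perplexity scores follow the confusion of the discriminator", {
  pw <- perplexity_scores(list(rep(0.5, 6)), 0)
  expect_equal(pw$p_s, log(2), tolerance = 1e-12)
  pw2 <- perplexity_scores(list(rep(0, 6)), 0.3)
  expect_equal(pw2$p_s, 0.3, tolerance = 1e-12)
  # raising every D raises the score
  set.seed(6)
  d <- runif(10, 0.1, 0.8)
  expect_gt(perplexity_scores(list(d + 0.1), 0)$p_s,
            perplexity_scores(list(d), 0)$p_s)
  # D = 1 exactly is clamped, not infinite
  expect_true(is.finite(perplexity_scores(list(rep(1, 4)), 0)$p_s))
})

test_that("classifier weights live on the simplex with a uniform fallback", {
  expect_equal(classifier_weights(c(2, 2)), c(0.5, 0.5))
  expect_equal(classifier_weights(c(1, 3)), c(0.25, 0.75))
  set.seed(7)
  for (rep in 1:50) {
    w <- classifier_weights(runif(sample(2:6, 1), 0, 5))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_message(wu <- classifier_weights(c(0, 0, 0)), "uniform")
  expect_equal(wu, rep(1 / 3, 3))
  expect_error(classifier_weights(c(-1, 2)), "non-negative")
})

test_that("ensemble prediction stores the literal average and thresholds the weighted mean", {
  s1 <- ensemble_predict(1, 0.8)
  expect_equal(s1$p_hat, 0.8)
  expect_equal(s1$pseudo_labels, 1L)
  # N = 2: literal p_hat is half the weighted mean
  s2 <- ensemble_predict(c(0.5, 0.5), matrix(c(0.8, 0.6), 2, 1))
  expect_equal(s2$p_hat, 0.35)
  expect_equal(s2$weighted, 0.7)
  expect_equal(s2$pseudo_labels, 1L)
  # identical classifiers: ranking equals the single-classifier ranking
  set.seed(8)
  p <- runif(9)
  r1 <- ensemble_predict(1, p)$ranking
  r3 <- ensemble_predict(rep(1 / 3, 3), rbind(p, p, p))$ranking
  expect_identical(r1, r3)
})

test_that("the ranked pool takes the top ceiling(Q n) with stable ties", {
  st <- ensemble_predict(1, c(0.9, 0.2, 0.8, 0.1, 0.5))
  expect_equal(select_target_pool(st, 0.8), c(1L, 3L, 5L, 2L))
  expect_equal(select_target_pool(st, 1), c(1L, 3L, 5L, 2L, 4L))
  ties <- ensemble_predict(1, rep(0.4, 5))
  expect_equal(select_target_pool(ties, 0.6), c(1L, 2L, 3L))
  expect_error(select_target_pool(st, 0), "Q")
  # invariance under a strictly increasing transform
  set.seed(9)
  p <- runif(20)
  a <- select_target_pool(ensemble_predict(1, p), 0.5)
  b <- select_target_pool(ensemble_predict(1, plogis(3 * p - 1)), 0.5)
  expect_identical(a, b)
})

test_that("balanced resampling equalizes the classes", {
  e <- tiny_subject(seed = 13, n_trials = 530)
  # imbalance 3 -> 132 deviants of 530
  bal <- balanced_source_sample(e, seed = 1)
  expect_equal(sum(bal$labels == 1L), sum(bal$labels == 0L))
  expect_equal(sum(bal$labels == 1L), sum(e$labels == 1L))
  expect_identical(balanced_source_sample(e, seed = 1)$labels,
                   balanced_source_sample(e, seed = 1)$labels)
  # already balanced: both classes kept in full
  eb <- const_epochs(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(dim(balanced_source_sample(eb, seed = 1)$trials)[1], 4)
  # fewer standards than deviants: all standards kept
  es <- const_epochs(c(1, 2, 3), c(1, 1, 0))
  expect_message(bs <- balanced_source_sample(es, seed = 1), "standards")
  expect_equal(sum(bs$labels == 0L), 1)
})

test_that("the total objective combines the weighted per-source sums", {
  tc <- train_config()
  bundle <- list(L_adv = c(1, 1), L_cls_src = c(1, 1), L_cls_tgt = c(1, 1))
  expect_equal(total_loss(bundle, tc), 2.4)
  zero <- list(L_adv = 0, L_cls_src = 0, L_cls_tgt = 0)
  expect_equal(total_loss(zero, tc), 0)
  # lambda = 0 removes the target term
  tc0 <- train_config(lambda = 0)
  expect_equal(total_loss(bundle, tc0), 0.2 * 2 + 0.8 * 2)
})
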