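# epoch set whose class ERPs are exactly prescribed constant matrices
flat_epochs <- function(dev_value, std_value, ch = 2L, T = 3L) {
  trials <- array(0, dim = c(4, ch, T))
  trials[1, , ] <- dev_value; trials[2, , ] <- dev_value
  trials[3, , ] <- std_value; trials[4, , ] <- std_value
  epoch_set(trials, c(1, 1, 0, 0), fs = 20)
}

test_that("deviant-ERP energy is the squared sum over channels and samples", {
  e <- flat_epochs(1, 0)
  expect_equal(criterion_deviant_energy(e)$vector, 6)      # 2 ch x 3 samp x 1^2
  expect_equal(criterion_deviant_energy(flat_epochs(0, 1))$vector, 0)
  # quadratic scaling: doubling the ERP quadruples the energy
  expect_equal(criterion_deviant_energy(flat_epochs(2, 0))$vector, 24)
})

test_that("energy ratio and SNR behave on constructed inputs", {
  expect_equal(criterion_energy_ratio(flat_epochs(1, 1))$vector, 1)
  expect_equal(criterion_energy_ratio(flat_epochs(2, 1))$vector, 4)
  expect_error(criterion_energy_ratio(flat_epochs(1, 0)), "zero")

  # all deviant trials identical: noise energy 0 -> infinite-SNR sentinel
  expect_equal(criterion_snr(flat_epochs(1, 0))$vector, Inf)
  e1 <- subset_epochs(flat_epochs(1, 0), c(1, 3))
  expect_error(criterion_snr(e1), "two deviant")

  # pure-noise subject: signal-free SNR is roughly 1/(n_deviants - 1)
  prof <- subject_profile("s", "strong", p3_gain = 0, noise_sd = 10)
  cfg <- synth_config(channels = 4, fs = 20, trial_len = 20, n_trials = 200,
                      imbalance_ratio = 1, noise_sd = 10)
  e <- simulate_subject(prof, cfg, seed = 9)
  expect_lt(criterion_snr(e)$vector, 0.05)

  # doubling the noise (signal fixed) lowers the SNR
  p_lo <- subject_profile("s", "strong", p3_gain = 2, noise_sd = 8)
  p_hi <- subject_profile("s", "strong", p3_gain = 2, noise_sd = 16)
  lo <- simulate_subject(p_lo, cfg, seed = 10)
  hi <- simulate_subject(p_hi, cfg, seed = 10)
  expect_gt(criterion_snr(lo)$vector, criterion_snr(hi)$vector)
})

test_that("stronger planted P3 yields a larger P3-map norm", {
  cfg <- synth_config(channels = 8, fs = 100, trial_len = 100, n_trials = 250,
                      imbalance_ratio = 4, noise_sd = 10)
  strong <- simulate_subject(subject_profile("a", "strong", 3), cfg, seed = 4)
  weak <- simulate_subject(subject_profile("b", "weak", 0.5), cfg, seed = 5)
  fs <- criterion_p3_map(strong); fw <- criterion_p3_map(weak)
  expect_gt(sqrt(sum(fs$vector^2)), sqrt(sum(fw$vector^2)))
  expect_length(fs$vector, 8)
  # deterministic on a duplicate epoch set
  expect_identical(criterion_p3_map(strong)$vector, fs$vector)
  # the same ordering holds for the scalar criteria
  expect_gt(criterion_deviant_energy(strong)$vector,
            criterion_deviant_energy(weak)$vector)
  expect_gt(criterion_energy_ratio(strong)$vector,
            criterion_energy_ratio(weak)$vector)
})

# exhaustive 1-d 3-means oracle: best contiguous 3-partition by within-SS
kmeans_1d_oracle <- function(x) {
  ord <- order(x, decreasing = TRUE)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
    gr <- c(rep(1, c1), rep(2, c2 - c1), rep(3, n - c2))
    ss <- sum(tapply(xs, gr, function(v) sum((v - mean(v))^2)))
    if (ss < best_ss) { best_ss <- ss; best <- gr }
  }
  out <- integer(n); out[ord] <- best
  out
}

test_that("k-means grouping matches the exhaustive 1-d oracle", {
  x <- c(10, 9, 5, 4.5, 1, 0.8)
  feats <- lapply(seq_along(x), function(i) {
    structure(list(subject_id = paste0("s", i), criterion = "deviant_energy",
                   vector = x[i]), class = "subject_feature")
  })
  asn <- cluster_subjects(feats, seed = 1)
  oracle <- kmeans_1d_oracle(x)  # 1 = strongest cluster
  expect_equal(unname(asn$groups),
               c("strong", "medium", "weak")[oracle])
  expect_equal(unname(asn$groups), c("strong", "strong", "medium", "medium",
                                     "weak", "weak"))
  # group centers are ordered strong >= medium >= weak by construction
  expect_true(all(diff(asn$group_centers) <= 0))
})

test_that("grouping is invariant to subject order and flags degeneracy", {
  x <- c(10, 9, 5, 4.5, 1, 0.8)
  feats <- lapply(seq_along(x), function(i) {
    structure(list(subject_id = paste0("s", i), criterion = "snr",
                   vector = x[i]), class = "subject_feature")
  })
  a1 <- cluster_subjects(feats, seed = 1)
  a2 <- cluster_subjects(rev(feats), seed = 1)
  expect_equal(a1$groups[names(a2$groups)], a2$groups)

  same <- lapply(1:4, function(i) {
    structure(list(subject_id = paste0("s", i), criterion = "snr",
                   vector = 2), class = "subject_feature")
  })
  ad <- cluster_subjects(same, seed = 1)
  expect_true(ad$degenerate)
  expect_error(cluster_subjects(feats[1:2]), "at least 3")
  other <- structure(list(subject_id = "x", criterion = "p3_map",
                          vector = 1), class = "subject_feature")
  expect_error(cluster_subjects(c(feats[1:3], list(other))), "mix")
})

test_that("source subject selection is seeded and bounded", {
  groups <- c(a = "strong", b = "strong", c = "strong", d = "weak")
  asn <- structure(list(groups = groups,
                        group_centers = c(strong = 3, medium = 2, weak = 1),
                        criterion = "p3_map", degenerate = FALSE),
                   class = "group_assignment")
  expect_setequal(select_source_subjects(asn, "strong"), c("a", "b", "c"))
  expect_length(select_source_subjects(asn, "strong", 0), 0)
  s1 <- select_source_subjects(asn, "strong", 2, seed = 3)
  expect_identical(s1, select_source_subjects(asn, "strong", 2, seed = 3))
  expect_length(s1, 2)
  expect_error(select_source_subjects(asn, "strong", 4), "only")
  expect_error(select_source_subjects(asn, "medium"), "empty")
})
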