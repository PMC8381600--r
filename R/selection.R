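#' Subject features for source-domain selection
#'
#' Four per-subject criteria for judging how usable a labeled subject is as a
#' source domain. `criterion_p3_map()` is the primary one: the scalp
#' topography at the P3 peak of the aligned deviant ERP. The three rivals are
#' scalar summaries: total deviant-ERP energy, the deviant/standard ERP energy
#' ratio, and the ERP signal-to-noise ratio.
#'
#' @param epochs an `epoch_set` for one subject (must contain deviants).
#' @param max_lag alignment search range in samples (see [align_trials()]).
#' @param window P3 search window in ms (see [extract_p3_map()]).
#' @param roi_channels optional explicit ROI channel names.
#' @return a `subject_feature`: list with `subject_id`, `criterion` and
#'   `vector` (length = channels for `p3_map`, length 1 otherwise).
#' @name selection_criteria
NULL

subject_feature <- function(subject_id, criterion, vector) {
  v <- as.numeric(vector)
  if (any(!is.finite(v))) stop("criterion '", criterion, "' produced non-finite values")
  structure(list(subject_id = subject_id, criterion = criterion, vector = v),
            class = "subject_feature")
}

#' @rdname selection_criteria
#' @export
criterion_p3_map <- function(epochs, max_lag = 20L, window = c(250, 600),
                             roi_channels = NULL) {
  tmpl <- average_erp(epochs, "deviant")
  aligned <- align_trials(epochs, tmpl, max_lag = max_lag,
                          roi_channels = roi_channels)
  tmpl2 <- average_erp(aligned, "deviant")
  map <- extract_p3_map(tmpl2, window = window, roi_channels = roi_channels)
  subject_feature(epochs$subject_id, "p3_map", map$topography)
}

erp_energy <- function(erp) sum(erp^2)

#' @rdname selection_criteria
#' @export
criterion_deviant_energy <- function(epochs) {
  tmpl <- average_erp(epochs, "deviant")
  subject_feature(epochs$subject_id, "deviant_energy", erp_energy(tmpl$erp))
}

#' @rdname selection_criteria
#' @export
criterion_energy_ratio <- function(epochs) {
  dev <- average_erp(epochs, "deviant")
  std <- average_erp(epochs, "standard")
  denom <- erp_energy(std$erp)
  if (denom <= 0) stop("standard ERP energy is zero; energy ratio undefined")
  subject_feature(epochs$subject_id, "energy_ratio",
                  erp_energy(dev$erp) / denom)
}

#' @rdname selection_criteria
#' @export
criterion_snr <- function(epochs) {
  idx <- which(epochs$labels == 1L)
  if (length(idx) < 2L)
    stop("SNR needs at least two deviant trials (noise is trial - ERP)")
  tmpl <- average_erp(epochs, "deviant")
  noise_energy <- mean(vapply(idx, function(i) {
    sum((matrix(epochs$trials[i, , ], nrow(tmpl$erp)) - tmpl$erp)^2)
  }, numeric(1)))
  sig <- erp_energy(tmpl$erp)
  snr <- if (noise_energy == 0) Inf else sig / noise_energy
  if (is.infinite(snr)) {
    # all trials identical: division guard, report a large finite sentinel
    return(structure(list(subject_id = epochs$subject_id, criterion = "snr",
                          vector = Inf), class = "subject_feature"))
  }
  subject_feature(epochs$subject_id, "snr", snr)
}

#' Cluster subjects into strong / medium / weak groups
#'
#' Runs seeded k-means (k = 3, multiple restarts) on the per-subject feature
#' vectors and relabels the clusters "strong", "medium", "weak" by descending
#' mean feature magnitude (L2 norm of member vectors; for scalar criteria this
#' is the scalar itself).
#'
#' @param features list of `subject_feature` objects sharing one criterion.
#' @param k number of groups (3).
#' @param nstart k-means restarts.
#' @param seed RNG seed for the restarts.
#' @return a `group_assignment`: list with `groups` (named character vector
#'   subject_id -> group), `group_centers` (named mean magnitudes, descending)
#'   and `degenerate` (TRUE when all feature magnitudes coincide).
#' @export
cluster_subjects <- function(features, k = 3L, nstart = 10L, seed = 1L) {
  if (length(features) < k)
    stop("need at least ", k, " subjects to form ", k, " groups")
  crit <- unique(vapply(features, `[[`, "", "criterion"))
  if (length(crit) != 1L) stop("features mix different criteria")
  X <- do.call(rbind, lapply(features, `[[`, "vector"))
  ids <- vapply(features, `[[`, "", "subject_id")
  mags <- sqrt(rowSums(X^2))
  degenerate <- (max(mags) - min(mags)) < 1e-12
  if (nrow(unique(X)) < k) {
    # fewer distinct feature vectors than groups: no meaningful partition;
    # spread subjects round-robin and flag the assignment as degenerate
    groups <- c("strong", "medium", "weak")[(seq_along(ids) - 1L) %% k + 1L]
    names(groups) <- ids
    centers <- stats::setNames(vapply(c("strong", "medium", "weak")[seq_len(k)],
                                      function(g) mean(mags[groups == g]),
                                      numeric(1)),
                               c("strong", "medium", "weak")[seq_len(k)])
    return(structure(list(groups = groups, group_centers = centers,
                          criterion = crit, degenerate = TRUE),
                     class = "group_assignment"))
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart))
  # order clusters by mean member magnitude, strongest first
  cl_mag <- vapply(seq_len(k), function(j) mean(mags[km$cluster == j]), numeric(1))
  ord <- order(cl_mag, decreasing = TRUE)
  group_names <- c("strong", "medium", "weak")[seq_len(k)]
  relabel <- character(k)
  relabel[ord] <- group_names
  groups <- relabel[km$cluster]
  names(groups) <- ids
  centers <- sort(cl_mag, decreasing = TRUE)
  names(centers) <- group_names
  structure(list(groups = groups, group_centers = centers,
                 criterion = crit, degenerate = degenerate),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> criterion:", x$criterion, "\n")
  for (g in names(x$group_centers)) {
    cat(sprintf("  %-6s (magnitude %.3g): %s\n", g, x$group_centers[[g]],
                paste(names(x$groups)[x$groups == g], collapse = ", ")))
  }
  if (x$degenerate) cat("  [degenerate: all feature magnitudes identical]\n")
  invisible(x)
}

#' Draw source subjects from a group
#'
#' @param assignment a `group_assignment`.
#' @param group group to draw from (default "strong", the recommended source
#'   pool).
#' @param n number of subjects to draw (uniformly, seeded).
#' @param seed RNG seed.
#' @return character vector of subject ids.
#' @export
select_source_subjects <- function(assignment, group = "strong", n = NULL,
                                   seed = 1L) {
  members <- names(assignment$groups)[assignment$groups == group]
  if (length(members) == 0L) stop("group '", group, "' is empty")
  if (is.null(n)) n <- length(members)
  if (n > length(members))
    stop("requested ", n, " subjects but group '", group, "' has only ",
         length(members))
  if (n == 0L) return(character(0))
  if (n == length(members)) return(members)
  set.seed(seed)
  members[sort(sample.int(length(members), n))]
}
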