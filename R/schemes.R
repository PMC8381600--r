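#' Scheme specification for the comparison harness
#'
#' Three ways of using labeled source subjects for a new target subject:
#' `"eegnet"` — pool the sources, train the convolutional classifier with no
#' adaptation; `"sda"` — pool the sources into one domain and adapt
#' adversarially; `"msda"` — split the source subjects evenly into
#' `n_source_domains` domains with per-domain discriminators and classifiers.
#'
#' @param scheme one of "eegnet", "sda", "msda".
#' @param source_subjects character vector of source subject ids.
#' @param n_source_domains number of source domains (msda only); must divide
#'   the subject count evenly.
#' @return an object of class `scheme_spec`.
#' @export
scheme_spec <- function(scheme = c("eegnet", "sda", "msda"),
                        source_subjects, n_source_domains = 1L) {
  scheme <- match.arg(scheme)
  n <- length(source_subjects)
  if (n < 1L) stop("at least one source subject is required")
  if (scheme == "msda") {
    if (n_source_domains < 1L || n %% n_source_domains != 0L)
      stop("n_source_domains must divide the number of source subjects evenly")
  } else {
    n_source_domains <- 1L
  }
  structure(list(scheme = scheme,
                 source_subjects = as.character(source_subjects),
                 n_source_domains = as.integer(n_source_domains)),
            class = "scheme_spec")
}

#' Run one scheme against one target subject
#'
#' Builds the source domain(s) from the named cohort subjects, trains the
#' scheme's model on them (plus, for the adaptation schemes, the unlabeled
#' target trials), predicts the target labels and scores them against the
#' target's true labels — which are used only here, for evaluation.
#'
#' @param spec a [scheme_spec()].
#' @param cohort named list of labeled `epoch_set` objects.
#' @param target_subject id of the target subject (must not be a source).
#' @param mcfg,tcfg model and training configuration.
#' @return list with `metrics` (a `detection_metrics`), `fit` (the trained
#'   model) and `spec`.
#' @export
run_scheme <- function(spec, cohort, target_subject, mcfg = NULL,
                       tcfg = train_config()) {
  stopifnot(inherits(spec, "scheme_spec"))
  if (target_subject %in% spec$source_subjects)
    stop("target subject must be excluded from the source subjects")
  missing <- setdiff(c(spec$source_subjects, target_subject), names(cohort))
  if (length(missing) > 0L)
    stop("unknown subject(s): ", paste(missing, collapse = ", "))
  target <- cohort[[target_subject]]
  src_sets <- cohort[spec$source_subjects]

  if (spec$scheme == "eegnet") {
    pooled <- pool_epochs(src_sets, "pooled_source")
    fit <- eegnet_fit(pooled, mcfg, tcfg)
    pred <- predict(fit, target, type = "label")
  } else {
    N <- spec$n_source_domains
    per <- length(src_sets) %/% N
    domains <- lapply(seq_len(N), function(j) {
      pool_epochs(src_sets[(j - 1L) * per + seq_len(per)],
                  paste0("domain", j))
    })
    fit <- p3msda(domains, target, mcfg, tcfg)
    pred <- predict(fit, target, type = "label")
  }
  list(metrics = compute_metrics(target$labels, pred), fit = fit, spec = spec)
}

#' Repeated random-validation grid over schemes
#'
#' For each repeat, draws a target subject and source subjects from the
#' requested groups at random (sources never include the target), runs every
#' scheme on the identical draw, and tabulates the metrics. Fully reproducible
#' from the seed.
#'
#' @param schemes named list; each entry is a list with `scheme` ("eegnet",
#'   "sda" or "msda"), `source_group` (group to draw sources from),
#'   `n_source_subjects`, and optionally `n_source_domains` (msda).
#' @param cohort named list of labeled `epoch_set` objects.
#' @param groups named character vector: subject id -> group (e.g. from
#'   [cluster_subjects()] or the simulator ground truth).
#' @param target_group group to draw the target from.
#' @param repeats number of random draws.
#' @param seed RNG seed.
#' @param mcfg,tcfg model and training configuration.
#' @return data.frame with one row per scheme x repeat: scheme, repeat,
#'   target_subject, target_group, f1, accuracy, hit_rate, far, seed.
#' @export
run_experiment_grid <- function(schemes, cohort, groups, target_group,
                                repeats = 1L, seed = 1L, mcfg = NULL,
                                tcfg = train_config()) {
  if (repeats < 1L) stop("repeats must be >= 1")
  rows <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- derive_seed(seed, r)
    set.seed(rep_seed)
    tgt_pool <- names(groups)[groups == target_group]
    if (length(tgt_pool) == 0L) stop("no subjects in target group")
    target_subject <- tgt_pool[sample.int(length(tgt_pool), 1L)]
    for (nm in names(schemes)) {
      sch <- schemes[[nm]]
      src_pool <- setdiff(names(groups)[groups == sch$source_group],
                          target_subject)
      if (length(src_pool) < sch$n_source_subjects)
        stop("scheme '", nm, "': not enough subjects in group '",
             sch$source_group, "'")
      set.seed(derive_seed(rep_seed, match(nm, names(schemes))))
      src <- src_pool[sample.int(length(src_pool), sch$n_source_subjects)]
      spec <- scheme_spec(sch$scheme, src, sch$n_source_domains %||% 1L)
      tc <- tcfg; tc$seed <- derive_seed(rep_seed, 1000L + match(nm, names(schemes)))
      res <- run_scheme(spec, cohort, target_subject, mcfg, tc)
      m <- res$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = nm, rep = r, target_subject = target_subject,
        target_group = target_group, f1 = m$f1, accuracy = m$accuracy,
        hit_rate = m$hit_rate, far = m$false_alarm_rate, seed = rep_seed)
    }
  }
  do.call(rbind, rows)
}

#' Ground-truth group lookup from simulator profiles
#'
#' @param profiles list of `subject_profile` objects (from
#'   [simulate_cohort()]).
#' @return named character vector subject id -> group.
#' @export
true_groups <- function(profiles) {
  stats::setNames(vapply(profiles, `[[`, "", "group"),
                  vapply(profiles, `[[`, "", "subject_id"))
}
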