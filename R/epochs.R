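#' Epoched EEG container
#'
#' `epoch_set()` bundles one subject's epoched trials with their binary labels
#' and acquisition metadata. It is the currency passed between the simulator,
#' the preprocessing steps, the source-domain selector and the trainer.
#'
#' @param trials numeric array `n x channels x T`, amplitudes in microvolts.
#' @param labels integer/logical vector of length `n`; 1 marks a deviant
#'   (target) trial, 0 a standard trial.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `channels`.
#' @param subject_id subject identifier.
#' @param require_both_classes validate that both classes occur (default TRUE;
#'   intermediate single-class subsets may disable it).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(trials, labels, fs, channel_names = NULL,
                      subject_id = "subject", require_both_classes = TRUE) {
  if (!is.array(trials) || length(dim(trials)) != 3L)
    stop("`trials` must be an n x channels x T array")
  n <- dim(trials)[1L]
  nch <- dim(trials)[2L]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("`labels` length (", length(labels), ") != number of trials (", n, ")")
  if (anyNA(trials) || anyNA(labels)) stop("epoch_set must not contain NA")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (require_both_classes && (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L))
    stop("both classes (deviant and standard) must be present")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nch))
  if (length(channel_names) != nch)
    stop("channel_names length != channel count")
  structure(
    list(trials = trials, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<epoch_set> subject '%s': %d trials (%d deviant / %d standard), %d channels, %d samples @ %g Hz\n",
              x$subject_id, d[1L], sum(x$labels == 1L), sum(x$labels == 0L),
              d[2L], d[3L], x$fs))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$trials)[1L]
n_channels <- function(epochs) dim(epochs$trials)[2L]
n_samples <- function(epochs) dim(epochs$trials)[3L]

#' Subset an epoch set by trial index
#'
#' @param epochs an `epoch_set`.
#' @param idx integer trial indices to keep.
#' @param require_both_classes passed through to [epoch_set()].
#' @return a new `epoch_set` with the selected trials, labels kept in lockstep.
#' @export
subset_epochs <- function(epochs, idx, require_both_classes = FALSE) {
  if (length(idx) == 0L) stop("subset would be empty")
  epoch_set(epochs$trials[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$fs, epochs$channel_names, epochs$subject_id,
            require_both_classes = require_both_classes)
}

#' Pool several subjects' epochs into one set
#'
#' Used to merge the subjects assigned to one source domain.
#'
#' @param epoch_list list of `epoch_set` objects with identical geometry.
#' @param subject_id identifier for the pooled set.
#' @return a single `epoch_set`.
#' @export
pool_epochs <- function(epoch_list, subject_id = "pooled") {
  stopifnot(length(epoch_list) >= 1L)
  ref <- epoch_list[[1L]]
  for (e in epoch_list) {
    if (n_channels(e) != n_channels(ref) || n_samples(e) != n_samples(ref) ||
        e$fs != ref$fs)
      stop("epoch sets to pool must share channels, samples and sampling rate")
  }
  trials <- do.call(abind_trials, lapply(epoch_list, `[[`, "trials"))
  labels <- unlist(lapply(epoch_list, `[[`, "labels"), use.names = FALSE)
  epoch_set(trials, labels, ref$fs, ref$channel_names, subject_id)
}

# rbind 3-d trial arrays along the first dimension
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  ns <- vapply(parts, function(a) dim(a)[1L], integer(1))
  out <- array(0, dim = c(sum(ns), d[2L], d[3L]))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Read or write the epoch container
#'
#' One file per subject holding trials, labels, sampling rate, channel names
#' and subject id, via native R serialization. Identical content written twice
#' produces byte-identical files.
#'
#' @param epochs an `epoch_set`.
#' @param path file path (conventionally `<subject>.rds`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   the `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path, compress = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "epoch_set")) stop("file does not contain an epoch_set")
  # revalidate on the way in
  epoch_set(x$trials, x$labels, x$fs, x$channel_names, x$subject_id,
            require_both_classes = FALSE)
}
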