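#' Centro-parietal region of interest
#'
#' Channels used for P3 peak finding and trial alignment: the channel named
#' "Pz" (the simulator's focus channel) and its two neighbours on the circular
#' montage; if no "Pz" exists, the middle channel and its neighbours. Pass
#' explicit channel names for real montages.
#'
#' @param channel_names character vector of channel names.
#' @param roi_channels optional character vector naming the ROI explicitly.
#' @return integer channel indices.
#' @export
centro_parietal_roi <- function(channel_names, roi_channels = NULL) {
  n <- length(channel_names)
  if (!is.null(roi_channels)) {
    idx <- match(roi_channels, channel_names)
    if (anyNA(idx)) stop("unknown ROI channel(s): ",
                         paste(roi_channels[is.na(idx)], collapse = ", "))
    return(idx)
  }
  ctr <- match("Pz", channel_names)
  if (is.na(ctr)) ctr <- max(1L, round(n / 2))
  if (n <= 3L) return(seq_len(n))
  sort(unique(((ctr - 1L + c(-1L, 0L, 1L)) %% n) + 1L))
}

#' Reject trials by peak amplitude
#'
#' Drops every trial whose absolute amplitude exceeds `threshold` anywhere;
#' labels are filtered in lockstep. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param threshold rejection threshold in microvolts (positive); the
#'   conventional artifact bound is 100.
#' @return the filtered `epoch_set`.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs$trials), 1L, max)
  keep <- which(peak <= threshold)
  if (length(keep) == 0L) stop("amplitude rejection removed every trial")
  subset_epochs(epochs, keep)
}

#' Channel-wise average ERP
#'
#' @param epochs an `epoch_set`.
#' @param class which trials to average: "deviant" or "standard".
#' @return an `erp_template`: list with `erp` (channels x T matrix, uV),
#'   `n_averaged` and `fs`.
#' @export
average_erp <- function(epochs, class = c("deviant", "standard")) {
  class <- match.arg(class)
  want <- if (class == "deviant") 1L else 0L
  idx <- which(epochs$labels == want)
  if (length(idx) == 0L) stop("no ", class, " trials to average")
  erp <- apply(epochs$trials[idx, , , drop = FALSE], c(2L, 3L), mean)
  structure(list(erp = erp, n_averaged = length(idx), fs = epochs$fs,
                 channel_names = epochs$channel_names),
            class = "erp_template")
}

# shift a channels x T matrix right by `lag` samples (left if negative),
# zero-padding at the edges rather than wrapping
shift_trial <- function(x, lag) {
  T <- ncol(x)
  if (lag == 0L) return(x)
  out <- matrix(0, nrow(x), T)
  if (lag > 0L) out[, (lag + 1L):T] <- x[, seq_len(T - lag)]
  else out[, seq_len(T + lag)] <- x[, (1L - lag):T]
  out
}

#' Align deviant trials to an ERP template
#'
#' Latency jitter is reduced by shifting each deviant trial by the lag (within
#' `max_lag`) that maximizes the cross-correlation between its mean
#' centro-parietal trace and the template's. Standard trials are left
#' untouched; trial counts and labels never change. Shifted samples falling
#' off the trial edge are zero-padded, not wrapped, so late components cannot
#' teleport to the trial start. This cross-correlation rule is a documented
#' stand-in for dedicated ERP alignment algorithms.
#'
#' @param epochs an `epoch_set`.
#' @param template an `erp_template` (typically [average_erp()] of the same
#'   subject's deviants).
#' @param max_lag maximum absolute shift in samples; must be < T/2.
#' @param roi_channels optional explicit ROI channel names (see
#'   [centro_parietal_roi()]).
#' @return an `epoch_set` with aligned deviant trials, plus an attribute
#'   `lags` (per-trial applied shift, 0 for standards).
#' @export
align_trials <- function(epochs, template, max_lag = 20L, roi_channels = NULL) {
  T <- n_samples(epochs)
  if (max_lag >= T / 2) stop("max_lag must be < T/2")
  roi <- centro_parietal_roi(epochs$channel_names, roi_channels)
  ref <- colMeans(template$erp[roi, , drop = FALSE])
  lags <- integer(n_trials(epochs))
  out <- epochs$trials
  if (max_lag > 0L) {
    for (i in which(epochs$labels == 1L)) {
      tr <- colMeans(matrix(epochs$trials[i, roi, ], length(roi), T))
      best <- 0L; best_cc <- -Inf
      for (lag in (-max_lag):max_lag) {
        # correlate template(t) with trial shifted by `lag`
        if (lag >= 0L) cc <- sum(ref[(lag + 1L):T] * tr[seq_len(T - lag)])
        else cc <- sum(ref[seq_len(T + lag)] * tr[(1L - lag):T])
        if (cc > best_cc + 1e-12) { best_cc <- cc; best <- lag }
      }
      lags[i] <- best
      if (best != 0L) out[i, , ] <- shift_trial(matrix(epochs$trials[i, , ],
                                                       n_channels(epochs), T),
                                                best)
    }
  }
  res <- epoch_set(out, epochs$labels, epochs$fs, epochs$channel_names,
                   epochs$subject_id, require_both_classes = FALSE)
  attr(res, "lags") <- lags
  res
}

#' Extract the P3 scalp map from an ERP template
#'
#' Finds the P3 peak as the argmax, inside a post-onset search window, of the
#' ERP averaged over the centro-parietal ROI, then reads out the scalp
#' topography (one value per channel) at that sample. Ties break toward the
#' earliest sample.
#'
#' @param template an `erp_template`.
#' @param window numeric length-2 vector, search window in ms (default
#'   250-600 ms, the usual P3 range for dynamic stimuli).
#' @param roi_channels optional explicit ROI channel names.
#' @return a `p3_map`: list with `topography` (uV per channel), `peak_time`
#'   (sample index, 1-based) and `window` (sample range searched).
#' @export
extract_p3_map <- function(template, window = c(250, 600), roi_channels = NULL) {
  T <- ncol(template$erp)
  fs <- template$fs
  s0 <- floor(window[1L] / 1000 * fs) + 1L
  s1 <- min(T, ceiling(window[2L] / 1000 * fs) + 1L)
  if (s0 < 1L || s0 > T || s1 < s0)
    stop("P3 search window is empty or outside the trial")
  roi <- centro_parietal_roi(template$channel_names %||%
                               sprintf("ch%02d", seq_len(nrow(template$erp))),
                             roi_channels)
  trace <- colMeans(template$erp[roi, s0:s1, drop = FALSE])
  peak <- s0 + which.max(trace) - 1L  # which.max takes the first maximum
  structure(list(topography = template$erp[, peak], peak_time = peak,
                 window = c(s0, s1)),
            class = "p3_map")
}
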