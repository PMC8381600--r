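#' ERP component specification
#'
#' Describes one event-related component as a Gaussian-windowed bump at a
#' (jittered) latency, projected onto the scalp through a per-channel
#' topography weight vector.
#'
#' @param name component label, e.g. "P1", "P2", "P3", "LateNeg".
#' @param latency_mean mean peak latency in ms after trial onset.
#' @param latency_jitter_sd trial-to-trial latency jitter SD in ms.
#' @param amplitude signed peak amplitude in microvolts.
#' @param width temporal width (FWHM-like scale) in ms; must be positive.
#' @param topography numeric weight vector in \[-1, 1\], one entry per channel.
#' @param deviant_only logical; if TRUE the component occurs only in deviant
#'   (target) trials.
#' @return an object of class `erp_component`.
#' @export
erp_component <- function(name, latency_mean, latency_jitter_sd, amplitude,
                          width, topography, deviant_only = FALSE) {
  if (width <= 0) stop("component width must be positive")
  if (any(abs(topography) > 1 + 1e-9)) stop("topography weights must lie in [-1, 1]")
  structure(list(name = name, latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd, amplitude = amplitude,
                 width = width, topography = as.numeric(topography),
                 deviant_only = isTRUE(deviant_only)),
            class = "erp_component")
}

#' Gaussian topography on a synthetic circular montage
#'
#' Channels are laid out evenly on a circle; weights fall off as a Gaussian of
#' the circular index distance from a focus channel. A crude but sufficient
#' stand-in for real montage geometry.
#'
#' @param n_channels channel count.
#' @param focus focus channel index.
#' @param spread Gaussian falloff scale in channel-index units.
#' @return numeric weight vector in (0, 1], maximal at `focus`.
#' @export
circular_topography <- function(n_channels, focus, spread = n_channels / 6) {
  i <- seq_len(n_channels)
  d <- pmin(abs(i - focus), n_channels - abs(i - focus))
  exp(-d^2 / (2 * spread^2))
}

# index of the "Pz-like" focus channel used by default components
pz_index <- function(n_channels) max(1L, round(n_channels * 0.5))

#' Default component set for an oddball trial
#'
#' P1 and P2 occur in every trial (exogenous visual responses); the P3 and a
#' late negative wave are target-related and occur only in deviant trials. The
#' P3 is centro-parietal with strong latency jitter; the late negativity is
#' more frontal. All values are plain configuration, adjustable per study.
#'
#' @param n_channels channel count of the montage.
#' @param fs sampling rate in Hz (used only for documentation of the window).
#' @return list of [erp_component()] objects.
#' @export
default_erp_components <- function(n_channels, fs = 100) {
  pz <- pz_index(n_channels)
  occ <- ((pz - 1L + round(n_channels / 5)) %% n_channels) + 1L
  fro <- ((pz - 1L - round(n_channels / 5)) %% n_channels) + 1L
  list(
    erp_component("P1", 100, 10, 2, 60, circular_topography(n_channels, occ)),
    erp_component("P2", 200, 10, 3, 80, circular_topography(n_channels, occ)),
    erp_component("P3", 400, 40, 8, 120, circular_topography(n_channels, pz),
                  deviant_only = TRUE),
    erp_component("LateNeg", 600, 25, -6, 150, circular_topography(n_channels, fro),
                  deviant_only = TRUE)
  )
}

#' Subject-level generative profile
#'
#' @param subject_id identifier.
#' @param group one of "strong", "medium", "weak" (the planted P3-strength
#'   group; downstream clustering tries to recover it).
#' @param p3_gain non-negative multiplier on the P3 component amplitude.
#' @param noise_sd background noise SD in microvolts.
#' @param jitter_scale multiplier on every component's latency jitter SD.
#' @param latency_shift subject-specific constant latency offset in ms (a
#'   domain-shift knob).
#' @param focus_offset circular rotation of every topography by this many
#'   channels (a spatial domain-shift knob).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = c("strong", "medium", "weak"),
                            p3_gain = 1, noise_sd = 10, jitter_scale = 1,
                            latency_shift = 0, focus_offset = 0L) {
  group <- match.arg(group)
  if (p3_gain < 0) stop("p3_gain must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(subject_id = as.character(subject_id), group = group,
                 p3_gain = p3_gain, noise_sd = noise_sd,
                 jitter_scale = jitter_scale, latency_shift = latency_shift,
                 focus_offset = as.integer(focus_offset)),
            class = "subject_profile")
}

#' Cohort simulation configuration
#'
#' Defaults mirror the recording conditions the method targets: 61 channels,
#' 100 Hz, 1-s epochs, roughly one deviant per 4.3 standards, ~400 valid
#' trials per subject, with subjects falling into strong/medium/weak P3
#' groups. Between-subject variability terms create the domain shift the
#' adaptation is meant to absorb.
#'
#' @param n_subjects_per_group subjects per P3-strength group.
#' @param channels channel count.
#' @param fs sampling rate (Hz).
#' @param trial_len samples per trial (T).
#' @param imbalance_ratio standard trials per deviant trial (>= 1).
#' @param n_trials trials per subject (50 to 2000).
#' @param seed master seed for the cohort.
#' @param group_gains named numeric vector of P3 gains for the three groups.
#' @param noise_sd baseline noise SD in microvolts.
#' @param subject_gain_cv lognormal coefficient of variation of per-subject
#'   gain around the group gain.
#' @param subject_latency_sd SD (ms) of per-subject constant latency offsets.
#' @param subject_focus_sd SD (channels) of per-subject topography rotation;
#'   the default scales with the montage (`channels / 30`) so a rotation
#'   means the same angular displacement on any montage size.
#' @param noise_range multiplicative range of per-subject noise SD.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_group = 5, channels = 61, fs = 100,
                         trial_len = 100, imbalance_ratio = 4.3,
                         n_trials = 400, seed = 1L,
                         group_gains = c(strong = 3, medium = 1.5, weak = 0.5),
                         noise_sd = 10, subject_gain_cv = 0.1,
                         subject_latency_sd = 15, subject_focus_sd = channels / 30,
                         noise_range = c(0.8, 1.2)) {
  if (imbalance_ratio < 1) stop("imbalance_ratio must be >= 1")
  if (n_trials < 50 || n_trials > 2000)
    stop("n_trials must be within [50, 2000]")
  if (!all(c("strong", "medium", "weak") %in% names(group_gains)))
    stop("group_gains must name strong, medium and weak")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 channels = as.integer(channels), fs = fs,
                 trial_len = as.integer(trial_len),
                 imbalance_ratio = imbalance_ratio,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 group_gains = group_gains, noise_sd = noise_sd,
                 subject_gain_cv = subject_gain_cv,
                 subject_latency_sd = subject_latency_sd,
                 subject_focus_sd = subject_focus_sd,
                 noise_range = noise_range),
            class = "synth_config")
}

# channel names: generic labels, with the P3 focus channel called "Pz" so the
# centro-parietal region of interest can be located by name downstream
synth_channel_names <- function(n_channels) {
  nm <- sprintf("ch%02d", seq_len(n_channels))
  nm[pz_index(n_channels)] <- "Pz"
  nm
}

# 1/f-shaped noise, one column per channel, normalized to unit overall SD.
pink_noise <- function(T, n_channels) {
  w <- matrix(stats::rnorm(T * n_channels), T, n_channels)
  f <- stats::mvfft(w)
  k <- seq_len(T) - 1
  s <- ifelse(k == 0, 0, 1 / sqrt(pmin(k, T - k)))
  y <- Re(stats::mvfft(f * s, inverse = TRUE)) / T
  sdy <- stats::sd(as.vector(y))
  if (sdy > 0) y <- y / sdy
  y
}

#' Simulate a single epoched trial
#'
#' Sums the configured components (each a Gaussian bump at a jittered latency
#' scaled by its topography; the P3 additionally by the subject's `p3_gain`)
#' and adds 1/f-plus-white Gaussian noise. Standard trials receive only the
#' components not flagged `deviant_only`. Draws from the current R random
#' stream, so results are deterministic given the RNG state.
#'
#' @param profile a [subject_profile()].
#' @param components list of [erp_component()] (topography lengths must match
#'   the implied channel count).
#' @param is_deviant logical; TRUE for a deviant (target) trial.
#' @param fs sampling rate (Hz).
#' @param trial_len samples per trial.
#' @return numeric matrix `channels x trial_len` in microvolts.
#' @export
simulate_trial <- function(profile, components, is_deviant, fs, trial_len) {
  nch <- length(components[[1L]]$topography)
  win_ms <- trial_len / fs * 1000
  t_ms <- (seq_len(trial_len) - 1) / fs * 1000
  trial <- matrix(0, nch, trial_len)
  for (comp in components) {
    if (length(comp$topography) != nch)
      stop("inconsistent topography lengths across components")
    if (comp$latency_mean < 0 || comp$latency_mean >= win_ms)
      stop("component '", comp$name, "' latency ", comp$latency_mean,
           " ms lies outside the trial window [0, ", win_ms, ") ms")
    if (!is_deviant && comp$deviant_only) next
    lat <- comp$latency_mean + profile$latency_shift +
      stats::rnorm(1) * comp$latency_jitter_sd * profile$jitter_scale
    amp <- comp$amplitude
    if (identical(comp$name, "P3")) amp <- amp * profile$p3_gain
    sigma <- comp$width / 2.3548  # FWHM -> Gaussian SD
    bump <- amp * exp(-(t_ms - lat)^2 / (2 * sigma^2))
    topo <- comp$topography
    if (profile$focus_offset != 0L) {
      off <- ((profile$focus_offset %% nch) + nch) %% nch
      if (off > 0L) topo <- c(topo[(nch - off + 1L):nch], topo[seq_len(nch - off)])
    }
    trial <- trial + outer(topo, bump)
  }
  if (profile$noise_sd > 0) {
    pn <- t(pink_noise(trial_len, nch))
    wn <- matrix(stats::rnorm(nch * trial_len), nch, trial_len)
    trial <- trial + profile$noise_sd * (sqrt(0.7) * pn + sqrt(0.3) * wn)
  }
  trial
}

# deviant count implied by the imbalance ratio
deviant_count <- function(n_trials, imbalance_ratio) {
  round(n_trials / (1 + imbalance_ratio))
}

#' Simulate one subject's epoch set
#'
#' @inheritParams simulate_trial
#' @param config a [synth_config()].
#' @param seed optional seed; if NULL the current RNG state is used.
#' @return an `epoch_set` with `config$n_trials` trials whose deviant:standard
#'   ratio matches `config$imbalance_ratio` within rounding.
#' @export
simulate_subject <- function(profile, config, components = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(components))
    components <- default_erp_components(config$channels, config$fs)
  n <- config$n_trials
  n_dev <- deviant_count(n, config$imbalance_ratio)
  labels <- integer(n)
  labels[sample.int(n, n_dev)] <- 1L
  trials <- array(0, dim = c(n, config$channels, config$trial_len))
  for (i in seq_len(n)) {
    trials[i, , ] <- simulate_trial(profile, components, labels[i] == 1L,
                                    config$fs, config$trial_len)
  }
  epoch_set(trials, labels, config$fs,
            synth_channel_names(config$channels), profile$subject_id)
}

#' Simulate a multi-subject cohort
#'
#' Generates `n_subjects_per_group` subjects for each of the strong, medium
#' and weak P3 groups. Per-subject gain, noise level, latency offset and
#' topography rotation are drawn around the group values, so subjects differ
#' in both response strength and response geometry (the domain shift).
#'
#' @param config a [synth_config()]; `config$group_gains` sets the planted
#'   group-level P3 gains.
#' @param components optional component list (default [default_erp_components()]).
#' @return list with `epochs` (list of `epoch_set`) and `profiles` (list of
#'   `subject_profile`, the ground truth for recovery tests).
#' @export
simulate_cohort <- function(config, components = NULL) {
  set.seed(config$seed)
  groups <- c("strong", "medium", "weak")
  profiles <- list()
  idx <- 0L
  for (g in groups) {
    for (s in seq_len(config$n_subjects_per_group)) {
      idx <- idx + 1L
      gain <- config$group_gains[[g]]
      if (config$subject_gain_cv > 0)
        gain <- gain * exp(stats::rnorm(1, 0, config$subject_gain_cv))
      profiles[[idx]] <- subject_profile(
        subject_id = sprintf("%s_%02d", g, s), group = g, p3_gain = gain,
        noise_sd = config$noise_sd *
          stats::runif(1, config$noise_range[1L], config$noise_range[2L]),
        jitter_scale = stats::runif(1, 0.8, 1.2),
        latency_shift = stats::rnorm(1, 0, config$subject_latency_sd),
        focus_offset = as.integer(round(stats::rnorm(1, 0, config$subject_focus_sd))))
    }
  }
  epochs <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    epochs[[i]] <- simulate_subject(profiles[[i]], config, components,
                                    seed = derive_seed(config$seed, i))
  }
  names(epochs) <- vapply(profiles, `[[`, "", "subject_id")
  list(epochs = epochs, profiles = profiles)
}
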