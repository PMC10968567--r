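# Synthetic 32-channel EEG with planted, band- and electrode-specific class
# differences. The generator exists so the full pipeline (filters, features,
# network, analyses) is testable end-to-end without access to recorded data.
#
# Background model: per channel, Gaussian noise shaped in the frequency
# domain by a 1/f^noise_exponent power envelope, plus band-limited
# oscillatory components (random-phase sinusoid mixtures realized as extra
# spectral amplitude across each band) whose per-trial amplitude carries
# Gaussian variability. The class difference is multiplicative on the
# planted band's spectral amplitude (factor sqrt(effect_size), i.e.
# effect_size on power) at the planted electrodes only, which makes the
# induced differential-entropy gap analytically predictable
# (delta DE = log(effect_size)/2 nats).

#' Frequency-band definitions
#'
#' The four awake-cognition EEG bands used throughout: theta 4-7 Hz,
#' alpha 8-13 Hz, beta 14-30 Hz, gamma 31-45 Hz.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30), gamma = c(31, 45))
}

#' Configuration for the synthetic EEG generator
#'
#' @param n_trials_per_class Trials per class (default 80).
#' @param fs Sampling rate in Hz (default 128).
#' @param dur_listen Listen-trial duration in seconds (default 15, the
#'   1920-sample epoch at 128 Hz).
#' @param dur_recall Recall/creation-trial duration in seconds (default 20).
#' @param planted_electrodes Channels carrying the class effect.
#' @param planted_band One of `"theta","alpha","beta","gamma"`.
#' @param effect_size Band-power ratio (class 1 / class 0) at planted
#'   electrodes; must be >= 1. 1 means no class difference.
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param osc_strength Relative amplitude of the band-limited oscillatory
#'   components over the 1/f background (default 1).
#' @param amp_sd Standard deviation of the per-trial Gaussian amplitude
#'   variability of the oscillatory components (default 0.1).
#' @param line_noise_amp Amplitude (uV) of optional 50 Hz line interference
#'   (default 0, off).
#' @param rms Target broadband RMS amplitude in uV (default 20).
#' @param seed Integer master seed for [generate_dataset()].
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 80L, fs = 128, dur_listen = 15,
                         dur_recall = 20,
                         planted_electrodes = c("FP1", "FPZ", "O1", "OZ", "O2"),
                         planted_band = "gamma", effect_size = 3,
                         noise_exponent = 1, osc_strength = 1, amp_sd = 0.1,
                         line_noise_amp = 0, rms = 20, seed = 1L) {
  cfg <- structure(list(
    n_trials_per_class = as.integer(n_trials_per_class), fs = fs,
    dur_listen = dur_listen, dur_recall = dur_recall,
    planted_electrodes = toupper(planted_electrodes),
    planted_band = match.arg(planted_band, names(eeg_bands())),
    effect_size = effect_size, noise_exponent = noise_exponent,
    osc_strength = osc_strength, amp_sd = amp_sd,
    line_noise_amp = line_noise_amp, rms = rms, seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$effect_size < 1) stop("effect_size must be >= 1")
  if (cfg$dur_listen <= 0 || cfg$dur_recall <= 0) stop("durations must be > 0")
  if (cfg$fs <= 2 * 45) stop("fs must exceed twice the 45 Hz upper band edge")
  unknown <- setdiff(cfg$planted_electrodes, montage_channels())
  if (length(unknown)) {
    stop("unknown electrode name(s): ", paste(unknown, collapse = ", "))
  }
  invisible(cfg)
}

#' Construct a labeled raw EEG trial container
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate in Hz.
#' @param channel_names 32 ordered 10-20 labels.
#' @param subject_id,trial_id Identifiers carried through the pipeline.
#' @param class_label 0 (listen) or 1 (recall/create), or NA.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_names = montage_channels(),
                          subject_id = "S01", trial_id = "T001",
                          class_label = NA_integer_) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names)) {
    stop("rows of `data` must equal length of `channel_names`")
  }
  if (!all(is.finite(data))) stop("non-finite samples in recording")
  if (fs <= 0) stop("fs must be positive")
  structure(list(data = data, fs = fs,
                 channel_names = toupper(channel_names),
                 subject_id = subject_id, trial_id = trial_id,
                 class_label = class_label),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s/%s: %d ch x %d samples @ %g Hz, class %s\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              x$class_label))
  invisible(x)
}

# Spectral amplitude envelope for one channel of one trial.
# freqs: rfft bin frequencies; band_gain: named per-band amplitude factors
# (per-trial variability); planted_gain applied multiplicatively across the
# planted band's bins.
spectral_envelope <- function(freqs, cfg, band_gain, planted_gain = 1) {
  env <- ifelse(freqs <= 0, 0, pmax(freqs, 1)^(-cfg$noise_exponent / 2))
  for (b in names(eeg_bands())) {
    edges <- eeg_bands()[[b]]
    in_band <- freqs >= edges[1] & freqs <= edges[2]
    env[in_band] <- env[in_band] * (1 + cfg$osc_strength * band_gain[[b]])
  }
  edges <- eeg_bands()[[cfg$planted_band]]
  in_band <- freqs >= edges[1] & freqs <= edges[2]
  env[in_band] <- env[in_band] * planted_gain
  env
}

#' Generate one synthetic labeled EEG trial
#'
#' Class 0 is the listen state (duration `dur_listen`), class 1 the
#' recall/creation state (duration `dur_recall`). Class 1 additionally has
#' its planted-band spectral power multiplied by `effect_size` at the
#' planted electrodes; everywhere else the two classes are drawn from the
#' same distribution.
#'
#' @param cfg A [synth_config()].
#' @param class_label 0 or 1.
#' @param trial_seed Integer; identical seeds give bit-identical trials.
#' @param subject_id,trial_id Identifiers stored in the recording.
#' @return A [raw_recording()].
#' @export
generate_trial <- function(cfg, class_label, trial_seed,
                           subject_id = "S01", trial_id = NULL) {
  validate_synth_config(cfg)
  stopifnot(class_label %in% c(0L, 1L))
  dur <- if (class_label == 0) cfg$dur_listen else cfg$dur_recall
  n <- round(cfg$fs * dur)
  if (n %% 2 == 1) n <- n + 1
  set.seed(as.integer(trial_seed))

  n_half <- n %/% 2
  freqs <- (0:n_half) * cfg$fs / n
  # trial-level oscillatory amplitude variability, shared across channels
  band_gain <- stats::setNames(
    pmax(stats::rnorm(4, mean = 1, sd = cfg$amp_sd), 0.1), names(eeg_bands()))
  env_base <- spectral_envelope(freqs, cfg, band_gain)
  # deterministic calibration: expected broadband variance -> target rms^2
  exp_var <- (2 * sum(env_base[2:n_half]^2) + env_base[n_half + 1]^2) / n^2
  base <- cfg$rms / sqrt(exp_var)

  chans <- montage_channels()
  planted <- class_label == 1 & chans %in% cfg$planted_electrodes
  line_phase <- stats::runif(1, 0, 2 * pi)
  data <- matrix(0, length(chans), n)
  for (ci in seq_along(chans)) {
    env <- if (planted[ci]) {
      spectral_envelope(freqs, cfg, band_gain, planted_gain = sqrt(cfg$effect_size))
    } else env_base
    re <- stats::rnorm(n_half + 1)
    im <- stats::rnorm(n_half + 1)
    z <- complex(real = re, imaginary = im) / sqrt(2) * env * base
    z[1] <- 0
    z[n_half + 1] <- re[n_half + 1] * env[n_half + 1] * base  # Nyquist bin real
    spec <- c(z, Conj(z[n_half:2]))
    data[ci, ] <- Re(stats::fft(spec, inverse = TRUE)) / n
  }
  if (cfg$line_noise_amp > 0) {
    tt <- (0:(n - 1)) / cfg$fs
    line <- cfg$line_noise_amp * sin(2 * pi * 50 * tt + line_phase)
    data <- sweep(data, 2, line, "+")
  }
  if (is.null(trial_id)) trial_id <- sprintf("C%d_seed%d", class_label, trial_seed)
  raw_recording(data, cfg$fs, chans, subject_id, trial_id,
                class_label = as.integer(class_label))
}

# Deterministic per-trial seed derivation from the master seed.
derive_trial_seed <- function(master_seed, class_label, index) {
  (as.numeric(master_seed) * 1000003 + class_label * 499979 +
     index * 7919) %% 2147483629
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_trials_per_class` trials per class with per-trial seeds
#' derived deterministically from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Subject identifier stamped on every trial.
#' @return Object of class `eeg_dataset`: list with `trials` (list of
#'   [raw_recording()]), `labels` (integer vector), and `config`.
#' @export
generate_dataset <- function(cfg, subject_id = "S01") {
  validate_synth_config(cfg)
  if (cfg$n_trials_per_class < 10) {
    warning("fewer than 10 trials per class; ten-fold cross-validation ",
            "downstream will not be possible")
  }
  trials <- list()
  labels <- integer(0)
  for (cl in c(0L, 1L)) {
    for (i in seq_len(cfg$n_trials_per_class)) {
      seed_i <- derive_trial_seed(cfg$seed, cl, i)
      trials[[length(trials) + 1L]] <- generate_trial(
        cfg, cl, seed_i, subject_id = subject_id,
        trial_id = sprintf("%s_c%d_%03d", subject_id, cl, i))
      labels <- c(labels, cl)
    }
  }
  structure(list(trials = trials, labels = labels, config = cfg),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d trials (%d per class), fs %g Hz\n",
              length(x$trials), x$config$n_trials_per_class, x$config$fs))
  invisible(x)
}
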