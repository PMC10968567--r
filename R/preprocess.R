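# Filtering and band decomposition. All filters are applied zero-phase
# (forward-backward, signal::filtfilt) so the 1-s feature windows stay
# temporally aligned with the raw signal; filters are applied to the full
# trial before any windowing.

check_band <- function(low, high, fs) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high edge ", high, " Hz is at or above Nyquist (",
                           fs / 2, " Hz)")
}

apply_filtfilt <- function(data, flt) {
  t(apply(data, 1, function(ch) signal::filtfilt(flt, ch)))
}

#' Zero-phase Butterworth bandpass filter
#'
#' Third-order (by default) Butterworth bandpass applied forward-backward,
#' preserving shape and channel order.
#'
#' @param rec A [raw_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Filter order (default 3).
#' @return Filtered [raw_recording()].
#' @export
bandpass <- function(rec, low, high, order = 3) {
  stopifnot(inherits(rec, "raw_recording"), order >= 1)
  check_band(low, high, rec$fs)
  flt <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- apply_filtfilt(rec$data, flt)
  out
}

#' Zero-phase notch filter for power-line interference
#'
#' Second-order IIR notch (biquad, quality factor `q`) applied
#' forward-backward. Attenuates `freq` by well over 20 dB while leaving
#' bands more than a few Hz away essentially untouched.
#'
#' @param rec A [raw_recording()].
#' @param freq Notch frequency in Hz (default 50).
#' @param q Quality factor (default 30; stopband width about `freq/q` Hz).
#' @return Filtered [raw_recording()].
#' @export
notch <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!(freq > 0 && freq < rec$fs / 2)) {
    stop("notch frequency must lie in (0, Nyquist)")
  }
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  out <- rec
  out$data <- apply_filtfilt(rec$data, flt)
  out
}

#' Resample a recording to a new rate
#'
#' Polyphase resampling (via `signal::resample`) used to reconcile the
#' 200 Hz acquisition rate with the 128 Hz rate the model consumes.
#'
#' @param rec A [raw_recording()].
#' @param target_fs Target rate in Hz; must exceed twice the 45 Hz upper
#'   band edge.
#' @return Resampled [raw_recording()] with `fs` updated.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "raw_recording"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs <= 2 * 45) stop("target_fs must exceed 90 Hz to retain the gamma band")
  if (target_fs == rec$fs) return(rec)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  p <- round(target_fs)
  q <- round(rec$fs)
  d <- g(p, q)
  p <- p / d
  q <- q / d
  n_out <- round(ncol(rec$data) * p / q)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) {
    y <- signal::resample(ch, p, q)
    length(y) <- n_out          # trim/pad the polyphase tail
    y[is.na(y)] <- 0
    y
  }))
  out$fs <- target_fs
  out
}

#' Decompose a recording into the four cognition-relevant bands
#'
#' Applies the third-order zero-phase Butterworth bandpass at the
#' theta/alpha/beta/gamma edges of [eeg_bands()]. An optional artifact hook
#' (e.g. an ICA cleanup routine supplied by the user) runs on the recording
#' first; the package deliberately ships no automatic artifact rejection.
#'
#' @param rec A [raw_recording()] (already notch-filtered if needed).
#' @param order Butterworth order (default 3).
#' @param artifact_hook Optional `function(rec) -> rec` applied before
#'   decomposition.
#' @return Object of class `band_signals`: list with `bands` (named list of
#'   channels x samples matrices), `fs`, `channel_names`, `meta`.
#' @export
decompose_bands <- function(rec, order = 3, artifact_hook = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.null(artifact_hook)) rec <- artifact_hook(rec)
  bands <- lapply(eeg_bands(), function(edges) {
    bandpass(rec, edges[1], edges[2], order = order)$data
  })
  structure(list(bands = bands, fs = rec$fs,
                 channel_names = rec$channel_names,
                 meta = list(subject_id = rec$subject_id,
                             trial_id = rec$trial_id,
                             class_label = rec$class_label)),
            class = "band_signals")
}
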