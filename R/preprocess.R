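#' Butterworth filter specification
#'
#' Second-order high- and low-pass Butterworth filters applied forward and
#' backward (zero phase, effective order 4 per band). Cut-offs default to the
#' conventional 20 Hz (high-pass) and 400 Hz (low-pass) surface-EMG band.
#'
#' @param hp_cutoff High-pass cut-off, Hz.
#' @param lp_cutoff Low-pass cut-off, Hz.
#' @param order Filter order per pass.
#' @param zero_phase Filter again in the reverse direction to cancel phase lag.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(hp_cutoff = 20, lp_cutoff = 400, order = 2,
                        zero_phase = TRUE) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff)) {
    stop("need 0 < hp_cutoff < lp_cutoff")
  }
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Full-wave rectification
#'
#' @param x Numeric vector of finite amplitudes.
#' @return Elementwise absolute value.
#' @export
rectify <- function(x) {
  if (!all(is.finite(x))) stop("rectify: samples must be finite")
  abs(x)
}

#' Peak-level normalization
#'
#' Scales a nonnegative (rectified) channel to its peak activation level so
#' that the maximum becomes 1.
#'
#' @param x Nonnegative numeric vector.
#' @return `x / max(x)`, in `[0, 1]`.
#' @export
normalize_peak <- function(x) {
  m <- max(x)
  if (m <= 0) stop("silent channel: all-zero signal cannot be normalized")
  x / m
}

# one zero-phase pass of an IIR filter with odd-reflective padding; the pad
# must cover the filter's transient (which scales with fs/cutoff), so the
# caller passes a cutoff-aware pad length (swing bursts can sit near record
# ends)
#' @noRd
filtfilt_reflect <- function(b, a, x, pad = 3 * max(length(a), length(b))) {
  n <- length(x)
  pad <- max(pad, 3 * max(length(a), length(b)))
  if (n <= pad) stop("signal too short for stable forward-backward filtering")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band filtering
#'
#' High-pass filters the signal (forward and backward, so order 2 per pass
#' becomes effective order 4 with zero phase), demeans the high-passed
#' result, then low-pass filters likewise. Output may dip slightly negative
#' even for a nonnegative input; downstream peak logic operates on it as-is.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length.
#' @export
butterworth_envelope <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$lp_cutoff >= fs / 2) {
    stop("lp_cutoff must be below the Nyquist frequency fs/2")
  }
  if (length(x) <= 6 * spec$order) stop("signal too short (need T > 6 * order)")
  hp <- signal::butter(spec$order, spec$hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, spec$lp_cutoff / (fs / 2), type = "low")
  one_pass <- function(flt, v, cutoff) {
    if (spec$zero_phase) {
      pad <- min(length(v) - 1, round(6 * fs / cutoff))
      filtfilt_reflect(flt$b, flt$a, v, pad = pad)
    } else {
      as.numeric(signal::filter(flt, v))
    }
  }
  y <- one_pass(hp, x, spec$hp_cutoff)
  y <- y - mean(y)
  one_pass(lp, y, spec$lp_cutoff)
}

#' Preprocess one recording for feature extraction
#'
#' Applies the fixed pipeline rectify -> normalize to peak -> zero-phase
#' Butterworth band filtering to every channel.
#'
#' @param rec An [emg_recording()].
#' @param spec A [filter_spec()].
#' @return List with matrices `rectified`, `normalized`, `filtered`
#'   (8 x T each) and the sampling rate `fs`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  rectified <- abs(rec$signal)
  normalized <- t(apply(rectified, 1, normalize_peak))
  filtered <- t(apply(normalized, 1, butterworth_envelope, fs = rec$fs, spec = spec))
  rownames(filtered) <- rownames(normalized) <- rownames(rectified) <- CHANNEL_NAMES
  list(rectified = rectified, normalized = normalized, filtered = filtered,
       fs = rec$fs)
}
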