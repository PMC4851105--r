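#' Bank of sliding Gaussian filters
#'
#' Four unit-area Gaussian kernels of increasing window length used for
#' multiscale smoothing of the rectified EMG. The Gaussian sigma is taken as
#' width/6 so the kernel support spans about +/-3 sigma.
#'
#' @param widths Strictly increasing window lengths in samples.
#' @return An object of class `gaussian_bank`: list of kernels, each summing
#'   to 1.
#' @export
gaussian_bank <- function(widths = c(256, 512, 1024, 2048)) {
  if (length(widths) != 4 || any(diff(widths) <= 0)) {
    stop("widths must be 4 strictly increasing window lengths")
  }
  kernels <- lapply(widths, gaussian_kernel)
  structure(list(widths = widths, kernels = kernels), class = "gaussian_bank")
}

#' Multiscale Gaussian smoothing of a rectified channel
#'
#' Convolves the rectified signal with each kernel of the bank (centered,
#' zero lag, reflective edge padding).
#'
#' @param rectified Nonnegative numeric vector (length > largest width).
#' @param bank A [gaussian_bank()].
#' @return List `v1`..`v4` of smoothed series, same length as the input.
#' @export
multiscale_filter <- function(rectified, bank = gaussian_bank()) {
  stopifnot(inherits(bank, "gaussian_bank"))
  if (length(rectified) <= max(bank$widths)) {
    stop("signal too short: need T > ", max(bank$widths), " samples")
  }
  v <- lapply(bank$kernels, function(k) conv_reflect(rectified, k))
  names(v) <- paste0("v", seq_along(v))
  v
}

#' Data-driven activation threshold for one channel
#'
#' The threshold is `alpha` times the mean rectified amplitude over a window
#' around the position of the widest-scale smoothed maximum: from `delta`
#' samples before it to `2 * delta` samples after it. Near record edges the
#' window is clipped and the mean taken over the samples actually available.
#'
#' @param rectified Nonnegative numeric vector.
#' @param v4 Widest-scale smoothed series from [multiscale_filter()].
#' @param alpha Threshold scale factor (default 1.2).
#' @param delta Half-window parameter in samples (default 500).
#' @return Scalar threshold.
#' @export
channel_threshold <- function(rectified, v4, alpha = 1.2, delta = 500) {
  n <- length(rectified)
  stopifnot(length(v4) == n, n > 0)
  t_star <- which.max(v4)
  lo <- max(1L, t_star - as.integer(delta))
  hi <- min(n, t_star + 2L * as.integer(delta))
  alpha * mean(rectified[lo:hi])
}

# last upward crossing of level thr before the global maximum of v; NA if none
#' @noRd
last_crossing_before_max <- function(v, thr) {
  m <- which.max(v)
  if (m < 2) return(NA_integer_)
  up <- which(v[2:m] >= thr & v[1:(m - 1)] < thr) + 1L
  if (length(up) == 0) NA_integer_ else up[length(up)]
}

#' Detect the swing-related activation onset of one channel
#'
#' For each of the three wider smoothing scales, the last upward crossing of
#' the channel threshold preceding that series' global maximum anchors a
#' search window extending `search_pad` samples beyond the earliest and
#' latest crossing; the onset is the steepest rise of the finest-scale
#' series within that window (the crossing rule skips low pre-swing
#' activity bumps, and the finest scale pins down where the swing burst
#' actually takes off -- the wider scales cross the threshold well before
#' it, which is why the window must extend past the last crossing).
#'
#' @param v List `v1`..`v4` from [multiscale_filter()].
#' @param threshold Channel threshold from [channel_threshold()].
#' @param search_pad Window extension on both sides of the crossings, samples.
#' @return Onset sample index.
#' @export
detect_onset <- function(v, threshold, search_pad = 256) {
  cr <- vapply(v[c("v2", "v3", "v4")], last_crossing_before_max,
               integer(1), thr = threshold)
  cr <- cr[!is.na(cr)]
  if (length(cr) == 0) stop("no activation: no smoothed series crosses the threshold")
  lo <- max(2L, min(cr) - as.integer(search_pad))
  hi <- min(length(v$v1), max(cr) + as.integer(search_pad))
  dv1 <- diff(v$v1)
  win <- lo:hi
  win[which.max(dv1[win - 1L])]
}

#' Onset detection and activation profile of one recording
#'
#' Runs the multiscale onset detector on every channel and assembles the
#' muscle activation profile: the vector of onset-time differences
#' `x_i = ts_8 - ts_i` (i = 1..7) of each muscle relative to the reference
#' channel 8 (left trapezius). Positive components mean the muscle activated
#' before the reference. A recording is flagged for manual review when the
#' largest reference-vs-other onset gap `lambda` falls outside
#' `[lambda_min, lambda_max]`.
#'
#' @param rec An [emg_recording()].
#' @param bank A [gaussian_bank()].
#' @param alpha,delta Threshold parameters, see [channel_threshold()].
#' @param lambda_min,lambda_max Review bounds for lambda, in samples;
#'   `NULL` disables the corresponding check (see [profile_map()] for
#'   dataset-level percentile defaults).
#' @return List with `onset` (class `onset_result`: per-channel onset sample
#'   indices `ts`, thresholds, `lambda`, `flagged`) and `profile` (class
#'   `activation_profile`: 7-vector `x` in ms, subject and shot ids).
#' @export
activation_profile <- function(rec, bank = gaussian_bank(),
                               alpha = 1.2, delta = 500,
                               lambda_min = NULL, lambda_max = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  rectified <- abs(rec$signal)
  ts <- integer(N_CHANNELS)
  thr <- numeric(N_CHANNELS)
  for (ch in seq_len(N_CHANNELS)) {
    v <- multiscale_filter(rectified[ch, ], bank)
    thr[ch] <- channel_threshold(rectified[ch, ], v$v4, alpha, delta)
    ts[ch] <- tryCatch(
      detect_onset(v, thr[ch]),
      error = function(e) stop("channel ", ch, ": ", conditionMessage(e))
    )
  }
  lambda <- max(abs(ts[REFERENCE_CHANNEL] - ts[-REFERENCE_CHANNEL]))
  flagged <- (!is.null(lambda_min) && lambda < lambda_min) ||
    (!is.null(lambda_max) && lambda > lambda_max)
  x <- (ts[REFERENCE_CHANNEL] - ts[-REFERENCE_CHANNEL]) / rec$fs * 1000
  names(x) <- paste0("x", 1:7)
  list(
    onset = structure(list(ts = ts, thresholds = thr, lambda = lambda,
                           flagged = flagged), class = "onset_result"),
    profile = structure(list(x = x, subject_id = rec$subject_id,
                             shot_id = rec$shot_id),
                        class = "activation_profile")
  )
}

#' Activation-profile map of a dataset
#'
#' Collects activation profiles into a subject-ordered matrix for export or
#' plotting, recomputes the review flag against dataset-level lambda bounds
#' (by default the 2.5th/97.5th percentiles of lambda over all processed
#' recordings), and reports flagged shots. Flagged recordings are reported,
#' never auto-corrected.
#'
#' @param profiles List of per-recording results from [activation_profile()].
#' @param lambda_probs Percentiles defining the lambda review band.
#' @return `data.frame` with columns shot_id, subject_id, x1..x7, lambda,
#'   flagged; rows ordered by subject then shot.
#' @export
profile_map <- function(profiles, lambda_probs = c(0.025, 0.975)) {
  if (length(profiles) == 0) stop("need at least one profile")
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(shot_id = p$profile$shot_id, subject_id = p$profile$subject_id,
               as.list(p$profile$x), lambda = p$onset$lambda,
               stringsAsFactors = FALSE)
  }))
  bounds <- type7_quantile(df$lambda, lambda_probs)
  df$flagged <- df$lambda < bounds[1] | df$lambda > bounds[2]
  df <- df[order(df$subject_id, df$shot_id), ]
  rownames(df) <- NULL
  df
}
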