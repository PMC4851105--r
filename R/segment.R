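#' Peak detection with local Gaussian refinement
#'
#' Detects peaks in a filtered envelope the way interactive biosignal peak
#' pickers do: smooth with a moving Gaussian whose window auto-scales with
#' the record length, take candidate peaks as local maxima of the smoothed
#' signal above 5% of its global maximum, then refine each candidate by a
#' least-squares parabola fit to the log of the samples above half of the
#' candidate height. The fit yields a sub-sample position, height and full
#' width at half maximum (FWHM); the Gaussian peak area is
#' `height * FWHM * 1.0646` and the fitting error is the RMS residual of the
#' local Gaussian fit as a percentage of the height.
#'
#' @param filtered Numeric vector (a filtered, normalized channel).
#' @param fs Sampling rate, Hz.
#' @param peak_density Auto-scaling parameter: the smoothing window is
#'   `max(3, round(T / (12 * peak_density)))` samples, i.e. about 1/24 of the
#'   record at the default density of 2 dominant peaks.
#' @param channel Optional channel number recorded in the output.
#' @return `data.frame` of peak descriptors: position (s), height, width
#'   (FWHM, s), area, fit_error (%), channel.
#' @export
find_peaks <- function(filtered, fs, peak_density = 2, channel = NA_integer_) {
  T <- length(filtered)
  w <- max(3, round(T / (12 * peak_density)))
  if (T <= w) stop("signal shorter than the smoothing window")
  sm <- conv_reflect(filtered, gaussian_kernel(w))
  d <- diff(sm)
  # downward zero-crossings of the smoothed first difference = local maxima
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # drop candidates without full smoothing support (edge-reflection artifacts)
  cand <- cand[cand > w %/% 2 & cand <= T - w %/% 2]
  gmax <- max(sm)
  cand <- cand[sm[cand] > 0.05 * gmax]
  if (length(cand) == 0) stop("no peaks")

  desc <- lapply(cand, function(p) {
    h0 <- sm[p]
    half <- h0 / 2
    lo <- p
    while (lo > 1 && sm[lo - 1] > half) lo <- lo - 1
    hi <- p
    while (hi < T && sm[hi + 1] > half) hi <- hi + 1
    idx <- lo:hi
    y <- sm[idx]
    pos_s <- (p - 0.5) / fs
    height <- h0
    width_s <- length(idx) / fs
    fit_err <- NA_real_
    if (length(idx) >= 3 && all(y > 0)) {
      ic <- idx - p  # center the design for numerical stability
      co <- stats::.lm.fit(cbind(1, ic, ic^2), log(y))$coefficients
      if (is.finite(co[3]) && co[3] < 0) {
        ctr <- p - co[2] / (2 * co[3])
        if (ctr >= lo - 1 && ctr <= hi + 1) {
          sigma2 <- -1 / (2 * co[3])
          pos_s <- (ctr - 0.5) / fs
          height <- exp(co[1] - co[2]^2 / (4 * co[3]))
          width_s <- 2 * sqrt(2 * log(2)) * sqrt(sigma2) / fs
          res <- y - height * exp(-(idx - ctr)^2 / (2 * sigma2))
          fit_err <- 100 * sqrt(mean(res^2)) / height
        }
      }
    }
    if (is.na(fit_err)) {
      # degenerate local fit: fall back to discrete estimates
      res <- y - h0 * exp(-(idx - p)^2 / (2 * (length(idx) / 2.355)^2))
      fit_err <- 100 * sqrt(mean(res^2)) / h0
    }
    data.frame(position = pos_s, height = height, width = width_s,
               area = height * width_s * 1.0646, fit_error = fit_err,
               channel = channel)
  })
  do.call(rbind, desc)
}

#' Retain the two highest peaks of a channel
#'
#' The two peaks with greatest height, re-labeled P1/P2 by order of
#' appearance in time.
#'
#' @param peaks Peak descriptors of one channel, from [find_peaks()].
#' @return The two rows, with a `rank` column (`"P1"`, `"P2"`), ordered by
#'   time; `NULL` when fewer than two peaks exist (degenerate channel).
#' @export
two_highest <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) < 2) return(NULL)
  top <- peaks[order(-peaks$height)[1:2], ]
  top <- top[order(top$position), ]
  top$rank <- c("P1", "P2")
  top
}

#' Box-plot pruning of outlier peak positions
#'
#' Pools the P1/P2 positions of all channels and applies Tukey fences
#' (1.5 IQR beyond the quartiles, type-7 quantiles): channels whose P1
#' (resp. P2) position falls outside the fences are removed from the idx1
#' (resp. idx2) retention list.
#'
#' @param p1_pos,p2_pos Named numeric vectors of P1 and P2 positions per
#'   channel (names = channel numbers).
#' @return List with `idx1`, `idx2` (retained channel numbers) and
#'   `fences` (lower/upper).
#' @export
prune_outliers <- function(p1_pos, p2_pos) {
  pool <- c(p1_pos, p2_pos)
  q <- type7_quantile(pool, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  fence <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  keep1 <- as.integer(names(p1_pos))[p1_pos >= fence[1] & p1_pos <= fence[2]]
  keep2 <- as.integer(names(p2_pos))[p2_pos >= fence[1] & p2_pos <= fence[2]]
  if (length(keep1) == 0 || length(keep2) == 0) stop("segmentation failed: all channels pruned")
  list(idx1 = keep1, idx2 = keep2, fences = fence)
}

#' Swing window from the marginal peaks
#'
#' The swing starts half a width before the earliest retained P1 and ends
#' half a width after the latest retained P2.
#'
#' @param p1,p2 Peak descriptor data frames (one row per retained channel)
#'   with columns position, width, channel.
#' @param t_max Record end in seconds (caps t2); t1 is floored at 0.
#' @return Numeric `c(t1, t2)` in seconds.
#' @export
swing_window <- function(p1, p2, t_max = Inf) {
  stopifnot(nrow(p1) >= 1, nrow(p2) >= 1)
  k1 <- which.min(p1$position)
  k2 <- which.max(p2$position)
  t1 <- max(0, p1$position[k1] - p1$width[k1] / 2)
  t2 <- min(t_max, p2$position[k2] + p2$width[k2] / 2)
  if (t1 >= t2) stop("invalid swing window: t1 >= t2")
  c(t1 = unname(t1), t2 = unname(t2))
}

#' Extract the swing segment of a recording
#'
#' Full segmentation loop over the preprocessed channels: detect peaks,
#' retain the two highest per channel, prune outlier channels by the
#' box-plot rule, compute the swing window from the marginal peaks, and
#' repeat peak retention on the restricted channel set until no new outliers
#' appear (at most `max_iter` iterations). Peak positions are finally also
#' expressed relative to the swing (fraction of the duration in `[0, 1]`).
#' Channels excluded by pruning still contribute a (P1, P2) pair computed
#' from their own two highest peaks, since all feature sets assume a fixed
#' 8-channel layout.
#'
#' @param rec An [emg_recording()].
#' @param spec A [filter_spec()].
#' @param peak_density Passed to [find_peaks()].
#' @param max_iter Maximum pruning iterations.
#' @param prep Optional precomputed [preprocess_recording()] result.
#' @return An object of class `swing_segment`: `t1`, `t2`, `duration`,
#'   `peaks` (16-row data frame: per channel P1/P2 descriptors with
#'   `rel_position`), `excluded_p1`, `excluded_p2`, `iterations`,
#'   `filtered` (matrix), `fs`.
#' @export
extract_segment <- function(rec, spec = filter_spec(), peak_density = 2,
                            max_iter = 5, prep = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(prep)) prep <- preprocess_recording(rec, spec)
  fs <- prep$fs
  t_max <- ncol(prep$filtered) / fs
  all_peaks <- lapply(seq_len(N_CHANNELS), function(ch) {
    find_peaks(prep$filtered[ch, ], fs, peak_density, channel = ch)
  })
  pairs <- lapply(all_peaks, two_highest)
  degenerate <- which(vapply(pairs, is.null, logical(1)))
  active <- setdiff(seq_len(N_CHANNELS), degenerate)
  if (length(active) == 0) stop("segmentation failed: no channel has two peaks")

  idx1 <- idx2 <- active
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > max_iter) stop("segmentation did not converge in ", max_iter, " iterations")
    p1_pos <- vapply(pairs[idx1], function(p) p$position[1], numeric(1))
    p2_pos <- vapply(pairs[idx2], function(p) p$position[2], numeric(1))
    names(p1_pos) <- idx1
    names(p2_pos) <- idx2
    pr <- prune_outliers(p1_pos, p2_pos)
    if (setequal(pr$idx1, idx1) && setequal(pr$idx2, idx2)) break
    idx1 <- pr$idx1
    idx2 <- pr$idx2
  }
  p1 <- do.call(rbind, lapply(pairs[idx1], function(p) p[1, ]))
  p2 <- do.call(rbind, lapply(pairs[idx2], function(p) p[2, ]))
  win <- swing_window(p1, p2, t_max = t_max)
  dur <- unname(win[2] - win[1])

  peaks <- do.call(rbind, lapply(active, function(ch) pairs[[ch]]))
  peaks$rel_position <- pmin(1, pmax(0, (peaks$position - win[1]) / dur))
  structure(
    list(t1 = unname(win[1]), t2 = unname(win[2]), duration = dur,
         peaks = peaks,
         excluded_p1 = setdiff(active, idx1), excluded_p2 = setdiff(active, idx2),
         degenerate = degenerate, iterations = iter,
         filtered = prep$filtered, fs = fs),
    class = "swing_segment"
  )
}

#' @export
print.swing_segment <- function(x, ...) {
  cat(sprintf("<swing_segment> [%.3f, %.3f] s (%.3f s), %d iteration(s)",
              x$t1, x$t2, x$duration, x$iterations))
  if (length(x$excluded_p1) || length(x$excluded_p2)) {
    cat(sprintf("; excluded P1: {%s} P2: {%s}",
                paste(x$excluded_p1, collapse = ","),
                paste(x$excluded_p2, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}
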