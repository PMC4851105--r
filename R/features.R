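STAT_NAMES <- c("min", "max", "mean", "median", "q_lo", "q_up", "sd", "iqr",
                "range_lo", "range_up", "skewness", "kurtosis")

#' Twelve summary statistics of a sample
#'
#' Minimum, maximum, mean, median, lower and upper quartile, standard
#' deviation, inter-quartile range, lower range (median - Qlo), upper range
#' (Qup - median), skewness and kurtosis. Skewness and kurtosis are the
#' standardized third and fourth central moments (kurtosis is not excess
#' kurtosis, so a normal sample gives about 3); for a constant sample both
#' are defined as 0. Quartiles use linear interpolation (type 7).
#'
#' @param x Numeric vector with at least 4 values.
#' @return Named numeric vector of length 12.
#' @export
stat_vector <- function(x) {
  if (length(x) < 4) stop("need at least 4 values")
  q <- type7_quantile(x, c(0.25, 0.5, 0.75))
  s <- stats::sd(x)
  if (s > 0) {
    z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    skew <- mean(z^3)
    kurt <- mean(z^4)
  } else {
    skew <- kurt <- 0
  }
  out <- c(min(x), max(x), mean(x), q[2], q[1], q[3], s, q[3] - q[1],
           q[2] - q[1], q[3] - q[2], skew, kurt)
  names(out) <- STAT_NAMES
  out
}

#' @noRd
window_samples <- function(seg, ch) {
  fs <- seg$fs
  i1 <- max(1L, as.integer(floor(seg$t1 * fs)) + 1L)
  i2 <- min(ncol(seg$filtered), as.integer(ceiling(seg$t2 * fs)))
  seg$filtered[ch, i1:i2]
}

#' Swing duration and side-channel statistics
#'
#' Swing duration (s) plus the 12 summary statistics of the filtered
#' swing-window samples of each of the four channels on one body side
#' (right = channels 1, 2, 5, 6; left = 3, 4, 7, 8): 49 features.
#'
#' @param seg A [extract_segment()] result.
#' @param side `"right"` or `"left"`.
#' @return Named numeric vector of length 49.
#' @export
chan_stats <- function(seg, side = c("right", "left")) {
  side <- match.arg(side)
  chans <- if (side == "right") RIGHT_CHANNELS else LEFT_CHANNELS
  out <- c(duration = seg$duration)
  for (ch in chans) {
    s <- stat_vector(window_samples(seg, ch))
    names(s) <- paste0("ch", ch, "_", STAT_NAMES)
    out <- c(out, s)
  }
  out
}

#' @noRd
pair_names <- function(prefix) {
  idx <- utils::combn(N_CHANNELS, 2)
  paste0(prefix, idx[1, ], "_", idx[2, ])
}

#' Correlation-contrast features
#'
#' For each of the 28 unordered channel pairs, the Pearson and Spearman
#' correlations of the filtered signals over the swing window are combined:
#' `delta` = Pearson - Spearman, `ratio` = Pearson / Spearman. With
#' `with_stats` the 12 summary statistics of the 28 values are appended
#' (28 + 12 = 40 features).
#'
#' @param seg A [extract_segment()] result.
#' @param mode `"delta"` or `"ratio"`.
#' @param with_stats Append the statistics block.
#' @return Named numeric vector of length 28 or 40.
#' @export
corr_features <- function(seg, mode = c("delta", "ratio"), with_stats = FALSE) {
  mode <- match.arg(mode)
  X <- t(vapply(seq_len(N_CHANNELS), function(ch) window_samples(seg, ch),
                numeric(length(window_samples(seg, 1)))))
  if (any(apply(X, 1, stats::sd) == 0)) {
    stop("zero-variance channel in swing window: correlations undefined")
  }
  pe <- stats::cor(t(X), method = "pearson")
  sp <- stats::cor(t(X), method = "spearman")
  idx <- utils::combn(N_CHANNELS, 2)
  p <- pe[t(idx)]
  s <- sp[t(idx)]
  vals <- if (mode == "delta") p - s else guarded_div(p, s)
  names(vals) <- pair_names(if (mode == "delta") "cd" else "cr")
  if (with_stats) {
    st <- stat_vector(vals)
    names(st) <- paste0("stat_", STAT_NAMES)
    vals <- c(vals, st)
  }
  vals
}

# division guard shared by the ratio-style feature builders: near-zero
# denominators yield 0 rather than blowing up
#' @noRd
guarded_div <- function(num, den) {
  out <- ifelse(abs(den) < 1e-9, 0, num / den)
  as.numeric(out)
}

#' @noRd
peak_matrix <- function(seg, rank) {
  pk <- seg$peaks[seg$peaks$rank == rank, ]
  pk <- pk[order(pk$channel), ]
  if (nrow(pk) != N_CHANNELS) {
    stop("peak descriptors missing for channels: ",
         paste(setdiff(seq_len(N_CHANNELS), pk$channel), collapse = ", "))
  }
  m <- as.matrix(pk[, c("rel_position", "height", "width", "area", "fit_error")])
  rownames(m) <- paste0("ch", seq_len(N_CHANNELS))
  m
}

#' Peak-property features
#'
#' The five properties (relative position, height, width, area, fitting
#' error) of each channel's peak: 5 x 8 = 40 features. `which = "P1"` or
#' `"P2"` uses that peak directly; `"delta"` is P1 - P2 and `"ratio"` is
#' P1 / P2 of the corresponding properties.
#'
#' @param seg A [extract_segment()] result.
#' @param which `"P1"`, `"P2"`, `"delta"` or `"ratio"`.
#' @return Named numeric vector of length 40.
#' @export
peak_property_features <- function(seg, which = c("P1", "P2", "delta", "ratio")) {
  which <- match.arg(which)
  m <- switch(which,
    P1 = peak_matrix(seg, "P1"),
    P2 = peak_matrix(seg, "P2"),
    delta = peak_matrix(seg, "P1") - peak_matrix(seg, "P2"),
    ratio = {
      a <- peak_matrix(seg, "P1")
      b <- peak_matrix(seg, "P2")
      matrix(guarded_div(a, b), nrow(a), ncol(a), dimnames = dimnames(a))
    }
  )
  out <- as.numeric(t(m))
  names(out) <- paste0(rep(rownames(m), each = 5), "_", rep(colnames(m), 8))
  out
}

#' @noRd
pairwise_position_diffs <- function(seg, rank, absolute) {
  rp <- peak_matrix(seg, rank)[, "rel_position"]
  idx <- utils::combn(N_CHANNELS, 2)
  d <- rp[idx[1, ]] - rp[idx[2, ]]  # lower-index minus higher-index channel
  if (absolute) abs(d) else d
}

#' Peak-concurrency features
#'
#' Concurrency of one peak's relative positions across channels: for each of
#' the 28 channel pairs the signed (or absolute) difference of relative
#' positions, plus the 12 summary statistics of the 28 values: 40 features.
#'
#' @param seg A [extract_segment()] result.
#' @param rank `"P1"` or `"P2"`.
#' @param absolute Use absolute differences.
#' @return Named numeric vector of length 40.
#' @export
sync_features <- function(seg, rank = c("P1", "P2"), absolute = FALSE) {
  rank <- match.arg(rank)
  d <- pairwise_position_diffs(seg, rank, absolute)
  names(d) <- pair_names("sy")
  st <- stat_vector(d)
  names(st) <- paste0("stat_", STAT_NAMES)
  c(d, st)
}

#' Combined two-peak concurrency features
#'
#' Combines the per-pair P1 and P2 concurrency values with a basic
#' arithmetic operation (`delta` subtracts, `sum` adds, `prod` multiplies,
#' `div` divides, the P2 value being the second operand), plus the 12
#' summary statistics of the 28 combined values: 40 features.
#'
#' @param seg A [extract_segment()] result.
#' @param op `"delta"`, `"sum"`, `"prod"` or `"div"`.
#' @param absolute Combine absolute rather than signed concurrencies.
#' @return Named numeric vector of length 40.
#' @export
sync_combo_features <- function(seg, op = c("delta", "sum", "prod", "div"),
                                absolute = FALSE) {
  op <- match.arg(op)
  d1 <- pairwise_position_diffs(seg, "P1", absolute)
  d2 <- pairwise_position_diffs(seg, "P2", absolute)
  v <- switch(op,
    delta = d1 - d2,
    sum = d1 + d2,
    prod = d1 * d2,
    div = guarded_div(d1, d2)
  )
  names(v) <- pair_names("cb")
  st <- stat_vector(v)
  names(st) <- paste0("stat_", STAT_NAMES)
  c(v, st)
}

#' Registry of the 22 feature sets
#'
#' @return `data.frame` with columns id, name, size (feature count excluding
#'   the leading sex column) and the builder closure for each registered set.
#' @export
feature_registry <- function() {
  spec <- list(
    list(1L, "RightChanStats", 49L, function(s) chan_stats(s, "right")),
    list(2L, "LeftChanStats", 49L, function(s) chan_stats(s, "left")),
    list(3L, "CorrDelta", 28L, function(s) corr_features(s, "delta", FALSE)),
    list(4L, "CorrRatio", 28L, function(s) corr_features(s, "ratio", FALSE)),
    list(5L, "StatsCorrDelta", 40L, function(s) corr_features(s, "delta", TRUE)),
    list(6L, "StatsCorrRatio", 40L, function(s) corr_features(s, "ratio", TRUE)),
    list(7L, "PeakP1", 40L, function(s) peak_property_features(s, "P1")),
    list(8L, "PeakP1Sync", 40L, function(s) sync_features(s, "P1", FALSE)),
    list(9L, "PeakP1AbsSync", 40L, function(s) sync_features(s, "P1", TRUE)),
    list(10L, "PeakP2", 40L, function(s) peak_property_features(s, "P2")),
    list(11L, "PeakP2Sync", 40L, function(s) sync_features(s, "P2", FALSE)),
    list(12L, "PeakP2AbsSync", 40L, function(s) sync_features(s, "P2", TRUE)),
    list(13L, "PeakDelta", 40L, function(s) peak_property_features(s, "delta")),
    list(14L, "PeakRatio", 40L, function(s) peak_property_features(s, "ratio")),
    list(15L, "PeakSyncDelta", 40L, function(s) sync_combo_features(s, "delta", FALSE)),
    list(16L, "PeakSyncSum", 40L, function(s) sync_combo_features(s, "sum", FALSE)),
    list(17L, "PeakSyncProd", 40L, function(s) sync_combo_features(s, "prod", FALSE)),
    list(18L, "PeakSyncDiv", 40L, function(s) sync_combo_features(s, "div", FALSE)),
    list(19L, "PeakAbsSyncDelta", 40L, function(s) sync_combo_features(s, "delta", TRUE)),
    list(20L, "PeakAbsSyncSum", 40L, function(s) sync_combo_features(s, "sum", TRUE)),
    list(21L, "PeakAbsSyncProd", 40L, function(s) sync_combo_features(s, "prod", TRUE)),
    list(22L, "PeakAbsSyncDiv", 40L, function(s) sync_combo_features(s, "div", TRUE))
  )
  data.frame(
    id = vapply(spec, `[[`, integer(1), 1),
    name = vapply(spec, `[[`, character(1), 2),
    size = vapply(spec, `[[`, integer(1), 3),
    builder = I(lapply(spec, `[[`, 4)),
    stringsAsFactors = FALSE
  )
}

#' Build all feature tables of a dataset
#'
#' Applies every registered feature builder to every shot's swing segment.
#' The very first feature of each table is always sex (0 woman, 1 man);
#' target columns (speed, distance) are appended. Shots whose builder fails
#' are dropped from that table with a warning naming the reason.
#'
#' @param ds A [shot_dataset()].
#' @param segments Named list of [extract_segment()] results (by shot_id).
#' @param sets Integer ids of the sets to build (default all 22).
#' @return Named list of `data.frame`s, one per feature set; each has
#'   shot_id and subject_id as attributes-free leading columns followed by
#'   sex, the named features, speed, distance.
#' @export
build_feature_tables <- function(ds, segments, sets = 1:22) {
  stopifnot(inherits(ds, "shot_dataset"))
  meta <- dataset_meta(ds)
  reg <- feature_registry()
  reg <- reg[reg$id %in% sets, ]
  out <- list()
  for (r in seq_len(nrow(reg))) {
    build <- reg$builder[[r]]
    rows <- list()
    for (i in seq_len(nrow(meta))) {
      sid <- meta$shot_id[i]
      seg <- segments[[sid]]
      if (is.null(seg)) stop("no segment for shot ", sid)
      feats <- tryCatch(build(seg), error = function(e) {
        warning("shot ", sid, " dropped from ", reg$name[r], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(feats)) next
      if (length(feats) != reg$size[r]) {
        stop(reg$name[r], ": expected ", reg$size[r], " features, got ",
             length(feats))
      }
      rows[[sid]] <- data.frame(
        shot_id = sid, subject_id = meta$subject_id[i], sex = meta$sex[i],
        as.list(feats), speed = meta$speed[i], distance = meta$distance[i],
        stringsAsFactors = FALSE, check.names = TRUE
      )
    }
    out[[reg$name[r]]] <- do.call(rbind, unname(rows))
  }
  out
}

#' Predictor column names of a feature table
#'
#' Sex plus the set's named features (everything except identifiers and
#' target columns).
#'
#' @param table A feature table from [build_feature_tables()].
#' @return Character vector.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("shot_id", "subject_id", "speed", "distance"))
}
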