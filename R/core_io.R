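#' Construct a single-shot EMG recording
#'
#' An `emg_recording` bundles the 8-channel surface-EMG signal of one golf
#' swing with its shot metadata. Channels follow the fixed map: 1 right FCR,
#' 2 right EDC, 3 left FCR, 4 left EDC, 5 right rhomboideus,
#' 6 right trapezius, 7 left rhomboideus, 8 left trapezius (the reference).
#'
#' @param shot_id Character scalar identifying the shot.
#' @param subject_id Character scalar identifying the player.
#' @param sex Integer flag, 0 = woman, 1 = man.
#' @param signal Numeric matrix, 8 rows (channels) by T columns (samples).
#'   Amplitudes may be signed; units are arbitrary and are never rescaled on
#'   input (peak normalization happens in preprocessing).
#' @param fs Sampling rate in Hz (default 1000).
#' @param speed Club head speed of the shot (km/h), or `NA`.
#' @param distance Ball carry distance of the shot (m), or `NA`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(shot_id, subject_id, sex, signal, fs = 1000,
                          speed = NA_real_, distance = NA_real_) {
  signal <- as.matrix(signal)
  if (nrow(signal) != N_CHANNELS) {
    stop("recording '", shot_id, "' must have exactly ", N_CHANNELS,
         " channels, got ", nrow(signal))
  }
  if (!is.numeric(signal) || anyNA(signal)) {
    stop("recording '", shot_id, "': signal must be numeric without NA")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (ncol(signal) < fs) {
    stop("recording '", shot_id, "' must hold at least 1 s of signal (T >= fs)")
  }
  if (!sex %in% c(0, 1)) stop("sex must be 0 (woman) or 1 (man)")
  if (!is.na(speed) && speed <= 0) stop("speed must be positive when present")
  if (!is.na(distance) && distance <= 0) stop("distance must be positive when present")
  rownames(signal) <- CHANNEL_NAMES
  structure(
    list(shot_id = as.character(shot_id), subject_id = as.character(subject_id),
         sex = as.integer(sex), fs = fs, signal = signal,
         speed = as.numeric(speed), distance = as.numeric(distance)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> shot %s (subject %s, %s), %d x %d @ %g Hz\n",
              x$shot_id, x$subject_id, if (x$sex == 1) "man" else "woman",
              nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

#' Construct a shot dataset
#'
#' Validated, ordered collection of [emg_recording()] objects. Subject IDs
#' partition the shots; every subject must contribute at least two shots so
#' that a personal-average effectiveness label is well defined.
#'
#' @param recordings List of `emg_recording` objects.
#' @return An object of class `shot_dataset`.
#' @export
shot_dataset <- function(recordings) {
  if (length(recordings) == 0) stop("dataset must contain at least one recording")
  ok <- vapply(recordings, inherits, logical(1), "emg_recording")
  if (!all(ok)) stop("all elements must be emg_recording objects")
  ids <- vapply(recordings, `[[`, character(1), "shot_id")
  if (anyDuplicated(ids)) stop("duplicate shot_id: ", ids[duplicated(ids)][1])
  subj <- vapply(recordings, `[[`, character(1), "subject_id")
  counts <- table(subj)
  if (any(counts < 2)) {
    stop("subject needs >=2 shots: ", paste(names(counts)[counts < 2], collapse = ", "))
  }
  names(recordings) <- ids
  structure(list(recordings = recordings), class = "shot_dataset")
}

#' @export
length.shot_dataset <- function(x) length(x$recordings)

#' @export
print.shot_dataset <- function(x, ...) {
  m <- dataset_meta(x)
  cat(sprintf("<shot_dataset> %d shots, %d subjects (%d men, %d women)\n",
              nrow(m), length(unique(m$subject_id)),
              length(unique(m$subject_id[m$sex == 1])),
              length(unique(m$subject_id[m$sex == 0]))))
  invisible(x)
}

#' Per-shot metadata of a dataset
#'
#' @param ds A [shot_dataset()].
#' @return `data.frame` with columns shot_id, subject_id, sex, fs, speed, distance.
#' @export
dataset_meta <- function(ds) {
  stopifnot(inherits(ds, "shot_dataset"))
  r <- ds$recordings
  data.frame(
    shot_id = vapply(r, `[[`, character(1), "shot_id"),
    subject_id = vapply(r, `[[`, character(1), "subject_id"),
    sex = vapply(r, `[[`, integer(1), "sex"),
    fs = vapply(r, `[[`, numeric(1), "fs"),
    speed = vapply(r, `[[`, numeric(1), "speed"),
    distance = vapply(r, `[[`, numeric(1), "distance"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Personal-effectiveness labels
#'
#' A shot is labeled effective (1) when its target value lies strictly above
#' the personal (subject-specific) average of that target; ties and values at
#' or below the average are ineffective (0). Per subject the minimum shot can
#' therefore never be labeled effective.
#'
#' @param ds A [shot_dataset()].
#' @param target `"speed"` or `"distance"`.
#' @return Integer vector of 0/1 labels, one per shot, named by shot_id.
#' @export
effectiveness_labels <- function(ds, target = c("speed", "distance")) {
  target <- match.arg(target)
  meta <- dataset_meta(ds)
  v <- meta[[target]]
  if (anyNA(v)) {
    stop("missing ", target, " for shots: ",
         paste(meta$shot_id[is.na(v)], collapse = ", "))
  }
  mu <- stats::ave(v, meta$subject_id, FUN = mean)
  lab <- as.integer(v > mu)
  names(lab) <- meta$shot_id
  lab
}

#' Write a dataset as wide CSV files
#'
#' One signal file per shot (`<shot_id>.csv`, eight named channel columns, one
#' row per sample) plus a `metadata.csv` table with columns shot_id,
#' subject_id, sex, fs, speed, distance. Reading this layout back reproduces
#' the dataset exactly.
#'
#' @param ds A [shot_dataset()].
#' @param path Directory to write into (created if needed).
#' @param format Only `"csv-wide"` is supported for writing.
#' @return Invisibly, the path.
#' @export
write_dataset <- function(ds, path, format = "csv-wide") {
  stopifnot(inherits(ds, "shot_dataset"))
  if (format != "csv-wide") stop("write_dataset supports only csv-wide")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  meta <- dataset_meta(ds)
  utils::write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE)
  for (rec in ds$recordings) {
    sig <- as.data.frame(t(rec$signal))
    names(sig) <- CHANNEL_NAMES
    utils::write.csv(sig, file.path(path, paste0(rec$shot_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset from disk
#'
#' @param path Directory holding `metadata.csv` plus per-shot signal files
#'   (csv-wide, see [write_dataset()]), or a single long-format CSV
#'   (csv-long: columns shot_id, sample, channel, value).
#' @param format `"csv-wide"` or `"csv-long"`. EDF hardware exports are not
#'   supported by this build; convert to CSV first.
#' @return A validated [shot_dataset()] with channels in canonical order.
#' @export
read_dataset <- function(path, format = c("csv-wide", "csv-long", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF reading is not available in this build; export to csv-wide instead")
  }
  meta_file <- file.path(path, "metadata.csv")
  if (!file.exists(meta_file)) stop("metadata.csv not found under ", path)
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  need <- c("shot_id", "subject_id", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (is.null(meta$fs)) meta$fs <- 1000
  if (is.null(meta$speed)) meta$speed <- NA_real_
  if (is.null(meta$distance)) meta$distance <- NA_real_

  long <- NULL
  if (format == "csv-long") {
    lf <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    lf <- setdiff(lf, meta_file)
    if (length(lf) != 1) stop("csv-long expects exactly one signal file next to metadata.csv")
    long <- utils::read.csv(lf[1], stringsAsFactors = FALSE)
    if (!all(c("shot_id", "sample", "channel", "value") %in% names(long))) {
      stop("csv-long file needs columns shot_id, sample, channel, value")
    }
  }

  recs <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$shot_id[i]
    if (format == "csv-wide") {
      f <- file.path(path, paste0(sid, ".csv"))
      if (!file.exists(f)) stop("signal file missing for shot ", sid)
      sig <- utils::read.csv(f, check.names = FALSE)
      miss <- setdiff(CHANNEL_NAMES, names(sig))
      if (length(miss)) {
        stop("shot ", sid, ": missing channel ", paste(miss, collapse = ", "))
      }
      sig <- sig[, CHANNEL_NAMES]  # normalize any column order to the fixed map
      bad <- !vapply(sig, is.numeric, logical(1))
      if (any(bad)) {
        col <- CHANNEL_NAMES[bad][1]
        row <- which(is.na(suppressWarnings(as.numeric(sig[[col]]))))[1]
        stop("shot ", sid, ": non-numeric sample in channel ", col, " row ", row)
      }
      mat <- t(as.matrix(sig))
    } else {
      sub <- long[long$shot_id == sid, ]
      if (nrow(sub) == 0) stop("signal rows missing for shot ", sid)
      chans <- sort(unique(sub$channel))
      miss <- setdiff(seq_len(N_CHANNELS), chans)
      if (length(miss)) stop("shot ", sid, ": missing channel ", miss[1])
      if (!is.numeric(sub$value)) stop("shot ", sid, ": non-numeric samples")
      mat <- do.call(rbind, lapply(seq_len(N_CHANNELS), function(ch) {
        s <- sub[sub$channel == ch, ]
        s$value[order(s$sample)]
      }))
    }
    emg_recording(sid, meta$subject_id[i], meta$sex[i], mat, fs = meta$fs[i],
                  speed = meta$speed[i], distance = meta$distance[i])
  })
  shot_dataset(recs)
}
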