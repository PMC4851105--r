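#' Simulation configuration for synthetic golf-swing EMG
#'
#' Defines the generative model used by [simulate_shots()]. Each channel of a
#' simulated shot is baseline noise plus (optionally) low pre-swing activity
#' bumps plus two Gaussian-envelope amplitude-modulated noise bursts: the
#' first burst starts at the channel's activation onset (backswing), the
#' second sits near ball impact. The EMG carrier under the envelope is
#' zero-mean band-limited (20-400 Hz) Gaussian noise, so full-wave
#' rectification recovers the planted envelope and the band-pass
#' preprocessing does not distort the planted structure.
#'
#' Target attributes (club head speed in km/h, carry distance in m) follow a
#' linear model of sex, a subject skill trait that also scales how early the
#' non-reference muscles activate, swing duration, and the per-shot
#' inter-channel concurrency spread of the impact burst, plus Gaussian noise.
#'
#' @param n_men,n_women Number of male / female subjects.
#' @param shots_per_subject Shots per subject (>= 2).
#' @param fs Sampling rate, Hz.
#' @param swing_duration_range Two-vector, swing time drawn uniformly (s).
#' @param onset_offsets Baseline per-channel onset delays after swing start
#'   (s); channel 8 (left trapezius, the reference) activates last, and
#'   channels 5-7 form the sequential "avalanche" motif 5 -> 6 -> 7 -> 8.
#' @param onset_subject_sd Per-subject, per-channel deviation of the onset
#'   offsets (s); gives every subject a stable personal ordering.
#' @param onset_jitter_sd Per-shot onset jitter (s).
#' @param burst1_sigma_range,burst2_sigma_range Envelope Gaussian sigma
#'   ranges (s); the backswing burst is the broader one (larger area, so the
#'   widest smoothing scale peaks over it), the impact burst the sharper one.
#' @param burst1_amp_range,burst2_amp_range Envelope amplitude ranges.
#' @param impact_frac Position of the impact burst as a fraction of swing
#'   duration.
#' @param sync_spread_range Per-shot range of the SD (s) of channel lags
#'   around the impact burst; small spread = well-synchronized impact.
#' @param baseline_noise_sd Baseline noise envelope, relative to burst scale.
#' @param pre_swing_prob,pre_swing_amp Probability and relative amplitude of
#'   a low pre-swing activity bump per channel.
#' @param sex_base Named list, per-target mean for men and women.
#' @param subject_sd Named vector, SD of the residual subject random effect.
#' @param skill_coef Named vector, target shift per unit subject skill trait
#'   (the same trait scales onset earliness by `1 + 0.35 * skill`).
#' @param effect Named list of per-target coefficients `dur` (per s of swing
#'   duration below 1.85 s) and `sync` (per s of concurrency spread below
#'   0.018 s); set to zeros for a null simulation.
#' @param noise_sd_target Named vector, per-shot target noise SD.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_men = 10, n_women = 5, shots_per_subject = 5,
                       fs = 1000,
                       swing_duration_range = c(1.5, 2.2),
                       onset_offsets = c(0.15, 0.20, 0.38, 0.40,
                                         0.05, 0.10, 0.25, 0.45),
                       onset_subject_sd = 0.04,
                       onset_jitter_sd = 0.010,
                       burst1_sigma_range = c(0.030, 0.042),
                       burst2_sigma_range = c(0.022, 0.032),
                       burst1_amp_range = c(0.95, 1.20),
                       burst2_amp_range = c(0.80, 1.05),
                       impact_frac = 0.78,
                       sync_spread_range = c(0.005, 0.030),
                       baseline_noise_sd = 0.02,
                       pre_swing_prob = 0.3,
                       pre_swing_amp = 0.12,
                       sex_base = list(speed = c(woman = 116, man = 132),
                                       distance = c(woman = 124, man = 155)),
                       subject_sd = c(speed = 4, distance = 8),
                       skill_coef = c(speed = 6, distance = 10),
                       effect = list(speed = c(dur = 10, sync = 250),
                                     distance = c(dur = 15, sync = 350)),
                       noise_sd_target = c(speed = 1, distance = 2),
                       seed = 1L) {
  cfg <- list(
    n_men = n_men, n_women = n_women, shots_per_subject = shots_per_subject,
    fs = fs, swing_duration_range = swing_duration_range,
    onset_offsets = onset_offsets, onset_subject_sd = onset_subject_sd,
    onset_jitter_sd = onset_jitter_sd,
    burst1_sigma_range = burst1_sigma_range,
    burst2_sigma_range = burst2_sigma_range,
    burst1_amp_range = burst1_amp_range, burst2_amp_range = burst2_amp_range,
    impact_frac = impact_frac, sync_spread_range = sync_spread_range,
    baseline_noise_sd = baseline_noise_sd,
    pre_swing_prob = pre_swing_prob, pre_swing_amp = pre_swing_amp,
    sex_base = sex_base, subject_sd = subject_sd, skill_coef = skill_coef,
    effect = effect, noise_sd_target = noise_sd_target, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$shots_per_subject < 2) stop("shots_per_subject must be >= 2")
  if (cfg$n_men + cfg$n_women < 1) stop("need at least one subject")
  if (any(cfg$swing_duration_range <= 0) ||
      diff(cfg$swing_duration_range) < 0) {
    stop("swing_duration_range must be positive and ordered")
  }
  if (any(cfg$burst1_sigma_range <= 0) || any(cfg$burst2_sigma_range <= 0)) {
    stop("degenerate cfg: zero-width bursts")
  }
  if (cfg$onset_subject_sd < 0 || cfg$onset_jitter_sd < 0 ||
      cfg$baseline_noise_sd < 0 || any(cfg$noise_sd_target < 0)) {
    stop("all SDs must be >= 0")
  }
  if (length(cfg$onset_offsets) != N_CHANNELS) stop("onset_offsets must have 8 entries")
  invisible(cfg)
}

#' Study-scale default simulation configuration
#'
#' Fifteen subjects (10 men, 5 women), five shots each, 1000 Hz sampling,
#' swing durations uniform in 1.5-2.2 s -- the recording conditions the
#' package's validation suite emulates.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_study_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

# 20-400 Hz band-limited unit-variance Gaussian carrier.
#' @noRd
emg_carrier <- function(n, fs) {
  x <- stats::rnorm(n + 400)
  bf <- signal::butter(2, c(20, min(400, fs / 2 * 0.98)) / (fs / 2), type = "pass")
  y <- signal::filter(bf, x)[-seq_len(400)]
  y / stats::sd(y)
}

#' Simulate a shot dataset with ground truth
#'
#' Generates a [shot_dataset()] from a [sim_config()] together with a ground
#' truth list usable as an oracle by every downstream stage.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `dataset` (a `shot_dataset`) and `truth`: one
#'   entry per shot holding `onset` (8-vector, samples), `p1`, `p2` (true
#'   burst centers, samples), `window` (true swing window, samples),
#'   `duration` (swing time, s), `sync_spread` (s), `speed0`, `distance0`
#'   (noise-free targets), and per-subject `skill`.
#' @export
simulate_shots <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$fs
  n_subj <- cfg$n_men + cfg$n_women
  sexes <- c(rep(1L, cfg$n_men), rep(0L, cfg$n_women))
  subj_ids <- sprintf("G%02d", seq_len(n_subj))

  recs <- list()
  truth <- list()
  for (s in seq_len(n_subj)) {
    skill <- stats::rnorm(1)
    # positive skill = non-reference muscles fire earlier relative to ch 8
    lead <- cfg$onset_offsets[REFERENCE_CHANNEL] - cfg$onset_offsets
    lead <- lead * (1 + 0.35 * skill)
    subj_off <- cfg$onset_offsets[REFERENCE_CHANNEL] - lead +
      c(stats::rnorm(N_CHANNELS - 1, 0, cfg$onset_subject_sd), 0)
    subj_off <- pmax(subj_off, 0.01)
    subj_re <- c(
      speed = stats::rnorm(1, 0, cfg$subject_sd[["speed"]]) +
        cfg$skill_coef[["speed"]] * skill,
      distance = stats::rnorm(1, 0, cfg$subject_sd[["distance"]]) +
        cfg$skill_coef[["distance"]] * skill
    )
    for (k in seq_len(cfg$shots_per_subject)) {
      shot_id <- sprintf("%s_S%d", subj_ids[s], k)
      D <- stats::runif(1, cfg$swing_duration_range[1], cfg$swing_duration_range[2])
      pre_roll <- 1.0
      post_roll <- 0.5
      T <- as.integer(round((pre_roll + D + post_roll) * fs))
      t_swing <- pre_roll
      sync_spread <- stats::runif(1, cfg$sync_spread_range[1], cfg$sync_spread_range[2])
      lags <- stats::rnorm(N_CHANNELS, 0, sync_spread)
      onset_t <- t_swing + subj_off +
        stats::rnorm(N_CHANNELS, 0, cfg$onset_jitter_sd)
      sig1 <- stats::runif(N_CHANNELS, cfg$burst1_sigma_range[1], cfg$burst1_sigma_range[2])
      sig2 <- stats::runif(N_CHANNELS, cfg$burst2_sigma_range[1], cfg$burst2_sigma_range[2])
      a1 <- stats::runif(N_CHANNELS, cfg$burst1_amp_range[1], cfg$burst1_amp_range[2])
      a2 <- stats::runif(N_CHANNELS, cfg$burst2_amp_range[1], cfg$burst2_amp_range[2])
      # envelope start (5% of peak) of the first swing burst defines the onset
      c1 <- onset_t + sqrt(2 * log(20)) * sig1
      c2 <- t_swing + cfg$impact_frac * D + lags
      tt <- (seq_len(T) - 0.5) / fs
      sig <- matrix(0, N_CHANNELS, T)
      for (ch in seq_len(N_CHANNELS)) {
        env <- a1[ch] * exp(-(tt - c1[ch])^2 / (2 * sig1[ch]^2)) +
          a2[ch] * exp(-(tt - c2[ch])^2 / (2 * sig2[ch]^2)) +
          cfg$baseline_noise_sd
        if (stats::runif(1) < cfg$pre_swing_prob) {
          pc <- stats::runif(1, 0.2, 0.7) * t_swing
          pw <- stats::runif(1, 0.05, 0.12)
          env <- env + cfg$pre_swing_amp * exp(-(tt - pc)^2 / (2 * pw^2))
        }
        sig[ch, ] <- env * emg_carrier(T, fs)
      }
      eff <- cfg$effect
      speed0 <- cfg$sex_base$speed[[if (sexes[s] == 1) "man" else "woman"]] +
        subj_re[["speed"]] +
        eff$speed[["dur"]] * (1.85 - D) + eff$speed[["sync"]] * (0.018 - sync_spread)
      distance0 <- cfg$sex_base$distance[[if (sexes[s] == 1) "man" else "woman"]] +
        subj_re[["distance"]] +
        eff$distance[["dur"]] * (1.85 - D) + eff$distance[["sync"]] * (0.018 - sync_spread)
      speed <- speed0 + stats::rnorm(1, 0, cfg$noise_sd_target[["speed"]])
      distance <- distance0 + stats::rnorm(1, 0, cfg$noise_sd_target[["distance"]])
      recs[[shot_id]] <- emg_recording(
        shot_id, subj_ids[s], sexes[s], sig, fs = fs,
        speed = speed, distance = distance
      )
      truth[[shot_id]] <- list(
        onset = round(onset_t * fs), p1 = round(c1 * fs), p2 = round(c2 * fs),
        window = c(round(min(onset_t) * fs),
                   round(max(c2 + sqrt(2 * log(20)) * sig2) * fs)),
        duration = D, sync_spread = sync_spread, skill = skill,
        speed0 = speed0, distance0 = distance0
      )
    }
  }
  list(dataset = shot_dataset(recs), truth = truth)
}
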