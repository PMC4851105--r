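# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small synthetic study: 4 men + 2 women, 3 shots each (18 shots)
small_sim <- function() {
  memo("small_sim", simulate_shots(
    default_study_config(seed = 402, n_men = 4, n_women = 2,
                         shots_per_subject = 3)))
}

small_segments <- function() {
  memo("small_segments",
       lapply(small_sim()$dataset$recordings, extract_segment))
}

small_tables <- function() {
  memo("small_tables",
       build_feature_tables(small_sim()$dataset, small_segments()))
}

# hand-built segment object for feature-builder unit tests: deterministic
# peaks and filtered signals with known structure
toy_segment <- function(rel1 = NULL, rel2 = NULL, filtered = NULL) {
  fs <- 1000
  if (is.null(filtered)) {
    set.seed(11)
    tt <- seq(0, 2.999, by = 1 / fs)
    filtered <- t(sapply(1:8, function(ch) {
      sin(2 * pi * (2 + ch / 4) * tt) + 0.1 * rnorm(length(tt))
    }))
  }
  if (is.null(rel1)) rel1 <- seq(0.10, 0.24, length.out = 8)
  if (is.null(rel2)) rel2 <- seq(0.70, 0.84, length.out = 8)
  peaks <- do.call(rbind, lapply(1:8, function(ch) {
    data.frame(
      position = c(0.5 + rel1[ch], 0.5 + rel2[ch]),
      height = c(0.9, 0.8) + ch / 100,
      width = c(0.10, 0.08),
      area = (c(0.9, 0.8) + ch / 100) * c(0.10, 0.08) * 1.0646,
      fit_error = c(3, 4),
      channel = ch,
      rank = c("P1", "P2"),
      rel_position = c(rel1[ch], rel2[ch])
    )
  }))
  structure(
    list(t1 = 0.5, t2 = 1.5, duration = 1.0, peaks = peaks,
         excluded_p1 = integer(0), excluded_p2 = integer(0),
         degenerate = integer(0), iterations = 1L,
         filtered = filtered, fs = fs),
    class = "swing_segment"
  )
}

# feature table with one planted informative feature, subject-grouped:
# 15 subjects (10 men, 5 women) x 5 shots, target driven by the feature
planted_table <- function(seed = 1, strength = 2, n_noise = 5) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", 1:15), each = 5)
  sex <- rep(c(rep(1L, 10), rep(0L, 5)), each = 5)
  n <- length(subj)
  signal <- rnorm(n)
  speed <- 100 + 10 * sex + strength * signal + rnorm(n)
  tab <- data.frame(shot_id = sprintf("T%03d", seq_len(n)), subject_id = subj,
                    sex = sex, signal = signal, stringsAsFactors = FALSE)
  for (k in seq_len(n_noise)) tab[[paste0("noise", k)]] <- rnorm(n)
  tab$speed <- speed
  tab$distance <- speed + rnorm(n)
  tab
}

# synthetic meta table: `informative` columns track the personal
# effectiveness signal, the rest are noise
synthetic_meta <- function(seed = 1, n_meta = 22, informative = 1:2,
                           strength = 0.8, n_subj = 15, shots = 5) {
  n_men <- round(2 * n_subj / 3)
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = shots)
  sex <- rep(c(rep(1L, n_men), rep(0L, n_subj - n_men)), each = shots)
  set.seed(seed)
  n <- length(subj)
  speed <- 100 + 10 * sex + rnorm(n, 0, 3)
  mu <- ave(speed, subj)
  lab_signal <- sign(speed - mu)
  meta <- data.frame(shot_id = sprintf("T%03d", seq_len(n)),
                     subject_id = subj, sex = sex, stringsAsFactors = FALSE)
  for (j in seq_len(n_meta)) {
    nm <- sprintf("set%02d", j)
    meta[[nm]] <- if (j %in% informative) {
      pmin(1, pmax(-1, strength * lab_signal + rnorm(n, 0, 0.4)))
    } else {
      runif(n, -1, 1)
    }
  }
  meta$speed <- speed
  meta$distance <- speed + rnorm(n)
  meta
}
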