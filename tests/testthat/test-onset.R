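test_that("gaussian bank kernels are unit-area and widths increase", {
  bank <- gaussian_bank()
  expect_equal(bank$widths, c(256, 512, 1024, 2048))
  for (k in bank$kernels) expect_equal(sum(k), 1)
  expect_error(gaussian_bank(c(512, 256, 1024, 2048)), "increasing")
})

test_that("multiscale filtering reproduces convolution identities", {
  bank <- gaussian_bank()
  n <- 2500
  v <- multiscale_filter(rep(4, n), bank)
  for (s in v) expect_equal(s, rep(4, n), tolerance = 1e-9)

  imp <- numeric(n); imp[1200] <- 1
  v <- multiscale_filter(imp, bank)
  for (k in seq_along(v)) {
    expect_equal(max(v[[k]]), max(bank$kernels[[k]]), tolerance = 1e-9)
    expect_equal(which.max(v[[k]]), 1200, tolerance = 1.01)
  }

  stp <- c(numeric(1200), rep(1, n - 1200))  # step turns on at index 1201
  v <- multiscale_filter(stp, bank)
  for (s in v) {
    cross <- which(s >= 0.5)[1]
    expect_lte(abs(cross - 1201), 1)
  }
  expect_error(multiscale_filter(rnorm(100), bank), "too short")
})

test_that("channel threshold is alpha times the window mean", {
  n <- 4000
  expect_equal(channel_threshold(rep(2, n), rep(1, n)), 1.2 * 2)

  set.seed(4)
  rectified <- abs(rnorm(n)) + dnorm(seq_len(n), 2200, 300) * 800
  v4 <- multiscale_filter(rectified, gaussian_bank())$v4
  t_star <- which.max(v4)
  manual <- mean(rectified[max(1, t_star - 500):min(n, t_star + 1000)])
  expect_equal(channel_threshold(rectified, v4), 1.2 * manual)
  expect_equal(channel_threshold(rectified, v4, alpha = 1), manual)

  # clipped window near the record start
  v4b <- v4; v4b[1] <- max(v4) * 2
  manual_clip <- mean(rectified[1:1001])
  expect_equal(channel_threshold(rectified, v4b), 1.2 * manual_clip)
})

test_that("onset detection recovers planted envelope starts", {
  sim <- memo("noiseless_small", simulate_shots(
    default_study_config(seed = 61, n_men = 2, n_women = 2,
                         shots_per_subject = 2, baseline_noise_sd = 0,
                         pre_swing_prob = 0)))
  errs <- c()
  for (id in names(sim$truth)) {
    ap <- activation_profile(sim$dataset$recordings[[id]])
    errs <- c(errs, ap$onset$ts - sim$truth[[id]]$onset)
  }
  expect_gte(mean(abs(errs) <= 64), 0.9)
})

test_that("onset detection is shift-equivariant and amplitude-invariant", {
  sim <- small_sim()
  rec <- sim$dataset$recordings[[3]]
  x <- abs(rec$signal[2, ])
  v <- multiscale_filter(x)
  thr <- channel_threshold(x, v$v4)
  ts0 <- detect_onset(v, thr)

  k <- 500
  xs <- c(rep(mean(x[1:100]), k), x)
  vs <- multiscale_filter(xs)
  thrs <- channel_threshold(xs, vs$v4)
  expect_lte(abs(detect_onset(vs, thrs) - (ts0 + k)), 2)

  vc <- lapply(v, function(s) 3 * s)
  expect_equal(channel_threshold(3 * x, 3 * v$v4), 3 * thr)
  expect_equal(detect_onset(vc, 3 * thr), ts0)

  expect_error(detect_onset(lapply(v, function(s) s * 0), thr), "no activation")
})

test_that("activation profiles recover planted offsets relative to channel 8", {
  sim <- memo("noiseless_small", simulate_shots(
    default_study_config(seed = 61, n_men = 2, n_women = 2,
                         shots_per_subject = 2, baseline_noise_sd = 0,
                         pre_swing_prob = 0)))
  for (id in names(sim$truth)[1:4]) {
    ap <- activation_profile(sim$dataset$recordings[[id]])
    x_true <- sim$truth[[id]]$onset[8] - sim$truth[[id]]$onset[1:7]
    expect_true(all(abs(ap$profile$x - x_true) <= 64 + 64))
  }
})

test_that("identical channels give a flat profile", {
  set.seed(8)
  base <- abs(rnorm(3000)) * (1 + 1500 * dnorm(seq_len(3000), 1800, 120))
  sig <- t(matrix(base, 3000, 8))
  rec <- emg_recording("s", "g", 1, sig)
  ap <- activation_profile(rec)
  expect_equal(unname(ap$profile$x), rep(0, 7))
  expect_equal(ap$onset$lambda, 0)
  expect_false(ap$onset$flagged)
  expect_true(activation_profile(rec, lambda_min = 5)$onset$flagged)
})

test_that("repeat shots of one subject give stable profiles", {
  sim <- simulate_shots(sim_config(n_men = 1, n_women = 1,
                                   shots_per_subject = 3, onset_jitter_sd = 0,
                                   baseline_noise_sd = 0, pre_swing_prob = 0,
                                   seed = 17))
  meta <- dataset_meta(sim$dataset)
  for (s in unique(meta$subject_id)) {
    ids <- meta$shot_id[meta$subject_id == s]
    xs <- sapply(ids, function(id) {
      activation_profile(sim$dataset$recordings[[id]])$profile$x
    })
    expect_lte(max(apply(xs, 1, sd)), 32)
  }
})

test_that("profile map orders subjects and flags lambda outliers", {
  sim <- small_sim()
  profs <- memo("small_profiles",
                lapply(sim$dataset$recordings, activation_profile))
  pm <- profile_map(profs)
  expect_equal(nrow(pm), length(sim$dataset))
  expect_equal(pm$subject_id, sort(pm$subject_id))
  expect_named(pm, c("shot_id", "subject_id", paste0("x", 1:7), "lambda",
                     "flagged"))
  pm1 <- profile_map(profs[1])
  expect_equal(nrow(pm1), 1L)
})
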