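test_that("the 12-statistic vector matches direct formulas", {
  s <- stat_vector(c(1, 2, 3, 4, 5))
  expect_equal(unname(s[c("min", "max", "mean", "median", "q_lo", "q_up",
                          "iqr", "skewness")]),
               c(1, 5, 3, 3, 2, 4, 2, 0))

  s0 <- stat_vector(c(7, 7, 7, 7))
  expect_equal(unname(s0[c("sd", "iqr", "skewness", "kurtosis")]), c(0, 0, 0, 0))

  set.seed(20)
  x <- rnorm(101)
  s <- stat_vector(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(x)
  sig <- sqrt(mean((x - m)^2))
  oracle <- c(min(x), max(x), m, q[2], q[1], q[3], sd(x), q[3] - q[1],
              q[2] - q[1], q[3] - q[2], mean((x - m)^3) / sig^3,
              mean((x - m)^4) / sig^4)
  expect_equal(unname(s), oracle, tolerance = 1e-10)
  expect_true(s[["min"]] <= s[["q_lo"]] && s[["q_lo"]] <= s[["median"]] &&
                s[["median"]] <= s[["q_up"]] && s[["q_up"]] <= s[["max"]])
  expect_error(stat_vector(1:3), "at least 4")
})

test_that("side-channel statistics scale as expected", {
  seg <- toy_segment()
  right <- chan_stats(seg, "right")
  expect_length(right, 49)
  expect_true(all(is.finite(right)))
  expect_equal(right[["duration"]], seg$duration)
  expect_identical(chan_stats(seg, "right"), chan_stats(seg, "right"))

  seg2 <- seg
  seg2$filtered[1, ] <- 2 * seg2$filtered[1, ]
  right2 <- chan_stats(seg2, "right")
  expect_equal(right2[["ch1_mean"]], 2 * right[["ch1_mean"]])
  expect_equal(right2[["ch1_sd"]], 2 * right[["ch1_sd"]])
  expect_equal(right2[["ch1_skewness"]], right[["ch1_skewness"]])
  expect_equal(right2[["ch1_kurtosis"]], right[["ch1_kurtosis"]])
  expect_equal(right2[["ch2_mean"]], right[["ch2_mean"]])
  left <- chan_stats(seg2, "left")
  expect_equal(left[-1], chan_stats(seg, "left")[-1])
})

test_that("correlation contrasts match a direct two-channel oracle", {
  seg <- toy_segment()
  cd <- corr_features(seg, "delta")
  cr <- corr_features(seg, "ratio")
  expect_length(cd, 28)
  expect_length(corr_features(seg, "delta", with_stats = TRUE), 40)
  expect_true(all(abs(cd) <= 2))

  fs <- seg$fs
  idx <- (floor(seg$t1 * fs) + 1):ceiling(seg$t2 * fs)
  x1 <- seg$filtered[1, idx]
  x2 <- seg$filtered[2, idx]
  expect_equal(cd[["cd1_2"]],
               cor(x1, x2) - cor(x1, x2, method = "spearman"),
               tolerance = 1e-10)
  expect_equal(cr[["cr1_2"]],
               cor(x1, x2) / cor(x1, x2, method = "spearman"),
               tolerance = 1e-10)

  # perfectly co-monotone linear channels: delta 0, ratio 1
  seg2 <- seg
  seg2$filtered[2, ] <- 3 * seg2$filtered[1, ] + 1
  cd2 <- corr_features(seg2, "delta")
  cr2 <- corr_features(seg2, "ratio")
  expect_equal(cd2[["cd1_2"]], 0)
  expect_equal(cr2[["cr1_2"]], 1)

  seg3 <- seg
  seg3$filtered[4, ] <- 0
  expect_error(corr_features(seg3, "delta"), "zero-variance")
})

test_that("peak property features honor the delta/ratio contracts", {
  seg <- toy_segment()
  p1 <- peak_property_features(seg, "P1")
  p2 <- peak_property_features(seg, "P2")
  dl <- peak_property_features(seg, "delta")
  rt <- peak_property_features(seg, "ratio")
  expect_length(p1, 40)
  expect_equal(unname(dl), unname(p1 - p2), tolerance = 1e-12)
  expect_equal(unname(rt), unname(p1 / p2), tolerance = 1e-12)

  # identical P1 and P2 descriptors: delta 0, ratio 1
  segi <- toy_segment(rel1 = rep(0.3, 8), rel2 = rep(0.3, 8))
  segi$peaks$height <- 0.9
  segi$peaks$width <- 0.1
  segi$peaks$area <- 0.9 * 0.1 * 1.0646
  segi$peaks$fit_error <- 2
  expect_equal(unname(peak_property_features(segi, "delta")), rep(0, 40))
  expect_equal(unname(peak_property_features(segi, "ratio")), rep(1, 40))
})

test_that("concurrency features are antisymmetric in the channel pair", {
  rel1 <- seq(0.10, 0.24, length.out = 8)
  seg <- toy_segment(rel1 = rel1)
  sy <- sync_features(seg, "P1")
  sa <- sync_features(seg, "P1", absolute = TRUE)
  expect_length(sy, 40)
  expect_equal(sy[["sy1_2"]], rel1[1] - rel1[2])
  expect_equal(sa[["sy1_2"]], abs(rel1[1] - rel1[2]))

  # swapping two channels' peaks negates the signed value
  rel1b <- rel1
  rel1b[c(1, 2)] <- rel1[c(2, 1)]
  syb <- sync_features(toy_segment(rel1 = rel1b), "P1")
  expect_equal(syb[["sy1_2"]], -sy[["sy1_2"]])
  sab <- sync_features(toy_segment(rel1 = rel1b), "P1", absolute = TRUE)
  expect_equal(sab[["sy1_2"]], sa[["sy1_2"]])

  # perfectly synchronized channels: all 28 values and their stats collapse
  seg0 <- toy_segment(rel1 = rep(0.2, 8))
  expect_equal(unname(sync_features(seg0, "P1")), rep(0, 40))
})

test_that("combined concurrency features satisfy algebraic identities", {
  seg <- toy_segment()
  d1 <- sync_features(seg, "P1")[1:28]
  d2 <- sync_features(seg, "P2")[1:28]
  dl <- sync_combo_features(seg, "delta")
  sm <- sync_combo_features(seg, "sum")
  pr <- sync_combo_features(seg, "prod")
  dv <- sync_combo_features(seg, "div")
  expect_length(dl, 40)
  expect_equal(unname(sm[1:28]), unname(dl[1:28] + 2 * d2), tolerance = 1e-12)
  expect_equal(unname(pr[1:28]), unname(d1 * d2), tolerance = 1e-12)

  # equal P1 and P2 concurrency: delta 0, div 1
  sege <- toy_segment(rel1 = seq(0.1, 0.31, length.out = 8),
                      rel2 = seq(0.1, 0.31, length.out = 8) + 0.4)
  expect_equal(unname(sync_combo_features(sege, "delta")[1:28]), rep(0, 28))
  expect_equal(unname(sync_combo_features(sege, "div")[1:28]), rep(1, 28))

  # division guard: zero denominator maps to 0
  seg0 <- toy_segment(rel2 = rep(0.7, 8))
  expect_equal(unname(sync_combo_features(seg0, "div")[1:28]), rep(0, 28))
})

test_that("all 22 feature tables conform to the registry sizes", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 22L)
  expect_equal(reg$size, c(49L, 49L, 28L, 28L, rep(40L, 18)))
  expect_false(anyDuplicated(reg$name) > 0)

  tabs <- small_tables()
  expect_length(tabs, 22L)
  expect_equal(names(tabs), reg$name)
  meta <- dataset_meta(small_sim()$dataset)
  for (r in seq_len(nrow(reg))) {
    tab <- tabs[[reg$name[r]]]
    cols <- feature_columns(tab)
    expect_equal(length(cols), reg$size[r] + 1L)  # sex always first
    expect_equal(cols[1], "sex")
    expect_equal(tab$sex, meta$sex[match(tab$shot_id, meta$shot_id)])
    expect_true(all(is.finite(as.matrix(tab[, cols]))))
  }
  # deterministic on fixed input
  tabs2 <- build_feature_tables(small_sim()$dataset, small_segments(),
                                sets = c(3, 9))
  expect_identical(tabs2$CorrDelta, tabs$CorrDelta)
  expect_identical(tabs2$PeakP1AbsSync, tabs$PeakP1AbsSync)
  # relative positions bounded
  expect_true(all(tabs$PeakP1[, grepl("rel_position", names(tabs$PeakP1))] >= 0))
  expect_true(all(tabs$PeakP1[, grepl("rel_position", names(tabs$PeakP1))] <= 1))
})
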