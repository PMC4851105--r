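test_that("grouped bootstrap keeps subjects whole and stratifies by sex", {
  subjects <- sprintf("S%02d", 1:15)
  sex <- stats::setNames(c(rep(1, 10), rep(0, 5)), subjects)
  set.seed(30)
  for (i in 1:50) {
    g <- group_bootstrap(subjects, sex, stratify = TRUE)
    expect_length(g$draws, 15)
    expect_equal(sum(sex[g$draws] == 1), 10)
    expect_equal(sum(sex[g$draws] == 0), 5)
    expect_length(intersect(unique(g$draws), g$oob), 0)
  }

  # unique-subject fraction approaches 1 - (1 - 1/n)^n
  set.seed(31)
  fr <- replicate(600, length(unique(group_bootstrap(subjects)$draws)) / 15)
  expect_lt(abs(mean(fr) - (1 - (1 - 1 / 15)^15)), 0.03)

  expect_error(group_bootstrap(subjects[1:10], sex, stratify = TRUE),
               "both sexes")
})

test_that("every tree keeps in-bag and out-of-bag subjects disjoint", {
  tab <- planted_table(seed = 41)
  fr <- fit_forest(tab, forest_config(B = 120, task = "detect", seed = 2))
  for (b in seq_len(120)) {
    inbag_subjects <- unique(tab$subject_id[fr$rf$inbag.counts[[b]] > 0])
    expect_length(intersect(inbag_subjects, fr$oob_subj[[b]]), 0)
    # shots of one subject are all-in or all-out
    cnt <- tapply(fr$rf$inbag.counts[[b]], tab$subject_id,
                  function(v) length(unique(v)))
    expect_true(all(cnt == 1))
  }
})

test_that("OOB detection scores reproduce the leaf-frequency contract", {
  # single root-leaf tree: constant feature blocks all splits, so the leaf
  # holds the in-bag class counts (3 ineffective, 1 effective)
  # bags drawing only subject a (shots with labels 0,0,0,1) produce the leaf
  # frequencies (3/4, 1/4) whatever the draw multiplicity
  tab <- data.frame(
    shot_id = paste0("s", 1:5),
    subject_id = c("a", "a", "a", "a", "c"),
    sex = c(1L, 1L, 1L, 1L, 1L),
    const = rep(1, 5),
    speed = rep(1, 5), distance = rep(1, 5),
    stringsAsFactors = FALSE
  )
  cfg <- forest_config(B = 12, task = "detect", stratify_sex = FALSE, seed = 1)
  fr <- fit_forest(tab, cfg, labels = c(0L, 0L, 0L, 1L, 1L))
  c_oob <- vapply(fr$oob_subj, function(s) "c" %in% s, logical(1))
  expect_gte(sum(c_oob), 1)
  sc <- oob_scores(fr)
  expect_equal(sc$score[5], 1 / 4 - 3 / 4)
  expect_equal(sc$oob_count[5], sum(c_oob))
})

test_that("OOB regression scores equal the mean of OOB tree outputs", {
  tab <- planted_table(seed = 43)
  fr <- fit_forest(tab, forest_config(B = 60, task = "regress", seed = 3),
                   target = "speed")
  pr <- predict(fr$rf, fr$frame, predict.all = TRUE, num.threads = 1)$predictions
  sc <- oob_scores(fr)
  i <- 7
  oob_trees <- which(vapply(fr$oob_subj, function(s) tab$subject_id[i] %in% s,
                            logical(1)))
  expect_equal(sc$score[i], mean(pr[i, oob_trees]))
  expect_equal(sc$oob_count[i], length(oob_trees))

  # constant-target dataset: OOB prediction is exactly that constant
  tabc <- tab
  tabc$speed <- 77
  frc <- fit_forest(tabc, forest_config(B = 40, task = "regress", seed = 4),
                    target = "speed")
  expect_equal(oob_scores(frc)$score, rep(77, nrow(tabc)))
})

test_that("forests are deterministic and score within [-1, 1]", {
  tab <- planted_table(seed = 44)
  cfg <- forest_config(B = 80, task = "detect", seed = 9)
  s1 <- oob_scores(fit_forest(tab, cfg, target = "speed"))
  s2 <- oob_scores(fit_forest(tab, cfg, target = "speed"))
  expect_identical(s1, s2)
  expect_true(all(s1$score >= -1 & s1$score <= 1))
  expect_true(all(s1$oob_count >= 1))

  # OOB count concentrates near B (1 - 1/n)^n
  expect_lt(abs(mean(s1$oob_count) - 80 * (1 - 1 / 15)^15), 8)
})

test_that("planted signal is detected and pure noise is not", {
  tab <- planted_table(seed = 45, strength = 4)
  cfg <- forest_config(B = 250, task = "detect", seed = 5)
  sc <- oob_scores(fit_forest(tab, cfg, target = "speed"))
  expect_gt(roc_auc(sc$score, sc$label)$auc, 0.75)

  tabn <- planted_table(seed = 46, strength = 0)
  scn <- oob_scores(fit_forest(tabn, forest_config(B = 250, task = "detect",
                                                   seed = 6), target = "speed"))
  expect_lt(abs(roc_auc(scn$score, scn$label)$auc - 0.5), 0.12)
})

test_that("permutation importance ranks the informative feature first", {
  tab <- planted_table(seed = 47, strength = 4)
  tab$flat <- 1  # constant feature: importance must be exactly zero
  fr <- fit_forest(tab, forest_config(B = 200, task = "detect", seed = 7),
                   target = "speed")
  imp <- permutation_importance(fr, n_repeats = 3, seed = 8)
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  noise_imp <- imp$importance[grepl("noise", imp$feature)]
  expect_true(all(abs(noise_imp) < imp$importance[1] / 2))
})

test_that("q grid search honors the argmin contract", {
  tab <- planted_table(seed = 48, strength = 3)
  cfg <- forest_config(B = 100, task = "regress", seed = 10)
  single <- q_grid_search(tab, cfg, grid = 3, target = "speed")
  expect_equal(single$q, 3)

  gs <- q_grid_search(tab, cfg, target = "speed")
  expect_true(all(gs$criterion <= gs$grid$criterion))
  expect_true(all(is.finite(gs$grid$criterion)))
  p <- length(feature_columns(tab))
  expect_equal(gs$grid$q,
               unique(pmin(p, c(ceiling(sqrt(p)), ceiling(2 * sqrt(p)),
                                ceiling(p / 3)))))
})

test_that("detection separability improves with planted effect size", {
  eers <- vapply(c(0, 2, 6), function(strength) {
    mean(vapply(1:3, function(s) {
      tab <- planted_table(seed = 100 + s, strength = strength)
      cfg <- forest_config(B = 120, task = "detect", seed = s)
      sc <- oob_scores(fit_forest(tab, cfg, target = "speed"))
      det_eer(sc$score, sc$label)$eer
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(eers) < 0))
})
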