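#' Random-forest configuration
#'
#' @param B Number of trees. 500 is the desk-scale default; set 5000 to
#'   reproduce full-scale runs.
#' @param q Features tried at each node (`NULL` = floor of sqrt(p), the
#'   usual classification default).
#' @param task `"detect"` (binary classification) or `"regress"`.
#' @param min_leaf Minimum terminal-node size (1 = unpruned trees).
#' @param stratify_sex Draw bootstrap subjects within sex strata so every
#'   bag preserves the sex ratio (used for the detection task).
#' @param seed Integer seed.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(B = 500, q = NULL, task = c("detect", "regress"),
                          min_leaf = 1, stratify_sex = NULL, seed = 1L) {
  task <- match.arg(task)
  if (B < 1) stop("B must be >= 1")
  if (is.null(stratify_sex)) stratify_sex <- (task == "detect")
  structure(list(B = as.integer(B), q = q, task = task,
                 min_leaf = as.integer(min_leaf),
                 stratify_sex = stratify_sex, seed = as.integer(seed)),
            class = "forest_config")
}

#' Subject-grouped bootstrap draw
#'
#' Samples subjects with replacement (as many draws as there are subjects),
#' optionally within sex strata so each bag preserves the sex ratio of the
#' dataset. All shots of a drawn subject enter the bag together (a subject
#' drawn k times contributes its shots k times); subjects never drawn are
#' out-of-bag. This turns per-tree validation into leave-subjects-out
#' validation, respecting the repeated-measures structure of multiple
#' swings per player.
#'
#' @param subjects Character vector of unique subject ids.
#' @param sex Named 0/1 vector giving each subject's sex (required when
#'   stratifying).
#' @param stratify Stratify the draw within sex.
#' @return List with `draws` (drawn subject ids, with multiplicity) and
#'   `oob` (subjects never drawn).
#' @export
group_bootstrap <- function(subjects, sex = NULL, stratify = FALSE) {
  if (stratify) {
    if (is.null(sex)) stop("sex needed for stratified sampling")
    sx <- sex[subjects]
    if (!all(c(0, 1) %in% sx)) stop("stratified sampling needs both sexes present")
    draws <- c(sample(subjects[sx == 1], sum(sx == 1), replace = TRUE),
               sample(subjects[sx == 0], sum(sx == 0), replace = TRUE))
  } else {
    draws <- sample(subjects, length(subjects), replace = TRUE)
  }
  list(draws = draws, oob = setdiff(subjects, draws))
}

#' Fit a random forest with subject-grouped bootstrap sampling
#'
#' Grows `B` unpruned CART-style trees (Gini splitting for detection,
#' variance reduction for regression, `q` random candidate features per
#' node) on subject-grouped bootstrap bags: the in-bag multiset of each
#' tree is generated by [group_bootstrap()], so a subject's shots are
#' jointly in-bag or out-of-bag. Detection trees are probability trees
#' whose leaves store training class frequencies.
#'
#' @param table Feature table (see [build_feature_tables()]); needs
#'   shot_id, subject_id, sex columns.
#' @param cfg A [forest_config()].
#' @param target `"speed"` or `"distance"`; for detection the personal
#'   effectiveness label of this target, for regression its value.
#' @param labels Optional explicit 0/1 labels (detection) overriding the
#'   personal-average rule (used for permutation checks).
#' @return An object of class `grouped_forest` wrapping the ranger forest,
#'   the per-tree OOB subject sets and the training frame.
#' @export
fit_forest <- function(table, cfg, target = "speed", labels = NULL) {
  stopifnot(inherits(cfg, "forest_config"))
  feats <- feature_columns(table)
  subjects <- unique(table$subject_id)
  subj_sex <- vapply(split(table$sex, table$subject_id), `[`, numeric(1), 1)
  if (cfg$task == "detect") {
    if (is.null(labels)) {
      v <- table[[target]]
      mu <- stats::ave(v, table$subject_id, FUN = mean)
      labels <- as.integer(v > mu)
    }
    if (length(unique(labels)) < 2) stop("detection needs both classes present")
    y <- factor(labels, levels = c(0, 1))
  } else {
    y <- table[[target]]
    if (anyNA(y)) stop("missing target values")
  }
  set.seed(cfg$seed)
  oob_subj <- vector("list", cfg$B)
  inbag <- vector("list", cfg$B)
  for (b in seq_len(cfg$B)) {
    g <- group_bootstrap(subjects, sex = subj_sex, stratify = cfg$stratify_sex)
    cnt <- tabulate(match(g$draws, subjects), nbins = length(subjects))
    inbag[[b]] <- cnt[match(table$subject_id, subjects)]
    oob_subj[[b]] <- g$oob
  }
  q <- cfg$q %||% max(1, floor(sqrt(length(feats))))
  q <- min(q, length(feats))
  df <- table[, feats, drop = FALSE]
  df$..y.. <- y
  rf <- ranger::ranger(
    dependent.variable.name = "..y..", data = df,
    num.trees = cfg$B, mtry = q, min.node.size = cfg$min_leaf,
    probability = cfg$task == "detect",
    inbag = inbag, keep.inbag = TRUE,
    num.threads = 1, seed = derive_seed(cfg$seed, 1),
    respect.unordered.factors = FALSE
  )
  structure(
    list(rf = rf, cfg = cfg, q = q, features = feats, target = target,
         y = y, shot_id = table$shot_id, subject_id = table$subject_id,
         sex = table$sex, oob_subj = oob_subj, frame = df),
    class = "grouped_forest"
  )
}

#' @noRd
oob_tree_mask <- function(forest) {
  # n x B logical: tree b treats shot i as out-of-bag
  vapply(forest$oob_subj, function(s) forest$subject_id %in% s,
         logical(length(forest$subject_id)))
}

#' Out-of-bag scores of a grouped forest
#'
#' For each shot, aggregates the predictions of the trees for which that
#' shot's subject is out-of-bag. Detection: the mean difference between the
#' leaf frequency of the effective class and the ineffective class (a score
#' in `[-1, 1]`). Regression: the mean of the OOB trees' predictions.
#'
#' @param forest A [fit_forest()] result.
#' @param newdata Optional replacement frame with the forest's feature
#'   columns (used by permutation importance); defaults to the training
#'   frame.
#' @return An object of class `score_set`: data.frame with shot_id,
#'   subject_id, sex, score, oob_count, and label (detect) or target
#'   (regress) columns.
#' @export
oob_scores <- function(forest, newdata = NULL) {
  stopifnot(inherits(forest, "grouped_forest"))
  df <- newdata %||% forest$frame
  pr <- stats::predict(forest$rf, data = df, predict.all = TRUE,
                       num.threads = 1)$predictions
  mask <- oob_tree_mask(forest)
  n <- length(forest$shot_id)
  L <- rowSums(mask)
  if (any(L < 1)) {
    stop("shot(s) never out-of-bag: ",
         paste(forest$shot_id[L < 1], collapse = ", "),
         "; grow a larger forest (B)")
  }
  if (forest$cfg$task == "detect") {
    # pr: n x 2 x B leaf class frequencies; score = f(effective) - f(ineffective)
    d <- pr[, "1", ] - pr[, "0", ]
    score <- rowSums(d * mask) / L
    out <- data.frame(shot_id = forest$shot_id, subject_id = forest$subject_id,
                      sex = forest$sex, score = score, oob_count = L,
                      label = as.integer(as.character(forest$y)),
                      stringsAsFactors = FALSE)
  } else {
    score <- rowSums(pr * mask) / L
    out <- data.frame(shot_id = forest$shot_id, subject_id = forest$subject_id,
                      sex = forest$sex, score = score, oob_count = L,
                      target = forest$y, stringsAsFactors = FALSE)
  }
  class(out) <- c("score_set", "data.frame")
  out
}

#' @noRd
score_criterion <- function(scores, task) {
  if (task == "detect") cllr(scores$score, scores$label)
  else sqrt(mean((scores$score - scores$target)^2))
}

#' Permutation importance on out-of-bag data
#'
#' Permutes each feature in turn (over all shots, `n_repeats` times) and
#' measures the mean decrease in OOB performance: decrease in OOB accuracy
#' of the thresholded score for detection, increase in OOB RMSE for
#' regression (reported as a positive importance when performance drops).
#'
#' @param forest A [fit_forest()] result.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @return `data.frame` with feature and importance, sorted decreasing.
#' @export
permutation_importance <- function(forest, n_repeats = 5, seed = 1L) {
  stopifnot(inherits(forest, "grouped_forest"))
  base <- oob_scores(forest)
  detect <- forest$cfg$task == "detect"
  perf <- function(sc) {
    if (detect) mean((sc$score > 0) == (sc$label == 1))
    else -sqrt(mean((sc$score - sc$target)^2))
  }
  p0 <- perf(base)
  set.seed(seed)
  imp <- vapply(forest$features, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      df <- forest$frame
      if (length(unique(df[[f]])) > 1) df[[f]] <- sample(df[[f]])
      p0 - perf(oob_scores(forest, newdata = df))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = forest$features, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Grid search over the node subspace size q
#'
#' Fits one forest per candidate q (same seed) and retains the q minimizing
#' the OOB criterion: Cllr for detection, RMSE for regression.
#'
#' @param table Feature table.
#' @param cfg A [forest_config()] (its q is ignored).
#' @param grid Candidate q values; default `{ceil(sqrt(p)), ceil(2 sqrt(p)),
#'   ceil(p/3)}` for p features.
#' @param target Target attribute.
#' @return List with `q`, `criterion`, `scores` (best model's score set) and
#'   the full `grid` results.
#' @export
q_grid_search <- function(table, cfg, grid = NULL, target = "speed") {
  p <- length(feature_columns(table))
  if (is.null(grid)) {
    grid <- unique(pmin(p, c(ceiling(sqrt(p)), ceiling(2 * sqrt(p)), ceiling(p / 3))))
  }
  if (length(grid) == 0) stop("empty q grid")
  res <- lapply(grid, function(qq) {
    c2 <- cfg
    c2$q <- qq
    sc <- oob_scores(fit_forest(table, c2, target = target))
    list(q = qq, criterion = score_criterion(sc, cfg$task), scores = sc)
  })
  crit <- vapply(res, `[[`, numeric(1), "criterion")
  best <- which.min(crit)
  list(q = grid[best], criterion = crit[best], scores = res[[best]]$scores,
       grid = data.frame(q = grid, criterion = crit))
}
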