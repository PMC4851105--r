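#' Assemble the meta-learner input table
#'
#' Stacks the per-feature-set out-of-bag scores into one table: sex first
#' (always present, never maskable), then one meta-feature per feature set
#' (the base learner's OOB class-posterior difference for detection, or OOB
#' target estimate for regression), aligned by shot_id.
#'
#' @param scoresets Named list of `score_set` objects (one per feature set).
#' @param ds The [shot_dataset()] the scores were computed on.
#' @return Meta feature table (data.frame) with shot_id, subject_id, sex,
#'   one column per score set, and the target columns.
#' @export
build_meta_table <- function(scoresets, ds) {
  stopifnot(length(scoresets) >= 1)
  meta <- dataset_meta(ds)
  ids <- meta$shot_id
  for (nm in names(scoresets)) {
    s <- scoresets[[nm]]
    if (!setequal(s$shot_id, ids)) {
      stop("score set '", nm, "' misaligned; missing shots: ",
           paste(setdiff(ids, s$shot_id), collapse = ", "),
           if (length(setdiff(s$shot_id, ids))) paste0("; extra shots: ",
             paste(setdiff(s$shot_id, ids), collapse = ", ")) else "")
    }
  }
  out <- data.frame(shot_id = ids, subject_id = meta$subject_id,
                    sex = meta$sex, stringsAsFactors = FALSE)
  for (nm in names(scoresets)) {
    s <- scoresets[[nm]]
    out[[nm]] <- s$score[match(ids, s$shot_id)]
  }
  out$speed <- meta$speed
  out$distance <- meta$distance
  out
}

#' Angle-modulated binary selection mask
#'
#' Evaluates the angle-modulation generating function
#' `g(x) = sin(2 pi (x - a) b cos(2 pi c (x - a))) + d`
#' on the grid `x_k = 0.1 k`, k = 1..n, and returns the sign pattern
#' `g_k = 1` iff `g(x_k) > 0`. Four continuous parameters thus encode a
#' length-n binary meta-feature selection mask.
#'
#' @param params Numeric 4-vector `(a, b, c, d)`.
#' @param n Mask length (default 22, the number of feature sets).
#' @return Integer 0/1 vector of length n.
#' @export
amde_mask <- function(params, n = 22) {
  stopifnot(length(params) == 4, all(is.finite(params)))
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  x <- 0.1 * seq_len(n)
  g <- sin(2 * pi * (x - a) * b * cos(2 * pi * cc * (x - a))) + d
  g[abs(g) < 1e-9] <- 0  # exact zeros of the generating function, up to float noise
  as.integer(g > 0)
}

#' Fuse base-learner scores with a meta random forest
#'
#' Fits the meta-learner (a grouped-bootstrap random forest with the same
#' sampling contracts as the base learner) on sex plus the masked
#' meta-features, trying every node subspace size q from 2 up to the number
#' of selected meta-features plus one (capped at the number of predictors),
#' and retains the best criterion: Cllr for detection, RMSE for regression.
#'
#' @param meta Meta table from [build_meta_table()].
#' @param mask 0/1 vector over the meta-feature columns (sex excluded).
#' @param task `"detect"` or `"regress"`.
#' @param target `"speed"` or `"distance"`.
#' @param B Trees of the meta forest.
#' @param seed Integer seed.
#' @return List with `scores` (best `score_set`), `q`, `criterion` and the
#'   per-q criteria.
#' @export
fuse <- function(meta, mask, task = c("detect", "regress"),
                 target = "speed", B = 500, seed = 1L) {
  task <- match.arg(task)
  meta_cols <- setdiff(names(meta), c("shot_id", "subject_id", "sex",
                                      "speed", "distance"))
  stopifnot(length(mask) == length(meta_cols))
  sel <- meta_cols[mask == 1]
  if (length(sel) == 0) stop("mask selects no meta-features")
  tab <- meta[, c("shot_id", "subject_id", "sex", sel, "speed", "distance")]
  p <- length(sel) + 1  # sex is always included
  qs <- seq(2, length(sel) + 1)
  qs <- unique(pmin(qs, p))
  if (length(qs) == 0) qs <- 1
  res <- lapply(seq_along(qs), function(i) {
    cfg <- forest_config(B = B, q = qs[i], task = task,
                         seed = derive_seed(seed, i))
    oob_scores(fit_forest(tab, cfg, target = target))
  })
  crit <- vapply(res, score_criterion, numeric(1), task = task)
  best <- which.min(crit)
  list(scores = res[[best]], q = qs[best], criterion = crit[best],
       grid = data.frame(q = qs, criterion = crit))
}

#' Meta-feature selection by angle-modulated differential evolution
#'
#' DE/rand/1/bin over the four angle-modulation parameters: each candidate
#' 4-vector is decoded to a binary meta-feature mask by [amde_mask()]
#' (all-zero masks are resampled), evaluated by [fuse()] and selected by the
#' fusion criterion (Cllr for detection, RMSE for regression). Elitist
#' one-to-one selection makes the best-so-far fitness non-increasing over
#' generations.
#'
#' @param meta Meta table from [build_meta_table()].
#' @param task `"detect"` or `"regress"`.
#' @param target Target attribute.
#' @param np Population size.
#' @param f DE scale factor.
#' @param cr Crossover rate.
#' @param generations Number of generations (0 = evaluate the initial
#'   population only).
#' @param stagnation Early stop after this many generations without
#'   improvement.
#' @param B Trees per meta forest evaluation.
#' @param seed Integer seed.
#' @return List with `mask`, `params`, `q`, `criterion`, `scores` of the
#'   best-ever candidate and the best-fitness `trajectory` per generation.
#' @export
optimize_fusion <- function(meta, task = c("detect", "regress"),
                            target = "speed", np = 20, f = 0.5, cr = 0.9,
                            generations = 30, stagnation = 10, B = 500,
                            seed = 1L) {
  task <- match.arg(task)
  n_meta <- length(setdiff(names(meta), c("shot_id", "subject_id", "sex",
                                          "speed", "distance")))
  set.seed(seed)
  rand_param <- function() stats::runif(4, -1, 1)
  nonzero <- function(p) {
    while (sum(amde_mask(p, n_meta)) == 0) p <- rand_param()
    p
  }
  pop <- lapply(seq_len(np), function(i) nonzero(rand_param()))
  eval_count <- 0
  fitness_of <- function(p) {
    eval_count <<- eval_count + 1
    fz <- fuse(meta, amde_mask(p, n_meta), task = task, target = target,
               B = B, seed = derive_seed(seed, eval_count))
    fz
  }
  evals <- lapply(pop, fitness_of)
  fit <- vapply(evals, `[[`, numeric(1), "criterion")
  best_i <- which.min(fit)
  best <- list(params = pop[[best_i]], fit = fit[best_i], fuse = evals[[best_i]])
  traj <- best$fit
  stagnant <- 0
  g <- 0
  while (g < generations && stagnant < stagnation) {
    g <- g + 1
    improved <- FALSE
    for (i in seq_len(np)) {
      rs <- sample(setdiff(seq_len(np), i), 3)
      v <- pop[[rs[1]]] + f * (pop[[rs[2]]] - pop[[rs[3]]])
      jr <- sample(4, 1)
      u <- pop[[i]]
      take <- stats::runif(4) < cr
      take[jr] <- TRUE
      u[take] <- v[take]
      u <- nonzero(u)
      ev <- fitness_of(u)
      if (ev$criterion <= fit[i]) {
        pop[[i]] <- u
        fit[i] <- ev$criterion
        if (ev$criterion < best$fit) {
          best <- list(params = u, fit = ev$criterion, fuse = ev)
          improved <- TRUE
        }
      }
    }
    traj <- c(traj, min(fit))
    stagnant <- if (improved) 0 else stagnant + 1
  }
  list(mask = amde_mask(best$params, n_meta), params = best$params,
       q = best$fuse$q, criterion = best$fit, scores = best$fuse$scores,
       trajectory = traj)
}

#' Repeated fusion with confidence intervals
#'
#' Repeats [fuse()] with a fixed mask under different forest seeds and
#' summarizes each performance metric as mean plus a normal-approximation
#' 95% confidence interval (1.96 SD / sqrt(n)).
#'
#' @param meta Meta table.
#' @param mask 0/1 meta-feature mask.
#' @param task `"detect"` or `"regress"`.
#' @param target Target attribute.
#' @param n_repeats Number of repetitions.
#' @param q Fixed meta q (`NULL` = per-repeat q sweep as in [fuse()]).
#' @param B Trees per repetition.
#' @param seed Integer seed (expanded into per-repeat seeds).
#' @return `data.frame` with metric, mean, ci95 (half-width) rows: Cllr,
#'   EER, AUC for detection; RMSE, MAPE, correlation for regression.
#' @export
repeat_fusion <- function(meta, mask, task = c("detect", "regress"),
                          target = "speed", n_repeats = 100, q = NULL,
                          B = 500, seed = 1L) {
  task <- match.arg(task)
  one <- function(r) {
    if (is.null(q)) {
      fz <- fuse(meta, mask, task = task, target = target, B = B,
                 seed = derive_seed(seed, r))
      sc <- fz$scores
    } else {
      meta_cols <- setdiff(names(meta), c("shot_id", "subject_id", "sex",
                                          "speed", "distance"))
      sel <- meta_cols[mask == 1]
      tab <- meta[, c("shot_id", "subject_id", "sex", sel, "speed", "distance")]
      cfg <- forest_config(B = B, q = q, task = task, seed = derive_seed(seed, r))
      sc <- oob_scores(fit_forest(tab, cfg, target = target))
    }
    if (task == "detect") {
      rep <- detection_report(sc$score, sc$label)
      c(cllr = rep$cllr, eer = rep$eer, auc = rep$auc)
    } else {
      m <- regression_metrics(sc$score, sc$target)
      c(rmse = m$rmse, mape = m$mape, corr = m$corr)
    }
  }
  res <- t(vapply(seq_len(n_repeats), one, numeric(3)))
  ci <- if (n_repeats > 1) 1.96 * apply(res, 2, stats::sd) / sqrt(n_repeats) else rep(0, 3)
  data.frame(metric = colnames(res), mean = colMeans(res), ci95 = unname(ci),
             row.names = NULL, stringsAsFactors = FALSE)
}
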