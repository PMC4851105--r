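# Pool-adjacent-violators: isotonic (non-decreasing) fit of y against
# increasing x order, with weights. Written out explicitly so the score
# calibration can be cross-checked against stats::isoreg in the tests.
#' @noRd
pav <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  # classic stack-based PAV
  val_s <- numeric(n)
  w_s <- numeric(n)
  len_s <- integer(n)
  top <- 0
  for (i in seq_len(n)) {
    top <- top + 1
    val_s[top] <- y[i]
    w_s[top] <- w[i]
    len_s[top] <- 1L
    while (top > 1 && val_s[top - 1] >= val_s[top]) {
      merged_w <- w_s[top - 1] + w_s[top]
      val_s[top - 1] <- (val_s[top - 1] * w_s[top - 1] + val_s[top] * w_s[top]) / merged_w
      w_s[top - 1] <- merged_w
      len_s[top - 1] <- len_s[top - 1] + len_s[top]
      top <- top - 1
    }
  }
  rep(val_s[seq_len(top)], len_s[seq_len(top)])
}

#' Calibrated log-likelihood ratios via the ROC convex hull
#'
#' Maps detector scores to monotone, calibrated log-likelihood ratios: the
#' pool-adjacent-violators algorithm (equivalent to walking the ROC convex
#' hull) yields the isotonic posterior of the effective class given the
#' score; the LLR is the posterior log-odds minus the prior log-odds.
#' LLRs are capped at +/- `cap` nats so perfectly separated sets stay
#' finite.
#'
#' @param scores Numeric detector scores (larger = more effective).
#' @param labels 0/1 labels.
#' @param cap Cap on |LLR| in nats.
#' @return Numeric LLR vector aligned with `scores` (order preserving).
#' @export
rocch_llr <- function(scores, labels, cap = 15) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  # pool tied scores first so the isotonic fit cannot split a tie group
  grp <- match(scores, sort(unique(scores)))
  w <- tabulate(grp)
  ybar <- vapply(split(labels, factor(grp, levels = seq_along(w))), mean,
                 numeric(1))
  post <- pav(ybar, w)
  eps <- 1e-12
  post <- pmin(pmax(post, eps), 1 - eps)
  prior_logodds <- log(sum(labels == 1) / sum(labels == 0))
  llr <- log(post / (1 - post)) - prior_logodds
  llr <- pmin(pmax(llr, -cap), cap)
  llr[grp]
}

#' Cost of the log-likelihood ratio (Cllr)
#'
#' The application-independent calibrated detection cost in bits,
#' `0.5 * (mean_eff log2(1 + exp(-llr)) + mean_ineff log2(1 + exp(llr)))`,
#' computed on ROC-convex-hull calibrated LLRs (min-Cllr). A useless
#' detector scores 1 bit; a perfect one approaches 0.
#'
#' @param scores Detector scores.
#' @param labels 0/1 labels.
#' @return Cllr in bits.
#' @export
cllr <- function(scores, labels) {
  labels <- as.integer(labels)
  llr <- rocch_llr(scores, labels)
  0.5 * (mean(log2(1 + exp(-llr[labels == 1]))) +
           mean(log2(1 + exp(llr[labels == 0]))))
}

# ROC step-curve points (FPR, TPR) for decreasing score thresholds,
# then the upper convex hull
#' @noRd
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels)[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # collapse ties on score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(lab == 0)),
             tpr = c(0, tp[keep] / sum(lab == 1)))
}

#' @noRd
roc_hull <- function(pts) {
  pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  h <- grDevices::chull(c(pts$fpr, 2, -1), c(pts$tpr, -1, -1))
  # drop the two sentinel points that force the lower edge out of the hull
  h <- h[h <= nrow(pts)]
  hp <- pts[sort(h), ]
  # chull drops collinear vertices; re-anchor the endpoints explicitly
  hp <- rbind(data.frame(fpr = 0, tpr = 0), hp, data.frame(fpr = 1, tpr = 1))
  hp <- hp[order(hp$fpr, hp$tpr), ]
  hp[!duplicated(hp), ]
}

#' DET operating points and equal error rate
#'
#' Sweeps thresholds over the ROC convex hull and locates the operating
#' point where the miss rate equals the false-alarm rate (linear
#' interpolation between adjacent hull vertices).
#'
#' @param scores Detector scores (larger = more effective).
#' @param labels 0/1 labels.
#' @return List with `det` (data.frame of miss/false-alarm rates along the
#'   hull) and `eer` in percent.
#' @export
det_eer <- function(scores, labels) {
  if (length(unique(as.integer(labels))) < 2) stop("both classes must be present")
  hp <- roc_hull(roc_points(scores, labels))
  miss <- 1 - hp$tpr
  fa <- hp$fpr
  # find the hull segment crossing miss == fa
  d <- miss - fa
  eer <- NA_real_
  for (i in seq_len(length(d) - 1)) {
    if (d[i] >= 0 && d[i + 1] <= 0) {
      if (d[i] == d[i + 1]) {
        eer <- fa[i]
      } else {
        t <- d[i] / (d[i] - d[i + 1])
        eer <- fa[i] + t * (fa[i + 1] - fa[i])
      }
      break
    }
  }
  list(det = data.frame(false_alarm = fa, miss = miss), eer = 100 * eer)
}

#' ROC curve and area under the curve
#'
#' AUC is computed as the normalized Mann-Whitney U statistic (ties count
#' one half), identical to the probability that a random effective shot
#' outscores a random ineffective one.
#'
#' @param scores Detector scores.
#' @param labels 0/1 labels.
#' @return List with `roc` (step-curve points) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc_points(scores, labels), auc = auc)
}

#' Full detection report
#'
#' @param scores Detector scores (larger = more effective).
#' @param labels 0/1 labels.
#' @return An object of class `detection_report`: cllr (bits), eer (%),
#'   auc, and the DET/ROC operating points.
#' @export
detection_report <- function(scores, labels) {
  de <- det_eer(scores, labels)
  ra <- roc_auc(scores, labels)
  structure(list(cllr = cllr(scores, labels), eer = de$eer, auc = ra$auc,
                 det_curve = de$det, roc_curve = ra$roc),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> Cllr %.3f bits, EER %.2f%%, AUC %.3f\n",
              x$cllr, x$eer, x$auc))
  invisible(x)
}

#' Regression error metrics
#'
#' Root mean squared error, mean absolute percentage error and Pearson
#' correlation between predictions and actual values.
#'
#' @param pred Predicted values.
#' @param actual Actual values (must be positive for MAPE).
#' @return Named list rmse, mape (%), corr. When either side is constant
#'   the correlation is reported as `NA`.
#' @export
regression_metrics <- function(pred, actual) {
  stopifnot(length(pred) == length(actual), length(pred) >= 2)
  if (any(actual == 0)) stop("MAPE undefined: zero actual value")
  corr <- if (stats::sd(pred) > 0 && stats::sd(actual) > 0) {
    stats::cor(pred, actual)
  } else if (all(pred == actual)) 1 else NA_real_
  list(rmse = sqrt(mean((pred - actual)^2)),
       mape = 100 * mean(abs(pred - actual) / actual),
       corr = corr)
}

#' Naive sex-average reference predictor
#'
#' Predicts every shot's target as the mean target over all same-sex shots
#' (full-sample sex-specific average) and reports the regression metrics of
#' that reference.
#'
#' @param ds A [shot_dataset()] (or any data.frame with sex and target
#'   columns).
#' @param target `"speed"` or `"distance"`.
#' @return List with `pred` and the metrics of [regression_metrics()].
#' @export
naive_baseline <- function(ds, target = c("speed", "distance")) {
  target <- match.arg(target)
  meta <- if (inherits(ds, "shot_dataset")) dataset_meta(ds) else ds
  v <- meta[[target]]
  if (anyNA(v)) stop("missing target values")
  pred <- stats::ave(v, meta$sex, FUN = mean)
  c(list(pred = pred), regression_metrics(pred, v))
}
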