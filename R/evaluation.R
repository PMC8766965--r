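# Evaluation metrics: threshold-sweep ROC with trapezoid AUC,
# precision-recall with all-points-interpolated average precision (both
# classifier and detector modes), and multi-trial averaging.

#' ROC curve and AUC
#'
#' Standard threshold sweep over the distinct score values (ties grouped),
#' AUC by the trapezoid rule. Equals the Mann-Whitney U statistic divided
#' by n_pos * n_neg.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical/0-1 positive indicators; both classes must occur.
#' @return list: `fpr`, `tpr` (curve points from (0,0) to (1,1)), `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- !duplicated(s)
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(c(grp[-1], TRUE))        # last index of each tie group
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

ap_from_ranked <- function(tp_flags, n_pos) {
  # all-points interpolation: integrate the precision envelope over recall
  if (n_pos == 0) stop("at least one positive required")
  tp <- cumsum(tp_flags)
  prec <- tp / seq_along(tp_flags)
  rec <- tp / n_pos
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Precision-recall curve and average precision
#'
#' Classifier mode: ranks samples by score and computes precision/recall at
#' every rank (ties broken by original order after a stable sort).
#' Detector mode: pass the output of [match_detections()] (or a list with
#' `labels`, `scores` and `fn`) and the ranked true-positive flags are used
#' with n_pos = tp + fn. Average precision integrates the precision
#' envelope over recall (all-points interpolation).
#'
#' @param scores numeric scores, or a [match_detections()] result.
#' @param labels positive indicators (classifier mode; ignored in detector
#'   mode).
#' @return list: `precision`, `recall`, `ap`.
#' @export
pr_curve_map <- function(scores, labels = NULL) {
  if (is.list(scores) && !is.null(scores$labels)) {
    flags <- scores$labels
    n_pos <- scores$tp + scores$fn
    o <- order(scores$scores, decreasing = TRUE)
    flags <- flags[o]
  } else {
    labels <- as.logical(labels)
    n_pos <- sum(labels)
    o <- order(scores, decreasing = TRUE)
    flags <- labels[o]
  }
  if (n_pos == 0) stop("at least one positive required")
  tp <- cumsum(flags)
  list(precision = tp / seq_along(flags), recall = tp / n_pos,
       ap = ap_from_ranked(flags, n_pos))
}

#' Macro-averaged one-vs-rest metrics from a score matrix
#'
#' @param score_mat (N x K) per-class scores.
#' @param y labels in 1..K.
#' @return named vector: `accuracy`, `map` (mean one-vs-rest AP),
#'   `roc_auc` (mean one-vs-rest AUC).
#' @export
multiclass_metrics <- function(score_mat, y) {
  K <- ncol(score_mat)
  acc <- mean(max.col(score_mat, ties.method = "first") == y)
  aps <- auc <- numeric(K)
  for (k in seq_len(K)) {
    pos <- y == k
    aps[k] <- pr_curve_map(score_mat[, k], pos)$ap
    auc[k] <- roc_curve_auc(score_mat[, k], pos)$auc
  }
  c(accuracy = acc, map = mean(aps), roc_auc = mean(auc))
}

#' Run an experiment over multiple seeded trials
#'
#' Runs `experiment_fn(seed)` with seeds `base_seed + 0 .. n_trials - 1`
#' and aggregates the named numeric vectors it returns.
#'
#' @param experiment_fn function(seed) -> named numeric vector.
#' @param n_trials `>= 1` (the study convention is 5).
#' @param base_seed integer.
#' @return object of class `trial_report`: `per_trial` (data.frame with
#'   `trial`, `seed` and one column per metric), `mean`, `sd` (0 for a
#'   single trial), `n_trials`.
#' @export
run_trials <- function(experiment_fn, n_trials = 5L, base_seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    seed <- base_seed + i - 1L
    v <- tryCatch(experiment_fn(seed),
                  error = function(e) stop("trial ", i, " (seed ", seed,
                                           ") failed: ", conditionMessage(e)))
    rows[[i]] <- data.frame(trial = i, seed = seed, t(v))
  }
  per <- do.call(rbind, rows)
  metrics <- setdiff(names(per), c("trial", "seed"))
  mu <- vapply(per[metrics], mean, numeric(1))
  sdv <- if (n_trials == 1) stats::setNames(rep(0, length(metrics)), metrics)
         else vapply(per[metrics], stats::sd, numeric(1))
  structure(list(per_trial = per, mean = mu, sd = sdv, n_trials = n_trials),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report> ", x$n_trials, " trials\n", sep = "")
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}
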