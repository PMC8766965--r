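# Matched-vs-max presentation-strategy experiment: how the number of
# stochastic presentations used at training time interacts with the number
# used at inference time.

#' Compare matched and max presentation strategies
#'
#' For the matched strategy a fresh network is trained and evaluated at
#' each N_pre in `n_grid`; for the max strategy one network per trial is
#' trained at `n_max` presentations and evaluated at every N_pre in
#' `n_grid`. Accuracy, macro mAP and macro ROC AUC on the test split are
#' averaged over `n_trials` seeded trials.
#'
#' @param spec a [network_spec()] for the classifier.
#' @param train_x,train_y,test_x,test_y data splits (arrays H x W x C x N,
#'   labels 1..K).
#' @param n_grid inference presentation counts to evaluate.
#' @param strategies subset of c("matched", "max").
#' @param n_trials seeded repetitions (default 5).
#' @param n_max training presentations of the max strategy (default 256).
#' @param dist input sampling distribution.
#' @param epochs,batch_size,lr training settings passed to [sbcnn_train()].
#' @param base_seed first trial seed.
#' @return list: `per_trial` (strategy, n_pre, trial, accuracy, map,
#'   roc_auc), `summary` (one row per strategy x n_pre with means and sds).
#' @export
evaluate_strategies <- function(spec, train_x, train_y, test_x, test_y,
                                n_grid = c(2L, 8L, 32L),
                                strategies = c("matched", "max"),
                                n_trials = 5L, n_max = 256L,
                                dist = "normal", epochs = 12L,
                                batch_size = 32L, lr = 0.01,
                                base_seed = 1L) {
  if (length(n_grid) == 0) stop("n_grid must be non-empty")
  rows <- list()
  for (trial in seq_len(n_trials)) {
    seed <- base_seed + (trial - 1L) * 1000L
    if ("max" %in% strategies) {
      net <- sbcnn_train(spec, train_x, train_y,
                         presentation_config(n_max, n_max, "max"),
                         dist = dist, epochs = epochs, batch_size = batch_size,
                         lr = lr, seed = seed)
      model <- export_model(net)
      for (n in n_grid) {
        sc <- sbcnn_infer(model, test_x, n_infer = n, seed = seed + n)
        m <- multiclass_metrics(sc, test_y)
        rows[[length(rows) + 1L]] <- data.frame(strategy = "max", n_pre = n,
                                                trial = trial, t(m))
      }
    }
    if ("matched" %in% strategies) {
      for (n in n_grid) {
        net <- sbcnn_train(spec, train_x, train_y,
                           presentation_config(n, n, "matched"),
                           dist = dist, epochs = epochs, batch_size = batch_size,
                           lr = lr, seed = seed)
        sc <- sbcnn_infer(export_model(net), test_x, n_infer = n, seed = seed + n)
        m <- multiclass_metrics(sc, test_y)
        rows[[length(rows) + 1L]] <- data.frame(strategy = "matched", n_pre = n,
                                                trial = trial, t(m))
      }
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, list(per$strategy, per$n_pre), drop = TRUE),
    function(g) data.frame(
      strategy = g$strategy[1], n_pre = g$n_pre[1],
      accuracy = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
      map = mean(g$map), map_sd = stats::sd(g$map),
      roc_auc = mean(g$roc_auc), roc_auc_sd = stats::sd(g$roc_auc))))
  agg <- agg[order(agg$strategy, agg$n_pre), ]
  rownames(agg) <- NULL
  list(per_trial = per, summary = agg)
}
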