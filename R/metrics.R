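#' Evaluate binary predictions
#'
#' Computes the evaluation measures for one run: confusion counts at the
#' decision threshold, accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall
#' `TP/(TP+FN)`, the area under the ROC curve (trapezoidal, ties counted
#' one half — computed by the equivalent midrank statistic), and the mean
#' binary cross-entropy
#' `-(1/n) * sum(y* log y + (1-y*) log(1-y))` with probabilities clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' When all labels belong to one class the AUC is undefined and returned as
#' `NA` with a warning; the other measures are still computed.
#'
#' @param labels 0/1 vector of true classes.
#' @param probs predicted probabilities in `[0, 1]`, same length.
#' @param threshold decision threshold for the confusion counts
#'   (default 0.5; predictions `>= threshold` count as positive).
#' @return an object of class `eval_metrics`: list with `accuracy`,
#'   `recall`, `auc`, `loss`, and counts `tp`, `tn`, `fp`, `fn`, `n`.
#' @examples
#' evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
#' @export
evaluate <- function(labels, probs, threshold = 0.5) {
  abort_if(length(labels) == 0L, "empty input: no predictions to evaluate")
  abort_if(length(labels) != length(probs),
           "labels and probs differ in length (%d vs %d)", length(labels),
           length(probs))
  abort_if(!all(labels %in% c(0L, 1L)), "labels must be 0/1")
  abort_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")

  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  accuracy <- (tp + tn) / length(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  recall <- if (n1 > 0L) tp / n1 else NA_real_

  auc <- if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: labels contain a single class", call. = FALSE)
    NA_real_
  } else {
    # midrank (Mann-Whitney) form of the trapezoidal ROC area
    r <- rank(probs)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }

  pc <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  loss <- -mean(labels * log(pc) + (1 - labels) * log(1 - pc))

  structure(list(accuracy = accuracy, recall = recall, auc = auc,
                 loss = loss, tp = tp, tn = tn, fp = fp, fn = fn,
                 n = length(labels)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  recall %.4f  auc %.4f  loss %.4f  (n = %d)\n",
              x$accuracy, x$recall, x$auc, x$loss, x$n))
  invisible(x)
}

#' Repeated hold-out validation
#'
#' Runs `n_repeats` independent cycles of stratified split, training and
#' hold-out evaluation, each under a seed derived from `base_seed`, and
#' summarizes every metric as mean and sample standard deviation in the
#' conventional "0.9434±0.0078" form. With a single repeat the standard
#' deviation is reported as 0 by convention.
#'
#' @param table a `pair_feature_table` with both classes present.
#' @param config a [model_config()] (ignored when `classifier` is not
#'   `"mlp"` except for its seed).
#' @param n_repeats number of split/train/evaluate cycles.
#' @param base_seed master seed; repeat r uses a derived seed.
#' @param n_train_pos,n_train_neg training class counts; default 75% of each
#'   class (floored).
#' @param classifier `"mlp"` or one of the [classic_classifier()] algorithm
#'   names.
#' @param ... passed on to [classic_classifier()].
#' @return an object of class `holdout_summary`: list with `summary` (a
#'   data.frame of metric, mean, sd, formatted) and `runs` (per-repeat
#'   metrics).
#' @export
holdout_repeat <- function(table, config = model_config(), n_repeats = 5L,
                           base_seed = 1L, n_train_pos = NULL,
                           n_train_neg = NULL, classifier = "mlp", ...) {
  abort_if(n_repeats < 1L, "`n_repeats` must be >= 1")
  if (is.null(n_train_pos)) n_train_pos <- floor(0.75 * table$n_pos)
  if (is.null(n_train_neg)) n_train_neg <- floor(0.75 * table$n_neg)
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    seed_r <- sub_seed(base_seed, 100L + r)
    sp <- split_train_holdout(table, n_train_pos, n_train_neg, seed = seed_r)
    model <- if (identical(classifier, "mlp")) {
      cfg <- config
      cfg$seed <- seed_r
      train_mlp(sp$train, cfg)
    } else {
      classic_classifier(sp$train, algorithm = classifier, seed = seed_r, ...)
    }
    m <- evaluate(sp$holdout$labels, predict(model, sp$holdout))
    runs[[r]] <- data.frame(run = r, accuracy = m$accuracy,
                            recall = m$recall, auc = m$auc, loss = m$loss)
  }
  runs <- do.call(rbind, runs)
  metrics <- c("accuracy", "recall", "auc", "loss")
  mu <- vapply(runs[metrics], mean, numeric(1))
  sdev <- if (n_repeats == 1L) setNames(rep(0, 4L), metrics)
          else vapply(runs[metrics], stats::sd, numeric(1))
  structure(list(
    summary = data.frame(metric = metrics, mean = unname(mu),
                         sd = unname(sdev),
                         formatted = sprintf("%.4f±%.4f", mu, sdev)),
    runs = runs),
    class = "holdout_summary")
}

#' @export
print.holdout_summary <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("%-9s %s\n", x$summary$metric[i], x$summary$formatted[i]))
  }
  invisible(x)
}
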