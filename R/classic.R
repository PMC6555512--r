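#' Classical classifier baselines
#'
#' Fits one of the off-the-shelf algorithms compared against the neural
#' network — decision tree, k-nearest neighbors or random forest — on a
#' pair-feature table, behind the same predict/evaluate contract as
#' [train_mlp()]. Hyperparameters are documented package defaults:
#' decision tree uses rpart's defaults; k-neighbors uses `k = 5` (the k-NN
#' "training" step only stores the data); random forest uses 200 trees.
#'
#' @param train a `pair_feature_table`.
#' @param algorithm `"decision_tree"`, `"k_neighbors"` or `"random_forest"`.
#' @param seed integer seed for the stochastic fitters.
#' @param k neighbors for `"k_neighbors"` (default 5).
#' @param ntree trees for `"random_forest"` (default 200).
#' @return an object of class `ppi_classifier` supporting
#'   `predict(model, table)` returning probabilities in `[0, 1]`.
#' @export
classic_classifier <- function(train,
                               algorithm = c("decision_tree", "k_neighbors",
                                             "random_forest"),
                               seed = 1L, k = 5L, ntree = 200L) {
  abort_if(!is.character(algorithm) ||
             !algorithm[1L] %in% c("decision_tree", "k_neighbors",
                                   "random_forest"),
           "unknown algorithm '%s'", as.character(algorithm[1L]))
  algorithm <- match.arg(algorithm)
  x <- train$x
  y <- train$labels
  abort_if(!is.matrix(x) || nrow(x) == 0L, "training table is empty")
  fit <- with_local_seed(sub_seed(seed, 21L), {
    switch(algorithm,
      decision_tree = {
        df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x)
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      k_neighbors = list(x = x, y = factor(y, levels = c(0L, 1L)), k = k),
      random_forest = randomForest::randomForest(
        x, factor(y, levels = c(0L, 1L)), ntree = ntree)
    )
  })
  structure(list(algorithm = algorithm, fit = fit, seed = seed),
            class = "ppi_classifier")
}

#' @export
predict.ppi_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pair_feature_table")) newdata$x else newdata
  abort_if(!is.matrix(x), "`newdata` must be a matrix or pair_feature_table")
  if (nrow(x) == 0L) return(numeric(0))
  switch(object$algorithm,
    decision_tree = {
      p <- stats::predict(object$fit, data.frame(x), type = "prob")
      unname(p[, "1"])
    },
    k_neighbors = {
      pred <- class::knn(object$fit$x, x, object$fit$y, k = object$fit$k,
                         prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    random_forest = {
      p <- stats::predict(object$fit, x, type = "prob")
      unname(p[, "1"])
    }
  )
}

#' @export
print.ppi_classifier <- function(x, ...) {
  cat(sprintf("ppi_classifier: %s\n", x$algorithm))
  invisible(x)
}
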