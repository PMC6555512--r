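test_that("the network separates two Gaussian blobs", {
  tab <- separable_table(n_per_class = 120L, dim = 58L, seed = 3)
  cfg <- model_config(width = 32L, depth = 2L, n_steps = 300L, seed = 4L)
  m <- train_mlp(tab, cfg)
  expect_s3_class(m, "mlp_model")
  # training loss decreases
  expect_lt(utils::tail(m$loss_history$loss, 1), m$loss_history$loss[1])
  p <- predict(m, tab)
  expect_gte(mean((p >= 0.5) == (tab$labels == 1L)), 0.99)
})

test_that("training is deterministic given the seed", {
  tab <- separable_table(n_per_class = 40L, dim = 10L, seed = 6)
  cfg <- model_config(width = 8L, depth = 2L, n_steps = 50L, seed = 11L)
  m1 <- train_mlp(tab, cfg)
  m2 <- train_mlp(tab, cfg)
  expect_identical(predict(m1, tab), predict(m2, tab))
})

test_that("prediction respects bounds, row identity and dimension checks", {
  tab <- separable_table(n_per_class = 40L, dim = 10L, seed = 8)
  m <- train_mlp(tab, model_config(width = 8L, depth = 2L, n_steps = 50L,
                                   seed = 2L))
  p <- predict(m, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(predict(m, tab$x[0, , drop = FALSE]), 0L) # empty input
  dup <- tab$x[c(1, 1), , drop = FALSE]
  pd <- predict(m, dup)
  expect_identical(pd[1], pd[2]) # duplicated rows, identical output
  expect_error(predict(m, tab$x[, 1:5, drop = FALSE]), "expects 10")
})

test_that("evaluation metrics match hand-computed confusions and ranks", {
  m <- evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$recall, 1.0)
  expect_equal(m$auc, 1.0)

  expect_equal(evaluate(c(1, 0), c(0.5, 0.5))$auc, 0.5) # tie convention

  m2 <- evaluate(c(1, 1, 0, 0), c(0.6, 0.4, 0.6, 0.4))
  expect_equal(m2$auc, 0.5)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$auc, auc_rank_oracle(c(1, 1, 0, 0), c(0.6, 0.4, 0.6, 0.4)))
})

test_that("AUC equals the exhaustive pairwise-rank statistic", {
  set.seed(141)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    probs <- round(stats::runif(n), sample(c(1, 2, 6), 1)) # force some ties
    expect_equal(evaluate(labels, probs)$auc, auc_rank_oracle(labels, probs))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(142)
  labels <- sample(c(0L, 1L), 150, replace = TRUE)
  labels[1:2] <- c(0L, 1L)
  probs <- round(stats::runif(150), 2)
  expect_equal(evaluate(labels, probs)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                              direction = "<"))))
})

test_that("cross-entropy loss hits its closed-form anchors", {
  labels <- rep(c(0L, 1L), 10)
  expect_lt(evaluate(labels, as.numeric(labels))$loss, 1e-11)
  expect_equal(evaluate(labels, rep(0.5, 20))$loss, log(2),
               tolerance = 1e-12)
})

test_that("metrics obey label-swap symmetry and row-order invariance", {
  set.seed(151)
  labels <- sample(c(0L, 1L), 60, replace = TRUE)
  labels[1:2] <- c(0L, 1L)
  probs <- stats::runif(60)
  m <- evaluate(labels, probs)
  swapped <- evaluate(1L - labels, 1 - probs)
  expect_equal(swapped$auc, m$auc)
  expect_equal(swapped$loss, m$loss)
  perm <- sample(60)
  mp <- evaluate(labels[perm], probs[perm])
  expect_equal(mp$accuracy, m$accuracy)
  expect_equal(mp$auc, m$auc)
  expect_equal(mp$loss, m$loss)
  # accuracy under swap: >= 0.5 threshold asymmetry only at exact ties
  if (!any(probs == 0.5)) expect_equal(swapped$accuracy, m$accuracy)
})

test_that("degenerate evaluation inputs are flagged", {
  expect_error(evaluate(integer(0), numeric(0)), "empty")
  expect_warning(m <- evaluate(c(1, 1), c(0.2, 0.9)), "single class")
  expect_true(is.na(m$auc))
  expect_equal(m$recall, 0.5) # other metrics still computed
})

test_that("repeated hold-out reports mean and spread per metric", {
  tab <- separable_table(n_per_class = 80L, dim = 12L, seed = 9)
  cfg <- model_config(width = 8L, depth = 2L, n_steps = 80L, seed = 1L)
  hr <- holdout_repeat(tab, cfg, n_repeats = 3L, base_seed = 5L)
  expect_s3_class(hr, "holdout_summary")
  expect_equal(nrow(hr$runs), 3L)
  expect_equal(hr$summary$metric, c("accuracy", "recall", "auc", "loss"))
  expect_true(all(grepl("^\\d\\.\\d{4}±\\d\\.\\d{4}$",
                        hr$summary$formatted)))
  acc <- hr$summary[hr$summary$metric == "accuracy", ]
  expect_gt(acc$mean, 0.9) # separable problem
  # a single repeat reports sd 0 by convention
  hr1 <- holdout_repeat(tab, cfg, n_repeats = 1L, base_seed = 5L)
  expect_true(all(hr1$summary$sd == 0))
})

test_that("classical baselines fit behind the same contract", {
  tab <- separable_table(n_per_class = 100L, dim = 12L, seed = 10)
  sp <- split_train_holdout(tab, 70L, 70L, seed = 2L)
  for (alg in c("decision_tree", "k_neighbors", "random_forest")) {
    cl <- classic_classifier(sp$train, alg, seed = 3L)
    p <- predict(cl, sp$holdout)
    expect_true(all(p >= 0 & p <= 1))
    m <- evaluate(sp$holdout$labels, p)
    expect_gt(m$accuracy, 0.9) # separable problem
  }
  rf <- classic_classifier(tab, "random_forest", seed = 3L)
  expect_gte(mean((predict(rf, tab) >= 0.5) == (tab$labels == 1L)), 0.99)
  expect_error(classic_classifier(tab, "gradient_boost"), "unknown")
})
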