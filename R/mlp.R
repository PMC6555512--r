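#' Feed-forward network configuration
#'
#' Hyperparameters of the fully-connected classifier. Defaults are the
#' selected operating point for MOS-encoded pairs: learning rate 0.01,
#' three hidden layers of 512 ReLU units, Adam, batch size 128, no dropout.
#' [baseline_model_config()] is the preset used for the wider comparison
#' encoders (learning rate 0.001, width 256, depth 3).
#'
#' @param learning_rate Adam step size.
#' @param width hidden-layer width (units).
#' @param depth number of hidden layers.
#' @param batch_size minibatch size per optimization step.
#' @param dropout hidden-unit dropout probability in `[0, 1)` (inverted
#'   dropout at train time; default 0).
#' @param n_steps number of minibatch steps ("iterations" are steps, not
#'   epochs).
#' @param seed integer seed controlling weight initialization and batch
#'   sampling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(learning_rate = 0.01, width = 512L, depth = 3L,
                         batch_size = 128L, dropout = 0, n_steps = 2000L,
                         seed = 1L) {
  abort_if(learning_rate <= 0, "`learning_rate` must be positive")
  abort_if(width < 1L || depth < 1L, "`width` and `depth` must be >= 1")
  abort_if(dropout < 0 || dropout >= 1, "`dropout` must be in [0, 1)")
  structure(list(learning_rate = learning_rate, width = as.integer(width),
                 depth = as.integer(depth), batch_size = as.integer(batch_size),
                 dropout = dropout, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), activation = "relu",
                 optimizer = "adam"),
            class = "model_config")
}

#' @rdname model_config
#' @param ... overrides passed to [model_config()].
#' @export
baseline_model_config <- function(...) {
  defaults <- list(learning_rate = 0.001, width = 256L, depth = 3L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

#' Train the feed-forward classifier
#'
#' Fits a fully-connected network on a labeled pair-feature table: input of
#' the encoder's per-pair dimension, `depth` hidden ReLU layers of `width`
#' units, a single sigmoid output, minimizing mean binary cross-entropy with
#' Adam (beta1 0.9, beta2 0.999, eps 1e-8) over `n_steps` minibatches of
#' `batch_size` rows. Weights start from fan-in-scaled uniform noise
#' (U(-s, s), s = sqrt(6 / fan_in)); biases start at zero. Fully
#' deterministic given the config seed.
#'
#' @param train a `pair_feature_table` (or a list with numeric matrix `x`
#'   and 0/1 `labels`).
#' @param config a [model_config()].
#' @return an object of class `mlp_model` with weights, the config, and a
#'   `loss_history` data.frame (step, minibatch loss every 50 steps).
#' @export
train_mlp <- function(train, config = model_config()) {
  x <- train$x
  y <- train$labels
  abort_if(!is.matrix(x) || nrow(x) == 0L, "training table is empty")
  abort_if(length(y) != nrow(x), "labels do not match feature rows")
  abort_if(!all(y %in% c(0L, 1L)), "labels must be 0/1")
  n <- nrow(x)
  dims <- c(ncol(x), rep(config$width, config$depth), 1L)
  nlayer <- length(dims) - 1L

  with_local_seed(sub_seed(config$seed, 11L), {
    W <- lapply(seq_len(nlayer), function(l) {
      s <- sqrt(6 / dims[l])
      matrix(stats::runif(dims[l] * dims[l + 1L], -s, s), dims[l],
             dims[l + 1L])
    })
    b <- lapply(seq_len(nlayer), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    hist_step <- integer(0); hist_loss <- numeric(0)

    for (step in seq_len(config$n_steps)) {
      idx <- if (n >= config$batch_size) {
        sample.int(n, config$batch_size)
      } else {
        sample.int(n, config$batch_size, replace = TRUE)
      }
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      bs <- length(idx)

      # forward
      a <- vector("list", nlayer + 1L)
      masks <- vector("list", nlayer)
      a[[1L]] <- xb
      for (l in seq_len(nlayer)) {
        z <- a[[l]] %*% W[[l]]
        z <- sweep(z, 2L, b[[l]], `+`)
        if (l < nlayer) {
          h <- pmax(z, 0)
          if (config$dropout > 0) {
            mask <- matrix(stats::rbinom(length(h), 1L, 1 - config$dropout),
                           nrow(h)) / (1 - config$dropout)
            h <- h * mask
            masks[[l]] <- mask
          }
          a[[l + 1L]] <- h
        } else {
          a[[l + 1L]] <- 1 / (1 + exp(-z)) # sigmoid output
        }
      }
      p <- as.numeric(a[[nlayer + 1L]])
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
      if (step %% 50L == 0L || step == 1L) {
        hist_step <- c(hist_step, step)
        hist_loss <- c(hist_loss, loss)
      }

      # backward: gradient of mean BCE through the sigmoid output
      delta <- matrix((p - yb) / bs, ncol = 1L)
      for (l in seq(nlayer, 1L)) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          back <- delta %*% t(W[[l]])
          back <- back * (a[[l]] > 0) # ReLU derivative
          if (config$dropout > 0 && !is.null(masks[[l - 1L]])) {
            back <- back * masks[[l - 1L]]
          }
          delta <- back
        }
        # Adam
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    structure(list(W = W, b = b, dims = dims, config = config,
                   loss_history = data.frame(step = hist_step,
                                             loss = hist_loss)),
              class = "mlp_model")
  })
}

#' Predict interaction probabilities with a trained network
#'
#' @param object an `mlp_model` from [train_mlp()].
#' @param newdata a `pair_feature_table` or a numeric matrix whose column
#'   count matches the model input dimension.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`, one per row (empty
#'   input gives an empty vector).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pair_feature_table")) newdata$x else newdata
  abort_if(!is.matrix(x), "`newdata` must be a matrix or pair_feature_table")
  if (nrow(x) == 0L) return(numeric(0))
  abort_if(ncol(x) != object$dims[1L],
           "input has %d columns but the model expects %d", ncol(x),
           object$dims[1L])
  nlayer <- length(object$W)
  a <- x
  for (l in seq_len(nlayer)) {
    z <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], `+`)
    a <- if (l < nlayer) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %s, %d steps, final minibatch loss %.4f\n",
              paste(x$dims, collapse = "-"), x$config$n_steps,
              utils::tail(x$loss_history$loss, 1L)))
  invisible(x)
}
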