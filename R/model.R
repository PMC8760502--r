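# The temporal+lead-axis residual convolutional classifier: an 8 x 2500
# sinus-rhythm sample in, probability of the AF label out.

#' Model hyperparameter configuration
#'
#' The network processes the eight leads independently along the temporal
#' axis (one shared-weight 1-D convolution stack), then merges them with a
#' convolution across the lead axis.  The temporal stack is a convolution /
#' batch-normalization / ReLU / max-pooling stem followed by
#' `n_residual_repeats` repetitions of two residual blocks plus average
#' pooling; channel counts start at `base_channels` and double per repetition
#' up to `max_channels`.
#'
#' @param n_residual_repeats N, the number of `[two residual blocks +
#'   average pooling]` repetitions; tuned via [tune_n()].
#' @param temporal_kernel Window length of the temporal convolutions
#'   (samples).
#' @param base_channels Filter count of the first convolution.
#' @param max_channels Cap on per-stage channel doubling.
#' @param pool_size Max/average pooling width.
#' @param dropout_rate Dropout proportion in `[0, 1)` before global average
#'   pooling.
#' @param epochs,batch_size,learning_rate,early_stop_patience Adam training
#'   schedule; training keeps the epoch with the best validation AUC and
#'   stops after `early_stop_patience` epochs without improvement.
#' @param seed Master seed fanned out to parameter initialization, batch
#'   order and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_residual_repeats = 2L, temporal_kernel = 16L,
                         base_channels = 16L, max_channels = 64L,
                         pool_size = 2L, dropout_rate = 0.2,
                         epochs = 20L, batch_size = 32L,
                         learning_rate = 1e-3, early_stop_patience = 5L,
                         seed = 1L) {
  stopifnot(n_residual_repeats >= 1, temporal_kernel >= 1, base_channels >= 1,
            max_channels >= base_channels, pool_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, early_stop_patience >= 1)
  structure(list(n_residual_repeats = as.integer(n_residual_repeats),
                 temporal_kernel = as.integer(temporal_kernel),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained network from a configuration
#'
#' Layer order: temporal stem (convolution, batch normalization, ReLU, max
#' pooling applied per lead with shared weights), N repetitions of two
#' residual blocks plus average pooling, lead-axis stage (batch normalization
#' + ReLU, convolution across the 8 leads, batch normalization + ReLU), and
#' the head (dropout, global average pooling, 2-way dense output normalized
#' by softmax at prediction time).  Construction is deterministic given
#' `config` (initialization draws from `config$seed`).
#'
#' @param config A [model_config()].
#' @return Object of class `af_cnn_net` with elements `layers`, `config`,
#'   `n_params`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_preserved_rng(config$seed, {
    p <- config$pool_size
    layers <- list(layer_conv(config$temporal_kernel, 1L, config$base_channels,
                              first = TRUE),
                   layer_bn(config$base_channels, act = TRUE),
                   layer_pool(p, "max"))
    tlen <- 2500L %/% p
    cprev <- config$base_channels
    for (s in seq_len(config$n_residual_repeats)) {
      cs <- min(config$base_channels * 2L^(s - 1L), config$max_channels)
      layers <- c(layers, list(
        layer_resblock(config$temporal_kernel, cprev, cs),
        layer_resblock(config$temporal_kernel, cs, cs),
        layer_pool(p, "avg")))
      tlen <- tlen %/% p
      if (tlen < 1L) {
        stop("n_residual_repeats = ", config$n_residual_repeats,
             " with pool_size = ", p, " exhausts the 2500-sample axis")
      }
      cprev <- cs
    }
    layers <- c(layers, list(
      layer_bn(cprev, act = TRUE),
      layer_leadconv(8L, cprev, cprev),
      layer_bn(cprev, act = TRUE),
      layer_dropout(config$dropout_rate), layer_gap(),
      layer_dense(cprev, 2L)))
    structure(list(layers = layers, config = config,
                   n_params = count_params(layers)),
              class = "af_cnn_net")
  })
}

#' @export
print.af_cnn_net <- function(x, ...) {
  cat("Untrained temporal+lead-axis residual CNN\n")
  cat("  residual repeats (N):", x$config$n_residual_repeats,
      " parameters:", x$n_params, "\n")
  invisible(x)
}

# probability of the AF label, eval mode, batched
net_predict_prob <- function(layers, x, batch_size = 64L) {
  check_input_geometry(x)
  n <- dim(x)[3]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    xb <- fold_leads(x[, , idx, drop = FALSE])
    logits <- nn_forward(layers, xb, train = FALSE)$out
    e <- exp(logits - pmax(logits[, 1], logits[, 2]))
    out[idx] <- e[, 2] / (e[, 1] + e[, 2])
  }
  out
}

# Mann-Whitney AUC with ties counted 1/2 (midranks); shared by training
# monitoring and the DeLong estimator
auc_rank <- function(prob, is_pos) {
  m <- sum(is_pos); n <- sum(!is_pos)
  if (m == 0L || n == 0L) stop("AUC undefined: both classes must be present")
  r <- rank(prob, ties.method = "average")
  (sum(r[is_pos]) - m * (m + 1) / 2) / (m * n)
}

as_label_factor <- function(y) {
  if (inherits(y, "ecg_samples")) y <- y$manifest$label
  factor(as.character(y), levels = c("SR", "AF"))
}

#' Fit the residual CNN classifier
#'
#' Trains the network of [build_network()] with Adam on two-class
#' cross-entropy, monitors the validation AUC after every epoch, and returns
#' the parameters of the best validation epoch (early stopping after
#' `early_stop_patience` epochs without improvement).  Fully seeded: the same
#' configuration and data reproduce the same fit on one machine.
#'
#' @param x Training samples: an `ecg_samples` object or an
#'   `8 x 2500 x n` array.
#' @param y Training labels (`"AF"`/`"SR"`); taken from the manifest when `x`
#'   is an `ecg_samples` object.
#' @param x_val,y_val Validation samples and labels (patients disjoint from
#'   training).
#' @param config A [model_config()].
#' @return An object of class `af_cnn` with elements `layers` (best-epoch
#'   parameters, including batch-normalization running statistics), `config`,
#'   `history` (per-epoch loss and validation AUC), `val_auc`, `threshold`
#'   (NULL until [tune_threshold()] is applied) and `n_params`.
#' @seealso [predict.af_cnn()], [tune_n()], [tune_threshold()]
#' @export
af_cnn <- function(x, y = NULL, x_val, y_val = NULL, config = model_config()) {
  if (inherits(x, "ecg_samples")) { if (is.null(y)) y <- x$manifest$label; x <- x$x }
  if (inherits(x_val, "ecg_samples")) {
    if (is.null(y_val)) y_val <- x_val$manifest$label
    x_val <- x_val$x
  }
  check_input_geometry(x); check_input_geometry(x_val)
  y <- as_label_factor(y); y_val <- as_label_factor(y_val)
  if (anyNA(y) || anyNA(y_val)) stop("labels must be 'AF' or 'SR'")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  if (length(unique(y_val)) < 2L) stop("validation set contains a single class")
  n <- dim(x)[3]
  stopifnot(length(y) == n, length(y_val) == dim(x_val)[3])

  net <- build_network(config)
  layers <- net$layers
  with_preserved_rng(config$seed + 1L, {
    state <- vector("list", length(layers))
    t_adam <- 0L
    best <- list(auc = -Inf, layers = layers, epoch = 0L)
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       val_auc = numeric(0))
    yi <- as.integer(y)  # 1 = SR, 2 = AF
    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- fold_leads(x[, , idx, drop = FALSE])
        fw <- nn_forward(layers, xb, train = TRUE)
        layers <- fw$layers
        sx <- softmax_xent(fw$out, yi[idx])
        tot <- tot + sx$loss * length(idx)
        grads <- nn_backward(layers, fw$caches, sx$dlogits)
        t_adam <- t_adam + 1L
        up <- adam_update(layers, grads, state, config$learning_rate, t_adam)
        layers <- up$layers
        state <- up$state
      }
      pv <- net_predict_prob(layers, x_val, config$batch_size)
      va <- auc_rank(pv, y_val == "AF")
      hist <- rbind(hist, data.frame(epoch = e, loss = tot / n, val_auc = va))
      if (va > best$auc) best <- list(auc = va, layers = layers, epoch = e)
      if (e - best$epoch >= config$early_stop_patience) break
    }
    structure(list(layers = best$layers, config = config, history = hist,
                   val_auc = best$auc, best_epoch = best$epoch,
                   threshold = NULL, n_params = net$n_params,
                   levels = c("SR", "AF")),
              class = "af_cnn")
  })
}

#' Predict AF probability (or class) for new samples
#'
#' @param object A fitted [af_cnn()] model.
#' @param newdata An `ecg_samples` object or `8 x 2500 x n` array.
#' @param type `"prob"` (probability of the AF label) or `"class"`.
#' @param threshold Decision threshold for `type = "class"`; defaults to the
#'   model's tuned threshold, else 0.5.
#' @param ... Unused.
#' @return Numeric vector of AF probabilities, or a factor with levels
#'   `SR`/`AF`.
#' @export
predict.af_cnn <- function(object, newdata, type = c("prob", "class"),
                           threshold = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ecg_samples")) newdata <- newdata$x
  p <- net_predict_prob(object$layers, newdata, object$config$batch_size)
  if (type == "prob") return(p)
  th <- if (!is.null(threshold)) threshold
        else if (!is.null(object$threshold)) object$threshold else 0.5
  factor(ifelse(p >= th, "AF", "SR"), levels = c("SR", "AF"))
}

#' @export
print.af_cnn <- function(x, ...) {
  cat("Residual CNN classifier (AF vs SR label)\n")
  cat("  residual repeats (N):", x$config$n_residual_repeats,
      " parameters:", x$n_params, "\n")
  cat("  trained epochs:", nrow(x$history),
      " best epoch:", x$best_epoch,
      sprintf(" validation AUC: %.3f\n", x$val_auc))
  if (!is.null(x$threshold)) {
    cat(sprintf("  decision threshold: %.3f\n", x$threshold))
  }
  invisible(x)
}

#' @export
summary.af_cnn <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Plot the training history of a fitted model
#'
#' @param x A fitted [af_cnn()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.af_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_auc), type = "b", pch = 19,
                    lty = 1, xlab = "epoch", ylab = "value", ...)
  graphics::legend("right", legend = c("training loss", "validation AUC"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Tune the residual repetition count N on validation AUC
#'
#' Trains one model per candidate N and returns the one whose validation AUC
#' is highest; exact ties break toward the smaller N.
#'
#' @param x,y,x_val,y_val As in [af_cnn()].
#' @param n_grid Integer vector of candidate repetition counts.
#' @param config Base [model_config()]; its `n_residual_repeats` is
#'   overridden by each grid value.
#' @return List with `best_n`, `results` (data frame of N and validation
#'   AUC) and `model` (the winning fit).
#' @export
tune_n <- function(x, y = NULL, x_val, y_val = NULL, n_grid = c(1L, 2L),
                   config = model_config()) {
  if (length(n_grid) == 0L) stop("n_grid must be non-empty")
  n_grid <- as.integer(n_grid)
  fits <- vector("list", length(n_grid))
  aucs <- numeric(length(n_grid))
  for (i in seq_along(n_grid)) {
    cfg <- config
    cfg$n_residual_repeats <- n_grid[i]
    fits[[i]] <- af_cnn(x, y, x_val, y_val, cfg)
    aucs[i] <- fits[[i]]$val_auc
  }
  best <- order(-aucs, n_grid)[1L]
  stopifnot(aucs[best] >= aucs)  # winner dominates every competitor
  list(best_n = n_grid[best],
       results = data.frame(n = n_grid, val_auc = aucs),
       model = fits[[best]])
}

#' Choose a decision threshold on the ROC curve by Youden's J
#'
#' Sweeps every midpoint between adjacent distinct validation probabilities,
#' computes J = sensitivity + specificity - 1 at each cut (predicting AF when
#' probability >= threshold), and returns the maximizing cut; among ties the
#' cut with the higher sensitivity (then the smaller threshold) wins.
#'
#' @param prob Validation-set probabilities of the AF label.
#' @param labels Validation labels (`"AF"`/`"SR"`); both classes required.
#' @return List with `threshold`, `youden_j`, `sensitivity`, `specificity`.
#' @export
tune_threshold <- function(prob, labels) {
  y <- as_label_factor(labels)
  if (length(unique(y)) < 2L) stop("threshold tuning requires both classes")
  u <- sort(unique(prob))
  if (length(u) < 2L) stop("all probabilities identical; no threshold separates the classes")
  cand <- (u[-length(u)] + u[-1]) / 2
  pos <- y == "AF"
  m <- sum(pos); nneg <- sum(!pos)
  sens <- vapply(cand, function(th) sum(prob >= th & pos) / m, numeric(1))
  spec <- vapply(cand, function(th) sum(prob < th & !pos) / nneg, numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -sens, cand)[1L]
  list(threshold = cand[best], youden_j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}
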