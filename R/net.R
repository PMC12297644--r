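#' Configuration of the tabular neural classifier
#'
#' A small feed-forward classifier for 13-feature clinical records: an
#' optional 1-D convolution over the ordered feature vector (with batch
#' normalization), a 100-unit dense ReLU layer, inverted dropout, and a
#' two-way softmax output. Training is explicit mini-batch SGD with
#' classical momentum on the cross-entropy loss.
#'
#' Defaults follow the baseline setting: learning rate 0.1, 32 epochs,
#' dropout 0.243, batch size 8, momentum 0.9, 100 dense units.
#'
#' @param input_dim number of input features (13 for the Cleveland
#'   schema).
#' @param use_conv add a 1-D convolution stage (stride 1, same
#'   padding) before the dense layer.
#' @param conv_filters,conv_kernel convolution geometry.
#' @param use_batchnorm batch-normalize the convolution output
#'   (default: on whenever `use_conv`).
#' @param dense_units hidden dense width (default 100).
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param learning_rate,momentum,epochs,batch_size SGD settings.
#' @param class_weighting `"none"` or `"inverse_frequency"` (weights the
#'   loss by inverse class frequency to counter imbalance).
#' @param seed optional integer seed for initialization, shuffling and
#'   dropout; fixed seed gives bitwise-identical training runs.
#' @return an object of class `net_config`.
#' @export
net_config <- function(input_dim = 13L, use_conv = FALSE,
                       conv_filters = 16L, conv_kernel = 3L,
                       use_batchnorm = use_conv, dense_units = 100L,
                       dropout_rate = 0.243, learning_rate = 0.1,
                       momentum = 0.9, epochs = 32L, batch_size = 8L,
                       class_weighting = c("none", "inverse_frequency"),
                       seed = NULL) {
  class_weighting <- match.arg(class_weighting)
  if (!is_count(input_dim)) stopf("`input_dim` must be a positive integer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("`dropout_rate` must lie in [0, 1)")
  if (momentum < 0 || momentum >= 1) stopf("`momentum` must lie in [0, 1)")
  if (learning_rate < 0) stopf("`learning_rate` must be non-negative")
  structure(list(input_dim = as.integer(input_dim), use_conv = use_conv,
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 use_batchnorm = use_batchnorm,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, n_classes = 2L,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weighting = class_weighting, seed = seed),
            class = "net_config")
}

# He-style seeded initialization
nn_build_ <- function(config) {
  d <- config$input_dim
  p <- list()
  if (config$use_conv) {
    k <- config$conv_kernel; nf <- config$conv_filters
    p$Wc <- matrix(rnorm(k * nf, sd = sqrt(2 / k)), k, nf)
    p$bc <- numeric(nf)
    if (config$use_batchnorm) {
      p$gamma <- rep(1, nf); p$beta <- numeric(nf)
      p$run_mean <- numeric(nf); p$run_var <- rep(1, nf)
    }
    d_in <- d * nf
  } else d_in <- d
  h <- config$dense_units
  p$W1 <- matrix(rnorm(d_in * h, sd = sqrt(2 / d_in)), d_in, h)
  p$b1 <- numeric(h)
  p$W2 <- matrix(rnorm(h * 2, sd = sqrt(2 / h)), h, 2)
  p$b2 <- numeric(2)
  p
}

#' Initialize network parameters
#'
#' He-style scaled-normal weights, zero biases, batch-norm scale/shift
#' at (1, 0) and running moments at (0, 1). Seeded through
#' `config$seed`.
#'
#' @param config a [net_config()].
#' @return a named list of parameter arrays (`ModelParams`).
#' @export
nn_build <- function(config) {
  stopifnot(inherits(config, "net_config"))
  local_seed(config$seed, nn_build_(config))
}

#' Count trainable parameters
#' @param params a parameter list from [nn_build()].
#' @return integer count (running batch-norm moments excluded).
#' @export
nn_param_count <- function(params) {
  train <- setdiff(names(params), c("run_mean", "run_var"))
  sum(vapply(params[train], length, integer(1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Returns probabilities and (optionally) the cache needed
# by the backward pass. Dropout mask can be forced for gradient checks.
nn_forward_ <- function(params, X, config, training = FALSE,
                        keep_cache = FALSE, dropmask = NULL) {
  if (anyNA(X)) stopf("NaN/NA in input at row %d", which(rowSums(is.na(X)) > 0)[1])
  n <- nrow(X)
  cache <- list(X = X)
  H <- X
  if (config$use_conv) {
    k <- config$conv_kernel; nf <- config$conv_filters; L <- config$input_dim
    padl <- (k - 1) %/% 2; padr <- k - 1 - padl
    Xpad <- cbind(matrix(0, n, padl), X, matrix(0, n, padr))
    P <- matrix(0, n * L, k)               # row = (pos-1)*n + sample
    for (t in seq_len(k)) P[, t] <- as.vector(Xpad[, (1:L) + t - 1])
    C <- P %*% params$Wc + matrix(params$bc, n * L, nf, byrow = TRUE)
    cache$P <- P
    if (config$use_batchnorm) {
      if (training) {
        mu <- colMeans(C)
        va <- colMeans(C^2) - mu^2          # biased variance
      } else {
        mu <- params$run_mean; va <- params$run_var
      }
      inv_sd <- 1 / sqrt(va + 1e-5)
      xhat <- sweep(sweep(C, 2, mu), 2, inv_sd, `*`)
      C2 <- sweep(sweep(xhat, 2, params$gamma, `*`), 2, params$beta, `+`)
      cache$bn <- list(xhat = xhat, inv_sd = inv_sd, mu = mu, va = va)
    } else C2 <- C
    A <- pmax(C2, 0)
    cache$conv_pre <- C2
    A3 <- A; dim(A3) <- c(n, L, nf)
    H <- matrix(aperm(A3, c(1, 3, 2)), n, L * nf) # col = (pos-1)*nf + f
  }
  cache$H <- H
  Z1 <- H %*% params$W1 + matrix(params$b1, n, length(params$b1), byrow = TRUE)
  A1 <- pmax(Z1, 0)
  cache$Z1 <- Z1
  if (training && config$dropout_rate > 0) {
    if (is.null(dropmask))
      dropmask <- matrix(runif(length(A1)) >= config$dropout_rate,
                         nrow(A1), ncol(A1)) / (1 - config$dropout_rate)
    A1 <- A1 * dropmask
    cache$dropmask <- dropmask
  }
  cache$A1 <- A1
  logits <- A1 %*% params$W2 + matrix(params$b2, n, 2, byrow = TRUE)
  probs <- softmax_rows(logits)
  if (keep_cache) list(probs = probs, cache = cache) else probs
}

#' Forward pass: class probabilities
#'
#' Rows of the result are softmax probability vectors. Dropout is
#' applied only when `training = TRUE` (inverted dropout); batch
#' normalization uses batch statistics in training mode and running
#' moments in inference mode.
#'
#' @param params parameters from [nn_build()] or [nn_train()].
#' @param X standardized feature matrix (`input_dim` columns).
#' @param config the [net_config()].
#' @param training logical.
#' @return `nrow(X)` x 2 probability matrix.
#' @export
nn_forward <- function(params, X, config, training = FALSE) {
  nn_forward_(params, as.matrix(X), config, training = training)
}

# loss and analytic gradients on one batch; y in {0,1}; w sample weights
nn_loss_grad <- function(params, X, y, config, w = NULL, dropmask = NULL) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  fw <- nn_forward_(params, X, config, training = TRUE, keep_cache = TRUE,
                    dropmask = dropmask)
  probs <- fw$probs; cache <- fw$cache
  sw <- sum(w)
  py <- probs[cbind(seq_len(n), y + 1L)]
  loss <- -sum(w * log(pmax(py, 1e-300))) / sw

  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (probs - Y) * (w / sw)
  g <- list()
  g$W2 <- t(cache$A1) %*% dlogits
  g$b2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(params$W2)
  if (!is.null(cache$dropmask)) dA1 <- dA1 * cache$dropmask
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$W1 <- t(cache$H) %*% dZ1
  g$b1 <- colSums(dZ1)
  if (config$use_conv) {
    k <- config$conv_kernel; nf <- config$conv_filters; L <- config$input_dim
    dH <- dZ1 %*% t(params$W1)             # n x (L*nf)
    dA3 <- array(dH, c(n, nf, L))
    dA <- matrix(aperm(dA3, c(1, 3, 2)), n * L, nf)
    dC2 <- dA * (cache$conv_pre > 0)
    if (config$use_batchnorm) {
      bn <- cache$bn
      g$gamma <- colSums(dC2 * bn$xhat)
      g$beta <- colSums(dC2)
      m <- nrow(dC2)
      dxh <- sweep(dC2, 2, params$gamma, `*`)
      dC <- sweep(dxh - matrix(colMeans(dxh), m, nf, byrow = TRUE) -
                    bn$xhat * matrix(colMeans(dxh * bn$xhat), m, nf,
                                     byrow = TRUE),
                  2, bn$inv_sd, `*`)
    } else dC <- dC2
    g$Wc <- t(cache$P) %*% dC
    g$bc <- colSums(dC)
  }
  list(loss = loss, grad = g, probs = probs, bn = cache$bn)
}

nn_accuracy <- function(probs, y) mean(((probs[, 2] > probs[, 1]) * 1L) == y)

nn_loss_eval <- function(params, X, y, config, w = NULL) {
  probs <- nn_forward_(params, X, config, training = FALSE)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  py <- probs[cbind(seq_len(n), y + 1L)]
  list(loss = -sum(w * log(pmax(py, 1e-300))) / sum(w),
       acc = nn_accuracy(probs, y))
}

#' Train the classifier by mini-batch SGD with momentum
#'
#' Minimizes the (optionally class-weighted) cross-entropy. Per epoch
#' the training data is reshuffled; batch-norm running moments are
#' updated with an exponential moving average. Fully deterministic
#' under `config$seed`.
#'
#' @param config a [net_config()].
#' @param X_train,y_train standardized features and 0/1 labels.
#' @param X_val,y_val optional validation split for the report.
#' @return list with `params` (trained `ModelParams`) and `report`, a
#'   data frame of per-epoch training/validation loss and accuracy.
#' @export
nn_train <- function(config, X_train, y_train, X_val = NULL, y_val = NULL) {
  stopifnot(inherits(config, "net_config"))
  X_train <- as.matrix(X_train); y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2)
    stopf("training data contains a single class; the loss is degenerate")
  if (config$batch_size > nrow(X_train))
    stopf("`batch_size` exceeds the training-set size")
  local_seed(config$seed, {
    params <- nn_build_(config)
    w <- rep(1, nrow(X_train))
    if (config$class_weighting == "inverse_frequency") {
      tab <- table(factor(y_train, levels = 0:1))
      cw <- as.numeric(sum(tab) / (2 * tab))
      w <- cw[y_train + 1L]
    }
    vel <- lapply(params, function(p) p * 0)
    trainable <- setdiff(names(params), c("run_mean", "run_var"))
    n <- nrow(X_train)
    report <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                         train_acc = NA_real_, val_loss = NA_real_,
                         val_acc = NA_real_)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        lg <- nn_loss_grad(params, X_train[idx, , drop = FALSE],
                           y_train[idx], config, w = w[idx])
        for (nm in trainable) {
          if (is.null(lg$grad[[nm]])) next
          vel[[nm]] <- config$momentum * vel[[nm]] -
            config$learning_rate * lg$grad[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        if (config$use_conv && config$use_batchnorm &&
            config$learning_rate > 0) {
          params$run_mean <- 0.9 * params$run_mean + 0.1 * lg$bn$mu
          params$run_var <- 0.9 * params$run_var + 0.1 * lg$bn$va
        }
      }
      tr <- nn_loss_eval(params, X_train, y_train, config, w = w)
      report$train_loss[ep] <- tr$loss; report$train_acc[ep] <- tr$acc
      if (!is.null(X_val)) {
        va <- nn_loss_eval(params, as.matrix(X_val), as.integer(y_val), config)
        report$val_loss[ep] <- va$loss; report$val_acc[ep] <- va$acc
      }
    }
    attr(report, "config") <- config
    list(params = params, report = report)
  })
}

#' Standardize a feature matrix
#'
#' Column-wise centering and scaling. When `center`/`scale` are omitted
#' they are computed from `X` (training-set statistics); constant
#' columns get scale 1. The statistics are attached as attributes so a
#' stored scaler can be re-applied to new data.
#'
#' @param X numeric matrix.
#' @param center,scale optional stored statistics.
#' @return standardized matrix with `center`/`scale` attributes.
#' @export
standardize_features <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  out <- sweep(sweep(X, 2, center), 2, scale, `/`)
  attr(out, "center") <- center; attr(out, "scale") <- scale
  out
}

#' Fit the heart-disease classifier
#'
#' The user-level fitting interface: standardizes the clinical feature
#' matrix (training-set mean/variance), trains the network with
#' [nn_train()], and returns a classed model holding the parameters,
#' the scaler, and the per-epoch training report.
#'
#' @param x feature matrix or data frame (numeric, `input_dim` columns).
#' @param y 0/1 labels (1 = abnormal).
#' @param config a [net_config()]; default uses the baseline settings.
#' @param x_val,y_val optional validation split.
#' @return an object of class `heart_net`.
#' @examples
#' co <- generate_cohort(cohort_spec(n = 120, seed = 1))
#' xy <- cohort_features(co)
#' fit <- heart_net(xy$x, xy$y, net_config(epochs = 5, seed = 1))
#' table(predict(fit, xy$x), xy$y)
#' @export
heart_net <- function(x, y, config = net_config(), x_val = NULL,
                      y_val = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != config$input_dim)
    stopf("`x` has %d columns but `input_dim` is %d", ncol(x),
          config$input_dim)
  Xs <- standardize_features(x)
  ctr <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  Xv <- if (!is.null(x_val)) standardize_features(as.matrix(x_val), ctr, scl)
  fit <- nn_train(config, Xs, y, Xv, y_val)
  structure(list(params = fit$params, config = config, center = ctr,
                 scale = scl, report = fit$report,
                 classes = c(normal = 0L, abnormal = 1L)),
            class = "heart_net")
}

#' Predict from a fitted heart_net
#'
#' Features are standardized with the stored training scaler; labels
#' are the argmax class, with exact ties broken toward class 0
#' (normal).
#'
#' @param object a `heart_net`.
#' @param newdata feature matrix.
#' @param type `"class"` (0/1 vector) or `"prob"` (n x 2 matrix).
#' @param ... unused.
#' @export
predict.heart_net <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- standardize_features(as.matrix(newdata), object$center, object$scale)
  probs <- nn_forward(object$params, X, object$config, training = FALSE)
  colnames(probs) <- names(object$classes)
  if (type == "prob") probs else as.integer(probs[, 2] > probs[, 1])
}

#' @export
print.heart_net <- function(x, ...) {
  cfg <- x$config
  cat("heart_net classifier\n")
  cat("  architecture : ",
      if (cfg$use_conv) sprintf("conv1d(%d filters, kernel %d)%s -> ",
                                cfg$conv_filters, cfg$conv_kernel,
                                if (cfg$use_batchnorm) " + batchnorm" else "")
      else "", sprintf("dense(%d, relu) -> dropout(%.3g) -> softmax(2)\n",
                       cfg$dense_units, cfg$dropout_rate), sep = "")
  cat("  parameters   :", nn_param_count(x$params), "\n")
  cat("  training     :", sprintf("lr %.4g, momentum %.3g, %d epochs, batch %d\n",
      cfg$learning_rate, cfg$momentum, cfg$epochs, cfg$batch_size))
  n_ep <- nrow(x$report)
  cat("  final train  :", sprintf("loss %.4f, accuracy %.4f\n",
      x$report$train_loss[n_ep], x$report$train_acc[n_ep]))
  if (!is.na(x$report$val_acc[n_ep]))
    cat("  final valid  :", sprintf("loss %.4f, accuracy %.4f\n",
        x$report$val_loss[n_ep], x$report$val_acc[n_ep]))
  invisible(x)
}

#' @export
summary.heart_net <- function(object, ...) {
  print(object)
  cat("\nPer-epoch report (last 5):\n")
  print(tail(object$report, 5), row.names = FALSE)
  invisible(object$report)
}

#' @export
plot.heart_net <- function(x, ...) {
  rep <- x$report
  oldpar <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(oldpar))
  plot(rep$epoch, rep$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "loss", ...)
  if (!all(is.na(rep$val_loss)))
    graphics::lines(rep$epoch, rep$val_loss, lty = 2)
  plot(rep$epoch, rep$train_acc, type = "l", xlab = "epoch",
       ylab = "accuracy", main = "accuracy", ylim = c(0, 1), ...)
  if (!all(is.na(rep$val_acc)))
    graphics::lines(rep$epoch, rep$val_acc, lty = 2)
  invisible(x)
}
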