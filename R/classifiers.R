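# Classifiers operating on the selected feature columns: a small
# feed-forward network (2 hidden layers of 20 ReLU units, softmax output,
# cross-entropy loss, full-batch Adam) and a radial-basis-kernel SVM.

#' Feed-forward network configuration
#'
#' Defaults follow the study protocol this package models: 2 hidden layers
#' with 20 nodes each, trained for exactly 300 epochs. Activation, optimizer and batch
#' handling are design choices: ReLU, softmax output with cross-entropy
#' loss, Adam at learning rate 1e-3, full batch (sample sizes here are
#' tiny).
#'
#' @param hiddenLayers,nodesPerLayer network shape.
#' @param epochs training epochs (each is one full-batch update pass).
#' @param learningRate Adam step size.
#' @param seed integer seed for the weight initialization.
#' @return Named list of settings.
#' @export
dnnConfig <- function(hiddenLayers = 2, nodesPerLayer = 20, epochs = 300,
                      learningRate = 1e-3, seed = 1) {
  stopifnot2(hiddenLayers >= 1 && nodesPerLayer >= 1 && epochs >= 1,
             "network shape and epochs must be positive integers")
  list(hiddenLayers = as.integer(hiddenLayers),
       nodesPerLayer = as.integer(nodesPerLayer),
       epochs = as.integer(epochs), learningRate = learningRate,
       seed = as.integer(seed))
}

#' Train the feed-forward classifier
#'
#' @param x numeric matrix, rows = samples (features already scaled).
#' @param y two-level factor or vector of class labels.
#' @param config see [dnnConfig()].
#' @return An object of class `"DnnClassifier"` carrying the weights, the
#'   class levels, the final-epoch training accuracy (`trainAccuracy`) and
#'   the per-epoch loss curve.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 3), ncol = 2))
#' y <- rep(c("a", "b"), each = 30)
#' fit <- trainDnn(x, y, dnnConfig(epochs = 100, seed = 1))
#' fit$trainAccuracy
trainDnn <- function(x, y, config = dnnConfig()) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training matrix")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) != 2L)
    stop("training requires exactly two classes in 'y'")
  p <- ncol(x); h <- config$nodesPerLayer
  sizes <- c(p, rep(h, config$hiddenLayers), 2L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  withSeed(config$seed, {
    for (l in seq_along(W)) {   # He-normal initialization
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                             sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  tgt <- cbind(as.integer(y) == 1L, as.integer(y) == 2L) * 1
  n <- nrow(x)
  adamM <- lapply(c(W, b), function(z) z * 0)
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learningRate
  losses <- numeric(config$epochs)
  nw <- length(W)
  for (ep in seq_len(config$epochs)) {
    # forward
    acts <- vector("list", nw + 1L); acts[[1]] <- x
    for (l in seq_len(nw)) {
      z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
      acts[[l + 1L]] <- if (l < nw) pmax(z, 0) else z
    }
    z <- acts[[nw + 1L]]
    z <- z - apply(z, 1, max)
    pr <- exp(z) / rowSums(exp(z))
    losses[ep] <- -mean(log(pmax(rowSums(pr * tgt), 1e-12)))
    # backward
    delta <- (pr - tgt) / n
    gW <- vector("list", nw); gb <- vector("list", nw)
    for (l in rev(seq_len(nw))) {
      gW[[l]] <- crossprod(acts[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
    }
    # Adam update over the flattened parameter list
    grads <- c(gW, gb)
    params <- c(W, b)
    for (k in seq_along(params)) {
      adamM[[k]] <- b1 * adamM[[k]] + (1 - b1) * grads[[k]]
      adamV[[k]] <- b2 * adamV[[k]] + (1 - b2) * grads[[k]]^2
      mhat <- adamM[[k]] / (1 - b1^ep)
      vhat <- adamV[[k]] / (1 - b2^ep)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    W <- params[seq_len(nw)]; b <- params[nw + seq_len(nw)]
  }
  fit <- structure(list(W = W, b = b, levels = levels(y),
                        features = colnames(x), config = config,
                        losses = losses),
                   class = "DnnClassifier")
  fit$trainAccuracy <- mean(predictDnn(fit, x)$labels == y)
  fit
}

#' Predict with the feed-forward classifier
#'
#' @param fit a `"DnnClassifier"` from [trainDnn()].
#' @param x numeric matrix with the training feature columns.
#' @return List with `labels` (factor) and `probabilities` (rows sum to 1).
#' @export
predictDnn <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$features) && !is.null(colnames(x))) {
    if (!all(fit$features %in% colnames(x)))
      stop("feature columns do not match the trained classifier")
    x <- x[, fit$features, drop = FALSE]
  } else if (ncol(x) != nrow(fit$W[[1]]))
    stop("feature columns do not match the trained classifier")
  a <- x
  nw <- length(fit$W)
  for (l in seq_len(nw)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < nw) pmax(z, 0) else z
  }
  a <- a - apply(a, 1, max)
  pr <- exp(a) / rowSums(exp(a))
  colnames(pr) <- fit$levels
  labels <- factor(fit$levels[max.col(pr, ties.method = "first")],
                   levels = fit$levels)
  list(labels = labels, probabilities = pr)
}

#' Train a radial-basis-function SVM
#'
#' Thin wrapper around [e1071::svm()] with C-classification, cost 1 and a
#' kernel width of `1 / (n_features * mean feature variance)` by default.
#'
#' @param x numeric matrix (features scaled).
#' @param y two-level class labels.
#' @param cost soft-margin cost parameter.
#' @param gamma kernel width; `NULL` for the variance-scaled default.
#' @return An object of class `"SvmClassifier"`.
#' @export
trainSvmRbf <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) != 2L)
    stop("training requires exactly two classes in 'y'")
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(svm = fit, levels = levels(y), features = colnames(x),
                 cost = cost, gamma = gamma),
            class = "SvmClassifier")
}

#' Predict with the RBF-SVM
#'
#' @param fit an `"SvmClassifier"` from [trainSvmRbf()].
#' @param x numeric matrix with the training feature columns.
#' @return Factor of predicted labels.
#' @export
predictSvmRbf <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$features) && !is.null(colnames(x)))
    x <- x[, fit$features, drop = FALSE]
  factor(as.character(predict(fit$svm, x)), levels = fit$levels)
}
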