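# Neural network with weighted fuzzy membership functions (NEWFM):
# per-feature, per-class weighted triangular fuzzy sets trained by online
# apex/weight updates; features ranked by the non-overlapping area between
# the two class-conditional bounded-sum curves; backward elimination driven
# by the ranks with a held-out stopping rule.

#' NEWFM training configuration
#'
#' @param m number of triangular membership functions per feature and class.
#' @param alpha apex learning rate (`v <- v + alpha * (x - v)` for the
#'   winning function of the sample's class).
#' @param beta weight learning rate (reinforce the winner of the own class,
#'   weaken the winner of the other class, both clamped to `[0, 1]`).
#' @param epochs passes over the training samples.
#' @param minFeatures hard floor of the backward elimination.
#' @param innerFraction held-out fraction of the stratified inner split used
#'   by the elimination stopping rule.
#' @return A named list of settings.
#' @export
newfmConfig <- function(m = 3, alpha = 0.05, beta = 0.01, epochs = 100,
                        minFeatures = 2, innerFraction = 0.2) {
  stopifnot2(m >= 1 && alpha >= 0 && beta >= 0 && epochs >= 0,
             "invalid NEWFM configuration")
  list(m = as.integer(m), alpha = alpha, beta = beta,
       epochs = as.integer(epochs), minFeatures = as.integer(minFeatures),
       innerFraction = innerFraction)
}

# min-max scaler fitted on training data; degenerate (constant) features map
# to the centre of the unit interval and are flagged
.fitScaler <- function(x) {
  mn <- apply(x, 2, min); rg <- apply(x, 2, max) - mn
  list(min = mn, range = rg)
}

.applyScaler <- function(scaler, x) {
  xs <- sweep(x, 2, scaler$min)
  rg <- ifelse(scaler$range > 0, scaler$range, 1)
  xs <- sweep(xs, 2, rg, "/")
  xs[, scaler$range == 0] <- 0.5
  xs
}

# initial model: m apexes evenly spaced over the scaled range, weights 0.5
.initWfm <- function(features, classes, m) {
  apexes <- if (m == 1) 0.5 else seq(0, 1, length.out = m)
  apex <- matrix(rep(apexes, length(features)),
                 nrow = m, ncol = length(features))
  w <- matrix(0.5, nrow = m, ncol = length(features))
  list(apex = setNames(list(apex, apex), classes),
       weight = setNames(list(w, w), classes))
}

#' Train a NEWFM model
#'
#' Features are min-max scaled to `[0, 1]` on the training data (the scaler
#' travels with the model). For every training sample and feature, the
#' maximally responding membership function of the sample's own class moves
#' its apex toward the value and gains weight; the winner of the other class
#' loses weight. Feet are re-derived from the sorted neighbouring apexes
#' after each epoch. Training is deterministic given the sample order.
#'
#' @param x numeric matrix (rows = samples).
#' @param y two-level factor or vector of class labels.
#' @param config see [newfmConfig()].
#' @return A [WfmModel-class].
#' @export
#' @examples
#' x <- matrix(c(rep(0.1, 20), rep(0.9, 20)), ncol = 1)
#' y <- rep(c("a", "b"), each = 20)
#' fit <- trainNewfm(x, y, newfmConfig(epochs = 50))
#' featureScores(fit)
trainNewfm <- function(x, y, config = newfmConfig()) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) != 2L)
    stop("NEWFM training requires exactly two classes in 'y'")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  scaler <- .fitScaler(x)
  xs <- .applyScaler(scaler, x)
  init <- .initWfm(colnames(x), levels(y), config$m)
  fit <- newfm_train_cpp(xs, as.integer(y) - 1L,
                         init$apex[[1]], init$apex[[2]],
                         init$weight[[1]], init$weight[[2]],
                         config$alpha, config$beta, config$epochs)
  new("WfmModel", features = colnames(x), classes = levels(y),
      apex = setNames(list(fit$a0, fit$a1), levels(y)),
      weight = setNames(list(fit$w0, fit$w1), levels(y)),
      scaler = scaler, degenerate = unname(scaler$range == 0),
      config = config)
}

# feet from sorted apexes: neighbouring apexes, outermost one spacing beyond
.feet <- function(v) {
  m <- length(v)
  span <- if (m > 1) max(v[m] - v[1], 1e-6) / (m - 1) else 0.5
  l <- c(if (m > 1) v[1] - span else v - span, v[-m])
  r <- c(v[-1], if (m > 1) v[m] + span else v + span)
  l <- pmin(l, v - 1e-6); r <- pmax(r, v + 1e-6)
  list(l = l, r = r)
}

.triMemb <- function(xs, l, v, r) {
  up <- (xs - l) / (v - l); dn <- (r - xs) / (r - v)
  mu <- pmin(up, dn)
  mu[xs <= l | xs >= r] <- 0
  mu[xs == v] <- 1
  pmin(pmax(mu, 0), 1)
}

# bounded-sum curve for one feature/class at scaled positions xs
.bswfmScaled <- function(model, j, class, xs) {
  v <- model@apex[[class]][, j]; w <- model@weight[[class]][, j]
  ft <- .feet(v)
  acc <- 0
  for (i in seq_along(v)) acc <- acc + w[i] * .triMemb(xs, ft$l[i], v[i], ft$r[i])
  pmin(acc, 1)
}

#' Bounded sum of weighted fuzzy membership functions
#'
#' Evaluates the class-conditional membership curve of one feature: the
#' weighted sum of its triangular membership functions capped at 1,
#' piecewise linear between breakpoints, and 0 beyond all feet.
#'
#' @param model a [WfmModel-class].
#' @param feature feature name or index.
#' @param class class label.
#' @param x numeric vector of raw (unscaled) feature values.
#' @return Membership values in `[0, 1]`.
#' @export
bswfm <- function(model, feature, class, x) {
  j <- if (is.character(feature)) match(feature, model@features)
       else as.integer(feature)
  stopifnot2(!is.na(j) && j >= 1 && j <= length(model@features),
             "unknown feature")
  class <- as.character(class)
  stopifnot2(class %in% model@classes, "unknown class")
  rg <- if (model@scaler$range[[j]] > 0) model@scaler$range[[j]] else 1
  xs <- (x - model@scaler$min[[j]]) / rg
  if (model@degenerate[j]) xs <- rep(0.5, length(x))
  unname(.bswfmScaled(model, j, class, xs))
}

#' Non-overlap feature scores and ranks
#'
#' On a uniform 256-point grid over each feature's (scaled) range, computes
#' the overlapping area `O` (integral of the pointwise minimum of the two
#' class curves) and total area `T` (integral of the maximum) by the
#' trapezoid rule. The score `(T - O) / T` is 1 for perfectly separated
#' class curves and 0 for identical ones (or when `T = 0`). Ranks are by
#' descending score; ties break by ascending feature index.
#'
#' @param model a [WfmModel-class].
#' @param gridSize number of grid points (default 256).
#' @return data.frame with `feature`, `score`, `rank`.
#' @export
featureScores <- function(model, gridSize = 256) {
  xs <- seq(0, 1, length.out = gridSize)
  p <- length(model@features)
  score <- numeric(p)
  for (j in seq_len(p)) {
    if (model@degenerate[j]) { score[j] <- 0; next }
    b0 <- .bswfmScaled(model, j, model@classes[1], xs)
    b1 <- .bswfmScaled(model, j, model@classes[2], xs)
    trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) / (gridSize - 1)
    O <- trap(pmin(b0, b1)); Tt <- trap(pmax(b0, b1))
    score[j] <- if (Tt > 0) (Tt - O) / Tt else 0
  }
  rank <- integer(p)
  rank[order(-score, seq_len(p))] <- seq_len(p)
  data.frame(feature = model@features, score = score, rank = rank)
}

#' Classify samples with a trained NEWFM model
#'
#' The score of a class is the mean over the active features of the
#' bounded-sum membership of the sample's value; the predicted class is the
#' argmax, with ties going to the first class level.
#'
#' @param model a [WfmModel-class].
#' @param x numeric matrix with the model's feature columns (raw scale).
#' @return Factor of predicted labels; class scores in attribute
#'   `"scores"`.
#' @export
classifyNewfm <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)))
    x <- x[, model@features, drop = FALSE]
  xs <- .applyScaler(model@scaler, x)
  n <- nrow(xs); p <- length(model@features)
  s <- matrix(0, n, 2, dimnames = list(NULL, model@classes))
  for (j in seq_len(p)) {
    s[, 1] <- s[, 1] + .bswfmScaled(model, j, model@classes[1], xs[, j])
    s[, 2] <- s[, 2] + .bswfmScaled(model, j, model@classes[2], xs[, j])
  }
  s <- s / p
  pred <- factor(model@classes[ifelse(s[, 2] > s[, 1], 2L, 1L)],
                 levels = model@classes)
  attr(pred, "scores") <- s
  pred
}

# stratified index of the held-out inner-validation rows
.stratifiedHoldout <- function(y, fraction, seed) {
  withSeed(seed, {
    idx <- unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      take <- max(1L, round(length(rows) * fraction))
      sample(rows, take)
    }))
    sort(idx)
  })
}

#' Backward feature elimination driven by NEWFM ranks
#'
#' Repeatedly trains NEWFM on the active feature set, ranks the features by
#' non-overlap score, measures classification accuracy on a stratified
#' held-out split (drawn once per call from `seed`), and deletes the
#' lowest-ranked feature. When a deletion lowers the held-out accuracy the
#' feature is restored and the search stops; at most
#' `config$minFeatures` features always survive. The full path is returned
#' for averaged-rank importance.
#'
#' @param x numeric matrix (rows = samples), at least 2 feature columns.
#' @param y two-level class labels.
#' @param config see [newfmConfig()].
#' @param seed integer seed for the inner split.
#' @return A list of class `"EliminationPath"` with elements `steps` (one
#'   per accepted model: `active`, `ranks`, `accuracy`), `selected` (the
#'   surviving feature set) and `rejected` (the step that triggered the
#'   stop, or `NULL`).
#' @export
backwardEliminate <- function(x, y, config = newfmConfig(), seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  stopifnot2(ncol(x) >= 2, "backward elimination needs at least 2 features")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  holdIdx <- .stratifiedHoldout(y, config$innerFraction, seed)
  trIdx <- setdiff(seq_len(nrow(x)), holdIdx)
  active <- colnames(x)
  steps <- list(); prevAcc <- -Inf; rejected <- NULL
  repeat {
    fit <- trainNewfm(x[trIdx, active, drop = FALSE], y[trIdx], config)
    sc <- featureScores(fit)
    pred <- classifyNewfm(fit, x[holdIdx, active, drop = FALSE])
    acc <- mean(pred == y[holdIdx])
    step <- list(active = active,
                 ranks = setNames(sc$rank, sc$feature),
                 accuracy = acc)
    if (acc < prevAcc) {            # deletion hurt: restore and stop
      rejected <- step
      active <- steps[[length(steps)]]$active
      break
    }
    steps[[length(steps) + 1L]] <- step
    prevAcc <- acc
    if (length(active) <= config$minFeatures) break
    worst <- sc$feature[which.max(sc$rank)]
    active <- setdiff(active, worst)
  }
  structure(list(steps = steps, selected = active, rejected = rejected),
            class = "EliminationPath")
}

#' @export
print.EliminationPath <- function(x, ...) {
  accs <- vapply(x$steps, `[[`, 0, "accuracy")
  cat(sprintf("EliminationPath: %d accepted steps, %d -> %d features, inner accuracy %.3f -> %.3f\n",
              length(x$steps), length(x$steps[[1]]$active),
              length(x$selected), accs[1], accs[length(accs)]))
  invisible(x)
}

#' Plot the two class membership curves of one feature
#'
#' Draws the bounded-sum curves of both classes over the feature's observed
#' range; the white area where the curves do not overlap is what drives the
#' feature's non-overlap score.
#'
#' @param model a [WfmModel-class].
#' @param feature feature name or index.
#' @param n grid resolution.
#' @export
plotMembership <- function(model, feature, n = 256) {
  j <- if (is.character(feature)) match(feature, model@features)
       else as.integer(feature)
  rg <- model@scaler$range[j]; mn <- model@scaler$min[j]
  xr <- mn + seq(0, 1, length.out = n) * ifelse(rg > 0, rg, 1)
  b0 <- .bswfmScaled(model, j, model@classes[1], seq(0, 1, length.out = n))
  b1 <- .bswfmScaled(model, j, model@classes[2], seq(0, 1, length.out = n))
  graphics::plot(xr, b0, type = "l", col = "firebrick", lwd = 2,
                 ylim = c(0, 1), xlab = model@features[j],
                 ylab = "bounded-sum membership")
  graphics::lines(xr, b1, col = "steelblue", lwd = 2)
  graphics::legend("topright", legend = model@classes, lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(NULL)
}

#' Serialize a NEWFM model to JSON
#'
#' @param model a [WfmModel-class].
#' @param path output file.
#' @export
writeWfmModel <- function(model, path) {
  obj <- list(features = model@features, classes = model@classes,
              apex = lapply(model@apex, unclass),
              weight = lapply(model@weight, unclass),
              scaler = model@scaler, degenerate = model@degenerate,
              config = model@config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
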