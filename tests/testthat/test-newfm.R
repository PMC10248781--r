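test_that("zero learning rates leave the initial model untouched", {
  d <- gaussToy(n = 40, shifts = c(0, 10), seed = 2)
  fit <- trainNewfm(d$x, d$y, newfmConfig(alpha = 0, beta = 0, epochs = 25))
  for (cl in fit@classes) {
    expect_equal(unname(fit@apex[[cl]]),
                 matrix(c(0, 0.5, 1), 3, 2), tolerance = 1e-12)
    expect_true(all(fit@weight[[cl]] == 0.5))
  }
})

test_that("apexes converge to concentrated class values", {
  x <- matrix(c(rep(0.1, 25), rep(0.9, 25)), ncol = 1)
  colnames(x) <- "f"
  y <- rep(c("lo", "hi"), each = 25)
  fit <- trainNewfm(x, y, newfmConfig(epochs = 50))
  # scalar recurrence oracle: v <- v + alpha (x - v), 50 epochs x 25 samples
  v <- 0; for (i in seq_len(50 * 25)) v <- v + 0.05 * (0 - v)
  domIdx <- which.max(fit@weight[["lo"]][, 1])
  rawApex <- fit@scaler$min["f"] +
    fit@apex[["lo"]][domIdx, 1] * fit@scaler$range["f"]
  expect_lt(abs(rawApex - 0.1), 0.05)
  expect_lt(abs(fit@apex[["lo"]][domIdx, 1] - v), 1e-6)
  expect_equal(mean(classifyNewfm(fit, x) == y), 1)
})

test_that("weights stay inside the unit interval under training", {
  for (s in 1:5) {
    d <- gaussToy(n = 50, shifts = c(1, 0.2, 0), seed = s)
    fit <- trainNewfm(d$x, d$y, newfmConfig(epochs = 40))
    for (cl in fit@classes) {
      expect_true(all(fit@weight[[cl]] >= 0 & fit@weight[[cl]] <= 1))
      expect_true(all(diff(fit@apex[[cl]]) >= 0))  # canonical sorted form
    }
  }
})

test_that("bounded-sum curves match the brute-force oracle on a fine grid", {
  d <- gaussToy(n = 80, shifts = c(1.5, 0.3), seed = 3)
  fit <- trainNewfm(d$x, d$y)
  xs <- seq(0, 1, length.out = 2560)
  for (j in 1:2) for (cl in fit@classes) {
    got <- phenofuzz:::.bswfmScaled(fit, j, cl, xs)
    want <- bswfmOracle(fit, j, cl, xs)
    expect_lt(max(abs(got - want)), 1e-6)
    expect_true(all(got >= 0 & got <= 1))
  }
  # raw-scale interface: beyond all feet the membership is zero
  far <- max(d$x[, 1]) + 10 * diff(range(d$x[, 1]))
  expect_equal(bswfm(fit, "f1", fit@classes[1], far), 0)
})

test_that("non-overlap scores separate informative from null features", {
  d <- gaussToy(n = 60, shifts = c(0, 0), seed = 4)
  fit <- trainNewfm(d$x, d$y, newfmConfig(alpha = 0, beta = 0))
  sc <- featureScores(fit)
  expect_equal(sc$score, c(0, 0))          # identical class curves
  expect_identical(sort(sc$rank), 1:2)     # ranks are a permutation
  # disjoint class supports built by hand -> score 1
  sep <- new("WfmModel", features = "f", classes = c("a", "b"),
             apex = list(a = matrix(c(0.05, 0.1, 0.15), 3),
                         b = matrix(c(0.85, 0.9, 0.95), 3)),
             weight = list(a = matrix(1, 3), b = matrix(1, 3)),
             scaler = list(min = c(f = 0), range = c(f = 1)),
             degenerate = FALSE, config = newfmConfig())
  expect_equal(featureScores(sep)$score, 1, tolerance = 1e-9)
})

test_that("a strong effect outranks a weak one in almost every run", {
  wins <- 0
  for (s in 1:100) {
    d <- gaussToy(n = 60, shifts = c(2, 0.2), seed = s)
    sc <- featureScores(trainNewfm(d$x, d$y))
    wins <- wins + (sc$rank[1] < sc$rank[2])
  }
  expect_gte(wins, 95)
})

test_that("rank expectation responds monotonically to effect size", {
  rankAt <- function(d) mean(vapply(1:20, function(s) {
    toy <- gaussToy(n = 60, shifts = c(d, 0.5, 0.5), seed = 300 + s)
    sc <- featureScores(trainNewfm(toy$x, toy$y))
    sc$rank[1]
  }, 0))
  expect_lte(rankAt(1.5), rankAt(0.5))
})

test_that("class scores are symmetric under label swap", {
  d <- gaussToy(n = 60, shifts = c(1.2, 0.4), seed = 6)
  f1 <- trainNewfm(d$x, d$y)
  ySwap <- factor(ifelse(d$y == "a", "b", "a"), levels = c("a", "b"))
  f2 <- trainNewfm(d$x, ySwap)
  expect_equal(unname(f1@apex[["a"]]), unname(f2@apex[["b"]]))
  expect_equal(unname(f1@weight[["b"]]), unname(f2@weight[["a"]]))
})

test_that("backward elimination keeps the informative feature", {
  kept <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- cbind(c(rnorm(30, 0), rnorm(30, 3)),
               matrix(rnorm(60 * 5), 60, 5))
    colnames(x) <- c("signal", paste0("noise", 1:5))
    y <- rep(c("a", "b"), each = 30)
    path <- backwardEliminate(x, y, newfmConfig(), seed = s)
    kept <- kept + ("signal" %in% path$selected)
  }
  expect_gte(kept, 95)
})

test_that("elimination paths are single-deletion and accuracy-monotone", {
  d <- gaussToy(n = 90, shifts = c(2, 1, 0.5, 0, 0), seed = 8)
  path <- backwardEliminate(d$x, d$y, newfmConfig(), seed = 8)
  sizes <- vapply(path$steps, function(s) length(s$active), 0L)
  expect_true(all(diff(sizes) == -1))
  accs <- vapply(path$steps, `[[`, 0, "accuracy")
  expect_true(all(diff(accs) >= 0))
  expect_gte(length(path$selected), 2)     # hard floor
  for (st in path$steps)
    expect_identical(sort(unname(st$ranks)), seq_along(st$active))
  expect_error(backwardEliminate(d$x[, 1, drop = FALSE], d$y),
               "at least 2")
})

test_that("degenerate constant features are flagged and score zero", {
  x <- cbind(flat = rep(1, 40), good = c(rnorm(20), rnorm(20, 2)))
  y <- rep(c("a", "b"), each = 20)
  fit <- trainNewfm(x, y)
  expect_true(fit@degenerate[1])
  sc <- featureScores(fit)
  expect_equal(sc$score[sc$feature == "flat"], 0)
  expect_error(trainNewfm(x[1:20, ], y[1:20]), "two classes")
})

test_that("models serialize to JSON and reload consistently", {
  d <- gaussToy(seed = 10)
  fit <- trainNewfm(d$x, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  writeWfmModel(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$features, fit@features)
  expect_equal(unname(as.matrix(back$weight$a)), unname(fit@weight[["a"]]),
               tolerance = 1e-12)
})

test_that("elimination paths export one row per active feature and step", {
  d <- gaussToy(n = 60, shifts = c(2, 0.5, 0), seed = 15)
  path <- backwardEliminate(d$x, d$y, newfmConfig(), seed = 15)
  file <- withr::local_tempfile(fileext = ".csv")
  writeEliminationPath(path, file)
  got <- read.csv(file)
  expect_identical(nrow(got),
                   sum(vapply(path$steps, function(s) length(s$active), 0L)))
  expect_identical(colnames(got), c("step", "feature", "rank", "accuracy"))
})
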