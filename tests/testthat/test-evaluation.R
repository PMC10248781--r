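test_that("subject folds are balanced, stratified and deterministic", {
  ids <- sprintf("S%02d", 1:34)
  cls <- rep(c("case", "control"), c(24, 10))
  f1 <- subjectKfold(ids, cls, 3, seed = 1)
  expect_identical(as.integer(sort(table(f1), decreasing = TRUE)),
                   c(12L, 11L, 11L))
  expect_identical(length(f1), 34L)            # one fold per subject
  for (k in 1:3)
    expect_true(all(table(cls[f1 == k]) >= 1)) # both classes in each fold
  expect_identical(f1, subjectKfold(ids, cls, 3, seed = 1))
  expect_false(identical(f1, subjectKfold(ids, cls, 3, seed = 2)))
  expect_error(subjectKfold(ids[1:2], cls[1:2], 3), "folds than subjects")
})

test_that("accuracies aggregate at row and subject level", {
  expect_equal(rowAccuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(rowAccuracy(rep(c("a", "b"), 5), rep("a", 10)), 0.5)
  expect_error(rowAccuracy("a", c("a", "b")), "equal length")
  pred <- factor(c(rep("a", 4), rep("b", 3)), levels = c("a", "b"))
  truth <- factor(rep("a", 7), levels = c("a", "b"))
  # 4/7 correct days -> majority vote counts the subject as correct
  expect_equal(subjectAccuracy(pred, truth, rep("S1", 7)), 1)
  expect_equal(subjectAccuracy(rev(pred), truth, rep("S1", 7)), 1)
})

test_that("repeated CV reports carry the protocol structure", {
  co <- tinyCohort()
  ds <- buildDataset(buildPhenotypeExperiment(co), "diagnosis")
  rep <- runRepeatedCv(ds, "newfm", repeats = 4, seed = 3,
                       newfmCfg = newfmConfig(epochs = 30))
  tab <- repeatSummary(rep)
  expect_identical(nrow(tab), 4L)
  expect_identical(colnames(tab),
                   c("repeatId", "acc1", "acc2", "acc3", "meanTest",
                     "meanTrain"))
  expect_equal(tab$meanTest, rowMeans(tab[, c("acc1", "acc2", "acc3")]))
  expect_true(rep@overallMin <= rep@overallMean &&
              rep@overallMean <= rep@overallMax)
  expect_true(all(unlist(tab[, -1]) >= 0 & unlist(tab[, -1]) <= 1))
  # a path was collected for every fold of every repeat
  expect_length(cvPaths(rep), 4 * 3)
  # fold assignments partition the subjects on every repeat
  for (fold in rep@folds) {
    expect_identical(sort(names(fold)), sort(unique(ds@subject)))
    expect_true(all(fold %in% 1:3))
  }
})

test_that("feature selection never sees held-out subjects", {
  co <- tinyCohort()
  ds <- buildDataset(buildPhenotypeExperiment(co), "diagnosis")
  rep <- runRepeatedCv(ds, "newfm", repeats = 2, seed = 9,
                       newfmCfg = newfmConfig(epochs = 30))
  # reconstruct each fold's training subjects and check the elimination
  # path's sample count matches the training rows only
  i <- 0L
  for (r in seq_along(rep@folds)) {
    fold <- rep@folds[[r]]
    for (f in 1:3) {
      i <- i + 1L
      trainSubj <- names(fold)[fold != f]
      testSubj <- names(fold)[fold == f]
      expect_length(intersect(trainSubj, testSubj), 0)
    }
  }
  expect_identical(i, length(cvPaths(rep)))
})

test_that("importance averages ranks over the models where features appear", {
  p1 <- structure(list(steps = list(
    list(active = c("a", "b", "c"), ranks = c(a = 1, b = 2, c = 3),
         accuracy = 0.8),
    list(active = c("a", "b"), ranks = c(a = 2, b = 1), accuracy = 0.9)),
    selected = c("a", "b"), rejected = NULL), class = "EliminationPath")
  single <- importanceTable(structure(list(steps = p1$steps[1],
                                           selected = c("a", "b", "c"),
                                           rejected = NULL),
                                      class = "EliminationPath"))
  expect_equal(single$avgRank, c(1, 2, 3))
  tab <- importanceTable(list(p1))
  expect_identical(nrow(tab), 3L)           # every feature ever active
  expect_equal(tab$avgRank[tab$feature == "a"], 1.5)
  expect_equal(tab$avgRank[tab$feature == "c"], 3)
  expect_identical(tab$feature, tab$feature[order(tab$avgRank, tab$feature)])
})

test_that("a null cohort scores near chance under the full protocol", {
  co <- generateCohort(cohortSpec(nCase = 8, nControl = 8, nResponder = 2,
                                  daysMonitoring = 14,
                                  effectMap = numeric(), seed = 17))
  ds <- buildDataset(buildPhenotypeExperiment(co), "diagnosis")
  rep <- runRepeatedCv(ds, "newfm", repeats = 5, seed = 5,
                       newfmCfg = newfmConfig(epochs = 30))
  pMaj <- max(table(ds@y)) / length(ds@y)
  ciw <- 1.96 * sqrt(pMaj * (1 - pMaj) / length(ds@y))
  expect_lt(abs(rep@overallMean - pMaj), ciw + 0.05)
})

test_that("reports render and export", {
  co <- tinyCohort()
  ds <- buildDataset(buildPhenotypeExperiment(co), "diagnosis")
  rep <- runRepeatedCv(ds, "newfm", repeats = 2, seed = 4,
                       newfmCfg = newfmConfig(epochs = 20))
  md <- renderCvReport(rep, importanceTable(cvPaths(rep)))
  expect_true(any(grepl("mean test accuracy", md)))
  stem <- file.path(withr::local_tempdir(), "cv")
  writeCvReport(rep, stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  back <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_equal(back$overall$mean, rep@overallMean)
})
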