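# Subject-level repeated 3-fold validation, accuracy aggregation and
# averaged-rank feature importance.

#' Subject-level, class-stratified k-fold assignment
#'
#' Subjects are shuffled by `seed` within class and dealt greedily to the
#' currently smallest fold, so fold subject counts never differ by more
#' than 1 and classes spread as evenly as the counts allow. Every
#' subject-day row inherits its subject's fold, which is what prevents
#' identity leakage between training and test folds.
#'
#' @param subjectIds character vector of unique subject ids.
#' @param classLabels class label per subject (same length).
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return Named integer vector: fold (1..k) per subject.
#' @export
#' @examples
#' f <- subjectKfold(sprintf("S%02d", 1:34),
#'                   rep(c("case", "control"), c(24, 10)), k = 3, seed = 1)
#' table(f)  # 12 / 11 / 11
subjectKfold <- function(subjectIds, classLabels, k = 3, seed = 1) {
  stopifnot2(length(subjectIds) == length(classLabels),
             "one class label per subject is required")
  stopifnot2(!anyDuplicated(subjectIds), "subject ids must be unique")
  if (k > length(subjectIds))
    stop("cannot form more folds than subjects")
  fold <- setNames(integer(length(subjectIds)), subjectIds)
  sizes <- integer(k)
  withSeed(seed, {
    classes <- names(sort(-table(classLabels)))
    for (cl in classes) {
      members <- sample(subjectIds[classLabels == cl])
      for (s in members) {
        tgt <- which.min(sizes)
        fold[s] <- tgt
        sizes[tgt] <- sizes[tgt] + 1L
      }
    }
  })
  fold
}

#' Row-level classification accuracy
#'
#' @param predictions,labels equal-length factors or vectors.
#' @return Proportion of correct predictions.
#' @export
rowAccuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  mean(as.character(predictions) == as.character(labels))
}

#' Subject-level accuracy by per-subject majority vote
#'
#' Each subject's predicted label is the mode of its row predictions (ties
#' go to the first factor level); a subject is counted correct when the
#' voted label matches its true label.
#'
#' @param predictions factor of row predictions.
#' @param labels true row labels (constant within subject).
#' @param subject subject id per row.
#' @return Proportion of correctly voted subjects.
#' @export
subjectAccuracy <- function(predictions, labels, subject) {
  if (length(predictions) != length(labels) ||
      length(labels) != length(subject))
    stop("predictions, labels and subject must have equal length")
  lv <- if (is.factor(predictions)) levels(predictions)
        else sort(unique(as.character(predictions)))
  ok <- vapply(split(seq_along(subject), subject), function(rows) {
    counts <- table(factor(as.character(predictions[rows]), levels = lv))
    voted <- lv[which.max(counts)]   # tie -> first level
    voted == as.character(labels[rows[1]])
  }, TRUE)
  mean(ok)
}

# one fold fit: NEWFM selection on the training rows only, then the outer
# classifier on the selected (min-max scaled) columns
.fitFold <- function(x, y, trainRows, testRows, classifier, select,
                     newfmCfg, dnnCfg, svmCost, svmGamma, seed) {
  xtr <- x[trainRows, , drop = FALSE]; ytr <- droplevels(y[trainRows])
  path <- NULL
  cols <- colnames(x)
  if (select) {
    path <- backwardEliminate(xtr, ytr, newfmCfg, seed = seed)
    cols <- path$selected
  }
  scaler <- .fitScaler(xtr[, cols, drop = FALSE])
  str <- .applyScaler(scaler, xtr[, cols, drop = FALSE])
  ste <- .applyScaler(scaler, x[testRows, cols, drop = FALSE])
  if (classifier == "dnn") {
    cfg <- dnnCfg; cfg$seed <- seed
    fit <- trainDnn(str, ytr, cfg)
    predTr <- predictDnn(fit, str)$labels
    predTe <- predictDnn(fit, ste)$labels
  } else if (classifier == "svm") {
    fit <- trainSvmRbf(str, ytr, cost = svmCost, gamma = svmGamma)
    predTr <- predictSvmRbf(fit, str)
    predTe <- predictSvmRbf(fit, ste)
  } else {
    fit <- trainNewfm(str, ytr, newfmCfg)
    predTr <- classifyNewfm(fit, str)
    predTe <- classifyNewfm(fit, ste)
  }
  list(trainAcc = rowAccuracy(predTr, ytr),
       testAcc = rowAccuracy(predTe, y[testRows]),
       predictions = predTe, path = path)
}

#' Repeated subject-level k-fold cross-validation
#'
#' For every repeat a fresh subject-level fold assignment is drawn; within
#' each fold, NEWFM backward elimination runs on the two training folds
#' only, the outer classifier is trained on the selected columns, and
#' accuracy is measured on the held-out fold. A repeat whose draw leaves a
#' test fold with a single class is re-drawn with the next sub-seed (and a
#' message is emitted). The report carries the k fold accuracies and their
#' mean per repeat, the mean training accuracy, and the overall
#' mean/maximum/minimum of the repeat means.
#'
#' @param dataset a [PhenoDataset-class].
#' @param classifier `"dnn"`, `"svm"` or `"newfm"`.
#' @param k folds (default 3).
#' @param repeats repeats (default 10).
#' @param seed integer seed.
#' @param select run NEWFM backward elimination inside each training fold.
#' @param newfmCfg,dnnCfg,svmCost,svmGamma model settings.
#' @return A [CvReport-class].
#' @export
runRepeatedCv <- function(dataset, classifier = c("dnn", "svm", "newfm"),
                          k = 3, repeats = 10, seed = 1, select = TRUE,
                          newfmCfg = newfmConfig(), dnnCfg = dnnConfig(),
                          svmCost = 1, svmGamma = NULL) {
  classifier <- match.arg(classifier)
  x <- dataset@x; y <- dataset@y; subject <- dataset@subject
  subjects <- unique(subject)
  subjClass <- vapply(subjects,
                      function(s) as.character(y[match(s, subject)]), "")
  paths <- list(); foldList <- list()
  rep_rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    attempt <- 0L
    repeat {
      fold <- subjectKfold(subjects, subjClass, k,
                           seed = subSeed(seed, r, attempt))
      rowFold <- fold[subject]
      ok <- all(vapply(seq_len(k), function(f)
        nlevels(droplevels(y[rowFold == f])) == 2L, TRUE))
      if (ok) break
      attempt <- attempt + 1L
      message(sprintf("repeat %d: single-class fold drawn, re-drawing (attempt %d)",
                      r, attempt))
      if (attempt > 50L) stop("could not draw folds with both classes present")
    }
    foldList[[r]] <- fold
    testAcc <- numeric(k); trainAcc <- numeric(k)
    for (f in seq_len(k)) {
      res <- .fitFold(x, y, which(rowFold != f), which(rowFold == f),
                      classifier, select, newfmCfg, dnnCfg, svmCost,
                      svmGamma, seed = subSeed(seed, r, f, 7))
      testAcc[f] <- res$testAcc; trainAcc[f] <- res$trainAcc
      if (!is.null(res$path)) paths[[length(paths) + 1L]] <- res$path
    }
    rep_rows[[r]] <- c(repeatId = r, setNames(testAcc, paste0("acc", seq_len(k))),
                       meanTest = mean(testAcc), meanTrain = mean(trainAcc))
  }
  repDf <- as.data.frame(do.call(rbind, rep_rows))
  new("CvReport", task = dataset@task, classifier = classifier,
      repeats = repDf,
      overallMean = mean(repDf$meanTest),
      overallMax = max(repDf$meanTest),
      overallMin = min(repDf$meanTest),
      paths = paths, folds = foldList)
}

#' Averaged-rank feature importance
#'
#' For every feature, averages its NEWFM rank over every elimination step
#' (across all folds and repeats) in which the feature was active. Lower
#' averaged rank means more important. The table is sorted ascending, ties
#' broken by feature name.
#'
#' @param paths list of `"EliminationPath"` objects (e.g. [cvPaths()] of a
#'   [CvReport-class]), or a single path.
#' @return data.frame with `feature`, `avgRank`, `nModels`.
#' @export
importanceTable <- function(paths) {
  if (inherits(paths, "EliminationPath")) paths <- list(paths)
  stopifnot2(length(paths) >= 1, "at least one elimination path is required")
  acc <- list()
  for (p in paths) for (st in p$steps) for (f in st$active) {
    acc[[f]] <- c(acc[[f]], st$ranks[[f]])
  }
  df <- data.frame(feature = names(acc),
                   avgRank = vapply(acc, mean, 0),
                   nModels = vapply(acc, length, 0L))
  df <- df[order(df$avgRank, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Render a CvReport and importance table as a small markdown report
#'
#' @param report a [CvReport-class].
#' @param importance optional data.frame from [importanceTable()].
#' @return Character vector of markdown lines.
#' @export
renderCvReport <- function(report, importance = NULL) {
  out <- c(sprintf("## %s task — %s classifier", report@task,
                   report@classifier),
           "",
           sprintf("- repeats: %d", nrow(report@repeats)),
           sprintf("- mean test accuracy: %.3f (min %.3f, max %.3f)",
                   report@overallMean, report@overallMin, report@overallMax),
           sprintf("- mean training accuracy: %.3f",
                   mean(report@repeats$meanTrain)))
  if (!is.null(importance)) {
    out <- c(out, "", "| Rank | Feature | Averaged rank |",
             "|---|---|---|",
             sprintf("| %d | %s | %.2f |", seq_len(nrow(importance)),
                     importance$feature, importance$avgRank))
  }
  out
}
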