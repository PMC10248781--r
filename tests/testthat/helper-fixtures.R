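# Small cohorts and toy datasets shared across test files.

tinySpec <- function(seed = 11, ...) {
  cohortSpec(nCase = 4, nControl = 3, nResponder = 2, daysMonitoring = 14,
             seed = seed, ...)
}

tinyCohort <- local({
  cache <- new.env()
  function(seed = 11) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- generateCohort(tinySpec(seed))
    cache[[key]]
  }
})

# two-class Gaussian toy matrix with per-feature mean shifts
gaussToy <- function(n = 60, shifts = c(2, 0), seed = 1) {
  set.seed(seed)
  x <- sapply(shifts, function(d) c(rnorm(n / 2, 0), rnorm(n / 2, d)))
  colnames(x) <- paste0("f", seq_along(shifts))
  list(x = x, y = factor(rep(c("a", "b"), each = n / 2)))
}

# importance table for the 14 raw base features from one subject-level
# 3-fold pass (the protocol used by the planted-recovery checks)
rawImportance <- function(cohort, rows = c("baseline", "all"), seed = 1) {
  rows <- match.arg(rows)
  pe <- buildPhenotypeExperiment(cohort)
  cd <- SummarizedExperiment::colData(pe)
  sel <- if (rows == "baseline") which(cd$week == 0L) else seq_len(ncol(pe))
  x <- t(SummarizedExperiment::assay(pe, "raw")[, sel, drop = FALSE])
  y <- factor(as.character(cd$group[sel]), levels = c("case", "control"))
  subj <- as.character(cd$subjectId[sel])
  cls <- tapply(as.character(y), subj, `[`, 1)[unique(subj)]
  fold <- subjectKfold(unique(subj), cls, 3, seed = seed)
  paths <- lapply(1:3, function(f)
    backwardEliminate(x[fold[subj] != f, , drop = FALSE],
                      y[fold[subj] != f], newfmConfig(), seed = seed + f))
  importanceTable(paths)
}

# subject-level label permutation of a PhenoDataset
permuteLabels <- function(dataset, seed) {
  subj <- unique(dataset@subject)
  perm <- phenofuzz:::withSeed(seed, sample(subj))
  names(perm) <- subj
  yp <- dataset@y[match(perm[dataset@subject], dataset@subject)]
  new("PhenoDataset", x = dataset@x, y = yp, subject = dataset@subject,
      task = dataset@task)
}

# brute-force bounded-sum oracle evaluated straight from the model slots
bswfmOracle <- function(model, j, class, xs) {
  v <- model@apex[[class]][, j]; w <- model@weight[[class]][, j]
  m <- length(v)
  span <- if (m > 1) max(v[m] - v[1], 1e-6) / (m - 1) else 0.5
  l <- c(if (m > 1) v[1] - span else v - span, v[-m])
  r <- c(v[-1], if (m > 1) v[m] + span else v + span)
  l <- pmin(l, v - 1e-6); r <- pmax(r, v + 1e-6)
  sapply(xs, function(x) {
    mu <- numeric(m)
    for (i in seq_len(m)) {
      if (x > l[i] && x < r[i]) {
        mu[i] <- if (x <= v[i]) (x - l[i]) / (v[i] - l[i])
                 else (r[i] - x) / (r[i] - v[i])
      }
      if (x == v[i]) mu[i] <- 1
    }
    min(1, sum(w * mu))
  })
}
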