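# Clinical labelling and group-comparison statistics: the 40% CDRS-R
# responder rule, two-sided t tests (pooled Student and Welch), the Fisher
# exact test, and baseline characteristic tables.

#' Antidepressant treatment-response label
#'
#' A case is a responder when the CDRS-R total decreased by at least 40%
#' between baseline and treatment week 8 (boundary inclusive).
#'
#' @param cdrsBaseline,cdrsWeek8 CDRS-R totals (range 17-113); a missing
#'   week-8 score yields `NA` (not evaluable, excluded from the response
#'   dataset).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
#' @examples
#' labelResponder(60, 36)  # TRUE: exactly 40%
#' labelResponder(60, 37)  # FALSE: 38.3%
labelResponder <- function(cdrsBaseline, cdrsWeek8) {
  if (is.na(cdrsBaseline) || cdrsBaseline <= 0)
    stop("baseline CDRS-R must be a positive score")
  if (any(c(cdrsBaseline, cdrsWeek8) < .cdrsrRange[1], na.rm = TRUE) ||
      any(c(cdrsBaseline, cdrsWeek8) > .cdrsrRange[2], na.rm = TRUE))
    stop("CDRS-R totals must lie in [17, 113]")
  if (is.na(cdrsWeek8)) return(NA)
  (cdrsBaseline - cdrsWeek8) / cdrsBaseline >= 0.40
}

#' Two-sided two-sample t test
#'
#' Pooled-variance Student t by default, with the Welch unequal-variance
#' variant available. Degenerate zero-variance input with equal means gives
#' `p = 1`.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
tTestTwoSided <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot2(length(a) >= 2 && length(b) >= 2,
             "each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-sided t test from group summaries
#'
#' Identical formulas to [tTestTwoSided()], computed from printed group
#' summaries (mean, SD, n) rather than raw data — handy for checking table
#' rows.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' # Welch vs pooled can disagree noticeably with unequal SDs and ns:
#' tTestFromSummary(104.9, 16.6, 24, 111.6, 6.1, 10, "welch")$p   # ~0.09
#' tTestFromSummary(104.9, 16.6, 24, 111.6, 6.1, 10, "pooled")$p  # ~0.23
tTestFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot2(nA >= 2 && nB >= 2, "each group needs n >= 2")
  stopifnot2(sdA >= 0 && sdB >= 0, "SDs must be >= 0")
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) return(list(t = 0, df = nA + nB - 2, p = 1))
    return(list(t = sign(meanA - meanB) * Inf, df = nA + nB - 2, p = 0))
  }
  if (variant == "pooled") {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    va <- sdA^2 / nA; vb <- sdB^2 / nB
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  }
  t <- (meanA - meanB) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over the hypergeometric support fixed by the table margins, the
#' probabilities of all tables no more probable than the observed one
#' (with a relative slack of 1e-12 for ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p value.
#' @export
#' @examples
#' fisherExact2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot2(all(dim(tab) == 2L), "a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

.fmtMeanSd <- function(m, s) sprintf("%.1f (%.1f)", m, s)

#' Format a count with its integer percentage
#'
#' Percentages are rounded half-up to integers, matching the convention of
#' printed baseline tables (17 of 24 prints as `"17 (71)"`).
#'
#' @param count,n non-negative integers.
#' @return Character scalar `"count (pct)"`.
#' @export
formatCountPct <- function(count, n) {
  sprintf("%d (%d)", as.integer(count), roundHalfUp(100 * count / n))
}

#' Baseline characteristics table
#'
#' Per-variable group means, SDs and ns with two-sided t-test p values
#' (both pooled Student and Welch are reported), and female counts with
#' integer percentages compared by Fisher exact test. Grouping is either
#' case vs control (`"diagnosis"`) or responder vs nonresponder within the
#' cases (`"response"`).
#'
#' @param cohort a [DigitalCohort-class] or a list of
#'   [ClinicalRecord-class] objects.
#' @param grouping `"diagnosis"` or `"response"`.
#' @return data.frame with one row per variable: group summaries, formatted
#'   display cells, test statistics and p values.
#' @export
baselineTable <- function(cohort, grouping = c("diagnosis", "response")) {
  grouping <- match.arg(grouping)
  recs <- if (is(cohort, "DigitalCohort")) clinicalRecords(cohort)
          else cohort
  if (grouping == "diagnosis") {
    gl <- vapply(recs, groupLabel, "")
    g1 <- recs[gl == "case"]; g2 <- recs[gl == "control"]
    labels <- c("case", "control")
  } else {
    recs <- Filter(function(r) groupLabel(r) == "case" &&
                     !is.na(isResponder(r)), recs)
    resp <- vapply(recs, isResponder, TRUE)
    g1 <- recs[resp]; g2 <- recs[!resp]
    labels <- c("responder", "nonresponder")
  }
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  pull <- function(rs, var) {
    if (var %in% c("age", "scared", "iq", "faces"))
      vapply(rs, function(r) as.numeric(baselineScores(r)[[var]]), 0)
    else
      vapply(rs, function(r) {
        ws <- weeklyScores(r); ws[[var]][ws$week == 0][1]
      }, 0)
  }
  vars <- c("age", "cdrsr", "cdi", "cssrs", "scared", "iq", "faces")
  rows <- lapply(vars, function(v) {
    a <- pull(g1, v); b <- pull(g2, v)
    tp <- tTestFromSummary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b), "pooled")
    tw <- tTestFromSummary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b), "welch")
    data.frame(variable = v, type = "continuous",
               n1 = length(a), n2 = length(b),
               mean1 = mean(a), sd1 = sd(a), mean2 = mean(b), sd2 = sd(b),
               display1 = .fmtMeanSd(mean(a), sd(a)),
               display2 = .fmtMeanSd(mean(b), sd(b)),
               statistic = tp$t, pPooled = tp$p, pWelch = tw$p,
               stringsAsFactors = FALSE)
  })
  nf1 <- sum(vapply(g1, function(r) baselineScores(r)$sex == "female", TRUE))
  nf2 <- sum(vapply(g2, function(r) baselineScores(r)$sex == "female", TRUE))
  fisherP <- fisherExact2x2(matrix(c(nf1, length(g1) - nf1,
                                     nf2, length(g2) - nf2), 2,
                                   byrow = TRUE))
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "female", type = "categorical",
    n1 = length(g1), n2 = length(g2),
    mean1 = nf1, sd1 = NA, mean2 = nf2, sd2 = NA,
    display1 = formatCountPct(nf1, length(g1)),
    display2 = formatCountPct(nf2, length(g2)),
    statistic = NA, pPooled = fisherP, pWelch = fisherP,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "groups") <- labels
  out
}
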