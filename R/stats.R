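# The study's statistical battery. Group summaries are reported as
# mean +/- s.e.m. throughout, matching the field's reporting convention.

groupSummary <- function(values) {
  n <- length(values)
  list(n = n, mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance (Student's) two-sample t-test with
#' `df = n_a + n_b - 2`. Welch's correction is available behind a flag for
#' heteroscedastic data.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param welch use Welch's unequal-variance form instead of the pooled one.
#' @return list (a group comparison): `method`, `statistic` (t), `df`,
#'   `pValue`, `groupSummaries`.
#' @export
ttestUnpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # zero pooled variance: degenerate but well-defined answers
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with unequal means: p = 0")
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
    return(list(method = "ttest", statistic = t,
                df = length(a) + length(b) - 2, pValue = p,
                groupSummaries = list(a = groupSummary(a),
                                      b = groupSummary(b))))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(method = "ttest", statistic = unname(ht$statistic),
       df = unname(ht$parameter), pValue = ht$p.value,
       groupSummaries = list(a = groupSummary(a), b = groupSummary(b)))
}

#' Multi-group comparison (ANOVA + Tukey or Kruskal-Wallis + Dunn)
#'
#' `"anova_tukey"`: one-way ANOVA omnibus with Tukey HSD adjusted pairwise
#' p-values. `"kw_dunn"`: Kruskal-Wallis omnibus (tie-corrected) with Dunn's
#' rank-based post hoc, adjusted with a Bonferroni-family correction.
#'
#' @param groups named list of numeric samples (>= 3 groups; use
#'   [ttestUnpaired()] for two).
#' @param method `"anova_tukey"` or `"kw_dunn"`.
#' @param adjust p adjustment for Dunn's test (any [stats::p.adjust()]
#'   method).
#' @return list (a group comparison): `method`, `statistic`, `pValue`,
#'   `groupSummaries`, `pairwise` (data.frame pair / pAdjusted).
#' @export
groupCompare <- function(groups, method = c("anova_tukey", "kw_dunn"),
                         adjust = "bonferroni") {
  method <- match.arg(method)
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use ttestUnpaired")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  minN <- if (method == "anova_tukey") 2L else 1L
  if (any(lengths(groups) < minN))
    stop("every group needs at least ", minN, " values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  summaries <- lapply(groups, groupSummary)
  if (method == "anova_tukey") {
    if (stats::var(value) == 0) {
      pairs <- utils::combn(names(groups), 2)
      return(list(method = method, statistic = 0, pValue = 1,
                  groupSummaries = summaries,
                  pairwise = data.frame(
                    pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                    pAdjusted = 1)))
    }
    fit <- stats::aov(value ~ grp)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$grp
    list(method = method, statistic = an[["F value"]][1],
         pValue = an[["Pr(>F)"]][1],
         groupSummaries = summaries,
         pairwise = data.frame(pair = rownames(tk),
                               pAdjusted = unname(tk[, "p adj"])))
  } else {
    if (stats::var(value) == 0) {
      # fully tied data: the tie-corrected statistic degenerates to 0
      pairs <- utils::combn(names(groups), 2)
      return(list(method = method, statistic = 0, pValue = 1,
                  groupSummaries = summaries,
                  pairwise = data.frame(
                    pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                    z = 0, pAdjusted = 1)))
    }
    kw <- stats::kruskal.test(value, grp)
    list(method = method, statistic = unname(kw$statistic),
         pValue = kw$p.value,
         groupSummaries = summaries,
         pairwise = dunnTest(value, grp, adjust = adjust))
  }
}

# Dunn's multiple-comparison z tests on rank sums with tie correction
dunnTest <- function(value, grp, adjust = "bonferroni") {
  N <- length(value)
  r <- rank(value)
  rbar <- tapply(r, grp, mean)
  n <- tapply(r, grp, length)
  ties <- table(value)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  praw <- 2 * stats::pnorm(-abs(z))
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = as.numeric(z),
             pAdjusted = stats::p.adjust(praw, method = adjust))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Probability-ordering two-sided p: the sum of hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list (a group comparison): `method`, `pValue`, `oddsRatio`,
#'   `table`.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: test undefined")
  ht <- stats::fisher.test(table)
  list(method = "fisher", pValue = ht$p.value,
       oddsRatio = unname(ht$estimate), table = table)
}

#' Area-under-the-curve comparison between two groups of curves
#'
#' Computes a trapezoid AUC per cell, then compares the two AUC samples with
#' an unpaired two-tailed Student's t-test - the procedure used for Sholl
#' and branch-level profiles. Curves within each group must share one x grid.
#'
#' @param curvesA,curvesB lists of curves; each curve is a list or
#'   data.frame with components `x` and `y` (>= 2 points).
#' @return list (a group comparison): `method`, `statistic`, `df`, `pValue`,
#'   `groupSummaries` (per-group AUC n/mean/sem), `auc` (the two AUC
#'   samples).
#' @export
aucCompare <- function(curvesA, curvesB) {
  aucOf <- function(curves, label) {
    if (!length(curves)) stop("empty curve group ", label)
    x0 <- curves[[1]]$x
    vapply(curves, function(cv) {
      if (!isTRUE(all.equal(cv$x, x0)))
        stop("curves in group ", label, " do not share an x grid")
      trapezoidAUC(cv$x, cv$y)
    }, numeric(1))
  }
  aucA <- aucOf(curvesA, "A")
  aucB <- aucOf(curvesB, "B")
  tt <- ttestUnpaired(aucA, aucB)
  list(method = "auc_ttest", statistic = tt$statistic, df = tt$df,
       pValue = tt$pValue,
       groupSummaries = list(A = groupSummary(aucA), B = groupSummary(aucB)),
       auc = list(A = aucA, B = aucB))
}

#' ROI fluorescence normalization
#'
#' `"ratio"`: signal divided by background (the no-enrichment baseline
#' is 1). `"subtract"`: raw signal minus background, reported as-is (may be
#' negative).
#'
#' @param signalMean mean intensity of the cell ROI.
#' @param backgroundMean mean intensity of the background ROI (> 0 for
#'   ratio mode).
#' @param mode `"ratio"` or `"subtract"`.
#' @return normalized intensity.
#' @export
roiNormalize <- function(signalMean, backgroundMean,
                         mode = c("ratio", "subtract")) {
  mode <- match.arg(mode)
  if (mode == "ratio") {
    if (any(backgroundMean <= 0))
      stop("background must be positive for ratio normalization")
    signalMean / backgroundMean
  } else {
    signalMean - backgroundMean
  }
}
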