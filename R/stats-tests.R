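## Classical tests used in the figures, wrapped with the package's input
## checks and documented edge conventions. The heavy lifting is base
## stats; tests in the suite verify each wrapper against full-enumeration
## oracles on small inputs.

#' Chi-squared goodness-of-fit against stated proportions
#'
#' X^2 = sum (O - E)^2 / E with E = n x proportion and df = categories - 1,
#' the construction used to compare observed genotype counts with
#' theoretical Mendelian ratios. \code{mode = "independence"} instead runs
#' the classical test of independence on a contingency table.
#'
#' @param observed non-negative counts (a vector for goodness-of-fit, a
#'   matrix for independence mode).
#' @param proportions expected proportions summing to 1 (goodness-of-fit
#'   mode only).
#' @param mode "gof" (default) or "independence".
#' @return list: statistic, df, p.value.
#' @export
chisqGoodnessOfFit <- function(observed, proportions = NULL,
                               mode = c("gof", "independence")) {
  mode <- match.arg(mode)
  if (any(observed < 0)) stop("observed counts must be >= 0")
  if (mode == "independence") {
    ct <- suppressWarnings(chisq.test(as.matrix(observed), correct = FALSE))
  } else {
    if (is.null(proportions)) stop("proportions required in gof mode")
    if (abs(sum(proportions) - 1) > 1e-8)
      stop("expected proportions must sum to 1")
    if (any(sum(observed) * proportions == 0))
      stop("expected count of zero in some category")
    ct <- suppressWarnings(chisq.test(observed, p = proportions))
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Exact unpaired Wilcoxon rank-sum test
#'
#' Two-sided exact p-value by enumeration of the rank-sum null when the
#' data are tie-free and small enough; with ties the normal approximation
#' with continuity correction is used (documented fallback).
#'
#' @param x,y numeric vectors (non-empty).
#' @param exactLimit largest min(n, m) for the exact path; default 50.
#' @return list: statistic (W), p.value, exact (logical).
#' @export
wilcoxonRankSumExact <- function(x, y, exactLimit = 50L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && min(length(x), length(y)) <= exactLimit
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied data carry no evidence
  list(statistic = unname(wt$statistic), p.value = min(p, 1),
       exact = exact)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables (at fixed
#' margins) no more probable than the observed one.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list: p.value, odds ratio estimate.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative entries")
  if (sum(table) == 0L) stop("empty table")
  ft <- fisher.test(table, alternative = "two.sided")
  list(p.value = ft$p.value, oddsRatio = unname(ft$estimate))
}

#' Welch two-sample t-test
#'
#' Unpaired two-sided t-test assuming unequal variances (Satterthwaite
#' degrees of freedom). When both groups have zero variance: p = 1 if the
#' means are equal (documented convention), p = 0 otherwise.
#'
#' @param x,y numeric vectors with n >= 2 each.
#' @return list: statistic, df, p.value.
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (var(x) == 0 && var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                df = NA_real_, p.value = if (eq) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}
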