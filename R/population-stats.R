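## Change metrics and the nonparametric population battery. Tests wrap the
## stats-package engines behind a uniform StatResult record; p-values are
## two-tailed and flagged exact vs asymptotic.

statResult <- function(method, statistic, df = NA_real_, p, exact,
                       alpha = 0.05, note = "") {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p), exact = exact,
                 alpha = alpha, note = note),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g%s, p = %.4g (%s, alpha %.4g)%s\n",
              x$method, x$statistic,
              if (is.finite(x$df)) sprintf(" (df %g)", x$df) else "",
              x$p, if (x$exact) "exact" else "asymptotic", x$alpha,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Modulation index of a paired change
#'
#' `MI = (deactivated - control) / (deactivated + control)`, bounded in
#' [-1, 1]; undefined (NA) when both values are zero.
#'
#' @param control,deactivated non-negative values (vectorised).
#' @return modulation index vector.
#' @examples
#' modulationIndex(50, 150)  # 0.5
#' @export
modulationIndex <- function(control, deactivated) {
  if (any(control < 0 | deactivated < 0, na.rm = TRUE))
    stop("modulation index is defined for non-negative measures")
  out <- (deactivated - control) / (deactivated + control)
  out[control + deactivated == 0] <- NA_real_
  out
}

#' Classify a paired change by a fractional criterion
#'
#' `increase` when `deactivated >= control * (1 + criterion)`, `decrease`
#' when `deactivated <= control * (1 - criterion)` (both boundaries
#' inclusive), else `none`. A unit silent in control that fires when
#' deactivated is an increase.
#'
#' @param control,deactivated non-negative values (vectorised).
#' @param criterion fractional change criterion (default 0.20).
#' @return character vector in `{increase, decrease, none}`.
#' @export
classifyChange <- function(control, deactivated, criterion = 0.20) {
  n <- max(length(control), length(deactivated))
  control <- rep_len(control, n); deactivated <- rep_len(deactivated, n)
  out <- rep("none", n)
  zero <- control == 0
  out[zero & deactivated > 0] <- "increase"
  eps <- 1e-12
  out[!zero & deactivated >= control * (1 + criterion) - eps] <- "increase"
  out[!zero & deactivated <= control * (1 - criterion) + eps] <- "decrease"
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with a two-tailed p-value (exact when the
#' sample-size product permits, else asymptotic, flagged).
#'
#' @param x,y numeric samples.
#' @param alpha nominal level recorded in the result.
#' @return a `StatResult`.
#' @export
ksTwoSample <- function(x, y, alpha = 0.05) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exactOK <- length(x) * length(y) < 10000 && !any(duplicated(c(x, y)))
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exactOK))
  statResult("two-sample Kolmogorov-Smirnov", kt$statistic, NA_real_,
             kt$p.value, exact = exactOK, alpha = alpha)
}

#' Friedman repeated-measures ANOVA on ranks
#'
#' Within-subject ranks (mid-ranks on ties), chi-squared statistic with
#' k - 1 degrees of freedom, asymptotic p.
#'
#' @param m subjects x conditions matrix, no missing cells.
#' @param alpha nominal level recorded in the result.
#' @return a `StatResult`.
#' @export
friedmanTest <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("Friedman test requires complete cells")
  if (ncol(m) < 3L) stop("need k >= 3 conditions")
  ft <- stats::friedman.test(m)
  if (!is.finite(ft$statistic))   # no rank variance at all: chi^2 = 0
    return(statResult("Friedman rank ANOVA", 0, ncol(m) - 1, 1,
                      exact = FALSE, alpha = alpha,
                      note = "degenerate: identical within-subject ranks"))
  statResult("Friedman rank ANOVA", ft$statistic, ft$parameter,
             ft$p.value, exact = FALSE, alpha = alpha)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are excluded, tied absolute differences get mid-ranks.
#' The p-value is exact by sign-assignment enumeration for n <= `exactMax`
#' remaining pairs without ties, else a normal approximation with
#' continuity correction; always two-tailed.
#'
#' @param x,y paired samples.
#' @param alpha nominal level recorded in the result (Sidak-corrected by
#'   the caller for post hoc use).
#' @param exactMax largest n for the exact path (default 25).
#' @return a `StatResult`.
#' @export
wilcoxonSignedRank <- function(x, y, alpha = 0.05, exactMax = 25L) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero")
  ties <- any(duplicated(abs(d)))
  useExact <- length(d) <= exactMax && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = useExact,
                                            correct = TRUE))
  statResult("Wilcoxon signed rank", wt$statistic, NA_real_, wt$p.value,
             exact = useExact, alpha = alpha,
             note = sprintf("n = %d nonzero pairs", length(d)))
}

#' Sidak-corrected per-test alpha
#'
#' `1 - (1 - alpha)^(1/m)` for m post hoc tests at family level `alpha`
#' (0.0253 for two tests at 0.05).
#'
#' @param alphaFamily family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return per-test alpha.
#' @examples
#' sidakAlpha(0.05, 2)  # 0.0253
#' @export
sidakAlpha <- function(alphaFamily, m) {
  if (!isScalarNumber(alphaFamily) || alphaFamily <= 0 || alphaFamily >= 1)
    stop("alphaFamily must be in (0, 1)")
  if (!isScalarNumber(m) || m < 1) stop("m must be >= 1")
  1 - (1 - alphaFamily)^(1 / m)
}

#' Spearman rank correlation
#'
#' Mid-ranks on ties; two-tailed p (exact for small untied samples, else
#' the t approximation, flagged).
#'
#' @param x,y equal-length samples (n >= 3).
#' @param alpha nominal level recorded in the result.
#' @return a `StatResult` (statistic = rho).
#' @export
spearmanCorrelation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length samples with n >= 3")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("rank variance is zero: correlation undefined")
  ties <- any(duplicated(x)) || any(duplicated(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = !ties))
  statResult("Spearman rank correlation", ct$estimate, length(x) - 2,
             ct$p.value, exact = !ties && length(x) <= 9, alpha = alpha)
}

#' Exact Fisher test on an r x 2 contingency table
#'
#' Two-sided exact p by probability ordering: the total multivariate
#' hypergeometric probability, over all tables with the observed margins,
#' of tables no more probable than the observed one.
#'
#' @param tab r x 2 matrix of non-negative integer counts.
#' @param alpha nominal level recorded in the result.
#' @return a `StatResult` (statistic = probability of the observed table).
#' @export
fisherExactRx2 <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L || nrow(tab) < 2L)
    stop("table must be r x 2 with r >= 2")
  if (!isCount(tab)) stop("table entries must be non-negative integers")
  ft <- tryCatch(stats::fisher.test(tab),
                 error = function(e)
                   stop("exact enumeration failed (", conditionMessage(e),
                        "); consider collapsing rows"))
  pObs <- .tableProb(tab)
  statResult("Fisher exact r x 2", pObs, NA_real_, ft$p.value,
             exact = TRUE, alpha = alpha)
}

## multivariate hypergeometric probability of a table given its margins
.tableProb <- function(tab) {
  exp(sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param x numeric sample (n >= 2).
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed integer seed; fixed seed gives an identical interval.
#' @return list with `median`, `lo`, `hi`, `level`.
#' @export
bootstrapMedianCI <- function(x, level = 0.95, nBoot = 10000L, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need n >= 2 finite values")
  meds <- withSeed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * nBoot, replace = TRUE),
                  nrow = nBoot)
    apply(idx, 1L, function(i) stats::median(x[i]))
  })
  qs <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(median = stats::median(x), lo = qs[1L], hi = qs[2L], level = level)
}
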