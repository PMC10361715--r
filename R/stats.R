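#' Group comparison with normality/variance diagnostics
#'
#' The statistical protocol used throughout the behavioral and
#' electrophysiological comparisons: Shapiro-Wilk normality and Levene
#' equality-of-variance diagnostics are computed and reported (not used to
#' switch tests automatically), then a paired or independent t-test is run
#' and its p-value Bonferroni-adjusted for the stated number of comparisons.
#' For independent samples the pooled-variance t-test is used when Levene's
#' test does not reject equal variances (p >= 0.05), otherwise Welch's.
#'
#' @param a,b numeric sample vectors (n >= 3 each; equal length if paired).
#' @param paired logical; paired or independent comparison.
#' @param n_comparisons number of comparisons in the family for the
#'   Bonferroni correction (default 1, i.e. no correction).
#' @param alpha nominal significance level, stored in the result.
#' @return Object of class `"comparison_result"`: `test_name`, `statistic`,
#'   `df`, `p_raw`, `p_adjusted` (`min(1, p_raw * n_comparisons)`),
#'   `n_comparisons`, `alpha`, plus `shapiro` (per-group or difference
#'   p-values) and `levene` (p-value, `NA` for paired data). Two constant
#'   groups yield an `NA` statistic with a warning; identical paired samples
#'   yield statistic 0 and p 1.
#' @export
compare_groups <- function(a, b, paired = FALSE, n_comparisons = 1,
                           alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length samples")
  if (n_comparisons < 1) stop("`n_comparisons` must be >= 1")
  sw <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  shapiro <- if (paired) c(difference = sw(a - b)) else c(a = sw(a), b = sw(b))
  levene <- NA_real_
  if (!paired && sd(c(a, b)) > 0) {
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    levene <- tryCatch(
      car::leveneTest(c(a, b) ~ g)[1, "Pr(>F)"],
      error = function(e) NA_real_)
  }
  test_name <- if (paired) "paired t-test" else "independent t-test"
  if (paired && sd(a - b) == 0) {
    statistic <- 0; df <- length(a) - 1; p_raw <- 1
  } else if (!paired && sd(a) == 0 && sd(b) == 0) {
    warning("zero variance in both groups: statistic undefined")
    statistic <- NA_real_; df <- NA_real_; p_raw <- NA_real_
  } else {
    var_equal <- !paired && (is.na(levene) || levene >= 0.05)
    tt <- t.test(a, b, paired = paired, var.equal = var_equal)
    if (!paired && !var_equal) test_name <- "Welch t-test"
    statistic <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p_raw <- tt$p.value
  }
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_raw = p_raw,
                 p_adjusted = if (is.na(p_raw)) NA_real_
                              else min(1, p_raw * n_comparisons),
                 n_comparisons = n_comparisons, alpha = alpha,
                 shapiro = shapiro, levene = levene,
                 paired = paired),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: t = %.4g, df = %.3g, p = %.4g (adjusted %.4g over %d comparisons)\n",
              x$test_name, x$statistic, x$df, x$p_raw, x$p_adjusted,
              x$n_comparisons))
  invisible(x)
}

#' Correlation of coupling strength with light-induced freezing
#'
#' Per-animal correlation between theta-gamma modulation index and
#' stimulation efficacy (percent light-induced freezing). Both an
#' unfiltered variant (all animals) and a filtered variant restricted to
#' animals that actually showed light-induced freezing (positive values)
#' are returned.
#'
#' @param mi numeric vector of per-animal modulation indices.
#' @param lif numeric vector of per-animal light-induced freezing values
#'   (percentage points); same length as `mi`, n >= 3.
#' @param method `"pearson"` (default, linear association) or
#'   `"spearman"`.
#' @return Object of class `"mi_freezing_cor"` with elements `unfiltered`
#'   and `filtered`, each a list `r`, `p`, `n` (the filtered variant is
#'   `NA` when fewer than 3 animals remain), plus `method`. Constant input
#'   yields `NA` with a warning.
#' @export
mi_freezing_correlation <- function(mi, lif,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mi <- as.numeric(mi); lif <- as.numeric(lif)
  if (length(mi) != length(lif)) stop("`mi` and `lif` must have equal length")
  if (length(mi) < 3L) stop("need at least 3 animals")
  one <- function(x, y) {
    if (length(x) < 3L) return(list(r = NA_real_, p = NA_real_, n = length(x)))
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant vector: correlation undefined")
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method))
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  keep <- lif > 0
  structure(list(unfiltered = one(mi, lif),
                 filtered = one(mi[keep], lif[keep]),
                 method = method),
            class = "mi_freezing_cor")
}

#' @export
print.mi_freezing_cor <- function(x, ...) {
  cat(sprintf("<mi_freezing_cor> %s r = %.3f (p = %.4g, n = %d); responders only: r = %.3f (p = %.4g, n = %d)\n",
              x$method, x$unfiltered$r, x$unfiltered$p, x$unfiltered$n,
              x$filtered$r, x$filtered$p, x$filtered$n))
  invisible(x)
}
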