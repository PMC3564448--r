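#' @include AllClasses.R
NULL

.testResult <- function(test, statistic, p, n, side, alpha = 0.05,
                        extra = NULL) {
  out <- list(test = test, statistic = statistic, p = p, n = n,
              side = side, alpha = alpha)
  out <- c(out, extra)
  class(out) <- "TestResult"
  out
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$test, x$statistic, x$p, x$side,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Exact binomial test against a chance level
#'
#' Classifier accuracies are tested against their guessing level with the
#' exact binomial tail: one-sided "greater" (the default used throughout,
#' testing better-than-chance performance) reports P(X >= k) under
#' Binomial(n, p0).
#'
#' @param k number of successes (correct laps).
#' @param n number of trials (laps).
#' @param p0 chance level, in (0, 1).
#' @param side "greater" (default), "less" or "two.sided".
#' @return a `TestResult` list: `test`, `statistic` (k), `p`, `n`, `side`.
#' @examples
#' binomialTest(10, 10, 0.5)$p   # 0.5^10
#' @export
binomialTest <- function(k, n, p0 = 0.5, side = c("greater", "less",
                                                  "two.sided")) {
  side <- match.arg(side)
  if (n < 1 || k < 0 || k > n || k != round(k))
    stop("input error: need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("input error: p0 must lie in (0, 1)")
  p <- switch(side,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two.sided = stats::binom.test(k, n, p0)$p.value)
  .testResult("binomial", k, p, n, side)
}

#' Wilcoxon rank-sum test with normal approximation
#'
#' Rank-sum comparison of two samples (Mann-Whitney), reporting the
#' tie-corrected normal-approximation Z statistic alongside the p value;
#' used to compare similarity-index distributions between comparison
#' classes.
#'
#' @param x,y numeric samples.
#' @param side "two.sided" (default), "greater" or "less" (of `x` vs `y`).
#' @return a `TestResult` list with `statistic` = Z, `W` (rank-sum based
#'   Mann-Whitney U of `x`), `p`, `n` (per group).
#' @export
wilcoxonRankSum <- function(x, y, side = c("two.sided", "greater", "less")) {
  side <- match.arg(side)
  if (length(x) == 0 || length(y) == 0)
    stop("input error: both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)
    stop("degenerate input: all pooled values identical")
  r <- rank(pooled)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2        # Mann-Whitney U of x
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
  Z <- (W - mu) / sqrt(sigma2)
  p <- switch(side,
    two.sided = 2 * stats::pnorm(-abs(Z)),
    greater = stats::pnorm(Z, lower.tail = FALSE),
    less = stats::pnorm(Z))
  .testResult("wilcoxon_rank_sum", Z, min(1, p), c(n1, n2), side,
              extra = list(W = W))
}

#' Kruskal-Wallis omnibus test with optional rank-based Tukey HSD
#'
#' Omnibus comparison of three or more groups by the Kruskal-Wallis rank
#' test; with `posthoc = TRUE`, pairwise comparisons are performed as a
#' Tukey honestly-significant-difference test on the rank-transformed data
#' (family-wise corrected).
#'
#' @param groups list of (>= 3) non-empty numeric samples; names are used
#'   in the post-hoc table.
#' @param posthoc compute pairwise rank-based Tukey HSD comparisons.
#' @return a `TestResult` list with `statistic` = H, chi-square `p`, `df`,
#'   and (when requested) `pairwise` (data.frame: pair, diff, p_adj).
#' @export
kruskalWallis <- function(groups, posthoc = FALSE) {
  if (!is.list(groups) || length(groups) < 3)
    stop("input error: need at least 3 groups")
  if (any(lengths(groups) == 0))
    stop("input error: all groups must be non-empty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- stats::kruskal.test(values, g)
  extra <- list(df = unname(kt$parameter))
  if (posthoc) {
    rdf <- data.frame(r = rank(values), g = g)
    tk <- stats::TukeyHSD(stats::aov(r ~ g, data = rdf))$g
    extra$pairwise <- data.frame(pair = rownames(tk),
                                 diff = tk[, "diff"],
                                 p_adj = tk[, "p adj"],
                                 row.names = NULL)
  }
  .testResult("kruskal_wallis", unname(kt$statistic), kt$p.value,
              lengths(groups), "two.sided", extra = extra)
}
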