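# Lightweight container for every test run by the pipeline, so reports can
# be serialised uniformly to TSV.

new_test_report <- function(method, statistic, p_value, n,
                            estimate = NA_real_, direction = NA_character_,
                            extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), n = n,
                   estimate = unname(estimate), direction = direction),
              extra),
            class = "aar_test_report")
}

#' @export
print.aar_test_report <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value),
      " n =", paste(x$n, collapse = "/"), "\n")
  if (!is.na(x$direction)) cat("  direction:", x$direction, "\n")
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, nonzero variance).
#' @return An `aar_test_report` with `estimate` = r, `statistic` = t and a
#'   two-sided p-value on n - 2 degrees of freedom.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_report("Pearson correlation", ct$statistic, ct$p.value,
                  length(x), estimate = ct$estimate,
                  direction = if (ct$estimate >= 0) "positive" else "negative")
}

#' Welch's unequal-variance two-sample t-test
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return An `aar_test_report`; `extra$df` carries the
#'   Welch-Satterthwaite degrees of freedom.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new_test_report("Welch two-sample t-test", tt$statistic, tt$p.value,
                  c(length(a), length(b)),
                  estimate = mean(a) - mean(b),
                  direction = if (mean(a) > mean(b)) "a_greater" else
                    if (mean(a) < mean(b)) "b_greater" else "equal",
                  extra = list(df = unname(tt$parameter),
                               mean_a = mean(a), mean_b = mean(b)))
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums. For large samples the two-sided
#' p-value uses the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction. For small samples (both n at most 8, where
#' the normal approximation is poor) all choose(n1+n2, n1) rank
#' assignments are enumerated instead and
#' p = min(1, 2 min(P(U <= u), P(U >= u))); ties are handled through
#' midranks in both modes.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param exact Logical or NULL; NULL (default) enumerates exhaustively
#'   when both samples have at most 8 observations. Enumeration is refused
#'   for large samples.
#' @return An `aar_test_report` with `statistic` = U of the first sample.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (is.null(exact)) exact <- (max(n1, n2) <= 8L)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  med_a <- stats::median(a); med_b <- stats::median(b)
  dir <- if (med_a > med_b) "a_greater" else if (med_a < med_b) "b_greater" else "equal"
  if (exact) {
    N <- n1 + n2
    if (choose(N, n1) > 20000) stop("exact enumeration refused for large samples")
    combs <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
    return(new_test_report("Mann-Whitney U (exact)", U, p, c(n1, n2),
                           direction = dir))
  }
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    p <- 1
    z <- 0
  } else {
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_test_report("Mann-Whitney U (normal approximation)", U, p, c(n1, n2),
                  direction = dir, extra = list(z = z))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing all hypergeometric outcome probabilities not
#' exceeding that of the observed table (relative tie tolerance 1e-7, the
#' usual convention). The reported odds ratio is the sample odds ratio
#' ad/bc, with 0/Inf flagged when a margin cell is empty.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return An `aar_test_report`; `extra$odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0), sum(tab) >= 1)
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  p <- min(1, sum(d[d <= d[x - lo + 1] * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_test_report("Fisher exact (2x2, two-sided)", x, p,
                  sum(tab), estimate = or,
                  extra = list(odds_ratio = or,
                               degenerate = (m == 0 || n == 0 || k == 0 || k == m + n)))
}

#' Grubbs's test for a single outlier
#'
#' G = max |x_i - mean| / sd. The two-sided p-value is obtained from the
#' classical t-distribution relation for the one-outlier statistic:
#' with t^2 = a (N-2) / (1 - a), a = G^2 N / (N-1)^2,
#' p = min(1, 2N P(T_{N-2} > t)).
#'
#' @param x Numeric vector, n >= 3.
#' @return An `aar_test_report`; `extra$outlier_index` flags the most
#'   extreme observation.
#' @export
grubbs_test <- function(x) {
  N <- length(x)
  stopifnot(N >= 3L)
  s <- stats::sd(x)
  if (s == 0) return(new_test_report("Grubbs single-outlier test", 0, 1, N,
                                     extra = list(outlier_index = NA_integer_)))
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  a <- G^2 * N / (N - 1)^2
  if (a >= 1) {
    p <- 0
  } else {
    t <- sqrt(a * (N - 2) / (1 - a))
    p <- min(1, 2 * N * stats::pt(t, df = N - 2, lower.tail = FALSE))
  }
  new_test_report("Grubbs single-outlier test", G, p, N,
                  extra = list(outlier_index = i, outlier_value = x[i]))
}

#' Add-one empirical p-value for a permutation/resampling null
#'
#' p = (number of null draws in the tail + 1) / (n + 1), so p is never 0; a
#' statistic exceeding all of 1000 null draws gives p = 1/1001 < 0.001.
#'
#' @param observed Observed statistic.
#' @param null_draws Numeric vector of null statistics.
#' @param tail `"ge"` (null >= observed counts against) or `"le"`.
#' @return Empirical p in \[1/(n+1), 1\].
#' @export
empirical_p <- function(observed, null_draws, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  stopifnot(length(null_draws) >= 1L)
  b <- if (tail == "ge") sum(null_draws >= observed) else sum(null_draws <= observed)
  (b + 1) / (length(null_draws) + 1)
}
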