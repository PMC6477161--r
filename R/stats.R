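#' Normality-gated choice of paired test
#'
#' The cohort comparison protocol: Shapiro-Wilk on the paired differences;
#' if normality is not rejected (p >= `threshold`) a paired t-test is used,
#' otherwise the Wilcoxon signed-rank test. Constant differences (degenerate
#' for Shapiro-Wilk) fall through to Wilcoxon.
#'
#' @param differences Numeric vector of paired differences, n >= 3.
#' @param threshold Normality gate on the Shapiro-Wilk p-value (default 0.05).
#' @return A list with `test` (`"t"` or `"wilcoxon"`) and `normality_p`.
#' @export
normalityGate <- function(differences, threshold = 0.05) {
  if (length(differences) < 3) stop("normalityGate: need at least 3 differences")
  if (stats::sd(differences) == 0)
    return(list(test = "wilcoxon", normality_p = NA_real_, degenerate = TRUE))
  p <- stats::shapiro.test(differences)$p.value
  list(test = if (p >= threshold) "t" else "wilcoxon",
       normality_p = p, degenerate = FALSE)
}

# exact null distribution of W+ over all 2^n sign patterns of ranks 1..n,
# by the generating-polynomial recursion; returns P(W+ = 0..n(n+1)/2)
.signedRankDistribution <- function(n) {
  counts <- 1
  for (r in seq_len(n)) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
  counts / 2^n
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped (their
#' count is reported); ties among absolute differences get mid-ranks. The
#' p-value is exact for `n <= 25`: from full enumeration of the `2^n` sign
#' patterns of the ranks, computed by the generating-function recursion in
#' the tie-free case and by explicit enumeration (doubled mid-ranks stay
#' integral) when ties are present and `n <= 16`. Otherwise a normal
#' approximation with tie correction is used.
#'
#' @param a,b Numeric vectors of paired observations.
#' @return A list of class `"ComparisonResult"`: `test_name`, `statistic`
#'   (W+, the positive-rank sum), `p_two_sided`, `n` (pairs used),
#'   `n_zero_dropped`, `exact`.
#' @export
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7), c(1, 2, 3))$p_two_sided  # 0.25
wilcoxonSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("wilcoxonSignedRank: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= 25) {
    dist <- .signedRankDistribution(n)
    wmax <- n * (n + 1) / 2
    # two-sided: double the smaller tail, capped at 1
    lower <- sum(dist[seq_len(w + 1)])           # P(W+ <= w)
    upper <- sum(dist[(w + 1):(wmax + 1)])        # P(W+ >= w)
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else if (ties && n <= 16) {
    # explicit enumeration of all sign patterns with mid-ranks
    r2 <- as.integer(round(2 * r))               # doubled mid-ranks: integers
    counts <- 1
    for (rr in r2) counts <- c(counts, numeric(rr)) + c(numeric(rr), counts)
    dist <- counts / 2^n
    w2 <- as.integer(round(2 * w))
    lower <- sum(dist[seq_len(w2 + 1)])
    upper <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_term <- sum(table(r)^3 - table(r)) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(test_name = "wilcoxon_signed_rank", statistic = w,
                 p_two_sided = p, n = n, n_zero_dropped = nz, exact = exact),
            class = "ComparisonResult")
}

#' Paired t-test result in the common comparison format
#'
#' @param a,b Numeric vectors of paired observations.
#' @return A `"ComparisonResult"` list: `test_name`, `statistic`,
#'   `p_two_sided`, `n`.
#' @export
pairedTTest <- function(a, b) {
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(test_name = "paired_t", statistic = unname(tt$statistic),
                 p_two_sided = tt$p.value, n = length(a)),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, two-sided p %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_two_sided, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho as the Pearson correlation of mid-ranks, with a two-sided
#' p-value from the t approximation `t = rho * sqrt((n-2) / (1-rho^2))`.
#'
#' @param x,y Numeric vectors, n >= 4.
#' @return A list of class `"CorrelationResult"`: `spearman_rho`,
#'   `p_two_sided`, `n`.
#' @export
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))$spearman_rho  # 0.8
spearmanCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("spearmanCorrelation: need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearmanCorrelation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(spearman_rho = rho, p_two_sided = p, n = n),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, two-sided p %.4g (n = %d)\n",
              x$spearman_rho, x$p_two_sided, x$n))
  invisible(x)
}
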