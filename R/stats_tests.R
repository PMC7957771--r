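new_stat_test <- function(test, statistic, p_value, n, exact = NA,
                          note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, exact = exact, note = note),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.6g (n = %d%s)%s\n", x$test,
              x$statistic, x$p_value, x$n,
              if (isTRUE(x$exact)) ", exact" else "",
              if (is.null(x$note)) "" else paste0("; ", x$note)))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W+ for n untied
# ranks: counting polynomial over subset rank sums.
signed_rank_counts <- function(n) {
  counts <- 1
  for (r in seq_len(n)) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
  counts  # counts[w + 1] = #subsets of {1..n} with sum w
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided paired test on `a - b`.  Zero differences are discarded
#' (Wilcoxon's original treatment).  With no ties among the absolute
#' differences and `n <= 25` pairs the exact null distribution of the
#' positive-rank sum is used; otherwise a normal approximation with tie
#' correction and continuity correction.  All differences zero returns
#' p = 1 with a note.
#'
#' @param a,b Paired numeric vectors (e.g. per-subject scores of two
#'   conditions).
#' @return A `stat_test_result` with the positive-rank sum `W` as statistic.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(new_stat_test("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                         n = 0, exact = TRUE, note = "all differences zero"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- any(duplicated(abs(d)))
  if (!has_ties && n <= 25) {
    counts <- signed_rank_counts(n)
    total <- 2^n
    p_le <- sum(counts[seq_len(w + 1)]) / total
    p_ge <- sum(counts[(w + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_stat_test("wilcoxon_signed_rank", w, p, n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_stat_test("wilcoxon_signed_rank", w, p, n, exact = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and the chi-square approximation of the
#' p-value (`k - 1` degrees of freedom).
#'
#' @param groups List of numeric vectors, one per group; no group may be
#'   empty.
#' @return A `stat_test_result` with `H` as statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group supplied")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), sizes)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) h <- h / corr
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_stat_test("kruskal_wallis", h, p, N)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `q_level` over a family of `m` hypotheses
#' (`m` defaults to the number of p-values but may be set to the stated
#' family size when some members are implicit).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q_level FDR level.
#' @param m Family size used in the step-up thresholds `i/m * q`.
#' @return List with `reject` (logical), `q_values` (BH-adjusted values,
#'   `min_{j >= i} m * p_(j) / j` capped at 1) and the inputs.
#' @export
fdr_correct <- function(p_values, q_level = 0.05, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  k <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o]
  below <- which(ranked <= seq_len(k) / m * q_level)
  reject <- logical(k)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  qv_sorted <- rev(cummin(rev(pmin(1, m * ranked / seq_len(k)))))
  q_values <- numeric(k)
  q_values[o] <- qv_sorted
  list(reject = reject, q_values = q_values, p_values = p_values,
       q_level = q_level, m = m)
}
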