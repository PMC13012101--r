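#' Two-sided Wilcoxon rank-sum p-value
#'
#' For small groups (`min(n, m) <= exact_max`) the p-value is computed by full
#' enumeration of all `choose(n + m, n)` assignments of the pooled mid-ranks
#' to the first group, which is exact in the presence of ties. The two-sided
#' p is `2 * min(P(W <= w), P(W >= w))`, capped at 1, where `W` is the first
#' group's rank sum. Larger groups use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest `min(n, m)` for which enumeration is used.
#' @return The two-sided p-value.
#' @export
wilcoxon_p <- function(x, y, exact_max = 8) {
  n <- length(x)
  m <- length(y)
  if (n < 2 || m < 2) abort("Each group needs at least 2 observations.")
  if (min(n, m) <= exact_max) {
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n)])
    sums <- combn(n + m, n, FUN = function(idx) sum(r[idx]))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= w + eps), mean(sums >= w - eps))
    min(p, 1)
  } else {
    suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
  }
}
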