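#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for every value u = 0..n*m, the number of labelings of n+m
#' observations into groups of sizes n and m that yield U = u, i.e. the
#' number of partitions of u into at most n parts each at most m. Computed by
#' dynamic programming on the Gaussian binomial coefficient
#' `[n+m choose n]_q` (polynomial multiplication by `(1 - q^(m+i))` and
#' exact synthetic division by `(1 - q^i)`), so the counts are exact
#' integers and sum to `choose(n+m, n)`.
#'
#' @param n,m group sizes.
#' @return Numeric vector of length `n*m + 1`; element `u+1` is the count
#'   for U = u.
#' @export
mwu_null_counts <- function(n, m) {
  stopifnot(n >= 0, m >= 0)
  if (n == 0 || m == 0) return(1)
  poly <- 1
  for (i in seq_len(n)) {
    d <- m + i
    p2 <- c(poly, rep(0, d)) - c(rep(0, d), poly)   # * (1 - q^(m+i))
    for (u in seq_along(p2)) if (u > i) p2[u] <- p2[u] + p2[u - i]  # / (1 - q^i)
    poly <- p2
  }
  poly[seq_len(n * m + 1)]
}

#' Exact one-tailed Mann-Whitney U test
#'
#' Computes `U` as the number of pairs `(a, b)` with `a < b` (direction
#' `"less"`) or `a > b` (direction `"greater"`), and the exact one-tailed
#' p-value `P(U' <= U)` under the uniform-permutation null via
#' [mwu_null_counts()]. Cross-group ties are refused rather than
#' approximated — cumulative-ROH inputs are effectively continuous, and a
#' tie would make the exact distribution inapplicable.
#'
#' @param group_a,group_b numeric vectors of per-sample totals.
#' @param tail direction of the alternative giving the U statistic:
#'   `"less"` counts pairs with `a < b`.
#' @return List with `U`, `p`, and the group sizes `n`, `m`.
#' @export
mwu_groups <- function(group_a, group_b, tail = c("less", "greater")) {
  tail <- match.arg(tail)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (any(outer(group_a, group_b, "==")))
    stop("cross-group ties present; exact U test refused")
  U <- if (tail == "less") sum(outer(group_a, group_b, "<"))
       else sum(outer(group_a, group_b, ">"))
  n <- length(group_a); m <- length(group_b)
  counts <- mwu_null_counts(n, m)
  p <- sum(counts[seq_len(U + 1)]) / choose(n + m, n)
  list(U = U, p = p, n = n, m = m)
}
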