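#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Classic step-up procedure: sort p ascending, set
#' `q_(i) = min_{j >= i} p_(j) * n / j`, clip at 1, restore the input
#' order. Names on `p` are preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`, no missing values.
#' @return numeric vector of q-values, same length and names as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || !all(is.finite(p))) stop("p-values must be finite")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  names(q) <- names(p)
  q
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` are marked, the probability of at least `k`
#' marked draws. Used for pathway over-representation of factor
#' categories. The tail is accumulated in log space for numerical
#' stability at large parameters.
#'
#' @param k observed overlap (integer, `0 <= k <= min(K, n)`).
#' @param K number of marked items in the universe.
#' @param n number of draws.
#' @param N universe size.
#' @return a probability in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(4, 4, 5, 10)   # 6/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (nm in c("k", "K", "n", "N")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v != round(v)) {
      stop(sprintf("parameter '%s' must be a single integer", nm))
    }
  }
  if (N < 0) stop("parameter 'N' must be non-negative")
  if (K < 0 || K > N) stop("parameter 'K' must satisfy 0 <= K <= N")
  if (n < 0 || n > N) stop("parameter 'n' must satisfy 0 <= n <= N")
  if (k < 0) return(1)
  if (k > min(K, n)) stop("parameter 'k' must satisfy k <= min(K, n)")
  i <- seq(k, min(K, n))
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logterms)
  min(1, exp(m + log(sum(exp(logterms - m)))))
}
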