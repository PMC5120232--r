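#' Upper-tail hypergeometric probability P(X >= m)
#'
#' Probability of observing at least `m` marked items when `n` items are
#' drawn without replacement from a population of `N` containing `M` marked
#' items:
#' \deqn{P(X \ge m) = \sum_{k=m}^{\min(M,n)} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}.}
#'
#' Computed through the hypergeometric survival function
#' (`phyper(m - 1, M, N - M, n, lower.tail = FALSE)`) rather than literal
#' summation, which stays numerically stable for genome-scale `N`. By
#' construction `P(X >= 0) = 1` exactly.
#'
#' All arguments are vectorized with the usual recycling.
#'
#' @param N population size (universe size).
#' @param M number of marked items (term-set size after universe
#'   intersection).
#' @param n number of draws (neighborhood size).
#' @param m observed overlap.
#' @return Numeric vector of tail probabilities in (0, 1].
#' @examples
#' upper_tail_hypergeom_p(N = 4, M = 2, n = 2, m = 2)  # 1/6
#' @export
upper_tail_hypergeom_p <- function(N, M, n, m) {
  args <- cbind(N = N, M = M, n = n, m = m)  # recycles
  N <- args[, "N"]; M <- args[, "M"]; n <- args[, "n"]; m <- args[, "m"]
  if (any(args != round(args)) || any(args < 0)) {
    stop("N, M, n, m must be non-negative integers", call. = FALSE)
  }
  if (any(M > N)) stop("invalid parameters: M > N", call. = FALSE)
  if (any(n > N)) stop("invalid parameters: n > N", call. = FALSE)
  if (any(m > pmin(M, n))) {
    stop("invalid parameters: m > min(M, n)", call. = FALSE)
  }
  p <- phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  unname(pmin(p, 1))
}
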