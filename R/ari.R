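#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed from the
#' contingency table of the two labelings:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}) - E}}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}.
#' 1 means identical partitions (up to relabeling), values near 0 random
#' agreement. Both inputs must label the same items; named vectors are
#' aligned by name.
#'
#' @param p1,p2 partition labels (vectors, optionally named).
#' @return a real in [-1, 1].
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions label different item sets")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions label different item sets")
  }
  n <- length(p1)
  tab <- table(p1, p2)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  a <- choose2(rowSums(tab))
  b <- choose2(colSums(tab))
  expected <- a * b / (n * (n - 1) / 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / denom
}
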