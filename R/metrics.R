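#' Contingency table between two partitions
#'
#' Overlap counts `n_ij = |C_ti intersect C_dj|` between the classes of a
#' reference partition (rows) and a detected partition (columns); the shared
#' backbone of [nmi()] and [ari()].
#'
#' @param truth,detected equal-length label vectors (any type).
#' @return Integer matrix of overlaps with row/column sums as attributes
#'   `a` and `b`.
#' @export
contingency_table <- function(truth, detected) {
  if (length(truth) != length(detected))
    stop("label vectors differ in length: ", length(truth), " vs ",
         length(detected))
  if (length(truth) == 0) stop("empty label vectors")
  tab <- table(truth = as.character(truth), detected = as.character(detected))
  tab <- unclass(tab)
  attr(tab, "a") <- rowSums(tab)
  attr(tab, "b") <- colSums(tab)
  tab
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(C_t, C_d) / sqrt(H(C_t) * H(C_d))`: mutual information
#' normalized by the geometric mean of the two entropies, all computed from
#' empirical frequencies with natural logarithms and the convention
#' `0 * log 0 = 0`. 1 means identical partitions (up to relabeling), 0 means
#' independent ones. When exactly one partition is single-class the mutual
#' information is 0 and NMI is defined as 0; when both are single-class the
#' partitions are identical and NMI is 1.
#'
#' @param truth,detected equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @examples
#' nmi(c("A", "A", "B", "B"), c(1, 1, 2, 2))  # 1
#' nmi(c("A", "A", "B", "B"), c(1, 2, 1, 2))  # 0
#' @export
nmi <- function(truth, detected) {
  tab <- contingency_table(truth, detected)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- attr(tab, "a") / n
  pj_ <- attr(tab, "b") / n
  ht <- -sum(xlogx(pi_))
  hd <- -sum(xlogx(pj_))
  if (ht == 0 && hd == 0) return(1)
  if (ht == 0 || hd == 0) return(0)
  ep <- pi_ %o% pj_
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / ep[nz]))
  max(0, min(1, mi / sqrt(ht * hd)))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Adjusted Rand index between two partitions
#'
#' The Rand index corrected for chance with the hypergeometric expectation
#' over the contingency table:
#' `ARI = [sum_ij C(n_ij,2) - E] / [(1/2)(sum_i C(a_i,2) + sum_j C(b_j,2)) - E]`
#' with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. 1 is perfect overlap;
#' 0 is the chance level (random labelings score about 0, and can go
#' slightly negative).
#'
#' @param truth,detected equal-length label vectors.
#' @return ARI (a number <= 1).
#' @examples
#' ari(c("A", "A", "B", "B"), c(2, 2, 1, 1))  # 1
#' @export
ari <- function(truth, detected) {
  tab <- contingency_table(truth, detected)
  n <- sum(tab)
  if (n < 2) return(1)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(attr(tab, "a"), 2))
  sb <- sum(choose(attr(tab, "b"), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial in the same way
  (sij - expected) / denom
}
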