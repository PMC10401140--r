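#' Contingency table of two labelings
#'
#' @param truth,pred vectors of equal length; any atomic label type.
#' @return integer matrix of co-occurrence counts (rows = truth clusters,
#'   columns = predicted clusters).
#' @keywords internal
contingency <- function(truth, pred) {
  if (length(truth) != length(pred))
    stopf("label vectors differ in length (%d vs %d)", length(truth), length(pred))
  if (length(truth) == 0) stopf("empty label vectors")
  unclass(table(factor(truth), factor(pred)))
}

#' Normalized mutual information
#'
#' `NMI(T, P) = 2 I(T, P) / (H(T) + H(P))`, computed from the contingency
#' table with natural logarithms (the base cancels). The sum-normalized
#' form scores 1 for identical partitions and 0 for statistically
#' independent ones. When both partitions are single-cluster (zero
#' entropy) the value is 1 if they are trivially identical, else 0.
#'
#' @param truth,pred label vectors of equal length.
#' @return numeric scalar in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  ct <- contingency(truth, pred)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ht <- ent(pi_); hp <- ent(pj_)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  if (ht + hp == 0) return(1)          # both partitions trivial, identical
  val <- 2 * mi / (ht + hp)
  min(max(val, 0), 1)
}

#' Adjusted Rand index
#'
#' Chance-corrected Rand index computed from the contingency table with
#' pair (binomial) counts: identical partitions score 1; the expected
#' value under random labelings with fixed margins is 0.
#'
#' @param truth,pred label vectors of equal length.
#' @return numeric scalar in `[-1, 1]`.
#' @export
ari <- function(truth, pred) {
  ct <- contingency(truth, pred)
  n <- sum(ct)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(ct))
  sum_i <- sum(choose2(rowSums(ct)))
  sum_j <- sum(choose2(colSums(ct)))
  tot <- choose2(n)
  expected <- sum_i * sum_j / tot
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}
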