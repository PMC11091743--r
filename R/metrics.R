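# External clustering agreement indices. All four are invariant to label
# permutation in either argument; labels need not be contiguous integers.

check_partitions <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions have different lengths (", length(a), " vs ",
         length(b), ")")
  if (length(a) == 0) stop("empty partitions")
  table(as.character(a), as.character(b))
}

entropy_counts <- function(n_k) {
  n <- sum(n_k)
  p <- n_k[n_k > 0] / n
  -sum(p * log(p))
}

mutual_info <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  sum(nij / n * (log(nij * n) - log(a[nz[, 1]] * b[nz[, 2]])))
}

#' Normalized mutual information
#'
#' Mutual information normalized by the arithmetic mean of the two partition
#' entropies (set \code{normalization} for the geometric/min/max variants).
#' A constant partition has zero entropy; by convention the score is then 0.
#'
#' @param a,b partitions (equal-length label vectors).
#' @param normalization one of \code{"arithmetic"}, \code{"geometric"},
#'   \code{"min"}, \code{"max"}.
#' @return value in [0, 1].
#' @export
nmi <- function(a, b, normalization = c("arithmetic", "geometric",
                                        "min", "max")) {
  normalization <- match.arg(normalization)
  ct <- check_partitions(a, b)
  ha <- entropy_counts(rowSums(ct)); hb <- entropy_counts(colSums(ct))
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  min = min(ha, hb),
                  max = max(ha, hb))
  if (denom <= 0) return(0)
  mi <- mutual_info(ct)
  min(1, max(0, mi / denom))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance:
#' (index - expected) / (max - expected).
#'
#' @param a,b partitions (equal-length label vectors).
#' @return value in [-1, 1]; 1 for identical partitions.
#' @export
ari <- function(a, b) {
  ct <- check_partitions(a, b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# expected mutual information under the hypergeometric (fixed-marginals) null
expected_mi <- function(a_marg, b_marg, n) {
  emi <- 0
  lfac <- lfactorial
  for (i in seq_along(a_marg)) {
    ai <- a_marg[i]
    for (j in seq_along(b_marg)) {
      bj <- b_marg[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lfac(ai) + lfac(bj) + lfac(n - ai) + lfac(n - bj) - lfac(n) -
        lfac(nij) - lfac(ai - nij) - lfac(bj - nij) - lfac(n - ai - bj + nij)
      emi <- emi + sum(nij / n * (log(nij * n) - log(ai * bj)) * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' (MI - E[MI]) / (mean entropy - E[MI]) with the hypergeometric
#' expected-mutual-information model, so independent partitions score about 0.
#'
#' @param a,b partitions (equal-length label vectors).
#' @return value <= 1; 1 for identical non-trivial partitions.
#' @export
ami <- function(a, b) {
  ct <- check_partitions(a, b)
  n <- sum(ct)
  am <- rowSums(ct); bm <- colSums(ct)
  ha <- entropy_counts(am); hb <- entropy_counts(bm)
  if (ha == 0 && hb == 0) return(1)   # both constant: trivially identical
  mi <- mutual_info(ct)
  emi <- expected_mi(am, bm, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  (mi - emi) / denom
}

#' Clustering accuracy
#'
#' Maximum fraction of agreeing cells over one-to-one matchings between
#' predicted clusters and true classes (Hungarian method on the contingency
#' table).
#'
#' @param truth,pred partitions (equal-length label vectors).
#' @return value in [0, 1].
#' @export
acc <- function(truth, pred) {
  ct <- check_partitions(truth, pred)
  assign <- solve_assignment(ct, maximize = TRUE)
  attr(assign, "cost") / sum(ct)
}

#' All four agreement metrics at once
#'
#' @param truth,pred partitions.
#' @return named numeric vector \code{nmi}, \code{ari}, \code{ami},
#'   \code{acc}.
#' @export
cluster_metrics <- function(truth, pred) {
  c(nmi = nmi(truth, pred), ari = ari(truth, pred),
    ami = ami(truth, pred), acc = acc(truth, pred))
}
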