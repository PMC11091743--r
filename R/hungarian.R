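#' Minimum-cost one-to-one assignment (Hungarian method)
#'
#' O(n^3) shortest-augmenting-path implementation with row/column potentials.
#' Rectangular matrices are padded with zeros to square, so with fewer rows
#' than columns every row is assigned and surplus columns stay unmatched.
#'
#' @param cost numeric cost matrix (rows <= columns, or any shape; padded
#'   internally).
#' @param maximize solve the maximum-profit problem instead.
#' @return integer vector \code{assignment} of length \code{nrow(cost)}:
#'   column assigned to each row; attribute \code{"cost"} holds the optimal
#'   total over the original (unpadded) entries.
#' @export
solve_assignment <- function(cost, maximize = FALSE) {
  cost <- as.matrix(cost)
  orig_r <- nrow(cost); orig_c <- ncol(cost)
  a <- if (maximize) -cost else cost
  n <- max(orig_r, orig_c)
  sq <- matrix(0, n, n)
  sq[seq_len(orig_r), seq_len(orig_c)] <- a

  J <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[J] <- i
    j0 <- J
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- sq[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J) break
    }
  }
  col_of_row <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) col_of_row[p[j]] <- j
  res <- col_of_row[seq_len(orig_r)]
  real <- res <= orig_c & res > 0L
  total <- sum(cost[cbind(which(real), res[real])])
  res[!real] <- NA_integer_
  attr(res, "cost") <- total
  res
}
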