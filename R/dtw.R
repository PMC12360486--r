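#' Multivariate dynamic time warping with a slanted-band constraint
#'
#' Aligns two multivariate time series by dynamic programming with the
#' symmetric2 step pattern, in which a diagonal move costs twice the local
#' distance and horizontal/vertical moves cost it once:
#' `D[i,j] = min(D[i-1,j-1] + 2 d, D[i-1,j] + d, D[i,j-1] + d)`.
#' Cells are restricted to a slanted band of half-width `band_bins`
#' around the line connecting `(1, 1)` to `(n, m)`, which bounds how far
#' the warp can deviate from a uniform time rescaling so alignment cannot
#' overfit noise. The local distance is Euclidean over the feature
#' dimensions.
#'
#' @param a,b numeric matrices `bins x dims` with matching `dims`.
#' @param band_bins slanted-band half-width in bins (may be fractional).
#' @return List with the warping path (`index_a`, `index_b`),
#'   the accumulated `cost` and `normalized_cost` (`cost / (n + m)`).
#' @export
dtw_align <- function(a, b, band_bins = Inf) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("series must share feature dimensions")
  n <- nrow(a); m <- nrow(b)
  if (n < 1 || m < 1) stop("series must be nonempty")
  # pairwise Euclidean local distances via the expansion of ||x - y||^2
  cross <- tcrossprod(a, b)
  d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross, 0))

  slope <- m / n
  inside <- function(i, j) abs(j - i * slope) <= band_bins + 1e-9
  D <- matrix(Inf, n, m)
  D[1, 1] <- 2 * d[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      if (!inside(i, j)) next
      up <- if (i > 1) D[i - 1, j] + d[i, j] else Inf
      left <- if (j > 1) D[i, j - 1] + d[i, j] else Inf
      diag <- if (i > 1 && j > 1) D[i - 1, j - 1] + 2 * d[i, j] else Inf
      D[i, j] <- min(up, left, diag)
    }
  }
  if (!is.finite(D[n, m])) {
    stop("alignment infeasible within the slanted band; widen band_bins")
  }

  ia <- n; jb <- m
  path_i <- integer(0); path_j <- integer(0)
  repeat {
    path_i <- c(ia, path_i); path_j <- c(jb, path_j)
    if (ia == 1 && jb == 1) break
    moves <- rbind(
      c(ia - 1, jb - 1, if (ia > 1 && jb > 1)
        D[ia - 1, jb - 1] + 2 * d[ia, jb] else Inf),
      c(ia - 1, jb, if (ia > 1) D[ia - 1, jb] + d[ia, jb] else Inf),
      c(ia, jb - 1, if (jb > 1) D[ia, jb - 1] + d[ia, jb] else Inf))
    best <- which.min(abs(moves[, 3] - D[ia, jb]) +
                        ifelse(is.finite(moves[, 3]), 0, Inf))
    ia <- moves[best, 1]; jb <- moves[best, 2]
  }
  list(index_a = as.integer(path_i), index_b = as.integer(path_j),
       cost = D[n, m], normalized_cost = D[n, m] / (n + m))
}
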