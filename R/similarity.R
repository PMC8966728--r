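# Cosine-similarity kernels shared by the phonological and semantic spaces.
# All pair enumeration is lexicographic over the upper triangle (i < j), and
# the linear position of pair (i, j) among the n(n-1)/2 pairs is
#   (i - 1) * n - i * (i + 1) / 2 + j
# which lets height sweeps index precomputed similarity vectors directly.

# Row norms; rows of (numerically) zero norm are flagged undefined.
row_norms <- function(x) sqrt(rowSums(x * x))

#' Cosine similarity for given index pairs
#'
#' Vectorized cosine between rows `i` and `j` of a matrix. Pairs involving a
#' zero-norm row are `NA` (undefined rather than zero: a sign with no
#' annotations in a scope has no direction in that space).
#'
#' @param x Numeric matrix (rows are vectors).
#' @param i,j Integer vectors of equal length; row indices.
#' @return Numeric vector of cosines in `[-1, 1]`, `NA` where undefined.
#' @export
cosine_pairs <- function(x, i, j) {
  stopifnot(length(i) == length(j))
  nr <- row_norms(x)
  denom <- nr[i] * nr[j]
  num <- rowSums(x[i, , drop = FALSE] * x[j, , drop = FALSE])
  out <- ifelse(denom > 0, num / denom, NA_real_)
  pmin(1, pmax(-1, out))
}

# Full upper-triangle cosine vector in lexicographic (i < j) order, computed
# in row blocks so the n x n similarity matrix is never materialized.
cosine_upper <- function(x, block_size = 512L) {
  n <- nrow(x)
  stopifnot(n >= 2)
  nr <- row_norms(x)
  ok <- nr > 0
  xn <- x
  xn[ok, ] <- x[ok, , drop = FALSE] / nr[ok]
  out <- numeric(n * (n - 1) / 2)
  pos <- 1L
  for (start in seq(1L, n - 1L, by = block_size)) {
    end <- min(start + block_size - 1L, n - 1L)
    sims <- tcrossprod(xn[start:end, , drop = FALSE], xn)
    for (ii in start:end) {
      m <- n - ii
      v <- sims[ii - start + 1L, (ii + 1L):n]
      if (!ok[ii]) v[] <- NA_real_
      v[!ok[(ii + 1L):n]] <- NA_real_
      out[pos:(pos + m - 1L)] <- pmin(1, pmax(-1, v))
      pos <- pos + m
    }
  }
  out
}

# Linear positions of pairs (i, j), i < j, in the lexicographic upper
# triangle of an n-point pair vector.
pair_position <- function(i, j, n) {
  (i - 1) * n - i * (i + 1) / 2 + j
}
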