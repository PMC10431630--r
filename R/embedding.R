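#' Extract all sliding-window subsequences of a series
#'
#' Slides a window of length `w_g` over the series with step 1 and stacks the
#' windows as rows of a matrix, so row `i` (1-based in R) is the subsequence
#' starting at 0-based sample index `i - 1`.
#'
#' @param x Numeric vector, the time series (finite values).
#' @param w_g Window length in samples; must satisfy `2 <= w_g <= length(x) - 1`.
#' @return An `N x w_g` numeric matrix with `N = length(x) - w_g + 1`.
#' @examples
#' extract_subsequences(1:10, 4)
#' @export
extract_subsequences <- function(x, w_g) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("series contains NA or non-finite values")
  w_g <- as.integer(w_g)
  if (length(w_g) != 1L || is.na(w_g) || w_g < 2L || w_g > n - 1L)
    stop(sprintf("w_g must be in [2, n - 1] = [2, %d]; got %s", n - 1L, w_g))
  N <- n - w_g + 1L
  Z <- matrix(0, N, w_g)
  for (j in seq_len(w_g)) Z[, j] <- x[j:(j + N - 1L)]
  Z
}

#' Z-normalize each subsequence (row) of a window matrix
#'
#' Each row is shifted to mean zero and scaled to unit *population* standard
#' deviation (divisor `w_g`, not `w_g - 1`), so comparison between windows is
#' shape-based rather than level-based.  Rows whose standard deviation falls
#' below `eps` (constant segments) are replaced by all-zero rows instead of
#' producing NaNs, and their indices are reported.
#'
#' @param Z Matrix of windows as returned by [extract_subsequences()].
#' @param eps Degeneracy threshold on the population standard deviation.
#' @return The normalized matrix, with attribute `degenerate_rows` holding the
#'   1-based indices of zeroed rows (possibly empty).
#' @export
znormalize <- function(Z, eps = 1e-12) {
  mu <- rowMeans(Z)
  sd_pop <- sqrt(pmax(rowMeans(Z * Z) - mu * mu, 0))
  degen <- which(sd_pop < eps)
  sd_safe <- ifelse(sd_pop < eps, 1, sd_pop)
  Zn <- (Z - mu) / sd_safe
  if (length(degen)) Zn[degen, ] <- 0
  attr(Zn, "degenerate_rows") <- degen
  Zn
}

#' Project z-normalized windows onto their top two principal components
#'
#' Computes an exact PCA of the row set (columns centered by their means) via
#' eigen-decomposition of the `w_g x w_g` covariance matrix and keeps the two
#' leading components, yielding the 2D spatial-temporal embedding in which
#' similarly shaped windows land close together.  The sign of each component
#' is fixed deterministically: the loading of largest absolute value is made
#' positive.
#'
#' @param Zn Normalized window matrix from [znormalize()], `N >= 2` rows.
#' @return A list of class `tsg_embedding`: `points` (`N x 2` coordinates in
#'   temporal order) and `explained` (variance fractions of the two kept
#'   components).
#' @export
project_2d <- function(Zn) {
  N <- nrow(Zn)
  if (is.null(N) || N < 2L || ncol(Zn) < 2L)
    stop("need at least 2 windows of length >= 2")
  Zc <- sweep(Zn, 2L, colMeans(Zn), check.margin = FALSE)
  e <- eigen(crossprod(Zc), symmetric = TRUE)
  v <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i_star <- which.max(abs(v[, j]))
    if (v[i_star, j] < 0) v[, j] <- -v[, j]
  }
  ev <- pmax(e$values, 0)
  total <- sum(ev)
  structure(list(
    points = Zc %*% v,
    explained = if (total > 0) ev[1:2] / total else c(0, 0)
  ), class = "tsg_embedding")
}

#' Embed a series into the 2D spatial-temporal space
#'
#' Convenience wrapper chaining [extract_subsequences()], [znormalize()] and
#' [project_2d()].
#'
#' @inheritParams extract_subsequences
#' @param eps Degeneracy threshold passed to [znormalize()].
#' @return A `tsg_embedding` (see [project_2d()]).
#' @export
embed_windows <- function(x, w_g, eps = 1e-12) {
  project_2d(znormalize(extract_subsequences(x, w_g), eps = eps))
}

#' @export
print.tsg_embedding <- function(x, ...) {
  cat(sprintf("2D window embedding: %d points, explained variance %.1f%% + %.1f%%\n",
              nrow(x$points), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}
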