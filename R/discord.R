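#' Brute-force nearest-neighbor discord baseline
#'
#' Classic discord ranking used as an independent baseline: each length-`l`
#' window is z-normalized and its Euclidean distance to the nearest
#' non-overlapping window (temporal offset `> exclusion`) is computed by
#' exhaustive comparison; windows are ranked by *descending* nearest-neighbor
#' distance and the top `k` are reported with the same exclusion-zone rule as
#' [detect_topk()].  By construction this definition misses recurrent
#' anomalies: when an abnormal shape occurs twice, each instance finds its
#' twin at a small distance and drops down the ranking.
#'
#' Distances are computed blockwise with BLAS matrix products, so memory
#' stays O(N * block) rather than O(N^2).
#'
#' @param x Numeric series.
#' @param l Window length.
#' @param k Number of discords to report.
#' @param exclusion Minimum temporal offset for a valid neighbor (default `l`,
#'   i.e. non-overlapping windows only).
#' @param block Rows per distance block.
#' @return An `anomaly_report` data.frame (`rank`, `start` 0-based, `length`,
#'   `score` = nearest-neighbor distance, descending).
#' @export
nn_discord_topk <- function(x, l, k = 1, exclusion = l, block = 512L) {
  A <- znormalize(extract_subsequences(x, l))
  N <- nrow(A)
  norms <- rowSums(A * A)
  nn <- numeric(N)
  for (b0 in seq(1L, N, by = block)) {
    b1 <- min(b0 + block - 1L, N)
    G <- A[b0:b1, , drop = FALSE] %*% t(A)
    for (r in seq_len(b1 - b0 + 1L)) {
      i <- b0 + r - 1L
      d2 <- norms[i] + norms - 2 * G[r, ]
      d2[max(1L, i - exclusion):min(N, i + exclusion)] <- Inf
      nn[i] <- sqrt(max(min(d2), 0))
    }
  }
  ord <- order(-nn, seq_len(N))
  alive <- rep(TRUE, N)
  starts <- integer(0)
  scores <- numeric(0)
  for (j in ord) {
    if (!alive[j]) next
    starts <- c(starts, j - 1L)
    scores <- c(scores, nn[j])
    alive[max(1L, j - l):min(N, j + l)] <- FALSE
    if (length(starts) >= k) break
  }
  structure(data.frame(rank = seq_along(starts), start = starts,
                       length = as.integer(l), score = scores),
            class = c("anomaly_report", "data.frame"),
            truncated = length(starts) < k)
}
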