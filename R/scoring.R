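# Per-transition edge weights along a node path, read from the graph.
# When path and graph come from the same build every edge is present;
# an unseen transition (foreign path) would get weight 0.
transition_weights <- function(graph, path) {
  N <- length(path)
  key <- as.numeric(path[-N]) * graph$grid$n_cell + as.numeric(path[-1L])
  gkey <- as.numeric(graph$edges$from) * graph$grid$n_cell + as.numeric(graph$edges$to)
  w <- graph$edges$weight[match(key, gkey)]
  w[is.na(w)] <- 0
  w
}

#' Score one subsequence by its mean edge weight
#'
#' The path of the length-`l` subsequence starting at 0-based index `i`
#' traverses the `l` edges `(v^i, v^{i+1}), ..., (v^{i+l-1}, v^{i+l})`; its
#' score is the sum of those edge weights divided by `l`.  Low scores mark
#' rarely traversed (anomalous) trajectories.
#'
#' @param graph A `tsg_graph`.
#' @param path Node path the graph was built from.
#' @param i 0-based start index, `0 <= i <= length(path) - l - 1`.
#' @param l Subsequence length in samples (`>= 1`).
#' @return The mean edge weight, a non-negative scalar.
#' @export
subsequence_score <- function(graph, path, i, l) {
  N <- length(path)
  if (l < 1L) stop("l must be >= 1")
  if (i < 0L || i > N - l - 1L)
    stop(sprintf("start index i must be in [0, %d]; got %s", N - l - 1L, i))
  tw <- transition_weights(graph, path)
  sum(tw[(i + 1L):(i + l)]) / l
}

#' Score every subsequence of one length along the path
#'
#' Computes [subsequence_score()] for all valid starts
#' `i = 0 .. length(path) - l - 1` in O(N) via a cumulative sum over the
#' per-transition weights.
#'
#' @inheritParams subsequence_score
#' @return An object of class `tsg_profile`: `scores` (element `i + 1` is the
#'   score of start `i`), `l`, and `smoothed = FALSE`.
#' @export
score_profile <- function(graph, path, l) {
  N <- length(path)
  l <- as.integer(l)
  if (l < 1L) stop("l must be >= 1")
  if (N < l + 1L) stop("path too short for this subsequence length")
  cs <- c(0, cumsum(transition_weights(graph, path)))
  i0 <- 0:(N - 1L - l)
  structure(list(scores = (cs[i0 + l + 1L] - cs[i0 + 1L]) / l,
                 l = l, smoothed = FALSE),
            class = "tsg_profile")
}

#' Smooth a score profile with a centered moving average
#'
#' Window `w` is centered on each index; near the boundaries the window
#' shrinks symmetrically (no padding values are invented), which keeps score
#' minima aligned with anomaly centers.  Even `w` is widened to the next odd
#' width.
#'
#' @param profile A `tsg_profile`.
#' @param w Smoothing window width in samples (`>= 1`); the usual choice is
#'   the embedding window `w_g`.
#' @return The smoothed `tsg_profile` (same length, `smoothed = TRUE`).
#' @export
smooth_scores <- function(profile, w) {
  stopifnot(inherits(profile, "tsg_profile"))
  w <- as.integer(w)
  if (w < 1L) stop("smoothing window must be >= 1")
  s <- profile$scores
  L <- length(s)
  h <- w %/% 2L
  idx <- seq_len(L)
  he <- pmin(h, idx - 1L, L - idx)          # symmetric shrink at both ends
  cs <- c(0, cumsum(s))
  profile$scores <- (cs[idx + he + 1L] - cs[idx - he]) / (2L * he + 1L)
  profile$smoothed <- TRUE
  profile
}

#' Rank the lowest-scoring subsequences with exclusion zones
#'
#' Greedy selection: repeatedly take the global minimum of the (smoothed)
#' score profile, report it, and mask all starts within `l` samples on either
#' side (the exclusion zone that suppresses trivial matches), until `k`
#' detections are found or the profile is exhausted.  Ties are broken by the
#' smaller start index.  With `k = NULL` the full ranked list surviving
#' exclusion is returned.
#'
#' @param profile A `tsg_profile` (smoothing recommended first).
#' @param k Number of anomalies to report, or `NULL` for all survivors.
#' @param l Reported subsequence length; defaults to the profile's own.
#' @return An `anomaly_report`: a data.frame with columns `rank`, `start`
#'   (0-based), `length`, `score`, ordered by ascending score.  Attribute
#'   `truncated` is `TRUE` when fewer than `k` survivors exist.
#' @export
detect_topk <- function(profile, k = NULL, l = profile$l) {
  stopifnot(inherits(profile, "tsg_profile"))
  s <- profile$scores
  L <- length(s)
  ord <- order(s, seq_len(L))
  alive <- rep(TRUE, L)
  starts <- integer(0)
  scores <- numeric(0)
  want <- if (is.null(k)) L else as.integer(k)
  if (want < 1L) stop("k must be >= 1")
  for (j in ord) {
    if (!alive[j]) next
    starts <- c(starts, j - 1L)
    scores <- c(scores, s[j])
    alive[max(1L, j - l):min(L, j + l)] <- FALSE
    if (length(starts) >= want) break
  }
  rep_df <- data.frame(rank = seq_along(starts), start = starts,
                       length = as.integer(l), score = scores)
  structure(rep_df, class = c("anomaly_report", "data.frame"),
            truncated = !is.null(k) && nrow(rep_df) < k)
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("anomaly report: %d detection(s), length %s\n",
              nrow(x), paste(unique(x$length), collapse = "/")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Scan a range of subsequence lengths from one graph build
#'
#' Scores every length `l` in `seq(minL, maxL, by = step)` against the *same*
#' graph and path (no re-embedding), returning a per-length report and a
#' merged cross-length ranking.  Scores are per-edge means and therefore
#' comparable across lengths; the merged list pools all detections, sorts by
#' ascending score, and greedily keeps interval-disjoint entries.
#'
#' @inheritParams subsequence_score
#' @param minL,maxL Inclusive length range (`1 <= minL <= maxL`).
#' @param step Length increment (`>= 1`).
#' @param k Detections per length.
#' @param smooth_window Moving-average width applied to each profile; `NULL`
#'   skips smoothing.
#' @param exclusion_pad Samples appended to the right end of each detection
#'   interval when testing overlap during the merge.  A detection at start
#'   `i` of length `l` scores the windows `i .. i+l`, i.e. the data span
#'   `[i, i + l + w_g)`; merging on that span (pass `exclusion_pad = w_g`)
#'   stops two short detections inside one long anomaly from being reported
#'   as two events.  Default 0 (bare intervals).
#' @return A list of class `tsg_scan`: `per_length` (named list of
#'   `anomaly_report`s keyed by length) and `merged` (data.frame with columns
#'   `rank`, `start`, `length`, `score`).
#' @export
scan_lengths <- function(graph, path, minL, maxL, step = 1, k = 1,
                         smooth_window = NULL, exclusion_pad = 0) {
  if (minL < 1 || maxL < minL || step < 1) stop("need 1 <= minL <= maxL and step >= 1")
  if (length(path) < maxL + 1L) stop("maxL too large for this path")
  lens <- seq(as.integer(minL), as.integer(maxL), by = as.integer(step))
  per <- lapply(lens, function(l) {
    p <- score_profile(graph, path, l)
    if (!is.null(smooth_window)) p <- smooth_scores(p, smooth_window)
    detect_topk(p, k = k, l = l)
  })
  names(per) <- as.character(lens)
  pool <- do.call(rbind, lapply(per, as.data.frame))
  pool <- pool[order(pool$score, pool$start), , drop = FALSE]
  keep <- logical(nrow(pool))
  ends <- pool$start + pool$length + exclusion_pad
  for (i in seq_len(nrow(pool))) {
    sel <- which(keep)
    keep[i] <- !any(pool$start[i] < ends[sel] & pool$start[sel] < ends[i])
  }
  merged <- pool[keep, c("start", "length", "score"), drop = FALSE]
  merged <- data.frame(rank = seq_len(nrow(merged)), merged, row.names = NULL)
  structure(list(per_length = per, merged = merged), class = "tsg_scan")
}

#' @export
print.tsg_scan <- function(x, ...) {
  cat(sprintf("variable-length scan: %d lengths, %d merged detection(s)\n",
              length(x$per_length), nrow(x$merged)))
  print.data.frame(utils::head(x$merged, 10L), row.names = FALSE)
  invisible(x)
}

#' Top-K accuracy of a report against ground truth
#'
#' A detection counts as a hit when its interval `[start, start + length)`
#' intersects a true anomaly interval not already claimed by a higher-ranked
#' detection (greedy one-to-one matching by rank).  Accuracy is `hits / k`.
#'
#' @param report An `anomaly_report` or data.frame with `start` and `length`.
#' @param truth Data.frame with half-open 0-based intervals `start`, `end`
#'   (non-overlapping), e.g. from [synth_series()].
#' @param k Divisor of the accuracy; defaults to the number of detections.
#' @param pad Samples appended to the right end of each detection interval
#'   before testing overlap.  A detection at start `i` of length `l` is
#'   scored from the path nodes of windows `i .. i+l`, i.e. it summarizes the
#'   data span `[i, i + l + w_g)`; passing `pad = w_g` judges overlap on that
#'   flagged span, which matters when `l` is shorter than the embedding
#'   window (variable-length scans).  Default 0 (bare subsequence interval).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_topk <- function(report, truth, k = nrow(report), pad = 0) {
  if (k < 1) stop("k must be >= 1")
  claimed <- rep(FALSE, nrow(truth))
  hits <- 0L
  for (i in seq_len(nrow(report))) {
    d0 <- report$start[i]
    d1 <- d0 + report$length[i] + pad
    open <- which(!claimed & truth$start < d1 & d0 < truth$end)
    if (length(open)) {
      claimed[open[1L]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits / k
}
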