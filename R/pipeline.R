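#' End-to-end subsequence anomaly detection
#'
#' Runs the full pipeline on a series: embed all length-`w_g` windows into
#' the 2D spatial-temporal space, bin them onto the grid, build the weighted
#' transition graph, score every length-`l` subsequence by its mean edge
#' weight, smooth the score profile with a centered moving average, and
#' report the `k` lowest-scoring subsequences under exclusion zones.
#'
#' Defaults follow the method's standard parameter policy: `n_cell = 100`
#' grid cells, `l = w_g`, smoothing window `= w_g`; `w_g` itself is usually
#' set slightly below the normal-pattern length (`period - 20`, see
#' [estimate_period_hint()]).
#'
#' @param x Numeric series (or a `tsg_synth`, whose `$values` are used).
#' @param w_g Embedding window length.
#' @param l Anomaly (scored subsequence) length; defaults to `w_g`.
#' @param n_cell Grid cells (perfect square).
#' @param k Detections to report; `NULL` returns the full ranked list.
#' @param smooth_window Moving-average width; `NULL` disables smoothing.
#' @return A list of class `tsg_result`: `report` (an `anomaly_report`),
#'   `profile`, `graph`, `path`, `embedding`, and the echoed parameters.
#' @examples
#' s <- synth_series(20, period = 100,
#'                   anomalies = data.frame(cycle = 9, length = 110, shape = "inverted"),
#'                   noise_sd = 0.02, seed = 7)
#' res <- tsg_detect(s, w_g = 80, l = 110, k = 1)
#' res$report
#' @export
tsg_detect <- function(x, w_g, l = w_g, n_cell = 100, k = NULL,
                       smooth_window = w_g) {
  if (inherits(x, "tsg_synth")) x <- x$values
  built <- build_series_graph(x, w_g, n_cell)
  profile <- score_profile(built$graph, built$path, l)
  if (!is.null(smooth_window)) profile <- smooth_scores(profile, smooth_window)
  report <- detect_topk(profile, k = k, l = l)
  if (isTRUE(attr(report, "truncated")))
    warning(sprintf("only %d detection(s) survive exclusion zones (k = %d)",
                    nrow(report), k))
  structure(list(report = report, profile = profile, graph = built$graph,
                 path = built$path, embedding = built$embedding,
                 params = list(w_g = w_g, l = l, n_cell = n_cell, k = k,
                               smooth_window = smooth_window)),
            class = "tsg_result")
}

#' @export
print.tsg_result <- function(x, ...) {
  st <- occupancy_stats(x$graph)
  cat(sprintf("series of %d windows -> graph with %d/%d nodes; l = %d\n",
              x$graph$n_windows, st$n_nodes, x$graph$grid$n_cell, x$profile$l))
  print(x$report)
  invisible(x)
}

#' End-to-end variable-length anomaly scan
#'
#' Builds the graph once and scans subsequence lengths `minL..maxL` against
#' it (see [scan_lengths()]).  The cross-length merge uses the flagged data
#' span (`exclusion_pad = w_g`) so one long anomaly is not reported twice via
#' two short detections.
#'
#' @inheritParams tsg_detect
#' @inheritParams scan_lengths
#' @return A list of class `tsg_scan_result`: `scan` (a `tsg_scan`), `graph`,
#'   `path`, and the echoed parameters.
#' @export
tsg_scan <- function(x, w_g, minL, maxL, step = 1, k = 1, n_cell = 100,
                     smooth_window = w_g) {
  if (inherits(x, "tsg_synth")) x <- x$values
  built <- build_series_graph(x, w_g, n_cell)
  scan <- scan_lengths(built$graph, built$path, minL, maxL, step = step,
                       k = k, smooth_window = smooth_window,
                       exclusion_pad = w_g)
  structure(list(scan = scan, graph = built$graph, path = built$path,
                 params = list(w_g = w_g, minL = minL, maxL = maxL,
                               step = step, k = k, n_cell = n_cell,
                               smooth_window = smooth_window)),
            class = "tsg_scan_result")
}

#' @export
print.tsg_scan_result <- function(x, ...) {
  print(x$scan)
  invisible(x)
}
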