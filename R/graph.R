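#' Partition the 2D embedding into a regular grid and map points to cells
#'
#' The bounding box of the embedded points is divided into `n_c` cells per
#' axis (`n_cell = n_c^2` total).  Point `(x, y)` falls in column
#' `floor((x - x_min) / s_x)` and row `floor((y - y_min) / s_y)`, both clamped
#' to `[0, n_c - 1]` so points exactly on the right/top boundary land in the
#' last cell.  A degenerate axis (all coordinates equal) maps every point to
#' column/row 0.  Cell (node) ids are row-major: `row * n_c + col`, 0-based.
#'
#' @param emb A `tsg_embedding` from [project_2d()], or an `N x 2` matrix.
#' @param n_cell Total number of grid cells; must be a perfect square `>= 4`.
#' @return A list: `grid` (list with `n_c`, `n_cell`, bounding box and cell
#'   sizes `s_x`, `s_y`) and `path` (integer vector of node ids, one per
#'   window, in temporal order).
#' @export
grid_partition <- function(emb, n_cell = 100) {
  pts <- if (inherits(emb, "tsg_embedding")) emb$points else as.matrix(emb)
  if (nrow(pts) < 1L || ncol(pts) != 2L) stop("embedding must be a non-empty N x 2 point set")
  n_c <- as.integer(round(sqrt(n_cell)))
  if (n_c < 2L || n_c * n_c != n_cell)
    stop("n_cell must be a perfect square >= 4")
  bb <- c(x_min = min(pts[, 1]), x_max = max(pts[, 1]),
          y_min = min(pts[, 2]), y_max = max(pts[, 2]))
  s_x <- (bb["x_max"] - bb["x_min"]) / n_c
  s_y <- (bb["y_max"] - bb["y_min"]) / n_c
  col <- if (s_x > 0) pmin(floor((pts[, 1] - bb["x_min"]) / s_x), n_c - 1L) else 0L
  row <- if (s_y > 0) pmin(floor((pts[, 2] - bb["y_min"]) / s_y), n_c - 1L) else 0L
  list(
    grid = list(n_c = n_c, n_cell = as.integer(n_cell),
                x_min = unname(bb["x_min"]), x_max = unname(bb["x_max"]),
                y_min = unname(bb["y_min"]), y_max = unname(bb["y_max"]),
                s_x = unname(s_x), s_y = unname(s_y)),
    path = as.integer(row * n_c + col)
  )
}

#' Build the weighted transition graph from a node path
#'
#' Each consecutive pair of path nodes `(path[t], path[t+1])` increments the
#' weight of that directed edge by one; equal ids produce self-loops.  The
#' node set is exactly the set of cell ids visited, so the graph never has
#' more than `n_cell` nodes regardless of series length, and the edge weights
#' sum to `length(path) - 1` exactly.
#'
#' @param path Integer vector of 0-based cell ids in temporal order
#'   (length `>= 2`), as produced by [grid_partition()].
#' @param grid Grid descriptor from [grid_partition()].
#' @return An object of class `tsg_graph`: `edges` (data.frame `from`, `to`,
#'   `weight`), `nodes` (data.frame `id`, `row`, `col`), `grid`, `n_windows`,
#'   and `step_weights` — the weight of the edge traversed at each of the
#'   `N - 1` transitions, used for fast scoring.
#' @export
build_graph <- function(path, grid) {
  N <- length(path)
  if (N < 2L) stop("path must contain at least 2 nodes")
  from <- path[-N]
  to <- path[-1L]
  key <- as.numeric(from) * grid$n_cell + as.numeric(to)  # unique per edge
  r <- rle(sort(key))
  edges <- data.frame(
    from = as.integer(r$values %/% grid$n_cell),
    to = as.integer(r$values %% grid$n_cell),
    weight = r$lengths
  )
  ids <- sort(unique(path))
  nodes <- data.frame(id = ids,
                      row = ids %/% grid$n_c,
                      col = ids %% grid$n_c)
  structure(list(
    edges = edges, nodes = nodes, grid = grid, n_windows = N,
    step_weights = r$lengths[match(key, r$values)]
  ), class = "tsg_graph")
}

#' Graph occupancy summary
#'
#' @param graph A `tsg_graph`.
#' @return A list: `n_nodes` (occupied cells, always `<= n_cell`),
#'   `self_loop_fraction` (share of total edge weight on self-loops) and
#'   `max_weight`.
#' @export
occupancy_stats <- function(graph) {
  stopifnot(inherits(graph, "tsg_graph"))
  w <- graph$edges$weight
  loops <- graph$edges$from == graph$edges$to
  list(
    n_nodes = nrow(graph$nodes),
    self_loop_fraction = sum(w[loops]) / sum(w),
    max_weight = max(w)
  )
}

#' @export
print.tsg_graph <- function(x, ...) {
  st <- occupancy_stats(x)
  cat(sprintf(
    "transition graph: %d nodes (grid %dx%d), %d edges, total weight %d (self-loops %.1f%%)\n",
    st$n_nodes, x$grid$n_c, x$grid$n_c, nrow(x$edges), sum(x$edges$weight),
    100 * st$self_loop_fraction))
  invisible(x)
}

#' Build the transition graph directly from a series
#'
#' Runs the full representation stage: window extraction, z-normalization,
#' 2D PCA embedding, grid partition and transition counting.
#'
#' @inheritParams extract_subsequences
#' @inheritParams grid_partition
#' @return A list: `graph` (a `tsg_graph`), `path` (node ids per window) and
#'   `embedding` (the `tsg_embedding`).
#' @export
build_series_graph <- function(x, w_g, n_cell = 100) {
  emb <- embed_windows(x, w_g)
  gp <- grid_partition(emb, n_cell)
  list(graph = build_graph(gp$path, gp$grid), path = gp$path, embedding = emb)
}
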