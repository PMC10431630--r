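# Delimiter sniffing for tabular text: first matching of tab, comma,
# semicolon wins; otherwise whitespace.
sniff_delim <- function(line) {
  if (grepl("\t", line)) "\t"
  else if (grepl(",", line)) ","
  else if (grepl(";", line)) ";"
  else ""
}

#' Read a univariate time series from a tabular text file
#'
#' Accepts single-column plain text, CSV or TSV (delimiter sniffed unless
#' given).  A non-numeric first row is treated as a header and skipped.  Any
#' non-numeric, NA, or non-finite value elsewhere is a hard error naming the
#' offending line: the method has no missing-data semantics, so nothing is
#' imputed.
#'
#' @param path Path to the file.
#' @param column Column to read: name (requires a header) or 1-based index.
#'   Default: the only column, or the first of several.
#' @param delim Field delimiter; `NULL` to sniff (`\t`, `,`, `;`, whitespace).
#' @return A list of class `tsg_series`: `values` (numeric), `name` (column
#'   label or file name), `n`.
#' @export
load_series <- function(path, column = NULL, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty file: %s", path))
  if (is.null(delim)) delim <- sniff_delim(lines[1L])
  tab <- utils::read.table(text = lines, sep = delim, header = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  first_vals <- suppressWarnings(as.numeric(tab[1L, ]))
  has_header <- anyNA(first_vals)
  header <- if (has_header) as.character(unlist(tab[1L, ])) else NULL
  body <- if (has_header) tab[-1L, , drop = FALSE] else tab
  if (!nrow(body))
    stop(sprintf("no numeric data in %s: non-numeric value '%s' at line 1 and no rows follow",
                 path, tab[1L, 1L]))

  ci <- 1L
  if (!is.null(column)) {
    if (is.character(column)) {
      if (is.null(header)) stop("column selected by name but file has no header")
      ci <- match(column, header)
      if (is.na(ci)) stop(sprintf("no column named '%s' (header: %s)",
                                  column, paste(header, collapse = ", ")))
    } else ci <- as.integer(column)
    if (ci < 1L || ci > ncol(body)) stop(sprintf("column index %d out of range", ci))
  }

  raw <- body[[ci]]
  vals <- suppressWarnings(as.numeric(raw))
  line_no <- seq_len(nrow(body)) + has_header
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite value '%s' at line %d of %s",
                 raw[bad[1L]], line_no[bad[1L]], path))
  if (length(vals) < 2L) stop("series must contain at least 2 points")
  structure(list(values = vals,
                 name = if (!is.null(header)) header[ci] else basename(path),
                 n = length(vals)),
            class = "tsg_series")
}

#' @export
print.tsg_series <- function(x, ...) {
  cat(sprintf("time series '%s': n = %d, range [%.4g, %.4g]\n",
              x$name, x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Write an anomaly report as TSV
#'
#' Columns `rank`, `start`, `length`, `score` (scores with 15 significant
#' digits, so a write/read round trip reproduces them to well below 1e-9).
#'
#' @param report An `anomaly_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- data.frame(rank = report$rank, start = report$start,
                    length = report$length,
                    score = formatC(report$score, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV anomaly report
#'
#' @param path Path written by [write_report()].
#' @return An `anomaly_report` data.frame.
#' @export
read_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(df, class = c("anomaly_report", "data.frame"))
}

#' Export the transition graph
#'
#' `graphml` writes standard GraphML (via igraph) with node attributes `id`
#' (grid cell id), `cell` (`"row,col"`) and edge attribute `weight`;
#' `edgelist` writes a TSV `src`, `dst`, `weight`.  Self-loops are preserved
#' in both dialects.
#'
#' @param graph A `tsg_graph`.
#' @param path Output path.
#' @param dialect `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, dialect = c("graphml", "edgelist")) {
  stopifnot(inherits(graph, "tsg_graph"))
  dialect <- match.arg(dialect)
  if (dialect == "edgelist") {
    utils::write.table(
      data.frame(src = graph$edges$from, dst = graph$edges$to,
                 weight = graph$edges$weight),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(graph$edges$from),
                     to = as.character(graph$edges$to),
                     weight = graph$edges$weight),
      directed = TRUE,
      vertices = data.frame(name = as.character(graph$nodes$id),
                            cell = paste0(graph$nodes$row, ",", graph$nodes$col)))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
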