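#' Write a trace in SWC format
#'
#' SWC encodes rooted trees: 1-based node ids, one parent per node (-1 for
#' roots), physical coordinates, radius = caliber. Traces containing loops
#' cannot be represented and are refused.
#'
#' @param trace a `neur_trace` that is a forest (no cycles).
#' @param path output file path.
#' @param type SWC structure-type code written for every node (default 2,
#'   axon).
#' @export
write_swc <- function(trace, path, type = 2L) {
  n <- nrow(trace$nodes)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  parent <- rep(-1L, n)
  adj <- adjacency_list(trace)
  visited <- logical(n)
  ncomp <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    ncomp <- ncomp + 1L
    queue <- root; visited[root] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (nrow(trace$edges) != n - ncomp) {
    cyc <- find_cycle(trace)
    stop(sprintf(
      "trace contains a cycle through nodes %s; SWC cannot represent loops",
      paste(cyc, collapse = " -> ")))
  }
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   seq_len(n), type, trace$nodes$x, trace$nodes$y,
                   trace$nodes$z, trace$nodes$caliber, parent)
  writeLines(c("# SWC written by neuritrace", lines), path)
  invisible(path)
}

# one explicit cycle, for the write_swc error message
find_cycle <- function(trace) {
  g <- igraph::make_graph(t(trace$edges), n = nrow(trace$nodes),
                          directed = FALSE)
  gr <- igraph::girth(g)
  as.integer(gr$circle)
}

#' Read an SWC file as a trace
#'
#' @param path SWC file path.
#' @return A `neur_trace`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_trace())
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) < 7) stop("malformed SWC: expected 7 columns")
  ids <- as.integer(m[, 1])
  remap <- match(as.integer(m[, 7]), ids)  # parent -> row, NA for -1
  nodes <- data.frame(x = m[, 3], y = m[, 4], z = m[, 5], caliber = m[, 6])
  has_par <- !is.na(remap)
  edges <- cbind(which(has_par), remap[has_par])
  make_trace(nodes, edges)
}

#' Serialize a trace to JSON (loops allowed)
#'
#' The JSON graph format stores the node table and the edge list losslessly,
#' including cycles, and is the package's native interchange format.
#'
#' @param trace a `neur_trace`.
#' @param path output file path.
#' @param meta optional named list written under `"meta"` (e.g. provenance).
#' @export
write_trace_json <- function(trace, path, meta = NULL) {
  obj <- list(format = "neuritrace-graph",
              version = 1L,
              nodes = trace$nodes,
              edges = if (nrow(trace$edges)) trace$edges else
                matrix(integer(0), 0, 2))
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a JSON trace
#'
#' @param path JSON file written by [write_trace_json()].
#' @return A `neur_trace`.
#' @export
read_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "neuritrace-graph")
    stop("not a neuritrace JSON trace file")
  nodes <- as.data.frame(obj$nodes)
  edges <- matrix(as.integer(obj$edges), ncol = 2)
  make_trace(nodes, edges)
}

#' Export the node table as CSV
#'
#' Columns: node id, position, caliber, degree.
#'
#' @param trace a `neur_trace`.
#' @param path output file path.
#' @export
trace_to_csv <- function(trace, path) {
  df <- cbind(id = seq_len(nrow(trace$nodes)), trace$nodes,
              degree = trace_degree(trace))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
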