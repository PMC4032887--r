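#' Construct a neurite trace
#'
#' A trace is a graph of nodes, each with a physical position and a caliber
#' (local neurite radius), connected by an arbitrary symmetric adjacency.
#' Unlike SWC trees, the representation permits loops; branch points are
#' nodes of degree >= 3, terminal points nodes of degree 1.
#'
#' @param nodes data.frame with columns `x`, `y`, `z`, `caliber` (calibers
#'   must be positive). Extra columns are preserved.
#' @param edges 2-column integer matrix of undirected edges (node indices);
#'   self-links are rejected, duplicates collapsed.
#' @return An object of class `neur_trace`.
#' @export
make_trace <- function(nodes, edges = matrix(integer(0), 0, 2)) {
  nodes <- as.data.frame(nodes)
  if (nrow(nodes) > 0) {
    stopifnot(all(c("x", "y", "z", "caliber") %in% names(nodes)))
    if (any(nodes$caliber <= 0)) stop("calibers must be positive")
  } else if (!all(c("x", "y", "z", "caliber") %in% names(nodes))) {
    nodes <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        caliber = numeric(0))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1 | edges > nrow(nodes)))
      stop("edge endpoint outside node range")
    if (any(edges[, 1] == edges[, 2])) stop("self-links are not allowed")
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
  }
  structure(list(nodes = nodes, edges = edges), class = "neur_trace")
}

#' An empty trace
#' @return A `neur_trace` with zero nodes.
#' @export
empty_trace <- function() make_trace(data.frame(
  x = numeric(0), y = numeric(0), z = numeric(0), caliber = numeric(0)))

#' @export
print.neur_trace <- function(x, ...) {
  deg <- trace_degree(x)
  cat(sprintf(
    "<neur_trace: %d nodes, %d edges, %d terminal, %d branch points, length %.3g>\n",
    nrow(x$nodes), nrow(x$edges), sum(deg == 1), sum(deg >= 3),
    trace_length(x)))
  invisible(x)
}

#' Node degrees of a trace
#' @param trace a `neur_trace`.
#' @return Integer vector of degrees.
#' @export
trace_degree <- function(trace) {
  deg <- integer(nrow(trace$nodes))
  if (nrow(trace$edges) > 0) {
    tb <- tabulate(c(trace$edges), nbins = nrow(trace$nodes))
    deg <- as.integer(tb)
  }
  deg
}

#' Total trace length (sum of edge lengths, physical units)
#' @param trace a `neur_trace`.
#' @return Numeric scalar.
#' @export
trace_length <- function(trace) {
  if (nrow(trace$edges) == 0) return(0)
  p <- as.matrix(trace$nodes[, c("x", "y", "z")])
  sum(sqrt(rowSums((p[trace$edges[, 1], , drop = FALSE] -
                      p[trace$edges[, 2], , drop = FALSE])^2)))
}

node_positions <- function(trace) as.matrix(trace$nodes[, c("x", "y", "z")])

edge_lengths <- function(trace) {
  if (nrow(trace$edges) == 0) return(numeric(0))
  p <- node_positions(trace)
  sqrt(rowSums((p[trace$edges[, 1], , drop = FALSE] -
                  p[trace$edges[, 2], , drop = FALSE])^2))
}

#' Indices of terminal points (degree 1) and branch points (degree >= 3)
#' @param trace a `neur_trace`.
#' @return List with `terminal` and `branch` integer vectors.
#' @export
critical_points <- function(trace) {
  deg <- trace_degree(trace)
  list(terminal = which(deg == 1), branch = which(deg >= 3))
}

adjacency_list <- function(trace) {
  adj <- vector("list", nrow(trace$nodes))
  if (nrow(trace$edges) > 0)
    for (e in seq_len(nrow(trace$edges))) {
      a <- trace$edges[e, 1]; b <- trace$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  adj
}

#' Decompose a trace into branches
#'
#' A branch is a maximal node chain whose interior nodes all have degree 2;
#' branches end only at topology-critical nodes (degree != 2). Isolated
#' cycles (every node degree 2) are split at their lowest-index node. Every
#' edge belongs to exactly one branch.
#'
#' @param trace a `neur_trace`.
#' @return List of branches; each branch is a list with `node_idx` (ordered
#'   chain of node indices into `trace`) and `length`.
#' @export
decompose_branches <- function(trace) {
  ne <- nrow(trace$edges)
  if (ne == 0) return(list())
  deg <- trace_degree(trace)
  adj <- adjacency_list(trace)
  # edge id lookup
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eid <- new.env(hash = TRUE)
  for (e in seq_len(ne))
    assign(ekey(trace$edges[e, 1], trace$edges[e, 2]), e, envir = eid)
  used <- logical(ne)
  branches <- list()
  walk <- function(from, to) {
    # follow the chain starting with edge from->to until a critical node
    chain <- c(from, to)
    used[get(ekey(from, to), envir = eid)] <<- TRUE
    prev <- from; cur <- to
    while (deg[cur] == 2) {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0) break       # degree-2 dead end cannot happen
      nxt <- nxt[1]
      e <- get(ekey(cur, nxt), envir = eid)
      if (used[e]) break                # closed a cycle back onto the start
      used[e] <<- TRUE
      chain <- c(chain, nxt)
      prev <- cur; cur <- nxt
    }
    chain
  }
  crit <- which(deg != 2)
  for (v in crit) {
    for (nb in adj[[v]]) {
      e <- get(ekey(v, nb), envir = eid)
      if (!used[e]) branches[[length(branches) + 1L]] <- walk(v, nb)
    }
  }
  # remaining edges form pure cycles; split each at its lowest-index node
  while (any(!used)) {
    e <- which(!used)[1]
    start <- min(trace$edges[e, ])
    nb <- adj[[start]]
    chain <- walk(start, nb[1])
    branches[[length(branches) + 1L]] <- chain
  }
  p <- node_positions(trace)
  lapply(branches, function(ch) {
    seg <- sqrt(rowSums((p[ch[-1], , drop = FALSE] -
                           p[ch[-length(ch)], , drop = FALSE])^2))
    list(node_idx = ch, length = sum(seg))
  })
}

#' Resample a trace to a maximum edge length
#'
#' Every edge is subdivided into equal pieces of length at most `d` by
#' linear interpolation of positions and calibers. Original nodes are kept,
#' so the topology and the total length are preserved exactly.
#'
#' @param trace a `neur_trace`.
#' @param d positive maximum edge length (physical units).
#' @return A resampled `neur_trace`. Node order: original nodes first, then
#'   interpolated nodes.
#' @export
resample_trace <- function(trace, d) {
  if (d <= 0) stop("d must be positive")
  ne <- nrow(trace$edges)
  if (ne == 0) return(trace)
  p <- node_positions(trace)
  cal <- trace$nodes$caliber
  lens <- edge_lengths(trace)
  newx <- list(); newe <- list()
  nn <- nrow(trace$nodes)
  for (e in seq_len(ne)) {
    a <- trace$edges[e, 1]; b <- trace$edges[e, 2]
    k <- max(1L, ceiling(lens[e] / d))
    if (k == 1L) { newe[[e]] <- cbind(a, b); next }
    t <- seq_len(k - 1) / k
    pts <- outer(1 - t, p[a, ]) + outer(t, p[b, ])
    cals <- (1 - t) * cal[a] + t * cal[b]
    ids <- nn + seq_len(k - 1)
    nn <- nn + k - 1L
    newx[[length(newx) + 1L]] <- data.frame(
      x = pts[, 1], y = pts[, 2], z = pts[, 3], caliber = cals)
    chain <- c(a, ids, b)
    newe[[e]] <- cbind(chain[-length(chain)], chain[-1])
  }
  nodes <- trace$nodes[, c("x", "y", "z", "caliber")]
  if (length(newx) > 0) nodes <- rbind(nodes, do.call(rbind, newx))
  make_trace(nodes, do.call(rbind, newe))
}
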