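#' Terminal-point table of a dismantled trace
#'
#' Decomposes the trace into branches and returns one row per branch
#' endpoint with its position, outward tangent (least-squares line fit to
#' the last up-to-5 nodes of the branch, oriented away from the interior),
#' and branch summary statistics (length, mean caliber, mean intensity
#' sampled from the stack by trilinear interpolation when one is given).
#'
#' @param trace a `neur_trace`.
#' @param stack optional [image_stack()] for branch mean intensities
#'   (`NA` otherwise).
#' @return data.frame with columns `branch_id`, `end` (1 or 2), `node_idx`,
#'   `x`, `y`, `z`, `tx`, `ty`, `tz`, `branch_len`, `mean_int`,
#'   `mean_caliber`.
#' @export
branch_terminals <- function(trace, stack = NULL) {
  brs <- decompose_branches(trace)
  p <- node_positions(trace)
  cal <- trace$nodes$caliber
  rows <- list()
  for (b in seq_along(brs)) {
    ch <- brs[[b]]$node_idx
    mi <- NA_real_
    if (!is.null(stack)) mi <- mean(stack_interp(stack, p[ch, , drop = FALSE]))
    for (end in 1:2) {
      idx <- if (end == 1) ch else rev(ch)
      tipward <- head(idx, min(5L, length(idx)))
      tang <- outward_tangent(p[rev(tipward), , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        branch_id = b, end = end, node_idx = idx[1],
        x = p[idx[1], 1], y = p[idx[1], 2], z = p[idx[1], 3],
        tx = tang[1], ty = tang[2], tz = tang[3],
        branch_len = brs[[b]]$length, mean_int = mi,
        mean_caliber = mean(cal[ch]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(branch_id = integer(0), end = integer(0),
                      node_idx = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), tx = numeric(0), ty = numeric(0),
                      tz = numeric(0), branch_len = numeric(0),
                      mean_int = numeric(0), mean_caliber = numeric(0)))
  do.call(rbind, rows)
}

# unit direction of a point chain ordered interior -> tip (least-squares
# line fit; falls back to tip - base for degenerate chains)
outward_tangent <- function(pts) {
  k <- nrow(pts)
  if (k == 1) return(c(1, 0, 0))
  t <- seq_len(k) - mean(seq_len(k))
  v <- colSums(pts * t) / sum(t^2) # slope of coordinate vs index
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    v <- pts[k, ] - pts[1, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(c(1, 0, 0))
  }
  v / nv
}

#' Cluster branch terminal points by distance
#'
#' Builds the all-to-all graph over terminal points, removes links longer
#' than `threshold`, and returns the connected components (single linkage)
#' with at least two members; singleton components are genuine terminals
#' and are dropped from the merging pool.
#'
#' @param terminals data.frame from [branch_terminals()].
#' @param threshold link-length threshold (physical); the field's default is
#'   10 voxel widths, i.e. `10 * sx`.
#' @return List of `merge_cluster` objects (see [merge_cluster()]).
#' @export
cluster_terminals <- function(terminals, threshold) {
  stopifnot(threshold > 0)
  n <- nrow(terminals)
  if (n == 0) return(list())
  pos <- as.matrix(terminals[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pos))
  # union-find single linkage
  parent <- seq_len(n)
  findroot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (dmat[i, j] <= threshold) {
      ri <- findroot(i); rj <- findroot(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_len(n), findroot, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[vapply(comps, length, integer(1)) >= 2]
  out <- list()
  for (cc in comps)
    out[[length(out) + 1L]] <-
      merge_cluster(terminals[cc, , drop = FALSE], id = length(out) + 1L)
  out
}

#' Construct a merge cluster
#'
#' A cluster of nearby branch terminal points together with (optionally)
#' its enumerated merging scenarios, feature matrix, label, and weight.
#'
#' @param terminals data.frame of the cluster's terminal points (rows of
#'   [branch_terminals()] output).
#' @param id integer identifier.
#' @param label index of the correct scenario, or `NA` if unlabeled.
#' @param weight positive cluster weight `Q` (default 1).
#' @return An object of class `merge_cluster`.
#' @export
merge_cluster <- function(terminals, id = NA_integer_, label = NA_integer_,
                          weight = 1) {
  stopifnot(weight > 0)
  structure(list(terminals = terminals, id = id, label = label,
                 weight = weight, scenarios = NULL, features = NULL),
            class = "merge_cluster")
}

#' @export
print.merge_cluster <- function(x, ...) {
  cat(sprintf("<merge_cluster %s: %d terminal points%s>\n",
              x$id, nrow(x$terminals),
              if (is.na(x$label)) "" else sprintf(", label %d", x$label)))
  invisible(x)
}

#' Enumerate all set partitions of n items
#'
#' Partitions are generated as restricted-growth strings in lexicographic
#' order, so the ordering is deterministic and the first partition is
#' all-in-one-block and the last all-singletons.
#'
#' @param n number of items (>= 1).
#' @return List of integer vectors; element `i` gives the block id (1-based,
#'   first-occurrence order) of item `i`. The list length is the Bell
#'   number B(n).
#' @export
set_partitions <- function(n) {
  stopifnot(n >= 1)
  out <- list()
  rec <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L))
      rec(c(prefix, b), max(maxblock, b))
  }
  rec(integer(0), 0L)
  out
}

#' Enumerate branch-merging scenarios of a cluster
#'
#' One scenario per set partition of the cluster's terminal points: every
#' block of size >= 2 becomes one junction joining those endpoints (blocks
#' of size >= 3 create a branch point), singletons stay free. Scenario
#' counts follow the Bell numbers: 2, 5, 15, 52, ... for 2, 3, 4, 5
#' terminal points.
#'
#' @param cluster a `merge_cluster` with at least 2 terminal points.
#' @param cap refuse clusters with more terminal points than this (default
#'   8; B(8) = 4140 scenarios). Raise deliberately for larger clusters.
#' @return The cluster with `scenarios` set to the list of partitions.
#' @export
enumerate_scenarios <- function(cluster, cap = 8L) {
  n <- nrow(cluster$terminals)
  if (n < 2) stop("cluster must have at least 2 terminal points")
  if (n > cap)
    stop(sprintf(paste0("cluster has %d terminal points (cap %d); the ",
                        "scenario count grows as the Bell numbers - raise ",
                        "`cap` explicitly if this is intended"), n, cap))
  cluster$scenarios <- set_partitions(n)
  cluster
}

# ordered within-block pairs of a partition: matrix with columns a, b
block_pairs <- function(partition) {
  blocks <- split(seq_along(partition), partition)
  prs <- list()
  for (bl in blocks) {
    if (length(bl) < 2) next
    cmb <- utils::combn(bl, 2)
    prs[[length(prs) + 1L]] <- t(cmb)
  }
  if (length(prs) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, prs)
}

# length of a quadratic Bezier bridge between endpoints a, b whose control
# point sits where the outward tangent lines approach each other (midpoint
# fallback for near-parallel tangents), divided by the endpoint distance
bridge_tortuosity <- function(ra, ua, rb, ub, nseg = 16L) {
  d <- sqrt(sum((rb - ra)^2))
  if (d < 1e-12) return(1)
  # closest approach of lines ra + t ua and rb + s ub with t, s >= 0
  w0 <- ra - rb
  aa <- 1; bb <- sum(ua * ub); cc <- 1
  dd <- sum(ua * w0); ee <- sum(ub * w0)
  den <- aa * cc - bb * bb
  if (abs(den) < 1e-9) {
    ctrl <- (ra + rb) / 2
  } else {
    t <- (bb * ee - cc * dd) / den
    s <- (aa * ee - bb * dd) / den
    t <- max(t, 0); s <- max(s, 0)
    t <- min(t, 2 * d); s <- min(s, 2 * d)
    ctrl <- ((ra + t * ua) + (rb + s * ub)) / 2
  }
  tt <- seq(0, 1, length.out = nseg + 1L)
  curve <- outer((1 - tt)^2, ra) + outer(2 * tt * (1 - tt), ctrl) +
    outer(tt^2, rb)
  len <- sum(sqrt(rowSums(diff(curve)^2)))
  len / d
}

#' Feature vector of a merging scenario
#'
#' Computes the 9 morphological features of one scenario, aggregated over
#' its junction blocks: (1) mean within-block endpoint distance; (2) mean
#' overrun `max(0, -(r_b - r_a) . u_a)` over ordered merged pairs; (3) mean
#' perpendicular offset `|(r_b - r_a) - ((r_b - r_a) . u_a) u_a|` over
#' ordered pairs; (4) mean tangent alignment `-u_a . u_b`; (5) mean
#' absolute difference of branch mean intensities; (6) mean intensity
#' standard deviation along the straight bridging segment; (7) mean
#' absolute caliber difference; (8) mean bridging-path tortuosity
#' (tangent-following Bezier bridge length / endpoint distance); (9) number
#' of free (singleton) terminal points. A scenario with no merged pairs has
#' features 1-8 equal to 0 by convention.
#'
#' @param partition integer block-assignment vector (one scenario from
#'   [set_partitions()]).
#' @param terminals the cluster's terminal data.frame.
#' @param stack optional [image_stack()]; without it feature 6 is 0.
#' @return Numeric feature vector of length 9.
#' @export
scenario_features <- function(partition, terminals, stack = NULL) {
  x <- numeric(9)
  x[9] <- sum(tabulate(partition) == 1)
  prs <- block_pairs(partition)
  if (nrow(prs) == 0) return(x)
  pos <- as.matrix(terminals[, c("x", "y", "z")])
  tan <- as.matrix(terminals[, c("tx", "ty", "tz")])
  dist <- ovr <- off <- ali <- dint <- bstd <- dcal <- tor <- numeric(0)
  for (q in seq_len(nrow(prs))) {
    a <- prs[q, 1]; b <- prs[q, 2]
    ra <- pos[a, ]; rb <- pos[b, ]
    ua <- tan[a, ]; ub <- tan[b, ]
    v <- rb - ra
    dist <- c(dist, sqrt(sum(v^2)))
    # ordered pair terms, both directions
    ovr <- c(ovr, max(0, -sum(v * ua)), max(0, sum(v * ub)))
    off <- c(off, sqrt(max(0, sum(v^2) - sum(v * ua)^2)),
             sqrt(max(0, sum(v^2) - sum(v * ub)^2)))
    ali <- c(ali, -sum(ua * ub))
    dint <- c(dint, abs(terminals$mean_int[a] - terminals$mean_int[b]))
    dcal <- c(dcal, abs(terminals$mean_caliber[a] -
                          terminals$mean_caliber[b]))
    tor <- c(tor, bridge_tortuosity(ra, ua, rb, ub))
    if (!is.null(stack)) {
      tt <- seq(0, 1, length.out = 9L)
      samp <- outer(1 - tt, ra) + outer(tt, rb)
      bstd <- c(bstd, sd(stack_interp(stack, samp)))
    } else bstd <- c(bstd, 0)
  }
  x[1] <- mean(dist)
  x[2] <- mean(ovr)
  x[3] <- mean(off)
  x[4] <- mean(ali)
  x[5] <- if (all(is.na(dint))) 0 else mean(dint, na.rm = TRUE)
  x[6] <- mean(bstd)
  x[7] <- if (all(is.na(dcal))) 0 else mean(dcal, na.rm = TRUE)
  x[8] <- mean(tor)
  x
}

#' Feature matrix over all scenarios of a cluster
#'
#' @param cluster a `merge_cluster` with scenarios enumerated.
#' @param stack optional [image_stack()] passed to [scenario_features()].
#' @return The cluster with `features` set (scenarios x 9 matrix).
#' @export
cluster_features <- function(cluster, stack = NULL) {
  if (is.null(cluster$scenarios)) cluster <- enumerate_scenarios(cluster)
  cluster$features <- do.call(rbind, lapply(
    cluster$scenarios, scenario_features, terminals = cluster$terminals,
    stack = stack))
  cluster
}

#' Subtractive within-cluster feature normalization
#'
#' For a labeled cluster, returns the differences
#' `dx^mu = x^(erroneous mu) - x^(correct)` for every erroneous scenario.
#' Comparing scenarios only within a cluster cancels additive per-cluster
#' offsets (local intensity, neurite density).
#'
#' @param cluster a labeled `merge_cluster` with features computed.
#' @return Matrix of `B(n) - 1` rows by 9 columns.
#' @export
normalize_within_cluster <- function(cluster) {
  if (is.na(cluster$label)) stop("cluster is unlabeled")
  if (is.null(cluster$features))
    stop("cluster features not computed; call cluster_features() first")
  xc <- cluster$features[cluster$label, ]
  dx <- sweep(cluster$features[-cluster$label, , drop = FALSE], 2, xc, "-")
  dx
}

#' Rebuild a trace from its branches under chosen merging scenarios
#'
#' The trace is cut into branches (each branch keeps its own copy of any
#' shared junction node, so all junctions are dissolved), then for every
#' cluster the chosen scenario is realized: blocks of two endpoints are
#' joined by an edge, blocks of three or more by a new junction node at
#' their centroid, singletons stay free.
#'
#' @param trace the `neur_trace` that was dismantled.
#' @param clusters list of `merge_cluster`s from [cluster_terminals()]
#'   (must come from this trace).
#' @param choices integer vector, chosen scenario index per cluster; `NA`
#'   leaves that cluster unmerged (all endpoints free).
#' @return The merged `neur_trace`.
#' @export
apply_merging <- function(trace, clusters, choices) {
  stopifnot(length(choices) == length(clusters))
  brs <- decompose_branches(trace)
  p <- node_positions(trace)
  cal <- trace$nodes$caliber
  nodes <- list(); edges <- list()
  nn <- 0L
  # endpoint lookup: branch_id, end -> new node index
  tip <- matrix(NA_integer_, length(brs), 2)
  for (b in seq_along(brs)) {
    ch <- brs[[b]]$node_idx
    ids <- nn + seq_along(ch)
    nn <- nn + length(ch)
    nodes[[b]] <- data.frame(x = p[ch, 1], y = p[ch, 2], z = p[ch, 3],
                             caliber = cal[ch])
    if (length(ch) > 1)
      edges[[b]] <- cbind(ids[-length(ids)], ids[-1])
    tip[b, 1] <- ids[1]
    tip[b, 2] <- ids[length(ids)]
  }
  nodes <- do.call(rbind, nodes)
  for (ci in seq_along(clusters)) {
    if (is.na(choices[ci])) next
    cl <- clusters[[ci]]
    part <- cl$scenarios[[choices[ci]]]
    blocks <- split(seq_along(part), part)
    for (bl in blocks) {
      if (length(bl) < 2) next
      ids <- tip[cbind(cl$terminals$branch_id[bl], cl$terminals$end[bl])]
      if (length(bl) == 2) {
        if (ids[1] != ids[2])
          edges[[length(edges) + 1L]] <- cbind(ids[1], ids[2])
      } else {
        ctr <- colMeans(cl$terminals[bl, c("x", "y", "z")])
        nn <- nn + 1L
        nodes <- rbind(nodes, data.frame(
          x = ctr[1], y = ctr[2], z = ctr[3],
          caliber = mean(cl$terminals$mean_caliber[bl])))
        edges[[length(edges) + 1L]] <- cbind(rep(nn, length(ids)), ids)
      }
    }
  }
  make_trace(nodes, do.call(rbind, edges))
}
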