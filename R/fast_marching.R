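#' Solve the Eikonal boundary-value problem by Fast Marching
#'
#' Computes the arrival-time map `T` of fronts propagating from a boundary
#' set at speed equal to the image intensity: `|grad T| * I = 1`,
#' `T(boundary) = 0`. The solver accepts voxels in nondecreasing `T` order
#' (min-heap) using the upwind discretization in which, per axis, only the
#' smaller accepted neighbor enters the quadratic, scaled by the voxel
#' dimensions `(sx, sy, sz)`. Voxels with zero intensity are hard barriers
#' and are never accepted.
#'
#' @param stack an [image_stack()].
#' @param boundary n x 3 integer matrix of 1-based voxel indices with
#'   `T = 0`; must be nonempty and have positive intensity.
#' @param labels optional integer front label per boundary voxel (default:
#'   all 1). Accepted voxels inherit the label of their first-arriving
#'   front; voxels where two labels meet are reported as collisions.
#' @param dmax optional physical front-travel limit; propagation halts when
#'   the next voxel to accept lies farther than `dmax` (Euclidean, to the
#'   nearest boundary voxel). `Inf` (default) solves the full reachable
#'   domain.
#' @return A `time_map`: list with 3D arrays `T` (arrival time, `Inf` where
#'   unreached), `label`, `state` (0 far / 1 trial / 2 accepted), plus
#'   `farthest` (voxel index triple, `dmax` runs only), `farthest_dist`,
#'   `halted`, `exhausted`, and a data.frame `collisions` with columns
#'   `i, j, k, T, label_a, label_b` ordered by arrival time.
#' @export
solve_eikonal <- function(stack, boundary, labels = NULL, dmax = Inf) {
  boundary <- rbind(boundary)
  if (nrow(boundary) == 0) stop("boundary must be nonempty")
  storage.mode(boundary) <- "integer"
  d <- dim(stack$voxels)
  if (any(boundary < 1) || any(boundary[, 1] > d[1]) ||
      any(boundary[, 2] > d[2]) || any(boundary[, 3] > d[3]))
    stop("boundary voxel outside stack bounds")
  if (any(stack$voxels[boundary] <= 0))
    stop("boundary voxel has zero intensity")
  if (is.null(labels)) labels <- rep(1L, nrow(boundary))
  labels <- as.integer(labels)
  res <- .fm_run_cpp(stack$voxels, as.integer(d), stack$voxel_size,
                     boundary, labels, dmax)
  far <- NULL
  if (res$farthest > 0) far <- as.integer(arrayInd(res$farthest, d))
  coll <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                     T = numeric(0), label_a = integer(0),
                     label_b = integer(0))
  if (length(res$collision_idx) > 0) {
    ci <- arrayInd(res$collision_idx, d)
    coll <- data.frame(i = ci[, 1], j = ci[, 2], k = ci[, 3],
                       T = res$collision_T, label_a = res$collision_labA,
                       label_b = res$collision_labB)
  }
  structure(list(T = res$T, label = res$label, state = res$state,
                 farthest = far, farthest_dist = res$farthest_dist,
                 halted = res$halted, exhausted = res$exhausted,
                 collisions = coll, voxel_size = stack$voxel_size),
            class = "time_map")
}

#' March a front a bounded distance from the boundary
#'
#' Runs Fast Marching until the next voxel to be accepted lies farther than
#' `dmax` (physical Euclidean distance to the nearest boundary voxel) and
#' returns the accepted voxel of maximal distance. If the reachable domain
#' is exhausted before the limit, the `exhausted` flag is set and the
#' farthest reached voxel is returned.
#'
#' @inheritParams solve_eikonal
#' @param dmax positive physical front-travel limit (`D_max`).
#' @return The `time_map` from [solve_eikonal()] (with `farthest`,
#'   `farthest_dist`, `exhausted` filled in).
#' @export
march_to_distance <- function(stack, boundary, labels = NULL, dmax) {
  stopifnot(is.finite(dmax), dmax > 0)
  solve_eikonal(stack, boundary, labels, dmax = dmax)
}

#' Gradient-descent centerline path on an arrival-time map
#'
#' From an accepted start voxel, repeatedly steps to the 26-neighborhood
#' voxel with the smallest arrival time (strictly decreasing), terminating
#' on a `T = 0` boundary voxel.
#'
#' @param tmap a `time_map` from [solve_eikonal()].
#' @param start length-3 integer voxel index, must be accepted.
#' @param restrict_label optional front label: only voxels carrying this
#'   label (or `T = 0` voxels) may be stepped on. Used to back-propagate
#'   from a collision voxel into one specific colliding region.
#' @return Integer matrix (n x 3) of voxel indices from `start` to the
#'   `T = 0` voxel. A start on the boundary yields a single-row chain.
#' @export
gradient_descent_path <- function(tmap, start, restrict_label = NULL) {
  d <- dim(tmap$T)
  start <- as.integer(start)
  if (tmap$state[start[1], start[2], start[3]] != 2L)
    stop("start voxel is not accepted in the time map")
  path <- list(start)
  cur <- start
  tcur <- tmap$T[start[1], start[2], start[3]]
  visited <- new.env(hash = TRUE)
  vkey <- function(v) paste(v, collapse = ",")
  assign(vkey(start), TRUE, envir = visited)
  repeat {
    if (tcur == 0) break
    ii <- max(1L, cur[1] - 1L):min(d[1], cur[1] + 1L)
    jj <- max(1L, cur[2] - 1L):min(d[2], cur[2] + 1L)
    kk <- max(1L, cur[3] - 1L):min(d[3], cur[3] + 1L)
    nb <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    nb <- nb[!(nb[, 1] == cur[1] & nb[, 2] == cur[2] & nb[, 3] == cur[3]), ,
             drop = FALSE]
    tn <- tmap$T[nb]
    acc <- is.finite(tn) & tmap$state[nb] == 2L
    if (is.null(restrict_label)) {
      best <- if (any(acc)) which(acc)[which.min(tn[acc])] else NA_integer_
      if (is.na(best)) stop("gradient descent stuck: no accepted neighbor")
      if (tn[best] >= tcur)
        stop("gradient descent hit a local minimum with T > 0 (invalid upwind map)")
    } else {
      # restricted mode: descend within the requested front; fronts meet at
      # equal arrival times, so the crossing step may be non-strict (a
      # visited guard prevents cycling on tied plateaus)
      seen <- vapply(seq_len(nrow(nb)), function(r)
        isTRUE(get0(vkey(nb[r, ]), envir = visited)), logical(1))
      ok <- acc & !seen & (tmap$label[nb] == restrict_label | tn == 0) &
        tn <= tcur
      best <- if (any(ok)) which(ok)[which.min(tn[ok])] else NA_integer_
      if (is.na(best)) {
        # no step inside the restricted region; fall back to the
        # unrestricted strict descent so the chain still reaches T = 0
        best <- if (any(acc & tn < tcur))
          which(acc & tn < tcur)[which.min(tn[acc & tn < tcur])] else
            NA_integer_
        if (is.na(best)) stop("gradient descent stuck: no accepted neighbor")
      }
    }
    cur <- as.integer(nb[best, ])
    tcur <- tn[best]
    assign(vkey(cur), TRUE, envir = visited)
    path[[length(path) + 1L]] <- cur
  }
  do.call(rbind, path)
}

#' Grow the initial trace from seed points
#'
#' Iterates the Fast Marching cycle: march all fronts out to `D_max`,
#' extract the gradient-descent path from the farthest front point back to
#' the `T = 0` boundary, add the path to the boundary, and re-initialize.
#' When fronts originating from distinct seeds collide, gradient-descent
#' paths back-propagate from the collision voxel into both colliding
#' regions, joining their boundaries (collisions are resolved one per
#' march, lowest arrival time first). Growth stops when the mean raw
#' intensity along the newest path falls below
#' `stop_fraction * mean(intensity of the existing trace)`, or when the
#' reachable domain is exhausted.
#'
#' @param stack an [image_stack()].
#' @param seeds a `seed_set` from [generate_seeds()], or an n x 3 integer
#'   matrix of seed voxels. Must be nonempty.
#' @param D_max physical front-travel limit per march; default `15 * sx`.
#' @param stop_fraction dim-path stopping threshold as a fraction of the
#'   mean trace intensity; default 0.2.
#' @param max_iter safety cap on march iterations.
#' @param on_stop optional callback `function(path_mean, trace_mean)`
#'   invoked when the stop rule triggers; return `TRUE` to continue growing
#'   past this path (interactive override hook), otherwise growth stops.
#' @return A `neur_trace` whose nodes are path voxels (physical
#'   coordinates, initial caliber `1 * sx`), carrying the per-node raw
#'   intensity in column `intensity`.
#' @export
grow_initial_trace <- function(stack, seeds,
                               D_max = 15 * stack$voxel_size[1],
                               stop_fraction = 0.2,
                               max_iter = 10000L,
                               on_stop = NULL) {
  pts <- if (inherits(seeds, "seed_set")) seeds$points else rbind(seeds)
  if (is.null(pts) || nrow(pts) == 0) stop("seeds must be nonempty")
  storage.mode(pts) <- "integer"
  d <- dim(stack$voxels)
  sx <- stack$voxel_size[1]

  lin <- function(v) v[, 1] + d[1] * ((v[, 2] - 1L) + d[2] * (v[, 3] - 1L))

  # trace bookkeeping: node table grows; voxel -> node id map
  nodes_ijk <- pts
  node_lab <- seq_len(nrow(pts))     # front label per node (union-find root)
  vox2node <- new.env(hash = TRUE)
  for (q in seq_len(nrow(pts)))
    assign(as.character(lin(pts[q, , drop = FALSE])), q, envir = vox2node)
  edges <- matrix(integer(0), 0, 2)
  parent <- seq_len(nrow(pts))       # union-find over seed labels
  findroot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  rejected <- list()                 # front pairs whose join was too dim
  is_rejected <- function(a, b) {
    for (p in rejected)
      if ((findroot(p[1]) == a && findroot(p[2]) == b) ||
          (findroot(p[1]) == b && findroot(p[2]) == a)) return(TRUE)
    FALSE
  }

  add_path <- function(chain_ijk, attach_extra = NULL) {
    # chain runs from a new far voxel to a T = 0 voxel (existing node);
    # returns indices of the added nodes
    added <- integer(0)
    prev_id <- attach_extra
    for (r in seq_len(nrow(chain_ijk))) {
      key <- as.character(lin(chain_ijk[r, , drop = FALSE]))
      if (exists(key, envir = vox2node)) {
        id <- get(key, envir = vox2node)
      } else {
        nodes_ijk <<- rbind(nodes_ijk, chain_ijk[r, , drop = FALSE])
        id <- nrow(nodes_ijk)
        node_lab <<- c(node_lab, 0L)  # label filled by caller
        assign(key, id, envir = vox2node)
        added <- c(added, id)
      }
      if (!is.null(prev_id) && prev_id != id)
        edges <<- rbind(edges, c(prev_id, id))
      prev_id <- id
    }
    list(added = added, last = prev_id)
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) { warning("march iteration cap reached"); break }
    labs <- vapply(node_lab, findroot, integer(1))
    tm <- march_to_distance(stack, nodes_ijk, labs, dmax = D_max)

    # resolve the earliest collision between distinct fronts, if any
    coll <- tm$collisions
    if (nrow(coll) > 0) {
      ra <- vapply(coll$label_a, findroot, integer(1))
      rb <- vapply(coll$label_b, findroot, integer(1))
      live <- which(ra != rb &
                      !mapply(is_rejected, ra, rb))
      if (length(live) > 0) {
        crow <- coll[live[1], ]
        cvox <- c(crow$i, crow$j, crow$k)
        la <- ra[live[1]]; lb <- rb[live[1]]
        pa <- gradient_descent_path(tm, cvox, restrict_label = NULL)
        # the unrestricted descent follows the first-arriving front; descend
        # into the other region explicitly
        reach_a <- findroot(node_lab[get(as.character(
          lin(pa[nrow(pa), , drop = FALSE])), envir = vox2node)])
        other <- if (reach_a == la) lb else la
        pb <- gradient_descent_path(tm, cvox, restrict_label = other)
        # the same dim-path rule applies to joins: fronts that can only
        # meet by creeping through background are left separate
        trim <- function(p) p[seq_len(max(1L, nrow(p) - 2L)), , drop = FALSE]
        join_int <- stack$voxels[unique(rbind(trim(pa), trim(pb)),
                                        MARGIN = 1)]
        if (mean(join_int) <
            stop_fraction * stats::median(stack$voxels[nodes_ijk])) {
          rejected[[length(rejected) + 1L]] <- c(la, lb)
          next
        }
        resa <- add_path(pa)
        for (id in c(resa$added)) node_lab[id] <- la
        # pb starts at the collision voxel (already a node now); attach
        resb <- add_path(pb[-1, , drop = FALSE],
                         attach_extra = get(as.character(
                           lin(pb[1, , drop = FALSE])), envir = vox2node))
        for (id in c(resb$added)) node_lab[id] <- other
        parent[findroot(la)] <- findroot(lb)
        next
      }
    }

    if (tm$exhausted &&
        (is.null(tm$farthest) || tm$farthest_dist < stack$voxel_size[1]))
      break
    if (is.null(tm$farthest)) break
    chain <- gradient_descent_path(tm, tm$farthest)
    if (nrow(chain) < 2) break  # no growth possible
    path_int <- stack$voxels[chain[-nrow(chain), , drop = FALSE]]
    # reference intensity: median over trace nodes, which stays at the
    # bright-structure level even after a few dim additions (a plain mean
    # decays with every accepted path and lets the threshold chase the
    # background down)
    trace_int <- stats::median(stack$voxels[nodes_ijk])
    if (mean(path_int) < stop_fraction * trace_int) {
      go_on <- !is.null(on_stop) && isTRUE(on_stop(mean(path_int),
                                                   trace_int))
      if (!go_on) break
    }
    end_key <- as.character(lin(chain[nrow(chain), , drop = FALSE]))
    end_lab <- findroot(node_lab[get(end_key, envir = vox2node)])
    res <- add_path(chain)
    for (id in res$added) node_lab[id] <- end_lab
    if (tm$exhausted) break  # last stub added; nothing further reachable
  }

  pos <- voxel_to_phys(stack, nodes_ijk)
  nodes <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      caliber = sx, intensity = stack$voxels[nodes_ijk])
  make_trace(nodes, edges)
}
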