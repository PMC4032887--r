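#' Specification of a synthetic neurite stack
#'
#' Describes bright tubes with Gaussian cross-sections laid over a noisy
#' background: the study conditions the generator emulates are single-axon
#' stacks (one bright, well-separated tube) and multi-axon stacks where
#' distinct axons pass within a voxel of each other (near-crossings) and
#' labeling gaps interrupt the fluorescence.
#'
#' @param shape integer length-3 stack dimensions (x, y, z).
#' @param voxel_size physical voxel dimensions, default `c(1, 1, 1)`.
#' @param tubes list of tubes; each a list with `path` (n x 3 matrix of
#'   physical control points), `sigma` (Gaussian cross-section radius,
#'   physical), `amplitude` in (0, 1], and optionally `gaps` (list of
#'   `c(from, to)` arc-length intervals where the tube's fluorescence is
#'   zeroed).
#' @param background background intensity level, default 0.05.
#' @param noise_sd additive Gaussian noise standard deviation, default 0.02.
#' @param seed RNG seed making the rendering reproducible.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(shape, voxel_size = c(1, 1, 1), tubes = list(),
                       background = 0.05, noise_sd = 0.02, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  for (tb in tubes) {
    stopifnot(!is.null(tb$path), ncol(rbind(tb$path)) == 3,
              tb$sigma > 0, tb$amplitude > 0, tb$amplitude <= 1)
  }
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size), tubes = tubes,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# densify a polyline to a given arc-length step; returns points and
# cumulative arc length
densify_path <- function(path, step) {
  path <- rbind(path)
  if (nrow(path) == 1)
    return(list(pts = path, arc = 0))
  pts <- list(path[1, , drop = FALSE])
  arc <- list(0)
  total <- 0
  for (s in seq_len(nrow(path) - 1)) {
    a <- path[s, ]; b <- path[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    k <- max(1L, ceiling(len / step))
    t <- seq_len(k) / k
    seg <- outer(1 - t, a) + outer(t, b)
    pts[[length(pts) + 1L]] <- seg
    arc[[length(arc) + 1L]] <- total + t * len
    total <- total + len
  }
  list(pts = do.call(rbind, pts), arc = unlist(arc))
}

#' Render a synthetic stack and its ground-truth trace
#'
#' Voxel intensity is `background + sum_tubes amplitude *
#' exp(-dist(voxel, centerline)^2 / (2 sigma^2)) + noise`, clipped to
#' `[0, 1]`; labeling gaps zero the tube's contribution over their
#' arc-length intervals. The ground-truth trace is the centerline polyline
#' resampled at about one voxel, with caliber `sigma` — gaps interrupt the
#' fluorescence, not the underlying neurite, so the truth spans them.
#'
#' @param spec a [synth_spec()].
#' @return List with `stack` (an [image_stack()], not re-normalized),
#'   `truth` (a `neur_trace` whose nodes carry `tube` id and `arc`
#'   position), and `spec`.
#' @export
render_stack <- function(spec) {
  set.seed(spec$seed)
  d <- spec$shape
  vs <- spec$voxel_size
  vox <- array(spec$background, dim = d)
  truth_nodes <- list(); truth_edges <- list()
  nnode <- 0L
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    dp <- densify_path(tb$path, step = min(vs) / 2)
    in_gap <- rep(FALSE, length(dp$arc))
    for (gp in tb$gaps %||% list())
      in_gap <- in_gap | (dp$arc >= gp[1] & dp$arc <= gp[2])
    # squared distance to the centerline plus the arc position of the
    # nearest sample; voxels whose nearest point falls inside a labeling
    # gap get no fluorescence from this tube (sharp gap edges)
    rad <- 3 * tb$sigma
    dist2 <- array(Inf, dim = d)
    arcf <- array(0, dim = d)
    for (q in seq_len(nrow(dp$pts))) {
      pt <- dp$pts[q, ]
      i0 <- max(1L, ceiling((pt[1] - rad) / vs[1]) + 1L)
      i1 <- min(d[1], floor((pt[1] + rad) / vs[1]) + 1L)
      j0 <- max(1L, ceiling((pt[2] - rad) / vs[2]) + 1L)
      j1 <- min(d[2], floor((pt[2] + rad) / vs[2]) + 1L)
      k0 <- max(1L, ceiling((pt[3] - rad) / vs[3]) + 1L)
      k1 <- min(d[3], floor((pt[3] + rad) / vs[3]) + 1L)
      if (i0 > i1 || j0 > j1 || k0 > k1) next
      dx2 <- ((i0:i1 - 1) * vs[1] - pt[1])^2
      dy2 <- ((j0:j1 - 1) * vs[2] - pt[2])^2
      dz2 <- ((k0:k1 - 1) * vs[3] - pt[3])^2
      block <- outer(outer(dx2, dy2, "+"), dz2, "+")
      cur <- dist2[i0:i1, j0:j1, k0:k1, drop = FALSE]
      closer <- block < cur
      dist2[i0:i1, j0:j1, k0:k1] <- pmin(cur, block)
      af <- arcf[i0:i1, j0:j1, k0:k1, drop = FALSE]
      af[closer] <- dp$arc[q]
      arcf[i0:i1, j0:j1, k0:k1] <- af
    }
    contrib <- tb$amplitude * exp(-dist2 / (2 * tb$sigma^2))
    contrib[!is.finite(contrib)] <- 0
    for (gp in tb$gaps %||% list())
      contrib[arcf >= gp[1] & arcf <= gp[2]] <- 0
    vox <- vox + contrib
    # ground-truth trace nodes at ~1 voxel spacing
    gt <- densify_path(tb$path, step = min(vs))
    ids <- nnode + seq_len(nrow(gt$pts))
    nnode <- nnode + nrow(gt$pts)
    truth_nodes[[ti]] <- data.frame(
      x = gt$pts[, 1], y = gt$pts[, 2], z = gt$pts[, 3],
      caliber = tb$sigma, tube = ti, arc = gt$arc)
    truth_edges[[ti]] <- cbind(ids[-length(ids)], ids[-1])
  }
  if (spec$noise_sd > 0)
    vox <- vox + rnorm(length(vox), 0, spec$noise_sd)
  vox <- pmin(pmax(vox, 0), 1)
  stack <- image_stack(vox, vs, normalize = FALSE)
  truth <- empty_trace()
  if (nnode > 0) {
    nodes <- do.call(rbind, truth_nodes)
    edges <- do.call(rbind, truth_edges)
    # weld coincident nodes of different tubes (< half a voxel apart) into
    # shared junctions, so a daughter starting on its parent's path yields
    # a true branch point in the ground truth
    weld <- 0.5 * min(vs)
    keep <- rep(TRUE, nrow(nodes))
    remap <- seq_len(nrow(nodes))
    pos <- as.matrix(nodes[, c("x", "y", "z")])
    for (i in seq_len(nrow(nodes))) {
      if (!keep[i]) next
      close_ <- which(keep & seq_len(nrow(nodes)) > i &
                        nodes$tube != nodes$tube[i] &
                        abs(pos[, 1] - pos[i, 1]) <= weld &
                        abs(pos[, 2] - pos[i, 2]) <= weld &
                        abs(pos[, 3] - pos[i, 3]) <= weld)
      if (length(close_) > 0) {
        d2 <- rowSums((pos[close_, , drop = FALSE] -
                         matrix(pos[i, ], length(close_), 3,
                                byrow = TRUE))^2)
        hit <- close_[d2 <= weld^2]
        keep[hit] <- FALSE
        remap[hit] <- i
      }
    }
    edges <- matrix(remap[edges], ncol = 2)
    new_id <- cumsum(keep)
    nodes <- nodes[keep, , drop = FALSE]
    rownames(nodes) <- NULL
    edges <- matrix(new_id[edges], ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    truth <- make_trace(nodes, edges)
  }
  list(stack = stack, truth = truth, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single straight tube spec
#'
#' One bright axon crossing the stack along x — the benign single-cell
#' condition: high contrast, no crossings, no gaps.
#'
#' @param length tube length in voxels (default 60).
#' @param sigma cross-section radius in voxels (default 1.5).
#' @param amplitude peak intensity (default 0.9).
#' @param noise_sd background noise (default 0.02); with the default 0.05
#'   background the peak signal-to-noise ratio is well above 5.
#' @param margin transverse stack half-width in voxels (default 8).
#' @param seed RNG seed.
#' @return A [synth_spec()].
#' @export
straight_tube_spec <- function(length = 60, sigma = 1.5, amplitude = 0.9,
                               noise_sd = 0.02, margin = 8, seed = 1L) {
  sh <- c(length + 2 * margin, 2 * margin + 1, 2 * margin + 1)
  ctr <- c(margin, margin)
  path <- rbind(c(margin, ctr[1], ctr[2]),
                c(margin + length, ctr[1], ctr[2]))
  synth_spec(sh, tubes = list(list(path = path, sigma = sigma,
                                   amplitude = amplitude)),
             noise_sd = noise_sd, seed = seed)
}

#' Y-shaped (bifurcating) tube spec
#'
#' A parent segment splitting into two daughters: one true branch point,
#' three terminal points.
#'
#' @inheritParams straight_tube_spec
#' @param arm daughter length in voxels (default 30).
#' @export
y_tube_spec <- function(arm = 30, sigma = 1.5, amplitude = 0.9,
                        noise_sd = 0.02, seed = 1L) {
  m <- 8
  fork <- c(m + arm, m + arm, m + 6)
  sh <- c(2 * m + 2 * arm, 2 * m + 2 * arm, 2 * m + 12)
  tube <- list(path = rbind(c(m, m, m + 6), fork,
                            c(m + 2 * arm, m + 2 * arm, m + 6)),
               sigma = sigma, amplitude = amplitude)
  daughter <- list(path = rbind(fork, c(m + 2 * arm, m, m + 6)),
                   sigma = sigma, amplitude = amplitude)
  synth_spec(sh, tubes = list(tube, daughter), noise_sd = noise_sd,
             seed = seed)
}

#' Multi-axon spec with near-crossings and labeling gaps
#'
#' Emulates densely labeled multi-cell stacks: several straight axons
#' crossing the volume, two pairs passing within about one voxel of each
#' other in depth (near-crossings, the condition that produces erroneously
#' merged "stolen" branches in initial traces), and labeling gaps of 5
#' voxel widths that break fluorescence continuity.
#'
#' @param n_tubes number of axons (default 4).
#' @param approach closest approach of crossing pairs in voxels (default 1).
#' @param gap_len gap length in voxels (default 5).
#' @param n_gaps number of gaps distributed over the tubes (default 3).
#' @inheritParams straight_tube_spec
#' @export
multi_axon_spec <- function(n_tubes = 4, approach = 1, gap_len = 5,
                         n_gaps = 3, sigma = 1.2, amplitude = 0.9,
                         noise_sd = 0.02, seed = 1L) {
  W <- 64; H <- 48; Z <- 13
  zmid <- (Z - 1) / 2
  tubes <- list()
  # two crossing pairs in x-y, separated by `approach` in z at the crossing
  mk <- function(p0, p1, dz) list(
    path = rbind(c(p0, zmid + dz / 2), c(p1, zmid + dz / 2)),
    sigma = sigma, amplitude = amplitude)
  cross_y <- c(0.3 * H, 0.7 * H)
  tubes[[1]] <- mk(c(4, cross_y[1] - 10), c(W - 5, cross_y[1] + 10),
                   -approach)
  tubes[[2]] <- mk(c(4, cross_y[1] + 10), c(W - 5, cross_y[1] - 10),
                   approach)
  if (n_tubes >= 3)
    tubes[[3]] <- mk(c(4, cross_y[2] - 8), c(W - 5, cross_y[2] + 8),
                     -approach)
  if (n_tubes >= 4)
    tubes[[4]] <- mk(c(4, cross_y[2] + 8), c(W - 5, cross_y[2] - 8),
                     approach)
  if (n_tubes > 4) for (t in 5:n_tubes) {
    y0 <- (t - 4) * H / (n_tubes - 2)
    tubes[[t]] <- mk(c(4, y0), c(W - 5, H - y0), 2 * approach)
  }
  # distribute gaps over the first tubes, away from the crossings
  tlen <- sqrt(sum((tubes[[1]]$path[2, ] - tubes[[1]]$path[1, ])^2))
  for (gi in seq_len(n_gaps)) {
    ti <- ((gi - 1) %% length(tubes)) + 1
    at <- tlen * 0.22
    tubes[[ti]]$gaps <- c(tubes[[ti]]$gaps %||% list(),
                          list(c(at, at + gap_len)))
  }
  synth_spec(c(W, H, Z), tubes = tubes, noise_sd = noise_sd, seed = seed)
}

#' Ground-truth labeling oracle for merge clusters
#'
#' Builds a labeling callback for [active_learning_loop()] or batch
#' labeling from the generator's ground-truth trace. Each terminal point's
#' branch is attributed to the ground-truth tube its nodes hug: the mean
#' nearest-centerline distance is computed per tube over the branch nodes
#' (preferring interior nodes, which are less ambiguous than the junction
#' vicinity), and the branch is assigned to the closest tube when the
#' attribution is decisive — closest mean under `max_dist` and clearly
#' below the runner-up. The correct scenario is the partition grouping
#' terminals of the same tube. Clusters with any ambiguous attribution are
#' declined (`NA`), mirroring an annotator who skips uncertain clusters
#' rather than risk mislabels.
#'
#' @param truth ground-truth `neur_trace` from [render_stack()] (nodes
#'   carry a `tube` column).
#' @param trace the traced `neur_trace` the clusters came from (for branch
#'   node access).
#' @param max_dist attribution distance limit (physical units, default 3).
#' @param decisive runner-up distance must exceed `decisive` times the best
#'   mean distance plus one voxel (default 1.5).
#' @return `function(cluster) -> scenario index or NA`.
#' @export
make_truth_oracle <- function(truth, trace, max_dist = 3, decisive = 1.5) {
  tp <- node_positions(truth)
  tube_ids <- sort(unique(truth$nodes$tube))
  tube_pts <- lapply(tube_ids, function(t)
    tp[truth$nodes$tube == t, , drop = FALSE])
  brs <- decompose_branches(trace)
  p <- node_positions(trace)
  attribute_branch <- function(branch_id, end) {
    ch <- brs[[branch_id]]$node_idx
    if (end == 2) ch <- rev(ch)
    # skip the 3 nodes nearest the junction when the branch is long enough
    use <- if (length(ch) > 6) ch[-(1:3)] else ch
    use <- head(use, 15L)
    md <- vapply(tube_pts, function(pts)
      mean(nn_search(p[use, , drop = FALSE], pts)$dist), numeric(1))
    ord <- order(md)
    best <- md[ord[1]]
    second <- if (length(md) > 1) md[ord[2]] else Inf
    if (best > max_dist) return(NA_integer_)
    if (second < decisive * best + 1) return(NA_integer_)
    tube_ids[ord[1]]
  }
  function(cluster) {
    tm <- cluster$terminals
    grp <- mapply(attribute_branch, tm$branch_id, tm$end)
    if (any(is.na(grp))) return(NA_integer_)
    rgs <- match(grp, unique(grp))
    hit <- which(vapply(cluster$scenarios, identical, logical(1),
                        as.integer(rgs)))
    if (length(hit) == 0) return(NA_integer_)
    hit[1]
  }
}

#' Planted-model pool of labeled merge clusters
#'
#' Generates random geometric clusters (2-5 terminal points in a ball,
#' random outward tangents, random branch statistics), computes the real
#' scenario features, and labels each cluster with the scenario minimizing
#' `w_star' x` plus optional Gaussian score noise. With `noise = 0` every
#' cluster is linearly separable by `w_star`; clusters whose best and
#' second-best scores differ by less than `margin` are rejected and
#' redrawn, so the pool has a controlled separability margin.
#'
#' @param n_clusters pool size.
#' @param w_star planted weight vector (length 9).
#' @param noise score noise standard deviation (default 0).
#' @param margin minimum score separation between the labeled and the
#'   runner-up scenario (default 0.5).
#' @param radius cluster radius in voxels (default 8).
#' @param seed RNG seed.
#' @return List of labeled `merge_cluster`s with features computed.
#' @export
planted_clusters <- function(n_clusters, w_star, noise = 0, margin = 0.5,
                             radius = 8, seed = 1L) {
  stopifnot(length(w_star) == 9)
  set.seed(seed)
  pool <- list()
  guard <- 0L
  while (length(pool) < n_clusters) {
    guard <- guard + 1L
    if (guard > 50L * n_clusters)
      stop("rejection sampling failed; margin too demanding")
    n <- sample(2:5, 1)
    pos <- matrix(rnorm(3 * n), ncol = 3) * radius / 2
    tan <- matrix(rnorm(3 * n), ncol = 3)
    tan <- tan / sqrt(rowSums(tan^2))
    terminals <- data.frame(
      branch_id = seq_len(n), end = 1L, node_idx = seq_len(n),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      tx = tan[, 1], ty = tan[, 2], tz = tan[, 3],
      branch_len = runif(n, 10, 50), mean_int = runif(n, 0.3, 0.9),
      mean_caliber = runif(n, 0.8, 2.5))
    cl <- merge_cluster(terminals, id = length(pool) + 1L)
    cl <- cluster_features(enumerate_scenarios(cl))
    scores <- as.numeric(cl$features %*% w_star)
    if (noise > 0) scores <- scores + rnorm(length(scores), 0, noise)
    ord <- order(scores)
    if (scores[ord[2]] - scores[ord[1]] < margin) next
    cl$label <- ord[1]
    pool[[length(pool) + 1L]] <- cl
  }
  pool
}
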