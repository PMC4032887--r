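#' Fitness parameters for trace optimization
#'
#' @param alpha_r position stiffness of the smoothness regularizer (> 0,
#'   default 1).
#' @param alpha_R caliber stiffness (> 0, default 1).
#' @param beta Newton step-size control (> 0, default 0.5).
#' @param regularizer position penalty form. `"elastic"` (default) sums a
#'   spring term (every edge keeps its input rest length) and a discrete
#'   curvature term (squared umbrella operator at nodes of degree >= 2):
#'   the springs resist re-spacing of nodes along the neurite and the
#'   curvature term resists folding — the intensity term is flat along a
#'   tube's axis, so a chain penalized by neither slides, bunches, or
#'   concertinas onto bright noise ripples — while lateral centering stays
#'   free. `"curvature"` and `"spacing"` apply only the umbrella or only a
#'   squared-first-difference penalty.
#' @param rel_tol convergence tolerance on the relative change of all three
#'   fitness terms (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @param trunc_sd truncation radius of the Laplacian-of-Gaussian kernel in
#'   standard deviations (default 4).
#' @param min_caliber lower clamp on calibers, in units of the smallest
#'   voxel dimension (default 0.5; sub-voxel kernels are not resolvable).
#' @return A list of class `fitness_params`.
#' @export
fitness_params <- function(alpha_r = 1, alpha_R = 1, beta = 0.5,
                           regularizer = c("elastic", "curvature",
                                           "spacing"),
                           rel_tol = 1e-8, max_iter = 200L, trunc_sd = 4,
                           min_caliber = 0.5) {
  regularizer <- match.arg(regularizer)
  stopifnot(alpha_r > 0, alpha_R > 0, beta > 0,
            rel_tol > 0, rel_tol < 1, max_iter >= 1, trunc_sd > 0)
  structure(list(alpha_r = alpha_r, alpha_R = alpha_R, beta = beta,
                 regularizer = regularizer,
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 trunc_sd = trunc_sd, min_caliber = min_caliber),
            class = "fitness_params")
}

# average node density of the trace: nodes per voxel width of trace
# length; ~1 for voxel-spaced initial traces, larger after resampling.
# Scales the regularizers so their stiffness tracks the sampling density.
node_density <- function(trace, stack) {
  len <- trace_length(trace) / stack$voxel_size[1]
  nrow(trace$nodes) / max(len, 1)
}

# clamp node positions into the stack (warn once if any were outside)
clamp_positions <- function(pos, stack, warn = TRUE) {
  d <- dim(stack$voxels)
  lo <- stack$origin
  hi <- stack$origin + (d - 1) * stack$voxel_size
  out <- sweep(pos, 2, lo, "<") | sweep(pos, 2, hi, ">")
  if (any(out) && warn)
    warning(sprintf("%d node coordinate(s) outside the stack were clamped",
                    sum(out)))
  for (a in 1:3) pos[, a] <- pmin(pmax(pos[, a], lo[a]), hi[a])
  pos
}

# quadratic penalty operator P for the "curvature" and "spacing" forms:
# the penalty on a per-node quantity q is |P q|^2
reg_matrix <- function(trace, type) {
  n <- nrow(trace$nodes)
  edges <- trace$edges
  if (nrow(edges) == 0) return(matrix(0, 0, n))
  if (type == "spacing") {
    P <- matrix(0, nrow(edges), n)
    for (e in seq_len(nrow(edges))) {
      P[e, edges[e, 1]] <- 1
      P[e, edges[e, 2]] <- -1
    }
    return(P)
  }
  deg <- trace_degree(trace)
  rows <- which(deg >= 2)
  P <- matrix(0, length(rows), n)
  if (length(rows) == 0) return(P)
  rowof <- match(seq_len(n), rows)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (!is.na(rowof[a])) {
      P[rowof[a], b] <- P[rowof[a], b] + 1 / deg[a]
      P[rowof[a], a] <- P[rowof[a], a] - 1 / deg[a]
    }
    if (!is.na(rowof[b])) {
      P[rowof[b], a] <- P[rowof[b], a] + 1 / deg[b]
      P[rowof[b], b] <- P[rowof[b], b] - 1 / deg[b]
    }
  }
  P
}

# position penalty value / gradient / Hessian parts. The elastic form
# returns spring blocks (per edge, Gauss-Newton) plus a quadratic
# curvature part; the pure quadratic forms return `quad` only.
# rest: per-edge rest lengths (elastic form only).
position_penalty <- function(pos, edges, type, P = NULL, rest = NULL,
                             derivs = FALSE) {
  quad_part <- function() {
    val <- sum((P %*% pos)^2)
    if (!derivs) return(list(value = val))
    G <- crossprod(P)
    list(value = val, grad = 2 * (G %*% pos), quad = 2 * G)
  }
  if (type != "elastic") return(quad_part())
  cp <- quad_part()   # curvature component (P is the umbrella operator)
  ne <- nrow(edges)
  if (ne == 0) {
    out <- list(value = cp$value)
    if (derivs) {
      out$grad <- cp$grad; out$quad <- cp$quad; out$blocks <- NULL
    }
    return(out)
  }
  dvec <- pos[edges[, 1], , drop = FALSE] - pos[edges[, 2], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  val <- sum((len - rest)^2) + cp$value
  if (!derivs) return(list(value = val))
  grad <- matrix(cp$grad, nrow(pos), 3)
  blocks <- vector("list", ne)
  for (e in seq_len(ne)) {
    if (len[e] < 1e-9) {
      blocks[[e]] <- 2 * diag(3)
      next
    }
    u <- dvec[e, ] / len[e]
    g <- 2 * (len[e] - rest[e]) * u
    grad[edges[e, 1], ] <- grad[edges[e, 1], ] + g
    grad[edges[e, 2], ] <- grad[edges[e, 2], ] - g
    # Gauss-Newton spring block, kept positive semidefinite
    c_perp <- max(0, 1 - rest[e] / len[e])
    blocks[[e]] <- 2 * (outer(u, u) + c_perp * (diag(3) - outer(u, u)))
  }
  list(value = val, grad = grad, quad = cp$quad, blocks = blocks)
}

#' Trace fitness: LoG intensity response plus smoothness regularizers
#'
#' The fitness maximized by [optimize_trace()] is
#' `F = sum_k L_k - alpha_r * lambda * E_pos - alpha_R * lambda * E_cal`,
#' where `L_k` is the scale-normalized Laplacian-of-Gaussian response of
#' the image at node `k` (kernel width set by the node caliber, truncated
#' at `trunc_sd` standard deviations and computed by explicit local
#' summation), `E_pos` is the position penalty chosen by
#' `params$regularizer` (rest-length springs by default), `E_cal` is the
#' squared caliber difference summed over edges, and `lambda` is the
#' average node density of the trace (nodes per voxel width of trace
#' length), which scales the regularizers with the sampling density.
#'
#' For the elastic form the rest lengths are the trace's own edge lengths,
#' so the position term of an unmodified trace is exactly zero.
#'
#' @param trace a `neur_trace` (nonempty). Nodes outside the stack are
#'   clamped with a warning.
#' @param stack an [image_stack()].
#' @param params a [fitness_params()].
#' @param rest optional per-edge rest lengths for the elastic penalty
#'   (default: the trace's current edge lengths).
#' @return List with `total`, `intensity`, `position`, `caliber` terms.
#' @export
trace_fitness <- function(trace, stack, params = fitness_params(),
                          rest = NULL) {
  if (nrow(trace$nodes) == 0) stop("trace is empty")
  pos <- clamp_positions(node_positions(trace), stack)
  sig <- trace$nodes$caliber
  d <- dim(stack$voxels)
  lambda <- node_density(trace, stack)
  res <- .log_terms_cpp(stack$voxels, as.integer(d), stack$voxel_size,
                        stack$origin, pos, sig, params$trunc_sd, FALSE)
  P <- reg_matrix(trace, if (params$regularizer == "spacing") "spacing"
                  else "curvature")
  if (params$regularizer == "elastic" && is.null(rest))
    rest <- edge_lengths(trace)
  pp <- position_penalty(pos, trace$edges, params$regularizer, P, rest)
  caliber <- 0
  if (nrow(trace$edges) > 0)
    caliber <- -params$alpha_R * lambda *
      sum((sig[trace$edges[, 1]] - sig[trace$edges[, 2]])^2)
  intensity <- sum(res$value)
  position <- -params$alpha_r * lambda * pp$value
  list(total = intensity + position + caliber,
       intensity = intensity, position = position, caliber = caliber)
}

#' Optimize a trace by Newton's method
#'
#' Maximizes [trace_fitness()] over all node positions and calibers
#' simultaneously. The Hessian combines per-node 4x4 blocks of the
#' intensity term (made negative definite by eigenvalue flipping) with the
#' regularizer coupling (exact for the quadratic forms, Gauss-Newton for
#' the elastic springs); the assembled system is damped to negative
#' definiteness before inversion, and each Newton step is scaled by `beta`
#' with step halving if the fitness would decrease. All nodes, including
#' branch and terminal points, are updated synchronously. Iteration stops
#' when the relative changes of all three fitness terms fall below
#' `rel_tol` or at `max_iter`.
#'
#' @inheritParams trace_fitness
#' @return The optimized `neur_trace`, with attributes `iterations`,
#'   `converged`, and `fitness` (final term list). Total fitness is never
#'   below the input's.
#' @export
optimize_trace <- function(trace, stack, params = fitness_params()) {
  n <- nrow(trace$nodes)
  if (n == 0) stop("trace is empty")
  d <- dim(stack$voxels)
  lambda <- node_density(trace, stack)
  sx <- stack$voxel_size
  min_cal <- params$min_caliber * min(sx)
  pos <- clamp_positions(node_positions(trace), stack)
  sig <- pmax(trace$nodes$caliber, min_cal)
  edges <- trace$edges

  type <- params$regularizer
  P <- reg_matrix(trace, if (type == "spacing") "spacing" else "curvature")
  rest <- if (type == "elastic") edge_lengths(trace) else NULL
  # caliber penalty: quadratic first differences over edges
  Gc <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      Gc[a, a] <- Gc[a, a] + 1; Gc[b, b] <- Gc[b, b] + 1
      Gc[a, b] <- Gc[a, b] - 1; Gc[b, a] <- Gc[b, a] - 1
    }
  }
  wr <- params$alpha_r * lambda
  wc <- params$alpha_R * lambda

  eval_terms <- function(pos, sig) {
    res <- .log_terms_cpp(stack$voxels, as.integer(d), sx, stack$origin,
                          pos, sig, params$trunc_sd, FALSE)
    pp <- position_penalty(pos, edges, type, P, rest)
    intensity <- sum(res$value)
    position <- -wr * pp$value
    caliber <- if (nrow(edges) == 0) 0 else
      -wc * sum((sig[edges[, 1]] - sig[edges[, 2]])^2)
    list(total = intensity + position + caliber, intensity = intensity,
         position = position, caliber = caliber)
  }

  # variable layout: (x, y, z, R) per node, node-major
  vidx <- function(node, comp) 4L * (node - 1L) + comp
  nv <- 4L * n

  cur <- eval_terms(pos, sig)
  iter <- 0L
  converged <- FALSE

  repeat {
    if (iter >= params$max_iter) break
    iter <- iter + 1L

    der <- .log_terms_cpp(stack$voxels, as.integer(d), sx, stack$origin,
                          pos, sig, params$trunc_sd, TRUE)
    pp <- position_penalty(pos, edges, type, P, rest, derivs = TRUE)
    grad <- numeric(nv)
    for (c in 1:3)
      grad[vidx(seq_len(n), c)] <- der$grad[, c] - wr * pp$grad[, c]
    grad[vidx(seq_len(n), 4L)] <- der$grad[, 4] -
      2 * wc * as.numeric(Gc %*% sig)

    # per-node 4x4 intensity blocks, made negative definite by flipping
    # positive eigenvalues to their negatives (saddle-free Newton): a node
    # sitting on a convex-ascent direction (e.g. a caliber collapsing onto
    # a noise spike) would otherwise force global damping that freezes
    # every other node
    H <- matrix(0, nv, nv)
    for (q in seq_len(n)) {
      B <- matrix(der$hess[q, ], 4, 4)
      B <- (B + t(B)) / 2
      eg <- eigen(B, symmetric = TRUE)
      lam <- -pmax(abs(eg$values), 0.05 * max(abs(eg$values)), 1e-8)
      B <- eg$vectors %*% (lam * t(eg$vectors))
      idx <- vidx(q, 1:4)
      H[idx, idx] <- H[idx, idx] + B
    }
    # regularizer Hessian: quadratic (curvature/spacing) part ...
    if (!is.null(pp$quad)) {
      Gp <- wr * pp$quad
      nzp <- which(Gp != 0, arr.ind = TRUE)
      for (c in 1:3) {
        ii <- vidx(nzp[, 1], c); jj <- vidx(nzp[, 2], c)
        H[cbind(ii, jj)] <- H[cbind(ii, jj)] - Gp[nzp]
      }
    }
    # ... plus the spring blocks of the elastic form
    if (type == "elastic" && !is.null(pp$blocks)) {
      for (e in seq_len(nrow(edges))) {
        Bq <- wr * pp$blocks[[e]]
        ia <- vidx(edges[e, 1], 1:3); ib <- vidx(edges[e, 2], 1:3)
        H[ia, ia] <- H[ia, ia] - Bq
        H[ib, ib] <- H[ib, ib] - Bq
        H[ia, ib] <- H[ia, ib] + Bq
        H[ib, ia] <- H[ib, ia] + Bq
      }
    }
    nzc <- which(Gc != 0, arr.ind = TRUE)
    if (nrow(nzc) > 0) {
      ii <- vidx(nzc[, 1], 4L); jj <- vidx(nzc[, 2], 4L)
      H[cbind(ii, jj)] <- H[cbind(ii, jj)] - 2 * wc * Gc[nzc]
    }

    # damp -H to positive definiteness, then solve for the ascent step
    A <- -(H + t(H)) / 2
    tau <- 0
    scale0 <- mean(abs(diag(A))) + 1e-12
    step <- NULL
    for (k in 0:40) {
      ok <- tryCatch({
        R <- chol(A + diag(tau, nv))
        step <- backsolve(R, forwardsolve(t(R), grad))
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      tau <- if (tau == 0) 1e-6 * scale0 else 2 * tau
    }
    if (is.null(step)) { # fall back to gradient ascent
      step <- grad / sqrt(sum(grad^2) + 1e-300) * min(sx)
    }
    # trust cap: no node may move more than 2 voxels per iteration (keeps
    # near-flat background nodes from taking wild quasi-Newton jumps)
    disp <- sqrt(step[vidx(seq_len(n), 1)]^2 + step[vidx(seq_len(n), 2)]^2 +
                   step[vidx(seq_len(n), 3)]^2 + step[vidx(seq_len(n), 4)]^2)
    cap <- 2 * max(sx)
    if (max(disp) > cap) step <- step * cap / max(disp)

    # beta-scaled step with halving on fitness decrease
    improved <- FALSE
    bfac <- params$beta
    for (h in 1:20) {
      npos <- pos + bfac * cbind(step[vidx(seq_len(n), 1)],
                                 step[vidx(seq_len(n), 2)],
                                 step[vidx(seq_len(n), 3)])
      nsig <- pmax(sig + bfac * step[vidx(seq_len(n), 4)], min_cal)
      npos <- clamp_positions(npos, stack, warn = FALSE)
      cand <- eval_terms(npos, nsig)
      if (cand$total >= cur$total) { improved <- TRUE; break }
      bfac <- bfac / 2
    }
    if (!improved) { converged <- TRUE; break }

    delta <- c(abs(cand$intensity - cur$intensity),
               abs(cand$position - cur$position),
               abs(cand$caliber - cur$caliber))
    pos <- npos; sig <- nsig; cur <- cand
    if (all(delta <= params$rel_tol * max(abs(cur$total), 1))) {
      converged <- TRUE
      break
    }
  }

  out <- trace
  out$nodes$x <- pos[, 1]; out$nodes$y <- pos[, 2]; out$nodes$z <- pos[, 3]
  out$nodes$caliber <- sig
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "fitness") <- cur
  out
}
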