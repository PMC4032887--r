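# Independent oracles and small fixture builders used across the suite.

# Bell numbers via the standard recurrence B(n+1) = sum_k C(n, k) B(k)
bell_number <- function(n) {
  B <- c(1)  # B(0)
  for (m in 0:(n - 1)) {
    B <- c(B, sum(choose(m, 0:m) * B[1:(m + 1)]))
  }
  B[n + 1]
}

# label-correcting (Bellman-Ford-style) Eikonal oracle: sweep the same
# upwind update until a fixed point; independent of the min-heap solver
eikonal_fixpoint <- function(stack, boundary, max_sweeps = 500) {
  d <- dim(stack$voxels)
  sp <- stack$voxel_size
  Tm <- array(Inf, d)
  for (b in seq_len(nrow(boundary)))
    Tm[boundary[b, 1], boundary[b, 2], boundary[b, 3]] <- 0
  is_b <- array(FALSE, d)
  is_b[boundary] <- TRUE
  upwind <- function(Tm, i, j, k) {
    inten <- stack$voxels[i, j, k]
    if (inten <= 0) return(Inf)
    tax <- rep(Inf, 3)
    for (a in 1:3) for (dir in c(-1L, 1L)) {
      ii <- i + (a == 1) * dir; jj <- j + (a == 2) * dir
      kk <- k + (a == 3) * dir
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3])
        tax[a] <- min(tax[a], Tm[ii, jj, kk])
    }
    ord <- order(tax); tax <- tax[ord]; ss <- sp[ord]
    rhs <- 1 / inten^2
    for (m in 1:3) {
      if (!is.finite(tax[m])) break
      w <- 1 / ss[1:m]^2
      A <- sum(w); B <- -2 * sum(w * tax[1:m])
      C <- sum(w * tax[1:m]^2) - rhs
      disc <- B^2 - 4 * A * C
      if (disc < 0) next
      Tc <- (-B + sqrt(disc)) / (2 * A)
      if (Tc < tax[m]) next
      if (m < 3 && is.finite(tax[m + 1]) && Tc > tax[m + 1]) next
      return(Tc)
    }
    if (is.finite(tax[1])) return(tax[1] + ss[1] / inten)
    Inf
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (is_b[i, j, k]) next
      tn <- upwind(Tm, i, j, k)
      if (tn < Tm[i, j, k] - 1e-15) { Tm[i, j, k] <- tn; changed <- TRUE }
    }
    if (!changed) break
  }
  Tm
}

# straight polyline trace along x at (y0, z0), n nodes spaced `by`
line_trace <- function(n, by = 1, y0 = 0, z0 = 0, x0 = 0, caliber = 1) {
  nodes <- data.frame(x = x0 + (seq_len(n) - 1) * by, y = y0, z = z0,
                      caliber = caliber)
  edges <- cbind(seq_len(n - 1), 2:n)
  make_trace(nodes, edges)
}

# small random tree trace grown by preferential attachment of nodes
random_tree_trace <- function(n = 20, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                      z = runif(n, 0, 10), caliber = runif(n, 0.5, 2))
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1),
                             integer(1)))
  make_trace(nodes, edges)
}

# Y-shaped trace: stem plus two arms from a shared fork node
y_trace <- function(arm = 6) {
  stem <- data.frame(x = 0:arm, y = 0, z = 0, caliber = 1)
  up <- data.frame(x = arm + seq_len(arm), y = seq_len(arm), z = 0,
                   caliber = 1)
  dn <- data.frame(x = arm + seq_len(arm), y = -seq_len(arm), z = 0,
                   caliber = 1)
  nodes <- rbind(stem, up, dn)
  fork <- arm + 1
  edges <- rbind(cbind(1:arm, 2:fork),
                 cbind(c(fork, fork + seq_len(arm - 1)),
                       fork + seq_len(arm)),
                 cbind(c(fork, fork + arm + seq_len(arm - 1)),
                       fork + arm + seq_len(arm)))
  make_trace(nodes, edges)
}

# terminal table row builder for hand-made merge clusters
terminal_row <- function(pos, tangent, branch_id, end = 1L,
                         mean_int = 0.5, caliber = 1, len = 20) {
  tangent <- tangent / sqrt(sum(tangent^2))
  data.frame(branch_id = branch_id, end = end, node_idx = branch_id,
             x = pos[1], y = pos[2], z = pos[3],
             tx = tangent[1], ty = tangent[2], tz = tangent[3],
             branch_len = len, mean_int = mean_int, mean_caliber = caliber)
}

# default planted weights used in learning tests (signs respect g)
planted_w <- function() c(1, 0.6, 0.8, 1.2, 0.5, 0.3, 0.4, 0.8, 0.7)
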