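#' Remove short terminal twigs and dim branches
#'
#' Repeatedly decomposes the trace into branches and removes (a) terminal
#' branches (at least one endpoint of degree <= 1) shorter than
#' `min_terminal_len` voxel widths and (b) branches whose mean intensity
#' (trilinear samples at node positions) is below `min_intensity`, until no
#' branch is removed. Removal can merge surviving branches, so the filter
#' is re-applied to a fixed point.
#'
#' @param trace a `neur_trace`.
#' @param stack optional [image_stack()]; without it the intensity filter
#'   is skipped.
#' @param min_terminal_len minimum terminal-branch length in voxel widths
#'   (`sx` units), default 12.
#' @param min_intensity minimum branch mean intensity, default 0.12.
#' @param sx voxel width used to convert `min_terminal_len`; defaults to
#'   the stack's, or 1 without a stack.
#' @return The filtered `neur_trace`.
#' @export
prefilter_trace <- function(trace, stack = NULL, min_terminal_len = 12,
                            min_intensity = 0.12,
                            sx = if (is.null(stack)) 1 else
                              stack$voxel_size[1]) {
  repeat {
    brs <- decompose_branches(trace)
    if (length(brs) == 0) return(trace)
    deg <- trace_degree(trace)
    p <- node_positions(trace)
    score <- rep(NA_real_, length(brs))  # lower = removed first
    for (b in seq_along(brs)) {
      ch <- brs[[b]]$node_idx
      terminal <- deg[ch[1]] <= 1 || deg[ch[length(ch)]] <= 1
      if (terminal && brs[[b]]$length < min_terminal_len * sx) {
        score[b] <- brs[[b]]$length
        next
      }
      if (!is.null(stack)) {
        mi <- mean(stack_interp(stack, p[ch, , drop = FALSE]))
        if (mi < min_intensity) score[b] <- min_terminal_len * sx + mi
      }
    }
    if (all(is.na(score))) return(trace)
    # remove one branch per pass: pruning a twig can merge its neighbors
    # into a branch that no longer qualifies, so simultaneous removal
    # over-prunes
    drop <- seq_along(brs) == which.min(score)
    keep_edges <- list()
    for (b in which(!drop)) {
      ch <- brs[[b]]$node_idx
      keep_edges[[length(keep_edges) + 1L]] <- cbind(ch[-length(ch)], ch[-1])
    }
    edges <- if (length(keep_edges)) do.call(rbind, keep_edges) else
      matrix(integer(0), 0, 2)
    used <- sort(unique(c(edges)))
    remap <- match(seq_len(nrow(trace$nodes)), used)
    nodes <- trace$nodes[used, , drop = FALSE]
    rownames(nodes) <- NULL
    edges <- matrix(remap[edges], ncol = 2)
    trace <- make_trace(nodes, edges)
  }
}

# nearest neighbor in b of every row of a (chunked brute force);
# returns index and distance vectors
nn_search <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(list(idx = rep(NA_integer_, na), dist = rep(Inf, na)))
  idx <- integer(na); dst <- numeric(na)
  chunk <- max(1L, floor(4e6 / nb))
  bb <- rowSums(b^2)
  for (s in seq(1, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    d2 <- outer(rowSums(a[s:e, , drop = FALSE]^2), bb, "+") -
      2 * a[s:e, , drop = FALSE] %*% t(b)
    idx[s:e] <- max.col(-d2, ties.method = "first")
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), idx[s:e])], 0))
  }
  list(idx = idx, dist = dst)
}

#' Node correspondence between a test and a gold-standard trace
#'
#' Bi-directional nearest-neighbor search: a test node has a corresponding
#' gold node if its nearest neighbor on the gold trace lies within `h`
#' voxel widths (a true positive; otherwise a false positive), and a gold
#' node without a test node within `h` is a false negative. The search is
#' run in both directions, and separately for terminal points and for
#' branch points. Both traces should be resampled to a common edge length
#' (`d = 0.25` voxels) first, so that nodes sample the curves densely and
#' the node-to-node distance approximates the curve-to-curve distance.
#'
#' @param test,gold `neur_trace`s, resampled.
#' @param h correspondence radius in voxel widths, default 10.
#' @param sx physical voxel width (default 1): `h` is scaled by it, and
#'   reported distances are divided by it.
#' @return List of class `trace_correspondence` with data.frames `nodes`,
#'   `terminal`, `branch` holding the corresponding (within-`h`) test-side
#'   pairs (columns `test`, `gold`, `dist` in voxel units), per-node
#'   distance vectors `test_dist`, `gold_dist` (voxel units, `Inf` when the
#'   other trace is empty), critical-point index sets, and the traces.
#' @export
correspond_traces <- function(test, gold, h = 10, sx = 1) {
  pt <- node_positions(test); pg <- node_positions(gold)
  fwd <- nn_search(pt, pg); bwd <- nn_search(pg, pt)
  keep <- which(fwd$dist <= h * sx)
  nodes <- data.frame(test = keep, gold = fwd$idx[keep],
                      dist = fwd$dist[keep] / sx)
  ct <- critical_points(test); cg <- critical_points(gold)
  pair_crit <- function(it, ig) {
    f <- nn_search(pt[it, , drop = FALSE], pg[ig, , drop = FALSE])
    b <- nn_search(pg[ig, , drop = FALSE], pt[it, , drop = FALSE])
    keep <- which(f$dist <= h * sx)
    list(pairs = data.frame(test = it[keep], gold = ig[f$idx[keep]],
                            dist = f$dist[keep] / sx),
         test_dist = f$dist / sx, gold_dist = b$dist / sx)
  }
  tp <- pair_crit(ct$terminal, cg$terminal)
  bp <- pair_crit(ct$branch, cg$branch)
  structure(list(nodes = nodes,
                 terminal = tp$pairs, branch = bp$pairs,
                 test_dist = fwd$dist / sx, gold_dist = bwd$dist / sx,
                 terminal_test_dist = tp$test_dist,
                 terminal_gold_dist = tp$gold_dist,
                 branch_test_dist = bp$test_dist,
                 branch_gold_dist = bp$gold_dist,
                 test_terminal = ct$terminal, gold_terminal = cg$terminal,
                 test_branch = ct$branch, gold_branch = cg$branch,
                 test = test, gold = gold, h = h, sx = sx),
            class = "trace_correspondence")
}

# length attributed to each node: half of its incident edge lengths
node_lengths <- function(trace) {
  nl <- numeric(nrow(trace$nodes))
  if (nrow(trace$edges) > 0) {
    el <- edge_lengths(trace)
    for (c in 1:2) {
      agg <- tapply(rep(el, 1), trace$edges[, c], sum)
      nl[as.integer(names(agg))] <- nl[as.integer(names(agg))] + agg / 2
    }
  }
  nl
}

#' Miss-Extra-Scores of a trace correspondence
#'
#' The length MES is the gold-standard length reduced by the false negative
#' length, divided by the gold-standard length increased by the false
#' positive length: `(L_gold - L_FN) / (L_gold + L_FP)`. Terminal- and
#' branch-point MES are defined analogously with point counts. Identical
#' traces give 1; an empty test trace gives a length MES of 0.
#'
#' @param corr a `trace_correspondence` from [correspond_traces()].
#' @return List with `mes_length`, `mes_tp`, `mes_bp`, and the underlying
#'   `fp_length`, `fn_length`, `fp_tp`, `fn_tp`, `fp_bp`, `fn_bp`,
#'   `gold_length`.
#' @export
mes_scores <- function(corr) {
  lt <- node_lengths(corr$test); lg <- node_lengths(corr$gold)
  gold_len <- sum(lg)
  if (gold_len == 0 && nrow(corr$gold$nodes) == 0)
    stop("empty gold-standard trace")
  h <- corr$h
  fp_len <- sum(lt[corr$test_dist > h])
  fn_len <- sum(lg[corr$gold_dist > h])
  fp_tp <- sum(corr$terminal_test_dist > h)
  fn_tp <- sum(corr$terminal_gold_dist > h)
  fp_bp <- sum(corr$branch_test_dist > h)
  fn_bp <- sum(corr$branch_gold_dist > h)
  safe_ratio <- function(num, den) if (den == 0) 1 else num / den
  list(mes_length = safe_ratio(gold_len - fn_len, gold_len + fp_len),
       mes_tp = safe_ratio(length(corr$gold_terminal) - fn_tp,
                           length(corr$gold_terminal) + fp_tp),
       mes_bp = safe_ratio(length(corr$gold_branch) - fn_bp,
                           length(corr$gold_branch) + fp_bp),
       fp_length = fp_len, fn_length = fn_len,
       fp_tp = fp_tp, fn_tp = fn_tp, fp_bp = fp_bp, fn_bp = fn_bp,
       gold_length = gold_len)
}

#' Full trace-to-trace comparison report
#'
#' Pipeline: prefilter (with a stack), resample both traces to edge length
#' `d` voxels, compute the mutual nearest-neighbor correspondence at radius
#' `h` voxels, and derive distance distributions, false positive/negative
#' lengths and point counts, and the three Miss-Extra-Scores.
#'
#' @param test,gold `neur_trace`s.
#' @param stack optional [image_stack()] used for prefiltering and to set
#'   the voxel width.
#' @param d resampling edge length in voxel widths, default 0.25.
#' @param h correspondence radius in voxel widths, default 10.
#' @param min_terminal_len,min_intensity prefilter settings (see
#'   [prefilter_trace()]); the intensity filter needs a stack.
#' @param prefilter apply the prefilter (default `TRUE`).
#' @param sx voxel width; defaults to the stack's, or 1.
#' @return List of class `trace_comparison`: `mes` (see [mes_scores()]),
#'   `node_distances`, `tp_distances`, `bp_distances` (voxel units), node
#'   and point counts, and the correspondence object.
#' @export
compare_report <- function(test, gold, stack = NULL, d = 0.25, h = 10,
                           min_terminal_len = 12, min_intensity = 0.12,
                           prefilter = TRUE,
                           sx = if (is.null(stack)) 1 else
                             stack$voxel_size[1]) {
  if (prefilter) {
    test <- prefilter_trace(test, stack, min_terminal_len, min_intensity,
                            sx = sx)
    gold <- prefilter_trace(gold, stack, min_terminal_len, min_intensity,
                            sx = sx)
  }
  test <- resample_trace(test, d * sx)
  gold <- resample_trace(gold, d * sx)
  corr <- correspond_traces(test, gold, h = h, sx = sx)
  m <- mes_scores(corr)
  structure(list(mes = m,
                 node_distances = corr$nodes$dist,
                 tp_distances = corr$terminal$dist,
                 bp_distances = corr$branch$dist,
                 n_test_nodes = nrow(test$nodes),
                 n_gold_nodes = nrow(gold$nodes),
                 correspondence = corr),
            class = "trace_comparison")
}

#' @export
print.trace_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<trace_comparison: MES length %.3f, TP %.3f, BP %.3f; ",
           "FP/FN length %.3g/%.3g>\n"),
    x$mes$mes_length, x$mes$mes_tp, x$mes$mes_bp,
    x$mes$fp_length, x$mes$fn_length))
  invisible(x)
}

#' Enumerate the comparisons of a multi-user tracing protocol
#'
#' Each manual trace of a stack serves once as the gold standard and is
#' compared against the remaining manual traces (inter-user) and every
#' automated trace (automated-to-user). With `U` manual and one automated
#' trace per stack this yields `U (U - 1)` inter-user and `U`
#' automated-to-user comparisons per stack.
#'
#' @param n_stacks number of stacks.
#' @param n_users manual traces per stack.
#' @param n_auto automated traces per stack (default 1).
#' @return data.frame with columns `stack`, `gold` ("user<g>"), `test`,
#'   `type` ("inter_user" or "auto_user").
#' @export
comparison_plan <- function(n_stacks, n_users, n_auto = 1) {
  rows <- list()
  for (s in seq_len(n_stacks)) {
    for (g in seq_len(n_users)) {
      for (u in setdiff(seq_len(n_users), g))
        rows[[length(rows) + 1L]] <- data.frame(
          stack = s, gold = paste0("user", g), test = paste0("user", u),
          type = "inter_user")
      for (a in seq_len(n_auto))
        rows[[length(rows) + 1L]] <- data.frame(
          stack = s, gold = paste0("user", g), test = paste0("auto", a),
          type = "auto_user")
    }
  }
  do.call(rbind, rows)
}

#' Run all comparisons of a multi-user protocol
#'
#' @param stacks list; each element is a list with `users` (list of manual
#'   `neur_trace`s), `auto` (list or single automated trace), and
#'   optionally `stack` (an [image_stack()] for prefiltering).
#' @param ... passed to [compare_report()].
#' @return data.frame with one row per comparison: plan columns plus
#'   `mes_length`, `mes_tp`, `mes_bp`, `mean_node_dist`.
#' @export
compare_set <- function(stacks, ...) {
  rows <- list()
  for (s in seq_along(stacks)) {
    st <- stacks[[s]]
    autos <- st$auto
    if (inherits(autos, "neur_trace")) autos <- list(autos)
    plan <- comparison_plan(1, length(st$users), length(autos))
    for (r in seq_len(nrow(plan))) {
      gi <- as.integer(sub("user", "", plan$gold[r]))
      gold <- st$users[[gi]]
      test <- if (plan$type[r] == "inter_user")
        st$users[[as.integer(sub("user", "", plan$test[r]))]]
      else autos[[as.integer(sub("auto", "", plan$test[r]))]]
      rep <- compare_report(test, gold, stack = st$stack, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        stack = s, gold = plan$gold[r], test = plan$test[r],
        type = plan$type[r], mes_length = rep$mes$mes_length,
        mes_tp = rep$mes$mes_tp, mes_bp = rep$mes$mes_bp,
        mean_node_dist = if (length(rep$node_distances))
          mean(rep$node_distances) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
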