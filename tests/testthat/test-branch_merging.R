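test_that("terminal clustering is single-linkage with the distance threshold", {
  mk <- function(...) do.call(rbind, list(...))
  terms <- rbind(terminal_row(c(0, 0, 0), c(-1, 0, 0), 1),
                 terminal_row(c(5, 0, 0), c(1, 0, 0), 2))
  cl <- cluster_terminals(terms, threshold = 10)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$terminals), 2)
  # 11 apart with threshold 10: two singletons, no clusters
  terms2 <- rbind(terminal_row(c(0, 0, 0), c(-1, 0, 0), 1),
                  terminal_row(c(11, 0, 0), c(1, 0, 0), 2))
  expect_length(cluster_terminals(terms2, threshold = 10), 0)
  # chain A-B-C at 8 apart (|AC| = 16): one cluster of three
  terms3 <- rbind(terminal_row(c(0, 0, 0), c(-1, 0, 0), 1),
                  terminal_row(c(8, 0, 0), c(1, 0, 0), 2),
                  terminal_row(c(16, 0, 0), c(1, 0, 0), 3))
  cl3 <- cluster_terminals(terms3, threshold = 10)
  expect_length(cl3, 1)
  expect_equal(nrow(cl3[[1]]$terminals), 3)
  # brute-force oracle: component membership from the full distance graph
  pos <- as.matrix(terms3[, c("x", "y", "z")])
  adj <- as.matrix(dist(pos)) <= 10
  reach <- adj
  for (t in 1:3) reach <- reach | (reach %*% adj > 0)
  expect_true(all(reach))
})

test_that("scenario counts follow the Bell numbers", {
  expect_equal(length(set_partitions(2)), 2)
  expect_equal(length(set_partitions(3)), 5)
  expect_equal(length(set_partitions(4)), 15)
  expect_equal(length(set_partitions(5)), 52)
  # oracle: Bell recurrence for n = 2..8
  for (n in 2:8)
    expect_equal(length(set_partitions(n)), bell_number(n))
  # partitions are valid restricted-growth strings in lexicographic order
  p4 <- set_partitions(4)
  expect_equal(p4[[1]], rep(1L, 4))
  expect_equal(p4[[length(p4)]], 1:4)
  strs <- vapply(p4, paste, character(1), collapse = "")
  expect_equal(strs, sort(strs))
  expect_equal(anyDuplicated(strs), 0L)
})

test_that("oversized clusters are refused with guidance", {
  terms <- do.call(rbind, lapply(1:9, function(i)
    terminal_row(c(i, 0, 0), c(1, 0, 0), i)))
  cl <- merge_cluster(terms)
  expect_error(enumerate_scenarios(cl), "cap")
  expect_length(enumerate_scenarios(cl, cap = 9)$scenarios,
                bell_number(9))
})

test_that("scenario features capture geometry as designed", {
  # all singletons: features 1-8 zero, feature 9 = n
  terms <- rbind(terminal_row(c(0, 0, 0), c(-1, 0, 0), 1),
                 terminal_row(c(4, 0, 0), c(1, 0, 0), 2),
                 terminal_row(c(0, 4, 0), c(0, 1, 0), 3))
  x <- scenario_features(1:3, terms)
  expect_equal(x, c(rep(0, 8), 3))
  # collinear abutting endpoints with opposite outward tangents (each
  # pointing across the gap toward the other branch, i.e. the natural
  # gap-merge geometry): overrun 0, offset 0, alignment 1, tortuosity 1
  ab <- rbind(terminal_row(c(0, 0, 0), c(1, 0, 0), 1),
              terminal_row(c(2, 0, 0), c(-1, 0, 0), 2))
  xab <- scenario_features(c(1, 1), ab)
  expect_equal(xab[1], 2)            # distance
  expect_equal(xab[2], 0)            # no overrun
  expect_equal(xab[3], 0)            # no offset
  expect_equal(xab[4], 1)            # alignment -u_a . u_b = 1
  expect_equal(xab[8], 1, tolerance = 1e-6)  # straight bridge
  expect_equal(xab[9], 0)
  # overlapping geometry (each branch extends past the other endpoint, so
  # the outward tangents point away from each other): full overrun
  over <- rbind(terminal_row(c(0, 0, 0), c(-1, 0, 0), 1),
                terminal_row(c(2, 0, 0), c(1, 0, 0), 2))
  xov <- scenario_features(c(1, 1), over)
  expect_equal(xov[2], 2)            # both ordered overruns = 2
  expect_equal(xov[3], 0)
  # perpendicular offset
  off <- rbind(terminal_row(c(0, 0, 0), c(1, 0, 0), 1),
               terminal_row(c(0, 3, 0), c(1, 0, 0), 2))
  expect_equal(scenario_features(c(1, 1), off)[3], 3)
})

test_that("correct pairing at a crossing scores higher tangent alignment than the stolen one", {
  # two straight axons crossing at a shallow angle; four endpoints at the
  # dissolved junction, outward tangents along each axon
  ang <- 20 * pi / 180
  uA <- c(cos(ang / 2), sin(ang / 2), 0)
  uB <- c(cos(ang / 2), -sin(ang / 2), 0)
  terms <- rbind(
    terminal_row(c(-1, 0, 0) * 1, -uA, 1),   # A left endpoint, faces -uA
    terminal_row(c(1, 0, 0) * 1, uA, 2),     # A right
    terminal_row(c(-1, 0.3, 0), -uB, 3),     # B left
    terminal_row(c(1, -0.3, 0), uB, 4))      # B right
  correct <- c(1, 1, 2, 2)   # {A-left, A-right}, {B-left, B-right}
  stolen <- c(1, 2, 2, 1)    # A-left with B-right, B-left with A-right
  xc <- scenario_features(correct, terms)
  xs <- scenario_features(stolen, terms)
  # oracle: alignment of the true continuation is cos(0) = 1, the stolen
  # pairing bends by the crossing angle
  expect_gt(xc[4], xs[4])
  expect_equal(xc[4], 1, tolerance = 1e-9)
})

test_that("features are invariant to rigid motion and intensity offsets", {
  set.seed(21)
  terms <- do.call(rbind, lapply(1:4, function(i)
    terminal_row(rnorm(3, sd = 4), rnorm(3), i,
                 mean_int = runif(1, 0.2, 0.8))))
  part <- c(1, 1, 2, 2)
  x0 <- scenario_features(part, terms)
  # random rotation + translation
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_) < 0) qr_[, 1] <- -qr_[, 1]
  shift <- c(5, -3, 2)
  terms2 <- terms
  terms2[, c("x", "y", "z")] <-
    t(qr_ %*% t(as.matrix(terms[, c("x", "y", "z")]))) +
    matrix(shift, 4, 3, byrow = TRUE)
  terms2[, c("tx", "ty", "tz")] <-
    t(qr_ %*% t(as.matrix(terms[, c("tx", "ty", "tz")])))
  x1 <- scenario_features(part, terms2)
  expect_equal(x1[c(1:4, 8, 9)], x0[c(1:4, 8, 9)], tolerance = 1e-9)
  # additive intensity offset cancels in feature 5
  terms3 <- terms
  terms3$mean_int <- terms3$mean_int + 0.17
  expect_equal(scenario_features(part, terms3)[5], x0[5], tolerance = 1e-12)
})

test_that("subtractive normalization yields B(n) - 1 deltas and removes offsets", {
  set.seed(31)
  terms <- do.call(rbind, lapply(1:4, function(i)
    terminal_row(rnorm(3, sd = 4), rnorm(3), i)))
  cl <- cluster_features(enumerate_scenarios(merge_cluster(terms)))
  cl$label <- 3L
  dx <- normalize_within_cluster(cl)
  expect_equal(nrow(dx), bell_number(4) - 1)
  # the correct scenario's own delta (zero vector) is excluded
  expect_false(any(apply(dx, 1, function(r) all(r == 0))))
  # a per-cluster additive constant on every scenario's features cancels
  cl2 <- cl
  cl2$features <- cl2$features + matrix(0.37, nrow(cl2$features), 9)
  expect_equal(normalize_within_cluster(cl2), dx, tolerance = 1e-12)
  # total comparisons over a labeled pool = total scenarios - n clusters
  pool <- planted_clusters(10, planted_w(), seed = 5)
  td <- neuritrace:::gather_deltas(pool)
  n_scen <- sum(vapply(pool, function(cl) length(cl$scenarios), integer(1)))
  expect_equal(nrow(td$deltas), n_scen - length(pool))
  # unlabeled cluster refuses
  cl$label <- NA_integer_
  expect_error(normalize_within_cluster(cl), "unlabeled")
})

test_that("applying chosen scenarios rebuilds the expected topology", {
  # X-shaped trace: two straight tubes crossing at a shared degree-4 node
  nodes <- data.frame(
    x = c(-3, -2, -1, 0, 1, 2, 3, -3, -2, -1, 1, 2, 3),
    y = c(3, 2, 1, 0, -1, -2, -3, -3, -2, -1, 1, 2, 3),
    z = 0, caliber = 1)
  edges <- rbind(cbind(1:6, c(2, 3, 4, 5, 6, 7)),
                 cbind(c(8, 9, 10, 4, 11, 12), c(9, 10, 4, 11, 12, 13)))
  xtrace <- make_trace(nodes, edges)
  expect_equal(sum(trace_degree(xtrace) == 4), 1)
  terms <- branch_terminals(xtrace)
  cls <- cluster_terminals(terms, threshold = 2)
  expect_length(cls, 1)          # the four cut ends at the old junction
  expect_equal(nrow(cls[[1]]$terminals), 4)
  cl <- cluster_features(enumerate_scenarios(cls[[1]]))
  # choose the scenario pairing each tube's two cut ends (no junction)
  tube_of <- function(b) {
    ch <- decompose_branches(xtrace)[[b]]$node_idx
    if (any(ch %in% 1:3)) 1 else if (any(ch %in% 5:7)) 1 else 2
  }
  grp <- vapply(seq_len(4), function(i) {
    ch <- decompose_branches(xtrace)[[cl$terminals$branch_id[i]]]$node_idx
    if (any(ch %in% c(1:3, 5:7))) 1L else 2L
  }, integer(1))
  rgs <- match(grp, unique(grp))
  pick <- which(vapply(cl$scenarios, identical, logical(1), rgs))
  merged <- apply_merging(xtrace, list(cl), pick)
  deg <- trace_degree(merged)
  expect_equal(sum(deg >= 3), 0)           # junction dissolved
  g <- igraph::make_graph(t(merged$edges), n = nrow(merged$nodes),
                          directed = FALSE)
  expect_equal(igraph::components(g)$no, 2)  # two separate axons
  # NA choice leaves the cluster unmerged: four components
  unmerged <- apply_merging(xtrace, list(cl), NA_integer_)
  gu <- igraph::make_graph(t(unmerged$edges), n = nrow(unmerged$nodes),
                           directed = FALSE)
  expect_equal(igraph::components(gu)$no, 4)
  # a block of >= 3 creates one new junction node
  allone <- apply_merging(xtrace, list(cl), 1L)
  expect_equal(sum(trace_degree(allone) >= 3), 1)
})
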