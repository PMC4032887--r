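test_that("prefilter removes short terminal twigs and dim branches to a fixed point", {
  # Y with one 5-voxel twig: only the straight path survives
  stem <- line_trace(21)
  twig <- data.frame(x = 10 + 1:5, y = 1:5, z = 0, caliber = 1)
  nodes <- rbind(stem$nodes, twig)
  edges <- rbind(stem$edges, cbind(c(11, 21 + 1:4), 21 + 1:5))
  y <- make_trace(nodes, edges)
  f <- prefilter_trace(y, min_terminal_len = 12, sx = 1)
  expect_equal(sum(trace_degree(f) >= 3), 0)
  expect_equal(nrow(f$nodes), 21)
  # all branches long: identity
  expect_equal(nrow(prefilter_trace(stem, min_terminal_len = 12)$nodes), 21)
  # cascade: removing a twig merges two 8-length halves into one 16-length
  # branch that then survives; but a dim merged branch is removed by the
  # intensity filter on re-application
  half1 <- line_trace(9)                      # x 0..8
  half2 <- line_trace(9, x0 = 8)              # x 8..16
  tw <- data.frame(x = 8, y = 1:3, z = 0, caliber = 1)
  nodes2 <- rbind(half1$nodes, half2$nodes[-1, ], tw)
  edges2 <- rbind(half1$edges,
                  cbind(c(9, 9 + 1:7), 9 + 1:8),
                  cbind(c(9, 17 + 1:2), 17 + 1:3))
  yy <- make_trace(nodes2, edges2)
  # dim stack everywhere: after the twig goes, the merged 16-branch is dim
  # and must also go (fixed-point re-application)
  dimstack <- image_stack(array(0.05, c(20, 8, 3)), c(1, 1, 1),
                          normalize = FALSE)
  expect_equal(nrow(prefilter_trace(yy, dimstack, min_terminal_len = 5,
                                    min_intensity = 0.12)$nodes), 0)
  # without the stack the merged branch survives
  kept <- prefilter_trace(yy, min_terminal_len = 5)
  expect_equal(nrow(kept$nodes), 17)
})

test_that("correspondence is bi-directional NN within h, in voxel units", {
  gold <- resample_trace(line_trace(41, y0 = 0), 0.25)
  # identical traces: everything corresponds at distance zero
  c0 <- correspond_traces(gold, gold, h = 10)
  expect_equal(nrow(c0$nodes), nrow(gold$nodes))
  expect_true(all(c0$nodes$dist == 0))
  # rigid perpendicular shift by 2: all correspond at distance 2
  sh <- gold; sh$nodes$y <- sh$nodes$y + 2
  c2 <- correspond_traces(sh, gold, h = 10)
  expect_equal(nrow(c2$nodes), nrow(gold$nodes))
  expect_equal(unique(round(c2$nodes$dist, 9)), 2)
  # shift beyond h: zero correspondences
  sh11 <- gold; sh11$nodes$y <- sh11$nodes$y + 11
  c11 <- correspond_traces(sh11, gold, h = 10)
  expect_equal(nrow(c11$nodes), 0)
  # distance histogram support is within [0, h]
  expect_true(all(c2$nodes$dist >= 0 & c2$nodes$dist <= 10))
})

test_that("Miss-Extra-Scores follow the printed definition", {
  gold <- line_trace(41)
  # identical: all three scores are 1
  rep0 <- compare_report(gold, gold, prefilter = FALSE)
  expect_equal(rep0$mes$mes_length, 1)
  expect_equal(rep0$mes$mes_tp, 1)
  expect_equal(rep0$mes$mes_bp, 1)
  # empty test: length score 0
  repe <- compare_report(empty_trace(), gold, prefilter = FALSE)
  expect_equal(repe$mes$mes_length, 0)
  expect_error(compare_report(gold, empty_trace(), prefilter = FALSE),
               "empty gold")
  # gold length 100 with FN 20 and FP 25: score 80/125 = 0.64. Construction:
  # gold = matched 80-segment + a far 20-segment (exact FN); test = the same
  # 80-segment + a different far 25-segment (exact FP)
  seg80 <- line_trace(81)
  gold2 <- make_trace(rbind(seg80$nodes,
                            data.frame(x = 0:20, y = 100, z = 0,
                                       caliber = 1)),
                      rbind(seg80$edges, cbind(81 + 1:20, 82 + 1:20)))
  test2 <- make_trace(rbind(seg80$nodes,
                            data.frame(x = 0:25, y = -100, z = 0,
                                       caliber = 1)),
                      rbind(seg80$edges, cbind(81 + 1:25, 82 + 1:25)))
  rep2 <- compare_report(test2, gold2, prefilter = FALSE)
  expect_equal(rep2$mes$fn_length, 20, tolerance = 1e-9)
  expect_equal(rep2$mes$fp_length, 25, tolerance = 1e-9)
  expect_equal(rep2$mes$mes_length, 0.64, tolerance = 1e-9)
})

test_that("swapping test and gold swaps the false positive and negative roles", {
  set.seed(3)
  a <- random_tree_trace(15, 1)
  b <- random_tree_trace(15, 2)
  ra <- compare_report(a, b, prefilter = FALSE, h = 5)
  rb <- compare_report(b, a, prefilter = FALSE, h = 5)
  expect_equal(ra$mes$fp_length, rb$mes$fn_length, tolerance = 1e-9)
  expect_equal(ra$mes$fn_length, rb$mes$fp_length, tolerance = 1e-9)
  expect_equal(ra$mes$fp_tp, rb$mes$fn_tp)
  expect_equal(ra$mes$fn_tp, rb$mes$fp_tp)
  # mes_length = 1 iff no length errors at all
  self <- compare_report(a, a, prefilter = FALSE)
  expect_equal(self$mes$mes_length, 1)
  expect_equal(self$mes$fp_length + self$mes$fn_length, 0)
})

test_that("the multi-user comparison protocol enumerates the printed counts", {
  plan1 <- comparison_plan(1, 3, 1)
  expect_equal(sum(plan1$type == "inter_user"), 6)
  expect_equal(sum(plan1$type == "auto_user"), 3)
  plan9 <- comparison_plan(9, 3, 1)
  expect_equal(sum(plan9$type == "inter_user"), 54)
  expect_equal(sum(plan9$type == "auto_user"), 27)
  # runner produces one row per planned comparison with MES fields
  tr <- line_trace(31)
  tr2 <- tr; tr2$nodes$y <- tr2$nodes$y + 0.5
  tr3 <- tr; tr3$nodes$y <- tr3$nodes$y - 0.5
  stacks <- list(list(users = list(tr, tr2, tr3), auto = tr2))
  res <- compare_set(stacks, prefilter = FALSE)
  expect_equal(nrow(res), 9)
  expect_true(all(c("mes_length", "mes_tp", "mes_bp") %in% names(res)))
  expect_true(all(res$mes_length > 0.99))
})
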