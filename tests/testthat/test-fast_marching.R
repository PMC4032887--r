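test_that("axis-aligned arrival times follow T = distance / speed", {
  st <- image_stack(array(1, c(11, 5, 5)), c(1, 1, 1), normalize = FALSE)
  tm <- solve_eikonal(st, cbind(1, 3, 3))
  expect_equal(tm$T[, 3, 3], 0:10, tolerance = 1e-12)
  # halved speed doubles every arrival time
  st2 <- image_stack(array(0.5, c(11, 5, 5)), c(1, 1, 1), normalize = FALSE)
  tm2 <- solve_eikonal(st2, cbind(1, 3, 3))
  expect_equal(tm2$T[, 3, 3], 2 * (0:10), tolerance = 1e-12)
  # anisotropic spacing enters per axis
  st3 <- image_stack(array(1, c(5, 5, 5)), c(1, 2, 3), normalize = FALSE)
  tm3 <- solve_eikonal(st3, cbind(3, 3, 3))
  expect_equal(tm3$T[5, 3, 3], 2, tolerance = 1e-12)
  expect_equal(tm3$T[3, 5, 3], 4, tolerance = 1e-12)
  expect_equal(tm3$T[3, 3, 5], 6, tolerance = 1e-12)
})

test_that("solver errors on bad boundaries and treats I = 0 as a barrier", {
  st <- image_stack(array(1, c(5, 5, 3)), c(1, 1, 1), normalize = FALSE)
  expect_error(solve_eikonal(st, matrix(integer(0), 0, 3)), "nonempty")
  v <- array(1, c(5, 5, 3)); v[3, 3, 2] <- 0
  stb <- image_stack(v, c(1, 1, 1), normalize = FALSE)
  expect_error(solve_eikonal(stb, cbind(3, 3, 2)), "zero intensity")
  # a zero-intensity wall is never accepted
  v2 <- array(1, c(7, 5, 3)); v2[4, , ] <- 0
  stw <- image_stack(v2, c(1, 1, 1), normalize = FALSE)
  tmw <- solve_eikonal(stw, cbind(1, 3, 2))
  expect_true(all(!is.finite(tmw$T[4:7, , ])))
  expect_true(all(tmw$state[4:7, , ] == 0))
})

test_that("solver matches the fixed-point oracle on random anisotropic grids", {
  set.seed(101)
  for (rep in 1:6) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(2:4, 1))
    st <- image_stack(array(runif(prod(d), 0.2, 1), d),
                      c(1, runif(1, 0.8, 1.5), runif(1, 1.5, 2.5)),
                      normalize = FALSE)
    b <- cbind(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    tm <- solve_eikonal(st, b)
    To <- eikonal_fixpoint(st, b)
    expect_lt(max(abs(tm$T - To)), 1e-6)
  }
})

test_that("uniformly scaling intensity by c scales arrival times by 1/c", {
  set.seed(7)
  d <- c(6, 5, 3)
  v <- array(runif(prod(d), 0.2, 0.5), d)
  st <- image_stack(v, c(1, 1, 1), normalize = FALSE)
  st2 <- image_stack(2 * v, c(1, 1, 1), normalize = FALSE)
  tm <- solve_eikonal(st, cbind(2, 2, 2))
  tm2 <- solve_eikonal(st2, cbind(2, 2, 2))
  expect_equal(tm2$T, tm$T / 2, tolerance = 1e-9)
})

test_that("march halts at D_max with the farthest point on the structure", {
  out <- render_stack(straight_tube_spec(length = 60, seed = 3))
  st <- out$stack
  seed <- cbind(39L, 9L, 9L)  # voxel on the centerline, mid-tube
  tm <- march_to_distance(st, seed, dmax = 15)
  expect_true(tm$halted)
  expect_false(tm$exhausted)
  far <- tm$farthest
  dist_phys <- sqrt(sum((voxel_to_phys(st, far) -
                           voxel_to_phys(st, seed))^2))
  expect_lte(dist_phys, 15)
  expect_gte(dist_phys, 14)  # within 1 voxel of the travel limit
  # oracle: farthest accepted voxel from a full solve + distance scan lies
  # on the tube (centerline within 1.5 voxels)
  expect_lte(sqrt(sum((voxel_to_phys(st, far)[2:3] - c(8, 8))^2)), 1.5)
})

test_that("an isolated blob exhausts the front before D_max", {
  v <- array(0, c(21, 21, 9))
  ctr <- c(11, 11, 5)
  for (i in 1:21) for (j in 1:21) for (k in 1:9) {
    if (sqrt(sum((c(i, j, k) - ctr)^2)) <= 3) v[i, j, k] <- 0.9
  }
  st <- image_stack(v, c(1, 1, 1), normalize = FALSE)
  tm <- march_to_distance(st, rbind(ctr), dmax = 15)
  expect_true(tm$exhausted)
  expect_false(tm$halted)
  expect_lte(tm$farthest_dist, 3.5)
})

test_that("front labels partition accepted voxels and collisions touch two fronts", {
  out <- render_stack(straight_tube_spec(length = 40, seed = 9))
  st <- out$stack
  seeds <- rbind(c(13L, 9L, 9L), c(43L, 9L, 9L))
  tm <- march_to_distance(st, seeds, labels = c(1L, 2L), dmax = 20)
  acc <- tm$state == 2L
  expect_true(all(tm$label[acc] %in% c(1L, 2L)))
  expect_true(all(tm$label[!acc] == 0L))
  expect_gt(nrow(tm$collisions), 0)
  # first collision voxel is adjacent to accepted voxels of both labels
  cv <- as.integer(tm$collisions[1, c("i", "j", "k")])
  d <- dim(tm$T)
  nb <- as.matrix(expand.grid(
    i = max(1, cv[1] - 1):min(d[1], cv[1] + 1),
    j = max(1, cv[2] - 1):min(d[2], cv[2] + 1),
    k = max(1, cv[3] - 1):min(d[3], cv[3] + 1)))
  labs <- tm$label[nb][tm$state[nb] == 2L]
  expect_setequal(unique(labs), c(1L, 2L))
})

test_that("gradient descent yields straight, strictly decreasing chains", {
  st <- image_stack(array(1, c(15, 7, 7)), c(1, 1, 1), normalize = FALSE)
  tm <- solve_eikonal(st, cbind(1, 4, 4))
  chain <- gradient_descent_path(tm, c(11, 4, 4))
  expect_equal(nrow(chain), 11)
  expect_true(all(chain[, 2] == 4) && all(chain[, 3] == 4))
  expect_equal(chain[11, ], c(1L, 4L, 4L), ignore_attr = TRUE)
  # random grid: T strictly decreases along the chain and ends at the seed
  set.seed(12)
  d <- c(5, 5, 3)
  str <- image_stack(array(runif(prod(d), 0.2, 1), d), c(1, 1, 1),
                     normalize = FALSE)
  tmr <- solve_eikonal(str, cbind(2, 2, 1))
  ch <- gradient_descent_path(tmr, c(5, 5, 3))
  tv <- tmr$T[ch]
  expect_true(all(diff(tv) < 0))
  expect_equal(ch[nrow(ch), ], c(2L, 2L, 1L), ignore_attr = TRUE)
  # starting on the boundary gives a single-voxel chain
  expect_equal(nrow(gradient_descent_path(tmr, c(2, 2, 1))), 1)
  # a start the front never reached (behind a zero-intensity wall) errors
  vw <- array(1, c(7, 5, 3)); vw[4, , ] <- 0
  stw <- image_stack(vw, c(1, 1, 1), normalize = FALSE)
  tmw <- solve_eikonal(stw, cbind(1, 3, 2))
  expect_error(gradient_descent_path(tmw, c(6, 3, 2)), "not accepted")
})

test_that("initial trace covers a clean tube and recalls >= 95% of its length", {
  out <- render_stack(straight_tube_spec(length = 60, seed = 3))
  tr <- grow_initial_trace(out$stack, generate_seeds(out$stack))
  rep <- compare_report(tr, out$truth, stack = out$stack, prefilter = FALSE,
                        h = 2)
  recall <- 1 - rep$mes$fn_length / rep$mes$gold_length
  expect_gte(recall, 0.95)
  deg <- trace_degree(tr)
  expect_equal(sum(deg >= 3), 0)
})

test_that("a single seed traces the whole tube via march-descend cycles", {
  out <- render_stack(straight_tube_spec(length = 60, seed = 6))
  tr <- grow_initial_trace(out$stack, cbind(39L, 9L, 9L))
  rep <- compare_report(tr, out$truth, stack = out$stack, prefilter = FALSE,
                        h = 2)
  expect_gte(1 - rep$mes$fn_length / rep$mes$gold_length, 0.95)
})

test_that("a bifurcating tube is traced with the correct topology", {
  out <- render_stack(y_tube_spec(seed = 5))
  st <- out$stack
  tr <- grow_initial_trace(st, generate_seeds(st))
  opt <- optimize_trace(tr, st, fitness_params(max_iter = 40))
  clean <- prefilter_trace(opt, st)
  deg <- trace_degree(clean)
  expect_equal(sum(deg >= 3), 1)
  expect_equal(sum(deg == 1), 3)
})

test_that("tubes separated by a dark gap wider than D_max stay separate", {
  tubes <- list(
    list(path = rbind(c(5, 10, 4), c(55, 10, 4)), sigma = 1.2,
         amplitude = 0.9),
    list(path = rbind(c(5, 30, 4), c(55, 30, 4)), sigma = 1.2,
         amplitude = 0.9))
  out <- render_stack(synth_spec(c(60, 40, 9), tubes = tubes,
                                 background = 0, noise_sd = 0, seed = 1))
  tr <- grow_initial_trace(out$stack, generate_seeds(out$stack))
  g <- igraph::make_graph(t(tr$edges), n = nrow(tr$nodes),
                          directed = FALSE)
  expect_equal(igraph::components(g)$no, 2)
  # the same holds with dim background: creeping fronts collide, but the
  # dim join is rejected by the intensity rule
  out2 <- render_stack(synth_spec(c(60, 40, 9), tubes = tubes,
                                  background = 0.05, noise_sd = 0.01,
                                  seed = 2))
  tr2 <- grow_initial_trace(out2$stack, generate_seeds(out2$stack))
  g2 <- igraph::make_graph(t(tr2$edges), n = nrow(tr2$nodes),
                           directed = FALSE)
  expect_equal(igraph::components(g2)$no, 2)
})

test_that("two seeds on one tube are joined through a front collision", {
  out <- render_stack(straight_tube_spec(length = 50, seed = 8))
  tr <- grow_initial_trace(out$stack, rbind(c(13L, 9L, 9L), c(53L, 9L, 9L)))
  g <- igraph::make_graph(t(tr$edges), n = nrow(tr$nodes),
                          directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})
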