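# independent projected-gradient reference for the SVM dual (small steps,
# many iterations; shares no code with the coordinate-ascent solver)
svm_reference <- function(deltas, C, N = ncol(deltas), iters = 20000,
                          lr = NULL) {
  m <- nrow(deltas)
  K <- deltas %*% t(deltas)
  if (is.null(lr)) lr <- 0.9 * N * m^2 / max(sum(abs(K)), 1e-12)
  a <- numeric(m)
  for (t in seq_len(iters)) {
    g <- 1 / m - as.numeric(K %*% a) / (N * m^2)
    a <- pmin(pmax(a + lr * g, 0), C)
  }
  list(alpha = a, w = as.numeric(t(deltas) %*% a) / m)
}

test_that("the sign-constrained perceptron learns a single example", {
  dx <- matrix(c(1, rep(0, 8)), 1, 9)
  st <- train_perceptron(dx, classifier_state(rng_seed = 1))
  expect_false(st$non_separable)
  expect_gte(st$w[1], 1)
  expect_gte(sum(st$w * dx) / 9, st$kappa / 9)
})

test_that("sign constraints are enforced and conflicts flagged non-separable", {
  # only satisfiable with w1 < 0, but g1 = +1: must flag non-separable
  dx <- matrix(c(-1, rep(0, 8)), 1, 9)
  st <- train_perceptron(dx, classifier_state(rng_seed = 1),
                         max_updates = 2000)
  expect_true(st$non_separable)
  expect_true(all(st$w * st$g >= 0))
  # property: w respects g after training on arbitrary random data
  set.seed(33)
  for (rep in 1:5) {
    dxr <- matrix(rnorm(30 * 9), 30, 9)
    str <- train_perceptron(dxr, classifier_state(rng_seed = rep),
                            max_updates = 500)
    expect_true(all(str$w * str$g >= 0))
  }
})

test_that("separable pools are learned to zero training error", {
  set.seed(44)
  w0 <- abs(rnorm(9)) + 0.2
  dx <- matrix(rnorm(50 * 9), 50, 9)
  marg <- as.numeric(dx %*% w0)
  # flip each example so the planted vector separates with margin >= 1
  dx <- dx * sign(marg)
  short <- abs(marg) < 1
  dx[short, ] <- dx[short, , drop = FALSE] +
    outer((1 - abs(marg[short])) / sum(w0^2), w0)
  st <- train_perceptron(dx, classifier_state(g = rep(0, 9),
                                              w = rep(0, 9), rng_seed = 9))
  expect_false(st$non_separable)
  expect_true(all(dx %*% st$w > 0))
})

test_that("SVM dual: closed form in one variable, reference agreement, box behavior", {
  # single example, large C: stationary alpha = N * m / |dx|^2, w along dx
  dx <- matrix(c(2, 1, rep(0, 7)), 1, 9)
  st <- train_svm(dx, classifier_state())
  a <- attr(st, "alpha")
  expect_equal(a, 9 / sum(dx^2), tolerance = 1e-6)
  expect_equal(st$w, as.numeric(a * dx), tolerance = 1e-8)
  expect_lt(attr(st, "kkt_residual"), 1e-6)

  # toy separable set agrees with an independent projected-gradient solver
  set.seed(5)
  w0 <- abs(rnorm(9)) + 0.5
  dxm <- matrix(rnorm(8 * 9), 8, 9)
  dxm <- dxm * sign(as.numeric(dxm %*% w0))
  st2 <- train_svm(dxm, classifier_state())
  ref <- svm_reference(dxm, C = 2^20)
  expect_equal(st2$w, ref$w, tolerance = 1e-3)
  expect_true(all(dxm %*% st2$w > 0))
  # dual objective at the solver's alpha is not below the reference's
  obj <- function(a) sum(a) / 8 -
    sum((dxm %*% t(dxm)) * outer(a, a)) / (2 * 9 * 64)
  expect_gte(obj(attr(st2, "alpha")), obj(ref$alpha) - 1e-8)

  # doubling C with an inactive box leaves w unchanged
  st3 <- train_svm(dxm, classifier_state(C = 2^21))
  expect_equal(st3$w, st2$w, tolerance = 1e-4)
})

test_that("confidence is a softmax over scenario scores and order-invariant in T", {
  expect_equal(confidence(0.7), 1)
  expect_equal(confidence(c(1, 1)), 0.5)
  expect_equal(confidence(c(0, 10, 10)), 1 / (1 + 2 * exp(-10)),
               tolerance = 1e-12)
  expect_error(confidence(numeric(0)), "empty")
  # T changes the spread; within a cluster the ordering of scenario
  # probabilities is exactly T-invariant (softmax is monotone in score)
  set.seed(6)
  for (T in c(0.5, 1, 2)) {
    s <- rnorm(5)
    p <- exp(-(s - min(s)) / T); p <- p / sum(p)
    expect_equal(order(p, decreasing = TRUE), order(s))
  }
})

test_that("isotropic planted deltas are recovered in direction by both learners", {
  set.seed(11)
  w_star <- planted_w()
  w_star <- w_star / sqrt(sum(w_star^2))
  dx <- matrix(rnorm(500 * 9), 500, 9)
  marg <- as.numeric(dx %*% w_star)
  dx <- dx * sign(marg)
  dx <- dx[abs(marg) > 0.1, ]
  cosine <- function(w) sum(w * w_star) / sqrt(sum(w^2))
  sp <- train_perceptron(dx, classifier_state(g = rep(0, 9), w = rep(0, 9),
                                              rng_seed = 2))
  sv <- train_svm(dx, classifier_state(g = rep(0, 9)))
  expect_gte(cosine(sp$w), 0.9)
  expect_gte(cosine(sv$w), 0.9)
})

test_that("active learning beats random on planted clusters; budget 0 is a no-op", {
  pool <- planted_clusters(120, planted_w(), seed = 17)
  orc <- function(cl) cl$label
  st0 <- classifier_state(rng_seed = 3)
  none <- active_learning_loop(pool, orc, budget = 0, state = st0)
  expect_equal(none$state$w, st0$w)
  res <- active_learning_loop(pool, orc, budget = 30, batch = 5,
                              state = st0)
  expect_lte(tail(res$history$error, 1), 0.05)
  # declining oracle marks clusters skipped, never queried again
  dec <- function(cl) NA_integer_
  skip <- active_learning_loop(pool[1:10], dec, budget = 30, batch = 2,
                               state = st0)
  expect_length(skip$queried, 0)
})

test_that("leave-one-out cross-validation scores cluster-level errors", {
  pool <- planted_clusters(12, planted_w(), seed = 23)
  err <- loocv(pool, classifier_state(rng_seed = 4))
  expect_lte(err, 0.25)
  # random labels over the scenario lists: high leave-one-out error
  set.seed(71)
  rnd <- planted_clusters(15, planted_w(), seed = 29)
  rnd <- lapply(rnd, function(cl) {
    cl$label <- sample.int(length(cl$scenarios), 1)
    cl
  })
  err_rnd <- loocv(rnd, classifier_state(rng_seed = 4), max_updates = 3000)
  expect_gte(err_rnd, 0.5)
  expect_error(loocv(rnd[1], classifier_state()), "at least 2")
})

test_that("trained perceptron and SVM agree on nearly all planted clusters", {
  pool <- planted_clusters(150, planted_w(), seed = 37)
  td <- neuritrace:::gather_deltas(pool[1:50])
  sp <- train_perceptron(td$deltas, classifier_state(rng_seed = 5),
                         Q = td$Q)
  sv <- train_svm(td$deltas, classifier_state(), Q = td$Q)
  agree <- mean(vapply(pool, function(cl)
    which.min(score_scenarios(cl, sp$w)) ==
      which.min(score_scenarios(cl, sv$w)), logical(1)))
  expect_gte(agree, 0.95)
})
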