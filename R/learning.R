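#' Linear classifier state for branch-merging decisions
#'
#' Holds the weight vector and the hyperparameters shared by the
#' sign-constrained perceptron and the cluster-weighted SVM. The sign
#' constraint vector `g` fixes the sign of selected weights: larger
#' distances, overruns, and offsets make a merger less likely (positive
#' weights), and a positive weight on the free-terminal count promotes
#' merging; all other weights are unconstrained. Scenario scores are
#' `w' x`, and by the training convention erroneous mergers score higher,
#' so the best scenario of a cluster is the argmin.
#'
#' @param N number of features (default 9).
#' @param g sign-constraint vector in `{-1, 0, 1}^N`; default
#'   `(1, 1, 1, 0, 0, 0, 0, 0, 1)`.
#' @param kappa perceptron robustness (margin analog), >= 0; default 1.
#' @param C SVM box parameter (> 0); default `2^20`.
#' @param T_conf confidence spread parameter (> 0); default 1.
#' @param w initial weight vector; default `g` (a feasible start under the
#'   sign constraints).
#' @param rng_seed optional seed used by the perceptron's example sampling.
#' @return Object of class `classifier_state`.
#' @export
classifier_state <- function(N = 9L, g = c(1, 1, 1, 0, 0, 0, 0, 0, 1),
                             kappa = 1, C = 2^20, T_conf = 1, w = NULL,
                             rng_seed = NULL) {
  stopifnot(length(g) == N, all(g %in% c(-1, 0, 1)),
            kappa >= 0, C > 0, T_conf > 0)
  if (is.null(w)) w <- as.numeric(g)
  stopifnot(length(w) == N, all(w * g >= 0))
  structure(list(w = w, g = as.numeric(g), N = as.integer(N),
                 kappa = kappa, C = C, T_conf = T_conf,
                 rng_seed = rng_seed, non_separable = FALSE),
            class = "classifier_state")
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf("<classifier_state: N = %d, kappa = %g, C = %g%s>\n w = %s\n",
              x$N, x$kappa, x$C,
              if (x$non_separable) ", non-separable" else "",
              paste(signif(x$w, 4), collapse = " ")))
  invisible(x)
}

# zero out weights violating their sign constraints
enforce_signs <- function(w, g) {
  w[w * g < 0] <- 0
  w
}

#' Train the sign-constrained perceptron
#'
#' Examples `dx` are presented asynchronously, drawn with probabilities
#' proportional to their cluster weights `Q`. An example already satisfying
#' the margin `(1/N) w' dx >= kappa / N` triggers no update; otherwise
#' `w <- w + (1/N) dx`, after which any weight violating its sign
#' constraint is set to zero. Training stops when a full deterministic pass
#' over all examples finds every margin satisfied, or flags the state
#' non-separable at the update cap.
#'
#' @param deltas m x N matrix of within-cluster feature differences
#'   (erroneous minus correct), e.g. rows of [normalize_within_cluster()].
#' @param state a [classifier_state()].
#' @param Q positive example weights (length m, default all 1).
#' @param max_updates update cap before declaring non-separability.
#' @return The updated `classifier_state` (fields `w`, `non_separable`,
#'   attribute `updates`).
#' @export
train_perceptron <- function(deltas, state = classifier_state(),
                             Q = NULL, max_updates = 100000L) {
  deltas <- rbind(deltas)
  m <- nrow(deltas)
  if (m == 0) stop("no training examples")
  stopifnot(ncol(deltas) == state$N)
  if (is.null(Q)) Q <- rep(1, m)
  stopifnot(length(Q) == m, all(Q > 0))
  if (!is.null(state$rng_seed)) set.seed(state$rng_seed)
  w <- enforce_signs(state$w, state$g)
  N <- state$N
  updates <- 0L
  state$non_separable <- FALSE
  repeat {
    # one stochastic epoch of m weighted draws
    mu <- sample.int(m, m, replace = TRUE, prob = Q)
    for (i in mu) {
      if (sum(w * deltas[i, ]) / N < state$kappa / N) {
        w <- enforce_signs(w + deltas[i, ] / N, state$g)
        updates <- updates + 1L
      }
    }
    # deterministic clean-pass convergence check
    margins <- as.numeric(deltas %*% w) / N
    if (all(margins >= state$kappa / N - 1e-12)) break
    if (updates >= max_updates) {
      state$non_separable <- TRUE
      break
    }
  }
  state$w <- w
  attr(state, "updates") <- updates
  state
}

#' Train the cluster-weighted SVM (dual coordinate ascent)
#'
#' Maximizes the dual
#' `L(a) = (1/m) sum_i a_i - 1/(2 N m^2) sum_ij (dx_i' dx_j) a_i a_j`
#' subject to the box constraints `0 <= a_i <= C Q_i` by projected
#' coordinate ascent; the box-only constraint structure (no equality
#' constraint) makes single-coordinate updates exact. The weight vector is
#' `w = (1/m) sum_i a_i dx_i`.
#'
#' @inheritParams train_perceptron
#' @param tol KKT tolerance on the scaled dual gradient (default 1e-6).
#' @param max_sweeps cap on full coordinate sweeps.
#' @return The updated `classifier_state` with attributes `alpha` and
#'   `kkt_residual`.
#' @export
train_svm <- function(deltas, state = classifier_state(), Q = NULL,
                      tol = 1e-6, max_sweeps = 10000L) {
  deltas <- rbind(deltas)
  m <- nrow(deltas)
  if (m == 0) stop("no training examples")
  stopifnot(ncol(deltas) == state$N)
  if (is.null(Q)) Q <- rep(1, m)
  N <- state$N
  K <- deltas %*% t(deltas)
  kd <- diag(K)
  upper <- state$C * Q
  alpha <- numeric(m)
  s <- numeric(m)               # s_j = sum_i K_ji alpha_i
  target <- N * m               # stationarity: s_i = N m
  resid <- Inf
  for (sweep in seq_len(max_sweeps)) {
    for (i in seq_len(m)) {
      if (kd[i] <= 0) next
      anew <- alpha[i] + (target - s[i]) / kd[i]
      anew <- min(max(anew, 0), upper[i])
      da <- anew - alpha[i]
      if (da != 0) {
        s <- s + da * K[, i]
        alpha[i] <- anew
      }
    }
    ghat <- (target - s) / target    # scaled dual gradient
    viol <- numeric(m)
    interior <- alpha > 0 & alpha < upper
    viol[interior] <- abs(ghat[interior])
    at0 <- alpha <= 0
    viol[at0] <- pmax(ghat[at0], 0)
    atC <- alpha >= upper
    viol[atC] <- pmax(-ghat[atC], 0)
    resid <- max(viol)
    if (resid < tol) break
  }
  state$w <- as.numeric(t(deltas) %*% alpha) / m
  attr(state, "alpha") <- alpha
  attr(state, "kkt_residual") <- resid
  state
}

#' Score a cluster's scenarios
#'
#' @param cluster a `merge_cluster` with features computed.
#' @param w weight vector.
#' @return Numeric scores `w' x` per scenario; the best scenario is the
#'   argmin (erroneous mergers score higher by the training convention).
#' @export
score_scenarios <- function(cluster, w) {
  if (is.null(cluster$features)) stop("cluster features not computed")
  as.numeric(cluster$features %*% w)
}

#' Confidence of the best merging scenario of a cluster
#'
#' `exp(-s_best / T) / sum_i exp(-s_i / T)` over all scenario scores
#' `s_i = w' x_i` of the cluster, where the best scenario is the argmin.
#' Values lie in (0, 1]; `T_conf` changes the spread of confidences but
#' never the ordering of scenario probabilities within a cluster.
#'
#' @param scores numeric vector of scenario scores (nonempty).
#' @param T_conf temperature (> 0).
#' @return Confidence value in (0, 1].
#' @export
confidence <- function(scores, T_conf = 1) {
  if (length(scores) == 0) stop("empty scenario list")
  z <- -(scores - min(scores)) / T_conf
  e <- exp(z)
  max(e) / sum(e)
}

# collect deltas + weights from labeled clusters
gather_deltas <- function(clusters) {
  dx <- list(); qw <- list()
  for (cl in clusters) {
    if (is.na(cl$label)) next
    d <- normalize_within_cluster(cl)
    dx[[length(dx) + 1L]] <- d
    qw[[length(qw) + 1L]] <- rep(cl$weight, nrow(d))
  }
  if (length(dx) == 0) return(NULL)
  list(deltas = do.call(rbind, dx), Q = unlist(qw))
}

#' Pool-based active learning of branch merging
#'
#' Repeats until the label budget is exhausted: score every unlabeled
#' cluster's confidence under the current weights, query the `batch`
#' lowest-confidence clusters via the labeling oracle, retrain on all
#' labels, and record the generalization error on the still-unlabeled part
#' of the pool (clusters whose argmin-scored scenario differs from their
#' true label, when truth is available). An oracle that declines a query
#' (returns `NA`) marks the cluster as skipped; it is never re-queried and
#' never used for training.
#'
#' @param pool list of `merge_cluster`s with features computed. For error
#'   tracking, clusters may carry the hidden truth in `$label` (it is only
#'   revealed through the oracle).
#' @param oracle `function(cluster)` returning the correct scenario index
#'   or `NA` to decline.
#' @param budget total number of label queries.
#' @param batch queries per round (default 1).
#' @param state initial [classifier_state()].
#' @param trainer `"perceptron"` or `"svm"`.
#' @return List with the final `state`, the labeled cluster indices
#'   `queried`, and `history` (data.frame: `n_labeled`, `error`).
#' @export
active_learning_loop <- function(pool, oracle, budget, batch = 1L,
                                 state = classifier_state(),
                                 trainer = c("perceptron", "svm")) {
  trainer <- match.arg(trainer)
  truth <- vapply(pool, function(cl) as.integer(cl$label), integer(1))
  labels <- rep(NA_integer_, length(pool))
  skipped <- logical(length(pool))
  history <- list()
  queried <- integer(0)
  spent <- 0L
  eval_error <- function(w) {
    idx <- which(is.na(labels) & !is.na(truth))
    if (length(idx) == 0) return(NA_real_)
    wrong <- vapply(idx, function(i)
      which.min(score_scenarios(pool[[i]], w)) != truth[i], logical(1))
    mean(wrong)
  }
  while (spent < budget) {
    open <- which(is.na(labels) & !skipped)
    if (length(open) == 0) break
    conf <- vapply(open, function(i)
      confidence(score_scenarios(pool[[i]], state$w), state$T_conf),
      numeric(1))
    take <- open[order(conf)][seq_len(min(batch, length(open),
                                          budget - spent))]
    for (i in take) {
      lab <- oracle(pool[[i]])
      spent <- spent + 1L
      if (is.na(lab)) { skipped[i] <- TRUE; next }
      labels[i] <- lab
      queried <- c(queried, i)
    }
    train_pool <- lapply(which(!is.na(labels)), function(i) {
      cl <- pool[[i]]; cl$label <- labels[i]; cl
    })
    td <- gather_deltas(train_pool)
    if (!is.null(td)) {
      state <- if (trainer == "perceptron")
        train_perceptron(td$deltas, state, Q = td$Q)
      else train_svm(td$deltas, state, Q = td$Q)
    }
    history[[length(history) + 1L]] <-
      data.frame(n_labeled = sum(!is.na(labels)),
                 error = eval_error(state$w))
  }
  list(state = state, queried = queried,
       history = do.call(rbind, history))
}

#' Leave-one-out cross-validation over labeled clusters
#'
#' Each labeled cluster is held out once; the classifier is trained on the
#' deltas of the others and the held-out cluster counts as an error if its
#' argmin-scored scenario differs from its label. Errors are counted at the
#' cluster level (the whole partition must match).
#'
#' @param clusters list of labeled `merge_cluster`s with features computed
#'   (at least 2).
#' @param state initial [classifier_state()].
#' @param trainer `"perceptron"` or `"svm"`.
#' @param ... further arguments passed to the trainer (e.g. `max_updates`).
#' @return Error rate in `[0, 1]`.
#' @export
loocv <- function(clusters, state = classifier_state(),
                  trainer = c("perceptron", "svm"), ...) {
  trainer <- match.arg(trainer)
  labeled <- Filter(function(cl) !is.na(cl$label), clusters)
  if (length(labeled) < 2) stop("need at least 2 labeled clusters")
  errs <- logical(length(labeled))
  for (i in seq_along(labeled)) {
    td <- gather_deltas(labeled[-i])
    st <- if (trainer == "perceptron")
      train_perceptron(td$deltas, state, Q = td$Q, ...)
    else train_svm(td$deltas, state, Q = td$Q, ...)
    pred <- which.min(score_scenarios(labeled[[i]], st$w))
    errs[i] <- pred != labeled[[i]]$label
  }
  mean(errs)
}
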