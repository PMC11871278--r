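rand_problem <- function(n, M, seed, s_active = 0, amp = 2, noise = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * M), n, M)
  colnames(X) <- feature_labels("Delta", eeg_feature_names(),
                                paste0("ch", seq_len(ceiling(M / 5))))[1:M]
  w <- numeric(M)
  if (s_active > 0) {
    idx <- seq(1, M, length.out = s_active)
    w[idx] <- amp * c(1, -1)[1 + (seq_len(s_active) %% 2)]
  }
  y <- as.numeric(X %*% w + rnorm(n, sd = noise))
  list(problem = list(X = X, y = y, feature_labels = colnames(X)),
       w_true = w)
}

test_that("design rows are subject sums stacked over videos", {
  k <- 6
  labs <- feature_labels("Delta", "energy", paste0("ch", 1:k))
  mk_tensor <- function(n_subj, T, scale = 1) {
    a <- array(rnorm(n_subj * T * k), c(n_subj, T, k),
               dimnames = list(paste0("s", 1:n_subj), NULL, labs))
    a * scale
  }
  set.seed(51)
  t1 <- mk_tensor(1, 4)
  p1 <- build_design(list(t1), list(runif(4)))
  expect_equal(unname(p1$X), unname(t1[1, , ]))        # K = 1: identity
  t2 <- array(NA_real_, c(2, 4, k), dimnames = list(c("a", "b"), NULL, labs))
  t2[1, , ] <- t1[1, , ]; t2[2, , ] <- t1[1, , ]
  p2 <- build_design(list(t2), list(runif(4)))
  expect_equal(unname(p2$X), unname(2 * t1[1, , ]))    # duplicated subject
  p3 <- build_design(list(t1, t1), list(runif(4), runif(4)))
  expect_equal(nrow(p3$X), 8)                          # videos stacked
  expect_equal(p3$video, rep(1:2, each = 4))
  expect_error(build_design(list(t1), list(runif(5))), "differ")
})

test_that("the penalty shrinks exactly to zero at the critical lambda", {
  rp <- rand_problem(40, 10, seed = 52)
  lam_max <- max(abs(crossprod(rp$problem$X, rp$problem$y))) / 40
  expect_true(all(lasso_fit(rp$problem, lam_max * 1.001) == 0))
  expect_true(any(lasso_fit(rp$problem, lam_max * 0.8) != 0))
})

test_that("lambda = 0 recovers least squares on a square full-rank system", {
  set.seed(53)
  X <- matrix(rnorm(64), 8, 8)
  y <- rnorm(8)
  w <- lasso_fit(list(X = X, y = y), 0)
  expect_equal(as.numeric(w), as.numeric(solve(X, y)), tolerance = 1e-8)
})

test_that("solutions satisfy the subgradient optimality conditions", {
  rp <- rand_problem(20, 10, seed = 54, s_active = 3)
  lam <- 0.1
  w <- lasso_fit(rp$problem, lam)
  g <- as.numeric(crossprod(rp$problem$X,
                            rp$problem$X %*% w - rp$problem$y)) / 20
  act <- which(w != 0)
  tol <- 1e-6 * max(1, max(abs(g)))
  if (length(act)) expect_lt(max(abs(g[act] + lam * sign(w[act]))), tol)
  if (length(act) < length(w))
    expect_lte(max(abs(g[-act])), lam + tol)
  # fitted objective never exceeds the all-zero objective
  obj <- function(w) sum((rp$problem$X %*% w - rp$problem$y)^2) / 40 +
    lam * sum(abs(w))
  expect_lte(obj(w), obj(numeric(10)))
})

test_that("sparsity is non-increasing along the penalty grid", {
  rp <- rand_problem(60, 25, seed = 55, s_active = 5)
  path <- lasso_selection_path(rp$problem, c(0.1, 1, 10, 100))
  expect_true(all(diff(path$count) <= 0))
  expect_equal(path$percent, 100 * path$count / 25)
})

test_that("a sparse ground truth is recovered exactly", {
  rp <- rand_problem(200, 50, seed = 56, s_active = 5, amp = 2.5,
                     noise = 0.05)
  sel <- selected_features(lasso_fit(rp$problem, 0.05))
  truth <- rp$problem$feature_labels[rp$w_true != 0]
  expect_setequal(sel$labels, truth)
  expect_equal(sel$count, 5)
  expect_equal(sel$percent, 10)
  # empty selection reports cleanly
  none <- selected_features(setNames(numeric(3),
                                     feature_labels("Delta", "energy",
                                                    paste0("c", 1:3))))
  expect_equal(none$count, 0)
  expect_equal(none$percent, 0)
})
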