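test_that("smoothing preserves constants, identity and the boxcar form", {
  x <- runif(12)
  expect_equal(smooth_score(x, smoother("none")), x)
  expect_equal(smooth_score(rep(0.4, 9), smoother("gaussian", sigma = 2)),
               rep(0.4, 9))
  expect_equal(smooth_score(rep(0.4, 9), smoother("mean", width = 3)),
               rep(0.4, 9))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(smooth_score(imp, smoother("mean", width = 3)),
               c(0, 0, 1, 1, 1, 0, 0) / 3)
  # missing values are interpolated before smoothing
  y <- c(0.2, NA, 0.4, 0.5)
  expect_false(anyNA(smooth_score(y, smoother("gaussian", sigma = 1))))
  expect_error(smoother("mean", width = 4), "odd")
})

test_that("segment matching follows each criterion's definition", {
  inc <- c(0.1, 0.2, 0.3, 0.4)
  expect_true(segment_match(inc, inc * 2, "spearman", 0.9))
  expect_false(segment_match(inc, rev(inc), "spearman", 0))
  # hand-computed ranks: d^2 = (1,0,1,0,0) -> rho_s = 1 - 6*2/(5*24) = 0.9
  sv <- c(0.1, 0.4, 0.2, 0.8, 0.6)
  sb <- c(0.2, 0.5, 0.1, 0.9, 0.7)
  expect_equal(cor(sv, sb, method = "spearman"), 0.9)
  expect_true(segment_match(sv, sb, "spearman", 0.85))
  expect_false(segment_match(sv, sb, "spearman", 0.95))
  # constant segment: undefined rank correlation counts as non-match
  flat <- segment_match(rep(0.5, 4), inc, "spearman", 0)
  expect_false(isTRUE(flat))
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_true(segment_match(c(0.1, 0.2), c(0.15, 0.25), "abs_diff", 0.06))
  expect_false(segment_match(c(0.1, 0.2), c(0.15, 0.3), "abs_diff", 0.06))
  expect_true(segment_match(c(1, 2, 1), c(5, 9, 2), "sign"))
  expect_false(segment_match(c(1, 2, 1), c(5, 9, 12), "sign"))
})

test_that("local rho covers matched positions for correlation criteria", {
  s <- sort(runif(10))
  expect_equal(local_rho(s, s, l = 4, "spearman", 0.9)$rho, 1)
  expect_equal(local_rho(s, rev(s), l = 4, "spearman", 0)$rho, 0)
  expect_error(local_rho(s, s, l = 11), "\\[1, T\\]")
})

test_that("a single matching window marks exactly its l positions", {
  # T = 8, l = 3, threshold just under 1: only perfectly concordant
  # windows match. Window at positions 4-6 is the only one.
  s_v <- c(0.9, 0.1, 0.9, 0.2, 0.5, 0.8, 0.1, 0.9)
  s_b <- c(0.1, 0.9, 0.1, 0.3, 0.4, 0.9, 0.8, 0.1)
  # independent brute-force window scan
  win <- vapply(1:6, function(t)
    cor(s_v[t:(t + 2)], s_b[t:(t + 2)], method = "spearman") > 0.99,
    logical(1))
  expect_equal(which(win), 4L)
  res <- local_rho(s_v, s_b, l = 3, "spearman", 0.99)
  expect_equal(res$window_match, win)
  expect_equal(which(res$match_mask), 4:6)
  expect_equal(res$rho, 3 / 8)
  expect_equal(res$M, 8L)
  # rho is recomputable from the mask
  expect_equal(res$rho, mean(res$match_mask))
})

test_that("element-wise criteria count windows, not positions", {
  s_v <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  s_b <- s_v + c(0.01, 0.01, 0.2, 0.01, 0.01)
  res <- local_rho(s_v, s_b, l = 2, "abs_diff", 0.05)
  expect_equal(res$M, 4L)                    # T - l + 1 windows
  expect_equal(res$window_match, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$rho, 2 / 4)
})

test_that("rho falls as the threshold rises and generally as l grows", {
  # coupling that holds locally but wanders in sign globally: short windows
  # match often, long windows straddle the sign flips and fail
  set.seed(23)
  s_v <- smooth_score(runif(60), smoother("gaussian", 1.5))
  env <- sin(2 * pi * 2.5 * seq_len(60) / 60)
  s_b <- smooth_score(env * scale(s_v)[, 1] + rnorm(60, sd = 0.4),
                      smoother("gaussian", 1.5))
  rho_th <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(th)
    local_rho(s_v, s_b, l = 5, "spearman", th)$rho, numeric(1))
  expect_true(all(diff(rho_th) <= 1e-12))
  rho_l <- vapply(c(5, 10, 15, 25), function(l)
    local_rho(s_v, s_b, l = l, "spearman", 0.6)$rho, numeric(1))
  expect_lt(rho_l[4], rho_l[1])
  expect_lt(mean(diff(rho_l)), 0)
})
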