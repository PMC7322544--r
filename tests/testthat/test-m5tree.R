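test_that("standard-deviation reduction matches its closed form", {
  expect_equal(sdr(c(0, 0, 10, 10), c(0, 0), c(10, 10)), 5)
  expect_equal(sdr(rep(3, 8), rep(3, 5), rep(3, 3)), 0)
  expect_identical(sdr(1:4, integer(0), 1:4), -Inf)
  expect_error(sdr(1:4, 1:3, 1:3), "partition")
})

# brute-force oracle: evaluate sdr() at every feature/midpoint split
oracle_best_split <- function(x, y) {
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[[j]]))
    if (length(vals) < 2) next
    for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
      sel <- x[[j]] <= thr
      red <- sdr(y, y[sel], y[!sel])
      if (is.null(best) || red > best$sdr + 1e-12) {
        best <- list(feature = j, threshold = thr, sdr = red)
      }
    }
  }
  best
}

test_that("split search equals exhaustive enumeration on small sets", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(5:12, 1)
    x <- data.frame(a = round(runif(n), 2), b = round(rnorm(n), 2))
    y <- rnorm(n)
    got <- qtsilico:::best_split(x, y, min_size = 1L)
    want <- oracle_best_split(x, y)
    expect_equal(got$feature, want$feature, label = paste("seed", s))
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sdr, want$sdr, tolerance = 1e-6)
  }
})

test_that("degenerate targets give single-leaf constant trees", {
  x <- data.frame(a = rnorm(10))
  fit <- m5tree(x, rep(2, 10))
  expect_equal(qtsilico:::n_leaves(fit$root), 1L)
  expect_equal(predict(fit, x), rep(2, 10))
})

test_that("a noiseless step function is recovered exactly", {
  set.seed(1)
  x <- data.frame(a = c(runif(10, -1, -0.1), runif(10, 0.1, 1)))
  y <- rep(c(1, 2), each = 10)
  fit <- m5tree(x, y, m5_control(smoothing_k = 0))
  expect_equal(fit$root$type, "split")
  expect_equal(fit$root$split_feature, "a")
  expect_lt(abs(fit$root$split_value), 0.11)
  expect_equal(predict(fit, x), y, tolerance = 1e-9)
})

test_that("a noiseless linear target collapses to one exact leaf", {
  x <- data.frame(x1 = seq(-2, 2, length.out = 25))
  y <- 3 * x$x1 + 2
  fit <- m5tree(x, y)
  expect_equal(qtsilico:::n_leaves(fit$root), 1L)
  expect_equal(unname(fit$root$model$coef["x1"]), 3, tolerance = 1e-9)
  expect_equal(fit$root$model$intercept, 2, tolerance = 1e-9)
})

test_that("pruning collapses structureless trees and keeps real splits", {
  set.seed(7)
  leaves <- vapply(1:40, function(i) {
    x <- data.frame(a = rnorm(40), b = rnorm(40))
    y <- rnorm(40)
    qtsilico:::n_leaves(m5tree(x, y)$root)
  }, numeric(1))
  expect_gte(mean(leaves == 1), 0.95)
  # strong two-regime signal: the split survives pruning
  d <- synth_tpkpd_dataset(n = 100, noise_sd = 0.05, seed = 3)
  fit <- m5tree(d$x, d$y)
  expect_equal(fit$root$type, "split")
  expect_equal(fit$root$split_feature, "herg_pic50")
  # a tree that is already a single leaf is unchanged by pruning
  x <- data.frame(a = 1:6)
  y <- c(2, 2, 2, 2.1, 2, 2)
  f1 <- m5tree(x, y, m5_control(prune = FALSE))
  f2 <- m5tree(x, y, m5_control(prune = TRUE))
  expect_equal(predict(f1, x, smoothing_k = 0), predict(f2, x, smoothing_k = 0))
})

test_that("smoothing follows the (n p + k q) / (n + k) recursion", {
  x <- data.frame(x1 = c(1, 2, 3, 10, 11, 12))
  y <- c(1, 1, 1, 5, 5, 5)
  k <- 15
  fit <- m5tree(x, y, m5_control(min_leaf = 2, smoothing_k = k))
  expect_equal(fit$root$type, "split")
  expect_equal(qtsilico:::n_leaves(fit$root), 2L)
  # leaf models are intercept-only constants
  expect_length(fit$root$left$model$coef, 0)
  expect_equal(fit$root$left$model$intercept, 1)
  # hand-computed smoothing: leaf value pulled toward the root model value
  q <- qtsilico:::model_value(fit$root$model, data.frame(x1 = 2))
  manual <- (3 * 1 + k * q) / (3 + k)
  expect_equal(predict(fit, data.frame(x1 = 2)), manual)
  # k = 0 gives the raw leaf prediction; single-leaf smoothing is identity
  expect_equal(predict(fit, data.frame(x1 = 2), smoothing_k = 0), 1)
  lin <- m5tree(data.frame(x1 = 1:12), 2 * (1:12))
  expect_equal(predict(lin, data.frame(x1 = 5)),
               predict(lin, data.frame(x1 = 5), smoothing_k = 0))
})

test_that("median imputation covers missing features at fit and predict", {
  set.seed(9)
  x <- data.frame(a = c(rnorm(20), NA, NA), b = rnorm(22))
  y <- 2 * ifelse(is.na(x$a), median(x$a, na.rm = TRUE), x$a) + rnorm(22, 0, 0.01)
  fit <- m5tree(x, y)
  p1 <- predict(fit, data.frame(a = NA_real_, b = 0))
  p2 <- predict(fit, data.frame(a = median(x$a, na.rm = TRUE), b = 0))
  expect_equal(p1, p2)
  # absent column is treated like a missing value
  p3 <- predict(fit, data.frame(b = 0))
  expect_equal(p1, p3)
})

test_that("leave-one-out equals the brute-force refit loop", {
  d <- synth_tpkpd_dataset(n = 12, noise_sd = 0.2, seed = 5)
  loo <- m5_loo(d$x, d$y)
  brute <- vapply(seq_along(d$y), function(i) {
    predict(m5tree(d$x[-i, , drop = FALSE], d$y[-i]),
            d$x[i, , drop = FALSE])
  }, numeric(1))
  expect_identical(loo, brute)
  # determinism
  expect_identical(loo, m5_loo(d$x, d$y))
  # constant target: every held-out prediction is the mean of the rest
  set.seed(3)
  xc <- data.frame(a = rnorm(6))
  yc <- rep(3.5, 6)
  looc <- m5_loo(xc, yc)
  expect_equal(looc, vapply(1:6, function(i) mean(yc[-i]), numeric(1)))
})

test_that("trees partition the training set and print readably", {
  d <- synth_tpkpd_dataset(n = 60, noise_sd = 0.1, seed = 2)
  fit <- m5tree(d$x, d$y)
  count_instances <- function(node) {
    if (node$type == "leaf") return(node$n)
    count_instances(node$left) + count_instances(node$right)
  }
  expect_equal(count_instances(fit$root), 60L)
  txt <- capture.output(print(fit))
  expect_match(txt[1], "M5 pruned model tree")
})
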