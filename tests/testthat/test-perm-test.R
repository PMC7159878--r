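test_that("correlation helper handles the standard and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_warning(out <- correlate(x, rep(2, 5)))
  expect_true(is.na(out))
  expect_error(correlate(c(1, 2, NA, 4), x[1:4]))
})

test_that("spearman matches brute-force rank correlation over all n=4 permutations", {
  x <- c(10, 20, 30, 40)
  perms <- list(c(1,2,3,4), c(2,1,3,4), c(4,3,2,1), c(3,1,4,2), c(1,4,2,3),
                c(2,4,1,3))
  for (p in perms) {
    y <- x[p]
    rx <- rank(x); ry <- rank(y)
    brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(suppressWarnings(correlate(x, y, "spearman")), brute)
  }
})

test_that("a perfect observed correlation gets the add-one minimum p-value", {
  set.seed(71)
  n <- 10
  ct <- rnorm(n, 160, 15)
  res <- permutation_corr_test(ct, ct, ssrt_beh = rep(220, n),
                               n_iter = 100, seed = 3)
  expect_equal(res$r_obs, 1)
  expect_equal(res$p, 1 / 101)
})

test_that("the p-value is monotone in the observed statistic for a fixed null", {
  set.seed(72)
  n <- 10
  ct <- rnorm(n, 160, 15)
  ssrt <- runif(n, 180, 260)
  r1 <- permutation_corr_test(ct, ct - 40 + rnorm(n, 0, 5), ssrt,
                              n_iter = 500, seed = 5)
  p_at <- function(r_obs) (1 + sum(r1$r_perm >= r_obs)) / (1 + r1$n_iter)
  expect_true(p_at(0.9) <= p_at(0.5))
  expect_true(all(r1$r_perm >= -1 & r1$r_perm <= 1))
})

test_that("results are deterministic for a fixed seed", {
  set.seed(73)
  n <- 8
  ct <- rnorm(n, 160, 15); bt <- rnorm(n, 120, 10)
  ssrt <- runif(n, 180, 260)
  a <- permutation_corr_test(ct, bt, ssrt, n_iter = 300, seed = 11)
  b <- permutation_corr_test(ct, bt, ssrt, n_iter = 300, seed = 11)
  expect_identical(a, b)
})

test_that("a lead-lag coupled cohort is detected with high power", {
  set.seed(74)
  hits <- 0
  for (r in 1:20) {
    n <- 12
    ssrt <- runif(n, 190, 250)
    ct <- rnorm(n, 160, 15)
    bt <- ct - 40 + rnorm(n, 0, 8)
    res <- permutation_corr_test(ct, bt, ssrt, burst_counts = rep(8, n),
                                 n_iter = 1000, seed = 100 + r)
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("input validation catches undefined designs", {
  expect_error(permutation_corr_test(1:3, 1:3, rep(200, 3)), "n >= 4")
  expect_error(permutation_corr_test(1:5, 1:5, c(-1, 200, 200, 200, 200)),
               "positive")
  expect_error(permutation_corr_test(rep(1, 5), 1:5, rep(200, 5)),
               "zero variance")
})
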