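test_that("partitioning is stratified, exhaustive and size-checked", {
  d <- tiny_combined(200, seed = 3)  # nA = nB = 100
  p1 <- partition_combined(d, 1, seed = 5)
  expect_length(p1$subsets, 1L)
  expect_identical(p1$subsets[[1]]$study_A$X1, d$study_A$X1)
  p5 <- partition_combined(d, 5, seed = 5)
  expect_true(all(vapply(p5$subsets, function(s) s$study_A$n, numeric(1)) == 20))
  expect_true(all(vapply(p5$subsets, function(s) s$study_B$n, numeric(1)) == 20))
  # every subset keeps the full-data missing rate
  expect_true(all(vapply(p5$subsets, `[[`, numeric(1), "missing_rate") == 0.5))
  # the union of subsets recovers the rows exactly once
  allY <- sort(unlist(lapply(p5$subsets, function(s) s$study_A$Y1)))
  expect_equal(allY, sort(d$study_A$Y1))
  expect_error(partition_combined(d, 3, seed = 1), "divisible")
})

test_that("aggregation preserves the grand mean exactly", {
  set.seed(7)
  mats <- lapply(1:4, function(j) {
    m <- matrix(rnorm(600, mean = j), 200, 3)
    colnames(m) <- c("beta1", "beta2", "delta_X1")
    m
  })
  agg <- aggregate_fits(mats)
  expect_equal(unname(agg$grand_mean),
               unname(colMeans(agg$subset_means)))
  expect_lt(max(abs(colMeans(agg$draws) - agg$grand_mean)), 1e-12)
  # J = 1 is the identity
  one <- aggregate_fits(mats[1])
  expect_equal(one$draws, mats[[1]])
})

test_that("aggregation is permutation invariant and validates inputs", {
  set.seed(8)
  mats <- lapply(1:3, function(j) {
    m <- matrix(rnorm(300, mean = j), 100, 3)
    colnames(m) <- c("beta1", "beta2", "V_Y1")
    m
  })
  a1 <- aggregate_fits(mats)
  a2 <- aggregate_fits(rev(mats))
  expect_equal(a1$grand_mean, a2$grand_mean)
  expect_equal(apply(a1$draws, 2, sort), apply(a2$draws, 2, sort))
  bad <- mats
  colnames(bad[[2]]) <- c("beta1", "beta2", "V_Y2")
  expect_error(aggregate_fits(bad), "different parameter sets")
  expect_error(aggregate_fits(mats, pars = "nope"), "unknown parameters")
})

test_that("scale correction divides the spread by sqrt(J)", {
  set.seed(9)
  mats <- lapply(1:4, function(j) {
    m <- matrix(rnorm(4000, sd = 2), 2000, 2)
    colnames(m) <- c("beta1", "beta2")
    m
  })
  raw <- aggregate_fits(mats, scale_correct = FALSE)
  cor <- aggregate_fits(mats, scale_correct = TRUE)
  expect_equal(var(cor$draws[, "beta1"]) * 4, var(raw$draws[, "beta1"]),
               tolerance = 0.02)
  expect_equal(raw$grand_mean, cor$grand_mean)
})

test_that("the 2-D KDE recovers a known density", {
  set.seed(10)
  x <- rnorm(50000); y <- rnorm(50000)
  # the argmax of a kernel estimate sits on the flat top of the Gaussian,
  # so locate the mode with a deliberately wide kernel
  k <- posterior_kde2d(x, y, n = 121, h = c(0.4, 0.4))
  peak <- which(k$z == max(k$z), arr.ind = TRUE)
  expect_lt(abs(k$x[peak[1]]), 0.1)
  expect_lt(abs(k$y[peak[2]]), 0.1)
  k <- posterior_kde2d(x, y, n = 121)
  peak <- which(k$z == max(k$z), arr.ind = TRUE)
  # normalisation by the trapezoid rule
  integral <- sum(k$z) * diff(k$x[1:2]) * diff(k$y[1:2])
  expect_equal(integral, 1, tolerance = 0.01)
  # translation equivariance: on a translated grid the density matrix is
  # identical and the mode moves with the draws
  k2 <- posterior_kde2d(x + 0.3, y + 0.3, n = 121,
                        lims = c(range(k$x) + 0.3, range(k$y) + 0.3))
  expect_equal(k2$z, k$z, tolerance = 1e-10)
  p2 <- which(k2$z == max(k2$z), arr.ind = TRUE)
  expect_equal(k2$x[p2[1]], k$x[peak[1]] + 0.3)
  expect_error(posterior_kde2d(rep(1, 100), rnorm(100)), "zero-variance")
  expect_error(posterior_kde2d(rnorm(10), rnorm(10)), "at least 50")
})

test_that("subset fits combine independently of evaluation order", {
  d <- tiny_combined(120, seed = 21)
  parts <- partition_combined(d, 2, seed = 4)
  fits <- lapply(seq_len(2), function(j) {
    bmr(parts$subsets[[j]], settings = fast_settings(seed = 100 + j))
  })
  fits_rev <- lapply(c(2L, 1L), function(j) {
    bmr(parts$subsets[[j]], settings = fast_settings(seed = 100 + j))
  })
  a <- aggregate_fits(fits)
  b <- aggregate_fits(rev(fits_rev))
  expect_equal(a$grand_mean, b$grand_mean)
})
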