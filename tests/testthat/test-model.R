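test_that("conditional means vanish when all parameters are zero", {
  lay <- tiny_layout()
  p <- structural_params(lay)
  set.seed(1)
  Z <- function(m) matrix(rbinom(10 * m, 2, 0.3), 10, m)
  d <- study_dataset("A", Z(3), Z(3), Z(2),
                     X1 = rnorm(10), X2 = rnorm(10),
                     Y1 = rnorm(10), Y2 = rnorm(10))
  mu <- conditional_means(p, d, U = rnorm(10))
  for (v in mu) expect_equal(v, rep(0, 10))
})

test_that("Study B adds its random-effect intercepts; Study A does not", {
  lay <- tiny_layout()
  p <- structural_params(lay, V = c(0.4, -0.2, 0.1, 0.3))
  Z <- function(m, n = 5) matrix(0, n, m)
  dB <- study_dataset("B", Z(3), Z(3), Z(2), Y1 = rnorm(5), Y2 = rnorm(5))
  mu <- conditional_means(p, dB, U = rep(0, 5), X1 = rep(0, 5), X2 = rep(0, 5))
  expect_equal(mu$X1, rep(0.4, 5))
  expect_equal(mu$X2, rep(-0.2, 5))
  expect_equal(mu$Y1, rep(0.1, 5))
  expect_equal(mu$Y2, rep(0.3, 5))
  dA <- study_dataset("A", Z(3), Z(3), Z(2), X1 = rep(0, 5), X2 = rep(0, 5),
                      Y1 = rnorm(5), Y2 = rnorm(5))
  muA <- conditional_means(p, dA, U = rep(0, 5))
  expect_equal(muA$X1, rep(0, 5))
})

test_that("exposure mean is the instrument dot product plus the confounder term", {
  # 15 instruments of strength 0.3 all carried by one individual with
  # dosage 1, shared block contributing nothing, delta_X1 * U = 0.5
  lay <- instrument_layout(15, 2, 3)
  p <- structural_params(lay, alpha1 = 0.3, delta = c(1, 0, 0, 0))
  d <- study_dataset("A",
                     Z1 = matrix(1, 1, 15), Z2 = matrix(0, 1, 2),
                     Z3 = matrix(2, 1, 3),
                     X1 = 0, X2 = 0, Y1 = 0, Y2 = 0)
  mu <- conditional_means(p, d, U = 0.5)
  expect_equal(mu$X1, 15 * 0.3 + 0.5)  # = 5.0
})

test_that("dimension mismatches raise shape errors", {
  p <- tiny_params()
  d <- tiny_combined(20)$study_A
  expect_error(conditional_means(p, d, U = rep(0, 3)), "length")
  p2 <- structural_params(instrument_layout(4, 3, 2))
  expect_error(conditional_means(p2, d, U = rep(0, 10)), "dimension")
})

test_that("log joint at the origin equals five standard-normal log densities", {
  lay <- instrument_layout(1, 1, 1)
  p <- structural_params(lay)  # all zero, sigmas 1
  d <- study_dataset("A", matrix(0, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                     X1 = 0, X2 = 0, Y1 = 0, Y2 = 0)
  # U plus four regression residuals, each a standard normal at zero
  expect_equal(log_joint(p, d, U = 0, include_priors = FALSE),
               5 * (-0.5 * log(2 * pi)))
})

test_that("log joint matches an independently coded per-observation sum", {
  set.seed(7)
  p <- tiny_params()
  d <- tiny_combined(12, seed = 3)$study_A
  U <- rnorm(6)
  pri <- prior_spec()
  # straightforward per-individual loop, written independently of the
  # vectorised implementation
  ref <- 0
  for (i in seq_len(6)) {
    mX1 <- sum(d$Z1[i, ] * p$alpha1) + sum(d$Z3[i, ] * p$alpha31) + 1 * U[i]
    mX2 <- sum(d$Z2[i, ] * p$alpha2) + sum(d$Z3[i, ] * p$alpha32) + 1 * U[i]
    mY1 <- 0.3 * d$X1[i] + 1 * U[i]
    mY2 <- 0.3 * d$X2[i] + 1 * U[i]
    ref <- ref + dnorm(U[i], log = TRUE) +
      dnorm(d$X1[i], mX1, 0.1, log = TRUE) +
      dnorm(d$X2[i], mX2, 0.1, log = TRUE) +
      dnorm(d$Y1[i], mY1, 0.1, log = TRUE) +
      dnorm(d$Y2[i], mY2, 0.1, log = TRUE)
  }
  expect_equal(log_joint(p, d, U, pri, include_priors = FALSE), ref)
  # prior part: normals on coefficients, inverse-gamma on the sds
  lp <- sum(dnorm(c(p$alpha1, p$alpha2, p$alpha31, p$alpha32), 0, 0.3, log = TRUE)) +
    sum(dnorm(c(0.3, 0.3), 0, 10, log = TRUE)) +
    sum(dnorm(p$delta, 0, 1, log = TRUE)) +
    sum(dnorm(p$V, 0, 1, log = TRUE)) +
    sum(3 * log(2) - lgamma(3) - 4 * log(p$sigma_A) - 2 / p$sigma_A) +
    sum(3 * log(2) - lgamma(3) - 4 * log(p$sigma_B) - 2 / p$sigma_B)
  expect_equal(log_joint(p, d, U, pri), ref + lp)
})

test_that("log joint decreases as an outcome moves away from its mean", {
  p <- tiny_params()
  d <- tiny_combined(20, seed = 5)$study_A
  U <- rep(0, 10)
  base <- log_joint(p, d, U, include_priors = FALSE)
  d2 <- d
  d2$Y1 <- d$Y1 + 5  # push all Y1 far from their conditional means
  expect_lt(log_joint(p, d2, U, include_priors = FALSE), base)
})

test_that("log joint is symmetric under swapping the two exposure-outcome pairs", {
  set.seed(11)
  p <- tiny_params(V = c(0.2, -0.1, 0.3, -0.4))
  # make the two pairs genuinely different
  p$alpha1 <- c(0.1, 0.2, 0.3); p$alpha2 <- c(-0.2, 0.4, 0.05)
  p$alpha31 <- c(0.3, -0.1); p$alpha32 <- c(0.2, 0.25)
  p$beta1 <- 0.3; p$beta2 <- -0.2
  p$delta <- setNames(c(1, 0.5, -0.7, 1.2), names(p$delta))
  p$sigma_B <- setNames(c(0.1, 0.2, 0.15, 0.3), names(p$sigma_B))
  d <- tiny_combined(8, seed = 2)$study_B
  d$X1 <- rnorm(4); d$X2 <- rnorm(4)  # supply exposures for evaluation
  U <- rnorm(4)
  swap <- function(x, i, j) { tmp <- x[[i]]; x[[i]] <- x[[j]]; x[[j]] <- tmp; x }
  p2 <- p
  p2$alpha1 <- p$alpha2; p2$alpha2 <- p$alpha1
  p2$alpha31 <- p$alpha32; p2$alpha32 <- p$alpha31
  p2$beta1 <- p$beta2; p2$beta2 <- p$beta1
  p2$delta <- p$delta[c(2, 1, 4, 3)]; names(p2$delta) <- names(p$delta)
  p2$sigma_A <- p$sigma_A[c(2, 1, 4, 3)]; names(p2$sigma_A) <- names(p$sigma_A)
  p2$sigma_B <- p$sigma_B[c(2, 1, 4, 3)]; names(p2$sigma_B) <- names(p$sigma_B)
  p2$V <- p$V[c(2, 1, 4, 3)]; names(p2$V) <- names(p$V)
  d2 <- study_dataset("B", d$Z2, d$Z1, d$Z3, Y1 = d$Y2, Y2 = d$Y1)
  expect_equal(log_joint(p, d, U, X1 = d$X1, X2 = d$X2),
               log_joint(p2, d2, U, X1 = d$X2, X2 = d$X1))
})

test_that("Study A equals Study B with all random effects zero", {
  p <- tiny_params(V = 0)
  cmb <- tiny_combined(12, seed = 9)
  dB <- cmb$study_B
  dA <- study_dataset("A", dB$Z1, dB$Z2, dB$Z3,
                      X1 = rnorm(6), X2 = rnorm(6), Y1 = dB$Y1, Y2 = dB$Y2)
  U <- rnorm(6)
  muA <- conditional_means(p, dA, U)
  dB2 <- study_dataset("B", dB$Z1, dB$Z2, dB$Z3, Y1 = dB$Y1, Y2 = dB$Y2)
  muB <- conditional_means(p, dB2, U, X1 = dA$X1, X2 = dA$X2)
  expect_equal(muA, muB)
})

test_that("log joint is additive over individuals", {
  p <- tiny_params()
  d <- tiny_combined(8, seed = 4)$study_A
  U <- rnorm(4)
  total <- log_joint(p, d, U, include_priors = FALSE)
  pieces <- vapply(seq_len(4), function(i) {
    di <- study_dataset("A", d$Z1[i, , drop = FALSE], d$Z2[i, , drop = FALSE],
                        d$Z3[i, , drop = FALSE], X1 = d$X1[i], X2 = d$X2[i],
                        Y1 = d$Y1[i], Y2 = d$Y2[i])
    log_joint(p, di, U[i], include_priors = FALSE)
  }, numeric(1))
  expect_equal(total, sum(pieces))
})

test_that("domain violations are rejected", {
  expect_error(structural_params(tiny_layout(), sigma_A = -1), "positive")
  expect_error(prior_spec(alpha_sd = 0), "positive")
  expect_error(instrument_layout(0, 0, 0), "at least one")
  p <- tiny_params()
  d <- tiny_combined(4, seed = 1)$study_B
  expect_error(log_joint(p, d, U = rnorm(2)), "exposure")
})
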