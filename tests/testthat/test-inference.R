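test_that("split R-hat behaves on canonical chain configurations", {
  # identical constant chains: unity by the zero-variance convention
  expect_equal(rhat(matrix(2, 100, 2)), 1)
  # stationary iid chains sit just above 1
  set.seed(3)
  expect_lt(rhat(matrix(rnorm(4000), 1000, 4)), 1.02)
  expect_gte(rhat(matrix(rnorm(4000), 1000, 4)), 0.99)
  # chains stuck at different locations blow up
  bad <- cbind(rnorm(500, -5), rnorm(500, 5))
  expect_gt(rhat(bad), 1.1)
  expect_error(rhat(matrix(1, 10, 1)), "2 chains")
  expect_error(rhat(matrix(1, 2, 3)), "4 iterations")
})

test_that("posterior summaries reduce to empirical quantiles", {
  s <- posterior_summary(matrix(5, 10, 1))
  expect_equal(unlist(s[, c("mean", "sd", "lower", "upper")]),
               c(mean = 5, sd = 0, lower = 5, upper = 5))
  x <- matrix(1:100, ncol = 1)
  s2 <- posterior_summary(x, level = 0.95)
  q <- unname(quantile(1:100, c(0.025, 0.5, 0.975)))
  expect_equal(unname(unlist(s2[, c("lower", "median", "upper")])), q)
  expect_error(posterior_summary(x, level = 1), "strictly between")
  expect_error(posterior_summary(x, level = 0), "strictly between")
})

test_that("the sampler recovers a non-zero causal effect", {
  cfg <- sim_config(n_total = 400, missing_rate = 0.2, alpha_level = 0.3,
                    beta_level = 0.3, seed = 31)
  d <- simulate_combined(cfg, 1)
  fit <- bmr(d, settings = mcmc_settings(seed = 4))
  s <- summary(fit)
  expect_lt(abs(s["beta1", "mean"] - 0.3), 3 * s["beta1", "sd"])
  expect_lt(abs(s["beta2", "mean"] - 0.3), 3 * s["beta2", "sd"])
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  expect_lt(max(fit$rhat), 1.1)
})

test_that("fitting requires the two-study missing-data pattern", {
  cmb <- tiny_combined(40)
  B <- cmb$study_B
  full_B <- study_dataset("A", B$Z1, B$Z2, B$Z3, X1 = rnorm(B$n),
                          X2 = rnorm(B$n), Y1 = B$Y1, Y2 = B$Y2)
  expect_error(combined_dataset(cmb$study_A, full_B), "absent")
  expect_error(bmr(list()), "mr_data")
  # an empty Study B (missing rate zero) cannot be constructed
  expect_error(study_dataset("B", matrix(0, 0, 2), matrix(0, 0, 2),
                             matrix(0, 0, 1), Y1 = numeric(0), Y2 = numeric(0)),
               "at least one individual")
})

test_that("posterior means of imputed exposures track the hidden truth", {
  cfg <- sim_config(n_total = 300, missing_rate = 0.5, alpha_level = 0.3,
                    beta_level = 0.3, seed = 17)
  d <- simulate_combined(cfg, 1, keep_truth = TRUE)
  fit <- bmr(d, settings = fast_settings(seed = 2))
  truth <- attr(d$study_B, "truth")
  expect_gt(cor(fit$latent$X1_B, truth$X1), 0.8)
  expect_gt(cor(fit$latent$X2_B, truth$X2), 0.8)
})

test_that("posteriors concentrate as the sample grows", {
  cfg_small <- sim_config(n_total = 400, missing_rate = 0.5,
                          alpha_level = 0.3, beta_level = 0.3, seed = 23)
  cfg_big <- sim_config(n_total = 4000, missing_rate = 0.5,
                        alpha_level = 0.3, beta_level = 0.3, seed = 23)
  f1 <- bmr(simulate_combined(cfg_small, 1), settings = fast_settings(seed = 6))
  f2 <- bmr(simulate_combined(cfg_big, 1), settings = fast_settings(seed = 6))
  expect_lt(summary(f2)["beta1", "sd"], summary(f1)["beta1", "sd"])
})

test_that("constraining the random effects to zero matches on homogeneous data", {
  set.seed(19)
  p <- structural_params(instrument_layout(5, 5, 2),
                         alpha1 = 0.3, alpha2 = 0.3, alpha31 = 0.3,
                         alpha32 = 0.3, beta1 = 0.3, beta2 = 0.3,
                         delta = 1, sigma_A = 0.1, sigma_B = 0.1, V = 0)
  d <- combined_dataset(simulate_study(p, 150, "A"),
                        simulate_study(p, 150, "B"))
  f_free <- bmr(d, settings = fast_settings(seed = 8))
  f_fixed <- bmr(d, settings = fast_settings(seed = 9), fix_V = TRUE)
  expect_true(all(abs(coef(f_fixed)[c("V_X1", "V_X2", "V_Y1", "V_Y2")]) < 1e-4))
  expect_lt(abs(coef(f_free)[["beta1"]] - coef(f_fixed)[["beta1"]]),
            3 * summary(f_free)["beta1", "sd"])
})

test_that("the Gibbs sampler agrees with an independent JAGS implementation", {
  skip_if_not_installed("rjags")
  set.seed(42)
  p <- tiny_params()
  A <- simulate_study(p, 80, "A")
  B <- simulate_study(p, 80, "B")
  d <- combined_dataset(A, B)
  fit <- bmr(d, settings = mcmc_settings(iter = 3000, warmup = 1500,
                                         chains = 2, seed = 3))
  model_string <- "model {
    for (i in 1:nA) {
      UA[i] ~ dnorm(0, 1)
      X1A[i] ~ dnorm(inprod(Z1A[i,], a1) + inprod(Z3A[i,], a31) + dX1*UA[i], pX1A)
      X2A[i] ~ dnorm(inprod(Z2A[i,], a2) + inprod(Z3A[i,], a32) + dX2*UA[i], pX2A)
      Y1A[i] ~ dnorm(b1*X1A[i] + dY1*UA[i], pY1A)
      Y2A[i] ~ dnorm(b2*X2A[i] + dY2*UA[i], pY2A)
    }
    for (i in 1:nB) {
      UB[i] ~ dnorm(0, 1)
      X1B[i] ~ dnorm(VX1 + inprod(Z1B[i,], a1) + inprod(Z3B[i,], a31) + dX1*UB[i], pX1B)
      X2B[i] ~ dnorm(VX2 + inprod(Z2B[i,], a2) + inprod(Z3B[i,], a32) + dX2*UB[i], pX2B)
      Y1B[i] ~ dnorm(VY1 + b1*X1B[i] + dY1*UB[i], pY1B)
      Y2B[i] ~ dnorm(VY2 + b2*X2B[i] + dY2*UB[i], pY2B)
    }
    for (j in 1:L) { a1[j] ~ dnorm(0, pa) }
    for (j in 1:K) { a2[j] ~ dnorm(0, pa) }
    for (j in 1:M) { a31[j] ~ dnorm(0, pa); a32[j] ~ dnorm(0, pa) }
    b1 ~ dnorm(0, 0.01); b2 ~ dnorm(0, 0.01)
    dX1 ~ dnorm(0, 1); dX2 ~ dnorm(0, 1); dY1 ~ dnorm(0, 1); dY2 ~ dnorm(0, 1)
    VX1 ~ dnorm(0, 1); VX2 ~ dnorm(0, 1); VY1 ~ dnorm(0, 1); VY2 ~ dnorm(0, 1)
    for (k in 1:8) { w[k] ~ dgamma(3, 2); sig[k] <- 1/w[k] }
    pX1A <- 1/(sig[1]*sig[1]); pX2A <- 1/(sig[2]*sig[2])
    pY1A <- 1/(sig[3]*sig[3]); pY2A <- 1/(sig[4]*sig[4])
    pX1B <- 1/(sig[5]*sig[5]); pX2B <- 1/(sig[6]*sig[6])
    pY1B <- 1/(sig[7]*sig[7]); pY2B <- 1/(sig[8]*sig[8])
  }"
  dat <- list(nA = A$n, nB = B$n, L = 3, K = 3, M = 2,
              Z1A = A$Z1, Z2A = A$Z2, Z3A = A$Z3, X1A = A$X1, X2A = A$X2,
              Y1A = A$Y1, Y2A = A$Y2,
              Z1B = B$Z1, Z2B = B$Z2, Z3B = B$Z3, Y1B = B$Y1, Y2B = B$Y2,
              pa = 1 / 0.3^2)
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = list(dX1 = 1, dX2 = 1, dY1 = 1, dY2 = 1),
                          n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b1", "b2", "dY1", "sig"),
                              n.iter = 5000, progress.bar = "none")
  ref <- summary(samp)$statistics
  s <- summary(fit)
  # posterior means agree within a few Monte-Carlo standard errors
  expect_lt(abs(s["beta1", "mean"] - ref["b1", "Mean"]), 0.02)
  expect_lt(abs(s["beta2", "mean"] - ref["b2", "Mean"]), 0.02)
  expect_lt(abs(s["delta_Y1", "mean"] - ref["dY1", "Mean"]), 0.05)
  expect_lt(abs(s["sigma_Y1A", "mean"] - ref["sig[3]", "Mean"]), 0.02)
  # and so do the posterior spreads of the causal effect
  expect_lt(abs(s["beta1", "sd"] - ref["b1", "SD"]) / ref["b1", "SD"], 0.25)
})
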