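#' MCMC settings
#'
#' @param iter Post-warmup iterations kept per chain.
#' @param warmup Warmup iterations discarded per chain.
#' @param chains Number of chains (at least 2 for \eqn{\hat R}).
#' @param thin Thinning interval.
#' @param seed Base seed; each chain runs on an independent substream.
#' @param init_scale Dispersion factor applied to the prior scales when
#'   drawing overdispersed initial values.
#' @return An object of class `mr_mcmc_settings`.
#' @export
mcmc_settings <- function(iter = 2000L, warmup = 1000L, chains = 4L,
                          thin = 1L, seed = 1L, init_scale = 0.1) {
  iter <- as.integer(iter); warmup <- as.integer(warmup)
  chains <- as.integer(chains); thin <- as.integer(thin)
  if (iter < 1L || warmup < 0L || thin < 1L || chains < 1L)
    stop("invalid MCMC settings")
  if (init_scale <= 0) stop("init_scale must be positive")
  structure(list(iter = iter, warmup = warmup, chains = chains, thin = thin,
                 seed = as.integer(seed), init_scale = init_scale),
            class = "mr_mcmc_settings")
}

# overdispersed chain-specific initial values; deltas start in the
# positive half-space to break the (delta, U) -> (-delta, -U) reflection
# symmetry consistently across chains
make_inits <- function(A, B, lay, priors, settings) {
  sc <- settings$init_scale
  init <- list(
    alpha1 = rnorm(lay$L, 0, priors$alpha_sd * sc),
    alpha2 = rnorm(lay$K, 0, priors$alpha_sd * sc),
    alpha31 = rnorm(lay$M, 0, priors$alpha_sd * sc),
    alpha32 = rnorm(lay$M, 0, priors$alpha_sd * sc),
    beta1 = rnorm(1, 0, priors$beta_sd * sc),
    beta2 = rnorm(1, 0, priors$beta_sd * sc),
    delta = priors$delta_sd * (0.5 + sc * abs(rnorm(4))),
    V = rnorm(4, 0, priors$V_sd * sc),
    sigma = priors$sigma_scale / (priors$sigma_shape + 1) *
      exp(rnorm(8, 0, sc)),
    UA = rnorm(A$n), UB = rnorm(B$n))
  # latent exposures start at the instrument-based linear prediction
  predict_from_A <- function(x, ZfullA, ZfullB) {
    XA <- cbind(1, ZfullA)
    fit <- lm.fit(XA, x)
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    drop(cbind(1, ZfullB) %*% cf)
  }
  init$X1B <- predict_from_A(A$X1, cbind(A$Z1, A$Z3), cbind(B$Z1, B$Z3))
  init$X2B <- predict_from_A(A$X2, cbind(A$Z2, A$Z3), cbind(B$Z2, B$Z3))
  init
}

#' Fit the random-effect Bayesian Mendelian-randomization model
#'
#' Samples the joint posterior of the structural parameters, the latent
#' per-individual confounders of both studies, and the imputed Study-B
#' exposures, by a data-augmentation Gibbs sampler: each sweep draws the
#' missing exposures from their conditional normals given the current
#' parameters, then updates the coefficient blocks of the four structural
#' equations, the residual standard deviations and the latent confounders
#' from their full conditionals.  Imputation and estimation therefore happen
#' simultaneously within one Markov chain.
#'
#' The causal effects of interest are `beta1` (first exposure on first
#' outcome) and `beta2` (second exposure on second outcome).  Study-B
#' heterogeneity enters through the four random-effect intercepts `V_*`.
#'
#' @param data An `mr_data` object ([combined_dataset()]): Study A with
#'   observed exposures, Study B with exposures absent.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param fix_V If `TRUE`, constrain all four random effects to zero
#'   (homogeneous-study model).
#' @param keep_latent Keep the full draws of the latent confounders and
#'   imputed exposures (memory grows with n); their posterior means are
#'   always returned.
#' @param standardise If `TRUE`, centre and scale the exposures and outcomes
#'   (exposure location/scale from Study A, outcome from both studies)
#'   before fitting; estimates are then on the standardised scale.
#' @return An object of class `bmr` with components `draws` (array
#'   iterations x chains x parameters), `summary` (posterior mean, sd,
#'   median, equal-tailed 95% interval and split-\eqn{\hat R} per structural
#'   parameter), `rhat`, `latent` (posterior means of latent quantities),
#'   and the call ingredients.
#' @seealso [summary.bmr()], [coef.bmr()], [confint.bmr()], [plot.bmr()]
#' @examples
#' cfg <- sim_config(n_total = 120, missing_rate = 0.5, n_replicates = 1)
#' d <- simulate_combined(cfg, 1)
#' fit <- bmr(d, settings = mcmc_settings(iter = 200, warmup = 200, chains = 2))
#' coef(fit)[c("beta1", "beta2")]
#' @export
bmr <- function(data, priors = prior_spec(), settings = mcmc_settings(),
                fix_V = FALSE, keep_latent = FALSE, standardise = FALSE) {
  if (!inherits(data, "mr_data"))
    stop("'data' must be an mr_data object (see combined_dataset())")
  stopifnot(inherits(priors, "mr_priors"),
            inherits(settings, "mr_mcmc_settings"))
  A <- data$study_A; B <- data$study_B
  if (standardise) {
    zx <- function(v, mu, s) (v - mu) / s
    mX1 <- mean(A$X1); sX1 <- sd(A$X1); mX2 <- mean(A$X2); sX2 <- sd(A$X2)
    mY1 <- mean(c(A$Y1, B$Y1)); sY1 <- sd(c(A$Y1, B$Y1))
    mY2 <- mean(c(A$Y2, B$Y2)); sY2 <- sd(c(A$Y2, B$Y2))
    A$X1 <- zx(A$X1, mX1, sX1); A$X2 <- zx(A$X2, mX2, sX2)
    A$Y1 <- zx(A$Y1, mY1, sY1); A$Y2 <- zx(A$Y2, mY2, sY2)
    B$Y1 <- zx(B$Y1, mY1, sY1); B$Y2 <- zx(B$Y2, mY2, sY2)
  }
  lay <- layout_of(data)
  pn <- param_names(lay)
  pr <- unclass(priors)

  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(substream_seed(settings$seed, 90000L + ch))
    init <- make_inits(A, B, lay, priors, settings)
    res <- gibbs_chain(A$Z1, A$Z2, A$Z3, A$X1, A$X2, A$Y1, A$Y2,
                       B$Z1, B$Z2, B$Z3, B$Y1, B$Y2,
                       pr, init, settings$iter, settings$warmup,
                       settings$thin, !fix_V, keep_latent)
    colnames(res$draws) <- pn
    # per-chain sign alignment of the (delta, U) reflection modes
    dcols <- c("delta_X1", "delta_X2", "delta_Y1", "delta_Y2")
    if (mean(res$draws[, "delta_X1"]) < 0) {
      res$draws[, dcols] <- -res$draws[, dcols]
      res$latent_mean$UA <- -res$latent_mean$UA
      res$latent_mean$UB <- -res$latent_mean$UB
      if (!is.null(res$latent_draws)) {
        res$latent_draws$UA <- -res$latent_draws$UA
        res$latent_draws$UB <- -res$latent_draws$UB
      }
    }
    chains[[ch]] <- res
  }

  nkeep <- nrow(chains[[1L]]$draws)
  draws <- array(NA_real_, dim = c(nkeep, settings$chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  pooled <- matrix(draws, nrow = nkeep * settings$chains, ncol = length(pn))
  colnames(pooled) <- pn
  summ <- posterior_summary(pooled, 0.95)
  rh <- if (settings$chains >= 2L && nkeep >= 4L)
    vapply(seq_along(pn), function(j) rhat(draws[, , j]), numeric(1))
  else rep(NA_real_, length(pn))
  names(rh) <- pn
  summ$rhat <- rh

  latent <- list(
    U_A = rowMeans(vapply(chains, function(c) c$latent_mean$UA, numeric(A$n))),
    U_B = rowMeans(vapply(chains, function(c) c$latent_mean$UB, numeric(B$n))),
    X1_B = rowMeans(vapply(chains, function(c) c$latent_mean$X1B, numeric(B$n))),
    X2_B = rowMeans(vapply(chains, function(c) c$latent_mean$X2B, numeric(B$n))))
  latent_draws <- if (keep_latent) lapply(chains, `[[`, "latent_draws")

  structure(list(draws = draws, summary = summ, rhat = rh, latent = latent,
                 latent_draws = latent_draws, layout = lay, priors = priors,
                 settings = settings, fix_V = fix_V,
                 standardise = standardise,
                 data_info = list(nA = A$n, nB = B$n,
                                  missing_rate = data$missing_rate),
                 call = match.call()),
            class = "bmr")
}

#' Pooled posterior draws of a fitted model
#'
#' @param x A `bmr` fit.
#' @param pars Optional character vector of parameter names to keep.
#' @param ... Unused.
#' @return Matrix of pooled post-warmup draws (all chains stacked),
#'   one column per structural parameter.
#' @export
as.matrix.bmr <- function(x, pars = NULL, ...) {
  d <- x$draws
  out <- matrix(d, nrow = dim(d)[1L] * dim(d)[2L], ncol = dim(d)[3L])
  colnames(out) <- dimnames(d)[[3L]]
  if (!is.null(pars)) {
    missing <- setdiff(pars, colnames(out))
    if (length(missing))
      stop("unknown parameters: ", paste(missing, collapse = ", "))
    out <- out[, pars, drop = FALSE]
  }
  out
}

#' @export
print.bmr <- function(x, ...) {
  cat("Random-effect Bayesian Mendelian randomization fit\n")
  cat(sprintf("  data: nA = %d, nB = %d (missing rate %.1f%%)\n",
              x$data_info$nA, x$data_info$nB, 100 * x$data_info$missing_rate))
  cat(sprintf("  sampler: %d chains, %d warmup + %d kept iterations\n",
              x$settings$chains, x$settings$warmup, x$settings$iter))
  cat("\nCausal effects (posterior):\n")
  print(round(x$summary[c("beta1", "beta2"), ], 4))
  if (!anyNA(x$rhat))
    cat(sprintf("\nMax split-Rhat over structural parameters: %.4f\n",
                max(x$rhat)))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object A `bmr` fit.
#' @param pars Optional parameter subset.
#' @param ... Unused.
#' @return Data frame of posterior mean, sd, median, equal-tailed 95%
#'   interval and split-\eqn{\hat R} per structural parameter.
#' @export
summary.bmr <- function(object, pars = NULL, ...) {
  s <- object$summary
  if (!is.null(pars)) s <- s[pars, , drop = FALSE]
  s
}

#' @export
coef.bmr <- function(object, ...) {
  setNames(object$summary$mean, rownames(object$summary))
}

#' Equal-tailed credible intervals
#'
#' @param object A `bmr` fit.
#' @param parm Parameter names (default: the two causal effects).
#' @param level Credible level.
#' @param ... Unused.
#' @return Matrix with one row per parameter and columns giving the
#'   equal-tailed interval endpoints.
#' @export
confint.bmr <- function(object, parm = c("beta1", "beta2"), level = 0.95, ...) {
  draws <- as.matrix(object, pars = parm)
  s <- posterior_summary(draws, level)
  out <- as.matrix(s[, c("lower", "upper")])
  a <- (1 - level) / 2
  dimnames(out) <- list(parm, sprintf("%.1f %%", 100 * c(a, 1 - a)))
  out
}

#' Plot a fitted model
#'
#' `type = "density"` draws contours of the 2-D Gaussian kernel density
#' estimate of the joint posterior of the two causal effects;
#' `type = "trace"` shows per-chain trace plots of selected parameters.
#'
#' @param x A `bmr` fit.
#' @param type Plot type.
#' @param pars Parameters for trace plots.
#' @param ... Passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.bmr <- function(x, type = c("density", "trace"),
                     pars = c("beta1", "beta2"), ...) {
  type <- match.arg(type)
  if (type == "density") {
    draws <- as.matrix(x, pars = c("beta1", "beta2"))
    k <- posterior_kde2d(draws[, 1L], draws[, 2L])
    graphics::contour(k$x, k$y, k$z, xlab = "beta1", ylab = "beta2", ...)
  } else {
    old <- graphics::par(mfrow = c(length(pars), 1L), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(old))
    for (p in pars) {
      graphics::matplot(x$draws[, , p], type = "l", lty = 1,
                        ylab = p, xlab = "iteration", ...)
    }
  }
  invisible(x)
}
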