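#' Per-instrument association
#'
#' Slope and standard error of the simple linear regression (with intercept)
#' of a response on a single instrument dosage.
#'
#' @param response Numeric response vector.
#' @param dosage Numeric dosage vector of the same length (at least 3
#'   observations).
#' @return Named vector `c(estimate, se)`; both `NA` (with a warning) when
#'   the dosage is constant, in which case the instrument should be dropped.
#' @export
instrument_assoc <- function(response, dosage) {
  n <- length(response)
  if (length(dosage) != n) stop("response and dosage lengths differ")
  if (n < 3L) stop("at least 3 observations are required")
  if (var(dosage) == 0) {
    warning("constant dosage: instrument dropped")
    return(c(estimate = NA_real_, se = NA_real_))
  }
  a <- assoc_block(response, matrix(dosage, ncol = 1L))
  c(estimate = a$estimate, se = a$se)
}

# slopes and standard errors of simple regressions of y on each column of Z
assoc_block <- function(y, Z) {
  n <- length(y)
  yc <- y - mean(y)
  Zc <- sweep(Z, 2L, colMeans(Z))
  Sxx <- colSums(Zc^2)
  Sxy <- drop(crossprod(Zc, yc))
  Syy <- sum(yc^2)
  est <- Sxy / Sxx
  rss <- pmax(Syy - Sxy^2 / Sxx, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  est[Sxx == 0] <- NA_real_
  se[Sxx == 0] <- NA_real_
  list(estimate = est, se = se)
}

# coefficients and standard errors of the multivariable regression of y on
# all columns of Z jointly (with intercept); constant columns come back NA
joint_assoc_block <- function(y, Z) {
  keep <- apply(Z, 2L, var) > 0
  X <- cbind(1, Z[, keep, drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("instrument design is rank deficient in the joint regression")
  cf <- qr.coef(qrx, y)
  res <- y - X %*% cf
  s2 <- sum(res^2) / (length(y) - ncol(X))
  XtXinv <- chol2inv(qr.R(qrx))
  est <- se <- rep(NA_real_, ncol(Z))
  est[keep] <- cf[-1L]
  se[keep] <- sqrt(s2 * diag(XtXinv)[-1L])
  list(estimate = est, se = se)
}

#' Inverse-variance weighted estimate from two-stage summary statistics
#'
#' Combines per-instrument exposure associations `gamma` (stage 1) and
#' outcome associations `Gamma` with standard errors `Gamma_se` (stage 2)
#' into the first-order-weights IVW estimate
#' \deqn{\hat\beta = \frac{\sum_i \gamma_i \Gamma_i / se(\Gamma_i)^2}
#'                        {\sum_i \gamma_i^2 / se(\Gamma_i)^2},}
#' equal to the weighted least-squares slope of `Gamma` on `gamma` through
#' the origin with weights \eqn{se(\Gamma_i)^{-2}}.
#'
#' Without stage-1 standard errors the usual first-order standard error
#' \eqn{(\sum_i \gamma_i^2/se(\Gamma_i)^2)^{-1/2}} is reported.  When
#' `gamma_se` is supplied (the default path from [ivw()], which has
#' individual-level data available), the standard error additionally
#' propagates stage-1 sampling uncertainty by the delta method applied to
#' the ratio of weighted sums,
#' \deqn{se^2 = \frac{1}{\sum_i w_i\gamma_i^2} +
#'   \frac{\sum_i \{w_i(\Gamma_i - 2\gamma_i\hat\beta)\}^2 se(\gamma_i)^2}
#'        {(\sum_i w_i \gamma_i^2)^2},}
#' which widens the interval exactly where instruments are weak.  The 95%
#' confidence interval is \eqn{\hat\beta \pm 1.96\, se}.
#'
#' @param gamma Per-instrument exposure slopes (stage 1).
#' @param Gamma Per-instrument outcome slopes (stage 2).
#' @param Gamma_se Standard errors of `Gamma`.
#' @param gamma_se Optional standard errors of `gamma`; when present they
#'   enter the delta-method standard error.
#' @return An object of class `ivw` with `beta_hat`, `se`, `ci95`,
#'   `n_instruments` and the per-instrument table.
#' @export
ivw_estimate <- function(gamma, Gamma, Gamma_se, gamma_se = NULL) {
  stopifnot(length(gamma) == length(Gamma), length(Gamma) == length(Gamma_se))
  if (length(gamma) < 1L) stop("no usable instruments")
  keep <- complete.cases(gamma, Gamma, Gamma_se)
  tab <- data.frame(gamma = gamma,
                    gamma_se = if (is.null(gamma_se)) NA_real_ else gamma_se,
                    Gamma = Gamma, Gamma_se = Gamma_se, used = keep)
  g <- gamma[keep]; G <- Gamma[keep]; Gse <- Gamma_se[keep]
  if (length(g) < 1L) stop("no usable instruments")
  w <- 1 / Gse^2
  denom <- sum(g^2 * w)
  if (denom == 0) stop("all inverse-variance weights are zero")
  beta_hat <- sum(g * G * w) / denom
  se2 <- 1 / denom
  if (!is.null(gamma_se)) {
    gs <- gamma_se[keep]
    se2 <- se2 + sum((w * (G - 2 * g * beta_hat))^2 * gs^2) / denom^2
  }
  se <- sqrt(se2)
  structure(list(beta_hat = beta_hat, se = se,
                 ci95 = c(lower = beta_hat - 1.96 * se,
                          upper = beta_hat + 1.96 * se),
                 n_instruments = length(g), instruments = tab),
            class = "ivw")
}

#' Two-sample IVW estimate of one causal effect from a combined dataset
#'
#' The comparator estimator: instrument-exposure associations are estimated
#' in Study A (observed exposures) and instrument-outcome associations in
#' Study B, exactly splitting the two samples; the summary statistics are
#' then combined by [ivw_estimate()].  Pair 1 (first exposure on first
#' outcome) uses the instrument set Z1 plus the shared block Z3; pair 2
#' uses Z2 plus Z3.
#'
#' Since individual-level data are available, the default association model
#' regresses the response on all of the pair's instruments jointly
#' (`assoc = "joint"`), which removes the variance explained by the other
#' instruments from each residual; `assoc = "marginal"` fits the
#' conventional per-instrument simple regressions instead.
#'
#' @param data An `mr_data` object.
#' @param pair 1 for the first exposure-outcome pair, 2 for the second.
#' @param assoc Association model for both stages.
#' @param blocks Optional character subset of the instrument blocks to use
#'   (default: the pair's own block plus the shared block).
#' @return An object of class `ivw` (see [ivw_estimate()]).
#' @examples
#' cfg <- sim_config(n_total = 200, missing_rate = 0.5, n_replicates = 1)
#' ivw(simulate_combined(cfg, 1), pair = 1)
#' @export
ivw <- function(data, pair = 1L, assoc = c("joint", "marginal"),
                blocks = NULL) {
  stopifnot(inherits(data, "mr_data"))
  assoc <- match.arg(assoc)
  pair <- as.integer(pair)
  if (!pair %in% c(1L, 2L)) stop("pair must be 1 or 2")
  if (is.null(blocks)) blocks <- c(if (pair == 1L) "Z1" else "Z2", "Z3")
  A <- data$study_A; B <- data$study_B
  ZA <- do.call(cbind, lapply(blocks, function(b) A[[b]]))
  ZB <- do.call(cbind, lapply(blocks, function(b) B[[b]]))
  expo <- if (pair == 1L) A$X1 else A$X2
  outc <- if (pair == 1L) B$Y1 else B$Y2
  fit <- if (assoc == "joint") joint_assoc_block else assoc_block
  stage1 <- fit(expo, ZA)
  stage2 <- fit(outc, ZB)
  n_const <- sum(is.na(stage1$estimate) | is.na(stage2$estimate))
  if (n_const > 0)
    warning(sprintf("%d constant-dosage instrument(s) dropped", n_const))
  est <- ivw_estimate(stage1$estimate, stage2$estimate, stage2$se,
                      gamma_se = stage1$se)
  est$pair <- pair
  est$assoc <- assoc
  est
}

#' @export
print.ivw <- function(x, ...) {
  cat(sprintf("Two-sample IVW estimate (%d instruments)\n", x$n_instruments))
  cat(sprintf("  beta_hat = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$beta_hat, x$se, x$ci95[["lower"]], x$ci95[["upper"]]))
  invisible(x)
}

#' @export
coef.ivw <- function(object, ...) c(beta_hat = object$beta_hat)

#' @export
confint.ivw <- function(object, parm = "beta_hat", level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$beta_hat - z * object$se,
                  object$beta_hat + z * object$se), nrow = 1L)
  a <- (1 - level) / 2
  dimnames(out) <- list("beta_hat", sprintf("%.1f %%", 100 * c(a, 1 - a)))
  out
}
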