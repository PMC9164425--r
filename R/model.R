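#' Conditional means of the structural equations
#'
#' Evaluates the conditional expectations of the four modelled variables for
#' every individual of a study, given the latent confounder values `U`.  The
#' exposure means depend on the instruments and `U`; the outcome means depend
#' on the exposures and `U`.  For Study B the corresponding random-effect
#' intercept `V` is added to each equation; Study A has none.
#'
#' @param params An [structural_params()] object.
#' @param dataset An `mr_study`.
#' @param U Numeric vector of latent confounder values, one per individual.
#' @param X1,X2 Optional exposure vectors overriding the dataset columns
#'   (needed to evaluate the outcome means when the study's exposures are
#'   absent, e.g. with imputed values).
#' @return A list of four length-n vectors `X1`, `X2`, `Y1`, `Y2`.
#' @export
conditional_means <- function(params, dataset, U, X1 = NULL, X2 = NULL) {
  stopifnot(inherits(params, "mr_params"), inherits(dataset, "mr_study"))
  n <- dataset$n
  U <- as.numeric(U)
  if (length(U) != n)
    stop(sprintf("U has length %d but the study has %d individuals", length(U), n))
  lay <- params$layout
  if (ncol(dataset$Z1) != lay$L || ncol(dataset$Z2) != lay$K ||
      ncol(dataset$Z3) != lay$M)
    stop("instrument dimensions of dataset and parameters disagree")
  x1 <- if (!is.null(X1)) as.numeric(X1) else dataset$X1
  x2 <- if (!is.null(X2)) as.numeric(X2) else dataset$X2
  V <- if (dataset$study == "B") params$V else c(X1 = 0, X2 = 0, Y1 = 0, Y2 = 0)
  mu_X1 <- V[["X1"]] + drop(dataset$Z1 %*% params$alpha1) +
    drop(dataset$Z3 %*% params$alpha31) + params$delta[["X1"]] * U
  mu_X2 <- V[["X2"]] + drop(dataset$Z2 %*% params$alpha2) +
    drop(dataset$Z3 %*% params$alpha32) + params$delta[["X2"]] * U
  mu_Y1 <- mu_Y2 <- NULL
  if (!is.null(x1)) {
    if (length(x1) != n || length(x2) != n)
      stop("exposure vectors must have one value per individual")
    mu_Y1 <- V[["Y1"]] + params$beta1 * x1 + params$delta[["Y1"]] * U
    mu_Y2 <- V[["Y2"]] + params$beta2 * x2 + params$delta[["Y2"]] * U
  }
  list(X1 = mu_X1 + numeric(n), X2 = mu_X2 + numeric(n),
       Y1 = mu_Y1, Y2 = mu_Y2)
}

# log density of Inv-Gamma(shape, scale) evaluated at x > 0
dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Log joint density of one study
#'
#' Sum of the standard-normal log density of the latent confounders, the four
#' conditional normal log densities of the structural equations, and (by
#' default) the log prior density of the full parameter set.  Exposure values
#' must be available, either observed in the dataset or supplied (imputed).
#'
#' @inheritParams conditional_means
#' @param priors A [prior_spec()].
#' @param include_priors If `FALSE`, return only the data part (U density
#'   plus the four conditional densities).  Useful when accumulating the
#'   joint density over the two studies, whose parameters share one prior.
#' @return A single finite number for finite inputs.
#' @export
log_joint <- function(params, dataset, U, priors = prior_spec(),
                      X1 = NULL, X2 = NULL, include_priors = TRUE) {
  stopifnot(inherits(priors, "mr_priors"))
  if (any(params$sigma_A <= 0) || any(params$sigma_B <= 0))
    stop("residual standard deviations must be positive")
  mu <- conditional_means(params, dataset, U, X1 = X1, X2 = X2)
  if (is.null(mu$Y1))
    stop("exposure values are required (observed or imputed) to evaluate the joint density")
  x1 <- if (!is.null(X1)) as.numeric(X1) else dataset$X1
  x2 <- if (!is.null(X2)) as.numeric(X2) else dataset$X2
  sig <- if (dataset$study == "B") params$sigma_B else params$sigma_A
  ll <- sum(dnorm(U, 0, 1, log = TRUE)) +
    sum(dnorm(x1, mu$X1, sig[["X1"]], log = TRUE)) +
    sum(dnorm(x2, mu$X2, sig[["X2"]], log = TRUE)) +
    sum(dnorm(dataset$Y1, mu$Y1, sig[["Y1"]], log = TRUE)) +
    sum(dnorm(dataset$Y2, mu$Y2, sig[["Y2"]], log = TRUE))
  if (include_priors) {
    lp <- sum(dnorm(c(params$alpha1, params$alpha2, params$alpha31, params$alpha32),
                    0, priors$alpha_sd, log = TRUE)) +
      sum(dnorm(c(params$beta1, params$beta2), 0, priors$beta_sd, log = TRUE)) +
      sum(dnorm(params$delta, 0, priors$delta_sd, log = TRUE)) +
      sum(dnorm(params$V, 0, priors$V_sd, log = TRUE)) +
      sum(dinvgamma_log(c(params$sigma_A, params$sigma_B),
                        priors$sigma_shape, priors$sigma_scale))
    ll <- ll + lp
  }
  ll
}
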