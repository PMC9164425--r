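#' Instrument block layout
#'
#' The model uses three blocks of mutually independent genetic instruments:
#' `Z1` (instruments of the first exposure only), `Z2` (second exposure only)
#' and `Z3` (shared by both exposures).
#'
#' @param L Number of instruments in block `Z1`.
#' @param K Number of instruments in block `Z2`.
#' @param M Number of instruments in the shared block `Z3`.
#' @return An object of class `mr_layout`.
#' @examples
#' instrument_layout(15, 15, 5)
#' @export
instrument_layout <- function(L = 15L, K = 15L, M = 5L) {
  L <- as.integer(L); K <- as.integer(K); M <- as.integer(M)
  if (any(c(L, K, M) < 0L)) stop("instrument counts must be non-negative")
  if (L + K + M < 1L) stop("at least one instrument is required")
  structure(list(L = L, K = K, M = M), class = "mr_layout")
}

#' @export
print.mr_layout <- function(x, ...) {
  cat(sprintf("Instrument layout: L = %d (Z1), K = %d (Z2), M = %d (Z3, shared)\n",
              x$L, x$K, x$M))
  invisible(x)
}

#' Structural parameters of the two-study Mendelian-randomization model
#'
#' Collects every coefficient of the linear structural-equation model: the
#' instrument-strength vectors `alpha1` (Z1 on X1), `alpha2` (Z2 on X2),
#' `alpha31`/`alpha32` (Z3 on X1/X2), the causal effects `beta1` (X1 on Y1)
#' and `beta2` (X2 on Y2), the confounder loadings `delta` of the latent
#' scalar confounder U on (X1, X2, Y1, Y2), the residual standard deviations
#' `sigma_A`, `sigma_B` per equation and study, and the Study-B random-effect
#' intercepts `V`.
#'
#' @param layout An [instrument_layout()].
#' @param alpha1,alpha2,alpha31,alpha32 Instrument-strength vectors of
#'   lengths `L`, `K`, `M`, `M`; scalars are recycled.
#' @param beta1,beta2 Scalar causal effects.
#' @param delta Length-4 vector of confounder loadings on (X1, X2, Y1, Y2);
#'   a scalar is recycled.
#' @param sigma_A,sigma_B Length-4 vectors of positive residual standard
#'   deviations for the (X1, X2, Y1, Y2) equations in Study A and Study B;
#'   scalars are recycled.
#' @param V Length-4 vector of Study-B random-effect intercepts for the
#'   (X1, X2, Y1, Y2) equations; a scalar is recycled.
#' @return An object of class `mr_params`.
#' @examples
#' p <- structural_params(instrument_layout(2, 2, 1),
#'                        alpha1 = 0.3, beta1 = 0.3, beta2 = 0.3)
#' p$beta1
#' @export
structural_params <- function(layout,
                              alpha1 = 0, alpha2 = 0, alpha31 = 0, alpha32 = 0,
                              beta1 = 0, beta2 = 0,
                              delta = 0,
                              sigma_A = 1, sigma_B = 1,
                              V = 0) {
  stopifnot(inherits(layout, "mr_layout"))
  rec <- function(x, len, nm) {
    if (length(x) == 1L) x <- rep(as.numeric(x), len)
    if (length(x) != len) stop(sprintf("'%s' must have length %d", nm, len))
    as.numeric(x)
  }
  eqs <- c("X1", "X2", "Y1", "Y2")
  out <- structure(list(
    layout  = layout,
    alpha1  = rec(alpha1,  layout$L, "alpha1"),
    alpha2  = rec(alpha2,  layout$K, "alpha2"),
    alpha31 = rec(alpha31, layout$M, "alpha31"),
    alpha32 = rec(alpha32, layout$M, "alpha32"),
    beta1   = as.numeric(beta1),
    beta2   = as.numeric(beta2),
    delta   = setNames(rec(delta, 4L, "delta"), eqs),
    sigma_A = setNames(rec(sigma_A, 4L, "sigma_A"), eqs),
    sigma_B = setNames(rec(sigma_B, 4L, "sigma_B"), eqs),
    V       = setNames(rec(V, 4L, "V"), eqs)
  ), class = "mr_params")
  if (any(out$sigma_A <= 0) || any(out$sigma_B <= 0))
    stop("all residual standard deviations must be positive")
  out
}

#' @export
print.mr_params <- function(x, ...) {
  cat("Structural parameters\n")
  cat(sprintf("  beta1 = %.4g, beta2 = %.4g\n", x$beta1, x$beta2))
  cat("  delta:  ", paste(sprintf("%s=%.3g", names(x$delta), x$delta), collapse = " "), "\n")
  cat("  V:      ", paste(sprintf("%s=%.3g", names(x$V), x$V), collapse = " "), "\n")
  cat("  sigma_A:", paste(sprintf("%.3g", x$sigma_A), collapse = " "),
      " sigma_B:", paste(sprintf("%.3g", x$sigma_B), collapse = " "), "\n")
  cat(sprintf("  |alpha1| = %d, |alpha2| = %d, |alpha31| = |alpha32| = %d\n",
              length(x$alpha1), length(x$alpha2), length(x$alpha31)))
  invisible(x)
}

#' Prior specification
#'
#' Independent priors for every unknown: zero-mean normals with standard
#' deviation `alpha_sd` on each instrument-strength component, `N(0,
#' beta_sd^2)` on each causal effect, `N(0, delta_sd^2)` on each confounder
#' loading, `N(0, V_sd^2)` on each Study-B random effect, and an
#' inverse-gamma distribution with shape `sigma_shape` and scale
#' `sigma_scale` on every residual standard deviation (on the standard
#' deviation itself, not the variance).
#'
#' @param alpha_sd Prior sd of every instrument-strength component.
#' @param beta_sd Prior sd of the causal effects.
#' @param sigma_shape,sigma_scale Inverse-gamma shape and scale for all
#'   residual standard deviations.
#' @param V_sd Prior sd of each random-effect intercept.
#' @param delta_sd Prior sd of each confounder loading.
#' @return An object of class `mr_priors`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(alpha_sd = 0.3, beta_sd = 10,
                       sigma_shape = 3, sigma_scale = 2,
                       V_sd = 1, delta_sd = 1) {
  vals <- c(alpha_sd = alpha_sd, beta_sd = beta_sd,
            sigma_shape = sigma_shape, sigma_scale = sigma_scale,
            V_sd = V_sd, delta_sd = delta_sd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive and finite")
  structure(as.list(vals), class = "mr_priors")
}

#' @export
print.mr_priors <- function(x, ...) {
  cat("Priors:\n")
  cat(sprintf("  alpha  ~ N(0, %.3g^2)   beta ~ N(0, %.3g^2)   delta ~ N(0, %.3g^2)\n",
              x$alpha_sd, x$beta_sd, x$delta_sd))
  cat(sprintf("  V      ~ N(0, %.3g^2)   sigma ~ Inv-Gamma(%.3g, %.3g)\n",
              x$V_sd, x$sigma_shape, x$sigma_scale))
  invisible(x)
}

# flat name vector for the structural parameter block, in sampler order
param_names <- function(layout) {
  c(if (layout$L) sprintf("alpha1[%d]", seq_len(layout$L)),
    if (layout$K) sprintf("alpha2[%d]", seq_len(layout$K)),
    if (layout$M) sprintf("alpha31[%d]", seq_len(layout$M)),
    if (layout$M) sprintf("alpha32[%d]", seq_len(layout$M)),
    "beta1", "beta2",
    "delta_X1", "delta_X2", "delta_Y1", "delta_Y2",
    "V_X1", "V_X2", "V_Y1", "V_Y2",
    "sigma_X1A", "sigma_X2A", "sigma_Y1A", "sigma_Y2A",
    "sigma_X1B", "sigma_X2B", "sigma_Y1B", "sigma_Y2B")
}
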