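#' Simulation configuration
#'
#' Describes one cell of the simulation grid: instrument layout, total
#' sample size and exposure missing rate, the common instrument strength,
#' causal effect, confounder loading and residual scale, the genotype
#' dosage distribution, and the uniform bounds of the Study-B random
#' effects.
#'
#' Genotypes are i.i.d. Binomial(2, `genotype_p`) dosages.  The Study-B
#' sample size is `nB = round(n_total * missing_rate)` (half up) and
#' `nA = n_total - nB`; configurations where rounding moves the realised
#' missing rate by more than one percentage point are rejected, as are
#' degenerate splits with an empty study.
#'
#' @param layout An [instrument_layout()]; defaults to blocks of 15, 15, 5.
#' @param n_total Combined sample size nA + nB.
#' @param missing_rate Fraction of individuals with missing exposures
#'   (Study B), strictly between 0 and 1.
#' @param alpha_level Common magnitude of every instrument-strength
#'   component (all positive).
#' @param beta_level Common causal effect beta1 = beta2.
#' @param delta_level Common confounder loading for all four equations.
#' @param sigma_level Common residual standard deviation for all equations
#'   and both studies.
#' @param genotype_p Binomial success probability of the dosage distribution.
#' @param V_low,V_high Bounds of the uniform distribution from which the
#'   four Study-B random effects are drawn afresh for every replicate.
#' @param n_replicates Number of replicate datasets in a simulation study.
#' @param seed Base seed; replicate r uses an independent substream derived
#'   from `(seed, r)` so replicates can be generated in any order.
#' @return An object of class `mr_sim_config`.
#' @examples
#' cfg <- sim_config(n_total = 400, missing_rate = 0.5,
#'                   alpha_level = 0.3, beta_level = 0.3)
#' @export
sim_config <- function(layout = instrument_layout(15, 15, 5),
                       n_total = 400, missing_rate = 0.5,
                       alpha_level = 0.3, beta_level = 0.3,
                       delta_level = 1, sigma_level = 0.1,
                       genotype_p = 0.3,
                       V_low = -0.5, V_high = 0.5,
                       n_replicates = 200, seed = 1L) {
  stopifnot(inherits(layout, "mr_layout"))
  if (missing_rate <= 0 || missing_rate >= 1)
    stop("missing_rate must lie strictly between 0 and 1")
  if (genotype_p <= 0 || genotype_p >= 1)
    stop("genotype_p must lie strictly between 0 and 1")
  if (V_high < V_low) stop("V_high must be >= V_low")
  nB <- floor(n_total * missing_rate + 0.5)  # round half up
  nA <- n_total - nB
  if (nA < 1 || nB < 1)
    stop(sprintf("degenerate split: nA = %d, nB = %d", nA, nB))
  if (abs(nB / n_total - missing_rate) > 0.01)
    stop("rounding the Study-B size changes the missing rate by more than 1%")
  structure(list(layout = layout, n_total = as.integer(n_total),
                 missing_rate = missing_rate, nA = as.integer(nA),
                 nB = as.integer(nB), alpha_level = alpha_level,
                 beta_level = beta_level, delta_level = delta_level,
                 sigma_level = sigma_level, genotype_p = genotype_p,
                 V_low = V_low, V_high = V_high,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' @export
print.mr_sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation configuration: n = %d (nA = %d, nB = %d, ",
                     "missing %.0f%%), alpha = %.3g, beta = %.3g\n"),
              x$n_total, x$nA, x$nB, 100 * x$missing_rate,
              x$alpha_level, x$beta_level))
  invisible(x)
}

# deterministic 31-bit substream seed from (base seed, replicate counter);
# order-independent across replicates
substream_seed <- function(seed, replicate) {
  s <- (as.double(seed) %% 2147483647) + 1
  r <- as.double(replicate) %% 2147483647
  as.integer((s * 48271 + r * 69621 + 2027) %% 2147483647)
}

#' Draw a genotype dosage matrix
#'
#' Entries are independent Binomial(2, p) dosages in \{0, 1, 2\}.
#'
#' @param n Number of individuals (rows).
#' @param m Number of variants (columns).
#' @param p Binomial success probability, strictly inside (0, 1).
#' @return An `n` by `m` integer matrix.
#' @export
draw_genotypes <- function(n, m, p = 0.3) {
  if (n < 1 || m < 1) stop("n and m must be at least 1")
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  matrix(rbinom(n * m, 2L, p), nrow = n, ncol = m)
}

#' Simulate one study from the structural model
#'
#' Draws the latent confounder U ~ N(0, 1) per individual, genotypes from
#' Binomial(2, `genotype_p`), then exposures and outcomes from the
#' conditional normal structural equations of the given study (Study B adds
#' its random-effect intercepts and uses the Study-B residual scales).  For
#' Study B the generated exposures are then masked as missing; with
#' `keep_truth = TRUE` the generated values are retained in the
#' `"truth"` attribute for diagnostics only.
#'
#' @param params An [structural_params()] object.
#' @param n Number of individuals.
#' @param study `"A"` or `"B"`.
#' @param genotype_p Dosage distribution parameter.
#' @param keep_truth Retain masked exposures (and U) as an attribute.
#' @return An `mr_study`.
#' @export
simulate_study <- function(params, n, study = c("A", "B"), genotype_p = 0.3,
                           keep_truth = FALSE) {
  study <- match.arg(study)
  stopifnot(inherits(params, "mr_params"))
  lay <- params$layout
  U <- rnorm(n)
  draw_block <- function(m) {
    if (m > 0) draw_genotypes(n, m, genotype_p) else matrix(0L, n, 0L)
  }
  Z1 <- draw_block(lay$L); Z2 <- draw_block(lay$K); Z3 <- draw_block(lay$M)
  skel <- study_dataset(study, Z1, Z2, Z3, Y1 = numeric(n), Y2 = numeric(n))
  sig <- if (study == "B") params$sigma_B else params$sigma_A
  mu <- conditional_means(params, skel, U)
  X1 <- rnorm(n, mu$X1, sig[["X1"]])
  X2 <- rnorm(n, mu$X2, sig[["X2"]])
  muY <- conditional_means(params, skel, U, X1 = X1, X2 = X2)
  Y1 <- rnorm(n, muY$Y1, sig[["Y1"]])
  Y2 <- rnorm(n, muY$Y2, sig[["Y2"]])
  out <- if (study == "B")
    study_dataset("B", Z1, Z2, Z3, Y1 = Y1, Y2 = Y2)
  else
    study_dataset("A", Z1, Z2, Z3, X1 = X1, X2 = X2, Y1 = Y1, Y2 = Y2)
  if (keep_truth)
    attr(out, "truth") <- list(U = U, X1 = X1, X2 = X2)
  out
}

#' Simulate a combined two-study replicate dataset
#'
#' Builds the structural parameters from the configuration levels (all
#' instrument strengths equal to `alpha_level`, causal effects
#' `beta_level`, loadings `delta_level`, residual scales `sigma_level`),
#' draws a fresh 4-vector of Study-B random effects from
#' Uniform(`V_low`, `V_high`), and simulates Study A of size nA (exposures
#' observed) and Study B of size nB (exposures masked).  Deterministic given
#' `(config$seed, replicate)`.
#'
#' @param config An [sim_config()].
#' @param replicate Replicate counter (1-based).
#' @param keep_truth Retain masked exposures and latent confounders as
#'   attributes (diagnostics only).
#' @return An `mr_data` object carrying the generating [structural_params()]
#'   in its `"truth"` attribute.
#' @export
simulate_combined <- function(config, replicate = 1L, keep_truth = FALSE) {
  stopifnot(inherits(config, "mr_sim_config"))
  set.seed(substream_seed(config$seed, replicate))
  V <- runif(4, config$V_low, config$V_high)
  params <- structural_params(
    config$layout,
    alpha1 = config$alpha_level, alpha2 = config$alpha_level,
    alpha31 = config$alpha_level, alpha32 = config$alpha_level,
    beta1 = config$beta_level, beta2 = config$beta_level,
    delta = config$delta_level,
    sigma_A = config$sigma_level, sigma_B = config$sigma_level,
    V = V)
  A <- simulate_study(params, config$nA, "A", config$genotype_p,
                      keep_truth = keep_truth)
  B <- simulate_study(params, config$nB, "B", config$genotype_p,
                      keep_truth = keep_truth)
  out <- combined_dataset(A, B)
  attr(out, "truth") <- params
  out
}
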