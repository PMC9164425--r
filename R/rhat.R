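#' Split-chain potential scale reduction
#'
#' Plain (non-rank-normalised) split-\eqn{\hat R}: each chain is split in
#' half, and the statistic compares the between- and within-sequence
#' variances of the resulting half-chains.  Values near 1 indicate that the
#' chains have mixed; values above about 1.1 flag non-convergence.
#'
#' @param x A matrix of draws for one parameter, iterations in rows and
#'   chains in columns (at least 2 chains and 4 iterations).
#' @return The split-chain potential-scale-reduction statistic.  When the
#'   pooled draws have zero variance the statistic is 1 by convention.
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(4000), 1000, 4))
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("rhat needs at least 2 chains")
  if (nrow(x) < 4L) stop("rhat needs at least 4 iterations per chain")
  n <- 2L * (nrow(x) %/% 2L)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n / 2L), j], x[(n / 2L + 1L):n, j])
  }))
  if (var(as.vector(halves)) == 0) return(1)
  m <- ncol(halves); len <- nrow(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2L, var))
  B <- len * var(mu)
  if (W == 0) return(Inf)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Posterior summaries of a draw matrix
#'
#' Equal-tailed credible intervals from empirical quantiles of the pooled
#' draws, with posterior mean, standard deviation and median.
#'
#' @param draws Matrix of pooled draws, iterations in rows, parameters in
#'   columns (a vector is treated as one parameter).
#' @param level Credible level, strictly inside (0, 1).
#' @return A data frame with one row per parameter: `mean`, `sd`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("no draws supplied")
  a <- (1 - level) / 2
  qs <- t(apply(draws, 2L, quantile, probs = c(a, 0.5, 1 - a), names = FALSE))
  out <- data.frame(mean = colMeans(draws), sd = apply(draws, 2L, sd),
                    median = qs[, 2L], lower = qs[, 1L], upper = qs[, 3L])
  rownames(out) <- colnames(draws)
  out
}
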