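#' Partition a combined dataset into equal subsets, stratified by study
#'
#' Randomly divides Study A and Study B separately into `J` equal parts and
#' pairs them, so every subset has exactly the missing rate of the full
#' data.  Both study sizes must be divisible by `J`.
#'
#' @param data An `mr_data` object.
#' @param J Number of subsets.
#' @param seed Seed for the random assignment.
#' @return A list with components `subsets` (list of `J` `mr_data` objects)
#'   and `plan` (subset count, per-subset size and the row assignments).
#' @export
partition_combined <- function(data, J, seed = 1L) {
  stopifnot(inherits(data, "mr_data"))
  J <- as.integer(J)
  if (J < 1L) stop("J must be at least 1")
  nA <- data$study_A$n; nB <- data$study_B$n
  if (nA %% J != 0L || nB %% J != 0L)
    stop(sprintf("study sizes (nA = %d, nB = %d) are not divisible by J = %d",
                 nA, nB, J))
  set.seed(substream_seed(seed, 777L))
  grp <- function(n) sample(rep(seq_len(J), each = n / J))
  gA <- grp(nA); gB <- grp(nB)
  take <- function(s, idx) {
    study_dataset(s$study,
                  s$Z1[idx, , drop = FALSE], s$Z2[idx, , drop = FALSE],
                  s$Z3[idx, , drop = FALSE],
                  X1 = if (has_exposures(s)) s$X1[idx],
                  X2 = if (has_exposures(s)) s$X2[idx],
                  Y1 = s$Y1[idx], Y2 = s$Y2[idx])
  }
  subsets <- lapply(seq_len(J), function(j) {
    combined_dataset(take(data$study_A, which(gA == j)),
                     take(data$study_B, which(gB == j)))
  })
  list(subsets = subsets,
       plan = list(J = J, q = (nA + nB) %/% J,
                   assignment_A = gA, assignment_B = gB, seed = seed))
}

#' Aggregate subset posteriors by recentring
#'
#' Implements the divide-and-combine rule: with subset posterior mean
#' vectors \eqn{\hat\mu_j} and their average \eqn{\hat\mu}, every draw
#' \eqn{\theta} from subset \eqn{j} is recentred to
#' \eqn{\theta - \hat\mu_j + \hat\mu} and the pooled recentred draws, with
#' equal subset weight, represent the aggregated posterior.  Their mean
#' equals the grand mean of the subset means by construction.
#'
#' Each subset sees only \eqn{q = n/J} observations, so an individual
#' subset posterior is roughly \eqn{J} times wider (in variance) than the
#' full-data posterior.  With `scale_correct = TRUE` (default) the draws
#' are therefore also rescaled about their subset means by \eqn{1/\sqrt{J}}
#' before pooling, which matches the aggregated second moment to the
#' full-data posterior (whose variance difference vanishes at rate faster
#' than \eqn{1/n}) while leaving the grand mean untouched.
#' `scale_correct = FALSE` pools the plainly recentred draws.
#'
#' @param fits A list of `bmr` fits (or of draw matrices with identical
#'   column names), one per subset.
#' @param pars Parameters to aggregate; default all shared structural
#'   parameters.  Latent per-individual quantities are never aggregated.
#' @param scale_correct Rescale subset draws by \eqn{1/\sqrt{J}} about
#'   their subset means so the aggregated variance matches the full-data
#'   posterior.
#' @return An object of class `bmr_agg` with components `draws` (pooled
#'   recentred draws), `grand_mean`, `subset_means` (J x p matrix) and `J`.
#' @export
aggregate_fits <- function(fits, pars = NULL, scale_correct = TRUE) {
  if (!length(fits)) stop("no subset fits supplied")
  mats <- lapply(fits, function(f) {
    if (inherits(f, "bmr")) as.matrix(f) else as.matrix(f)
  })
  cn <- colnames(mats[[1L]])
  if (is.null(cn)) stop("draws must carry parameter names")
  for (m in mats) {
    if (!identical(colnames(m), cn))
      stop("subset fits report different parameter sets")
  }
  if (!is.null(pars)) {
    missing <- setdiff(pars, cn)
    if (length(missing))
      stop("unknown parameters: ", paste(missing, collapse = ", "))
    mats <- lapply(mats, function(m) m[, pars, drop = FALSE])
    cn <- pars
  }
  if (length(unique(vapply(mats, nrow, integer(1)))) != 1L)
    stop("subsets must contribute equal numbers of draws")
  subset_means <- do.call(rbind, lapply(mats, colMeans))
  grand_mean <- colMeans(subset_means)
  J <- length(mats)
  shrink <- if (scale_correct) 1 / sqrt(J) else 1
  recentred <- lapply(seq_len(J), function(j) {
    centred <- sweep(mats[[j]], 2L, subset_means[j, ])
    sweep(shrink * centred, 2L, grand_mean, "+")
  })
  structure(list(draws = do.call(rbind, recentred),
                 grand_mean = grand_mean, subset_means = subset_means,
                 J = J, scale_correct = scale_correct),
            class = "bmr_agg")
}

#' @export
print.bmr_agg <- function(x, ...) {
  cat(sprintf("Aggregated posterior from %d subset fits\n", x$J))
  show <- intersect(c("beta1", "beta2"), names(x$grand_mean))
  if (length(show)) {
    cat("  grand means:",
        paste(sprintf("%s = %.4f", show, x$grand_mean[show]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.bmr_agg <- function(object, level = 0.95, ...) {
  posterior_summary(object$draws, level)
}

#' @export
as.matrix.bmr_agg <- function(x, pars = NULL, ...) {
  if (is.null(pars)) x$draws else x$draws[, pars, drop = FALSE]
}

#' @export
plot.bmr_agg <- function(x, pars = c("beta1", "beta2"), ...) {
  k <- posterior_kde2d(x$draws[, pars[1L]], x$draws[, pars[2L]])
  graphics::contour(k$x, k$y, k$z, xlab = pars[1L], ylab = pars[2L], ...)
  invisible(x)
}

#' Two-dimensional Gaussian kernel density estimate of posterior draws
#'
#' Gaussian product kernel with a Scott-type per-dimension rule-of-thumb
#' bandwidth (draw standard deviation times \eqn{N^{-1/6}}), evaluated on a
#' regular grid wide enough that the trapezoid integral of the density is
#' close to 1.  Kernel evaluation is delegated to [MASS::kde2d()].
#'
#' @param x,y Equal-length draw vectors (at least 50 draws).
#' @param n Grid resolution per axis.
#' @param h Optional length-2 bandwidth override (kernel standard
#'   deviations).
#' @param lims Optional grid limits `c(xmin, xmax, ymin, ymax)`.
#' @return A list with grid vectors `x`, `y`, the density matrix `z` and
#'   the bandwidths `h` used.
#' @export
posterior_kde2d <- function(x, y, n = 101L, h = NULL, lims = NULL) {
  if (length(x) != length(y)) stop("draw vectors must have equal length")
  if (length(x) < 50L) stop("at least 50 draws are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance draws: kernel bandwidth degenerates")
  if (is.null(h)) h <- c(sd(x), sd(y)) * length(x)^(-1 / 6)
  if (any(h <= 0)) stop("bandwidths must be positive")
  if (is.null(lims))
    lims <- c(range(x) + c(-3, 3) * h[1L], range(y) + c(-3, 3) * h[2L])
  k <- MASS::kde2d(x, y, h = 4 * h, n = n, lims = lims)
  k$h <- h
  k
}
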