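#' Replicate simulation study over a configuration grid
#'
#' For every configuration, simulates `n_replicates` combined datasets and
#' estimates both causal effects with the Bayesian random-effect model
#' and/or the two-sample IVW comparator, then evaluates four metrics per
#' configuration, method and effect: mean and standard deviation of the
#' point estimates (posterior mean for the Bayesian method), coverage of
#' the 95% intervals at the true effect, and power (proportion of intervals
#' excluding zero; reported only for non-zero true effects).
#'
#' A Bayesian replicate whose structural parameters show split-\eqn{\hat R}
#' above 1.1 is refit once with doubled iterations and excluded (with a
#' count in the `"n_excluded"` attribute) if still non-convergent.
#'
#' @param grid A list of [sim_config()] objects (a single config is
#'   accepted).
#' @param settings [mcmc_settings()] for the Bayesian fits.
#' @param methods Subset of `c("bayesian", "ivw")`.
#' @param n_replicates Optional override of each configuration's replicate
#'   count (reduced-replicate smoke runs).
#' @param priors Priors for the Bayesian fits.
#' @return A data frame of class `mr_metrics` keyed by
#'   (missing_rate, alpha, beta, method, effect) with columns
#'   mean, sd, coverage, power, n_replicates.
#' @export
run_small_study <- function(grid, settings = mcmc_settings(),
                            methods = c("bayesian", "ivw"),
                            n_replicates = NULL, priors = prior_spec()) {
  if (inherits(grid, "mr_sim_config")) grid <- list(grid)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  excluded <- 0L
  for (cfg in grid) {
    R <- if (is.null(n_replicates)) cfg$n_replicates else as.integer(n_replicates)
    est <- list()  # method:effect -> vector / interval matrix
    for (m in methods) for (e in 1:2) {
      est[[paste(m, e)]] <- list(point = numeric(0),
                                 ci = matrix(numeric(0), ncol = 2L))
    }
    for (r in seq_len(R)) {
      d <- simulate_combined(cfg, r)
      if ("ivw" %in% methods) {
        for (e in 1:2) {
          iv <- ivw(d, pair = e)
          key <- paste("ivw", e)
          est[[key]]$point <- c(est[[key]]$point, iv$beta_hat)
          est[[key]]$ci <- rbind(est[[key]]$ci, unname(iv$ci95))
        }
      }
      if ("bayesian" %in% methods) {
        st <- settings
        st$seed <- substream_seed(settings$seed, 4000L + 131L * r)
        fit <- bmr(d, priors = priors, settings = st)
        if (max(fit$rhat, na.rm = TRUE) > 1.1) {
          st$iter <- 2L * st$iter; st$warmup <- 2L * st$warmup
          st$seed <- substream_seed(settings$seed, 8000L + 131L * r)
          fit <- bmr(d, priors = priors, settings = st)
        }
        if (max(fit$rhat, na.rm = TRUE) > 1.1) {
          excluded <- excluded + 1L
          next
        }
        for (e in 1:2) {
          p <- paste0("beta", e)
          key <- paste("bayesian", e)
          est[[key]]$point <- c(est[[key]]$point, fit$summary[p, "mean"])
          est[[key]]$ci <- rbind(est[[key]]$ci,
                                 c(fit$summary[p, "lower"],
                                   fit$summary[p, "upper"]))
        }
      }
    }
    for (m in methods) for (e in 1:2) {
      s <- est[[paste(m, e)]]
      if (!length(s$point)) next
      row <- cbind(data.frame(missing_rate = cfg$missing_rate,
                              alpha = cfg$alpha_level, beta = cfg$beta_level,
                              method = m, effect = paste0("beta", e)),
                   metrics_row(s$point, s$ci, cfg$beta_level))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  class(out) <- c("mr_metrics", class(out))
  out
}

#' Large-study experiment: full-data fit versus divide-and-combine
#'
#' Simulates a single large combined dataset from `config`, fits the model
#' on the full data for `J = 1` and, for every other `J`, partitions the
#' data into `J` study-stratified subsets, fits each subset independently
#' and aggregates the recentred subset posteriors.  Returns, per `J`, the
#' (grand) posterior means of the causal effects and a 2-D Gaussian KDE of
#' their joint posterior for contour overlays.
#'
#' @param config An [sim_config()]; its `n_total` should be divisible by
#'   every `J`.
#' @param J_list Integer vector of subset counts (1 = full-data fit).
#' @param settings [mcmc_settings()] used for every fit; subset j of a
#'   partition runs on its own seed substream.
#' @param priors Priors for the fits.
#' @param kde_n KDE grid resolution.
#' @return A list of class `mr_large_study`: per `J`, a list with the `bmr`
#'   fit or `bmr_agg` aggregate, the grand means of (beta1, beta2), their
#'   distance to the true effect, and the KDE grid.
#' @export
run_large_study <- function(config, J_list = c(1L, 5L, 50L),
                            settings = mcmc_settings(),
                            priors = prior_spec(), kde_n = 101L) {
  stopifnot(inherits(config, "mr_sim_config"))
  d <- simulate_combined(config, 1L)
  res <- list()
  for (J in as.integer(J_list)) {
    if (J == 1L) {
      st <- settings
      st$seed <- substream_seed(settings$seed, 600L)
      fit <- bmr(d, priors = priors, settings = st)
      draws <- as.matrix(fit, pars = c("beta1", "beta2"))
      gm <- colMeans(draws)
      obj <- fit
    } else {
      parts <- partition_combined(d, J, seed = substream_seed(settings$seed, J))
      fits <- lapply(seq_len(J), function(j) {
        st <- settings
        st$seed <- substream_seed(settings$seed, 1000L * J + j)
        bmr(parts$subsets[[j]], priors = priors, settings = st)
      })
      obj <- aggregate_fits(fits)
      draws <- obj$draws[, c("beta1", "beta2")]
      gm <- obj$grand_mean[c("beta1", "beta2")]
    }
    res[[as.character(J)]] <- list(
      J = J, fit = obj, grand_mean = gm,
      error = gm - config$beta_level,
      kde = posterior_kde2d(draws[, 1L], draws[, 2L], n = kde_n))
  }
  structure(list(results = res, config = config, truth = config$beta_level),
            class = "mr_large_study")
}

#' @export
print.mr_large_study <- function(x, ...) {
  cat("Large-study divide-and-combine experiment\n")
  for (r in x$results) {
    cat(sprintf("  J = %2d: beta1 = %.4f, beta2 = %.4f\n",
                r$J, r$grand_mean[["beta1"]], r$grand_mean[["beta2"]]))
  }
  cat(sprintf("  true effects: beta1 = beta2 = %.3g\n", x$truth))
  invisible(x)
}

#' Overlay the joint-posterior contours of a large-study experiment
#'
#' @param x An `mr_large_study` result.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.mr_large_study <- function(x, ...) {
  cols <- c("red", "orange", "blue", "darkgreen")
  xr <- range(unlist(lapply(x$results, function(r) r$kde$x)))
  yr <- range(unlist(lapply(x$results, function(r) r$kde$y)))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "beta1", ylab = "beta2")
  for (i in seq_along(x$results)) {
    k <- x$results[[i]]$kde
    graphics::contour(k$x, k$y, k$z, add = TRUE,
                      col = cols[(i - 1L) %% length(cols) + 1L], ...)
  }
  graphics::points(x$truth, x$truth, pch = 16)
  graphics::legend("topright", legend = sprintf("J = %d",
                   vapply(x$results, `[[`, integer(1), "J")),
                   col = cols[seq_along(x$results)], lty = 1, bty = "n")
  invisible(x)
}
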