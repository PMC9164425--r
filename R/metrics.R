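#' Coverage and power of interval estimates
#'
#' `coverage_prop` is the proportion of intervals containing the true value;
#' `power_prop` the proportion not containing zero.  Intervals are treated
#' as closed, so a truth lying exactly on an endpoint counts as covered.
#'
#' @param intervals A two-column matrix or data frame of interval endpoints
#'   (lower, upper), one row per replicate.
#' @param truth True parameter value.
#' @return A proportion in \[0, 1\].
#' @examples
#' coverage_prop(rbind(c(-1, 1), c(2, 3)), 0)  # 0.5
#' power_prop(rbind(c(-1, 1), c(2, 3)))        # 0.5
#' @export
coverage_prop <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) < 1L) stop("empty interval list")
  if (ncol(intervals) != 2L) stop("intervals must have two columns")
  mean(intervals[, 1L] <= truth & truth <= intervals[, 2L])
}

#' @rdname coverage_prop
#' @export
power_prop <- function(intervals) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) < 1L) stop("empty interval list")
  if (ncol(intervals) != 2L) stop("intervals must have two columns")
  mean(intervals[, 1L] > 0 | intervals[, 2L] < 0)
}

# one metrics row from replicate point estimates and intervals
metrics_row <- function(est, intervals, truth) {
  out <- data.frame(mean = mean(est), sd = sd(est),
                    coverage = coverage_prop(intervals, truth),
                    power = if (truth != 0) power_prop(intervals) else NA_real_,
                    n_replicates = length(est))
  out
}
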