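#' Individual-level data for one study
#'
#' Bundles genotype dosage matrices for the three instrument blocks with the
#' exposure and outcome vectors of one study.  Study A carries observed
#' exposures; Study B follows the missing-exposure pattern, in which both
#' exposures are absent while outcomes remain observed.
#'
#' @param study Study label, `"A"` or `"B"`.
#' @param Z1,Z2,Z3 Dosage matrices (entries in \{0, 1, 2\}) with `L`, `K` and
#'   `M` columns.
#' @param X1,X2 Exposure vectors, or `NULL` when the study lacks exposure
#'   data.  Either both are present or both absent.
#' @param Y1,Y2 Outcome vectors (always observed).
#' @return An object of class `mr_study`.
#' @export
study_dataset <- function(study, Z1, Z2, Z3, X1 = NULL, X2 = NULL, Y1, Y2) {
  study <- match.arg(study, c("A", "B"))
  Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2); Z3 <- as.matrix(Z3)
  n <- nrow(Z1)
  if (n < 1L) stop("a study must contain at least one individual")
  if (nrow(Z2) != n || nrow(Z3) != n)
    stop("instrument blocks must have the same number of rows")
  for (nm in c("Z1", "Z2", "Z3")) {
    Z <- get(nm)
    if (ncol(Z) > 0L && !all(Z %in% c(0, 1, 2)))
      stop(sprintf("dosage entries of %s must be 0, 1 or 2", nm))
  }
  if (is.null(X1) != is.null(X2))
    stop("X1 and X2 must be both present or both absent")
  if (!is.null(X1)) {
    X1 <- as.numeric(X1); X2 <- as.numeric(X2)
    if (length(X1) != n || length(X2) != n)
      stop("exposure vectors must match the number of genotype rows")
  }
  Y1 <- as.numeric(Y1); Y2 <- as.numeric(Y2)
  if (length(Y1) != n || length(Y2) != n)
    stop("outcome vectors must match the number of genotype rows")
  structure(list(study = study, n = n, Z1 = Z1, Z2 = Z2, Z3 = Z3,
                 X1 = X1, X2 = X2, Y1 = Y1, Y2 = Y2),
            class = "mr_study")
}

has_exposures <- function(x) !is.null(x$X1)

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("Study %s: n = %d, instruments %d + %d + %d, exposures %s\n",
              x$study, x$n, ncol(x$Z1), ncol(x$Z2), ncol(x$Z3),
              if (has_exposures(x)) "observed" else "missing"))
  invisible(x)
}

#' Combine a fully observed study with an exposure-missing study
#'
#' @param study_A An `mr_study` with observed exposures.
#' @param study_B An `mr_study` with absent exposures.
#' @return An object of class `mr_data` with components `study_A`,
#'   `study_B` and `missing_rate` = nB / (nA + nB).
#' @export
combined_dataset <- function(study_A, study_B) {
  stopifnot(inherits(study_A, "mr_study"), inherits(study_B, "mr_study"))
  if (!has_exposures(study_A))
    stop("study_A must carry observed exposures")
  if (has_exposures(study_B))
    stop("study_B must have exposures absent")
  dims <- function(s) c(ncol(s$Z1), ncol(s$Z2), ncol(s$Z3))
  if (!identical(dims(study_A), dims(study_B)))
    stop("instrument layouts of the two studies differ")
  structure(list(study_A = study_A, study_B = study_B,
                 missing_rate = study_B$n / (study_A$n + study_B$n)),
            class = "mr_data")
}

#' @export
print.mr_data <- function(x, ...) {
  cat(sprintf("Combined two-study dataset: nA = %d, nB = %d (missing rate %.1f%%)\n",
              x$study_A$n, x$study_B$n, 100 * x$missing_rate))
  invisible(x)
}

layout_of <- function(data) {
  s <- if (inherits(data, "mr_data")) data$study_A else data
  instrument_layout(ncol(s$Z1), ncol(s$Z2), ncol(s$Z3))
}

study_to_df <- function(s) {
  lab <- function(base, p) if (p > 0) sprintf("%s_%d", base, seq_len(p)) else character()
  df <- data.frame(study = rep(s$study, s$n))
  Z <- cbind(s$Z1, s$Z2, s$Z3)
  colnames(Z) <- c(lab("Z1", ncol(s$Z1)), lab("Z2", ncol(s$Z2)), lab("Z3", ncol(s$Z3)))
  df <- cbind(df, as.data.frame(Z))
  df$X1 <- if (has_exposures(s)) s$X1 else NA_real_
  df$X2 <- if (has_exposures(s)) s$X2 else NA_real_
  df$Y1 <- s$Y1
  df$Y2 <- s$Y2
  df
}

#' Write and read combined datasets as delimited text
#'
#' The on-disk format is a single CSV table with a `study` column, dosage
#' columns `Z1_1..Z1_L`, `Z2_1..Z2_K`, `Z3_1..Z3_M`, exposures `X1`, `X2`
#' (empty fields where missing) and outcomes `Y1`, `Y2`.
#'
#' @param data An `mr_data` object.
#' @param path File path.
#' @return `write_combined` returns `path` invisibly; `read_combined`
#'   returns an `mr_data` object.
#' @export
write_combined <- function(data, path) {
  stopifnot(inherits(data, "mr_data"))
  df <- rbind(study_to_df(data$study_A), study_to_df(data$study_B))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_combined
#' @export
read_combined <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  grab <- function(d, base) {
    cols <- grep(sprintf("^%s_\\d+$", base), names(d), value = TRUE)
    cols <- cols[order(as.integer(sub(".*_", "", cols)))]
    as.matrix(d[, cols, drop = FALSE])
  }
  mk <- function(d, lab) {
    expos <- !all(is.na(d$X1))
    study_dataset(lab, grab(d, "Z1"), grab(d, "Z2"), grab(d, "Z3"),
                  X1 = if (expos) d$X1, X2 = if (expos) d$X2,
                  Y1 = d$Y1, Y2 = d$Y2)
  }
  combined_dataset(mk(df[df$study == "A", , drop = FALSE], "A"),
                   mk(df[df$study == "B", , drop = FALSE], "B"))
}

#' Read a prior specification and instrument layout from a YAML file
#'
#' Recognised keys: `L`, `K`, `M` and any field of [prior_spec()].
#'
#' @param path Path to a YAML file.
#' @return A list with components `layout` (or `NULL`) and `priors`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layout <- if (all(c("L", "K", "M") %in% names(cfg)))
    instrument_layout(cfg$L, cfg$K, cfg$M)
  pargs <- cfg[intersect(names(cfg), names(formals(prior_spec)))]
  list(layout = layout, priors = do.call(prior_spec, pargs))
}
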