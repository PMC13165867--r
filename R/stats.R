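#' Aggregate per-fold metric reports
#'
#' Computes, per metric column, the mean and the population standard
#' deviation (divide by n, not n-1): folds are treated as the full set of
#' measurements being summarized, not a sample from a larger population.
#'
#' @param fold_metrics data frame of numeric metric columns, one row per
#'   fold (at least two rows).
#' @return object of class \code{cv_summary} with named vectors \code{mean}
#'   and \code{std}, and \code{n_folds}.
#' @export
aggregate_folds <- function(fold_metrics) {
  fold_metrics <- as.data.frame(fold_metrics)
  num <- vapply(fold_metrics, is.numeric, logical(1))
  fold_metrics <- fold_metrics[, num, drop = FALSE]
  if (nrow(fold_metrics) < 2)
    stop("need at least 2 folds to aggregate, got ", nrow(fold_metrics))
  mu <- vapply(fold_metrics, mean, numeric(1))
  pop_sd <- vapply(fold_metrics, function(x) {
    m <- mean(x)
    sqrt(mean((x - m)^2))
  }, numeric(1))
  structure(list(mean = mu, std = pop_sd, n_folds = nrow(fold_metrics)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, digits = 4, ...) {
  cat("Cross-validation summary (", x$n_folds, " folds)\n", sep = "")
  tab <- data.frame(mean = round_half_up(x$mean, digits),
                    pop_std = round_half_up(x$std, digits))
  print(format(tab, nsmall = digits))
  invisible(x)
}

#' @export
summary.cv_summary <- function(object, ...) {
  cat("Aggregate over", object$n_folds, "folds (mean +/- population std):\n")
  for (nm in names(object$mean))
    cat(sprintf("  %-10s %s +/- %s\n", nm,
                format_fixed(object$mean[[nm]]),
                format_fixed(object$std[[nm]])))
  if (!is.null(object$fold_metrics)) {
    cat("Per-fold means:\n")
    print(object$fold_metrics, row.names = FALSE)
  }
  invisible(object)
}

# Round half away from zero (so 0.91785 -> 0.9179 at 4 digits), immune to
# the bankers'-rounding surprises of base round() on these magnitudes.
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a metric at fixed decimal places
#'
#' Serializes with round-half-up at \code{digits} decimals, the convention
#' used for all reported tables (e.g. 0.91785 prints as "0.9179").
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return character vector.
#' @export
format_fixed <- function(x, digits = 4) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Paired two-sided t-test on per-fold (or per-image) metrics
#'
#' Thin wrapper over \code{stats::t.test(paired = TRUE)} that additionally
#' flags the degenerate case of zero-variance differences (all pairs differ
#' by the same amount), where the statistic is undefined rather than
#' infinitely significant.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @return list of class \code{paired_comparison}: \code{mean_difference},
#'   \code{statistic}, \code{p_value}, \code{df}, \code{n},
#'   \code{degenerate}.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  # constant differences up to floating-point noise make t undefined
  degenerate <- stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))
  if (degenerate) {
    out <- list(mean_difference = mean(d), statistic = NA_real_,
                p_value = NA_real_, df = length(d) - 1L, n = length(d),
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    out <- list(mean_difference = unname(tt$estimate),
                statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter),
                n = length(d), degenerate = FALSE)
  }
  structure(out, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired two-sided t-test (n = ", x$n, ")\n", sep = "")
  cat("  mean difference:", format_fixed(x$mean_difference), "\n")
  if (x$degenerate) {
    cat("  degenerate: all differences identical; t undefined\n")
  } else {
    cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$statistic, x$df,
                x$p_value))
  }
  invisible(x)
}

#' Internal-vs-external validation report
#'
#' Quantifies the generalization gap between internal test performance and
#' an external cohort: absolute Dice drop, the same drop expressed in
#' percentage points (x 100), and the AUC drop.
#'
#' @param internal,external named lists or one-row data frames holding at
#'   least \code{dice} and \code{auc}.
#' @return list of class \code{external_validation}: both reports plus
#'   \code{dice_drop}, \code{dice_drop_pct_points}, \code{auc_drop}.
#' @export
external_validation_report <- function(internal, external) {
  internal <- as.list(internal); external <- as.list(external)
  for (nm in c("dice", "auc"))
    if (is.null(internal[[nm]]) || is.null(external[[nm]]))
      stop("both reports must contain '", nm, "'")
  dd <- internal$dice - external$dice
  structure(list(internal = internal, external = external,
                 dice_drop = dd, dice_drop_pct_points = 100 * dd,
                 auc_drop = internal$auc - external$auc),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation report\n")
  cat("  internal Dice:", format_fixed(x$internal$dice),
      " AUC:", format_fixed(x$internal$auc), "\n")
  cat("  external Dice:", format_fixed(x$external$dice),
      " AUC:", format_fixed(x$external$auc), "\n")
  cat("  Dice drop:", format_fixed(x$dice_drop),
      sprintf("(%.2f percentage points)", x$dice_drop_pct_points), "\n")
  cat("  AUC drop: ", format_fixed(x$auc_drop), "\n")
  invisible(x)
}

#' Load a bundled reference results table
#'
#' The package ships the published benchmark tables (per-fold
#' cross-validation metrics, external validation, and the preprocessing /
#' architecture / controlled-training comparisons) as CSV fixtures so the
#' aggregation and delta arithmetic can be checked against them.
#'
#' @param name one of \code{"cv_folds"}, \code{"external"},
#'   \code{"preprocessing"}, \code{"architecture"}, \code{"controlled"}.
#' @return data frame.
#' @export
reference_table <- function(name = c("cv_folds", "external", "preprocessing",
                                     "architecture", "controlled")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "imauseg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
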