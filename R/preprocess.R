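#' Flag distribution-tail outliers
#'
#' A record is an outlier when at least one structural variable falls in a
#' tail of the estimated (empirical, per-class) distribution of that
#' variable: strictly below the `lower_q` quantile or strictly above the
#' `upper_q` quantile, defaults 0.5% and 99.5%. Quantiles use linear
#' interpolation between order statistics (R type 7) within each class.
#'
#' @param table Feature table.
#' @param lower_q,upper_q Tail probabilities.
#' @return Object of class `outlier_report`: per-class/per-variable cutoffs,
#'   a logical `flagged` vector aligned with the table rows, the flagged
#'   variables per record, and per-class totals.
#' @export
flag_outliers <- function(table, lower_q = 0.005, upper_q = 0.995) {
  check_feature_table(table)
  stopifnot(lower_q > 0, upper_q < 1, lower_q < upper_q)
  vars <- feature_vars_of(table)
  n <- nrow(table)
  flagged <- rep(FALSE, n)
  which_vars <- vector("list", n)
  cutoffs <- list()
  for (cl in unique(table$label)) {
    rows <- which(table$label == cl)
    if (length(rows) < 10L) {
      warning(sprintf("class '%s' has %d records; too few to estimate %.1f%% tails, no flags",
                      cl, length(rows), 100 * lower_q), call. = FALSE)
      next
    }
    cut <- data.frame(variable = vars, lower = NA_real_, upper = NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(vars)) {
      x <- table[[vars[k]]][rows]
      q <- quantile(x, c(lower_q, upper_q), names = FALSE, type = 7)
      cut$lower[k] <- q[1]; cut$upper[k] <- q[2]
      out <- x < q[1] | x > q[2]
      flagged[rows[out]] <- TRUE
      for (i in rows[out]) which_vars[[i]] <- c(which_vars[[i]], vars[k])
    }
    cutoffs[[cl]] <- cut
  }
  totals <- tapply(flagged, table$label, sum)
  structure(list(cutoffs = cutoffs, flagged = flagged,
                 flagged_variables = which_vars,
                 totals = stats::setNames(as.integer(totals), names(totals)),
                 n = n, lower_q = lower_q, upper_q = upper_q),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d of %d records flagged (tails %.3f / %.3f)\n",
              sum(x$flagged), x$n, x$lower_q, x$upper_q))
  for (cl in names(x$totals))
    cat(sprintf("  %s: %d flagged\n", cl, x$totals[[cl]]))
  invisible(x)
}

#' Remove flagged outliers from a feature table
#'
#' @param table The feature table the report was built from.
#' @param report An [outlier_report][flag_outliers] for the same table.
#' @return The table without flagged records, original order preserved.
#' @export
remove_outliers <- function(table, report) {
  check_feature_table(table)
  if (!inherits(report, "outlier_report") || report$n != nrow(table))
    stop("report does not match table (row count differs)", call. = FALSE)
  out <- table[!report$flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance class sizes by subsampling the majority class
#'
#' Draws a simple random sample without replacement from the larger class
#' equal in size to the smaller class; the minority class is untouched.
#'
#' @param table Feature table with two classes.
#' @param seed Integer seed for the subsample.
#' @return Balanced feature table.
#' @export
balance_classes <- function(table, seed = 1L) {
  check_feature_table(table)
  sizes <- base::table(table$label)
  if (length(sizes) != 2L || any(sizes == 0))
    stop("need two non-empty classes to balance", call. = FALSE)
  if (sizes[1] == sizes[2]) return(table)
  minority <- names(sizes)[which.min(sizes)]
  majority <- names(sizes)[which.max(sizes)]
  maj_rows <- which(table$label == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_rows, min(sizes))))
  out <- table[sort(c(which(table$label == minority), keep_maj)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
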