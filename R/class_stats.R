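#' Shapiro-Wilk test of Gaussianity
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `statistic` (W) and `p.value`.
#' @export
test_gaussianity <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least 3 finite observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("sample is constant; Gaussianity test undefined", call. = FALSE)
  fit <- shapiro.test(x)
  list(statistic = unname(fit$statistic), p.value = fit$p.value)
}

#' Wilcoxon rank-sum comparison of location
#'
#' Two-sided rank-sum test between two samples: exact null distribution for
#' small tie-free samples, midranks with the tie-corrected normal
#' approximation otherwise. A rank test compares the whole location of the
#' distributions (a location-shift test), which under finite variance tracks
#' the difference in means.
#'
#' @param x,y Numeric samples with >= 2 observations each.
#' @return List with `statistic` (rank-sum W) and `p.value`.
#' @export
compare_location <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need >= 2 observations", call. = FALSE)
  fit <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(fit$statistic), p.value = fit$p.value)
}

#' Fligner-Killeen comparison of dispersion
#'
#' Rank-based test of homogeneity of variances on normal scores of centered
#' absolute deviations; the statistic is chi-squared with one degree of
#' freedom for two groups.
#'
#' @param x,y Numeric samples with >= 2 observations each.
#' @return List with `statistic` and `p.value`.
#' @export
compare_dispersion <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need >= 2 observations", call. = FALSE)
  fit <- fligner.test(list(x, y))
  list(statistic = unname(fit$statistic), p.value = fit$p.value)
}

#' Per-variable class comparison summary
#'
#' For each of the eleven structural variables: class means and SDs, a
#' Wilcoxon rank-sum p-value for location, a Fligner-Killeen p-value for
#' dispersion, and a Shapiro-Wilk Gaussianity p-value per class. Also
#' returns the per-class Pearson correlation matrix of the variables.
#'
#' @param table Feature table with exactly two classes, >= 2 records each.
#' @return List with `comparisons` (data frame, one row per variable) and
#'   `correlations` (named list of 11 x 11 matrices).
#' @export
summarize_by_class <- function(table) {
  check_feature_table(table)
  classes <- sort(unique(table$label))
  if (length(classes) != 2)
    stop("need exactly two classes to compare", call. = FALSE)
  if (any(base::table(table$label) < 2))
    stop("each class needs >= 2 records", call. = FALSE)
  vars <- feature_vars_of(table)
  display <- feature_variables()[vars]
  display[is.na(display)] <- vars[is.na(display)]
  a <- table[table$label == classes[1], ]
  b <- table[table$label == classes[2], ]
  shapiro_max <- 5000L  # stats::shapiro.test sample-size limit
  subsample <- function(x) if (length(x) > shapiro_max) x[seq_len(shapiro_max)] else x
  rows <- lapply(vars, function(v) {
    x <- a[[v]]; y <- b[[v]]
    shap <- function(z) tryCatch(test_gaussianity(subsample(z))$p.value,
                                 error = function(e) NA_real_)
    data.frame(
      variable = v, display = unname(display[v]),
      mean_1 = mean(x), mean_2 = mean(y), sd_1 = stats::sd(x), sd_2 = stats::sd(y),
      p_location = compare_location(x, y)$p.value,
      p_dispersion = compare_dispersion(x, y)$p.value,
      p_shapiro_1 = shap(x), p_shapiro_2 = shap(y),
      stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)
  names(comparisons) <- sub("_1$", paste0("_", classes[1]), names(comparisons))
  names(comparisons) <- sub("_2$", paste0("_", classes[2]), names(comparisons))
  correlations <- lapply(stats::setNames(classes, classes), function(cl) {
    cor(as.matrix(table[table$label == cl, vars, drop = FALSE]))
  })
  list(comparisons = comparisons, correlations = correlations)
}

#' Write a class-comparison summary as CSV
#'
#' Columns follow the published layout: variable name, the two class means,
#' the location p-value, the two class SDs, the dispersion p-value.
#'
#' @param summary Result of [summarize_by_class()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_class_summary <- function(summary, path) {
  cmp <- summary$comparisons
  cols <- names(cmp)
  mean_cols <- grep("^mean_", cols, value = TRUE)
  sd_cols <- grep("^sd_", cols, value = TRUE)
  out <- data.frame(`Variable Name` = cmp$display, check.names = FALSE)
  for (m in mean_cols) out[[sub("mean_", "Mean ", m)]] <- cmp[[m]]
  out[["p-value (location)"]] <- cmp$p_location
  for (s in sd_cols) out[[sub("sd_", "SD ", s)]] <- cmp[[s]]
  out[["p-value (dispersion)"]] <- cmp$p_dispersion
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Summarize a fold-hit table
#'
#' Recomputes, per classification set, the number of proteins, the number
#' with a structural hit, the number of hits with Z-score above 2 (the
#' spurious-match threshold), and the mean and SD of Z-score and RMSD over
#' non-missing values.
#'
#' @param t Fold-hit table as returned by [table2_fixture()].
#' @return Data frame, one row per set.
#' @export
summarize_fold_hits <- function(t) {
  stopifnot(all(c("set", "hit_id", "rmsd", "z") %in% names(t)))
  do.call(rbind, lapply(split(t, t$set), function(s) {
    data.frame(set = s$set[1],
               n = nrow(s),
               n_hits = sum(!is.na(s$hit_id)),
               n_z_gt2 = sum(s$z > 2, na.rm = TRUE),
               mean_z = mean(s$z, na.rm = TRUE),
               sd_z = stats::sd(s$z[!is.na(s$z)]),
               mean_rmsd = mean(s$rmsd, na.rm = TRUE),
               sd_rmsd = stats::sd(s$rmsd[!is.na(s$rmsd)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
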