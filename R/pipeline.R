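#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis with a single
#' master seed from which all stage seeds are derived. Exactly one input
#' mode is used: `"synthetic"` (simulate a feature table from the packaged
#' class moments), `"feature-table"` (read a CSV produced by
#' [write_feature_table()]) or `"pdb-dir"` (extract features from PDB files
#' in `path/natural/` and `path/random/`).
#'
#' @param input Input mode.
#' @param path Input path (feature-table CSV or PDB directory).
#' @param n_natural,n_random Class sizes for synthetic mode.
#' @param shape Distribution shape for synthetic mode
#'   (see [simulate_feature_table()]).
#' @param lower_q,upper_q Outlier tail probabilities.
#' @param ga A [ga_config()] (its seed field is overridden by a derived seed).
#' @param mlp An [mlp_config()].
#' @param holdout Holdout fraction for the final classifier.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "feature-table", "pdb-dir"),
                            path = NULL, n_natural = 902, n_random = 20494,
                            shape = "gaussian", lower_q = 0.005, upper_q = 0.995,
                            ga = ga_config(), mlp = mlp_config(),
                            holdout = 0.3, seed = 1L) {
  input <- match.arg(input)
  if (input != "synthetic" && is.null(path))
    stop(sprintf("input mode '%s' requires `path`", input), call. = FALSE)
  if (!inherits(ga, "ga_config")) stop("`ga` must be a ga_config", call. = FALSE)
  if (!inherits(mlp, "mlp_config")) stop("`mlp` must be an mlp_config", call. = FALSE)
  structure(list(input = input, path = path, n_natural = n_natural,
                 n_random = n_random, shape = shape, lower_q = lower_q,
                 upper_q = upper_q, ga = ga, mlp = mlp, holdout = holdout,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full natural-vs-random analysis
#'
#' Pipeline order: obtain a feature table, remove distribution-tail
#' outliers, balance the classes, run the exploratory statistical battery,
#' evolve the variable-selecting networks, evaluate a final classifier on
#' the selected mask, and summarize the packaged fold-hit fixture. Every
#' stage seed is derived from the master seed and logged, so two runs with
#' the same configuration produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `randnat_report` (a named list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  seeds <- derive_seeds(config$seed,  4L)
  names(seeds) <- c("simulate", "balance", "enna", "final")

  table <- switch(config$input,
    "synthetic" = suppressMessages(simulate_feature_table(
      n_per_class = c(natural = config$n_natural, random = config$n_random),
      shape = config$shape, seed = seeds[["simulate"]])),
    "feature-table" = read_feature_table(config$path),
    "pdb-dir" = features_from_pdb_dir(config$path))
  check_feature_table(table)
  sizes_before <- as.list(base::table(table$label))

  report_out <- flag_outliers(table, config$lower_q, config$upper_q)
  filtered <- remove_outliers(table, report_out)
  sizes_after <- as.list(base::table(filtered$label))
  balanced <- balance_classes(filtered, seed = seeds[["balance"]])

  stats_summary <- summarize_by_class(balanced)

  ga <- config$ga; ga$seed <- seeds[["enna"]]
  enna <- evolve(balanced, ga = ga, mlp = config$mlp)
  final <- final_classifier(balanced, enna$best_mask, mlp = config$mlp,
                            holdout = config$holdout, seed = seeds[["final"]])

  fold_hits <- summarize_fold_hits(table2_fixture())

  report <- list(
    input = config$input,
    seeds = as.list(seeds),
    master_seed = config$seed,
    sizes_before = sizes_before,
    flagged = as.list(report_out$totals),
    sizes_after = sizes_after,
    sizes_balanced = as.list(base::table(balanced$label)),
    class_summary = stats_summary$comparisons,
    occurrence = as.list(enna$occurrence),
    selected_variables = names(enna$best_mask)[enna$best_mask],
    best_cv_misclassification = enna$best_fitness,
    fitness_trace = enna$trace,
    accuracy_holdout = final$accuracy_holdout,
    accuracy_cv = final$accuracy_cv,
    accuracy_whole = final$accuracy_whole,
    fold_hits = fold_hits)
  class(report) <- "randnat_report"
  report
}

features_from_pdb_dir <- function(path) {
  rows <- list()
  for (cl in c("natural", "random")) {
    files <- list.files(file.path(path, cl), pattern = "\\.pdb$",
                        full.names = TRUE)
    for (f in files) {
      model <- read_structure(f)
      rows[[length(rows) + 1L]] <-
        extract_features(model, id = sub("\\.pdb$", "", basename(f)), label = cl)
    }
  }
  if (length(rows) == 0)
    stop(sprintf("no PDB files under %s/natural or %s/random", path, path),
         call. = FALSE)
  do.call(rbind, rows)
}

#' Write and read a pipeline report
#'
#' `write_report()` writes a machine-readable `report.json` plus a
#' human-readable `summary.txt` into a directory; the content is a pure
#' function of the report, so identical runs give byte-identical files.
#' `read_report()` loads the JSON back.
#'
#' @param report A [randnat_report][run_pipeline].
#' @param path Output directory (created if needed).
#' @return `write_report()` returns the paths invisibly; `read_report()`
#'   the report list.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "randnat_report") || length(report) == 0)
    stop("`report` must be a non-empty randnat_report", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(path, "report.json")
  jsonlite::write_json(list(schema = "randnat-report/1", report = unclass(report)),
                       json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt_path <- file.path(path, "summary.txt")
  writeLines(format_report(report), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
  if (!identical(obj$schema, "randnat-report/1"))
    stop("unrecognized report schema", call. = FALSE)
  obj$report
}

format_report <- function(report) {
  fv <- feature_variables()
  disp <- stats::setNames(
    ifelse(names(report$occurrence) %in% names(fv),
           fv[names(report$occurrence)], names(report$occurrence)),
    names(report$occurrence))
  c("Natural vs random protein classification report",
    "================================================",
    sprintf("input mode: %s (master seed %d)", report$input, report$master_seed),
    sprintf("records before filtering: %s",
            paste(sprintf("%s=%s", names(report$sizes_before),
                          unlist(report$sizes_before)), collapse = ", ")),
    sprintf("outliers flagged: %s",
            paste(sprintf("%s=%s", names(report$flagged),
                          unlist(report$flagged)), collapse = ", ")),
    sprintf("after filtering: %s",
            paste(sprintf("%s=%s", names(report$sizes_after),
                          unlist(report$sizes_after)), collapse = ", ")),
    sprintf("after balancing: %s",
            paste(sprintf("%s=%s", names(report$sizes_balanced),
                          unlist(report$sizes_balanced)), collapse = ", ")),
    "",
    "variable occurrence probabilities in the final population:",
    sprintf("  %-24s %.3f", disp[names(report$occurrence)],
            unlist(report$occurrence)),
    sprintf("selected variables: %s",
            paste(disp[unlist(report$selected_variables)], collapse = ", ")),
    sprintf("best CV misclassification rate: %.4f",
            report$best_cv_misclassification),
    sprintf("correct classification rate (holdout): %.2f%%",
            100 * report$accuracy_holdout),
    sprintf("correct classification rate (10-fold CV): %.2f%%",
            100 * report$accuracy_cv),
    sprintf("correct classification rate (whole-data fit): %.2f%%",
            100 * report$accuracy_whole))
}

#' @export
print.randnat_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
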