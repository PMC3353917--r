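#' Published per-class moments of the eleven structural variables
#'
#' Mean and standard deviation of each structural variable for the natural
#' and the random (artificially generated) protein class, as reported for
#' the curated 762 + 762 study datasets. These parameterize the synthetic
#' feature-table simulator.
#'
#' @return Data frame with columns `variable` (internal names, see
#'   [feature_variables()]), `class` (`natural` / `random`), `mean`, `sd`.
#' @export
table1_params <- function() {
  v <- names(feature_variables())
  natural_mean <- c(0.7100, 8706.4310, 3952.0580, 18.0276, 14.7192, 23.3032,
                    33.8530, 21.3976, 26.0394, 55.2100, 0.3568)
  random_mean <- c(0.0591, 9279.6090, 3951.5030, 17.7349, 7.4567, 34.5538,
                   49.3625, 10.6532, 25.3356, 60.0151, 0.3738)
  natural_sd <- c(5.335634, 1067.166, 603.5493, 9.03813, 12.33831, 17.71133,
                  25.9784, 17.86945, 12.77989, 17.92994, 0.0695038)
  random_sd <- c(3.753989, 356.8877, 237.2047, 6.887919, 4.236918, 7.646621,
                 10.92395, 6.052317, 9.839893, 10.10049, 0.05349438)
  # note: the Table-1 ordering here differs from feature_variables(); map by name
  order_in_table <- c("net_charge", "volume", "surface", "coil", "beta",
                      "alpha", "pct_alpha", "pct_beta", "pct_coil",
                      "pct_secondary", "surface_hydrophobicity")
  out <- rbind(
    data.frame(variable = order_in_table, class = "natural",
               mean = natural_mean, sd = natural_sd, stringsAsFactors = FALSE),
    data.frame(variable = order_in_table, class = "random",
               mean = random_mean, sd = random_sd, stringsAsFactors = FALSE))
  out$variable <- factor(out$variable, levels = v)
  out <- out[order(out$class, out$variable), ]
  out$variable <- as.character(out$variable)
  rownames(out) <- NULL
  out
}

#' Simulate a feature table from per-class moments
#'
#' Draws independent per-variable samples matching the supplied class means
#' and standard deviations. Three distribution shapes are available:
#' `gaussian` (normal; the default), `skewed` (standardized gamma, skewness
#' 1) and `flat-wide` (uniform with matched mean/SD, mimicking the broad,
#' plateau-like spread seen for natural proteins). Values are clipped to
#' their physical ranges afterwards - percentages to [0, 100], the
#' hydrophobicity fraction to [0, 1], counts and areas to >= 0 - and the
#' number of clipped values is recorded in the `n_clipped` attribute.
#'
#' @param params Class parameters as returned by [table1_params()].
#' @param n_per_class Named counts, e.g. `c(natural = 762, random = 762)`.
#' @param shape `"gaussian"`, `"skewed"` or `"flat-wide"` (single value or
#'   named per class).
#' @param seed Integer seed.
#' @param clip Clip values to their physical ranges (default). With
#'   `clip = FALSE` the raw draws are returned, whose sample moments converge
#'   exactly to `params`; clipping biases the moments of variables whose
#'   mean sits within a few SDs of a bound (e.g. beta-sheet counts near 0).
#' @return Feature table (data frame: `id`, eleven variables, `label`) with
#'   attribute `n_clipped`.
#' @export
simulate_feature_table <- function(params = table1_params(),
                                   n_per_class = c(natural = 762, random = 762),
                                   shape = "gaussian", seed = 1L, clip = TRUE) {
  classes <- unique(params$class)
  if (is.null(names(n_per_class)))
    names(n_per_class) <- classes[seq_along(n_per_class)]
  shapes <- c("gaussian", "skewed", "flat-wide")
  if (length(shape) == 1L) shape <- stats::setNames(rep(shape, length(classes)), classes)
  if (!all(shape %in% shapes))
    stop(sprintf("unknown shape; must be one of: %s", paste(shapes, collapse = ", ")),
         call. = FALSE)
  vars <- names(feature_variables())
  if (!all(params$sd > 0)) stop("all sd entries must be > 0", call. = FALSE)

  draw <- function(n, mean, sd, shape) {
    switch(shape,
      "gaussian" = rnorm(n, mean, sd),
      "skewed" = { k <- 4; mean + sd * (rgamma(n, shape = k, rate = 1) - k) / sqrt(k) },
      "flat-wide" = runif(n, mean - sqrt(3) * sd, mean + sqrt(3) * sd))
  }
  lower <- c(net_charge = -Inf, volume = 0, surface = 0, coil = 0, beta = 0,
             alpha = 0, pct_alpha = 0, pct_beta = 0, pct_coil = 0,
             pct_secondary = 0, surface_hydrophobicity = 0)
  upper <- c(net_charge = Inf, volume = Inf, surface = Inf, coil = Inf,
             beta = Inf, alpha = Inf, pct_alpha = 100, pct_beta = 100,
             pct_coil = 100, pct_secondary = 100, surface_hydrophobicity = 1)

  n_clipped <- 0L
  out <- with_seed(seed, {
    blocks <- lapply(names(n_per_class), function(cl) {
      n <- n_per_class[[cl]]
      cols <- lapply(vars, function(v) {
        p <- params[params$class == cl & params$variable == v, ]
        if (nrow(p) != 1)
          stop(sprintf("params grid incomplete: %s / %s", cl, v), call. = FALSE)
        x <- draw(n, p$mean, p$sd, shape[[cl]])
        if (!clip) return(x)
        outside <- x < lower[[v]] | x > upper[[v]]
        n_clipped <<- n_clipped + sum(outside)
        pmin(pmax(x, lower[[v]]), upper[[v]])
      })
      names(cols) <- vars
      prefix <- if (cl == "natural") "nat" else "rnd"
      cbind(data.frame(id = sprintf("%s_%05d", prefix, seq_len(n)),
                       stringsAsFactors = FALSE),
            as.data.frame(cols),
            data.frame(label = rep(cl, n), stringsAsFactors = FALSE))
    })
    do.call(rbind, blocks)
  })
  rownames(out) <- NULL
  if (n_clipped > 0)
    message(sprintf("simulate_feature_table: clipped %d values to physical range",
                    n_clipped))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Structural-similarity hits of classified random proteins
#'
#' Packaged fixture reproducing the published fold-search results for the 32
#' random proteins misclassified as natural and 32 correctly classified
#' ones: the best natural-structure hit per protein with its RMSD (Angstrom)
#' and Z-score; `"no chain"` rows become missing values. The summary rows
#' printed alongside the original table are kept verbatim in the
#' `printed_summary` attribute (they are not recomputed from the rows; see
#' [summarize_fold_hits()] for recomputation).
#'
#' @return Data frame with columns `set` (`misclassified` / `correct`),
#'   `protein_id`, `hit_id` (NA when no hit), `rmsd`, `z`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_fold_hits.tsv", package = "randnat",
                      mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", "character"))
  raw$hit_id[raw$hit_id == "no chain"] <- NA_character_
  raw$rmsd <- suppressWarnings(as.numeric(ifelse(raw$rmsd == "n.a.", NA, raw$rmsd)))
  raw$z <- suppressWarnings(as.numeric(ifelse(raw$z == "n.a.", NA, raw$z)))
  attr(raw, "printed_summary") <- data.frame(
    set = c("misclassified", "correct"),
    mean_rmsd = c(3.2, 3.4), sd_rmsd = c(0.3, 0.5),
    mean_z = c(2.6, 1.7), sd_z = c(0.9, 0.7),
    stringsAsFactors = FALSE)
  raw
}
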