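#' Genetic-algorithm configuration for the evolutionary search
#'
#' A population of 30 binary chromosomes (one bit per structural variable)
#' evolves for 10 generations under roulette-wheel selection, single-point
#' crossover and per-bit mutation with probability 0.01. Fitness of a
#' chromosome is the 10-fold cross-validated misclassification rate of the
#' network trained on its selected variables; selection weights are
#' `1 - misclassification` so better networks reproduce more (set
#' `literal_fitness_weights = TRUE` to weight by the raw misclassification
#' rate instead, for fidelity experiments).
#'
#' @param pop_size Population size (even, for pairing).
#' @param generations Number of generations.
#' @param mutation_prob Per-bit mutation probability.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param folds Cross-validation folds for the fitness.
#' @param seed Master seed; all randomness derives from it.
#' @param literal_fitness_weights Use the raw misclassification rate as the
#'   selection weight.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 30L, generations = 10L, mutation_prob = 0.01,
                      elitism = 1L, folds = 10L, seed = 1L,
                      literal_fitness_weights = FALSE) {
  if (pop_size %% 2 != 0) stop("pop_size must be even", call. = FALSE)
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must be in [0, 1]", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob, elitism = as.integer(elitism),
                 folds = as.integer(folds), seed = as.integer(seed),
                 literal_fitness_weights = isTRUE(literal_fitness_weights)),
            class = "ga_config")
}

# initial population: i.i.d. fair-coin bits, all-zero rows redrawn
random_population <- function(pop_size, n_vars) {
  pop <- matrix(sample(0:1, pop_size * n_vars, replace = TRUE), pop_size, n_vars)
  for (i in seq_len(pop_size)) {
    while (sum(pop[i, ]) == 0)
      pop[i, ] <- sample(0:1, n_vars, replace = TRUE)
  }
  pop
}

#' One generation of the genetic algorithm
#'
#' Copies the best `elitism` chromosomes, then fills the population by
#' roulette-wheel selection of parent pairs, single-point crossover and
#' per-bit mutation. When all selection weights are equal (or zero),
#' selection is uniform. Uses the current RNG stream; [evolve()] seeds it.
#'
#' @param population 0/1 matrix, one chromosome per row.
#' @param fitnesses Misclassification rates aligned with rows.
#' @param config A [ga_config()].
#' @return Next-generation population matrix of the same size.
#' @export
ga_step <- function(population, fitnesses, config = ga_config()) {
  pop_size <- nrow(population)
  if (pop_size != config$pop_size || length(fitnesses) != pop_size)
    stop("population/fitness size does not match config", call. = FALSE)
  n_vars <- ncol(population)
  w <- if (config$literal_fitness_weights) fitnesses else 1 - fitnesses
  if (all(w <= 0) || diff(range(w)) == 0) w <- rep(1, pop_size)

  nxt <- matrix(0L, pop_size, n_vars)
  n_elite <- min(config$elitism, pop_size)
  if (n_elite > 0)
    nxt[seq_len(n_elite), ] <- population[order(fitnesses)[seq_len(n_elite)], , drop = FALSE]

  i <- n_elite
  while (i < pop_size) {
    parents <- sample.int(pop_size, 2, replace = TRUE, prob = w)
    p1 <- population[parents[1], ]; p2 <- population[parents[2], ]
    if (n_vars > 1) {
      k <- sample.int(n_vars - 1, 1)  # exchange point
      c1 <- c(p1[1:k], p2[(k + 1):n_vars])
      c2 <- c(p2[1:k], p1[(k + 1):n_vars])
    } else {
      c1 <- p1; c2 <- p2
    }
    for (child in list(c1, c2)) {
      if (i >= pop_size) break
      flip <- runif(n_vars) < config$mutation_prob
      child[flip] <- 1L - child[flip]
      i <- i + 1L
      nxt[i, ] <- child
    }
  }
  nxt
}

#' Evolve variable-selecting networks over a feature table
#'
#' The full evolutionary neural network search: a random initial population
#' of binary variable masks is scored by cross-validated misclassification
#' of the two-hidden-layer network, then evolved by selection, crossover and
#' mutation. Chromosomes that mutate to all-zero are not evaluated and get
#' the worst fitness (1.0). Fitness of a mask is cached, and all fold
#' assignments come from one derived seed, so a mask has the same fitness
#' whenever it reappears.
#'
#' @param table Preprocessed, balanced feature table.
#' @param ga A [ga_config()].
#' @param mlp An [mlp_config()].
#' @return Object of class `enna_result`: final `population`, `fitnesses`,
#'   per-variable `occurrence` probabilities, `best_mask` (logical),
#'   `best_fitness`, and `trace` (best fitness at initialization and after
#'   each generation; length `generations + 1`).
#' @export
evolve <- function(table, ga = ga_config(), mlp = mlp_config()) {
  check_feature_table(table)
  vars <- feature_vars_of(table)
  n_vars <- length(vars)
  seeds <- derive_seeds(ga$seed, 2L + ga$generations)
  cv_seed <- seeds[1]

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    if (sum(bits) == 0) return(1.0)
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_misclassification(as.logical(bits), table, folds = ga$folds,
                                seed = cv_seed, mlp = mlp)
    cache[[key]] <- val
    val
  }

  population <- with_seed(seeds[2], random_population(ga$pop_size, n_vars))
  fitnesses <- apply(population, 1, fitness_of)
  trace <- min(fitnesses)

  for (g in seq_len(ga$generations)) {
    population <- with_seed(seeds[2 + g], ga_step(population, fitnesses, ga))
    fitnesses <- apply(population, 1, fitness_of)
    trace <- c(trace, min(fitnesses))
  }

  best <- which.min(fitnesses)
  res <- list(population = population, fitnesses = fitnesses,
              occurrence = stats::setNames(colMeans(population), vars),
              best_mask = stats::setNames(as.logical(population[best, ]), vars),
              best_fitness = fitnesses[best],
              trace = trace, ga = ga, mlp = mlp, cv_seed = cv_seed,
              variables = vars, n_evaluated = length(ls(cache)))
  class(res) <- "enna_result"
  res
}

#' @export
print.enna_result <- function(x, ...) {
  cat(sprintf("<enna_result> %d chromosomes, best CV misclassification %.4f\n",
              nrow(x$population), x$best_fitness))
  cat("selected variables:",
      paste(names(x$best_mask)[x$best_mask], collapse = ", "), "\n")
  cat("occurrence probabilities:\n")
  print(round(x$occurrence, 3))
  invisible(x)
}

#' Per-variable occurrence probability in a population
#'
#' The fraction of chromosomes carrying each variable; variables with
#' probability close to 1 in the final population are the robustly selected
#' ones.
#'
#' @param population 0/1 matrix, one chromosome per row.
#' @param vars Optional variable names for the columns.
#' @return Named numeric vector in [0, 1].
#' @export
variable_occurrence <- function(population, vars = NULL) {
  if (is.null(dim(population)) || nrow(population) == 0)
    stop("population is empty", call. = FALSE)
  p <- colMeans(population)
  if (!is.null(vars)) names(p) <- vars
  else if (ncol(population) == length(feature_variables()))
    names(p) <- names(feature_variables())
  p
}

#' Train and evaluate a final classifier on a fixed mask
#'
#' Given a set of selected variables, reports three correct-classification
#' rates: on a stratified holdout split, by cross-validation, and the
#' apparent rate of one network trained and evaluated on the whole data
#' (the in-sample fit).
#'
#' @param table Feature table with two classes.
#' @param mask Variable mask (logical vector or variable names).
#' @param mlp An [mlp_config()].
#' @param holdout Fraction of records held out for evaluation.
#' @param seed Integer seed (split and network initialization).
#' @param folds Folds for the cross-validated rate.
#' @return List with `accuracy_holdout`, `accuracy_cv`, `accuracy_whole`,
#'   the trained `model` (fit on the non-holdout split) and the `mask`.
#' @export
final_classifier <- function(table, mask, mlp = mlp_config(), holdout = 0.3,
                             seed = 1L, folds = 10L) {
  check_feature_table(table)
  all_vars <- feature_vars_of(table)
  mask <- normalize_mask(mask, all_vars)
  if (!any(mask)) stop("mask selects no variables", call. = FALSE)
  vars <- all_vars[mask]
  X <- as.matrix(table[, vars, drop = FALSE])
  y <- factor(table$label)
  seeds <- derive_seeds(seed, 4L)

  test <- logical(nrow(table))
  with_seed(seeds[1], {
    for (cl in levels(y)) {
      rows <- which(y == cl)
      test[sample(rows, round(holdout * length(rows)))] <- TRUE
    }
  })
  cfg <- mlp; cfg$seed <- seeds[2]
  model <- suppressWarnings(train_mlp(X[!test, , drop = FALSE], y[!test], cfg))
  acc_holdout <- mean(predict(model, X[test, , drop = FALSE]) ==
                        as.character(y[test]))
  cfg$seed <- seeds[3]
  whole <- suppressWarnings(train_mlp(X, y, cfg))
  acc_whole <- mean(predict(whole, X) == as.character(y))
  acc_cv <- 1 - cv_misclassification(mask, table, folds = folds,
                                     seed = seeds[4], mlp = mlp)
  list(accuracy_holdout = acc_holdout, accuracy_cv = acc_cv,
       accuracy_whole = acc_whole, model = model,
       mask = stats::setNames(mask, all_vars))
}
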