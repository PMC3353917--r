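fast_mlp <- function(epochs = 200, hidden = c(3, 3), seed = 1) {
  mlp_config(hidden = hidden, epochs = epochs, seed = seed)
}

test_that("the network learns XOR and is deterministic", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  model <- train_mlp(X, y, mlp_config(hidden = c(4, 4), epochs = 5000, seed = 2))
  expect_equal(as.numeric(predict(model, X)), y)

  m1 <- train_mlp(X, y, mlp_config(hidden = c(4, 4), epochs = 300, seed = 7))
  m2 <- train_mlp(X, y, mlp_config(hidden = c(4, 4), epochs = 300, seed = 7))
  expect_identical(m1$weights, m2$weights)
  m3 <- train_mlp(X, y, mlp_config(hidden = c(4, 4), epochs = 300, seed = 8))
  expect_false(identical(m1$weights, m3$weights))

  # sigmoid output stays in [0, 1]
  p <- predict(model, X, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("single-class data yields a constant predictor with a warning", {
  X <- matrix(rnorm(20), 10, 2)
  expect_warning(m <- train_mlp(X, rep("natural", 10)), "single-class")
  expect_equal(unique(predict(m, X)), "natural")
})

test_that("cross-validated misclassification behaves across signal regimes", {
  # well-separated classes: near-zero error
  tab <- toy_table(n_per_class = 100, k = 2, shift = 20, seed = 10)
  rate <- cv_misclassification("v1", tab, folds = 10, seed = 1,
                               mlp = fast_mlp())
  expect_lte(rate, 0.02)

  # permuted labels: chance-level error
  set.seed(11)
  tab$label <- sample(tab$label)
  rate0 <- cv_misclassification(c("v1", "v2"), tab, folds = 10, seed = 1,
                                mlp = fast_mlp())
  expect_true(abs(rate0 - 0.5) <= 0.1)
  expect_true(rate0 >= 0 && rate0 <= 1)

  expect_error(cv_misclassification(rep(0, 2), tab), "no variables")
  expect_error(cv_misclassification("v1", tab[1:5, ], folds = 10), "folds")
})

test_that("fitness is invariant to the order of records", {
  tab <- toy_table(n_per_class = 40, k = 3, shift = 3, seed = 12)
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  r1 <- cv_misclassification("v1", tab, seed = 4, mlp = fast_mlp())
  r2 <- cv_misclassification("v1", shuffled, seed = 4, mlp = fast_mlp())
  expect_identical(r1, r2)
})

test_that("one GA generation preserves size, elites and operator semantics", {
  set.seed(20)
  cfg <- ga_config(pop_size = 30, elitism = 2)
  pop <- randnat:::random_population(30, 11)
  fit <- runif(30)
  nxt <- ga_step(pop, fit, cfg)
  expect_equal(dim(nxt), dim(pop))
  ord <- order(fit)
  expect_identical(nxt[1, ], pop[ord[1], ])
  expect_identical(nxt[2, ], pop[ord[2], ])
  expect_error(ga_step(pop[1:10, ], fit[1:10], cfg), "does not match")

  # single-point crossover of all-ones x all-zeros gives a ones-prefix
  # pattern (or its complement); mutation off
  cfg0 <- ga_config(pop_size = 4, elitism = 0, mutation_prob = 0)
  pop2 <- rbind(rep(1L, 8), rep(0L, 8), rep(1L, 8), rep(0L, 8))
  set.seed(21)
  child <- ga_step(pop2, c(0.1, 0.1, 0.1, 0.1), cfg0)
  is_prefix_pattern <- function(b) {
    runs <- rle(b)
    length(runs$values) <= 2
  }
  expect_true(all(apply(child, 1, is_prefix_pattern)))

  # mutation probability 1 complements every child bit
  cfg1 <- ga_config(pop_size = 2, elitism = 0, mutation_prob = 1)
  pop3 <- rbind(rep(1L, 6), rep(1L, 6))
  set.seed(22)
  child1 <- ga_step(pop3, c(0.5, 0.5), cfg1)
  expect_true(all(child1 == 0L))  # crossover of identical parents, then flip
})

test_that("occurrence probabilities are bit means", {
  pop <- rbind(rep(1L, 11), rep(1L, 11))
  expect_equal(unname(variable_occurrence(pop)), rep(1, 11))
  pop2 <- matrix(0L, 30, 11); pop2[1:15, 3] <- 1L
  expect_equal(unname(variable_occurrence(pop2)[3]), 0.5)
  expect_true(all(variable_occurrence(pop2) >= 0 &
                    variable_occurrence(pop2) <= 1))
  expect_error(variable_occurrence(matrix(0L, 0, 4)), "empty")
})

test_that("evolution is reproducible, elitist and finds the informative mask", {
  tab <- toy_table(n_per_class = 30, k = 4, shift = 5, seed = 30)
  ga <- ga_config(generations = 3, seed = 99)
  r1 <- evolve(tab, ga = ga, mlp = fast_mlp())
  r2 <- evolve(tab, ga = ga, mlp = fast_mlp())
  expect_identical(r1$population, r2$population)
  expect_identical(r1$trace, r2$trace)
  expect_length(r1$trace, 4L)  # generations + 1

  # elitism >= 1: best-so-far fitness never degrades
  expect_true(all(diff(r1$trace) <= 1e-12))

  # zero generations: initial population only
  r0 <- evolve(tab, ga = ga_config(generations = 0, seed = 5),
               mlp = fast_mlp())
  expect_length(r0$trace, 1L)
  expect_equal(nrow(r0$population), 30L)

  # occurrence of the informative variable dominates after evolution
  r <- evolve(tab, ga = ga_config(generations = 10, seed = 17),
              mlp = fast_mlp())
  expect_gt(r$occurrence[["v1"]], 0.9)
})

test_that("GA matches exhaustive mask enumeration on 4-variable toys", {
  n_seeds <- 20
  hits <- 0
  for (s in seq_len(n_seeds)) {
    tab <- toy_table(n_per_class = 30, k = 4, shift = 5, seed = 400 + s)
    res <- evolve(tab, ga = ga_config(generations = 10, seed = 500 + s),
                  mlp = fast_mlp())
    # enumerate all 2^4 - 1 masks with the same fitness function and seed
    masks <- as.matrix(expand.grid(rep(list(0:1), 4)))[-1, ]
    fits <- apply(masks, 1, function(b)
      cv_misclassification(as.logical(b), tab, folds = res$ga$folds,
                           seed = res$cv_seed, mlp = fast_mlp()))
    if (res$best_fitness <= min(fits) + 1e-12) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("the final classifier reports consistent accuracies", {
  tab <- toy_table(n_per_class = 60, k = 3, shift = 6, seed = 60)
  fin <- final_classifier(tab, c("v1"), mlp = fast_mlp(), holdout = 0.3,
                          seed = 3)
  expect_true(fin$accuracy_holdout >= 0 && fin$accuracy_holdout <= 1)
  expect_gt(fin$accuracy_holdout, 0.9)
  expect_gt(fin$accuracy_cv, 0.9)
  expect_gt(fin$accuracy_whole, 0.9)
  expect_s3_class(fin$model, "mlp_model")
  expect_error(final_classifier(tab, rep(0, 3)), "no variables")

  # all variables on signal-bearing data beats chance
  fin_all <- final_classifier(tab, rep(1, 3), mlp = fast_mlp(), seed = 4)
  expect_gt(fin_all$accuracy_holdout, 0.5)
})
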