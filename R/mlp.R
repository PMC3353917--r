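#' Multilayer-perceptron training configuration
#'
#' Two sigmoid hidden layers trained by online backpropagation with a fixed
#' learning rate of 0.3 and momentum 0.2, for 500 epochs by default. When
#' `hidden` is `NULL` each hidden layer gets `ceiling((m + 2) / 2)` units,
#' where `m` is the number of input variables after masking.
#'
#' @param hidden Integer vector of length 2 (units per hidden layer) or
#'   `NULL` to derive from the input size.
#' @param learning_rate Positive step size for weight updates.
#' @param momentum Momentum coefficient in [0, 1).
#' @param epochs Training epochs (full passes over the data).
#' @param seed Integer seed for weight initialization and epoch shuffling.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden = NULL, learning_rate = 0.3, momentum = 0.2,
                       epochs = 500L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!is.null(hidden) && (length(hidden) != 2 || any(hidden < 1)))
    stop("hidden must be two sizes >= 1, or NULL", call. = FALSE)
  structure(list(hidden = hidden, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train a two-hidden-layer sigmoid network
#'
#' Inputs are standardized (z-score) internally using the training data.
#' The single output unit is sigmoid, so predictions lie in [0, 1]; the
#' decision threshold is 0.5 and exact ties go to the second class level
#' (for natural-vs-random labels, to `"random"`).
#'
#' @param features Numeric matrix, one row per record.
#' @param labels Binary labels (factor, character or 0/1), aligned with rows.
#' @param config An [mlp_config()].
#' @return Object of class `mlp_model`.
#' @export
train_mlp <- function(features, labels, config = mlp_config()) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 records", call. = FALSE)
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
  if (length(lv) > 2) stop("labels must be binary", call. = FALSE)
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(features, 2, center), 2, scale, "/")

  if (length(lv) == 1) {
    warning("single-class training data: constant predictor", call. = FALSE)
    model <- list(constant = lv, levels = lv, center = center, scale = scale,
                  config = config)
    class(model) <- "mlp_model"
    return(model)
  }
  y <- as.integer(as.character(labels) == lv[2])
  m <- ncol(X)
  hidden <- config$hidden %||% rep(ceiling((m + 2) / 2), 2)
  w <- mlp_train_cpp(X, y, as.integer(hidden[1]), as.integer(hidden[2]),
                     config$learning_rate, config$momentum, config$epochs,
                     config$seed)
  model <- list(weights = w, levels = lv, center = center, scale = scale,
                hidden = hidden, config = config)
  class(model) <- "mlp_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param object An `mlp_model`.
#' @param newdata Numeric matrix of inputs.
#' @param type `"class"` for labels, `"prob"` for the sigmoid output
#'   (probability of the second class level).
#' @param ... Unused.
#' @rdname train_mlp
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    return(if (type == "class") rep(object$constant, nrow(newdata))
           else rep(as.numeric(object$constant == object$levels[length(object$levels)]),
                    nrow(newdata)))
  }
  X <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- mlp_forward_cpp(object$weights$W1, object$weights$W2, object$weights$W3, X)
  if (type == "prob") return(p)
  ifelse(p >= 0.5, object$levels[2], object$levels[1])
}

#' Cross-validated misclassification rate of a variable mask
#'
#' The fitness function of the evolutionary search: restrict the feature
#' table to the variables selected by `mask`, build stratified folds from a
#' seeded shuffle, train the network on each training split and pool the
#' held-out errors.
#'
#' @param mask Logical/0-1 vector over the eleven variables, or a character
#'   vector of variable names.
#' @param table Feature table with two classes.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and fold-level
#'   network seeds.
#' @param mlp An [mlp_config()].
#' @return Misclassification rate in [0, 1].
#' @export
cv_misclassification <- function(mask, table, folds = 10L, seed = 1L,
                                 mlp = mlp_config()) {
  check_feature_table(table)
  all_vars <- feature_vars_of(table)
  mask <- normalize_mask(mask, all_vars)
  if (!any(mask)) stop("mask selects no variables", call. = FALSE)
  table <- table[order(table$id), , drop = FALSE]  # record-order invariance
  n <- nrow(table)
  if (n < folds) stop("fewer records than folds", call. = FALSE)
  vars <- all_vars[mask]
  X <- as.matrix(table[, vars, drop = FALSE])
  y <- factor(table$label)

  seeds <- derive_seeds(seed, folds + 1L)
  fold_id <- integer(n)
  with_seed(seeds[1], {
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      fold_id[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  errors <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    cfg <- mlp
    cfg$seed <- seeds[f + 1L]
    model <- suppressWarnings(train_mlp(X[!test, , drop = FALSE], y[!test], cfg))
    pred <- predict(model, X[test, , drop = FALSE])
    errors <- errors + sum(pred != as.character(y[test]))
  }
  errors / n
}

normalize_mask <- function(mask, vars = names(feature_variables())) {
  if (is.character(mask)) {
    bad <- setdiff(mask, vars)
    if (length(bad) > 0)
      stop(sprintf("unknown variable(s) in mask: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    return(vars %in% mask)
  }
  if (length(mask) != length(vars))
    stop(sprintf("mask must have length %d", length(vars)), call. = FALSE)
  as.logical(mask)
}
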