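#' Random hidden-layer parameters
#'
#' Draws the ELM's input weights (L x d) and biases (length L) uniformly
#' from [-1, 1], from a private seeded stream; deterministic per seed.
#'
#' @param hidden_nodes Hidden-layer size L (>= 1).
#' @param input_dim Input dimension d (>= 1).
#' @param seed Integer seed.
#' @return List with `weights` (L x d) and `biases` (length L).
#' @export
init_hidden <- function(hidden_nodes, input_dim, seed = 0L) {
  if (hidden_nodes < 1) stop("hidden_nodes must be at least 1")
  stopifnot(input_dim >= 1)
  rng <- local_rng(seed)
  list(weights = matrix(rng$runif(hidden_nodes * input_dim, -1, 1),
                        hidden_nodes, input_dim),
       biases = rng$runif(hidden_nodes, -1, 1))
}

#' Hidden-layer output matrix
#'
#' `H[i, j] = g(w_j . a_i + c_j)` with the Gaussian radial squashing
#' `g(z) = exp(-z^2)` applied to the affine input (the default), or the
#' distance form `g = exp(-gamma * ||a_i - w_j||^2)`. Either way entries lie
#' in (0, 1].
#'
#' @param x n x d matrix of (already scaled) inputs.
#' @param weights L x d input-weight matrix.
#' @param biases Length-L bias vector.
#' @param activation `"rbf-affine"` (default) or `"rbf-distance"`.
#' @param gamma Width for the distance form.
#' @return n x L matrix with entries in (0, 1].
#' @export
hidden_matrix <- function(x, weights, biases,
                          activation = c("rbf-affine", "rbf-distance"),
                          gamma = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (ncol(x) != ncol(weights)) stop("dimension mismatch")
  if (activation == "rbf-affine") {
    z <- x %*% t(weights)
    z <- sweep(z, 2, biases, "+")
    exp(-z^2)
  } else {
    d2 <- outer(rowSums(x^2), rowSums(weights^2), "+") -
      2 * x %*% t(weights)
    exp(-gamma * pmax(d2, 0))
  }
}

#' Extreme learning machine classifier
#'
#' Single-hidden-layer feedforward network whose hidden weights and biases
#' are drawn randomly (untrained) and whose output weights are solved in
#' closed form: with hidden output matrix `H` and one-hot target matrix `B`,
#' `beta = H^+ B` via the Moore-Penrose pseudoinverse, the minimum-norm
#' least-squares solution of `H beta = B`. Inputs are standardized
#' internally (column z-score, additionally scaled by `1/sqrt(d)`) so the
#' affine argument of the Gaussian squashing stays of order one regardless
#' of dimension; the scaling is stored in the model and re-applied at
#' prediction time.
#'
#' @param x A labeled [feature_matrix()], or an n x d numeric matrix.
#' @param y Class labels when `x` is a plain matrix.
#' @param hidden_nodes Hidden-layer size L; default `min(1000, n)`.
#' @param activation See [hidden_matrix()].
#' @param gamma Width for the `"rbf-distance"` activation.
#' @param seed Integer seed for the random hidden layer.
#' @param hidden Optional list with pre-drawn `weights` (L x d) and `biases`
#'   (length L), overriding the seeded draw. Used by the wrapper selector to
#'   share one master weight matrix across candidate feature subsets
#'   (common random numbers), so fitness differences reflect the subsets
#'   rather than weight redraws.
#' @return Object of class `elm`: hidden parameters, solved `output_weights`
#'   (L x C), `classes`, input scaling, and the training call metadata.
#' @examples
#' fm <- make_features(synthetic_spec(n_samples = 60, n_classes = 3,
#'                                    n_informative = 4, n_noise = 6))
#' fit <- elm(fm, hidden_nodes = 30, seed = 1)
#' mean(predict(fit, fm$values) == fm$labels)
#' @export
elm <- function(x, y = NULL, hidden_nodes = NULL,
                activation = c("rbf-affine", "rbf-distance"),
                gamma = 1, seed = 0L, hidden = NULL) {
  activation <- match.arg(activation)
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("labels are required")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least two classes")
  n <- nrow(x)
  if (n < 2L || n != length(y)) stop("need n >= 2 samples with labels")
  d <- ncol(x)
  if (is.null(hidden_nodes)) hidden_nodes <- min(1000L, n)
  center <- colMeans(x)
  # population (1/n) standard deviation: duplicating every sample must not
  # change the fitted model
  scale <- sqrt(colMeans(sweep(x, 2, center)^2)) * sqrt(d)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  if (is.null(hidden)) {
    hidden <- init_hidden(hidden_nodes, d, seed)
  } else {
    stopifnot(ncol(hidden$weights) == d)
    hidden_nodes <- nrow(hidden$weights)
  }
  h <- hidden_matrix(xs, hidden$weights, hidden$biases, activation, gamma)
  b <- matrix(0, n, nlevels(y))
  b[cbind(seq_len(n), as.integer(y))] <- 1
  beta <- MASS::ginv(h, tol = 1e-12) %*% b
  scores <- h %*% beta
  pred <- factor(levels(y)[apply(scores, 1, which.max)], levels = levels(y))
  structure(list(input_weights = hidden$weights, biases = hidden$biases,
                 output_weights = beta, activation = activation,
                 gamma = gamma, classes = levels(y),
                 hidden_nodes = hidden_nodes, seed = seed,
                 center = center, scale = scale, n_train = n,
                 training_accuracy = 100 * mean(pred == y)),
            class = "elm")
}

#' Predict classes with a fitted ELM
#'
#' Computes `H beta` for the new inputs and returns the class of the argmax
#' column per row; ties break to the lowest class index.
#'
#' @param object A fitted [elm()].
#' @param newdata n x d matrix (same columns as training).
#' @param type `"class"` for labels, `"score"` for the raw n x C score
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or a score matrix.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) stop("dimension mismatch")
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  h <- hidden_matrix(xs, object$input_weights, object$biases,
                     object$activation, object$gamma)
  scores <- h %*% object$output_weights
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  factor(object$classes[apply(scores, 1, which.max)], levels = object$classes)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("extreme learning machine: %d hidden nodes (%s), %d classes\n",
              x$hidden_nodes, x$activation, length(x$classes)))
  cat(sprintf("trained on %d samples, training accuracy %.2f%%\n",
              x$n_train, x$training_accuracy))
  invisible(x)
}

#' @export
summary.elm <- function(object, ...) {
  cat("Extreme learning machine classifier\n")
  cat(sprintf("  hidden nodes L       : %d\n", object$hidden_nodes))
  cat(sprintf("  activation           : %s\n", object$activation))
  cat(sprintf("  input dimension      : %d\n", length(object$center)))
  cat(sprintf("  classes              : %s\n",
              paste(object$classes, collapse = ", ")))
  cat(sprintf("  training samples     : %d\n", object$n_train))
  cat(sprintf("  training accuracy    : %.2f%%\n", object$training_accuracy))
  cat(sprintf("  |output weights|_max : %.4g\n",
              max(abs(object$output_weights))))
  invisible(object)
}

#' @export
coef.elm <- function(object, ...) object$output_weights

#' Classification metrics
#'
#' The evaluation convention of the pipeline's reports: accuracy in percent,
#' macro-averaged precision in percent (a class that is never predicted
#' contributes 0 to the average), false discovery rate defined as
#' `100 - precision`, and the full confusion table (rows = truth, columns =
#' predicted).
#'
#' @param predicted Predicted labels.
#' @param truth True labels.
#' @param classes Class set; defaults to the union of levels. Labels outside
#'   it are an error.
#' @param elapsed_time Optional wall-clock seconds to record.
#' @return Object of class `classification_metrics`: `accuracy`,
#'   `precision`, `fdr` (all percent), `confusion`, `elapsed_time`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = NULL,
                                 elapsed_time = NA_real_) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (is.null(classes))
    classes <- sort(unique(c(as.character(predicted), as.character(truth))))
  if (!all(as.character(predicted) %in% classes) ||
      !all(as.character(truth) %in% classes))
    stop("unknown label")
  predicted <- factor(predicted, levels = classes)
  truth <- factor(truth, levels = classes)
  confusion <- table(truth = truth, predicted = predicted)
  accuracy <- 100 * sum(diag(confusion)) / length(truth)
  per_class <- vapply(seq_along(classes), function(k) {
    tp <- confusion[k, k]
    pp <- sum(confusion[, k])
    if (pp == 0) 0 else tp / pp
  }, numeric(1))
  precision <- 100 * mean(per_class)
  structure(list(accuracy = accuracy, precision = precision,
                 fdr = 100 - precision, per_class_precision = per_class,
                 confusion = confusion, elapsed_time = elapsed_time),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  FDR %.2f%%",
              x$accuracy, x$precision, x$fdr))
  if (is.finite(x$elapsed_time))
    cat(sprintf("  time %.3f s", x$elapsed_time))
  cat("\n")
  invisible(x)
}

#' Persist an ELM model as JSON
#'
#' @param model A fitted [elm()].
#' @param path Output path.
#' @export
write_elm <- function(model, path) {
  jsonlite::write_json(
    list(input_weights = model$input_weights, biases = model$biases,
         output_weights = model$output_weights, activation = model$activation,
         gamma = model$gamma, classes = model$classes,
         hidden_nodes = model$hidden_nodes, seed = model$seed,
         center = model$center, scale = model$scale,
         n_train = model$n_train,
         training_accuracy = model$training_accuracy),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Load an ELM model written by [write_elm()]
#'
#' @param path JSON path.
#' @return An object of class `elm`.
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$input_weights <- as.matrix(obj$input_weights)
  obj$output_weights <- as.matrix(obj$output_weights)
  structure(obj, class = "elm")
}
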