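#' Wrapper-selection fitness
#'
#' Weighted combination of classifier error and subset-size ratio:
#' `alpha_weight * error_rate + beta_weight * n_selected / total_features`,
#' lower is better. The error-dominant defaults (0.99 / 0.01) are standard in
#' wrapper feature selection.
#'
#' @param error_rate Classification error in [0, 1].
#' @param n_selected Number of selected features (>= 1).
#' @param total_features Total feature count.
#' @param alpha_weight,beta_weight Non-negative weights summing to 1.
#' @return Scalar fitness, lower is better.
#' @export
selection_fitness <- function(error_rate, n_selected, total_features,
                              alpha_weight = 0.99, beta_weight = 0.01) {
  if (n_selected < 1) stop("empty subset")
  stopifnot(n_selected <= total_features, error_rate >= 0, error_rate <= 1,
            alpha_weight >= 0, beta_weight >= 0,
            abs(alpha_weight + beta_weight - 1) < 1e-12)
  alpha_weight * error_rate + beta_weight * n_selected / total_features
}

#' Binarize a continuous position into a feature mask
#'
#' Feature j is selected iff `position[j] >= threshold` (inclusive). An
#' all-empty mask is repaired by forcing on the single feature with the
#' largest position value.
#'
#' @param position Numeric vector in [0, 1].
#' @param threshold Selection threshold in (0, 1).
#' @return Logical vector with at least one `TRUE`.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  mask <- position >= threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Refine a score vector by its absolute mean deviation
#'
#' Computes the AMD of the scores (reference = their mean) and retains the
#' features whose score is at least that dispersion value, considered in
#' descending score order. If fewer than `min_features` survive, the top
#' `min_features` by score are retained instead.
#'
#' @param best_position Numeric score vector (the optimizer's best position).
#' @param min_features Minimum number of features to retain.
#' @return Logical retention mask.
#' @export
amd_refine <- function(best_position, min_features = 1L) {
  d <- length(best_position)
  stopifnot(d >= 1, min_features >= 1, min_features <= d)
  md <- compute_amd(best_position, mean(best_position))
  keep <- best_position >= md
  if (sum(keep) < min_features) {
    keep <- rep(FALSE, d)
    keep[order(best_position, decreasing = TRUE)[seq_len(min_features)]] <- TRUE
  }
  keep
}

#' Feature selection result
#'
#' @param mask Logical selection mask over feature columns.
#' @param scores Continuous per-feature scores.
#' @param method `"hwoa"` or `"emi"`.
#' @param fitness_trace Optional per-iteration best-fitness trace.
#' @param extra Optional named list of method-specific fields.
#' @return Object of class `selection_result`.
#' @export
selection_result <- function(mask, scores, method,
                             fitness_trace = NULL, extra = list()) {
  stopifnot(is.logical(mask), length(mask) == length(scores), any(mask))
  structure(c(list(mask = mask, scores = scores,
                   n_selected = sum(mask), method = method,
                   fitness_trace = fitness_trace), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d of %d features selected\n",
              x$method, x$n_selected, length(x$mask)))
  if (!is.null(x$fitness_trace))
    cat(sprintf("final fitness: %.6f over %d iterations\n",
                x$fitness_trace[length(x$fitness_trace)],
                length(x$fitness_trace)))
  invisible(x)
}

## internal: ELM cross-validated error used as the wrapper fitness phi_r.
## Fixed stratified folds (fitness_seed) keep candidate comparisons stable
## across the whole run; averaging over folds keeps the error estimate
## reliable enough to resolve single-feature differences.
## master_hidden: L x D weights + biases shared across candidate subsets
## (common random numbers): masks differing in one feature share every other
## weight, so fitness differences reflect the subsets, not weight redraws.
elm_cv_error <- function(fm, mask, hidden_nodes, fitness_seed,
                         fitness_folds = 3L, master_hidden = NULL) {
  cols <- which(mask)
  sub <- fm_subset(fm, cols = cols)
  folds <- split_data(sub, cv_folds = fitness_folds, seed = fitness_seed)
  hidden <- if (is.null(master_hidden)) NULL else
    list(weights = master_hidden$weights[, cols, drop = FALSE],
         biases = master_hidden$biases)
  errs <- vapply(seq_len(fitness_folds), function(k) {
    tr <- fm_subset(sub, rows = which(folds != k))
    va <- fm_subset(sub, rows = which(folds == k))
    # keep L well below the fold-training size: an interpolating ELM
    # generalizes poorly and flattens the fitness landscape
    L <- min(hidden_nodes, floor(nrow(tr$values) / 2))
    hk <- if (is.null(hidden)) NULL else
      list(weights = hidden$weights[seq_len(L), , drop = FALSE],
           biases = hidden$biases[seq_len(L)])
    model <- elm(tr, hidden_nodes = L, seed = fitness_seed, hidden = hk)
    mean(as.character(predict(model, va$values)) !=
           as.character(va$labels))
  }, numeric(1))
  mean(errs)
}

#' Hybrid whale-optimization feature selection
#'
#' Wrapper selection: continuous whale-optimization search over [0,1]^D
#' feature-subset encodings, scored by the stratified cross-validated error
#' of a small extreme learning machine trained on the candidate subset
#' (combined with a subset-size penalty via [selection_fitness()]); the
#' folds are fixed for the whole run so candidate comparisons are stable,
#' and fold-averaging keeps the error estimate reliable enough to resolve
#' single-feature differences. After the search, the best position is
#' refined by retaining the features whose score reaches the AMD of the
#' score vector ([amd_refine()]), which can both discard weakly scored
#' selections and re-admit features the hard binarization threshold barely
#' missed. Deterministic given `seed`.
#'
#' @param features A labeled [feature_matrix()] with >= 2 classes and >= 2
#'   feature columns.
#' @param n_agents Number of search agents.
#' @param max_iter Number of optimizer iterations.
#' @param threshold Binarization threshold for positions.
#' @param min_features Minimum number of retained features (default 5% of D,
#'   at least 1).
#' @param hidden_nodes Hidden-layer size of the fitness ELM.
#' @param alpha_weight,beta_weight Fitness weights, see [selection_fitness()].
#' @param fitness_folds Number of stratified folds behind the fitness error
#'   estimate.
#' @param seed Integer seed for the optimizer and the fitness folds.
#' @return A [selection_result()] with method `"hwoa"`, carrying the
#'   continuous scores (best position), the non-increasing fitness trace and
#'   the refined mask.
#' @export
hwoa_select <- function(features, n_agents = 30L, max_iter = 100L,
                        threshold = 0.5, min_features = NULL,
                        hidden_nodes = 50L, alpha_weight = 0.99,
                        beta_weight = 0.01, fitness_folds = 5L,
                        seed = 0L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels) || nlevels(features$labels) < 2L)
    stop("hwoa_select needs labels with at least two classes")
  d <- ncol(features$values)
  if (d < 2L) stop("need at least two feature columns")
  if (is.null(min_features)) min_features <- max(1L, ceiling(0.05 * d))
  fitness_seed <- seed + 1000003L
  master_hidden <- init_hidden(hidden_nodes, d, fitness_seed)
  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    mask <- binarize_position(position, threshold)
    key <- paste(which(mask), collapse = ",")
    err <- cache[[key]]
    if (is.null(err)) {
      err <- elm_cv_error(features, mask, hidden_nodes, fitness_seed,
                          fitness_folds, master_hidden)
      cache[[key]] <- err
    }
    selection_fitness(err, sum(mask), d, alpha_weight, beta_weight)
  }
  opt <- woa_optimize(objective, dim = d, n_agents = n_agents,
                      max_iter = max_iter, lower = 0, upper = 1, seed = seed)
  scores <- opt$best_position
  mask <- binarize_position(scores, threshold)
  refined <- amd_refine(scores, min_features = min_features)
  selection_result(refined, scores, "hwoa", fitness_trace = opt$trace,
                   extra = list(best_fitness = opt$best_fitness,
                                pre_refine_mask = mask, seed = seed))
}

#' Write a selection mask to JSON
#'
#' @param result A [selection_result()].
#' @param path Output path.
#' @export
write_mask <- function(result, path) {
  jsonlite::write_json(
    list(method = result$method,
         indices = which(result$mask),
         scores = result$scores,
         fitness_trace = result$fitness_trace),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a selection mask from JSON
#'
#' @param path JSON path written by [write_mask()].
#' @param n_features Total feature count the mask refers to.
#' @return A [selection_result()].
#' @export
read_mask <- function(path, n_features) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- rep(FALSE, n_features)
  mask[obj$indices] <- TRUE
  selection_result(mask, as.numeric(obj$scores), obj$method,
                   fitness_trace = obj$fitness_trace)
}
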