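## internal: counter-based seed fan-out so every stage has an independent,
## reproducible stream derived from one master seed (kept below 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

## internal: stratified train/test index split
stratified_holdout <- function(labels, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  rng <- local_rng(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * train_fraction))
    if (length(idx) >= 2L) n_tr <- min(n_tr, length(idx) - 1L)
    train <- c(train, idx[rng$sample_int(length(idx), n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Split a labeled feature matrix for evaluation
#'
#' Stratified 50:50 holdout (the default evaluation protocol) or stratified
#' k-fold cross-validation assignment. Deterministic per seed; every class
#' is represented in the training side of a holdout split.
#'
#' @param features A labeled [feature_matrix()].
#' @param holdout_fraction Training fraction for the holdout split.
#' @param cv_folds If not `NULL`, return stratified fold assignments
#'   (>= 2 folds) instead of a holdout split.
#' @param seed Integer seed.
#' @return For holdout: list with `train` and `test` index vectors. For CV:
#'   integer vector of fold labels (1..k), one per sample.
#' @export
split_data <- function(features, holdout_fraction = 0.5, cv_folds = NULL,
                       seed = 0L) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- features$labels
  if (is.null(labels)) stop("split_data needs labels")
  if (nrow(features$values) < 2L * nlevels(labels))
    stop("need at least two samples per class")
  if (is.null(cv_folds))
    return(stratified_holdout(labels, holdout_fraction, seed))
  stopifnot(cv_folds >= 2)
  rng <- local_rng(seed)
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop(sprintf("class %s has a single sample; cannot cross-validate", cl))
    folds[idx[rng$sample_int(length(idx), length(idx))]] <-
      rep_len(seq_len(cv_folds), length(idx))
  }
  folds
}

## internal: CV error of an ELM on a labeled matrix (fixed stratified folds)
elm_cv_error_matrix <- function(x, labels, hidden_nodes, seed, folds = 3L) {
  fmx <- feature_matrix(x, labels)
  fa <- split_data(fmx, cv_folds = folds, seed = seed)
  mean(vapply(seq_len(folds), function(k) {
    tr <- fm_subset(fmx, rows = which(fa != k))
    va <- fm_subset(fmx, rows = which(fa == k))
    L <- min(hidden_nodes, floor(nrow(tr$values) / 2))
    m <- elm(tr, hidden_nodes = max(1L, L), seed = seed)
    mean(as.character(predict(m, va$values)) != as.character(va$labels))
  }, numeric(1)))
}

## internal: pick the number of canonical pairs by internal cross-validation
## on the fused training matrix; empirical canonical correlations overfit
## badly when the set dimensions approach the sample count, so the spec-style
## "keep every nonzero eigenvalue" default is a poor choice here
select_fusion_rank <- function(train_sets, labels, corr_threshold,
                               hidden_nodes, seed) {
  dmax <- min(vapply(train_sets, ncol, integer(1)))
  cands <- sort(unique(pmin(dmax, c(2L, 3L, 5L, 7L, 10L, 14L, 20L, dmax))))
  errs <- vapply(cands, function(d) {
    fit <- mdcca(train_sets, d = d)
    ftr <- fuse_sets(fit, train_sets, sort = TRUE)
    pr <- remove_redundant(ftr$fused, corr_threshold)
    elm_cv_error_matrix(pr$pruned, labels, hidden_nodes, seed)
  }, numeric(1))
  cands[which.min(errs)]
}

## internal: train/evaluate one experiment on given train/test column subsets
run_experiment <- function(train_x, train_y, test_x, test_y, classes,
                           hidden_nodes, seed) {
  t0 <- proc.time()[["elapsed"]]
  model <- elm(train_x, train_y, hidden_nodes = hidden_nodes, seed = seed)
  pred <- predict(model, test_x)
  evaluate_predictions(pred, test_y, classes,
                       elapsed_time = proc.time()[["elapsed"]] - t0)
}

#' Run the full classification pipeline
#'
#' Orchestrates enhance -> extract -> select (two routes) -> fuse ->
#' classify -> report. Input is either a labeled feature matrix or a list of
#' labeled images (which are contrast-enhanced against the pooled dataset
#' mean and passed through the feature backbone). The data are split by a
#' stratified holdout, both selectors are fitted on the training side only,
#' the selected sets are fused by multiset CCA with redundancy pruning, and
#' four experiments are evaluated on the same split: original features,
#' hybrid-whale-selected, entropy/mutual-information-selected, and fused.
#' All stage seeds are derived from one master seed, so the whole run is
#' reproducible.
#'
#' @param features A labeled [feature_matrix()] (alternative to `images`).
#' @param images List of images (requires `labels`).
#' @param labels Class labels when `images` is given.
#' @param enhance Apply the hybrid contrast enhancement to images.
#' @param backbone [backbone_spec()] for feature extraction from images.
#' @param holdout_fraction Training fraction of the stratified split.
#' @param hwoa Named list of overrides for [hwoa_select()].
#' @param emi Named list of overrides for [emi_select()].
#' @param corr_threshold Redundancy-pruning threshold for the fused matrix.
#' @param fusion_d Number of canonical pairs for the fusion stage; `NULL`
#'   (default) selects it by internal cross-validation on the training side.
#' @param hidden_nodes Hidden-layer size of the evaluation ELM.
#' @param experiments Character subset of
#'   `c("original", "hwoa", "emi", "fused")`.
#' @param seed Master seed.
#' @return Object of class `pipeline_report`: `metrics` (one
#'   [evaluate_predictions()] block per experiment), `selected` counts,
#'   `selections` (the two [selection_result()]s), `fusion` (the [mdcca()]
#'   fit and kept columns), `split`, `config`, `timings`.
#' @export
run_pipeline <- function(features = NULL, images = NULL, labels = NULL,
                         enhance = TRUE, backbone = backbone_spec("toy"),
                         holdout_fraction = 0.5, hwoa = list(), emi = list(),
                         corr_threshold = 0.95, fusion_d = NULL,
                         hidden_nodes = 50L,
                         experiments = c("original", "hwoa", "emi", "fused"),
                         seed = 0L) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  if (is.null(features)) {
    if (is.null(images)) stop("missing inputs: provide features or images")
    if (is.null(labels)) stop("images require labels")
    t0 <- tic()
    if (enhance) images <- enhance_dataset(images)$images
    timings$enhance <- tic() - t0
    t0 <- tic()
    features <- extract_features(images, labels, backbone)
    timings$extract <- tic() - t0
  }
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels)) stop("pipeline needs labeled features")
  classes <- levels(features$labels)

  split <- split_data(features, holdout_fraction, seed = derive_seed(seed, 1))
  train <- fm_subset(features, rows = split$train)
  test <- fm_subset(features, rows = split$test)

  need_hwoa <- any(c("hwoa", "fused") %in% experiments)
  need_emi <- any(c("emi", "fused") %in% experiments)
  sel_hwoa <- NULL; sel_emi <- NULL
  if (need_hwoa) {
    t0 <- tic()
    sel_hwoa <- do.call(hwoa_select,
                        c(list(features = train, seed = derive_seed(seed, 2)),
                          hwoa))
    timings$hwoa <- tic() - t0
  }
  if (need_emi) {
    t0 <- tic()
    sel_emi <- do.call(emi_select, c(list(features = train), emi))
    timings$emi <- tic() - t0
  }

  metrics <- list()
  selected <- list()
  elm_seed <- derive_seed(seed, 3)
  if ("original" %in% experiments) {
    metrics$original <- run_experiment(train$values, train$labels,
                                       test$values, test$labels, classes,
                                       hidden_nodes, elm_seed)
    selected$original <- ncol(train$values)
  }
  if ("hwoa" %in% experiments) {
    cols <- which(sel_hwoa$mask)
    metrics$hwoa <- run_experiment(train$values[, cols, drop = FALSE],
                                   train$labels,
                                   test$values[, cols, drop = FALSE],
                                   test$labels, classes, hidden_nodes,
                                   elm_seed)
    selected$hwoa <- length(cols)
  }
  if ("emi" %in% experiments) {
    cols <- which(sel_emi$mask)
    metrics$emi <- run_experiment(train$values[, cols, drop = FALSE],
                                  train$labels,
                                  test$values[, cols, drop = FALSE],
                                  test$labels, classes, hidden_nodes,
                                  elm_seed)
    selected$emi <- length(cols)
  }
  fusion <- NULL
  if ("fused" %in% experiments) {
    t0 <- tic()
    ca <- which(sel_hwoa$mask); cb <- which(sel_emi$mask)
    train_sets <- list(train$values[, ca, drop = FALSE],
                       train$values[, cb, drop = FALSE])
    if (is.null(fusion_d))
      fusion_d <- select_fusion_rank(train_sets, train$labels,
                                     corr_threshold, hidden_nodes, elm_seed)
    fit <- mdcca(train_sets, d = fusion_d)
    ftr <- fuse_sets(fit, train_sets, sort = TRUE)
    pr <- remove_redundant(ftr$fused, corr_threshold)
    fte <- fuse_sets(fit, list(test$values[, ca, drop = FALSE],
                               test$values[, cb, drop = FALSE]),
                     sort = FALSE)
    test_fused <- fte$fused[, ftr$column_order, drop = FALSE]
    test_fused <- test_fused[, pr$kept_columns, drop = FALSE]
    timings$fuse <- tic() - t0
    metrics$fused <- run_experiment(pr$pruned, train$labels, test_fused,
                                    test$labels, classes, hidden_nodes,
                                    elm_seed)
    selected$fused <- length(pr$kept_columns)
    fusion <- list(fit = fit, kept_columns = pr$kept_columns,
                   column_order = ftr$column_order)
  }
  structure(list(metrics = metrics, selected = selected,
                 selections = list(hwoa = sel_hwoa, emi = sel_emi),
                 fusion = fusion, split = split,
                 config = list(holdout_fraction = holdout_fraction,
                               corr_threshold = corr_threshold,
                               fusion_d = fusion_d,
                               hidden_nodes = hidden_nodes,
                               hwoa = hwoa, emi = emi,
                               experiments = experiments, seed = seed),
                 timings = timings),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-9s %4d features: accuracy %6.2f%%  precision %6.2f%%  FDR %6.2f%%\n",
                nm, x$selected[[nm]], m$accuracy, m$precision, m$fdr))
  }
  cat(sprintf("  split: %d train / %d test, master seed %d\n",
              length(x$split$train), length(x$split$test), x$config$seed))
  invisible(x)
}

#' @export
plot.pipeline_report <- function(x, ...) {
  acc <- vapply(x$metrics, function(m) m$accuracy, numeric(1))
  graphics::barplot(acc, ylim = c(0, 100), ylab = "accuracy (%)",
                    main = "pipeline experiments", ...)
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A [run_pipeline()] report.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- list(
    metrics = lapply(report$metrics, function(m)
      list(accuracy = m$accuracy, precision = m$precision, fdr = m$fdr,
           elapsed_time = m$elapsed_time,
           confusion = as.matrix(unclass(m$confusion)))),
    selected = report$selected,
    config = report$config,
    timings = report$timings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
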