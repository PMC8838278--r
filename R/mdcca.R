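## internal: validate a list of sample-aligned feature sets
check_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  sets <- lapply(sets, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  })
  ns <- vapply(sets, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("row-count mismatch across feature sets")
  if (ns[1] < 2L) stop("need at least two samples")
  sets
}

#' Within- and cross-set covariance blocks
#'
#' Column-centers each feature set and returns the sample covariance blocks
#' (divide by n - 1): one within-set block per set and one cross block per
#' ordered pair. Optionally adds a relative ridge `ridge * trace(Z_kk)/d_k *
#' I` to each within block so they are invertible even when selected-feature
#' sets are collinear.
#'
#' @param sets List of 2 or 3 matrices sharing their rows (samples).
#' @param ridge Relative ridge scale for the within blocks (0 = none).
#' @return List with `within` (list of d_k x d_k matrices), `cross` (named
#'   list, `"1_2"` etc., of d_j x d_k matrices), `centers` (per-set column
#'   means) and `n`.
#' @export
covariance_blocks <- function(sets, ridge = 0) {
  sets <- check_sets(sets)
  n <- nrow(sets[[1]])
  centers <- lapply(sets, colMeans)
  centered <- mapply(function(s, mu) sweep(s, 2, mu), sets, centers,
                     SIMPLIFY = FALSE)
  m <- length(sets)
  within <- lapply(centered, function(x) crossprod(x) / (n - 1))
  if (ridge > 0) {
    within <- lapply(within, function(z) {
      z + diag(ridge * sum(diag(z)) / ncol(z), ncol(z))
    })
  }
  cross <- list()
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (j != k) {
        cross[[paste(j, k, sep = "_")]] <-
          crossprod(centered[[j]], centered[[k]]) / (n - 1)
      }
    }
  }
  list(within = within, cross = cross, centers = centers, n = n)
}

#' Multiset canonical correlation analysis
#'
#' Finds per-set projection directions maximizing cross-set correlation by
#' solving the generalized eigenproblem on the covariance blocks. For two
#' sets this is classical CCA: the leading eigenpairs of
#' `Zxx^-1 Zxy Zyy^-1 Zyx`, whose eigenvalues are the squared canonical
#' correlations. For three sets the sum-of-pairwise-correlations multiset
#' formulation is used: `(R - D) a = lambda D a` with `R` the full block
#' covariance and `D` its block diagonal. Within blocks are ridge-stabilized
#' (`ridge * trace/d_k`); projection columns are normalized so each projected
#' variate has unit sample variance.
#'
#' @param sets List of 2 or 3 sample-aligned matrices.
#' @param d Number of projection pairs; default keeps the eigenvalues above
#'   `tol`, capped at the smallest set dimension.
#' @param ridge Relative ridge added to within-set covariance blocks.
#' @param tol Eigenvalue tolerance for the automatic choice of `d`.
#' @return Object of class `mdcca`: `projections` (list of d_k x d
#'   matrices), `eigenvalues` (length d, descending), `correlations`
#'   (canonical correlations, two-set case only), `centers`, `d`, `m`,
#'   `ridge`.
#' @export
mdcca <- function(sets, d = NULL, ridge = 1e-6, tol = 1e-8) {
  sets <- check_sets(sets)
  m <- length(sets)
  dims <- vapply(sets, ncol, integer(1))
  dmax <- min(dims)
  if (!is.null(d) && d > dmax) stop("d exceeds the smallest set dimension")
  raw <- covariance_blocks(sets, ridge = 0)
  blocks <- raw
  blocks$within <- lapply(raw$within, function(z)
    z + diag(ridge * sum(diag(z)) / ncol(z), ncol(z)))
  if (m == 2L) {
    zxx <- blocks$within[[1]]; zyy <- blocks$within[[2]]
    zxy <- blocks$cross[["1_2"]]; zyx <- blocks$cross[["2_1"]]
    mmat <- solve(zxx, zxy) %*% solve(zyy, zyx)
    eg <- eigen(mmat)
    if (max(abs(Im(eg$values))) > 1e-6) stop("non-finite eigen-solution")
    vals <- Re(eg$values); vecs <- Re(eg$vectors)
    ord <- order(vals, decreasing = TRUE)
    vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
    if (is.null(d)) d <- max(1L, min(dmax, sum(vals > tol)))
    ax <- vecs[, seq_len(d), drop = FALSE]
    ay <- solve(zyy, zyx %*% ax)
    proj <- list(ax, ay)
    eigenvalues <- pmax(vals[seq_len(d)], 0)
  } else {
    dtot <- sum(dims)
    r <- matrix(0, dtot, dtot)
    offs <- c(0, cumsum(dims))
    for (j in seq_len(m)) {
      for (k in seq_len(m)) {
        blk <- if (j == k) blocks$within[[j]] else
          blocks$cross[[paste(j, k, sep = "_")]]
        r[(offs[j] + 1):offs[j + 1], (offs[k] + 1):offs[k + 1]] <- blk
      }
    }
    dmat <- matrix(0, dtot, dtot)
    for (j in seq_len(m))
      dmat[(offs[j] + 1):offs[j + 1], (offs[j] + 1):offs[j + 1]] <-
        blocks$within[[j]]
    ch <- chol(dmat)                      # D = t(ch) %*% ch
    b <- backsolve(ch, t(backsolve(ch, t(r - dmat), transpose = TRUE)),
                   transpose = TRUE)
    b <- (b + t(b)) / 2
    eg <- eigen(b, symmetric = TRUE)
    if (is.null(d)) d <- max(1L, min(dmax, sum(eg$values > tol)))
    u <- eg$vectors[, seq_len(d), drop = FALSE]
    a <- backsolve(ch, u)
    proj <- lapply(seq_len(m), function(j)
      a[(offs[j] + 1):offs[j + 1], , drop = FALSE])
    eigenvalues <- eg$values[seq_len(d)]
  }
  # unit-variance normalization of each projected variate (a' Z_kk a = 1,
  # unridged covariance) so fused columns are on a common scale
  proj <- mapply(function(a, z) {
    sc <- sqrt(pmax(colSums(a * (z %*% a)), .Machine$double.eps))
    sweep(a, 2, sc, "/")
  }, proj, raw$within, SIMPLIFY = FALSE)
  correlations <- NULL
  if (m == 2L) {
    # report the empirical correlation of each canonical variate pair; this
    # is exact for identical sets and second-order insensitive to the ridge
    cx <- sweep(sets[[1]], 2, raw$centers[[1]]) %*% proj[[1]]
    cy <- sweep(sets[[2]], 2, raw$centers[[2]]) %*% proj[[2]]
    correlations <- vapply(seq_len(d), function(j) {
      r <- stats::cor(cx[, j], cy[, j])
      if (is.na(r)) 0 else r
    }, numeric(1))
    flip <- correlations < 0
    if (any(flip)) {
      proj[[2]][, flip] <- -proj[[2]][, flip]
      correlations <- abs(correlations)
    }
    correlations <- pmin(correlations, 1 + 1e-8)
  }
  structure(list(projections = proj, eigenvalues = eigenvalues,
                 correlations = correlations, centers = blocks$centers,
                 d = d, m = m, ridge = ridge, dims = dims),
            class = "mdcca")
}

#' @export
print.mdcca <- function(x, ...) {
  cat(sprintf("mdcca: %d sets (dims %s), %d canonical pairs\n",
              x$m, paste(x$dims, collapse = ", "), x$d))
  if (!is.null(x$correlations))
    cat("canonical correlations:",
        paste(sprintf("%.3f", x$correlations), collapse = " "), "\n")
  invisible(x)
}

#' Project and concatenate feature sets through a fitted mdcca
#'
#' Centers each set with the training means, projects it through its
#' canonical directions and concatenates the projected variates of all sets
#' into one fused matrix. With `sort = TRUE` the fused columns are sorted by
#' decreasing sample variance (a stable sort; ties keep canonical order).
#'
#' @param object A fitted [mdcca()].
#' @param sets List of sample-aligned matrices with the training dimensions.
#' @param sort Sort fused columns by decreasing variance.
#' @return List with `fused` (n x (m*d) matrix) and `column_order` (the
#'   permutation applied; identity when `sort = FALSE`).
#' @export
fuse_sets <- function(object, sets, sort = TRUE) {
  stopifnot(inherits(object, "mdcca"))
  sets <- check_sets(sets)
  if (length(sets) != object$m) stop("shape mismatch: wrong number of sets")
  if (!all(vapply(sets, ncol, integer(1)) == object$dims))
    stop("shape mismatch: set dimensions differ from the fit")
  proj <- mapply(function(s, mu, a) sweep(s, 2, mu) %*% a,
                 sets, object$centers, object$projections, SIMPLIFY = FALSE)
  fused <- do.call(cbind, proj)
  colnames(fused) <- unlist(lapply(seq_along(proj), function(k)
    sprintf("set%d_cv%02d", k, seq_len(object$d))))
  column_order <- seq_len(ncol(fused))
  if (sort) {
    v <- apply(fused, 2, stats::var)
    column_order <- order(v, decreasing = TRUE)
    fused <- fused[, column_order, drop = FALSE]
  }
  list(fused = fused, column_order = column_order)
}

#' Prune redundant fused columns
#'
#' Greedy left-to-right scan over variance-sorted columns: a column is
#' dropped if it duplicates a kept column or if its absolute Pearson
#' correlation with any kept column exceeds `corr_threshold`. The first
#' (highest-variance) column is always kept.
#'
#' @param fused Numeric matrix, columns sorted by decreasing variance.
#' @param corr_threshold Correlation threshold in (0, 1].
#' @return List with `pruned` (matrix of kept columns) and `kept_columns`
#'   (indices into `fused`, in original order).
#' @export
remove_redundant <- function(fused, corr_threshold = 0.95) {
  stopifnot(is.matrix(fused), corr_threshold > 0, corr_threshold <= 1)
  kept <- integer(0)
  for (j in seq_len(ncol(fused))) {
    xj <- fused[, j]
    drop <- FALSE
    for (k in kept) {
      xk <- fused[, k]
      if (isTRUE(all.equal(xj, xk, tolerance = 1e-12))) { drop <- TRUE; break }
      if (stats::sd(xj) == 0 || stats::sd(xk) == 0) {
        if (stats::sd(xj) == 0 && stats::sd(xk) == 0) { drop <- TRUE; break }
        next
      }
      if (abs(stats::cor(xj, xk)) > corr_threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  list(pruned = fused[, kept, drop = FALSE], kept_columns = kept)
}
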