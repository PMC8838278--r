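#' Fuzzy entropy of membership degrees
#'
#' Shannon-style entropy of fuzzy memberships in [0, 1]:
#' `-K * sum(m*log(m) + (1-m)*log(1-m))` with natural logarithm and the
#' convention `0 * log 0 = 0`. Zero for crisp (0/1) memberships, maximal when
#' every membership is 0.5.
#'
#' @param memberships Numeric vector with all values in [0, 1].
#' @param K Positive scale constant.
#' @return Non-negative scalar (nats, scaled by K).
#' @export
fuzzy_entropy <- function(memberships, K = 1) {
  if (any(memberships < 0 | memberships > 1, na.rm = TRUE) ||
      any(!is.finite(memberships)))
    stop("memberships must lie in [0, 1]")
  stopifnot(K > 0)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  -K * sum(xlogx(memberships) + xlogx(1 - memberships))
}

#' Joint and conditional entropy of a discrete joint distribution
#'
#' `H(X, Y) = -sum p(x,y) log p(x,y)` and
#' `H(X | Y) = -sum p(x,y) log p(x|y)`, natural logarithm (nats). Rows of
#' `joint` index X, columns index Y.
#'
#' @param joint Non-negative matrix of joint probabilities summing to 1
#'   (within 1e-8).
#' @return List with `joint_entropy` and `conditional_entropy`; both
#'   non-negative, and `conditional_entropy <= joint_entropy`.
#' @export
joint_and_conditional_entropy <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("negative probabilities")
  if (abs(sum(joint) - 1) > 1e-8) stop("probabilities must sum to 1")
  p <- joint[joint > 0]
  hxy <- -sum(p * log(p))
  py <- colSums(joint)
  # H(X|Y) = H(X,Y) - H(Y)
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  list(joint_entropy = hxy, conditional_entropy = hxy - hy)
}

## internal: discretize a numeric vector into equal-width bins; factors and
## small-integer codes pass through unchanged
discretize <- function(x, n_bins) {
  if (is.factor(x) || is.character(x)) return(factor(x))
  ux <- unique(x)
  if (length(ux) <= n_bins) return(factor(x))
  rng <- range(x)
  if (rng[1] == rng[2]) return(factor(rep(1L, length(x))))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  br[1] <- br[1] - 1e-9; br[n_bins + 1L] <- br[n_bins + 1L] + 1e-9
  factor(cut(x, br, labels = FALSE))
}

#' Empirical mutual information
#'
#' `I(X;Y) = sum p(x,y) log[p(x,y) / (p(x) p(y))]` over the empirical joint
#' table, in nats. Continuous inputs are equal-width binned; categorical
#' inputs are used as-is. Satisfies `I = H(X) + H(Y) - H(X,Y)` exactly on
#' the table, and is non-negative.
#'
#' @param x,y Equal-length sample vectors (numeric or categorical).
#' @param n_bins Number of equal-width bins for continuous inputs (>= 2).
#' @return Non-negative scalar mutual information (nats).
#' @export
mutual_information <- function(x, y, n_bins = 16L) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two samples")
  stopifnot(n_bins >= 2)
  joint <- table(discretize(x, n_bins), discretize(y, n_bins))
  joint <- joint / sum(joint)
  px <- rowSums(joint); py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / outer_p[nz])))
}

#' Fuzzy entropy-mutual information filter selection
#'
#' Supervised filter: each feature is min-max normalized to [0, 1] to give
#' fuzzy memberships, its fuzzy entropy FE and its mutual information MI
#' with the class label are computed, and the combined score
#' `s_j = MI_j * FE_j / max_k FE_k` is thresholded at its mean. The fuzzy
#' weighting suppresses near-constant features (a zero-variance feature is
#' assigned FE = 0 and can never be selected) while preserving the MI
#' ranking among features of comparable fuzziness. Fully deterministic.
#'
#' @param features A labeled [feature_matrix()] with >= 2 classes.
#' @param n_bins Bins for the MI estimator.
#' @param K Fuzzy-entropy scale constant.
#' @return A [selection_result()] with method `"emi"`; `scores` holds the
#'   combined scores, and `fuzzy_entropy` / `mi` carry the components.
#' @export
emi_select <- function(features, n_bins = 16L, K = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels) || nlevels(features$labels) < 2L)
    stop("emi_select needs labels with at least two classes")
  v <- features$values
  d <- ncol(v)
  fe <- numeric(d); mi <- numeric(d)
  for (j in seq_len(d)) {
    x <- v[, j]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      fe[j] <- 0          # zero-variance guard: degenerate normalization
      mi[j] <- 0
    } else {
      memb <- (x - rng[1]) / (rng[2] - rng[1])
      fe[j] <- fuzzy_entropy(memb, K)
      mi[j] <- mutual_information(x, features$labels, n_bins)
    }
  }
  if (max(fe) == 0) stop("no informative variance")
  s <- mi * fe / max(fe)
  mask <- s >= mean(s)
  if (!any(mask)) mask[which.max(s)] <- TRUE
  selection_result(mask, s, "emi",
                   extra = list(fuzzy_entropy = fe, mi = mi,
                                threshold = mean(s)))
}
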