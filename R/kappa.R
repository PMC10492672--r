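#' Ordinal penalty weight matrix for weighted kappa
#'
#' Builds the \code{N x N} penalty matrix \eqn{w_{ij} = |i-j|^k / (N-1)^k}
#' used by the weighted-kappa agreement statistic and its loss form. The
#' diagonal is zero (exact agreement carries no penalty) and the maximal
#' penalty, between the extreme ratings, is 1. \code{k = 1} gives the
#' classical linear weighting, \code{k = 2} the quadratic one.
#'
#' @param N number of ordinal rating levels (>= 2); 5 for GEARS/OSATS.
#' @param k penalty exponent (>= 1).
#' @return an \code{N x N} numeric matrix with entries in \[0, 1\].
#' @export
#' @examples
#' weight_matrix(5, 1)[1, 5]  # 1: maximal disagreement
weight_matrix <- function(N, k = 1) {
  if (!is.numeric(N) || length(N) != 1L || N < 2) {
    stop("N must be a single integer >= 2")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a single number >= 1")
  }
  idx <- seq_len(N)
  abs(outer(idx, idx, "-"))^k / (N - 1)^k
}

#' Observed agreement matrix from two hard score vectors
#'
#' Cross-tabulates two equal-length vectors of integer ratings:
#' \code{O[i, j]} counts the items scored \code{i} by the first rater and
#' \code{j} by the second.
#'
#' @param scores_a,scores_b integer vectors of ratings in \code{1..N}.
#' @param N number of rating levels.
#' @return \code{N x N} count matrix with \code{sum(O) == length(scores_a)}.
#' @export
observed_matrix <- function(scores_a, scores_b, N = 5) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must have equal length")
  }
  a <- as.integer(scores_a)
  b <- as.integer(scores_b)
  if (any(a < 1L | a > N) || any(b < 1L | b > N)) {
    stop("scores must lie in 1..", N)
  }
  O <- matrix(0, N, N)
  for (n in seq_along(a)) O[a[n], b[n]] <- O[a[n], b[n]] + 1
  O
}

#' Soft (differentiable) observed matrix from predicted probabilities
#'
#' Differentiable surrogate for [observed_matrix()] used when training with
#' the weighted-kappa loss: row \code{i} collects the predicted probability
#' mass of all items whose true score is \code{i}, so
#' \code{O[i, j] = sum_n 1\[y_n = i\] p_n\[j\]}. With one-hot probability rows
#' it reduces exactly to the hard count matrix.
#'
#' @param probabilities \code{n x N} matrix; each row a distribution over the
#'   \code{N} levels (rows must sum to 1).
#' @param true_scores integer vector of length \code{n}, values in
#'   \code{1..N}.
#' @return \code{N x N} matrix of non-negative masses summing to \code{n}.
#' @export
soft_observed <- function(probabilities, true_scores) {
  P <- as.matrix(probabilities)
  N <- ncol(P)
  y <- as.integer(true_scores)
  if (length(y) != nrow(P)) stop("one true score per probability row required")
  if (any(y < 1L | y > N)) stop("true scores must lie in 1..", N)
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("probability rows must sum to 1")
  Y <- matrix(0, nrow(P), N)
  Y[cbind(seq_along(y), y)] <- 1
  crossprod(Y, P)
}

#' Expected agreement matrix under rater independence
#'
#' The chance-agreement matrix of weighted kappa: the outer product of the
#' row and column marginals of the observed matrix, rescaled so that
#' \code{sum(E) == sum(O)}.
#'
#' @param O observed matrix (hard counts or soft masses), \code{sum(O) > 0}.
#' @return matrix \code{E} of the same dimension.
#' @export
expected_matrix <- function(O) {
  O <- as.matrix(O)
  tot <- sum(O)
  if (tot <= 0) stop("observed matrix must have positive total mass")
  r <- rowSums(O)
  cc <- colSums(O)
  outer(r, cc) * (tot / (sum(r) * sum(cc)))
}

#' Weighted kappa and its logarithmic loss form
#'
#' Computes \eqn{\kappa = 1 - \sum w O / \sum w E} together with the training
#' loss \eqn{l = \log(1 - \kappa + \epsilon)}. \eqn{\kappa = 1} indicates
#' perfect agreement (all observed mass on the diagonal), \eqn{\kappa = 0}
#' agreement no better than chance (\code{O == E}).
#'
#' @param O observed matrix (see [observed_matrix()], [soft_observed()]).
#' @param E expected matrix (see [expected_matrix()]); defaults to
#'   \code{expected_matrix(O)}.
#' @param w penalty matrix (see [weight_matrix()]); defaults to linear
#'   weights for \code{nrow(O)} levels.
#' @param epsilon small positive constant guarding \code{log(0)} when
#'   agreement is perfect.
#' @return list with elements \code{kappa} and \code{loss}.
#' @export
#' @examples
#' O <- observed_matrix(c(1, 1, 2), c(1, 2, 2))
#' weighted_kappa_loss(O)$kappa  # 0.4
weighted_kappa_loss <- function(O, E = expected_matrix(O),
                                w = weight_matrix(nrow(O), 1),
                                epsilon = 1e-6) {
  O <- as.matrix(O)
  num <- sum(w * O)
  den <- sum(w * E)
  if (den <= 0) {
    stop("degenerate marginals: sum(w * E) is zero, kappa undefined")
  }
  kappa <- 1 - num / den
  list(kappa = kappa, loss = log(1 - kappa + epsilon))
}

#' Weighted-kappa loss of a probability batch, with analytic gradient
#'
#' Batch form of the weighted-kappa loss used to train ordinal heads: builds
#' the soft observed matrix from predicted probabilities, the expected matrix
#' from its marginals, and returns \code{log(1 - kappa + epsilon)} together
#' with the gradient with respect to the probabilities. The gradient is exact
#' (verified against finite differences in the test suite).
#'
#' @param P \code{n x N} predicted probability matrix (rows sum to 1).
#' @param y integer true scores, length \code{n}.
#' @param w penalty matrix; linear weights by default.
#' @param epsilon guard constant for \code{log}.
#' @return list: \code{loss}, \code{kappa}, and \code{dP} (\code{n x N}
#'   gradient of the loss in the probabilities).
#' @export
wk_batch_loss <- function(P, y, w = weight_matrix(ncol(P), 1),
                          epsilon = 1e-6) {
  P <- as.matrix(P)
  n <- nrow(P)
  N <- ncol(P)
  y <- as.integer(y)
  O <- soft_observed(P, y)
  r <- rowSums(O)                      # true-score counts, constant in P
  cc <- colSums(O)
  A <- sum(w * O)
  B <- as.numeric(crossprod(r, w %*% cc)) / n
  if (B <= 0) stop("degenerate marginals: weighted expected agreement is zero")
  kappa <- 1 - A / B
  loss <- log(A / B + epsilon)         # == log(1 - kappa + epsilon)
  # dA/dP[m, j] = w[y_m, j];  dB/dP[m, j] = (w' r)[j] / n
  wr <- as.numeric(crossprod(w, r)) / n
  denom <- A + epsilon * B
  dP <- w[y, , drop = FALSE] / denom -
    matrix(wr, n, N, byrow = TRUE) * (A / (B * denom))
  list(loss = loss, kappa = kappa, dP = dP)
}
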