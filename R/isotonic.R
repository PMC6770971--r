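# Min-max isotonic transformation.
#
# For a simple order mu_1 <= ... <= mu_K the order-restricted value is
#   mu~_k = min_{t >= k} max_{s <= k} Av(s, t),
# where Av(s, t) = 1' V[s:t]^{-1} mu[s:t] / 1' V[s:t]^{-1} 1 is the
# covariance-weighted block mean over the contiguous block s..t. With a
# diagonal V this is the precision-weighted mean and the transform
# coincides with weighted pool-adjacent-violators.

# Precompute the block weight vectors a(s,t) = V[s:t]^{-1} 1 (normalised)
# for all contiguous blocks; V fixed across draws.
block_weights <- function(V) {
  K <- nrow(V)
  blocks <- list()
  for (s in seq_len(K)) {
    for (t in s:K) {
      a <- solve(V[s:t, s:t, drop = FALSE], rep(1, t - s + 1))
      blocks[[paste(s, t)]] <- list(s = s, t = t, w = a / sum(a))
    }
  }
  blocks
}

#' Min-max isotonic transformation of a draw matrix
#'
#' Applies the covariance-weighted min-max isotonic transformation row by
#' row, mapping unconstrained draws of the group effects onto the monotone
#' cone `mu~_1 <= ... <= mu~_K`. Also flags, per row, the complete-pooling
#' event `mu~_K = mu~_1` (all groups collapsed to one weighted mean),
#' which is detected through the shared full-range block mean rather than
#' by comparing independently rounded floats.
#'
#' @param draws S x K numeric matrix of draws (or a single K-vector).
#' @param V K x K symmetric positive-definite weight matrix; the posterior
#'   covariance of the group effects (diagonal in the standard scalar-
#'   block case). Identity by default, appropriate for exchangeable prior
#'   draws.
#' @return A list with `draws` (S x K matrix of transformed rows, each
#'   nondecreasing) and `pooled` (logical length-S vector of the
#'   complete-pooling events).
#' @examples
#' transform_draws(rbind(c(4, 3, 2, 1)))$draws  # all 2.5: total pooling
#' @export
transform_draws <- function(draws, V = NULL) {
  if (is.vector(draws)) draws <- matrix(draws, nrow = 1)
  S <- nrow(draws); K <- ncol(draws)
  if (K < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(V)) V <- diag(K)
  V <- as.matrix(V)
  stopifnot(nrow(V) == K, ncol(V) == K)
  if (any(diag(V) <= 0)) {
    stop("weight matrix must have positive diagonal", call. = FALSE)
  }
  if (!all(is.finite(draws))) stop("draws must be finite", call. = FALSE)

  bw <- tryCatch(block_weights(V), error = function(e) {
    stop("singular block submatrix in weight matrix: ",
         conditionMessage(e), call. = FALSE)
  })
  # block means for every contiguous block, vectorised across rows
  bm <- lapply(bw, function(b) {
    as.vector(draws[, b$s:b$t, drop = FALSE] %*% b$w)
  })
  out <- matrix(NA_real_, S, K, dimnames = dimnames(draws))
  for (k in seq_len(K)) {
    inner <- NULL
    for (t in k:K) {
      mx <- NULL
      for (s in 1:k) {
        v <- bm[[paste(s, t)]]
        mx <- if (is.null(mx)) v else pmax(mx, v)
      }
      inner <- if (is.null(inner)) mx else pmin(inner, mx)
    }
    out[, k] <- inner
  }
  # mu~_1 minimises over a set containing the full-range mean M and
  # mu~_K maximises over a set containing the same computed M, so
  # mu~_1 <= M <= mu~_K holds exactly in floating point and equality
  # identifies complete pooling.
  list(draws = out, pooled = out[, 1] == out[, K])
}

#' Min-max isotonic transformation of a single vector
#'
#' @param mu Numeric K-vector of unconstrained values.
#' @param V Optional K x K weight matrix (see [transform_draws()]).
#' @return The order-restricted K-vector.
#' @examples
#' minmax_transform(c(4, 3, 2, 1))  # rep(2.5, 4)
#' minmax_transform(1:4)            # unchanged
#' @export
minmax_transform <- function(mu, V = NULL) {
  as.vector(transform_draws(matrix(mu, nrow = 1), V)$draws)
}
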