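# Order-restricted Bayes factor.
#
# M0: mu_1 = ... = mu_K  versus  M1: mu_1 <= ... <= mu_K (some strict).
# After the min-max transformation, a draw supports M0 exactly when it is
# completely pooled (mu~_K = mu~_1) and M1 otherwise, so
#   BF = [P(mu~_K > mu~_1 | data) / P(mu~_K0 > mu~_10)] /
#        [P(mu~_K = mu~_1 | data) / P(mu~_K0 = mu~_10)],
# with all four probabilities estimated as pooling-flag frequencies over
# posterior and prior draws.

#' Compute the order-restricted Bayes factor from transformed draws
#'
#' @param posterior Output of [transform_draws()] on posterior draws
#'   (weighted by the posterior covariance of the group effects).
#' @param prior Output of [transform_draws()] on exchangeable prior draws
#'   (identity weights).
#' @return A one-row tibble: `bf`, `post_gt`, `post_eq`, `prior_gt`,
#'   `prior_eq`, `n_posterior_draws`, `n_prior_draws`, and `bf_censored`
#'   (`TRUE` when no posterior draw was completely pooled, in which case
#'   `post_eq` is replaced by `1 / (2 S)` and `bf` is a finite lower
#'   bound).
#' @examples
#' post <- transform_draws(matrix(rnorm(4000), 1000, 4))
#' prior <- transform_draws(matrix(rnorm(40000), 10000, 4))
#' compute_bf(post, prior)
#' @export
compute_bf <- function(posterior, prior) {
  S <- length(posterior$pooled)
  S0 <- length(prior$pooled)
  if (S == 0 || S0 == 0) stop("empty draw set", call. = FALSE)
  post_eq <- mean(posterior$pooled)
  prior_eq <- mean(prior$pooled)
  if (prior_eq == 0) {
    stop("no prior draw was completely pooled; increase the number of ",
         "prior draws", call. = FALSE)
  }
  censored <- post_eq == 0
  post_eq_adj <- if (censored) 1 / (2 * S) else post_eq
  post_gt <- 1 - post_eq_adj
  prior_gt <- 1 - prior_eq
  bf <- (post_gt / prior_gt) / (post_eq_adj / prior_eq)
  tibble::tibble(
    bf = bf, post_gt = post_gt, post_eq = post_eq_adj,
    prior_gt = prior_gt, prior_eq = prior_eq,
    n_posterior_draws = S, n_prior_draws = S0, bf_censored = censored
  )
}

#' Bayes factor for a fitted window
#'
#' Convenience wrapper: transforms the posterior draws of a [bfm_fit]
#' (weighted by its estimated posterior covariance), transforms prior
#' draws with identity weights, and forms the order-restricted Bayes
#' factor.
#'
#' @param fit A `bfm_fit` from [fit_bfm_window()].
#' @param prior Optional pre-transformed prior draws (the output of
#'   `transform_draws(sample_prior_mu(...))`), reusable across windows.
#' @param n_prior_draws,prior_seed Used to draw the prior when `prior` is
#'   not supplied.
#' @return The one-row tibble of [compute_bf()] plus an `evidence` column.
#' @export
window_bf <- function(fit, prior = NULL, n_prior_draws = 10000,
                      prior_seed = derive_seed(fit$seed, "prior")) {
  if (is.null(prior)) {
    prior <- transform_draws(
      sample_prior_mu(fit$K, n_prior_draws, fit$control$mu_prior_sd,
                      prior_seed))
  }
  post <- transform_draws(fit$mu, fit$V)
  res <- compute_bf(post, prior)
  res$evidence <- evidence_category(res$bf)
  res
}

#' Jeffreys evidence category for a Bayes factor
#'
#' `none` for BF <= 3, `positive` for 3 < BF <= 10, `strong` for
#' 10 < BF <= 100, `decisive` for BF > 100.
#'
#' @param bf Numeric vector of nonnegative Bayes factors.
#' @return An ordered factor with levels none < positive < strong <
#'   decisive.
#' @examples
#' evidence_category(c(1, 5, 18.79, 8554.12))
#' @export
evidence_category <- function(bf) {
  if (any(bf < 0, na.rm = TRUE)) {
    stop("Bayes factors must be nonnegative", call. = FALSE)
  }
  cut(bf, breaks = c(-Inf, 3, 10, 100, Inf),
      labels = c("none", "positive", "strong", "decisive"),
      ordered_result = TRUE)
}
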