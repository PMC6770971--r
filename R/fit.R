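#' Control parameters for the window-level model fit
#'
#' Collects the MCMC settings and hyperprior parameters of the
#' mixed-effect logistic model. Defaults follow the reference analysis:
#' 3000 Gibbs iterations with a 1000-iteration burn-in, vague
#' `N(0, 1000^2)` priors on the group effects, `IG(1, 100)` on the
#' individual random-effect variance and `Wishart(I_m, m)` on the
#' between-site precision matrix.
#'
#' @param n_iter Total Gibbs iterations.
#' @param n_burnin Burn-in iterations discarded from the front.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param mu_prior_sd Prior SD of each group effect mu_k.
#' @param ig_shape,ig_scale Inverse-gamma hyperparameters shared by the
#'   variance components.
#' @param hierarchical_mu If `TRUE`, the group effects get a hierarchical
#'   prior `mu_k ~ N(mu_mu, sigma_mu^2)` with `sigma_mu^2 ~ IG(ig_shape,
#'   ig_scale)` and `mu_mu ~ N(0, mu_prior_sd^2)` instead of the fixed
#'   vague prior. Experimental; the Bayes factor prior draws always use
#'   the fixed `N(0, mu_prior_sd^2)` prior.
#' @param random_effects If `FALSE`, both random-effect terms are pinned
#'   to zero (useful for validation against conjugate oracles).
#' @param beta_prior_sd Prior SD for optional covariate coefficients.
#' @param pg_exact_max Coverage count up to which Polya-Gamma variables
#'   are drawn by the exact Devroye sampler; larger counts use a
#'   moment-matched normal approximation.
#' @return A list of class `bfm_control`.
#' @export
bfm_control <- function(n_iter = 3000, n_burnin = 1000, thin = 1,
                        mu_prior_sd = 1000, ig_shape = 1, ig_scale = 100,
                        hierarchical_mu = FALSE, random_effects = TRUE,
                        beta_prior_sd = 1000, pg_exact_max = 8) {
  stopifnot(n_burnin < n_iter, thin >= 1, mu_prior_sd > 0,
            ig_shape > 0, ig_scale > 0)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 mu_prior_sd = mu_prior_sd, ig_shape = ig_shape,
                 ig_scale = ig_scale, hierarchical_mu = hierarchical_mu,
                 random_effects = random_effects,
                 beta_prior_sd = beta_prior_sd,
                 pg_exact_max = as.integer(pg_exact_max)),
            class = "bfm_control")
}

# Pivot a (window-restricted) methylation tibble into matrices for the
# sampler: individuals x sites count matrices plus group labels.
meth_matrices <- function(data) {
  data <- dplyr::arrange(data, .data$chrom, .data$pos, .data$sample)
  samples <- sort(unique(data$sample))
  sites <- dplyr::distinct(data, .data$chrom, .data$pos)
  wide_m <- tidyr::pivot_wider(
    dplyr::select(data, "chrom", "pos", "sample", "meth"),
    names_from = "sample", values_from = "meth", values_fill = 0L
  )
  wide_c <- tidyr::pivot_wider(
    dplyr::select(data, "chrom", "pos", "sample", "cov"),
    names_from = "sample", values_from = "cov", values_fill = 0L
  )
  meth <- t(as.matrix(wide_m[, samples, drop = FALSE]))
  cov <- t(as.matrix(wide_c[, samples, drop = FALSE]))
  groups <- dplyr::distinct(data, .data$sample, .data$group)
  groups <- groups$group[match(samples, groups$sample)]
  list(meth = meth, cov = cov, group = as.integer(groups),
       samples = samples, sites = sites)
}

#' Fit the mixed-effect logistic model to one window
#'
#' Gibbs-samples the posterior of the ordinal group effects
#' (mu_1, ..., mu_K) for a single window of CpG sites under the binomial
#' logit model with an individual-level random intercept and a correlated
#' site-level random effect. The likelihood is augmented with Polya-Gamma
#' variables so every conditional update is conjugate.
#'
#' @param data Methylation tibble restricted to the window's sites (use
#'   `sites` to subset a larger table).
#' @param sites Optional integer site indices (1-based, in position order
#'   within each chromosome) selecting the window from `data`.
#' @param control A [bfm_control()] list.
#' @param seed Integer seed for the sampler.
#' @param covariates Optional numeric matrix (one row per sample, ordered
#'   by sample name) of fixed-effect covariates; experimental.
#' @return An object of class `bfm_fit`: a list with `mu` (S x K matrix of
#'   retained draws), `V` (K x K diagonal posterior covariance of the
#'   group effects, estimated from the draws), `sigma_v0_sq` draws,
#'   `Sigma` (last between-site covariance), `diagnostics` (per-group
#'   effective sample sizes), and the call metadata.
#' @examples
#' d <- simulate_methylation(n_per_group = 3, n_reads = 20, seed = 1)
#' fit <- fit_bfm_window(d, sites = 10:15,
#'                       control = bfm_control(n_iter = 200, n_burnin = 100),
#'                       seed = 1)
#' tidy(fit)
#' @export
fit_bfm_window <- function(data, sites = NULL,
                           control = bfm_control(), seed = 1,
                           covariates = NULL) {
  data <- validate_meth_data(data)
  if (!is.null(sites)) {
    pos_tbl <- dplyr::distinct(data, .data$chrom, .data$pos)
    pos_tbl <- dplyr::mutate(dplyr::group_by(pos_tbl, .data$chrom),
                             site_index = dplyr::row_number())
    pos_tbl <- dplyr::ungroup(pos_tbl)
    keep <- dplyr::filter(pos_tbl, .data$site_index %in% sites)
    data <- dplyr::semi_join(data, keep, by = c("chrom", "pos"))
  }
  mats <- meth_matrices(data)
  m <- ncol(mats$meth)
  K <- max(mats$group)
  if (m < 2) stop("window must contain at least 2 CpG sites", call. = FALSE)
  cov_by_group <- tapply(rowSums(mats$cov), mats$group, sum)
  if (any(cov_by_group == 0)) {
    stop("group(s) ", paste(names(cov_by_group)[cov_by_group == 0],
                            collapse = ", "),
         " have zero total coverage in this window", call. = FALSE)
  }
  X <- if (is.null(covariates)) matrix(0, nrow(mats$meth), 0)
       else as.matrix(covariates)

  set.seed(seed)
  res <- .bfm_gibbs(mats$meth, mats$cov, mats$group, K,
                    control$n_iter, control$n_burnin, control$thin,
                    control$mu_prior_sd, control$ig_shape, control$ig_scale,
                    control$hierarchical_mu, control$random_effects,
                    X, control$beta_prior_sd, control$pg_exact_max)
  mu <- res$mu
  colnames(mu) <- paste0("mu", seq_len(K))
  structure(list(
    mu = mu,
    V = diag(apply(mu, 2, var), K),
    beta = res$beta,
    sigma_v0_sq = res$sigma_v0_sq,
    Sigma = res$Sigma,
    diagnostics = tibble::tibble(
      term = colnames(mu), ess = apply(mu, 2, ess)
    ),
    K = K, n_sites = m, sites = mats$sites, samples = mats$samples,
    control = control, seed = seed
  ), class = "bfm_fit")
}

#' Draw group effects from the prior
#'
#' I.i.d. draws `mu_k0 ~ N(0, sd^2)`, independent across the K groups, as
#' used for the denominator of the order-restricted Bayes factor.
#'
#' @param K Number of groups.
#' @param n_draws Number of prior draws (rows).
#' @param sd Prior standard deviation (default 1000).
#' @param seed Integer seed.
#' @return An `n_draws` x K numeric matrix.
#' @export
sample_prior_mu <- function(K, n_draws = 10000, sd = 1000, seed = 1) {
  stopifnot(n_draws >= 1, K >= 2)
  set.seed(seed)
  matrix(rnorm(n_draws * K, 0, sd), n_draws, K,
         dimnames = list(NULL, paste0("mu", seq_len(K))))
}

#' @export
print.bfm_fit <- function(x, ...) {
  cat("Mixed-effect logistic window fit (", nrow(x$mu), " draws, K = ",
      x$K, ", ", x$n_sites, " sites)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy the posterior of a window fit
#'
#' @param x A `bfm_fit`.
#' @param ... Unused.
#' @return One row per group effect with posterior mean, SD, 95% credible
#'   interval, the implied methylation rate (inverse-logit of the
#'   posterior mean) and effective sample size.
#' @method tidy bfm_fit
#' @export
tidy.bfm_fit <- function(x, ...) {
  tibble::tibble(
    term = colnames(x$mu),
    estimate = colMeans(x$mu),
    std.error = apply(x$mu, 2, stats::sd),
    conf.low = apply(x$mu, 2, quantile, 0.025),
    conf.high = apply(x$mu, 2, quantile, 0.975),
    meth_rate = inv_logit(colMeans(x$mu)),
    ess = x$diagnostics$ess
  )
}

#' One-line summary of a window fit
#'
#' @param x A `bfm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with draw counts and the minimum effective
#'   sample size across group effects.
#' @method glance bfm_fit
#' @export
glance.bfm_fit <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$mu), n_groups = x$K, n_sites = x$n_sites,
    n_samples = length(x$samples),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' Posterior density plot of the group effects
#'
#' @param object A `bfm_fit`.
#' @param ... Unused.
#' @return A ggplot of per-group posterior densities on the logit scale.
#' @method autoplot bfm_fit
#' @export
autoplot.bfm_fit <- function(object, ...) {
  draws <- tibble::as_tibble(object$mu)
  long <- tidyr::pivot_longer(draws, dplyr::everything(),
                              names_to = "term", values_to = "mu")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, colour = .data$term)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(mu[k]), y = "posterior density",
                  colour = "group effect") +
    ggplot2::theme_minimal()
}
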