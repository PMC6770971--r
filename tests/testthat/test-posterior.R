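test_that("with random effects pinned, the fit matches the beta-binomial oracle", {
  # one group, two sites sharing mu_1, counts 50/100 at each site; with a
  # flat prior the pooled conjugate posterior is Beta(100.5, 100.5)
  d <- tibble::tibble(
    chrom = "c", pos = c(10L, 20L, 10L, 20L),
    sample = rep(c("a", "b"), each = 2), group = 1L,
    meth = 50L, cov = 100L
  )
  fit <- fit_bfm_window(d, control = bfm_control(random_effects = FALSE),
                        seed = 7)
  rate <- mean(inv_logit_test(fit$mu[, 1]))
  expect_lt(abs(rate - 0.5), 0.01)
  expect_true(abs(rate - 0.5) < 0.05 / sqrt(100))  # tighter CLT-style bound

  # asymmetric counts: oracle mean 30.5/101 ~ 0.302
  d2 <- d; d2$meth <- c(15L, 15L, 15L, 15L); d2$cov <- 50L
  fit2 <- fit_bfm_window(d2, control = bfm_control(random_effects = FALSE),
                         seed = 8)
  expect_lt(abs(mean(inv_logit_test(fit2$mu[, 1])) - 0.3), 0.02)
})

test_that("posterior concentrates on the pooled empirical rate at high coverage", {
  set.seed(2)
  d <- make_counts_tbl(n_sites = 3, n_per_group = 2, K = 2, cov = 10000,
                       rate = 0.37, seed = 2)
  d$meth[d$group == 2] <- rbinom(sum(d$group == 2), 10000, 0.62)
  fit <- fit_bfm_window(d, control = bfm_control(random_effects = FALSE),
                        seed = 3)
  emp <- vapply(1:2, function(k) {
    sel <- d$group == k
    sum(d$meth[sel]) / sum(d$cov[sel])
  }, numeric(1))
  post <- inv_logit_test(colMeans(fit$mu))
  expect_lt(max(abs(post - emp)), 0.02)
})

test_that("two groups with identical data give a symmetric posterior", {
  half <- make_counts_tbl(n_sites = 4, n_per_group = 4, K = 1, cov = 30,
                          rate = 0.5, seed = 5)
  other <- half
  other$sample <- sub("^g1", "g2", other$sample)
  other$group <- 2L
  d <- dplyr::bind_rows(half, other)
  fit <- fit_bfm_window(d, seed = 11)
  diffs <- fit$mu[, 1] - fit$mu[, 2]
  mcse <- stats::sd(diffs) / sqrt(min(fit$diagnostics$ess))
  expect_lt(abs(mean(diffs)), 3 * mcse + 0.02)
})

test_that("permuting group labels permutes the posterior", {
  d <- make_counts_tbl(n_sites = 4, n_per_group = 4, K = 2, cov = 200,
                       rate = 0.3, seed = 6)
  d$meth[d$group == 2] <- rbinom(sum(d$group == 2), 200, 0.7)
  fit <- fit_bfm_window(d, seed = 12)
  swapped <- d
  swapped$group <- 3L - d$group
  fit_sw <- fit_bfm_window(swapped, seed = 12)
  expect_equal(colMeans(fit$mu), rev(colMeans(fit_sw$mu)),
               tolerance = 0.15, ignore_attr = TRUE)
})

test_that("chains are reproducible and error cases are caught", {
  d <- make_counts_tbl(n_sites = 3, n_per_group = 3, K = 2, seed = 7)
  f1 <- fit_bfm_window(d, control = fast_ctrl(), seed = 99)
  f2 <- fit_bfm_window(d, control = fast_ctrl(), seed = 99)
  expect_identical(f1$mu, f2$mu)

  dz <- d; dz$cov[dz$group == 2] <- 0L; dz$meth[dz$group == 2] <- 0L
  expect_error(fit_bfm_window(dz, control = fast_ctrl()), "zero total coverage")
  expect_error(fit_bfm_window(d[d$pos == 10, ], control = fast_ctrl()),
               "at least 2 CpG sites")
  expect_error(bfm_control(n_iter = 100, n_burnin = 100))
})

test_that("hierarchical prior and covariate modes run and stay finite", {
  d <- make_counts_tbl(n_sites = 3, n_per_group = 3, K = 2, seed = 8)
  fh <- fit_bfm_window(d, control = fast_ctrl(hierarchical_mu = TRUE),
                       seed = 13)
  expect_true(all(is.finite(fh$mu)))
  X <- matrix(rnorm(6), ncol = 1)
  fx <- fit_bfm_window(d, control = fast_ctrl(), seed = 14, covariates = X)
  expect_true(all(is.finite(fx$beta)))
  expect_equal(ncol(fx$beta), 1)
})

test_that("prior draws are iid with the declared scale", {
  pr <- sample_prior_mu(4, n_draws = 10000, sd = 1000, seed = 21)
  expect_equal(dim(pr), c(10000, 4))
  # CLT bound on each column mean
  expect_true(all(abs(colMeans(pr)) < 4 * 1000 / sqrt(10000)))
  # chi-square interval for the sample SD
  sds <- apply(pr, 2, stats::sd)
  expect_true(all(sds > 960 & sds < 1040))
  # exchangeability: KS between two columns
  ks <- suppressWarnings(stats::ks.test(pr[, 1], pr[, 3]))
  expect_gt(ks$p.value, 0.01)
})
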