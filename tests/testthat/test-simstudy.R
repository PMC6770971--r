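fake_study <- function(windows) {
  structure(list(windows = windows, n_replicates = max(windows$replicate),
                 n_per_group = 50, scenario = 1, window_size = 6,
                 dmr_range = c(10L, 15L), seed = 1),
            class = "bfm_simstudy")
}

test_that("DMC counts per window start follow the overlap rule", {
  expect_equal(window_dmc_count(1:19, 6, c(10, 15)),
               c(0L, 0L, 0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L, 5L, 4L, 3L, 2L,
                 1L, 0L, 0L, 0L, 0L))
  expect_equal(window_dmc_count(1, 24, c(10, 15)), 6L)
  expect_equal(window_dmc_count(16, 6, c(10, 15)), 0L)
})

test_that("null cutoffs are empirical quantiles with input validation", {
  set.seed(9)
  u <- runif(10000)
  cu <- null_cutoffs(u, levels = c(0.95, 0.99))
  expect_equal(cu$cutoff, c(0.95, 0.99), tolerance = 0.01)
  expect_equal(cu$level, c(0.95, 0.99))
  const <- null_cutoffs(rep(2.5, 200))
  expect_equal(const$cutoff, c(2.5, 2.5))
  expect_error(null_cutoffs(runif(50)), "at least 100")
})

test_that("null definitions select the intended windows", {
  w <- tidyr::crossing(replicate = 1:20, start_site = 1:19)
  w$end_site <- w$start_site + 5L
  w$n_dmc <- window_dmc_count(w$start_site, 6, c(10, 15))
  w$bf <- 1 + w$start_site / 100  # distinct per start
  w$bf_censored <- FALSE
  st <- fake_study(w)
  # zero-DMC: starts 1-4 and 16-19
  c0 <- null_cutoffs(st, levels = 0.5)
  expect_equal(c0$cutoff, stats::median(1 + c(1:4, 16:19) / 100))
  # excluding the left DMR boundary sites keeps starts 1-4 and 12-19
  c1 <- null_cutoffs(st, levels = 0.5, null = "excl_left")
  expect_equal(c1$cutoff, stats::median(1 + c(1:4, 12:19) / 100))
})

test_that("exceedance is tabulated by DMC stratum", {
  w <- tidyr::crossing(replicate = 1:50, start_site = c(1, 5, 6, 10))
  w$end_site <- w$start_site + 5L
  w$n_dmc <- window_dmc_count(w$start_site, 6, c(10, 15))
  set.seed(4)
  w$bf <- c(1, 2, 5, 50)[match(w$start_site, c(1, 5, 6, 10))] *
    exp(rnorm(nrow(w), sd = 0.1))
  w$bf_censored <- FALSE
  ex <- exceedance_by_dmc(fake_study(w), cutoffs = c(1.34, 1.5))
  expect_equal(nrow(ex), 8)  # 4 strata x 2 cutoffs
  expect_true(all(ex$exceedance >= 0 & ex$exceedance <= 1))
  # monotone in the number of DMCs at each cutoff
  for (ct in c(1.34, 1.5)) {
    sub <- ex[ex$cutoff == ct, ]
    sub <- sub[order(sub$n_dmc), ]
    expect_true(all(diff(sub$exceedance) >= 0))
  }
})

test_that("a micro simulation study has the declared shape and is reproducible", {
  st <- run_sim_study(n_replicates = 2, n_per_group = 2, n_reads = 15,
                      starts = c(1, 10), seed = 77,
                      control = bfm_control(n_iter = 120, n_burnin = 40))
  expect_s3_class(st, "bfm_simstudy")
  expect_equal(nrow(st$windows), 4)
  expect_equal(sort(unique(st$windows$start_site)), c(1L, 10L))
  expect_equal(st$windows$n_dmc[st$windows$start_site == 10], c(6L, 6L))
  td <- tidy(st)
  expect_equal(td$n, c(2L, 2L))
  st2 <- run_sim_study(n_replicates = 2, n_per_group = 2, n_reads = 15,
                       starts = c(1, 10), seed = 77,
                       control = bfm_control(n_iter = 120, n_burnin = 40))
  expect_identical(st$windows, st2$windows)
  gl <- glance(st)
  expect_equal(gl$peak_start, 10L)
})
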