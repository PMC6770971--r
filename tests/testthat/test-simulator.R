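test_that("the reference branching profile matches its printed anchors", {
  prof <- scenario1_profile()
  p <- function(g, s) prof$p[prof$group == g & prof$site == s]
  q <- function(g, s) prof$q[prof$group == g & prof$site == s]
  expect_equal(p(4, 12), 0.96)
  expect_equal(p(1, 1), 0.44)
  expect_equal(p(3, 10), 0.82)
  expect_equal(q(2, 12), 0.56)  # 0.76 - 0.2
  # flank anchors shared by all groups, 0.02 steps
  for (g in 1:4) {
    expect_equal(p(g, 2), 0.46)
    expect_equal(p(g, 9), 0.60)
    expect_equal(p(g, 16), 0.60)
    expect_equal(p(g, 17), 0.58)
    expect_equal(p(g, 24), 0.44)
  }
  # DMR symmetry about sites 12-13 and monotone severity ordering
  dmr <- attr(prof, "dmr_range")
  expect_equal(dmr, c(10L, 15L))
  for (g in 1:4) {
    row <- prof$p[prof$group == g][10:15]
    expect_equal(row, rev(row))
    expect_equal(max(row), 0.56 + 0.1 * g)
  }
  expect_true(all(prof$q >= 0 & prof$p <= 1))
  expect_equal(prof$q, prof$p - 0.2)
})

test_that("peak randomisation keeps the value multiset, unimodal shape, and uniform peaks", {
  prof <- scenario1_profile()
  set.seed(20)
  rp <- randomize_peaks(prof, 2500)  # 4 groups x 2500 = 10,000 peaks
  peaks <- attr(rp, "peaks")
  expect_equal(nrow(peaks), 10000)
  # chi-square GOF for uniformity over sites 10..15
  tab <- table(factor(peaks$peak, levels = 10:15))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  sub <- dplyr::filter(rp, .data$individual <= 50)
  for (key in split(sub, interaction(sub$group, sub$individual))) {
    row <- key$p[order(key$site)]
    r <- peaks$peak[peaks$group == key$group[1] &
                      peaks$individual == key$individual[1]]
    expect_equal(row[r], max(row[10:15]))  # peak value sits at r (ties left)
    expect_true(all(diff(row[10:r]) >= 0))
    expect_true(all(diff(row[r:15]) <= 0))
    # multiset preserved against the group's scenario-1 DMR values
    ref <- sort(prof$p[prof$group == key$group[1]][10:15])
    expect_equal(sort(row[10:15]), ref)
    # non-DMR sites untouched
    expect_equal(row[c(1:9, 16:24)],
                 prof$p[prof$group == key$group[1]][c(1:9, 16:24)])
  }
  # a peak drawn at site 13 reproduces the scenario-1 row exactly
  i13 <- peaks[peaks$peak == 13, ][1, ]
  row13 <- dplyr::filter(rp, .data$group == i13$group,
                         .data$individual == i13$individual)
  expect_equal(row13$p[order(row13$site)],
               prof$p[prof$group == i13$group])
})

test_that("read simulation follows the branching chain", {
  prof <- scenario1_profile()
  p <- prof$p[prof$group == 1]
  q <- prof$q[prof$group == 1]

  # degenerate absorbing chain: read equals its first state repeated
  set.seed(1)
  for (i in 1:20) {
    y <- simulate_read(rep(1, 24), rep(0, 24), a = 3, len = 10)
    expect_true(all(y == y[1]))
  }

  # first-site marginal (p + q) / 2 and the full recursion oracle
  set.seed(2)
  n <- 50000
  cnt <- bfmeth:::simulate_read_counts(p, q, starts = rep(1L, n),
                                       lens = rep(24L, n))
  expect_equal(cnt$cov, rep(n, 24))
  marg <- chain_marginal_oracle(p, q, 1, 24)
  expect_equal(marg[1], (0.44 + 0.24) / 2)
  expect_equal(cnt$meth / n, marg, tolerance = 0.01)

  # positive lag-1 autocorrelation whenever p > q
  set.seed(3)
  reads <- t(replicate(5000, simulate_read(p, q, a = 11, len = 2)))
  expect_gt(suppressWarnings(stats::cor(reads[, 1], reads[, 2])), 0.05)
})

test_that("datasets aggregate reads into consistent counts", {
  # single full-length read covers every site exactly once
  prof <- scenario1_profile()
  p <- prof$p[prof$group == 2]
  set.seed(5)
  cnt <- bfmeth:::simulate_read_counts(p, p - 0.2, starts = 1L, lens = 24L)
  expect_equal(cnt$cov, rep(1L, 24))

  # coverage equals the number of overlapping reads
  starts <- c(1L, 5L, 5L, 20L); lens <- c(10L, 4L, 6L, 5L)
  cnt <- bfmeth:::simulate_read_counts(p, p - 0.2, starts, lens)
  manual <- vapply(1:24, function(j)
    sum(starts <= j & starts + lens - 1 >= j), integer(1))
  expect_equal(cnt$cov, manual)
  expect_true(all(cnt$meth <= cnt$cov))

  d <- simulate_methylation(n_per_group = 5, n_reads = 40, seed = 9)
  expect_true(all(d$meth <= d$cov))
  expect_equal(dplyr::n_distinct(d$sample), 20)
  expect_equal(nrow(d), 20 * 24)

  # determinism under a fixed seed, and invariance of early individuals
  d2 <- simulate_methylation(n_per_group = 5, n_reads = 40, seed = 9)
  expect_identical(d, d2)
  d3 <- simulate_methylation(n_per_group = 7, n_reads = 40, seed = 9)
  expect_equal(dplyr::semi_join(d3, d, by = "sample"), d,
               ignore_attr = TRUE)
})

test_that("group 4 is more methylated than group 1 at the DMR peak", {
  d <- simulate_methylation(n_per_group = 50, n_reads = 100, seed = 31)
  at12 <- dplyr::filter(d, .data$pos == 50 * 12, .data$group %in% c(1, 4))
  rates <- at12$meth / at12$cov
  tt <- stats::t.test(rates[at12$group == 4], rates[at12$group == 1],
                      alternative = "greater")
  expect_lt(tt$p.value, 1e-10)
  expect_gt(mean(rates[at12$group == 4]), mean(rates[at12$group == 1]) + 0.2)
})
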