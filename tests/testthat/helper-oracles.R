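# Independent oracles used to cross-check the implementation.

# Weighted pool-adjacent-violators for the simple increasing order.
# Classic stack algorithm; weights w > 0. Independent of the min-max
# formula used by the package.
pava_oracle <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  top <- 0
  for (i in seq_len(n)) {
    top <- top + 1
    val[top] <- y[i]; wt[top] <- w[i]; len[top] <- 1L
    while (top > 1 && val[top - 1] > val[top]) {
      wtot <- wt[top - 1] + wt[top]
      val[top - 1] <- (wt[top - 1] * val[top - 1] + wt[top] * val[top]) / wtot
      wt[top - 1] <- wtot
      len[top - 1] <- len[top - 1] + len[top]
      top <- top - 1
    }
  }
  rep(val[seq_len(top)], times = len[seq_len(top)])
}

# Marginal methylation probability at each site of a read starting at a,
# by the chain recursion P_j = p_j P_{j-1} + q_j (1 - P_{j-1}),
# P_a = (p_a + q_a) / 2.
chain_marginal_oracle <- function(p, q, a, len) {
  out <- numeric(len)
  out[1] <- (p[a] + q[a]) / 2
  if (len > 1) {
    for (s in 2:len) {
      j <- a + s - 1
      out[s] <- p[j] * out[s - 1] + q[j] * (1 - out[s - 1])
    }
  }
  out
}

# Small synthetic methylation table: two chromosomes optional.
make_counts_tbl <- function(n_sites = 10, n_per_group = 3, K = 2,
                            rate = 0.5, cov = 20, seed = 1,
                            chrom = "chrT") {
  set.seed(seed)
  grid <- expand.grid(site = seq_len(n_sites),
                      g = seq_len(K), i = seq_len(n_per_group))
  tibble::tibble(
    chrom = chrom,
    pos = grid$site * 10L,
    sample = sprintf("g%d_i%d", grid$g, grid$i),
    group = as.integer(grid$g),
    cov = as.integer(cov),
    meth = rbinom(nrow(grid), cov, rate)
  )[, c("chrom", "pos", "sample", "group", "meth", "cov")]
}

fast_ctrl <- function(...) bfm_control(n_iter = 300, n_burnin = 100, ...)

inv_logit_test <- function(x) 1 / (1 + exp(-x))
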