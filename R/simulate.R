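# Branching-process short-read simulator.
#
# Methylation states along a read are a two-state Markov chain ("branching
# process" on the multivariate Bernoulli): P(Y_j = 1 | Y_{j-1} = 1) = p_kj,
# P(Y_j = 1 | Y_{j-1} = 0) = q_kj, first covered site marginal
# (p_ka + q_ka) / 2. Reads are independent given the profile.

#' Branching-probability profile for the reference simulation scenario
#'
#' Returns the per-group conditional methylation probabilities for a
#' 24-site CpG island with a 6-site DMR at sites 10-15 and four severity
#' groups. Inside the DMR the profile is symmetric about sites 12-13 with
#' peak values 0.66, 0.76, 0.86 and 0.96 for groups 1-4; the flanks are
#' shared by all groups and step linearly by 0.02 per site (0.44 at the
#' island edges up to 0.60 adjacent to the DMR). Throughout,
#' `q = p - 0.2`.
#'
#' @param K Number of ordinal groups (default 4; the DMR peak for group k
#'   is `0.56 + 0.1 * k`).
#' @return A tibble with columns `group`, `site`, `p`, `q` and attribute
#'   `dmr_range = c(10, 15)`.
#' @examples
#' prof <- scenario1_profile()
#' subset(prof, group == 4 & site == 12)  # p = 0.96
#' @export
scenario1_profile <- function(K = 4) {
  m <- 24
  flank <- numeric(m)
  flank[1:9] <- 0.44 + 0.02 * (0:8)     # 0.44 ... 0.60
  flank[16:24] <- 0.60 - 0.02 * (0:8)   # 0.60 ... 0.44
  prof <- purrr::map_dfr(seq_len(K), function(k) {
    p <- flank
    peak <- 0.56 + 0.1 * k
    p[10:15] <- peak - 0.04 + c(0, 0.02, 0.04, 0.04, 0.02, 0)
    tibble::tibble(group = k, site = seq_len(m), p = p, q = p - 0.2)
  })
  attr(prof, "dmr_range") <- c(10L, 15L)
  prof
}

#' Randomise the DMR peak location per individual
#'
#' Implements the second simulation scenario: for each individual a peak
#' site r is drawn uniformly on the DMR; the group's DMR branching
#' probabilities are rearranged so that they increase from the left DMR
#' boundary to r and decrease from r to the right boundary. The
#' rearrangement assigns the group's sorted scenario-1 DMR values outward
#' from r (nearer sites get larger values; ties in distance are resolved
#' left-first, so r = 13 reproduces the scenario-1 row exactly).
#' Non-DMR sites are unchanged, and `q = p - 0.2` is preserved.
#'
#' @param profile A profile tibble from [scenario1_profile()].
#' @param n_individuals Number of individuals per group.
#' @return A tibble with columns `individual` (1..n within group),
#'   `group`, `site`, `p`, `q`, and attributes `dmr_range` and `peaks`
#'   (tibble of drawn peak sites).
#' @export
randomize_peaks <- function(profile, n_individuals) {
  dmr <- attr(profile, "dmr_range")
  if (is.null(dmr)) stop("profile has no dmr_range attribute", call. = FALSE)
  dmr_sites <- dmr[1]:dmr[2]
  groups <- sort(unique(profile$group))

  out <- purrr::map_dfr(groups, function(k) {
    row <- dplyr::arrange(dplyr::filter(profile, .data$group == k),
                          .data$site)
    vals <- sort(row$p[dmr_sites], decreasing = TRUE)
    purrr::map_dfr(seq_len(n_individuals), function(i) {
      r <- sample(dmr_sites, 1)
      # distance from the peak, left-first on ties
      ord <- order(abs(dmr_sites - r), dmr_sites)
      p <- row$p
      p[dmr_sites[ord]] <- vals
      tibble::tibble(individual = i, group = k, site = row$site,
                     p = p, q = p - 0.2, peak = r)
    })
  })
  peaks <- dplyr::distinct(out, .data$group, .data$individual, .data$peak)
  out$peak <- NULL
  attr(out, "dmr_range") <- dmr
  attr(out, "peaks") <- peaks
  out
}

#' Simulate the methylation states of one short read
#'
#' First covered site is Bernoulli((p\[a\] + q\[a\]) / 2); each subsequent
#' site j is Bernoulli(p\[j\]) if the previous state was methylated and
#' Bernoulli(q\[j\]) otherwise.
#'
#' @param p,q Numeric vectors of branching probabilities over all island
#'   sites (one group / individual).
#' @param a Start site (1-based index).
#' @param len Read length in sites; the read covers `a .. a + len - 1`.
#' @return Integer vector of 0/1 methylation states, length `len`.
#' @export
simulate_read <- function(p, q, a, len) {
  stopifnot(a >= 1, a + len - 1 <= length(p))
  y <- integer(len)
  y[1] <- rbinom(1, 1, (p[a] + q[a]) / 2)
  if (len > 1) {
    for (s in 2:len) {
      j <- a + s - 1
      y[s] <- rbinom(1, 1, if (y[s - 1] == 1) p[j] else q[j])
    }
  }
  y
}

# Vectorised across reads: all reads of one individual at once.
# starts/lens define the read windows; returns meth/cov count vectors.
simulate_read_counts <- function(p, q, starts, lens) {
  m <- length(p)
  meth <- integer(m)
  cov <- integer(m)
  n <- length(starts)
  ends <- starts + lens - 1
  state <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    covering <- which(starts <= j & ends >= j)
    if (length(covering) == 0) next
    new <- covering[starts[covering] == j]
    cont <- covering[starts[covering] < j]
    if (length(new) > 0) {
      state[new] <- rbinom(length(new), 1, (p[j] + q[j]) / 2)
    }
    if (length(cont) > 0) {
      prev <- state[cont]
      state[cont] <- rbinom(length(cont), 1, ifelse(prev == 1, p[j], q[j]))
    }
    meth[j] <- meth[j] + sum(state[covering])
    cov[j] <- cov[j] + length(covering)
  }
  list(meth = meth, cov = cov)
}

#' Simulate an RRBS-like methylation data set
#'
#' Generates `n_reads` short reads per individual over a CpG island and
#' aggregates them into per-site methylated counts and coverages. Read
#' start positions are uniform over the island and read lengths uniform on
#' `read_len_range` (clamped so reads end within the island), giving mean
#' per-site coverage of about `n_reads * mean(read_len) / m` (~33x at the
#' defaults). Under `scenario = 2` each individual receives a
#' peak-randomised profile via [randomize_peaks()].
#'
#' @param profile Branching profile tibble (default [scenario1_profile()]).
#' @param n_per_group Individuals per ordinal group (default 50).
#' @param n_reads Short reads per individual (default 100).
#' @param read_len_range Integer range of read lengths in sites
#'   (default `c(4, 12)`).
#' @param scenario 1 (fixed symmetric peak) or 2 (per-individual random
#'   peak location).
#' @param seed Integer seed; per-individual substreams are derived with
#'   [derive_seed()] so earlier individuals are unaffected by
#'   `n_per_group` increases.
#' @param chrom Chromosome label for the simulated island.
#' @param bp_per_site Base-pair spacing of consecutive CpG sites; site j
#'   is placed at `bp_per_site * j`.
#' @return A methylation tibble (see [validate_meth_data()]) with
#'   attributes `dmr_range` (site indices) and `profile`.
#' @examples
#' d <- simulate_methylation(n_per_group = 2, n_reads = 10, seed = 1)
#' dplyr::count(d, group)
#' @export
simulate_methylation <- function(profile = scenario1_profile(),
                                 n_per_group = 50, n_reads = 100,
                                 read_len_range = c(4L, 12L), scenario = 1,
                                 seed = 1, chrom = "island1",
                                 bp_per_site = 50L) {
  stopifnot(scenario %in% c(1, 2), n_per_group >= 1, n_reads >= 1)
  m <- max(profile$site)
  groups <- sort(unique(profile$group))
  K <- length(groups)

  if (scenario == 2) {
    set.seed(derive_seed(seed, "peaks"))
    profile <- randomize_peaks(profile, n_per_group)
    # p[site, individual, group], rows of randomize_peaks are ordered
    # group > individual > site
    prof_sorted <- profile[order(match(profile$group, groups),
                                 profile$individual, profile$site), ]
    p_arr <- array(prof_sorted$p, dim = c(m, n_per_group, K))
    q_arr <- array(prof_sorted$q, dim = c(m, n_per_group, K))
  } else {
    prof_sorted <- profile[order(match(profile$group, groups),
                                 profile$site), ]
    p_mat <- matrix(prof_sorted$p, nrow = m, ncol = K)
    q_mat <- matrix(prof_sorted$q, nrow = m, ncol = K)
  }

  total <- K * n_per_group * m
  meth_all <- integer(total)
  cov_all <- integer(total)
  sample_all <- character(K * n_per_group)
  group_all <- integer(K * n_per_group)
  idx <- 0L
  for (kk in seq_len(K)) {
    k <- groups[kk]
    for (i in seq_len(n_per_group)) {
      p <- if (scenario == 2) p_arr[, i, kk] else p_mat[, kk]
      q <- if (scenario == 2) q_arr[, i, kk] else q_mat[, kk]
      set.seed(derive_seed(seed, "ind", k, i))
      starts <- sample.int(m, n_reads, replace = TRUE)
      lens <- sample(seq(read_len_range[1], read_len_range[2]),
                     n_reads, replace = TRUE)
      lens <- pmin(lens, m - starts + 1L)
      cnt <- simulate_read_counts(p, q, starts, lens)
      sl <- idx * m + seq_len(m)
      meth_all[sl] <- cnt$meth
      cov_all[sl] <- cnt$cov
      idx <- idx + 1L
      sample_all[idx] <- sprintf("g%d_i%03d", k, i)
      group_all[idx] <- k
    }
  }
  out <- validate_meth_data(tibble::tibble(
    chrom = chrom,
    pos = rep(bp_per_site * seq_len(m), K * n_per_group),
    sample = rep(sample_all, each = m),
    group = rep(group_all, each = m),
    meth = meth_all, cov = cov_all
  ))
  attr(out, "dmr_range") <- attr(profile, "dmr_range")
  attr(out, "profile") <- profile
  out
}
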