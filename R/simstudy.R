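# Simulation-study layer: replicate the island simulation, scan each
# replicate, and aggregate Bayes factors by window start and by the
# number of differentially methylated CpG sites (DMCs) per window.

#' Number of DMR sites covered by each window start
#'
#' @param starts Integer vector of window start sites.
#' @param window_size Window size in sites.
#' @param dmr_range Length-2 inclusive site range of the true DMR.
#' @return Integer vector: for each start, the count of window sites
#'   inside the DMR.
#' @examples
#' window_dmc_count(1:19, 6, c(10, 15))
#' @export
window_dmc_count <- function(starts, window_size, dmr_range = c(10, 15)) {
  lo <- pmax(starts, dmr_range[1])
  hi <- pmin(starts + window_size - 1, dmr_range[2])
  pmax(hi - lo + 1L, 0L)
}

#' Run the replicated simulation study
#'
#' For each replicate: simulate the CpG island, scan it with the moving
#' window, and record the Bayes factor per window start together with the
#' window's DMC count. Per-replicate seeds are derived from the master
#' seed and replicate index, so the result is invariant to evaluation
#' order and `n_replicates` extensions re-use earlier replicates.
#'
#' @param n_replicates Number of simulated replicates.
#' @param n_per_group Individuals per ordinal group.
#' @param scenario Simulation scenario, 1 or 2 (see
#'   [simulate_methylation()]).
#' @param profile Branching profile (default [scenario1_profile()]).
#' @param window_size Window size in CpG sites (default 6).
#' @param control A [bfm_control()].
#' @param seed Master integer seed.
#' @param starts Optional window starts to restrict the scan (all
#'   windows by default).
#' @param n_reads,read_len_range Passed to [simulate_methylation()].
#' @return An object of class `bfm_simstudy`: list with `windows` (tibble
#'   `replicate`, `start_site`, `bf`, `bf_censored`, `n_dmc`) and the
#'   study settings.
#' @export
run_sim_study <- function(n_replicates = 100, n_per_group = 50,
                          scenario = 1, profile = scenario1_profile(),
                          window_size = 6, control = bfm_control(),
                          seed = 1, starts = NULL, n_reads = 100,
                          read_len_range = c(4L, 12L)) {
  stopifnot(n_replicates >= 1)
  dmr <- attr(profile, "dmr_range")
  windows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    rep_seed <- derive_seed(seed, "rep", r)
    d <- simulate_methylation(profile, n_per_group = n_per_group,
                              n_reads = n_reads,
                              read_len_range = read_len_range,
                              scenario = scenario, seed = rep_seed)
    w <- scan_bfm(d, window_size = window_size, control = control,
                  seed = rep_seed, starts = starts)
    w$replicate <- r
    w
  })
  windows$n_dmc <- window_dmc_count(windows$start_site, window_size, dmr)
  structure(list(
    windows = dplyr::select(windows, "replicate", "start_site", "end_site",
                            "bf", "bf_censored", "n_dmc"),
    n_replicates = n_replicates, n_per_group = n_per_group,
    scenario = scenario, window_size = window_size, dmr_range = dmr,
    seed = seed
  ), class = "bfm_simstudy")
}

#' @export
print.bfm_simstudy <- function(x, ...) {
  cat("Simulation study: ", x$n_replicates, " replicates, scenario ",
      x$scenario, ", N = ", x$n_per_group, "/group, window ",
      x$window_size, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Per-start mean Bayes factors of a simulation study
#'
#' @param x A `bfm_simstudy`.
#' @param ... Unused.
#' @return A tibble with `start_site`, `end_site`, `n_dmc`, `mean_bf`,
#'   and the replicate count.
#' @method tidy bfm_simstudy
#' @export
tidy.bfm_simstudy <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$windows, .data$start_site, .data$end_site,
                    .data$n_dmc),
    mean_bf = mean(.data$bf), n = dplyr::n(), .groups = "drop")
}

#' @method glance bfm_simstudy
#' @export
glance.bfm_simstudy <- function(x, ...) {
  peak <- dplyr::filter(tidy(x), .data$n_dmc == max(.data$n_dmc))
  tibble::tibble(
    n_replicates = x$n_replicates, n_windows = nrow(x$windows),
    peak_start = peak$start_site[which.max(peak$mean_bf)],
    peak_mean_bf = max(peak$mean_bf)
  )
}

#' @method autoplot bfm_simstudy
#' @export
autoplot.bfm_simstudy <- function(object, ...) {
  w <- object$windows
  w$chrom <- "island"
  plot_bf_profile(w)
}

#' Empirical null Bayes-factor cutoffs
#'
#' Computes empirical quantiles of Bayes factors from "null" windows of a
#' simulation study, usable as cutoffs for frequentist-style error
#' calibration. Two null definitions are supported: `"zero_dmc"` (windows
#' containing no DMR site; the primary definition) and `"excl_left"`
#' (windows not covering the two leftmost DMR sites, which also admits
#' windows overlapping the right of the DMR).
#'
#' @param study A `bfm_simstudy`, or a numeric vector of null Bayes
#'   factors.
#' @param levels Quantile levels (default 0.95 and 0.99).
#' @param null Null-window definition (ignored when `study` is numeric).
#' @return A tibble with `level` and `cutoff`.
#' @export
null_cutoffs <- function(study, levels = c(0.95, 0.99),
                         null = c("zero_dmc", "excl_left")) {
  if (is.numeric(study)) {
    bfs <- study
  } else {
    null <- match.arg(null)
    w <- study$windows
    bfs <- if (null == "zero_dmc") {
      w$bf[w$n_dmc == 0]
    } else {
      lo <- study$dmr_range[1]
      keep <- !(w$start_site <= lo + 1 &
                  w$start_site + study$window_size - 1 >= lo)
      w$bf[keep]
    }
  }
  if (length(bfs) < 100) {
    stop("need at least 100 null Bayes factors (have ", length(bfs), ")",
         call. = FALSE)
  }
  tibble::tibble(level = levels,
                 cutoff = unname(quantile(bfs, levels, type = 7)))
}

#' Exceedance proportions by DMC count
#'
#' For each cutoff, tabulates the proportion of window Bayes factors
#' above the cutoff, stratified by the number of DMR sites in the window
#' (0 DMCs gives the empirical type I error at that cutoff; >= 1 DMC
#' gives power).
#'
#' @param study A `bfm_simstudy`.
#' @param cutoffs Numeric vector of Bayes-factor cutoffs (e.g. the output
#'   of [null_cutoffs()]).
#' @return A tibble with `cutoff`, `n_dmc`, `n_windows`, `exceedance`.
#' @export
exceedance_by_dmc <- function(study, cutoffs) {
  w <- study$windows
  purrr::map_dfr(cutoffs, function(cut) {
    dplyr::summarise(dplyr::group_by(w, .data$n_dmc),
      cutoff = cut, n_windows = dplyr::n(),
      exceedance = mean(.data$bf > cut), .groups = "drop")
  })
}
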