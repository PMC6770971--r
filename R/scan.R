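#' Scan a methylation table with moving windows
#'
#' Slides a window of `window_size` CpG sites (advancing `step` sites per
#' move, never spanning chromosomes) along the genome, fits the
#' mixed-effect logistic model in each window and computes the
#' order-restricted Bayes factor. Prior draws are generated once per scan;
#' per-window sampler seeds are derived from `(seed, chrom, start)` so
#' results are identical regardless of evaluation order. Chromosomes with
#' fewer than `window_size` sites are skipped with a warning.
#'
#' @param data Methylation tibble (see [validate_meth_data()]).
#' @param window_size Number of CpG sites per window (default 6).
#' @param step Sites advanced per move (default 1).
#' @param control A [bfm_control()].
#' @param seed Master integer seed.
#' @param n_prior_draws Prior draws for the Bayes factor denominator.
#' @param starts Optional integer vector restricting the scan to the
#'   given window start indices (per chromosome).
#' @return A tibble with one row per window: `chrom`, `start_site`,
#'   `end_site`, `start_bp`, `end_bp`, `bf`, `bf_censored`, `post_eq`,
#'   `evidence`.
#' @examples
#' \donttest{
#' d <- simulate_methylation(n_per_group = 5, n_reads = 30, seed = 1)
#' scan_bfm(d, control = bfm_control(n_iter = 300, n_burnin = 100),
#'          starts = c(1, 10), seed = 1)
#' }
#' @export
scan_bfm <- function(data, window_size = 6, step = 1,
                     control = bfm_control(), seed = 1,
                     n_prior_draws = 10000, starts = NULL) {
  stopifnot(window_size >= 2, step >= 1)
  data <- validate_meth_data(data)
  K <- max(data$group)
  prior <- transform_draws(
    sample_prior_mu(K, n_prior_draws, control$mu_prior_sd,
                    derive_seed(seed, "prior")))

  chroms <- unique(data$chrom)
  out <- purrr::map_dfr(chroms, function(ch) {
    d <- dplyr::filter(data, .data$chrom == ch)
    positions <- sort(unique(d$pos))
    n_sites <- length(positions)
    if (n_sites < window_size) {
      warning("chromosome ", ch, " has ", n_sites,
              " sites < window size ", window_size, "; skipped",
              call. = FALSE)
      return(NULL)
    }
    st <- seq(1L, n_sites - window_size + 1L, by = step)
    if (!is.null(starts)) st <- intersect(st, as.integer(starts))
    purrr::map_dfr(st, function(s) {
      idx <- s:(s + window_size - 1L)
      win <- dplyr::filter(d, .data$pos %in% positions[idx])
      fit <- fit_bfm_window(win, control = control,
                            seed = derive_seed(seed, ch, s))
      res <- window_bf(fit, prior = prior)
      tibble::tibble(
        chrom = ch, start_site = s, end_site = s + window_size - 1L,
        start_bp = positions[idx[1]], end_bp = positions[idx[window_size]],
        bf = res$bf, bf_censored = res$bf_censored, post_eq = res$post_eq,
        evidence = res$evidence
      )
    })
  })
  out
}

#' Merge significant windows into DMR calls
#'
#' Windows with Bayes factor above `threshold` that overlap in site
#' indices (on the same chromosome) are merged into a single DMR,
#' annotated with the maximum window Bayes factor. With `merge = FALSE`
#' the significant windows are returned unmerged, as tabulated per start
#' site.
#'
#' @param windows Window tibble from [scan_bfm()], in genomic order.
#' @param threshold Bayes factor cutoff (exclusive). Default 3, Jeffreys
#'   "positive"; 2 and 19 are sensible alternatives for lenient binary
#'   and stringent multi-group analyses respectively.
#' @param merge Merge overlapping significant windows (default `TRUE`).
#' @return A tibble of disjoint, sorted DMRs: `chrom`, `start_site`,
#'   `end_site`, `start_bp`, `end_bp`, `n_windows`, `bf` (maximum over
#'   merged windows), `evidence`.
#' @export
call_dmrs <- function(windows, threshold = 3, merge = TRUE) {
  sig <- dplyr::filter(windows, .data$bf > threshold)
  if (nrow(sig) == 0) return(sig[0, , drop = FALSE])
  sig <- dplyr::arrange(sig, .data$chrom, .data$start_site)
  if (!merge) return(sig)
  out <- purrr::map_dfr(split(sig, sig$chrom), function(d) {
    # new run when a window starts past every previous window's end
    d$run <- cumsum(c(TRUE, d$start_site[-1] > cummax(head(d$end_site, -1))))
    dplyr::summarise(dplyr::group_by(d, .data$run),
      chrom = dplyr::first(.data$chrom),
      start_site = min(.data$start_site),
      end_site = max(.data$end_site),
      start_bp = min(.data$start_bp),
      end_bp = max(.data$end_bp),
      n_windows = dplyr::n(),
      bf = max(.data$bf),
      .groups = "drop"
    )
  })
  out$run <- NULL
  out$evidence <- evidence_category(out$bf)
  dplyr::arrange(out, .data$chrom, .data$start_site)
}

#' Mean Bayes-factor profile plot
#'
#' @param windows Window tibble from [scan_bfm()] or the `windows`
#'   element of a [run_sim_study()] result; if several replicates are
#'   present the per-start mean Bayes factor is plotted.
#' @return A ggplot of (mean) Bayes factor against window start site,
#'   log-scaled.
#' @export
plot_bf_profile <- function(windows) {
  prof <- dplyr::summarise(
    dplyr::group_by(windows, .data$chrom, .data$start_site),
    bf = mean(.data$bf), .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$start_site, y = .data$bf)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "window start (CpG site index)",
                  y = "Bayes factor (log scale)") +
    ggplot2::theme_minimal()
}
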