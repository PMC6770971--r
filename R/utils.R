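# Deterministic seed derivation so that windows / replicates are
# independently reproducible regardless of execution order.

#' Derive a reproducible child seed
#'
#' Hashes a master seed together with any number of labels (chromosome
#' names, window start indices, replicate numbers, ...) into an integer
#' seed in `[1, 2^31 - 2]`. The hash is a multiplicative congruential mix
#' computed in double precision, so it is stable across platforms.
#'
#' @param seed Integer master seed.
#' @param ... Additional labels (character or numeric scalars) mixed into
#'   the hash.
#' @return A single integer usable with [set.seed()].
#' @examples
#' derive_seed(1, "chr19", 42)
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (tok in list(...)) {
    codes <- if (is.character(tok)) utf8ToInt(paste(tok, collapse = "/"))
             else as.numeric(tok)
    for (v in codes) {
      h <- (h * 69069 + (v %% mod) + 1) %% mod
    }
  }
  as.integer(h %% (mod - 2) + 1)
}

# Effective sample size from the initial-positive-sequence of
# autocorrelations (Geyer-style, single chain).
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (rho in acf_x) {
    if (rho <= 0) break
    s <- s + rho
  }
  n / (1 + 2 * s)
}

inv_logit <- function(x) 1 / (1 + exp(-x))
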