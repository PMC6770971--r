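---
title: "Order-restricted Bayes factors for methylation trends: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-restricted Bayes factors for methylation trends: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bfmeth` detects differentially methylated regions (DMRs) whose
methylation rates increase (or decrease) monotonically with an ordinal
phenotype — disease stages, risk strata, marker-defined severity groups —
from bisulfite-sequencing counts. This vignette is the package's account
of the statistical machinery: the window model, the order-restricted
Bayes factor, the sampler, the simulator, and the numerical decisions a
user should know about before trusting the output.

## The window model

Patients are classified into ordinal groups $k = 1, \dots, K$. At CpG
site $j$ of individual $i$ in group $k$ we observe $m_{kij}$ methylated
reads out of coverage $c_{kij}$, modelled as

$$m_{kij} \sim \mathrm{Binomial}(c_{kij},\, p_{kij}), \qquad
\mathrm{logit}(p_{kij}) = \mu_k + \nu_{0ki} + \nu_{1kij},$$

within each moving window of $m$ CpG sites (default 6, one start per
site, never spanning chromosomes). The two random effects carry the two
correlation structures methylation data are known to have:
$\nu_{0ki} \sim N(0, \sigma_{\nu_0}^2)$ makes the counts of one
individual correlated across sites (inter-individual variation within a
site), and the site vector
$(\nu_{1ki1}, \dots, \nu_{1kim})^\top \sim N_m(0, \Sigma)$ with a free
covariance $\Sigma$ captures the correlation of methylation rates
between nearby sites. Hyperpriors are vague:
$\mu_k \sim N(0, 1000^2)$, $\sigma_{\nu_0}^2 \sim \mathrm{IG}(1, 100)$,
$\Sigma^{-1} \sim \mathrm{Wishart}(I_m, m)$. An optional hierarchical
prior for the group effects
($\mu_k \sim N(\mu_\mu, \sigma_\mu^2)$, `hierarchical_mu = TRUE`) and an
optional fixed-effect covariate matrix are available but experimental;
the defaults are the fixed vague priors above.

Two points about these hyperpriors deserve attention. First, the
$\mathrm{IG}(1, 100)$ prior places essentially no mass below
$\sigma^2 \approx 20$ a priori (its CDF at 1 is $e^{-100}$), so with $N$
individuals the posterior for $\sigma_{\nu_0}^2$ is approximately
$(100 + \tfrac12\sum \nu_{0}^2)/(N/2)$ — about $200/N$ even when the
data carry no individual heterogeneity. This floor propagates into the
posterior spread of $\mu_k$ (roughly $\sigma_{\nu_0}^2 / n_k$ from this
source), which matters for the Bayes factor scale discussed below.
Second, $\mathrm{Wishart}(I_m, m)$ is the minimal proper degrees of
freedom, a deliberately heavy-tailed prior on $\Sigma$; with realistic
$N$ the data dominate it.

## The order-restricted Bayes factor

For each window we compare
$M_0: \mu_1 = \cdots = \mu_K$ against the simple order
$M_1: \mu_1 \le \cdots \le \mu_K$ with at least one strict inequality.
Unconstrained posterior draws $(\mu_1, \dots, \mu_K)$ are mapped onto
the monotone cone by the min–max isotonic transformation

$$\tilde\mu_k = \min_{t \ge k} \max_{s \le k}
\frac{\mathbf 1^\top V_{[s:t]}^{-1} \mu_{[s:t]}}
     {\mathbf 1^\top V_{[s:t]}^{-1} \mathbf 1},$$

with $V$ the (diagonal, per-group) posterior covariance of the group
effects estimated from the draws. For diagonal $V$ this is exactly
weighted pool-adjacent-violators — the test suite verifies agreement
with an independent PAVA implementation to $10^{-10}$ on random
instances. A draw supports $M_0$ precisely when the transformation pools
all $K$ components into one block ($\tilde\mu_K = \tilde\mu_1$), and
supports $M_1$ otherwise. The same transformation (with identity
weights) is applied to i.i.d. prior draws
$\mu_{k0} \sim N(0, 1000^2)$, for which complete pooling occurs with
probability exactly $1/K$. The Bayes factor is the posterior-to-prior
odds ratio

$$\mathrm{BF} =
\frac{P(\tilde\mu_K > \tilde\mu_1 \mid \text{data}) \,/\,
      P(\tilde\mu_{K0} > \tilde\mu_{10})}
     {P(\tilde\mu_K = \tilde\mu_1 \mid \text{data}) \,/\,
      P(\tilde\mu_{K0} = \tilde\mu_{10})},$$

with all four probabilities estimated as pooling frequencies over draws.
Evidence is banded by Jeffreys' rule: positive for
$3 < \mathrm{BF} \le 10$, strong for $10 < \mathrm{BF} \le 100$,
decisive above 100.

Pooling is detected combinatorially, not by comparing rounded floats:
$\tilde\mu_1$ minimises over a set of block means containing the
full-range mean $M$ and $\tilde\mu_K$ maximises over a set containing
the identical computed value, so
$\tilde\mu_1 \le M \le \tilde\mu_K$ holds exactly in floating point and
$\tilde\mu_1 = \tilde\mu_K$ identifies complete pooling.

### Monte-Carlo censoring of large Bayes factors

With $S$ retained posterior draws the smallest resolvable pooling
probability is $1/S$. When *no* posterior draw pools (a saturated
window: the data put essentially all mass on the strict ordering), the
package substitutes $1/(2S)$ — a standard continuity correction — and
flags the result (`bf_censored`). At the defaults
($S = 2000$, $K = 4$) every censored window therefore reports the same
finite lower bound, approximately
$2S \cdot \tfrac{P(\text{prior pooled})}{P(\text{prior ordered})}
\approx 1333$. Two consequences:

* Bayes factors above a few hundred are *resolution-bound lower
  bounds*, not estimates; they rank windows correctly against
  unsaturated ones but not against each other. Reported magnitudes in
  this regime are determined by the draw count, so analyses at other
  draw counts (or with other zero-count conventions, which the odds
  formula does not itself dictate) will report different large values
  for identical data.
* Increasing `n_iter` tightens the resolution linearly; the defaults
  (3000 iterations, 1000 burn-in) follow the reference analysis
  settings and keep a genome scan affordable.

In the bundled simulation study this matters visibly: with four groups
of 50 and ~33x coverage the posterior standard deviation of each
$\mu_k$ is ~0.15 while the group separations at the simulated DMR are
~0.5–0.7 logits, so windows containing three or more differentially
methylated sites saturate and report the censored bound. Windows with
zero to two such sites are far from saturation, and their Bayes-factor
distribution is what the empirical-cutoff machinery calibrates.

## The sampler

The binomial-logit likelihood is augmented with Pólya-Gamma variables
$\omega_{kij} \sim \mathrm{PG}(c_{kij}, \psi_{kij})$, after which every
conditional update is conjugate (normal for $\mu$, $\nu_0$, $\nu_1$ and
covariate effects; inverse-gamma for $\sigma_{\nu_0}^2$;
inverse-Wishart for $\Sigma$), giving an exact Gibbs sampler.
PG draws use the exact alternating-series rejection sampler for
$\mathrm{PG}(1, z)$, summed for integer shapes up to `pg_exact_max`
(default 8), and a moment-matched normal approximation above that —
accurate to a fraction of a percent at those shapes, and the
augmentation variables are nuisances. Zero-coverage cells contribute
nothing to the likelihood; their random effects are drawn from the
prior conditionals.

Because the likelihood identifies $\mu_k$ only jointly with the group
means of $\nu_0$ and $\nu_1$, a vanilla Gibbs scan random-walks along
the weakly identified directions. The sampler therefore interleaves two
centred-parameterisation sweeps per iteration (re-drawing each $\mu_k$
from its conjugate conditional given $\eta_{ki} = \mu_k + \nu_{0ki}$,
then given $u_{ki\cdot} = \mu_k \mathbf 1 + \nu_{1ki\cdot}$, and
shifting the random effects to compensate). Both sweeps are exact Gibbs
steps on reparameterisations of the same posterior; they raise the
effective sample size of the $\mu_k$ chains from a few dozen to well
over a thousand out of 2000 retained draws. Chains are deterministic
given a seed, and per-window seeds are derived by hashing
`(seed, chromosome, start)`, so scan results do not depend on window
evaluation order and single windows can be reproduced in isolation.

## The simulator

`simulate_methylation()` generates RRBS-like short reads over one CpG
island (24 equally spaced sites, a 6-site DMR at sites 10–15, $K = 4$
severity groups by default). Along each read, methylation states form a
two-state Markov chain — equivalently a branching process on the
multivariate Bernoulli — with transition probabilities
$p_{kj} = P(Y_j = 1 \mid Y_{j-1} = 1)$ and
$q_{kj} = P(Y_j = 1 \mid Y_{j-1} = 0) = p_{kj} - 0.2$, and first-site
marginal $(p + q)/2$. The default profile places group peaks 0.66,
0.76, 0.86, 0.96 at the DMR centre, symmetric about sites 12–13, with
flanks shared across groups stepping by 0.02 per site (0.44 at the
island edges). Scenario 2 re-draws the peak location uniformly within
the DMR per individual and rearranges each group's DMR values so they
rise to the peak and fall after it (ties in distance resolved leftward,
so a central peak reproduces the symmetric profile exactly).

Read starts are uniform over the island and read lengths uniform on
4–12 sites (clamped at the island end), giving each individual
100 reads and a mean per-site coverage of ~33x, comparable to typical
RRBS depth; both are configurable. Two emergent properties of this
design are worth knowing. Edge sites get systematically lower coverage
(a site can only be covered by reads starting at or before it). And
because read states are generated left to right, elevated DMR
methylation bleeds a short distance into the *right* flank through
reads that enter it from the DMR — windows just right of the DMR show
mildly elevated Bayes factors, and the Bayes-factor profile across
window starts is asymmetric with the right side higher. This is a
property of the data-generating process, not an artifact of the scan.

What the simulator does *not* emulate: sequencing error, strand
effects, non-CpG methylation, coverage overdispersion between samples,
genuine inter-individual random effects, and long-range correlation
beyond the read length. Passing simulation tests therefore demonstrate
correctness of the machinery under the assumed correlation structure,
not robustness to everything real data do.

## Calibration and the simulation study

`run_sim_study()` repeats simulate-and-scan over replicates and
collects per-window Bayes factors with their DMC counts (number of
window sites inside the true DMR). `null_cutoffs()` turns the 0-DMC
windows into empirical 95%/99% Bayes-factor cutoffs — the analogue of
5% and 1% type-I error thresholds — and `exceedance_by_dmc()` tabulates
power against those cutoffs by DMC stratum. Because the 0-DMC set
includes the right-flank windows subject to the spillover described
above, these cutoffs are conservative relative to pure-noise windows;
`null_cutoffs(..., null = "excl_left")` implements the alternative
convention that excludes only windows covering the left DMR boundary.

Problem sizes: the packaged tests run the study at 30–100 replicates
per configuration with the analysis defaults (window 6, 3000/1000
MCMC), and the acceptance script uses 100 replicates for peak windows
and 50 for flank/null windows. Monte-Carlo tolerances in the tests are
sized accordingly (binomial standard errors for proportions,
log-scale bands for heavy-tailed Bayes-factor means).

## Defaults that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window_size` | 6 sites | moving-window width; windows advance 1 site |
| `n_iter`, `n_burnin` | 3000, 1000 | Gibbs iterations; 2000 retained draws |
| `mu_prior_sd` | 1000 | vague prior SD of each group effect (logit scale) |
| `ig_shape`, `ig_scale` | 1, 100 | IG hyperprior of variance components |
| `n_prior_draws` | 10000 | prior draws for the BF denominator, drawn once per scan |
| `pg_exact_max` | 8 | largest PG shape drawn exactly |
| DMR threshold | 3 | Jeffreys "positive"; 2 (lenient, binary designs) and 19 (stringent, multi-group genome scans) are the conventional alternatives |

## Known limitations

* Windows within a chromosome are analysed independently; correlation
  beyond the window is ignored, and chromosomes shorter than the window
  are skipped rather than fitted with a reduced window.
* Only the simple increasing order is supported (reverse the group
  labels to test decreasing trends); no tree or umbrella orders.
* The min–max transformation makes the Bayes factor an approximation to
  the exact order-restricted Bayes factor; no correction is attempted.
* Merging significant windows into DMRs (`call_dmrs()`) is a
  convenience overlap rule; per-window output (`merge = FALSE`) is the
  primitive quantity.
* Covariate adjustment and the hierarchical group-effect prior are
  implemented but lightly exercised; treat them as experimental.
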