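---
title: "Modeling GWAS replication under Winner's Curse and study-specific confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling GWAS replication under Winner's Curse and study-specific confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwrep)
```

## The model and its assumptions

A GWAS association statistic for variant $k$ in a study of $N$
individuals is asymptotically $s_k \sim N(\sqrt{N}\,\beta_k/\sigma_e, 1)$:
a unit-variance normal whose mean is the standardized effect scaled by
the square root of the sample size. `gwrep` works entirely at this
z-score level; genotype and phenotype data never enter.

For a discovery study (sample size $N_1$) and a replication study
($N_2$) of the same trait, each variant's standardized effect is
decomposed as a *shared genetic* component
$\lambda \sim N(0, \sigma_g^2)$ plus a *study-specific confounding*
component $\delta^{(i)} \sim N(0, \sigma_{ci}^2)$, $i \in \{1, 2\}$,
independent across studies and variants. Marginalizing the latent
effects, the paired z-scores are bivariate normal with mean zero,
variances $N_i\sigma_g^2 + N_i\sigma_{ci}^2 + 1$ and covariance
$\sqrt{N_1 N_2}\,\sigma_g^2$ (`joint_distribution()`). Because only the
genetic component is shared, confounding inflates each study's marginal
variance without contributing covariance — this asymmetry is what makes
the two sources of inflation separable from summary data alone.

Conditioning on the observed discovery statistic
(`conditional_replication()`) yields the Winner's-Curse-corrected
predictive law of the replication statistic: a shrinkage of the
discovery z-score by
$\sqrt{N_1 N_2}\,\sigma_g^2 / (N_1\sigma_g^2 + N_1\sigma_{c1}^2 + 1)$,
with a conditional variance that is free of the selection event. Note a
property worth internalizing: selection (keeping only significant
variants) biases the *marginal* distribution of the selected discovery
statistics, but the *conditional* law of $s_2$ given $s_1 = x$ is
untouched by selection on $s_1$. This is why per-variant prediction and
expected replication rates can condition on the observed discovery
values without any truncation adjustment.

Key assumptions, and what violates them: variants are independent (LD
is not modeled — prune correlated panels first); discovery and
replication cohorts share no individuals (overlap induces covariance
the model would read as genetics); confounding is a single
study-level Gaussian scale, so structured, variant-specific
confounding (e.g. stratification concentrated in a few loci) is
captured only in aggregate.

## Estimation

The variance components $(\sigma_g^2, \sigma_{c1}^2, \sigma_{c2}^2)$
are estimated by maximizing the bivariate normal likelihood
(`fit_mle()`). Two data regimes are supported:

* **Complete data** — z-scores for all $N$ tested variants. The
  zero-mean Gaussian likelihood depends on the data only through
  $\sum z_1^2$, $\sum z_2^2$, $\sum z_1 z_2$ and $N$, so objective
  evaluations are $O(1)$ after one pass over the data; million-variant
  fits cost milliseconds.
* **Significant-only data** — the realistic case for published studies.
  Each of the $N - |A|$ unreported variants contributes its probability
  of discovery non-significance $P(|s_1| \le z^*)$ under the discovery
  marginal; the $|A|$ reported variants contribute the untruncated
  joint density. When all variants are supplied the censoring term has
  weight zero and the two regimes coincide exactly. The selected
  variants' densities are deliberately *not* additionally conditioned
  on $|s_1| > z^*$: selection enters once, through the censored count,
  with each variant contributing either its density or its
  non-significance probability so the two terms partition the sample.

Numerical choices: nonnegativity is enforced by optimizing over
standard deviations and squaring (smooth and unconstrained, avoiding
the flat regions that boundary clipping creates for a simplex method);
the three-parameter model uses Nelder–Mead with a moment-matched start
($\sigma_{g,0} = \sqrt{\max((\overline{z_1^2} - 1)/N_1, 10^{-10})}$,
confounding at half that) and two additional multiplicatively jittered
restarts, because the objective is not relied on to be convex; the
one-parameter WC-only model uses golden-section search instead, since
Nelder–Mead is unreliable in one dimension. Convergence is reported as
a flag rather than raised as an error so that batch fitting over many
study pairs never aborts. Sums in the sufficient statistics are sorted
before accumulation, making likelihood values and fits bit-reproducible
under any permutation of the input rows. Two-sided thresholds are used
throughout ($z^* = \Phi^{-1}(1 - t/2)$), and tail probabilities of
extreme z-scores are computed in log space, since genome-wide hits
routinely exceed the $|z| \approx 38$ resolution of the normal CDF in
double precision.

## Replication rates and the variance decomposition

The observed replication rate counts discovery-significant variants
with a two-sided replication p-value below $\alpha$ *and* a matching
direction of effect. The model-expected rate
(`expected_replication_rate()`) averages
$P(|s_2| > z_\alpha \mid s_1 = x_k)$ over the significant variants.
These two rules differ slightly: the expected-rate formula is
direction-agnostic, while the observed rule requires the matching sign.
The package's default follows the direction-agnostic formula (the
two-tailed form is the canonical definition here, and the
wrong-direction tail is negligible for well-separated hits); a
`direction_aware = TRUE` variant of every relevant function exposes the
strictly consistent alternative, which is never larger. Under the
all-zero model the expected rate is exactly the nominal level — a
useful analytic anchor that the tests assert to machine precision.

`variance_explained()` reports
$p_g = \sigma_g^2 / (\sigma_g^2 + \sigma_{c1}^2)$ and its complement
$p_{c1}$: the genetic vs confounded shares of the non-noise discovery
signal (sample size cancels). Low observed replication with high
$p_{c1}$ is the model's signature of a confounded discovery study,
and this anticorrelation is reproduced on simulated grids in the test
suite.

## The simulator

`simulate_pair()` draws the generative model directly: per variant,
$\lambda$, $\delta^{(1)}$, $\delta^{(2)}$, then
$z_1 \sim N(\sqrt{N_1}(\lambda + \delta^{(1)}), 1)$ and
$z_2 \sim N(\sqrt{N_2}(\lambda + \delta^{(2)}), 1)$. Defaults emulate
the package's reference simulation conditions: $N_1 = 2000$,
$N_2 = 1000$, $10^6$ independent variants, discovery threshold
$5\times10^{-8}$, replication level $0.05$, and sigma grids over
$\{0.018, 0.022, 0.026, 0.03\}$ — values chosen so that well under 1%
of variants reach genome-wide significance, as in realistic GWAS. The
grid values are standard deviations and are squared internally wherever
the formulas consume variances.

What the simulator does *not* emulate: linkage disequilibrium,
allele-frequency-dependent power, sample overlap, non-Gaussian effect
size distributions (e.g. a point mass at zero for non-causal variants —
here every variant has an infinitesimal effect), or variant-specific
confounding. Passing tests therefore demonstrate correctness and
calibration *under the model's own assumptions*; they do not certify
performance on real data where those features are present.

The core is compiled (Rcpp): each simulation seeds its own
`mt19937_64` stream via splitmix64 mixing of the base seed, a
combination index and a replicate index, so any subset of a grid
reproduces bit-identically in isolation and grids never share or
consume R's global RNG state. Per-simulation storage is controlled by a
`keep` flag; grid runs retain only counts, rates, latent-draw summaries
and the likelihood's sufficient statistics, which is why 6,400
million-variant simulations fit comfortably in memory. Replicates with
zero significant variants record an undefined (not `NaN`) replication
rate and are excluded from rate summaries but counted explicitly.

## Problem sizes and reproducible reruns

The package's own studies, rerun by `scripts/acceptance.R` and the test
suite, use the reference conditions at reduced replicate counts chosen
as a sensible desk-scale compromise: 100 replicates per combination for
the 64-combination confounded grid, 250 per value for the
no-confounding grid, and 20 replicates per combination for the
parameter-recovery study. Extremes of order statistics at these counts
sit slightly inside the extremes of 1,000-replicate runs, and the
tests' tolerances are set from that order-statistic reasoning, not from
observed outcomes. Parameter recovery is judged by pooled per-component
mean signed relative bias (below 5%) and by the matched-replicate
ordering that truncated-data estimates vary strictly more than
complete-data estimates.

## Known limitations

* The confounding estimate says nothing about the *source* of
  confounding; it is a study-level aggregate.
* No standard errors or tests are reported for the variance components
  themselves (point estimates only); uncertainty in the expected
  replication rate is assessed empirically, by the robustness of the
  rate to parameter variation.
* Two studies only; a multi-study extension would replace the
  bivariate normal with a higher-dimensional one.
* With very few significant variants the truncated-likelihood fit is
  noisy; expected rates remain usable but the variance decomposition
  should be read with caution.
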