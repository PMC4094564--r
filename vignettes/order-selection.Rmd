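---
title: "Selecting the order of a Markov chain for categorical path data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the order of a Markov chain for categorical path data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovmemory)
```

## The model

A corpus is a set of paths, each an ordered tuple of categorical states
from a finite alphabet — navigation sessions over page topics are the
motivating case.  An order-k Markov chain assumes the next state depends
on exactly the k preceding states, with time-homogeneous conditional
probabilities: estimates depend only on transition counts, never on the
position within a path.  Order 0 is weighted random selection by marginal
frequency; order 1 is the classical memoryless chain.

Two modelling questions follow.  How should independent paths be glued
into one estimation problem?  And how much memory does the data actually
support?

**RESET augmentation.**  Each path of length $L$ is padded to
$(\mathrm{RESET}^{k},\, s_1, \dots, s_L,\, \mathrm{RESET})$ and all $L+1$
sliding windows (length-$k$ history, next state) are counted *within* the
augmented path.  Windows never span two paths, so histories cannot leak
across paths, and termination is a predictable event: RESET is a
first-class state and the state space has $m = |\text{labels}| + 1$
states.  A consequence of per-path windowing is that many nominal
history rows are structurally unreachable — no window ever has RESET in a
non-prefix position — which matters for degrees of freedom below.

**Estimators.**  The maximum-likelihood estimate of a row is the count
ratio $\hat p(j\mid i) = n_{ij} / n_i$.  MLE rows are left *undefined*
for unobserved histories rather than imputed: that keeps the training
log-likelihood $\sum_{ij} n_{ij}\log p(j \mid i)$ finite and exactly equal
to its closed form, and makes $-\infty$ a legal return value on held-out
data (a signal of unexplained transitions, not an error).  Smoothing is
exclusively the Bayesian estimator's job: with a Dirichlet prior of
pseudo-counts $\alpha$ on every cell, the posterior mean
$(\alpha_{ij}+n_{ij})/(A_i+N_i)$ is a convex combination of the MLE and
the prior mean, converging to the MLE as data grow.  The default
$\alpha = 1$ is the uniform (Laplace) prior; pseudo-counts are placed on
the full nominal table, including structurally unreachable cells — those
rows never receive data, contribute a factor of one to the evidence, and
only shift the smoothed floor by a vanishing amount.

## Four selection frameworks

Raw likelihood cannot select an order: lower orders are nested in higher
ones, so $\log L$ is non-decreasing in $k$ on any corpus (a property the
test suite asserts).  Each framework penalises complexity differently.

**Likelihood-ratio test.**  For nested orders $k_0 < k_1$ the statistic
$2(\log L_1 - \log L_0)$ is asymptotically $\chi^2$.  The default degrees
of freedom use the full nominal table,
$(m^{k_1} - m^{k_0})(m - 1)$.  Under per-path windowing this overcounts —
unreachable rows contribute no likelihood — so the nominal test is
*conservative*: on simulated true-order-1 corpora (4 data states, $10^4$
clicks, 500 replicates) the mean 1-vs-2 statistic is ~65 against a
nominal 80 degrees of freedom, and the 1%-level rejection rate is ~0.
The `df_mode = "observed"` sensitivity option instead counts observed
histories, $(H_{k_1} - H_{k_0})(m-1)$, and is well calibrated in that
regime (measured rate ≈ 0.01).  Both conventions are reported by the
acceptance script.  Significance is flagged at the 1% and 0.1% levels;
no multiple-testing correction is applied across the test table.  One
subtlety the calibration exposed: the minimum-length filter makes
path-*initial* transitions structurally unable to reach RESET, so a
filtered corpus from an order-1 generator is genuinely *not* first order
in augmented space (histories (RESET, s) differ from (x, s)); the null
simulation therefore scores unfiltered corpora.

**Bayesian evidence.**  With conjugate Dirichlet rows the parameters
integrate out exactly:
$$ P(D \mid k) \;=\; \prod_i
   \frac{\Gamma(A_i)}{\Gamma(A_i + N_i)}
   \prod_j \frac{\Gamma(\alpha_{ij} + n_{ij})}{\Gamma(\alpha_{ij})}, $$
computed with `lgamma` throughout.  Rows with no observations contribute
a factor of one, so summing over observed rows only is *exact*, not an
approximation — the package exploits this to stay sparse.  Evidences are
normalised into model posteriors with the log-sum-exp trick (the largest
log-evidence is pulled out of the sum), so magnitudes near $-10^5$ pose
no underflow problem.  Two model priors are offered: uniform, and an
exponential complexity penalty $\propto \exp(-m^k)$ in the state count of
the order-k chain; the evidence already carries a built-in Occam's razor,
and on every synthetic corpus we evaluate, the two priors select the same
order.  The penalty base uses the full vocabulary including RESET; the
converted-chain state count over feasible histories only would be
smaller, but since the penalty only ever strengthens the preference for
small $k$ the choice does not change selections in practice.

**Information criteria.**  $\mathrm{AIC} = -2\log L + 2p$ and
$\mathrm{BIC} = -2\log L + p\ln N$ with $p = m^k(m-1)$.  The AIC is
implemented in its standard form; the historical ratio-vs-top-order loss
differs from it only by a $k$-independent constant, so the minimum-AIC
choice is identical, and a relative column (vs. $k_{\max}$) is reported
alongside.  BIC dominates AIC whenever $\ln N > 2$ and is the consistent
estimator of the pair; AIC may overestimate the order.

**Cross-validated prediction rank.**  Stratified 10-fold CV assigns
*whole paths* to folds — splitting one path's transitions between train
and test would leak its history — by seeded shuffle followed by greedy
packing into the lightest fold by click weight, which provably balances
folds to within one path.  Prediction uses the posterior-mean
($\alpha = 1$) matrix: fake counts are required, or unseen events could
not be scored at all.  The true next state's rank is read under modified
competition ranking — every member of a tie group gets the group's worst
rank ("14445") — and any cell unobserved in training sits at the smoothed
floor and scores the maximum rank $m$.  This is a deliberate, natural
Occam penalty: higher orders produce sparser rows, more ties, and worse
ranks.  Transitions into RESET are scored by default (they are counted,
predictable events); a flag excludes them.  A Top-K hit rate
($K = 5$ by default) mirrors the rank evaluation, resolving boundary
ties by seeded uniform draws with inclusion probability $s/g$ for $s$
free slots in a tie group of size $g$.

## Synthetic study conditions

The generators define the conditions under which the package's claims are
tested; they are fixed, not tuned.

* **Uniform control**: 26 states, one terminal — drawing it ends the path
  (the symbol itself is dropped; RESET later re-models termination, so
  the model space again has 26 states).  Path lengths are
  Geometric(1/26) in draws; ~$10^5$ clicks.  On this corpus raw
  likelihood rises with $k$, yet BIC, both Bayesian posteriors and CV all
  select order 0 — the memoryless truth.
* **Order-2 recovery**: 5 data states, a random symmetric-Dirichlet(1)
  tensor over all 25 histories (almost surely genuinely second order),
  geometric stopping at $p = 0.05$ (mean path length 20, a realistic
  session scale), $5\times10^4$ clicks.  BIC, both posteriors, and CV
  recover $k = 2$; AIC lands in $\{2, 3\}$; the third-order CV rank trails
  the second by well under one fold standard deviation.
* **LRT null**: order-1 tensor, 4 data states, $10^4$ clicks, 500
  replicate corpora (unfiltered, for the reason above).

These corpora emulate the *statistical* structure of navigation data —
session-length decay, sparse high-order tables, known memory depth — but
not its semantics: real corpora have heavy-tailed state frequencies,
user-level heterogeneity, and non-stationarity within sessions.  Passing
the recovery tests shows the machinery is correct and calibrated at desk
scale, not that any particular real dataset has a given order.

## Numerical choices

* All products over probabilities are carried in log space; evidence uses
  `lgamma` only.  Row-sum tolerance is 1e-9, generic comparisons 1e-6.
* Histories are encoded as dense base-$m$ integer codes (doubles, exact
  below $2^{52}$); counting is sparse aggregation over observed cells, so
  memory scales with observed windows, not with $m^k$.
* Parameter counts guard against exceeding $2^{53}$ and error out rather
  than silently losing integer precision.
* Tie-breaks: `top_transitions` breaks probability ties by vocabulary
  order; relabelling ties are drawn once per source label under a seed
  (fixed per label, not per occurrence, and independent of mapping
  order); CV tie draws derive from the master seed.
* Degenerate inputs: empty corpora, empty rows, $k_{\max} = 0$, unseen
  histories, and $-\infty$ log-likelihoods all have defined behaviour and
  tests.

## Problem sizes

The shipped tests and the acceptance script run the control corpus at
$10^5$ clicks, the recovery corpus at $5\times10^4$, and the LRT
calibration at 500 replicates of $10^4$ clicks — sizes at which every
selection result above is stable across seeds while the whole suite runs
in a few minutes on a single core.  Larger corpora only sharpen the
same conclusions; the estimators and counters are sparse and scale
linearly in total clicks for fixed $k_{\max}$.

## Known limitations

* The LRT's nominal degrees of freedom are a conservative convention;
  exact feasible-cell counting is not implemented (the observed-history
  mode is the provided sensitivity analysis).
* Rank-based CV requires a scalar smoothing pseudo-count, since only then
  does the posterior ordering within a row coincide with the count
  ordering that the sparse rank computation exploits.
* Hyperparameters are per-target, shared across histories; fully general
  per-cell tables are not supported.
* No back-off or interpolated smoothing across orders, no variable-order,
  hidden, or semi-Markov models; state dwell times are outside the model
  class.
* `relabel()` expects a user-supplied label-to-category table; deriving
  categories from an ontology or category graph is out of scope.
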