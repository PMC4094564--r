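# markovmemory

How much memory does a categorical event sequence carry?  `markovmemory`
fits discrete Markov chains of arbitrary order k to corpora of paths over a
finite alphabet — navigation sessions, clickstreams, symbolic event
sequences — and decides the appropriate order (memory length) with four
complementary model-selection frameworks:

* **Likelihood-ratio tests** between nested orders, with the statistic
  2(log L₁ − log L₀) calibrated against a χ² distribution;
* **Bayesian model comparison** via the closed-form Dirichlet-multinomial
  marginal likelihood (evidence)
  ∏ᵢ Γ(Aᵢ)/Γ(Aᵢ+Nᵢ) ∏ⱼ Γ(αᵢⱼ+nᵢⱼ)/Γ(αᵢⱼ),
  normalised into model posteriors under a uniform prior and under an
  exponential complexity-penalty prior, with the log-sum-exp trick;
* **Information criteria** AIC = −2 log L + 2p and BIC = −2 log L + p ln N,
  where p = mᵏ(m−1) free parameters grows exponentially with the order;
* **Cross-validated prediction rank**: stratified 10-fold evaluation of the
  average rank of the true next state in the smoothed (Laplace, α = 1)
  transition row, under modified competition ranking ("14445": every tie
  group receives its worst rank, so sparse high-order models pay for their
  ties), plus a Top-K hit rate.

Before counting, every path is RESET-augmented: k boundary symbols are
prepended and one appended, so order-k histories never leak across paths
and path termination is itself a predicted event.  The state space has
m = |labels| + 1 states.  Structural analyses round out the toolkit:
globally-normalised transition tables, top-transition edge lists,
self-transition ("stickiness") profiles by conditioning order, and
endpoint-conditioned corpus splits.

## Worked example

Simulate a genuinely second-order chain over 5 states (a random
Dirichlet(1) transition tensor), 50,000 clicks, and ask every framework
for the order:

```r
library(markovmemory)

tensor <- random_stochastic_tensor(5L, 2L, concentration = 1, seed = 42L)
spec   <- generator_spec(5L, 2L, tensor,
                         terminal_policy = list(kind = "geometric", p = 0.05),
                         total_clicks = 5e4, seed = 42L)
corpus <- filter_min_length(generate_markov_corpus(spec), 2L)

report <- select_order(corpus, k_max = 4L, alpha = 1)
report$orders[, c("order", "logL", "aic", "bic",
                  "posterior_uniform", "posterior_exp_penalty")]
#>   order      logL      aic      bic posterior_uniform posterior_exp_penalty
#> 1     0 -89349.62 178709.2 178753.5                 0                     0
#> 2     1 -84862.90 169785.8 170051.7                 0                     0
#> 3     2 -71924.32 144208.6 145804.1                 1                     1
#> 4     3 -71617.05 145394.1 154967.1                 0                     0
#> 5     4 -70150.84 153261.7 210699.6                 0                     0
report$selected
#>                   aic                   bic              evidence
#>                     2                     2                     2
#>     posterior_uniform posterior_exp_penalty                   lrt
#>                     2                     2                     2

cv_order_evaluation(corpus, k_max = 4L, n_folds = 10L, seed = 42L, topk = 5L)
#> <cv_result> 10-fold, seed 42
#>  order mean_rank sd_rank   top5
#>      0     2.932 0.01499 0.9545
#>      1     2.618 0.01578 0.9550
#>      2     2.171 0.02335 0.9800
#>      3     2.185 0.02329 0.9794
#>      4     2.254 0.02927 0.9755
#> Selected order (min mean rank): 2
```

The raw log-likelihood rises at every order — it always does, because the
models are nested — but every penalised criterion, both Bayesian priors,
and held-out prediction rank all recover k = 2, with the third-order model
a close runner-up in cross-validation, exactly the signature of a true
second-order process.  On a memoryless control corpus
(`generate_uniform_corpus(26L, 1e5, seed)`), the same pipeline selects
order 0 across the board while the raw likelihood still rises with k.

Real corpora come in through `read_paths()` (delimited, one path per line)
or `read_msnbc()` (the UCI sequence dialect: comment lines, a category
legend, then 1-based index sequences), followed by `filter_min_length()`
and optionally `relabel()` to map page-level labels onto topical
categories with seeded tie-breaking.

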