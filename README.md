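# whalehealth

Individual health indicators — body condition, endocrine state, structural
size — shape whether a female gray whale produces a calf, and monitoring them
can warn of population decline long before abundance estimates do.
`whalehealth` implements a hierarchical Bayesian state-space model for the
Pacific Coast Feeding Group (PCFG) of gray whales that links two latent
yearly health states per individual to female calving probability, for
quantitative ecologists working with sparse, individual-based longitudinal
monitoring data.

## The model

For individual `i` in year `t` (8 study years; 2 latent pre-study years
supply the lags):

```
h[i,t] = H_t + beta_h h*[i,t-1] + eps,            eps ~ N(0, sigma_h)       nutritional state
s[i,t] = S_t + beta_s1 h*[i,t-1] + beta_s2 a*[i,t]
              + beta_s3 g[i] + ups,               ups ~ N(0, sigma_s)       stress state
bai    ~ N(h + delta1 d + delta2 P, sqrt(nu_h^2 + bai_sd^2))                BAI observation
fgc    ~ N(exp(s + zeta'm + zeta4 y), nu_s)                                 faecal glucocorticoids
logit(phi) = gamma1 + gamma2 h*[t-1] + gamma3 L3*[t-1] + gamma4 r[t-2]      calving probability
c[t]   ~ Bernoulli(phi (1 - P[t])),  P[t-1] = c[t]                          calving / pregnancy
k[t]   ~ Bernoulli(c p e),  logit(p) = eta1 + eta2 f*                       calf detection
```

`H_t`, `S_t` are yearly population effects; starred covariates are
standardised with constants frozen from the observed data; `r` is the
residual stress state (deviation from the demographic-class expectation);
the pregnancy identity enforces the two-year minimum inter-calf interval as
a hard constraint. Unknown sexes, uncertain ages, lengths and below-LOD
hormone values are latent with explicit priors. Inference is by a compiled
Metropolis-within-Gibbs sampler whose key move draws each female's whole
calving/pregnancy sequence from its exact conditional by enumerating all
constraint-feasible binary sequences. A forward simulator generates
study-like synthetic datasets (sample sizes, sparsity, censoring and
missingness calibrated to the published study) so the entire machinery is
verifiable by parameter recovery; a quadrature-plus-enumeration brute-force
oracle validates the samplers on small instances.

## Worked example

```r
library(whalehealth)

sim <- make_study_like_dataset(seed = 1)
sim$dataset
#> <gw_dataset> 139 individuals, 8 study years ( 2016 - 2023 )
#>   BAI records:       673
#>   faecal records:    278
#>   sighting records:  1085

fit <- run_mcmc(sim$dataset)             # ~50 s: 2 chains x 7000 iterations
subset(posterior_summary(fit), parameter == "gamma3")
#> # A tibble: 1 x 7
#>   parameter median    q2.5 q97.5 p_positive  rhat   ess
#>   <chr>      <dbl>   <dbl> <dbl>      <dbl> <dbl> <dbl>
#> 1 gamma3      1.15 -0.0515  2.66      0.971     1   352.

missed_calving_count(fit)$median
#> [1] 66
```

`gamma3` is the effect of (standardised, cubed) body length in the previous
year on the log-odds of calving: a posterior median of 1.15 with 97% of the
posterior above zero says larger females are substantially more likely to
calve, recovering the generating value 1.36 used by the simulator within its
credible interval.
The missed-calving median counts calving events the posterior believes were
never observed; it exceeds the simulation truth by design-limited
identifiability discussed in the methods vignette
(`vignettes/whale-health-model.Rmd`).

The numbered drivers under `analysis/` run the full workflow (simulate, fit,
derived summaries and figures, parameter recovery), writing tables under
`results/run1/`.

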