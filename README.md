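# epscore

Bayesian adjustment for *unmeasured* confounding in area-referenced
(ecological) environmental-health studies, via a **generalized ecological
propensity score (EPS)** for continuous exposures.

## The problem

Disease-mapping studies regress area-level counts on an area-level
exposure,

```
Y_i ~ Poisson(E_i * mu_i),   log mu_i = b0 + X_i bX + C_i' bC + theta_i (+ phi_i),
```

using registry data with complete spatial coverage but almost no
confounder information. Omitted confounders bias the exposure effect
`bX`. When a survey measures candidate confounders `m_ijk` on a few
subjects in a *subset* of areas, that information can be folded in:

1. **Design stage** — the survey variables are up-scaled to latent
   area-level confounders `M_ik` with a multivariate intrinsic CAR
   (MICAR) spatial prior (`g_k(M_ik) = nu_k + xi_ik`,
   `Sigma_xi^-1 ~ Wishart(v, B)`), and jointly a Gaussian conditional
   exposure model

   ```
   X_i | C_i, M_i ~ N(delta0 + C_i' deltaC + M_i' deltaM, sigma_X^2),
   Z_i^(0) = M_i' deltaM
   ```

   defines the generalized EPS `Z^(0)`: a scalar score that balances the
   confounder distribution with respect to the exposure given `C`.

2. **Analysis stage** — the outcome model gains a flexible score term
   `f(Z_i)`. Design-stage posterior moments enter as data (a two-stage
   *cut*: no feedback into score estimation), with their uncertainty
   propagated through `Z_i^(*0) ~ N(Zhat_i^(0), sigma2_Z0_i)`. Areas
   without survey coverage get the score *imputed* from
   `Z_i ~ N(gamma0 + X_i gammaX + s_q(C_i) + phi_i, sigma_Z^2)` (spline
   in `C`, ICAR residual), under a missing-at-random mechanism or a
   missing-not-at-random logistic selection model
   `logit P(ell_i = 1) = a0 + X_i aX + C_i' aC + Z_i aZ`.

The package ships the full machinery: spatial domains and
exponential-covariance Gaussian processes, a Gaussian-copula generator
for mixed-type confounders, the design-stage Gibbs sampler, the
JAGS-based analysis stage (naive, true-benchmark, complete-case, MAR and
MNAR variants), convergence diagnostics, and a replication harness
computing mean bias, RMSE, 95% coverage and interval width.

## Worked example

```r
library(epscore)

## geography: 10 x 10 lattice, 1.5 km spacing; survey covers ~60% of areas
dom <- build_domain("lattice", nx = 10, ny = 10, spacing = 1.5)
dat <- generate_dataset(dom, sim_config("MAR", "linear"), seed = 101)

## naive model: confounded
naive <- fit_outcome_model(dat$eco, dom, "naive",
                           settings = mcmc_settings("fast", seed = 1))

## two-stage EPS adjustment
des <- fit_design_stage(dat$indiv, dat$eco, dom,
                        settings = mcmc_settings("fast", seed = 2))
eps <- fit_outcome_model(dat$eco, dom, "eps_mar", design_result = des,
                         f = "linear",
                         settings = mcmc_settings("fast",
                                                  n_iter = 12000,
                                                  n_burnin = 6000,
                                                  seed = 3))
naive
eps
percent_change(eps, delta_x = 1)$mean
```

Output from this exact script:

```
Health-effect fit (naive):
  beta_X = 0.857 (95% CI 0.749 to 0.968)
MCMC convergence: OK (max rhat 1.000, threshold 1.10, 3 parameters)
Health-effect fit (eps_mar):
  beta_X = 0.509 (95% CI 0.094 to 0.933)
MCMC convergence: OK (max rhat 1.033, threshold 1.10, 6 parameters)
[1] 70.26543
```

The generating exposure coefficient is 0.20. The naive model reports
0.86 with a tight interval excluding the truth — the classic unmeasured
confounding failure. The EPS-adjusted fit shifts the posterior toward
the truth and (honestly) widens it until it covers 0.20; at 100 areas a
single replicate is noisy, which is why conclusions rest on replicate
averages. The replication harness (`run_replications()` +
`metrics_table()`) averages over replicates: on a 400-area lattice with
10 replicates it reports averaged posterior means of 0.792 for the naive
model (coverage 0%) and 0.203 for the benchmark with the true
confounders, and at 196 areas with 10 replicates the full two-stage fit
averages within 0.06 of the study's 0.21.

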