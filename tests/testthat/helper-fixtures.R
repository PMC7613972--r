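## Shared fixtures: small domains and configs built in code.

small_domain <- function(nx = 6, ny = 6, spacing = 1.5)
  build_domain("lattice", nx = nx, ny = ny, spacing = spacing)

fast_settings <- function(seed = 1, n_iter = 3000, n_burnin = 1500)
  mcmc_settings("fast", n_iter = n_iter, n_burnin = n_burnin, seed = seed)

## a design-stage result stub with a known score, for analysis-stage
## tests that do not need a real design fit
stub_design_result <- function(domain, sidx, Z0_mean, Z0_var) {
  structure(list(
    Z0_mean = stats::setNames(Z0_mean, domain$area_id[sidx]),
    Z0_var = stats::setNames(Z0_var, domain$area_id[sidx]),
    Z0_var_pooled = mean(Z0_var),
    in_sample_idx = sidx
  ), class = "eps_design_result")
}
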