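test_that("percent change transforms coefficient draws correctly", {
  r0 <- list(beta_X_draws = rep(0, 100))
  pc0 <- percent_change(r0, delta_x = 1)
  expect_equal(pc0$mean, 0)
  expect_equal(pc0$p_risk_gt_1, 0.5)  # undefined-at-null convention
  ## exact closed form
  d <- sqrt(10 + 10) - sqrt(10)
  r1 <- list(beta_X_draws = rep(log(1.05) / d, 10))
  pc1 <- percent_change(r1, delta_x = 10, transform = "sqrt_scale",
                        baseline = 10)
  expect_equal(pc1$mean, 5, tolerance = 1e-10)
  expect_error(percent_change(r1, transform = "sqrt_scale"), "baseline")
  ## lognormal-mean oracle for Gaussian draws
  set.seed(1)
  r2 <- list(beta_X_draws = rnorm(200000, 0.2, 0.05))
  pc2 <- percent_change(r2, delta_x = 1)
  truth <- 100 * (exp(0.2 + 0.05^2 / 2) - 1)
  expect_equal(pc2$mean, truth, tolerance = 0.05)
  expect_gt(pc2$p_risk_gt_1, 0.99)
})

test_that("EPS variants demand a design-stage result", {
  dom <- small_domain()
  eco <- generate_ecological(dom, sim_config(), seed = 1)
  expect_error(fit_outcome_model(eco, dom, "eps_mar"), "design-stage")
})

test_that("a degenerate uncertainty model pins the score", {
  dom <- small_domain(5, 5)
  dat <- generate_dataset(dom, sim_config(), seed = 3)
  ## a score unrelated to the exposure keeps the coefficient posteriors
  ## well-separated, so the plug-in equivalence is sharp
  set.seed(4)
  z <- rnorm(25)
  des <- stub_design_result(dom, seq_len(25), z, rep(1e-12, 25))
  st <- fast_settings(seed = 7, n_iter = 1500, n_burnin = 700)
  fit <- fit_outcome_model(dat$eco, dom, "complete_case",
                           design_result = des, f = "linear",
                           settings = st)
  zc <- fit$summary[grep("^Zc\\[", rownames(fit$summary)), "mean"]
  expect_equal(unname(zc), z, tolerance = 1e-4)
  ## equals the plug-in fit with the score as a fixed covariate
  eco2 <- dat$eco; eco2$Zfix <- z
  plug <- run_jags("model{
    for (i in 1:N) {
      Y[i] ~ dpois(E[i]*exp(b0 + bX*X[i] + bC*C[i] + bZ*Z[i] + th[i]))
      th[i] ~ dnorm(0, tau) }
    b0 ~ dnorm(0,0.1) bX ~ dnorm(0,0.1) bC ~ dnorm(0,0.1)
    bZ ~ dnorm(0,0.1) tau ~ dgamma(2,1) }",
    list(Y = eco2$Y, E = eco2$E, X = eco2$X, C = eco2$C, Z = z, N = 25),
    "bX", st)
  expect_equal(unname(fit$beta_X["mean"]),
               unname(plug$summary["bX", "mean"]), tolerance = 0.05)
})

test_that("intercept-only imputation collapses to the global level", {
  dom <- small_domain(5, 5)
  dat <- generate_dataset(dom, sim_config("MAR"), seed = 5)
  sidx <- which(dat$eco$ell == 0)
  des <- stub_design_result(dom, sidx, dat$eco$Z_true[sidx],
                            rep(1e-6, length(sidx)))
  st <- fast_settings(seed = 8, n_iter = 1500, n_burnin = 700)
  fit <- fit_outcome_model(dat$eco, dom, "eps_mar", design_result = des,
                           f = "linear", settings = st,
                           impute_terms = character(0))
  g0 <- fit$summary["g0", "mean"]
  zi <- fit$Z_imputed[, "mean"]
  ## outcome feedback perturbs the imputations only slightly around g0
  expect_lt(max(abs(zi - g0)), 0.35)
  expect_lt(sd(zi), sd(dat$eco$Z_true[dat$eco$ell == 1]))
})

test_that("ICAR smoothing pulls imputations toward their neighbors", {
  ## in-sample score follows a west-east gradient; the missing areas sit
  ## in the east corner, so their imputed values must exceed the mean
  dom <- small_domain(5, 5, spacing = 1)
  dat <- generate_dataset(dom, sim_config(), seed = 9)
  grad <- dom$centroids[, "x"] - mean(dom$centroids[, "x"])
  dat$eco$Z_true <- grad
  dat$eco$X <- rnorm(25, 0, 0.1)  # keep X out of the story
  miss <- which(dom$centroids[, "x"] == max(dom$centroids[, "x"]))[1:2]
  dat$eco$ell <- as.integer(seq_len(25) %in% miss)
  sidx <- setdiff(seq_len(25), miss)
  des <- stub_design_result(dom, sidx, grad[sidx], rep(1e-6, 23))
  st <- fast_settings(seed = 9, n_iter = 1500, n_burnin = 700)
  fit <- fit_outcome_model(dat$eco, dom, "eps_mar", design_result = des,
                           f = "linear", settings = st,
                           impute_terms = "icar", s_q_df = 0)
  zi <- fit$Z_imputed[, "mean"]
  expect_true(all(zi > mean(grad[sidx])))
})

test_that("design result is untouched by the analysis stage (cut)", {
  dom <- small_domain(5, 5)
  dat <- generate_dataset(dom, sim_config(), seed = 11)
  des <- stub_design_result(dom, seq_len(25), dat$eco$Z_true,
                            rep(0.01, 25))
  before <- serialize(des, NULL)
  st <- fast_settings(seed = 10, n_iter = 800, n_burnin = 400)
  fit1 <- fit_outcome_model(dat$eco, dom, "complete_case",
                            design_result = des, settings = st)
  eco2 <- dat$eco; eco2$Y <- rev(eco2$Y)
  fit2 <- fit_outcome_model(eco2, dom, "complete_case",
                            design_result = des, settings = st)
  expect_identical(serialize(des, NULL), before)
  expect_false(identical(fit1$beta_X, fit2$beta_X))
})

test_that("MNAR with a_Z = 0 reduces to the MAR fit", {
  dom <- small_domain(6, 6)
  dat <- generate_dataset(dom, sim_config("MAR"), seed = 13)
  sidx <- which(dat$eco$ell == 0)
  des <- stub_design_result(dom, sidx, dat$eco$Z_true[sidx],
                            rep(0.01, length(sidx)))
  st <- fast_settings(seed = 11, n_iter = 2500, n_burnin = 1200)
  mar <- fit_outcome_model(dat$eco, dom, "eps_mar", design_result = des,
                           f = "linear", settings = st)
  mnar0 <- fit_outcome_model(dat$eco, dom, "eps_mnar",
                             design_result = des, f = "linear",
                             settings = st, aZ_mode = 0)
  se <- sqrt(mar$beta_X["sd"]^2 + mnar0$beta_X["sd"]^2)
  expect_lt(abs(mar$beta_X["mean"] - mnar0$beta_X["mean"]),
            unname(0.5 * se) + 0.05)
})

test_that("spline f with too few areas is rejected", {
  dom <- small_domain(5, 5)
  dat <- generate_dataset(dom, sim_config("MAR"), seed = 15)
  sidx <- which(dat$eco$ell == 0)
  des <- stub_design_result(dom, sidx, dat$eco$Z_true[sidx],
                            rep(0.01, length(sidx)))
  expect_error(
    fit_outcome_model(dat$eco, dom, "eps_mar", design_result = des,
                      settings = fast_settings(), s_q_df = 100),
    "spline basis df")
})
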