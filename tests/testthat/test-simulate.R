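test_that("Gaussian copula honors identity correlation and marginals", {
  marg2 <- list(list(family = "normal", mean = 0, sd = 1),
                list(family = "normal", mean = 0, sd = 1))
  x <- gaussian_copula_sample(diag(2), marg2, 10000, seed = 3)
  expect_lt(abs(stats::cor(x)[1, 2]), 3 / sqrt(10000))
  expect_lt(abs(mean(x[, 1])), 3 / sqrt(10000))
})

test_that("Beta margins reproduce the intended confounder means", {
  marg <- list(list(family = "beta", shape1 = 12, shape2 = 12),
               list(family = "beta", shape1 = 6, shape2 = 14))
  x <- gaussian_copula_sample(diag(2), marg, 10000, seed = 4)
  expect_equal(mean(x[, 1]), 0.5, tolerance = 0.01)
  expect_equal(mean(x[, 2]), 0.3, tolerance = 0.01)
  ## distributional check against the spec'd margin
  expect_gt(suppressWarnings(
    stats::ks.test(x[, 1], stats::pbeta, 12, 12)$p.value), 0.01)
})

test_that("copula correlation propagates through Gaussian margins", {
  R <- matrix(c(1, 0.7, 0.7, 1), 2)
  marg2 <- list(list(family = "normal", mean = 0, sd = 1),
                list(family = "normal", mean = 0, sd = 1))
  x <- gaussian_copula_sample(R, marg2, 10000, seed = 5)
  se <- (1 - 0.7^2) / sqrt(10000)
  expect_lt(abs(stats::cor(x)[1, 2] - 0.7), 3 * se)
})

test_that("copula input validation", {
  marg2 <- list(list(family = "normal", mean = 0, sd = 1),
                list(family = "cauchy"))
  expect_error(gaussian_copula_sample(diag(2), marg2, 10),
               "unsupported marginal")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(gaussian_copula_sample(bad, marg2[c(1, 1)], 10),
               "positive definite")
})

test_that("ecological generator matches its stated distributions", {
  dom <- build_domain("lattice", nx = 32, ny = 32, spacing = 1.5)
  eco <- generate_ecological(dom, sim_config(), seed = 10)
  expect_true(all(eco$Y >= 0), all(eco$Y == round(eco$Y)))
  expect_true(all(eco$E >= 15 & eco$E <= 30))
  expect_equal(mean(eco$E), 22.5, tolerance = 0.5)
  expect_equal(sd(eco$theta), sqrt(0.05), tolerance = 0.02)
  expect_true(all(eco$ell == 0))
  ## Z_true is the stated confounder combination
  expect_equal(eco$Z_true,
               as.numeric(as.matrix(eco[paste0("M", 1:5)]) %*%
                          c(0.2, 0.3, 0.4, 0.1, 0.1)))
  ## marginal distribution checks at the generator's n
  expect_gt(suppressWarnings(
    stats::ks.test(eco$M1, "pnorm")$p.value), 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(eco$M4, stats::pbeta, 12, 12)$p.value), 0.01)
})

test_that("without confounding the log-risk slopes are recovered", {
  dom <- build_domain("lattice", nx = 32, ny = 32, spacing = 1.5)
  cfg <- sim_config(beta_M_true = rep(0, 5))
  eco <- generate_ecological(dom, cfg, seed = 12)
  fit <- lm(log((Y + 0.5) / E) ~ X + C, data = eco)
  expect_equal(unname(coef(fit)["X"]), 0.2, tolerance = 0.05)
  expect_equal(unname(coef(fit)["C"]), 0.2, tolerance = 0.05)
})

test_that("confounding is active under the default configuration", {
  dom <- build_domain("lattice", nx = 16, ny = 16, spacing = 1.5)
  for (s in c(21, 22, 23)) {
    eco <- generate_ecological(dom, sim_config(), seed = s)
    covs <- sapply(paste0("M", 1:5), function(k) cov(eco$X, eco[[k]]))
    expect_true(all(covs > 0))
    naive <- coef(glm(Y ~ X + C, offset = log(E), family = poisson,
                      data = eco))["X"]
    adj <- coef(glm(Y ~ X + C + M1 + M2 + M3 + M4 + M5,
                    offset = log(E), family = poisson, data = eco))["X"]
    expect_gt(naive, adj)  # omitting M inflates the exposure effect
  }
})

test_that("individual records are unbiased for the area-level values", {
  dom <- build_domain("lattice", nx = 12, ny = 12, spacing = 1.5)
  cfg <- sim_config()
  eco <- generate_ecological(dom, cfg, seed = 30)
  ind <- generate_individual(dom, eco, cfg, seed = 31)
  expect_true(all(ind$m4 %in% c(0, 1)), all(ind$m5 %in% c(0, 1)))
  mbar <- rowsum(ind$m1, ind$area) / 20
  d <- mbar - eco$M1
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(nrow(eco)))
  ## pooled residual correlation approximates the copula's 0.7
  r1 <- ind$m1 - eco$M1[ind$area]
  r2 <- ind$m2 - eco$M2[ind$area]
  expect_equal(cor(r1, r2), 0.7, tolerance = 3 * (1 - 0.49) / sqrt(nrow(ind)))
})

test_that("missingness designs hit their stated rates", {
  dom <- build_domain("lattice", nx = 16, ny = 16, spacing = 1.5)
  ## all-zero coefficients: every area misses with probability one half
  cfg0 <- sim_config("MAR",
                     missingness_coefs = c(intercept = 0, X = 0, C = 0))
  eco <- generate_ecological(dom, cfg0, seed = 40)
  ind <- generate_individual(dom, eco, cfg0, seed = 41)
  ms <- apply_missingness(eco, ind, cfg0, seed = 42)
  expect_lt(abs(mean(ms$eco$ell) - 0.5), 3 * 0.5 / sqrt(256))
  ## stated MAR and MNAR coefficients: roughly half the areas missing.
  ## The exact plug-in rate implied by the stated logistic coefficients
  ## and variable distributions is ~0.40; the empirical fraction must
  ## match that plug-in oracle, and sit in a broad "about half" band.
  for (des in c("MAR", "MNAR")) {
    fr <- pl <- numeric(4)
    for (r in 1:4) {
      cfg <- sim_config(des)
      eco <- generate_ecological(dom, cfg, seed = 100 + r)
      ind <- generate_individual(dom, eco, cfg, seed = 200 + r)
      cf <- cfg$missingness_coefs
      lin <- cf[["intercept"]] + cf[["X"]] * eco$X + cf[["C"]] * eco$C
      if (des == "MNAR") lin <- lin + cf[["Z"]] * eco$Z_true
      pl[r] <- mean(plogis(lin))
      ms <- apply_missingness(eco, ind, cfg, seed = 300 + r)
      fr[r] <- mean(ms$eco$ell)
    }
    expect_lt(abs(mean(fr) - mean(pl)), 3 * 0.5 / sqrt(4 * 256))
    expect_gt(mean(fr), 0.25)
    expect_lt(mean(fr), 0.60)
  }
  ## individual records only remain for observed areas
  dat <- generate_dataset(dom, sim_config("MAR"), seed = 50)
  expect_setequal(unique(dat$indiv$area), which(dat$eco$ell == 0))
})

test_that("a dominant selection coefficient empties the top score decile", {
  dom <- build_domain("lattice", nx = 16, ny = 16, spacing = 1.5)
  cfg <- sim_config("MNAR",
                    missingness_coefs = c(intercept = 0, X = 0, C = 0,
                                          Z = 25))
  eco <- generate_ecological(dom, cfg, seed = 60)
  eco$Z_true <- as.numeric(scale(eco$Z_true))
  ind <- generate_individual(dom, eco, cfg, seed = 61)
  ms <- apply_missingness(eco, ind, cfg, seed = 62)
  top <- eco$Z_true >= quantile(eco$Z_true, 0.9)
  ## oracle: plug-in logistic probability in that decile
  expect_gt(mean(plogis(25 * eco$Z_true[top])), 0.999)
  expect_gt(mean(ms$eco$ell[top]), 0.95)
})

test_that("full design leaves missingness untouched, with a warning", {
  dom <- small_domain()
  cfg <- sim_config("full")
  eco <- generate_ecological(dom, cfg, seed = 70)
  ind <- generate_individual(dom, eco, cfg, seed = 71)
  expect_warning(ms <- apply_missingness(eco, ind, cfg), "full")
  expect_identical(ms$eco, eco)
})

test_that("replicates are bit-reproducible by seed", {
  dom <- small_domain()
  cfg <- sim_config("MNAR")
  a <- generate_dataset(dom, cfg, seed = 81)
  b <- generate_dataset(dom, cfg, seed = 81)
  c <- generate_dataset(dom, cfg, seed = 82)
  expect_identical(a$eco, b$eco)
  expect_identical(a$indiv, b$indiv)
  expect_false(identical(a$eco$Y, c$eco$Y))
})

test_that("dataset serialization round-trips through delimited text", {
  dom <- small_domain()
  dat <- generate_dataset(dom, sim_config("MAR"), seed = 90)
  dir <- tempfile()
  write_dataset(dat, dir)
  eco2 <- utils::read.table(file.path(dir, "replicate_eco.tsv"),
                            header = TRUE, sep = "\t")
  expect_equal(eco2$Y, dat$eco$Y)
  expect_equal(eco2$Z_true, dat$eco$Z_true, tolerance = 1e-12)
  cfg2 <- jsonlite::read_json(file.path(dir, "replicate_config.json"))
  expect_equal(cfg2$seed, 90)
  expect_equal(cfg2$config$design, "MAR")
})
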