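#' Sample mixed-type variables through a Gaussian copula
#'
#' Draws latent vectors \eqn{z \sim N(0, R)}, maps each coordinate through
#' the standard normal cdf to a uniform, then through the inverse cdf of
#' the requested marginal. Bernoulli margins threshold the uniform at
#' `1 - p`, the standard Gaussian-copula treatment of binary variables.
#'
#' @param corr K x K correlation matrix (symmetric positive definite, unit
#'   diagonal).
#' @param marginals list of K marginal specs; each is a list with `family`
#'   in `"normal"`, `"beta"`, `"bernoulli"` and parameters `mean`/`sd`,
#'   `shape1`/`shape2`, or `prob`. Parameters may be length-1 or length-n
#'   vectors (area-varying margins).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return n x K numeric matrix.
#' @examples
#' R <- diag(2)
#' m <- list(list(family = "normal", mean = 0, sd = 1),
#'           list(family = "beta", shape1 = 12, shape2 = 12))
#' x <- gaussian_copula_sample(R, m, 100, seed = 1)
#' @export
gaussian_copula_sample <- function(corr, marginals, n, seed = NULL) {
  K <- length(marginals)
  stopifnot(nrow(corr) == K, ncol(corr) == K)
  if (max(abs(corr - t(corr))) > 1e-10 || any(abs(diag(corr) - 1) > 1e-10))
    stop("corr must be a symmetric correlation matrix")
  L <- tryCatch(chol(corr), error = function(e)
    stop("corr is not positive definite"))
  if (!is.null(seed)) set.seed(seed)
  U <- stats::pnorm(matrix(stats::rnorm(n * K), n, K) %*% L)
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    sp <- marginals[[k]]
    out[, k] <- switch(sp$family,
      normal = stats::qnorm(U[, k], mean = sp$mean, sd = sp$sd),
      beta = stats::qbeta(U[, k], sp$shape1, sp$shape2),
      bernoulli = as.numeric(U[, k] > 1 - sp$prob),
      stop("unsupported marginal family: ", sp$family))
  }
  out
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults are
#' the generating conditions of the simulation study the package is
#' designed around: five correlated mixed-type latent confounders (three
#' Gaussian, two Beta) coupled by a Gaussian copula; a measured covariate
#' and the third confounder centered on two independent exponential-
#' covariance spatial processes; a continuous exposure that is a linear
#' function of covariate and confounders; and a Poisson count outcome with
#' exchangeable log-normal heterogeneity. Two binary missingness designs
#' (MAR and MNAR logistic selection) delete the individual-level survey
#' records of roughly half the areas.
#'
#' @param design `"full"`, `"MAR"`, or `"MNAR"` spatial coverage of the
#'   individual-level data.
#' @param scenario `"linear"` or `"nonlinear"` relation between outcome
#'   and the first two latent confounders (nonlinear adds quadratic terms
#'   `0.2*M1^2` and `0.2*M2^2` to the log-risk).
#' @param n_subjects_per_area survey sample size J per covered area.
#' @param beta_X_true generating (target) exposure coefficient.
#' @param copula_corr 5 x 5 correlation matrix of the confounders.
#' @param sigma_C sd of the measured covariate around the first spatial
#'   process (default `sqrt(0.5)`, i.e. variance 0.5).
#' @param sigma_X sd of the exposure residual (default 0.25).
#' @param delta_C,delta_M exposure-model coefficients for C and M.
#' @param beta_C_true,beta_M_true outcome-model coefficients for C and M.
#' @param outcome_theta_sd sd of the exchangeable heterogeneity theta
#'   (default `sqrt(0.05)`, i.e. variance 0.05).
#' @param E_range range of the uniform expected counts (default c(15, 30)).
#' @param gp1,gp2 [gp_config()]s for the two latent spatial processes
#'   (defaults: variance 1, effective ranges 15 and 25 km).
#' @param missingness_coefs named numeric vector of logistic coefficients;
#'   defaults are design-specific: MAR `(-0.4, X 0.6, C 0.5)`, MNAR
#'   `(-0.9, X 0.7, C 0.7, Z 1.0)`.
#' @param n_replicates replicate count for harness runs.
#' @return list of class `eps_sim_config`.
#' @export
sim_config <- function(design = c("full", "MAR", "MNAR"),
                       scenario = c("linear", "nonlinear"),
                       n_subjects_per_area = 20,
                       beta_X_true = 0.20,
                       copula_corr = default_copula_corr(),
                       sigma_C = sqrt(0.5),
                       sigma_X = 0.25,
                       delta_C = 0.3,
                       delta_M = c(0.2, 0.3, 0.4, 0.1, 0.1),
                       beta_C_true = 0.2,
                       beta_M_true = rep(0.2, 5),
                       outcome_theta_sd = sqrt(0.05),
                       E_range = c(15, 30),
                       gp1 = gp_config(1, effective_range = 15),
                       gp2 = gp_config(1, effective_range = 25),
                       missingness_coefs = NULL,
                       n_replicates = 100) {
  design <- match.arg(design)
  scenario <- match.arg(scenario)
  stopifnot(is.finite(beta_X_true), E_range[1] >= 1, E_range[2] > E_range[1])
  if (is.null(missingness_coefs)) {
    missingness_coefs <- switch(design,
      full = c(intercept = 0, X = 0, C = 0),
      MAR = c(intercept = -0.4, X = 0.6, C = 0.5),
      MNAR = c(intercept = -0.9, X = 0.7, C = 0.7, Z = 1.0))
  }
  if (design == "MNAR" && !"Z" %in% names(missingness_coefs))
    stop("MNAR design requires a Z term in missingness_coefs")
  cc <- copula_corr
  if (max(abs(cc - t(cc))) > 1e-10 || any(abs(diag(cc) - 1) > 1e-10) ||
      any(eigen(cc, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("copula_corr must be symmetric positive definite with unit diagonal")
  structure(list(
    design = design, scenario = scenario,
    n_subjects_per_area = n_subjects_per_area,
    beta_X_true = beta_X_true, copula_corr = copula_corr,
    sigma_C = sigma_C, sigma_X = sigma_X,
    delta_C = delta_C, delta_M = delta_M,
    beta_C_true = beta_C_true, beta_M_true = beta_M_true,
    outcome_theta_sd = outcome_theta_sd, E_range = E_range,
    gp1 = gp1, gp2 = gp2,
    missingness_coefs = missingness_coefs,
    n_replicates = n_replicates
  ), class = "eps_sim_config")
}

#' Default confounder correlation matrix
#'
#' The 5 x 5 correlation structure coupling the three Gaussian and two
#' Beta latent confounders.
#' @export
default_copula_corr <- function() {
  R <- diag(5)
  R[lower.tri(R)] <- c(0.7, 0.3, 0.2, 0.2,
                       0.2, 0.1, 0.1,
                       0.4, 0.4,
                       0.5)
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  R
}

#' Generate the ecological (area-level) dataset
#'
#' Simulates, over a spatial domain: two latent Gaussian processes
#' `zeta1`, `zeta2`; a measured covariate `C_i ~ N(zeta1_i, sigma_C^2)`;
#' five copula-coupled latent confounders with margins N(0,1), N(0,1),
#' N(zeta2_i, 1), Beta(12,12), Beta(6,14); exposure
#' `X_i ~ N(0.3 C_i + M_i' delta_M, sigma_X^2)`; expected counts
#' `E_i ~ U(E_range)`; heterogeneity `theta_i ~ N(0, theta_sd^2)`; and
#' Poisson counts with log-risk
#' `beta_X X + 0.2 C + 0.2 sum(M) + theta` (linear scenario) or with
#' quadratic terms `0.2 M1^2 + 0.2 M2^2` added (nonlinear). `Z_true` is
#' the confounder part of the exposure mean, `M' delta_M`.
#'
#' @param domain an `eps_domain`.
#' @param config an [sim_config()].
#' @param seed optional integer seed.
#' @return data frame of class `eps_eco` with one row per area: `area_id`,
#'   `Y`, `E`, `X`, `C`, `M1..M5`, `Z_true`, `theta`, `zeta1`, `zeta2`,
#'   `ell` (missingness indicator, all 0 until [apply_missingness()]).
#' @export
generate_ecological <- function(domain, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- domain$n_areas
  zeta1 <- simulate_gp(domain, config$gp1)
  zeta2 <- simulate_gp(domain, config$gp2)
  C <- stats::rnorm(n, zeta1, config$sigma_C)
  marg <- list(
    list(family = "normal", mean = 0, sd = 1),
    list(family = "normal", mean = 0, sd = 1),
    list(family = "normal", mean = zeta2, sd = 1),
    list(family = "beta", shape1 = 12, shape2 = 12),
    list(family = "beta", shape1 = 6, shape2 = 14))
  M <- gaussian_copula_sample(config$copula_corr, marg, n)
  colnames(M) <- paste0("M", 1:5)
  Z_true <- drop(M %*% config$delta_M)
  X <- stats::rnorm(n, config$delta_C * C + Z_true, config$sigma_X)
  E <- stats::runif(n, config$E_range[1], config$E_range[2])
  theta <- stats::rnorm(n, 0, config$outcome_theta_sd)
  logrisk <- config$beta_X_true * X + config$beta_C_true * C +
    drop(M %*% config$beta_M_true) + theta
  if (config$scenario == "nonlinear")
    logrisk <- logrisk + config$beta_M_true[1] * M[, 1]^2 +
      config$beta_M_true[2] * M[, 2]^2
  Y <- stats::rpois(n, E * exp(logrisk))
  out <- data.frame(area_id = domain$area_id, Y = Y, E = E, X = X, C = C,
                    M, Z_true = Z_true, theta = theta,
                    zeta1 = zeta1, zeta2 = zeta2, ell = 0L)
  class(out) <- c("eps_eco", "data.frame")
  out
}

#' Generate individual-level survey records
#'
#' For each area draws `J` subjects with five mixed-type confounder
#' measurements through a Gaussian copula with the same correlation matrix
#' as the area-level confounders. Continuous margins are
#' `N(M_ik, 1)` for k = 1..3 (centered on the area's latent value);
#' binary margins are `Bernoulli(M_ik)` for k = 4, 5 (success probability
#' equal to the area's Beta-distributed latent value).
#'
#' @param domain an `eps_domain`.
#' @param eco the matching [generate_ecological()] output.
#' @param config an [sim_config()].
#' @param seed optional integer seed.
#' @return data frame of class `eps_indiv`: `area_id`, `area` (index),
#'   `subject_id`, `m1..m5`, plus attribute `types`.
#' @export
generate_individual <- function(domain, eco, config, seed = NULL) {
  if (nrow(eco) != domain$n_areas ||
      !identical(as.character(eco$area_id), domain$area_id))
    stop("ecological dataset does not match the domain")
  if (!is.null(seed)) set.seed(seed)
  J <- config$n_subjects_per_area
  idx <- rep(seq_len(domain$n_areas), each = J)
  marg <- list(
    list(family = "normal", mean = eco$M1[idx], sd = 1),
    list(family = "normal", mean = eco$M2[idx], sd = 1),
    list(family = "normal", mean = eco$M3[idx], sd = 1),
    list(family = "bernoulli", prob = eco$M4[idx]),
    list(family = "bernoulli", prob = eco$M5[idx]))
  m <- gaussian_copula_sample(config$copula_corr, marg, length(idx))
  colnames(m) <- paste0("m", 1:5)
  out <- data.frame(area_id = domain$area_id[idx], area = idx,
                    subject_id = rep(seq_len(J), domain$n_areas), m)
  attr(out, "types") <- c(rep("gaussian", 3), rep("bernoulli", 2))
  class(out) <- c("eps_indiv", "data.frame")
  out
}

#' Apply a missingness design to a simulated dataset
#'
#' Draws the per-area binary indicator `ell_i` from the logistic model of
#' the configured design (MAR: intercept, X, C; MNAR: additionally
#' `Z_true`), then deletes the individual-level records of areas with
#' `ell_i = 1`. Ecological outcome, expected counts, exposure and measured
#' covariate are retained everywhere: only the confounder information goes
#' missing.
#'
#' @param eco ecological dataset.
#' @param indiv individual dataset.
#' @param config an [sim_config()] with design `"MAR"` or `"MNAR"`.
#' @param seed optional integer seed.
#' @return list with elements `eco` (ell filled in) and `indiv` (records
#'   of missing areas removed).
#' @export
apply_missingness <- function(eco, indiv, config, seed = NULL) {
  if (config$design == "full") {
    warning("design = 'full': no missingness applied")
    return(list(eco = eco, indiv = indiv))
  }
  if (!is.null(seed)) set.seed(seed)
  cf <- config$missingness_coefs
  lin <- cf[["intercept"]] + cf[["X"]] * eco$X + cf[["C"]] * eco$C
  if (config$design == "MNAR") lin <- lin + cf[["Z"]] * eco$Z_true
  p <- stats::plogis(lin)
  eco$ell <- stats::rbinom(nrow(eco), 1, p)
  if (all(eco$ell == 1L)) eco$ell[which.min(p)] <- 0L  # keep >= 1 in-sample
  indiv <- indiv[indiv$area %in% which(eco$ell == 0L), , drop = FALSE]
  list(eco = eco, indiv = indiv)
}

#' Generate a complete replicate dataset
#'
#' Convenience wrapper running [generate_ecological()],
#' [generate_individual()] and, for sparse designs,
#' [apply_missingness()] under a single seed.
#'
#' @inheritParams generate_ecological
#' @return list with `eco`, `indiv`, `config`, `seed`.
#' @export
generate_dataset <- function(domain, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eco <- generate_ecological(domain, config)
  indiv <- generate_individual(domain, eco, config)
  if (config$design != "full") {
    ms <- apply_missingness(eco, indiv, config)
    eco <- ms$eco; indiv <- ms$indiv
  }
  list(eco = eco, indiv = indiv, config = config, seed = seed)
}

#' Write a replicate dataset as delimited text plus a JSON sidecar
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_dataset <- function(dataset, dir, prefix = "replicate") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$eco, file.path(dir, paste0(prefix, "_eco.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$indiv,
                     file.path(dir, paste0(prefix, "_indiv.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- dataset$config
  cfg$gp1 <- unclass(cfg$gp1); cfg$gp2 <- unclass(cfg$gp2)
  jsonlite::write_json(
    list(config = unclass(cfg), seed = dataset$seed),
    file.path(dir, paste0(prefix, "_config.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
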