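#' Fit the analysis stage: health-effect models with EPS adjustment
#'
#' Fits the Poisson disease-mapping outcome model
#' `Y_i ~ Poisson(E_i exp(beta_0 + X_i beta_X + C_i' beta_C + f(Z_i) +
#' theta_i))` in one of five variants:
#'
#' * `"naive"` — no confounder adjustment beyond the measured covariates
#'   (the classical ecological model; exchangeable `theta`, optionally a
#'   convolution with an ICAR residual via `use_phi_outcome`).
#' * `"benchmark"` — the latent confounders `M1..MK` entered directly
#'   (simulation truth; quantifies the information ceiling).
#' * `"complete_case"` — EPS adjustment restricted to in-sample areas.
#' * `"eps_mar"` — full-domain EPS adjustment: for in-sample areas the
#'   score enters through the uncertainty model
#'   `Z_i^(*0) ~ N(Zhat_i^(0), sigma2_{Z^(0),i})` (design-stage posterior
#'   moments as data — the two-stage "cut"); for out-of-sample areas it is
#'   imputed from
#'   `Z_i ~ N(gamma_0 + X_i gamma_X + s_q(C_i) + phi_i, sigma_Z^2)` with a
#'   natural-cubic-spline `s_q` and an ICAR spatial residual `phi`
#'   (conditional-variance prior Inverse-Gamma(2, 1)), with feedback from
#'   the outcome likelihood; in-sample areas contribute to the imputation
#'   likelihood at their pinned design-stage means.
#' * `"eps_mnar"` — adds the logistic selection (missingness) model
#'   `logit P(ell_i = 1) = a_0 + X_i a_X + C_i' a_C + Z_i a_Z`, jointly
#'   fitted, with `a_Z` either estimated (N(0, 10) prior) or fixed.
#'
#' Coefficient priors are N(0, 10); the heterogeneity variance has an
#' Inverse-Gamma(2, 1) prior. The ICAR prior is realized through its
#' pairwise-difference kernel over the neighbor-graph edges with the
#' Laplacian-rank determinant correction, plus a tight zero-mean
#' constraint on the average; intercept shifts absorb the constraint.
#'
#' @param eco ecological dataset (columns `Y`, `E`, `X`, covariates in
#'   `C_cols`, `ell`; `M*` columns for the benchmark variant).
#' @param domain the full `eps_domain`.
#' @param variant one of `"naive"`, `"benchmark"`, `"complete_case"`,
#'   `"eps_mar"`, `"eps_mnar"`.
#' @param design_result an `eps_design_result` (required for the EPS
#'   variants); used as fixed data — no feedback to the design stage.
#' @param f functional form for the score in the outcome model:
#'   `"quadratic"` (default), `"linear"`, or `"poly"` with degree `f_df`.
#' @param f_df polynomial degree when `f = "poly"`.
#' @param settings an [mcmc_settings()].
#' @param C_cols measured-covariate column names.
#' @param aZ_mode `"estimated"` or a fixed numeric value for the
#'   selection-model coefficient on the score (MNAR only).
#' @param s_q_df degrees of freedom of the natural cubic spline on the
#'   first covariate in the imputation mean.
#' @param impute_terms which terms enter the imputation mean besides the
#'   intercept: any subset of `"X"`, `"spline"`, `"icar"` (all by
#'   default). An empty subset gives intercept-only imputation.
#' @param Z0_variance `"per_area"` (default) or `"pooled"` design-stage
#'   variance in the uncertainty model.
#' @param use_phi_outcome include an ICAR residual in the outcome model.
#' @return object of class `eps_health_result`: `beta_X` (posterior mean,
#'   sd, 2.5/50/97.5 percentiles), `beta_X_draws`, `summary`, `draws`,
#'   `Z_imputed` (posterior summaries for out-of-sample areas, EPS
#'   variants), `Zstar0` (in-sample uncertainty-model summaries),
#'   `convergence`, `variant`, `settings`.
#' @export
fit_outcome_model <- function(eco, domain,
                              variant = c("naive", "benchmark",
                                          "complete_case", "eps_mar",
                                          "eps_mnar"),
                              design_result = NULL,
                              f = c("quadratic", "linear", "poly"),
                              f_df = 3,
                              settings = mcmc_settings("fast"),
                              C_cols = "C",
                              aZ_mode = "estimated",
                              s_q_df = 4,
                              impute_terms = c("X", "spline", "icar"),
                              Z0_variance = c("per_area", "pooled"),
                              use_phi_outcome = FALSE) {
  variant <- match.arg(variant)
  f <- match.arg(f)
  Z0_variance <- match.arg(Z0_variance)
  eps_variant <- variant %in% c("complete_case", "eps_mar", "eps_mnar")
  if (eps_variant && is.null(design_result))
    stop("variant '", variant, "' needs a design-stage result")

  Cmat <- as.matrix(eco[, C_cols, drop = FALSE])
  Q <- ncol(Cmat)
  mon <- c("b0", "bX", "bC")
  dat <- list()
  parts <- character()

  ## ---- outcome linear predictor pieces
  fz_term <- switch(f,
    linear = "bZ1*Zc[i]",
    quadratic = "bZ1*Zc[i] + bZ2*Zc[i]*Zc[i]",
    poly = paste(sprintf("bZ%d*pow(Zc[i],%d)", seq_len(f_df), seq_len(f_df)),
                 collapse = " + "))
  nfz <- switch(f, linear = 1L, quadratic = 2L, poly = f_df)
  m_term <- ""

  if (variant == "benchmark") {
    Mt <- as.matrix(eco[, grep("^M[0-9]+$", names(eco)), drop = FALSE])
    if (ncol(Mt) == 0) stop("benchmark variant needs M columns in eco")
    dat$Mt <- Mt; dat$KM <- ncol(Mt)
    m_term <- " + inprod(Mt[i,], bM)"
    parts <- c(parts, "for (k in 1:KM) { bM[k] ~ dnorm(0, 0.1) }")
    mon <- c(mon, "bM")
  }

  if (!eps_variant) {
    keep <- seq_len(nrow(eco))
    fz <- ""
  } else {
    sidx <- design_result$in_sample_idx
    Z0hat <- unname(design_result$Z0_mean)
    Z0var <- if (Z0_variance == "pooled")
      rep(design_result$Z0_var_pooled, length(sidx)) else
      unname(design_result$Z0_var)
    Z0var <- pmax(Z0var, 1e-12)
    fz <- paste0(" + ", fz_term)
    parts <- c(parts,
      sprintf("for (q in 1:%d) { bZ[q] ~ dnorm(0, 0.1) }", nfz),
      paste(sprintf("bZ%d <- bZ[%d]", seq_len(nfz), seq_len(nfz)),
            collapse = "\n"))
    mon <- c(mon, "bZ")
    keep <- if (variant == "complete_case") sidx else seq_len(nrow(eco))
  }

  N <- length(keep)
  dat <- c(dat, list(Y = eco$Y[keep], logE = log(eco$E[keep]),
                     X = eco$X[keep], Cm = Cmat[keep, , drop = FALSE],
                     N = N, Q = Q))

  outcome <- sprintf("
 for (i in 1:N) {
   Y[i] ~ dpois(lam[i])
   log(lam[i]) <- logE[i] + b0 + bX*X[i] + inprod(Cm[i,], bC)%s%s + theta[i]%s
   theta[i] ~ dnorm(0, tau_th)
 }
 b0 ~ dnorm(0, 0.1)
 bX ~ dnorm(0, 0.1)
 for (q in 1:Q) { bC[q] ~ dnorm(0, 0.1) }
 tau_th ~ dgamma(2, 1)",
    m_term, fz, if (use_phi_outcome) " + phiO[i]" else "")
  parts <- c(outcome, parts)

  if (use_phi_outcome) {
    ed <- domain_edges(domain, keep)
    dat <- c(dat, list(eiO = ed$i, esO = ed$s, NEO = ed$n,
                       zeO = numeric(ed$n), zc0O = 0, zpO = 0,
                       rankO = ed$rank))
    parts <- c(parts, "
 for (e in 1:NEO) { zeO[e] ~ dnorm(phiO[eiO[e]] - phiO[esO[e]], tau_phO) }
 zc0O ~ dnorm(mean(phiO[1:N]), 1.0E6)
 zpO ~ dpois(-0.5*(rankO - NEO)*log(tau_phO) + 200)
 for (i in 1:N) { phiO[i] ~ dnorm(0, 1.0E-6) }
 tau_phO ~ dgamma(2, 1)")
  }

  full_coverage <- eps_variant && variant == "eps_mar" &&
    length(setdiff(keep, sidx)) == 0
  if (variant == "complete_case" || full_coverage) {
    ## uncertainty model only. For the complete case all modeled areas
    ## are in-sample; under full survey coverage there is nothing to
    ## impute and the imputation submodel shares no unknowns with the
    ## outcome likelihood (a disconnected factor), so it is dropped.
    dat <- c(dat, list(Z0hat = Z0hat, precZ0 = 1 / Z0var))
    parts <- c(parts, "
 for (i in 1:N) {
   Zc[i] ~ dnorm(Z0hat[i], precZ0[i])
 }")
    mon <- c(mon, "Zc")
  } else if (eps_variant) {
    midx <- setdiff(keep, sidx)
    spos <- match(sidx, keep)
    use_X <- "X" %in% impute_terms
    use_sp <- "spline" %in% impute_terms && s_q_df > 0
    use_icar <- "icar" %in% impute_terms
    ZimpDat <- rep(NA_real_, N)
    ZimpDat[spos] <- Z0hat          # pinned in-sample values (the cut)
    dat <- c(dat, list(Z0hat = Z0hat, precZ0 = 1 / Z0var,
                       Sn = length(sidx), spos = spos, Zimp = ZimpDat))
    muZ <- "g0"
    pri <- "g0 ~ dnorm(0, 0.1)"
    if (use_X) {
      muZ <- paste0(muZ, " + gX*X[i]")
      pri <- paste(pri, "gX ~ dnorm(0, 0.1)", sep = "\n ")
      mon <- c(mon, "gX")
    }
    if (use_sp) {
      ## natural cubic spline on the first covariate for s_q(C)
      SC <- splines::ns(Cmat[keep, 1], df = s_q_df)
      if (nrow(SC) < ncol(SC)) stop("fewer areas than spline basis df")
      if (Q > 1) SC <- cbind(SC, Cmat[keep, -1, drop = FALSE])
      dat$SC <- SC; dat$nSC <- ncol(SC)
      muZ <- paste0(muZ, " + inprod(SC[i,], gS)")
      pri <- paste(pri, "for (q in 1:nSC) { gS[q] ~ dnorm(0, 0.1) }",
                   sep = "\n ")
    }
    if (use_icar) {
      ed <- domain_edges(domain, keep)
      dat <- c(dat, list(ei = ed$i, es = ed$s, NE = ed$n,
                         ze = numeric(ed$n), zc0 = 0, zp = 0,
                         rankQl = ed$rank))
      muZ <- paste0(muZ, " + phi[i]")
      pri <- paste(pri, "
 for (e in 1:NE) { ze[e] ~ dnorm(phi[ei[e]] - phi[es[e]], tau_ph) }
 zc0 ~ dnorm(mean(phi[1:N]), 1.0E6)
 zp ~ dpois(-0.5*(rankQl - NE)*log(tau_ph) + 200)
 tau_ph ~ dgamma(2, 1)", sep = "\n ")
    }
    imput <- sprintf("
 for (t in 1:Sn) {
   Zstar[t] ~ dnorm(Z0hat[t], precZ0[t])
   Zc[spos[t]] <- Zstar[t]
 }
 for (i in 1:N) {
   Zimp[i] ~ dnorm(muZ[i], tauZ)
   muZ[i] <- %s
   %s
 }
 %s
 tauZ ~ dgamma(1, 0.1)",
      muZ,
      if (use_icar) "phi[i] ~ dnorm(0, 1.0E-6)" else "",
      pri)
    if (length(midx)) {
      dat$mpos <- match(midx, keep); dat$Mn <- length(midx)
      imput <- paste0(imput,
        "\n for (u in 1:Mn) { Zc[mpos[u]] <- Zimp[mpos[u]] }")
      mon <- c(mon, "Zimp")
    }
    parts <- c(parts, imput)
    mon <- c(mon, "Zstar", "g0")
  }

  if (variant == "eps_mnar") {
    dat$ell <- eco$ell[keep]
    aZ_fixed <- is.numeric(aZ_mode)
    sel <- "
 for (i in 1:N) {
   ell[i] ~ dbern(pi[i])
   logit(pi[i]) <- a0 + aX*X[i] + inprod(Cm[i,], aC) + aZ*Zc[i]
 }
 a0 ~ dnorm(0, 0.1)
 aX ~ dnorm(0, 0.1)
 for (q in 1:Q) { aC[q] ~ dnorm(0, 0.1) }"
    if (aZ_fixed) {
      dat$aZ <- as.numeric(aZ_mode)
      mon <- c(mon, "a0", "aX")
    } else {
      sel <- paste0(sel, "\n aZ ~ dnorm(0, 0.1)")
      mon <- c(mon, "a0", "aX", "aZ")
    }
    parts <- c(parts, sel)
  }

  model_string <- paste0("model{", paste(parts, collapse = "\n"), "\n}")

  ## regression-based starting values: the exposure and score coefficients
  ## sit on a narrow ridge (the exposure is nearly a function of the
  ## score), which generic samplers traverse very slowly from the origin;
  ## chains start at jittered plug-in estimates instead
  ini <- outcome_inits(dat, variant, eps_variant, f, nfz,
                       if (eps_variant) Z0hat else NULL,
                       if (eps_variant && variant != "complete_case" &&
                           !full_coverage)
                         list(spos = dat$spos, mpos = dat$mpos,
                              SC = dat$SC,
                              use_X = "X" %in% impute_terms,
                              use_sp = !is.null(dat$SC)) else NULL)
  inits <- NULL
  if (length(ini)) {
    set.seed(settings$seed + 97L)
    inits <- lapply(seq_len(settings$n_chains), function(ch)
      lapply(ini, function(v)
        if (is.numeric(v)) v + stats::rnorm(length(v), 0, 0.05) else v))
  }
  fit <- run_jags(model_string, dat, unique(mon), settings, inits = inits,
                  rhat_on = c("b0", "bX", "bC", "bZ", "bM", "g0", "gX",
                              "a0", "aX", "aZ"))

  bx <- as.matrix(fit$draws[, "bX", drop = TRUE])
  sm <- fit$summary
  Zimp_sum <- NULL; Zstar_sum <- NULL
  if (eps_variant && variant != "complete_case" && !full_coverage) {
    zs <- grep("^Zstar\\[", rownames(sm))
    Zstar_sum <- sm[zs, , drop = FALSE]
    rownames(Zstar_sum) <- domain$area_id[sidx]
    if (length(setdiff(keep, sidx))) {
      mp <- match(setdiff(keep, sidx), keep)
      zi <- paste0("Zimp[", mp, "]")
      Zimp_sum <- sm[intersect(zi, rownames(sm)), , drop = FALSE]
      rownames(Zimp_sum) <- domain$area_id[setdiff(keep, sidx)]
    }
  }
  structure(list(
    variant = variant, f = if (eps_variant) f else NA_character_,
    beta_X = sm["bX", ], beta_X_draws = drop(bx),
    summary = sm, draws = fit$draws,
    Z_imputed = Zimp_sum, Zstar0 = Zstar_sum,
    convergence = fit$convergence, settings = settings,
    model_string = model_string
  ), class = "eps_health_result")
}

#' @export
print.eps_health_result <- function(x, ...) {
  cat("Health-effect fit (", x$variant, "):\n", sep = "")
  cat(sprintf("  beta_X = %.3f (95%% CI %.3f to %.3f)\n",
              x$beta_X["mean"], x$beta_X["2.5%"], x$beta_X["97.5%"]))
  print(x$convergence)
  invisible(x)
}

## Plug-in starting values for the outcome (and imputation) coefficients.
## Outcome: Poisson GLM on the areas where the score is available (all
## areas for naive/benchmark, in-sample for EPS variants, score entered
## at its design-stage mean). Imputation: linear regression of the
## in-sample score means on its model terms; latent out-of-sample scores
## start at the fitted values.
outcome_inits <- function(dat, variant, eps_variant, f, nfz, Z0hat, imp) {
  out <- tryCatch({
    ini <- list()
    if (eps_variant) {
      rows <- if (variant == "complete_case") seq_len(dat$N) else dat$spos
      fb <- outer(Z0hat, seq_len(nfz), `^`)
      Xd <- cbind(1, dat$X[rows], dat$Cm[rows, , drop = FALSE], fb)
    } else {
      rows <- seq_len(dat$N)
      Xd <- cbind(1, dat$X, dat$Cm)
      if (variant == "benchmark") Xd <- cbind(Xd, dat$Mt)
    }
    gf <- suppressWarnings(stats::glm.fit(
      Xd, dat$Y[rows], family = stats::poisson(),
      offset = dat$logE[rows]))
    cf <- ifelse(is.na(gf$coefficients), 0, gf$coefficients)
    q <- ncol(dat$Cm)
    ini$b0 <- cf[1]; ini$bX <- cf[2]; ini$bC <- cf[3:(2 + q)]
    pos <- 2 + q
    if (variant == "benchmark") {
      ini$bM <- cf[(pos + 1):(pos + ncol(dat$Mt))]
    } else if (eps_variant) {
      ini$bZ <- cf[(pos + 1):(pos + nfz)]
    }
    if (!is.null(imp)) {
      W <- cbind(1, if (imp$use_X) dat$X,
                 if (imp$use_sp) imp$SC)
      lf <- stats::lm.fit(W[imp$spos, , drop = FALSE], Z0hat)
      lc <- ifelse(is.na(lf$coefficients), 0, lf$coefficients)
      ini$g0 <- lc[1]
      k <- 2
      if (imp$use_X) { ini$gX <- lc[k]; k <- k + 1 }
      if (imp$use_sp) ini$gS <- lc[k:length(lc)]
      if (!is.null(imp$mpos)) {
        zi <- rep(NA_real_, dat$N)
        zi[imp$mpos] <- drop(W[imp$mpos, , drop = FALSE] %*% lc)
        ini$Zimp <- zi
      }
    }
    ini
  }, error = function(e) list())
  out
}

## edge list (each unordered pair once) of the neighbor graph restricted
## to `keep`, with the Laplacian rank for the determinant correction
domain_edges <- function(domain, keep) {
  sub <- if (length(keep) == domain$n_areas) domain else
    restrict_domain(domain, keep)
  ei <- integer(0); es <- integer(0)
  for (i in seq_len(sub$n_areas)) {
    js <- sub$neighbors[[i]]
    js <- js[js > i]
    ei <- c(ei, rep(i, length(js))); es <- c(es, js)
  }
  list(i = ei, s = es, n = length(ei),
       rank = sub$n_areas - sub$n_components)
}

#' Posterior percent change in risk per exposure increment
#'
#' Transforms exposure-coefficient draws to the percent change in relative
#' risk for an increment `delta_x` of the exposure:
#' `100 (exp(beta_X * delta) - 1)` per draw. When the model was fitted on
#' a square-root exposure scale (`transform = "sqrt_scale"`), the
#' effective increment is `sqrt(x0 + delta_x) - sqrt(x0)` at a stated
#' baseline `x0`, so the change is reported on the original scale.
#'
#' @param result an `eps_health_result` (or any object with
#'   `beta_X_draws`).
#' @param delta_x exposure increment on the original scale.
#' @param transform `"identity"` or `"sqrt_scale"`.
#' @param baseline baseline exposure `x0` (required for `sqrt_scale`).
#' @return list with `mean`, `ci` (95%), `p_risk_gt_1` (posterior
#'   probability of a positive effect; at an exactly null posterior this
#'   is reported as 0.5 by convention), and the per-draw `draws`.
#' @export
percent_change <- function(result, delta_x = 1,
                           transform = c("identity", "sqrt_scale"),
                           baseline = NULL) {
  transform <- match.arg(transform)
  d <- if (transform == "identity") delta_x else {
    if (is.null(baseline)) stop("sqrt_scale transform requires a baseline")
    sqrt(baseline + delta_x) - sqrt(baseline)
  }
  draws <- 100 * (exp(result$beta_X_draws * d) - 1)
  p <- mean(draws > 0)
  if (all(draws == 0)) p <- 0.5
  list(mean = mean(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))),
       p_risk_gt_1 = p, draws = draws)
}
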