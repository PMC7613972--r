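#' Fit the design stage: confounder up-scaling and generalized EPS
#'
#' Jointly fits, over the in-sample areas (those with individual-level
#' survey records), the multivariate spatial up-scaling model and the
#' Gaussian conditional exposure model that defines the generalized
#' ecological propensity score (EPS):
#'
#' * per-variable likelihoods `m_ijk ~ N(M_ik, sigma_k^2)` (continuous)
#'   or `m_ijk ~ Bernoulli(M_ik)` (binary, logit link), with
#'   `g_k(M_ik) = nu_k + xi_ik`;
#' * a multivariate intrinsic CAR (MICAR) prior on the S x K spatial
#'   effects `xi`, cross-variable precision `Omega = Sigma_xi^{-1}` with a
#'   `Wishart(v, B)` prior (`v > K - 1`; `B` defaults to the inverse of the
#'   empirical correlation matrix of the pooled records, ridge-regularized
#'   if near-singular), flat intercepts `nu_k`;
#' * the exposure model
#'   `X_i ~ N(delta_0 + C_i' delta_C + M_i' delta_M, sigma_X^2)` with
#'   `N(0, 100)` coefficient priors and `Gamma(1, 0.1)` precision prior;
#'   the generalized EPS is `Z_i^(0) = M_i' delta_M`.
#'
#' Inference is by a model-specific blocked Gibbs/Metropolis sampler:
#' spatial effects are updated single-site with exact MICAR full
#' conditionals (conjugate for continuous variables, adaptive random-walk
#' Metropolis for binary), vectorized over conditionally independent color
#' classes of the neighbor graph; `Omega` has an exact conjugate Wishart
#' update using the rank of the graph Laplacian; regression coefficients
#' and variances are conjugate. Impropriety of the MICAR prior is resolved
#' by re-centering `xi` each sweep with a compensating shift of `nu`
#' (an exact move along the prior's null direction).
#'
#' @param indiv individual dataset ([generate_individual()] schema:
#'   columns `area`, `m1..mK`, attribute `types` giving `"gaussian"` or
#'   `"bernoulli"` per variable).
#' @param eco ecological dataset with columns `X` and the covariates in
#'   `C_cols`.
#' @param domain the full `eps_domain`; the fit restricts it to in-sample
#'   areas.
#' @param settings an [mcmc_settings()].
#' @param v Wishart degrees of freedom (default K + 1; must exceed K - 1).
#' @param B Wishart scale matrix (default inverse empirical correlation of
#'   pooled records).
#' @param C_cols names of measured-covariate columns in `eco`.
#' @return object of class `eps_design_result` with `Z0_mean`, `Z0_var`
#'   (per-area posterior moments of the EPS), `Z0_var_pooled`, `M_mean`,
#'   `M_sd`, `delta` (posterior summary), `draws` (mcmc.list of scalar
#'   parameters and per-area EPS), `Z0_draws` (matrix, retained draws x
#'   areas, chains stacked), `in_sample_idx`, `subdomain`, `convergence`,
#'   `settings`.
#' @export
fit_design_stage <- function(indiv, eco, domain,
                             settings = mcmc_settings("fast"),
                             v = NULL, B = NULL, C_cols = "C") {
  types <- attr(indiv, "types")
  mcols <- grep("^m[0-9]+$", names(indiv), value = TRUE)
  K <- length(mcols)
  if (is.null(types)) types <- ifelse(vapply(indiv[mcols], function(x)
    all(x %in% c(0, 1)), logical(1)), "bernoulli", "gaussian")
  if (K < 1) stop("no individual-level variables found")
  v <- v %||% (K + 1)
  if (v <= K - 1) stop("Wishart degrees of freedom must exceed K - 1")

  sidx <- sort(unique(indiv$area))
  if (length(sidx) < 2) stop("need at least two in-sample areas")
  if (!all(sidx %in% seq_len(domain$n_areas)))
    stop("individual records reference unknown areas")
  sub <- if (length(sidx) == domain$n_areas) domain else
    restrict_domain(domain, sidx)
  S <- sub$n_areas
  area <- match(indiv$area, sidx)
  X <- eco$X[sidx]
  Cmat <- as.matrix(eco[sidx, C_cols, drop = FALSE])
  if (anyNA(X) || anyNA(Cmat))
    stop("exposure and measured covariates must be observed in-sample")
  m <- as.matrix(indiv[mcols])

  ## empirical correlation -> default Wishart scale B = R_emp^{-1}
  Remp <- stats::cor(m, use = "pairwise.complete.obs")
  ev <- eigen(Remp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) Remp <- Remp + diag(1e-6, K)
  if (is.null(B)) B <- solve(Remp)
  Binv <- solve(B)

  ## sufficient statistics and graph structures
  J <- tabulate(area, nbins = S)
  if (any(J == 0)) stop("every in-sample area needs at least one record")
  summ <- rowsum(m, area)                     # S x K sums
  gk <- which(types == "gaussian"); bk <- which(types == "bernoulli")
  A <- adjacency_sparse(sub)
  nnb <- sub$n_neighbors
  rankQ <- S - sub$n_components
  colors <- color_graph(sub$neighbors)
  color_sets <- split(seq_len(S), colors)
  ## flattened neighbor indices per color class for fast neighbor means
  color_nbrs <- lapply(color_sets, function(I)
    unlist(sub$neighbors[I], use.names = FALSE))
  color_grp <- lapply(color_sets, function(I)
    rep(seq_along(I), nnb[I]))

  n_keep <- settings$n_retained
  seeds <- chain_seeds(settings)
  chains <- lapply(seq_len(settings$n_chains), function(ch) {
    set.seed(seeds[ch])
    gibbs_design_chain(m, area, X, Cmat, types, J, summ, A, nnb, rankQ,
                       color_sets, color_nbrs, color_grp, Binv, v,
                       settings)
  })

  ## assemble draws; the EPS is identified only up to affine
  ## transformations (level trades off against nu/delta0, scale against
  ## the score coefficient downstream, both absorbed by the outcome and
  ## imputation models), so each draw is affinely standardized to the
  ## posterior-mean level and cross-area scale: only the identified
  ## per-area component remains in the reported uncertainty
  scalars <- lapply(chains, function(chn) coda::mcmc(chn$scalars))
  Z0d <- lapply(chains, function(chn) chn$Z0)
  lev_grand <- mean(unlist(lapply(Z0d, rowMeans)))
  sd_grand <- mean(unlist(lapply(Z0d, function(z) apply(z, 1, stats::sd))))
  Z0d <- lapply(Z0d, function(z) {
    lev <- rowMeans(z)
    sdr <- apply(z, 1, stats::sd)
    (z - lev) * (sd_grand / sdr) + lev_grand
  })
  Z0all <- do.call(rbind, Z0d)
  Z0_mean <- colMeans(Z0all)
  Z0_var <- apply(Z0all, 2, stats::var)
  names(Z0_mean) <- names(Z0_var) <- domain$area_id[sidx]
  Mmean <- Reduce(`+`, lapply(chains, `[[`, "M_mean")) / length(chains)
  Msd <- sqrt(pmax(0, Reduce(`+`, lapply(chains, `[[`, "M_sq")) /
                     length(chains) - Mmean^2))
  ## diagnostics over scalar parameters plus per-area EPS
  dl <- coda::mcmc.list(lapply(seq_along(chains), function(ch)
    coda::mcmc(cbind(chains[[ch]]$scalars,
                     `colnames<-`(Z0d[[ch]], paste0("Z0[", seq_len(S), "]"))))))
  conv <- convergence_report(dl)
  delta_cols <- grep("^delta", colnames(chains[[1]]$scalars), value = TRUE)
  sm <- summarize_draws(dl)
  structure(list(
    Z0_mean = Z0_mean, Z0_var = Z0_var,
    Z0_var_pooled = mean(Z0_var),
    M_mean = Mmean, M_sd = Msd,
    delta = sm[delta_cols, , drop = FALSE],
    summary = sm, draws = dl, Z0_draws = Z0all,
    xi_colsum_draws = do.call(rbind, lapply(chains, `[[`, "xi_colsums")),
    in_sample_idx = sidx, subdomain = sub,
    convergence = conv, settings = settings,
    types = types, v = v, B = B
  ), class = "eps_design_result")
}

#' @export
print.eps_design_result <- function(x, ...) {
  cat("Design-stage fit:", length(x$Z0_mean), "in-sample areas,",
      length(x$types), "up-scaled variables\n")
  print(x$convergence)
  cat("EPS posterior mean range:",
      signif(range(x$Z0_mean), 3), "\n")
  invisible(x)
}

## sparse adjacency of an eps_domain
adjacency_sparse <- function(domain) {
  i <- rep(seq_len(domain$n_areas), domain$n_neighbors)
  j <- unlist(domain$neighbors)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(domain$n_areas, domain$n_areas))
}

## greedy graph coloring: same-color areas are never neighbors
color_graph <- function(nbr) {
  n <- length(nbr)
  col <- integer(n)
  for (i in order(-lengths(nbr))) {
    used <- col[nbr[[i]]]
    col[i] <- min(setdiff(seq_len(n), used))
  }
  col
}

#' MICAR single-site full-conditional moments
#'
#' For spatial effects `xi` (S x K) under the intrinsic multivariate CAR
#' prior with cross-variable precision `Omega`, returns the conditional
#' prior mean and variance of `xi[i, k]` given all other effects:
#' the joint conditional of row i is `N(mean of neighbor rows,
#' (n_i Omega)^{-1})`, and the scalar conditional follows by Gaussian
#' conditioning within the row. Exposed for verification against the
#' joint-precision form `Q %x% Omega` on small instances.
#'
#' @param i area index; @param k variable index.
#' @param xi current effect matrix; @param Omega K x K precision;
#' @param neighbors neighbor index list.
#' @return list with `mean` and `var`.
#' @export
micar_conditional <- function(i, k, xi, Omega, neighbors) {
  nb <- neighbors[[i]]
  xibar <- colMeans(xi[nb, , drop = FALSE])
  mu <- xibar[k] - sum(Omega[k, -k] * (xi[i, -k] - xibar[-k])) / Omega[k, k]
  list(mean = mu, var = 1 / (length(nb) * Omega[k, k]))
}

## One chain of the design-stage Gibbs sampler. Returns scalar draws,
## per-area EPS draws, and accumulated M posterior moments.
gibbs_design_chain <- function(m, area, X, Cmat, types, J, summ, A, nnb,
                               rankQ, color_sets, color_nbrs, color_grp,
                               Binv, v, settings) {
  S <- length(X); K <- ncol(m); Q <- ncol(Cmat)
  gk <- which(types == "gaussian"); bk <- which(types == "bernoulli")
  n_iter <- settings$n_iter; n_burn <- settings$n_burnin
  thin <- settings$thin; n_keep <- settings$n_retained

  ## initial values from per-area summaries
  Mbar <- summ / J
  nu <- numeric(K)
  nu[gk] <- colMeans(Mbar[, gk, drop = FALSE])
  nu[bk] <- stats::qlogis(pmin(pmax(colMeans(Mbar[, bk, drop = FALSE]),
                                    0.02), 0.98))
  xi <- matrix(0, S, K)
  Mcur <- matrix(0, S, K)
  Mcur[, gk] <- rep(nu[gk], each = S)
  Mcur[, bk] <- rep(stats::plogis(nu[bk]), each = S)
  W0 <- cbind(1, Cmat, Mbar)
  delta <- drop(stats::coef(stats::lm.fit(W0, X)))
  delta[is.na(delta)] <- 0
  sigX2 <- max(1e-4, mean(stats::lm.fit(W0, X)$residuals^2))
  sig2 <- rep(1, K)  # only gaussian entries used
  Omega <- v * solve(Binv)   # prior mean of Wishart(v, B)
  step <- matrix(0.3, S, K)  # RW scales for binary xi sites
  step_nu <- rep(0.1, K)
  acc <- matrix(0, S, K); acc_nu <- numeric(K); batch <- 0L

  scal_names <- c("delta0",
                  paste0("deltaC", seq_len(Q)),
                  paste0("deltaM", seq_len(K)),
                  paste0("nu", seq_len(K)), "sigX2",
                  paste0("sig2_", gk))
  scalars <- matrix(NA_real_, n_keep, length(scal_names),
                    dimnames = list(NULL, scal_names))
  Z0_draws <- matrix(NA_real_, n_keep, S)
  xi_colsums <- matrix(NA_real_, n_keep, K)
  M_mean <- matrix(0, S, K); M_sq <- matrix(0, S, K)
  kept <- 0L

  for (it in seq_len(n_iter)) {
    d0 <- delta[1]
    dC <- delta[2:(1 + Q)]
    dM <- delta[(2 + Q):(1 + Q + K)]
    Xb <- X - d0 - drop(Cmat %*% dC)   # exposure minus measured part

    ## --- xi updates, color class by color class (same-color areas are
    ## never neighbors, so the neighbor means NB of a class are fixed
    ## while its own sites update and can be computed once for all K)
    for (ci in seq_along(color_sets)) {
      I <- color_sets[[ci]]
      NB <- rowsum(xi[color_nbrs[[ci]], , drop = FALSE],
                   color_grp[[ci]], reorder = FALSE) / nnb[I]
      XiNB <- xi[I, , drop = FALSE] - NB
      MdM <- drop(Mcur[I, , drop = FALSE] %*% dM)   # running M'deltaM
      for (k in seq_len(K)) {
        a <- dM[k]
        prec0 <- nnb[I] * Omega[k, k]
        mu0 <- NB[, k] -
          (drop(XiNB %*% Omega[, k]) - XiNB[, k] * Omega[k, k]) /
          Omega[k, k]
        rX <- Xb[I] - (MdM - a * Mcur[I, k])
        Mold <- Mcur[I, k]
        if (k %in% gk) {
          P <- prec0 + J[I] / sig2[k] + a^2 / sigX2
          mn <- (prec0 * mu0 + (summ[I, k] - J[I] * nu[k]) / sig2[k] +
                 a * (rX - a * nu[k]) / sigX2) / P
          xi[I, k] <- stats::rnorm(length(I), mn, sqrt(1 / P))
          Mcur[I, k] <- nu[k] + xi[I, k]
        } else {
          x0 <- xi[I, k]
          xp <- x0 + step[I, k] * stats::rnorm(length(I))
          p0 <- stats::plogis(nu[k] + x0); pp <- stats::plogis(nu[k] + xp)
          s <- summ[I, k]
          ll0 <- s * log(p0) + (J[I] - s) * log1p(-p0) -
            (rX - a * p0)^2 / (2 * sigX2) - 0.5 * prec0 * (x0 - mu0)^2
          llp <- s * log(pp) + (J[I] - s) * log1p(-pp) -
            (rX - a * pp)^2 / (2 * sigX2) - 0.5 * prec0 * (xp - mu0)^2
          ok <- log(stats::runif(length(I))) < llp - ll0
          xi[I, k] <- ifelse(ok, xp, x0)
          Mcur[I, k] <- stats::plogis(nu[k] + xi[I, k])
          if (it <= n_burn) acc[I, k] <- acc[I, k] + ok
        }
        XiNB[, k] <- xi[I, k] - NB[, k]
        MdM <- MdM + a * (Mcur[I, k] - Mold)
      }
    }

    ## --- recenter xi (flat direction), compensate nu
    mns <- colMeans(xi)
    xi <- sweep(xi, 2, mns)
    nu <- nu + mns

    ## --- nu updates
    for (k in gk) {
      a <- dM[k]
      rX2 <- Xb - drop(Mcur[, -k, drop = FALSE] %*% dM[-k]) - a * xi[, k]
      P <- sum(J) / sig2[k] + S * a^2 / sigX2
      mn <- (sum(summ[, k] - J * xi[, k]) / sig2[k] + a * sum(rX2) / sigX2) / P
      nu[k] <- stats::rnorm(1, mn, sqrt(1 / P))
      Mcur[, k] <- nu[k] + xi[, k]
    }
    for (k in bk) {
      a <- dM[k]
      rX <- Xb - drop(Mcur[, -k, drop = FALSE] %*% dM[-k])
      lp_nu <- function(nuk) {
        p <- stats::plogis(nuk + xi[, k])
        sum(summ[, k] * log(p) + (J - summ[, k]) * log1p(-p)) -
          sum((rX - a * p)^2) / (2 * sigX2)
      }
      prop <- nu[k] + step_nu[k] * stats::rnorm(1)
      if (log(stats::runif(1)) < lp_nu(prop) - lp_nu(nu[k])) {
        nu[k] <- prop
        if (it <= n_burn) acc_nu[k] <- acc_nu[k] + 1
      }
      Mcur[, k] <- stats::plogis(nu[k] + xi[, k])
    }

    ## --- exposure model: conjugate regression + variance
    W <- cbind(1, Cmat, Mcur)
    Pp <- crossprod(W) / sigX2 + diag(1 / 100, ncol(W))
    ch <- chol(Pp)
    mn <- backsolve(ch, backsolve(ch, crossprod(W, X) / sigX2,
                                  transpose = TRUE))
    delta <- drop(mn + backsolve(ch, stats::rnorm(ncol(W))))
    res <- X - drop(W %*% delta)
    sigX2 <- 1 / stats::rgamma(1, 1 + S / 2, 0.1 + sum(res^2) / 2)

    ## --- measurement variances for continuous variables
    for (k in gk) {
      r <- m[, k] - nu[k] - xi[area, k]
      sig2[k] <- 1 / stats::rgamma(1, 1 + length(r) / 2,
                                   0.1 + sum(r^2) / 2)
    }

    ## --- Omega: exact conjugate Wishart (rank of Laplacian, not edges)
    SSxi <- crossprod(xi, as.matrix(A %*% xi))
    SSxi <- diag(colSums(xi^2 * nnb), K) - (SSxi + t(SSxi)) / 2
    Wscal <- solve(Binv + SSxi)
    Wscal <- (Wscal + t(Wscal)) / 2
    ev <- min(eigen(Wscal, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) Wscal <- Wscal + diag(1e-8 - min(0, ev), K)
    Omega <- drop(stats::rWishart(1, v + rankQ, Wscal))

    ## --- adapt RW steps in burn-in
    if (it <= n_burn && it %% 50 == 0) {
      batch <- batch + 1L
      rate <- acc / 50; rate_nu <- acc_nu / 50
      step <- step * exp(0.3 * (rate - 0.44))
      step_nu <- step_nu * exp(0.3 * (rate_nu - 0.44))
      acc[] <- 0; acc_nu[] <- 0
    }

    ## --- record
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      kept <- kept + 1L
      dM <- delta[(2 + Q):(1 + Q + K)]
      Z0 <- drop(Mcur %*% dM)
      scalars[kept, ] <- c(delta, nu, sigX2, sig2[gk])
      Z0_draws[kept, ] <- Z0
      xi_colsums[kept, ] <- colSums(xi)
      M_mean <- M_mean + Mcur; M_sq <- M_sq + Mcur^2
    }
  }
  list(scalars = scalars[seq_len(kept), , drop = FALSE],
       Z0 = Z0_draws[seq_len(kept), , drop = FALSE],
       xi_colsums = xi_colsums[seq_len(kept), , drop = FALSE],
       M_mean = M_mean / kept, M_sq = M_sq / kept)
}

#' Balancing check for a fitted generalized EPS
#'
#' The EPS is constructed so that, conditional on the measured covariates
#' and the score, exposure carries no residual association with the
#' latent confounders. On simulated data (where the true `M` are known)
#' this is checkable: for each confounder the partial correlation of
#' exposure and `M_k` given `C` alone should attenuate toward zero once
#' the posterior-mean EPS is added to the conditioning set.
#'
#' @param result an `eps_design_result`.
#' @param eco the generating ecological dataset (columns `X`, `C`,
#'   `M1..MK`).
#' @param C_cols measured-covariate columns.
#' @return data.frame with one row per confounder: partial correlation
#'   given C, given C and the EPS, and an `attenuated` flag.
#' @export
balancing_check <- function(result, eco, C_cols = "C") {
  sidx <- result$in_sample_idx
  if (length(sidx) < 10) stop("balance report unreliable below 10 areas")
  X <- eco$X[sidx]
  Cm <- as.matrix(eco[sidx, C_cols, drop = FALSE])
  Mk <- as.matrix(eco[sidx, grep("^M[0-9]+$", names(eco)), drop = FALSE])
  Z0 <- result$Z0_mean
  pc <- function(xx, yy, ctrl) {
    rx <- stats::lm.fit(cbind(1, ctrl), xx)$residuals
    ry <- stats::lm.fit(cbind(1, ctrl), yy)$residuals
    suppressWarnings(stats::cor(rx, ry))
  }
  out <- data.frame(
    confounder = colnames(Mk),
    pcor_given_C = apply(Mk, 2, pc, xx = X, ctrl = Cm),
    pcor_given_C_Z0 = apply(Mk, 2, pc, xx = X, ctrl = cbind(Cm, Z0)))
  out$attenuated <- abs(out$pcor_given_C_Z0) < abs(out$pcor_given_C)
  rownames(out) <- NULL
  out
}
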