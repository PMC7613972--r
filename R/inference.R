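#' MCMC settings
#'
#' Chain-management contract shared by both model stages. The `"fast"`
#' profile (2 chains of 3,000 iterations, 1,500 burn-in, no thinning) is
#' intended for tests and desk-scale replication runs; the `"paper"`
#' profile (2 chains of 100,000 iterations, 80,000 burn-in, thinning 10)
#' matches the long-run configuration used for case-study-scale inference.
#'
#' @param profile `"fast"` or `"paper"`; presets overridden by any
#'   explicitly supplied argument.
#' @param n_chains number of independent chains.
#' @param n_iter total iterations per chain (including burn-in).
#' @param n_burnin discarded prefix per chain.
#' @param thin retention stride; retained draws per chain are
#'   `(n_iter - n_burnin) / thin`.
#' @param seed integer seed; all chain RNG seeds derive from it.
#' @return list of class `eps_mcmc_settings`.
#' @export
mcmc_settings <- function(profile = c("fast", "paper"),
                          n_chains = 2, n_iter = NULL, n_burnin = NULL,
                          thin = NULL, seed = 1) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    fast = list(n_iter = 3000, n_burnin = 1500, thin = 1),
    paper = list(n_iter = 100000, n_burnin = 80000, thin = 10))
  n_iter <- n_iter %||% preset$n_iter
  n_burnin <- n_burnin %||% preset$n_burnin
  thin <- thin %||% preset$thin
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(profile = profile, n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, thin = thin, seed = as.integer(seed),
                 n_retained = floor((n_iter - n_burnin) / thin)),
            class = "eps_mcmc_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-chain RNG seeds derived from the master seed (kept < 2^31)
chain_seeds <- function(settings) {
  (settings$seed * 1000L + 7L * seq_len(settings$n_chains)) %% 2147483647L
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic two-estimator form: with m chains of n retained draws,
#' within-chain variance W, between-chain variance B (n times the variance
#' of chain means), the pooled posterior-variance estimate is
#' `(n-1)/n W + B/n` and the statistic is `sqrt` of its ratio to W.
#'
#' @param x matrix with one column per chain (rows are draws), or an
#'   `mcmc.list` for a single parameter.
#' @return the psrf (>= 1 up to estimator noise).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "mcmc.list")) x <- sapply(x, as.numeric)
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2) return(NA_real_)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

#' Convergence report for a set of monitored parameters
#'
#' @param draws an `mcmc.list` (coda).
#' @param threshold convergence declared when all psrf fall below it
#'   (default 1.1).
#' @return list of class `eps_convergence`: `rhat` and `ess` named
#'   vectors, `converged`, `threshold`, `monitored`.
#' @export
convergence_report <- function(draws, threshold = 1.1) {
  vn <- coda::varnames(draws)
  rhat <- vapply(vn, function(p)
    gelman_rubin(sapply(draws[, p, drop = TRUE], as.numeric)), numeric(1))
  ess <- coda::effectiveSize(draws)
  structure(list(rhat = rhat, ess = ess[vn],
                 converged = all(rhat < threshold, na.rm = TRUE),
                 threshold = threshold, monitored = vn),
            class = "eps_convergence")
}

#' @export
print.eps_convergence <- function(x, ...) {
  cat("MCMC convergence:", if (x$converged) "OK" else "NOT converged",
      sprintf("(max rhat %.3f, threshold %.2f, %d parameters)\n",
              max(x$rhat, na.rm = TRUE), x$threshold, length(x$monitored)))
  invisible(x)
}

#' Run a JAGS model under the package's settings contract
#'
#' Thin wrapper around `rjags`: compiles the model with per-chain
#' Mersenne-Twister seeds derived from `settings$seed`, spends
#' `n_burnin` iterations on adaptation plus burn-in, retains
#' `(n_iter - n_burnin)/thin` draws per chain, and attaches a
#' [convergence_report()]. The `glm` module is loaded for efficient
#' block samplers on the Poisson regression layers. Convergence failure
#' is reported, never raised.
#'
#' @param model_string JAGS model code.
#' @param data named list of data.
#' @param monitors character vector of nodes to record.
#' @param settings an [mcmc_settings()].
#' @param inits optional initial values: a single named list applied to
#'   every chain, or a list with one named list per chain.
#' @param rhat_on monitors to include in the convergence report (defaults
#'   to all scalar monitors).
#' @return list of class `eps_fit`: `draws` (mcmc.list), `summary`
#'   (matrix: mean, sd, 2.5%, 50%, 97.5% per parameter), `convergence`,
#'   `settings`.
#' @export
run_jags <- function(model_string, data, monitors, settings,
                     inits = NULL, rhat_on = NULL) {
  if (!"glm" %in% rjags::list.modules()) rjags::load.module("glm", quiet = TRUE)
  seeds <- chain_seeds(settings)
  per_chain <- !is.null(inits) && is.null(names(inits))
  ilist <- lapply(seq_along(seeds), function(ch)
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seeds[ch]),
      if (per_chain) inits[[ch]] else inits))
  n_adapt <- min(1000L, max(100L, settings$n_burnin %/% 2L))
  jm <- suppressWarnings(rjags::jags.model(
    textConnection(model_string), data = data,
    n.chains = settings$n_chains, n.adapt = n_adapt,
    inits = ilist, quiet = TRUE))
  extra_burn <- settings$n_burnin - n_adapt
  if (extra_burn > 0) stats::update(jm, extra_burn)
  draws <- rjags::coda.samples(jm, monitors,
                               n.iter = settings$n_iter - settings$n_burnin,
                               thin = settings$thin)
  fit_from_draws(draws, settings, rhat_on)
}

## assemble the common fit object from an mcmc.list
fit_from_draws <- function(draws, settings, rhat_on = NULL) {
  sm <- summarize_draws(draws)
  sub <- draws
  if (!is.null(rhat_on)) {
    keep <- coda::varnames(draws)[
      sub("\\[.*", "", coda::varnames(draws)) %in% rhat_on]
    sub <- draws[, keep, drop = FALSE]
  }
  conv <- convergence_report(sub)
  structure(list(draws = draws, summary = sm, convergence = conv,
                 settings = settings), class = "eps_fit")
}

summarize_draws <- function(draws) {
  X <- as.matrix(draws)
  t(apply(X, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, c(0.025, 0.5, 0.975)))))
}

#' @export
print.eps_fit <- function(x, ...) {
  cat("Posterior fit:", nrow(x$summary), "monitored parameters,",
      x$settings$n_chains, "chains x", x$settings$n_retained,
      "retained draws\n")
  print(x$convergence)
  invisible(x)
}
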