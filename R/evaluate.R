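#' Run a replication study
#'
#' The full simulation pipeline, replicated: for replicate r, generate a
#' dataset on `domain` under `config` with an independent seed, fit the
#' design stage if any requested variant needs the generalized EPS, fit
#' every requested outcome-model variant, and record the posterior mean
#' and 95% credible interval of the exposure coefficient together with
#' convergence bookkeeping.
#'
#' @param domain an `eps_domain` shared by all replicates.
#' @param config an [sim_config()].
#' @param variants character vector from `"naive"`, `"benchmark"`,
#'   `"complete_case"`, `"eps_mar"`, `"eps_mnar"`.
#' @param settings [mcmc_settings()] for the outcome models.
#' @param design_settings [mcmc_settings()] for the design stage
#'   (defaults to `settings`).
#' @param n_replicates number of replicates (>= 1).
#' @param f score functional form passed to the EPS variants.
#' @param aZ_mode selection-model coefficient mode for `"eps_mnar"`.
#' @param seed master seed; replicate r uses dataset seed
#'   `(seed * 1000 + r) mod (2^31 - 1)`.
#' @return object of class `eps_replication`: per-variant data frames
#'   (`replicate`, `est`, `lo`, `hi`, `converged`), pooled exposure-
#'   coefficient draws per variant, and the config echo.
#' @export
run_replications <- function(domain, config, variants,
                             settings = mcmc_settings("fast"),
                             design_settings = settings,
                             n_replicates = 10,
                             f = "quadratic", aZ_mode = "estimated",
                             seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  bad <- setdiff(variants, c("naive", "benchmark", "complete_case",
                             "eps_mar", "eps_mnar"))
  if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "))
  needs_eps <- any(variants %in% c("complete_case", "eps_mar", "eps_mnar"))
  rows <- stats::setNames(
    replicate(length(variants), list(), simplify = FALSE), variants)
  pooled <- stats::setNames(
    replicate(length(variants), list(), simplify = FALSE), variants)
  skipped <- character(0)

  for (r in seq_len(n_replicates)) {
    dseed <- (seed * 1000 + r) %% 2147483647
    dat <- generate_dataset(domain, config, seed = dseed)
    des <- NULL
    if (needs_eps) {
      ds <- design_settings; ds$seed <- as.integer((dseed + 31) %% 2147483647)
      des <- fit_design_stage(dat$indiv, dat$eco, domain, settings = ds)
    }
    for (vv in variants) {
      if (vv == "benchmark" && !any(grepl("^M[0-9]+$", names(dat$eco)))) {
        skipped <- c(skipped, paste0("benchmark:r", r)); next
      }
      st <- settings; st$seed <- as.integer((dseed + 67) %% 2147483647)
      fit <- fit_outcome_model(dat$eco, domain, variant = vv,
                               design_result = des, f = f,
                               settings = st, aZ_mode = aZ_mode)
      rows[[vv]][[r]] <- data.frame(
        replicate = r,
        est = unname(fit$beta_X["mean"]),
        lo = unname(fit$beta_X["2.5%"]),
        hi = unname(fit$beta_X["97.5%"]),
        converged = fit$convergence$converged)
      pooled[[vv]][[r]] <- fit$beta_X_draws
    }
  }
  structure(list(
    results = lapply(rows, function(l) do.call(rbind, l)),
    pooled_draws = lapply(pooled, function(l) unlist(l)),
    variants = variants, config = config, seed = seed,
    n_replicates = n_replicates, skipped = skipped
  ), class = "eps_replication")
}

#' Performance metrics against the generating target
#'
#' Computes, for one variant of a replication run: the average posterior
#' mean; the mean bias (MB) and root mean squared error (RMSE) of the
#' per-replicate posterior means against the target; the coverage of the
#' nominal 95% credible intervals (percent of replicates whose interval
#' contains the target); and the mean interval width. When pooled draws
#' are available the per-draw MB/RMSE (pooling every retained MCMC draw
#' across replicates against the target) are reported alongside.
#'
#' Replicates flagged as non-converged are excluded and counted.
#'
#' @param rep_result an `eps_replication`, or a data frame with columns
#'   `est`, `lo`, `hi` (and optionally `converged`).
#' @param variant variant name (when `rep_result` is an
#'   `eps_replication`).
#' @param target generating exposure coefficient (default 0.20).
#' @param pooled_draws optional numeric vector of pooled posterior draws.
#' @return data frame of class `eps_metrics` with columns
#'   `posterior_mean`, `MB`, `RMSE`, `coverage` (percent), `ci_width`,
#'   `target`, `n_replicates`, `n_excluded`, and (if draws supplied)
#'   `MB_pooled`, `RMSE_pooled`.
#' @export
compute_metrics <- function(rep_result, variant = NULL, target = 0.20,
                            pooled_draws = NULL) {
  if (inherits(rep_result, "eps_replication")) {
    stopifnot(!is.null(variant))
    df <- rep_result$results[[variant]]
    pooled_draws <- pooled_draws %||% rep_result$pooled_draws[[variant]]
  } else df <- rep_result
  if (is.null(df) || nrow(df) == 0) stop("no replicates to summarize")
  n0 <- nrow(df)
  if (!is.null(df$converged)) df <- df[df$converged, , drop = FALSE]
  if (nrow(df) == 0) stop("all replicates excluded for non-convergence")
  est <- df$est
  out <- data.frame(
    posterior_mean = mean(est),
    MB = mean(est) - target,
    RMSE = sqrt(mean((est - target)^2)),
    coverage = 100 * mean(df$lo <= target & target <= df$hi),
    ci_width = mean(df$hi - df$lo),
    target = target,
    n_replicates = nrow(df),
    n_excluded = n0 - nrow(df))
  if (!is.null(pooled_draws)) {
    out$MB_pooled <- mean(pooled_draws) - target
    out$RMSE_pooled <- sqrt(mean((pooled_draws - target)^2))
  }
  class(out) <- c("eps_metrics", "data.frame")
  out
}

#' Metrics table across variants
#'
#' Applies [compute_metrics()] to every variant of a replication run and
#' binds the rows, mirroring the layout of a simulation-study results
#' table (variant, averaged posterior mean, MB, RMSE, coverage, width).
#'
#' @inheritParams compute_metrics
#' @export
metrics_table <- function(rep_result, target = 0.20) {
  do.call(rbind, lapply(rep_result$variants, function(vv) {
    m <- compute_metrics(rep_result, vv, target)
    cbind(variant = vv, m)
  }))
}
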