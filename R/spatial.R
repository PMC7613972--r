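#' Build an areal spatial domain
#'
#' Constructs the geography used throughout the package: areal-unit
#' centroids, the symmetric matrix of pairwise centroid distances, and a
#' distance-based neighborhood structure in which every area is guaranteed
#' at least one neighbor.
#'
#' Two modes are available. `"lattice"` places areas on a regular
#' `nx` by `ny` grid with the given spacing (in km); this is the default
#' stand-in geography for simulation studies (a 25 x 25 lattice at 1.5 km
#' spacing spans centroid distances of about 1.5--51 km, comparable to a
#' dense urban ward system). `"centroid_table"` takes a data frame with
#' columns `area_id`, `x`, `y` (km), e.g. read from a delimited file, so a
#' real geography can be supplied.
#'
#' Neighbors are all areas within a distance cutoff. By default the cutoff
#' is the smallest radius under which every area has at least
#' `min_neighbors` neighbors; areas left isolated under a user-supplied
#' cutoff are connected to their nearest area, and the relation is always
#' symmetrized.
#'
#' @param mode `"lattice"` or `"centroid_table"`.
#' @param nx,ny lattice dimensions (lattice mode).
#' @param spacing lattice spacing in km (lattice mode).
#' @param centroids data frame with columns `area_id`, `x`, `y`
#'   (centroid_table mode).
#' @param cutoff optional neighborhood distance cutoff (km). `NULL` selects
#'   the smallest radius giving every area at least `min_neighbors`
#'   neighbors.
#' @param min_neighbors minimum neighbor count targeted by the automatic
#'   cutoff (default 4).
#' @return An object of class `eps_domain`: a list with `n_areas`,
#'   `area_id`, `centroids` (n x 2 matrix, km), `dist` (n x n symmetric),
#'   `neighbors` (list of integer index vectors), `n_neighbors`, `cutoff`,
#'   and `n_components` (connected components of the neighbor graph).
#' @examples
#' dom <- build_domain("lattice", nx = 5, ny = 5, spacing = 1.5)
#' dom$n_areas
#' @export
build_domain <- function(mode = c("lattice", "centroid_table"),
                         nx = 25, ny = 25, spacing = 1.5,
                         centroids = NULL,
                         cutoff = NULL, min_neighbors = 4) {
  mode <- match.arg(mode)
  if (mode == "lattice") {
    if (nx < 1 || ny < 1) stop("lattice dimensions must be positive")
    g <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                     y = (seq_len(ny) - 1) * spacing)
    xy <- as.matrix(g)
    ids <- paste0("a", seq_len(nrow(xy)))
  } else {
    if (is.null(centroids) || nrow(centroids) == 0)
      stop("centroid table is empty")
    req <- c("area_id", "x", "y")
    if (!all(req %in% names(centroids)))
      stop("centroid table needs columns area_id, x, y")
    ids <- as.character(centroids$area_id)
    if (anyDuplicated(ids)) stop("duplicate area ids in centroid table")
    xy <- cbind(centroids$x, centroids$y)
    if (!all(is.finite(xy))) stop("non-finite centroid coordinates")
  }
  n <- nrow(xy)
  if (n < 2) stop("domain must contain at least two areas (no neighbor possible)")
  colnames(xy) <- c("x", "y")
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- NULL

  if (is.null(cutoff)) {
    ## smallest pairwise distance giving >= min_neighbors everywhere
    cand <- sort(unique(round(D[upper.tri(D)], 10)))
    k <- min(min_neighbors, n - 1)
    kth <- apply(D + diag(Inf, n), 1, function(d) sort(d)[k])
    cutoff <- max(kth)
  }
  A <- (D <= cutoff & D > 0)
  ## ensure at least one neighbor: connect isolated areas to nearest area
  iso <- which(rowSums(A) == 0)
  for (i in iso) {
    j <- which.min(replace(D[i, ], i, Inf))
    A[i, j] <- A[j, i] <- TRUE
  }
  A <- A | t(A)
  nbr <- apply(A, 1, which, simplify = FALSE)
  structure(list(
    n_areas = n, area_id = ids, centroids = xy, dist = D,
    neighbors = nbr, n_neighbors = lengths(nbr),
    cutoff = cutoff,
    n_components = n_graph_components(nbr)
  ), class = "eps_domain")
}

#' @export
print.eps_domain <- function(x, ...) {
  cat("Areal domain:", x$n_areas, "areas;",
      "distance range", signif(min(x$dist[x$dist > 0]), 3), "-",
      signif(max(x$dist), 3), "km;",
      "neighbor cutoff", signif(x$cutoff, 3), "km;",
      "neighbors per area", min(x$n_neighbors), "-", max(x$n_neighbors),
      ";", x$n_components, "graph component(s)\n")
  invisible(x)
}

#' Restrict a domain to a subset of areas
#'
#' Keeps the listed areas and rebuilds the neighbor structure among them:
#' the original cutoff is reused, and any area left without an in-subset
#' neighbor is reconnected to its nearest retained area, so the survey
#' (in-sample) sub-geography always supports an intrinsic CAR prior.
#'
#' @param domain an `eps_domain`.
#' @param idx integer indices of areas to keep.
#' @return An `eps_domain` over the retained areas, with attribute
#'   `"orig_idx"` mapping back to the parent domain.
#' @export
restrict_domain <- function(domain, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 2) stop("restricted domain must keep at least two areas")
  D <- domain$dist[idx, idx, drop = FALSE]
  n <- length(idx)
  A <- (D <= domain$cutoff & D > 0)
  iso <- which(rowSums(A) == 0)
  for (i in iso) {
    j <- which.min(replace(D[i, ], i, Inf))
    A[i, j] <- A[j, i] <- TRUE
  }
  A <- A | t(A)
  nbr <- apply(A, 1, which, simplify = FALSE)
  out <- structure(list(
    n_areas = n, area_id = domain$area_id[idx],
    centroids = domain$centroids[idx, , drop = FALSE], dist = D,
    neighbors = nbr, n_neighbors = lengths(nbr),
    cutoff = domain$cutoff,
    n_components = n_graph_components(nbr)
  ), class = "eps_domain")
  attr(out, "orig_idx") <- idx
  out
}

## connected components of a neighbor list by breadth-first search
n_graph_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      new <- nbr[[v]][comp[nbr[[v]]] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  k
}

#' Exponential-covariance Gaussian process configuration
#'
#' Stationary covariance \eqn{\sigma^2 \exp(-\psi \|d\|)} between areas at
#' centroid distance \eqn{\|d\|} km. Either the decay rate `psi` (1/km) or
#' the effective range (the distance at which correlation drops to 0.05,
#' `-log(0.05)/psi`) may be given.
#'
#' @param sigma2 process variance (> 0).
#' @param psi decay rate per km (> 0); ignored when `effective_range` given.
#' @param effective_range distance (km) at which correlation equals 0.05.
#' @return list with `sigma2`, `psi`, `effective_range`.
#' @export
gp_config <- function(sigma2 = 1, psi = NULL, effective_range = NULL) {
  if (!is.null(effective_range)) {
    if (effective_range <= 0) stop("effective_range must be positive")
    psi <- -log(0.05) / effective_range
  }
  if (is.null(psi) || psi <= 0) stop("psi must be positive")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  list(sigma2 = sigma2, psi = psi, effective_range = -log(0.05) / psi)
}

#' Simulate a Gaussian process over an areal domain
#'
#' One draw from \eqn{N(0, \Sigma)} with
#' \eqn{\Sigma_{is} = \sigma^2 \exp(-\psi d_{is})}. A jitter of
#' `1e-8 * sigma2` is added to the diagonal before the Cholesky
#' factorization for numerical stability.
#'
#' @param domain an `eps_domain`.
#' @param config a [gp_config()].
#' @param seed optional integer seed (draw is reproducible given it).
#' @return numeric vector of length `domain$n_areas`.
#' @export
simulate_gp <- function(domain, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- gp_covariance(domain, config)
  L <- tryCatch(chol(S), error = function(e)
    stop("GP covariance not positive definite after jitter: ",
         conditionMessage(e)))
  drop(crossprod(L, stats::rnorm(domain$n_areas)))
}

#' @rdname simulate_gp
#' @export
gp_covariance <- function(domain, config) {
  S <- config$sigma2 * exp(-config$psi * domain$dist)
  S + diag(1e-8 * config$sigma2, domain$n_areas)
}

#' Spectral basis of the intrinsic CAR precision
#'
#' The intrinsic (multivariate) CAR prior with neighbor weights
#' \eqn{1/n_i} has improper joint precision proportional to the graph
#' Laplacian \eqn{Q = D - A} of the neighbor graph. This function
#' eigen-decomposes \eqn{Q} and returns the basis restricted to positive
#' eigenvalues: writing the spatial effects as `basis %*% w` with
#' independent coefficients `w_j ~ N(0, (tau * lambda_j)^{-1})` reproduces
#' the intrinsic prior exactly while enforcing the sum-to-zero constraint
#' per connected component by construction (the dropped null space is
#' spanned by the component indicators).
#'
#' @param domain an `eps_domain`.
#' @return list with `basis` (n x m eigenvector matrix,
#'   m = n - n_components), `lambda` (positive eigenvalues),
#'   `scaled_basis` (`basis %*% diag(1/sqrt(lambda))`, so unit-precision
#'   coefficients give the intrinsic prior at tau = 1), and `Q`.
#' @export
icar_spectral <- function(domain) {
  n <- domain$n_areas
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, domain$neighbors[[i]]] <- 1
  Q <- diag(rowSums(A)) - A
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > 1e-8 * max(e$values)
  lambda <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  list(basis = V, lambda = lambda,
       scaled_basis = V %*% diag(1 / sqrt(lambda), length(lambda)),
       Q = Q)
}

#' Read and write neighborhood structures
#'
#' The export format is a symmetric sparse adjacency list: one `i s` pair
#' of 1-based area indices per line, both orientations present.
#'
#' @param domain an `eps_domain`.
#' @param file path.
#' @export
write_neighbors <- function(domain, file) {
  pairs <- do.call(rbind, lapply(seq_len(domain$n_areas), function(i)
    cbind(i, domain$neighbors[[i]])))
  utils::write.table(pairs, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_neighbors
#' @param n_areas number of areas the adjacency list refers to.
#' @export
read_neighbors <- function(file, n_areas) {
  pairs <- as.matrix(utils::read.table(file))
  nbr <- lapply(seq_len(n_areas), function(i)
    sort(unique(pairs[pairs[, 1] == i, 2])))
  if (any(lengths(nbr) == 0)) stop("adjacency list leaves an area isolated")
  nbr
}

#' Read a centroid table from a delimited file
#'
#' Expects a header with columns `area_id`, `x`, `y` (km).
#'
#' @param file path to a whitespace- or comma-delimited file.
#' @export
read_centroids <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  utils::read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}
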