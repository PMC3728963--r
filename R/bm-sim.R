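# Brownian-motion rate estimation from contrasts and seeded multivariate
# simulation on a tree; the engine behind the simulation-based ANCOVA null.

#' Estimate the Brownian (co)variance rate matrix from contrasts
#'
#' REML-style cross-products of the standardized contrasts:
#' `R[a, b] = sum_k c_a(k) * c_b(k) / (n - 1)` over the `n - 1` contrasts of
#' an n-tip binary tree. Diagonal entries are per-trait BM rates
#' (trait-units^2 per branch-length unit); off-diagonals the evolutionary
#' covariances.
#'
#' @param tree a rooted binary [ape::phylo].
#' @param traits named list of named trait vectors, or a matrix/data frame
#'   with species rownames.
#' @return a symmetric positive semi-definite rate matrix.
#' @export
estimate_rates <- function(tree, traits) {
  if (is.matrix(traits) || is.data.frame(traits)) {
    m <- as.matrix(traits)
    traits <- lapply(seq_len(ncol(m)), function(j) stats::setNames(m[, j], rownames(m)))
    names(traits) <- colnames(m)
  }
  cs <- lapply(traits, function(tr) compute_contrasts(tree, tr)$contrast)
  cm <- do.call(cbind, cs)
  R <- crossprod(cm) / nrow(cm)
  dimnames(R) <- list(names(traits), names(traits))
  R
}

# Matrix square root of a PSD rate matrix; chol when possible, eigen fallback
# for rank-deficient matrices.
rate_sqrt <- function(rates, tol = 1e-10) {
  rates <- as.matrix(rates)
  if (!isSymmetric(unname(rates), tol = 1e-8))
    stop("rate matrix must be symmetric")
  ev <- eigen(rates, symmetric = TRUE)
  if (min(ev$values) < -tol * max(abs(ev$values), 1))
    stop("rate matrix is not positive semi-definite")
  if (min(ev$values) > tol) return(t(chol(rates)))
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(rates))
}

#' Simulate Brownian trait evolution on a tree
#'
#' Each branch adds an independent (multivariate) Gaussian increment with
#' covariance `rates * branch length`; tips receive the root value plus the
#' summed increments along their path. Increments are drawn branch by branch
#' in a fixed pre-order traversal, so a given seed reproduces the draws
#' exactly.
#'
#' @param tree a rooted [ape::phylo].
#' @param rates a p x p positive semi-definite rate matrix (a scalar is
#'   taken as a 1 x 1 matrix).
#' @param root numeric root state vector of length p.
#' @param seed optional integer seed (set once at entry).
#' @param nsim number of independent replicate data sets.
#' @return if `nsim == 1`, a tips x p matrix (species as rownames);
#'   otherwise a tips x p x nsim array.
#' @export
simulate_bm <- function(tree, rates, root, seed = NULL, nsim = 1) {
  validate_phylo(tree)
  if (!is.null(seed)) set.seed(seed)
  rates <- as.matrix(rates)
  p <- nrow(rates)
  if (length(root) != p) stop("root vector length must match rate dimension")
  Lr <- rate_sqrt(rates)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  # pre-order = reverse of postorder edge list
  po <- ape::reorder.phylo(tree, "postorder")
  eord <- rev(seq_len(nrow(po$edge)))
  edge <- po$edge[eord, , drop = FALSE]
  el <- po$edge.length[eord]

  vals <- array(0, dim = c(n + nn, p, nsim))
  rootnode <- n + 1L
  vals[rootnode, , ] <- root
  for (k in seq_len(nrow(edge))) {
    z <- matrix(stats::rnorm(p * nsim), p, nsim)
    incr <- sqrt(el[k]) * (Lr %*% z)
    vals[edge[k, 2], , ] <- vals[edge[k, 1], , ] + incr
  }
  tips <- vals[seq_len(n), , , drop = FALSE]
  dimnames(tips) <- list(tree$tip.label, rownames(rates), NULL)
  if (nsim == 1)
    array(tips[, , 1], dim = c(n, p),
          dimnames = list(tree$tip.label, rownames(rates)))
  else tips
}

#' Rescale simulated tip values to an empirical mean and variance
#'
#' The affine transform that makes the across-species mean and variance of a
#' simulated trait equal their empirical targets exactly; used so ANCOVA
#' null data sets retain the observed flock mean and variance. F statistics
#' are invariant under this map.
#'
#' @param sim named numeric vector of simulated tip values (>= 2 distinct).
#' @param target_mean,target_var empirical targets (variance with the usual
#'   n - 1 denominator).
#' @return the rescaled vector.
#' @export
rescale_to_empirical <- function(sim, target_mean, target_var) {
  if (stats::var(sim) == 0) stop("simulated values have zero variance")
  (sim - mean(sim)) * sqrt(target_var / stats::var(sim)) + target_mean
}
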