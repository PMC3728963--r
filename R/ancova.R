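# Simulation-based phylogenetic ANCOVA: the habitat effect on total muscle
# mass with SL as covariate, tested against a null F distribution from
# Brownian re-simulation on the tree, then aggregated over tree ensembles.

# Fast residual sums of squares for fixed design matrices.
rss_fit <- function(X, y) sum(stats::.lm.fit(X, y)$residuals^2)

#' ANCOVA F statistic for a group effect with one covariate
#'
#' Ordinary (non-phylogenetic) analysis of covariance on tip data: the F for
#' the group main effect given the covariate, from the sequential
#' sum-of-squares comparison of the common-slope model `y ~ x + g` against
#' `y ~ x`. `df_num = groups - 1`, `df_den = n - groups - 1`.
#'
#' @param y named response vector (e.g. cube-rooted total muscle mass).
#' @param x named covariate vector (e.g. standard length).
#' @param g named group labels (e.g. habitat `"B"`/`"L"`); every group must
#'   contain at least 2 species.
#' @return list with `F`, `df_num`, `df_den`.
#' @export
ancova_f <- function(y, x, g) {
  if (is.null(names(y)) || is.null(names(x)) || is.null(names(g)))
    stop("y, x and g must be named vectors")
  sp <- names(y)
  if (length(setdiff(sp, names(x))) || length(setdiff(sp, names(g))))
    stop("x and g must cover every species in y")
  x <- as.numeric(x[sp]); gf <- factor(as.character(g[sp])); y <- as.numeric(y)
  if (nlevels(gf) < 2) stop("need at least 2 groups")
  if (any(table(gf) < 2)) stop("every group needs at least 2 species")
  if (stats::var(x) == 0) stop("covariate is constant")
  n <- length(y)
  k <- nlevels(gf)
  Xred <- cbind(1, x)
  Xfull <- cbind(Xred, stats::model.matrix(~ gf)[, -1, drop = FALSE])
  rss_red <- rss_fit(Xred, y)
  rss_full <- rss_fit(Xfull, y)
  df_num <- k - 1L
  df_den <- n - k - 1L
  list(F = ((rss_red - rss_full) / df_num) / (rss_full / df_den),
       df_num = df_num, df_den = df_den)
}

#' Phylogenetic ANCOVA through simulation
#'
#' The empirical ANCOVA F for the group effect is compared to a null
#' distribution of F statistics obtained by re-simulating the continuous
#' traits under Brownian motion on the tree (rates estimated from the data
#' by [estimate_rates()]), rescaling each simulated trait to the empirical
#' mean and variance, and recomputing F with the group labels held fixed at
#' the tips. The p-value is the proportion of simulated F statistics
#' strictly greater than the empirical one.
#'
#' With `cosimulate = TRUE` (default) the response and covariate are
#' co-simulated under their estimated bivariate rate matrix, preserving
#' their evolutionary covariance; with `FALSE` only the response is
#' re-simulated under its marginal rate and the covariate stays at its
#' observed values.
#'
#' @param tree a rooted binary [ape::phylo].
#' @param y,x,g named response, covariate and group vectors over the tips.
#' @param nsim number of null simulations (>= 100 recommended; fewer warns).
#' @param seed optional integer seed.
#' @param cosimulate co-simulate the covariate with the response?
#' @param rescale rescale each simulated trait to the empirical mean and
#'   variance? (F is invariant to this affine map, so it only matters for
#'   inspecting the simulated trait values themselves.)
#' @param pseudocount if `TRUE`, use the `(r + 1)/(nsim + 1)` p estimator
#'   instead of the raw proportion.
#' @return an object of class `ancova_result`: `F`, `df_num`, `df_den`,
#'   `null_F` (length `nsim`), `p`, `nsim`, `seed`.
#' @export
phylo_ancova_p <- function(tree, y, x, g, nsim = 1000, seed = NULL,
                           cosimulate = TRUE, rescale = TRUE,
                           pseudocount = FALSE) {
  validate_phylo(tree, require_binary = TRUE)
  if (nsim < 100) warning("nsim < 100 gives a very coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  sp <- tree$tip.label
  y <- y[sp]; x <- x[sp]; g <- g[sp]
  emp <- ancova_f(y, x, g)

  gf <- factor(as.character(g))
  n <- length(sp)
  Xg <- stats::model.matrix(~ gf)[, -1, drop = FALSE]
  ym <- mean(y); yv <- stats::var(y)
  xm <- mean(x); xv <- stats::var(x)

  if (cosimulate) {
    R <- estimate_rates(tree, cbind(y = y, x = x))
    root <- c(ym, xm)
  } else {
    R <- estimate_rates(tree, cbind(y = y))
    root <- ym
  }
  sims <- simulate_bm(tree, R, root, nsim = nsim)
  if (length(dim(sims)) == 2) dim(sims) <- c(dim(sims), 1)

  nullF <- numeric(nsim)
  Xred_fixed <- cbind(1, as.numeric(x))
  for (s in seq_len(nsim)) {
    ys <- sims[, 1, s]
    if (rescale) ys <- rescale_to_empirical(ys, ym, yv)
    if (cosimulate) {
      xs <- sims[, 2, s]
      if (rescale) xs <- rescale_to_empirical(xs, xm, xv)
      Xred <- cbind(1, xs)
    } else {
      Xred <- Xred_fixed
    }
    Xfull <- cbind(Xred, Xg)
    rr <- rss_fit(Xred, ys)
    rf <- rss_fit(Xfull, ys)
    nullF[s] <- ((rr - rf) / emp$df_num) / (rf / emp$df_den)
  }
  r <- sum(nullF > emp$F)
  p <- if (pseudocount) (r + 1) / (nsim + 1) else r / nsim
  structure(list(F = emp$F, df_num = emp$df_num, df_den = emp$df_den,
                 null_F = nullF, p = p, nsim = nsim, seed = seed),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("Phylogenetic ANCOVA through simulation (nsim = %d)\n", x$nsim))
  cat(sprintf("  empirical F(%d, %d) = %.4f,  P = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

#' Apply a per-tree analysis across an ensemble and summarize
#'
#' Runs `analysis(tree, ...)` (which must return a single number, e.g. a
#' p-value) on every tree in the ensemble and reports the per-tree values
#' with their mean and standard error `sd/sqrt(n_trees)`. Trees whose
#' analysis fails are excluded and recorded in `failures`.
#'
#' @param ensemble a `tree_ensemble` (or list of trees).
#' @param analysis a function of a tree returning a scalar statistic.
#' @param ... passed on to `analysis`.
#' @param statistic name of the statistic for reporting (default `"P"`).
#' @return an object of class `ensemble_summary`: `values`, `mean`, `se`,
#'   `statistic`, `source_label`, `failures` (named list of condition
#'   messages).
#' @export
aggregate_over_trees <- function(ensemble, analysis, ..., statistic = "P") {
  if (inherits(ensemble, "phylo")) ensemble <- list(ensemble)
  if (!length(ensemble)) stop("empty ensemble")
  values <- rep(NA_real_, length(ensemble))
  failures <- list()
  for (i in seq_along(ensemble)) {
    res <- tryCatch(analysis(ensemble[[i]], ...), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
    } else {
      values[i] <- as.numeric(res)
    }
  }
  ok <- values[!is.na(values)]
  if (!length(ok)) stop("analysis failed on every tree in the ensemble")
  structure(list(values = values, mean = mean(ok),
                 se = stats::sd(ok) / sqrt(length(ok)),
                 n_trees = length(ok), statistic = statistic,
                 source_label = attr(ensemble, "source_label"),
                 failures = failures),
            class = "ensemble_summary")
}

#' @export
format.ensemble_summary <- function(x, digits = 3, ...) {
  sprintf("%s = %.*f \u00b1 %.*f", x$statistic, digits, x$mean, digits, x$se)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  lab <- if (is.null(x$source_label)) "" else sprintf(" [%s]", x$source_label)
  cat(sprintf("%s over %d trees%s\n", format(x), x$n_trees, lab))
  if (length(x$failures))
    cat(sprintf("  (%d tree(s) failed and were excluded)\n", length(x$failures)))
  invisible(x)
}
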