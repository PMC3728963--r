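# Felsenstein's independent contrasts and what the study builds on them:
# through-origin PIC correlations with Holm family-wise adjustment,
# standardization diagnostics, and GLS size correction on the tree.

#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm. At each internal node the contrast is
#' the difference between the two daughter values, standardized by the
#' square root of the summed (extended) daughter branch lengths; the
#' ancestral value is the branch-length-weighted average of the daughters
#' and the node's own branch is extended by `v1*v2/(v1+v2)`. Contrast signs
#' follow the child order as written in the tree; all downstream statistics
#' are invariant to that convention.
#'
#' If both daughter branches at a node have length zero, a small epsilon
#' (`1e-8` times tree depth) is added to each with a warning rather than
#' dividing by zero.
#'
#' @param tree a rooted binary [ape::phylo] (see [parse_newick()]).
#' @param trait named numeric vector with one value per tip.
#' @return an object of class `contrast_set`: list with `node` (internal
#'   node ids, pruning order), `contrast` (standardized contrasts), `sd`
#'   (the standardizing square-root branch lengths) and `n_tips`.
#' @export
compute_contrasts <- function(tree, trait) {
  validate_phylo(tree, require_binary = TRUE)
  if (is.null(names(trait))) stop("trait must be a named vector (species names)")
  missing_sp <- setdiff(tree$tip.label, names(trait))
  if (length(missing_sp))
    stop("trait value missing for species: ", paste(missing_sp, collapse = ", "))
  if (anyNA(trait[tree$tip.label]))
    stop("trait value missing (NA) for species: ",
         paste(tree$tip.label[is.na(trait[tree$tip.label])], collapse = ", "))

  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  # children edge indices per node, in written (cladewise) order
  childs <- vector("list", n + nn)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    childs[[p]] <- c(childs[[p]], k)
  }
  po_nodes <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])

  eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
  if (eps == 0) eps <- 1e-8

  x <- numeric(n + nn)
  x[seq_len(n)] <- as.numeric(trait[tree$tip.label])
  v <- numeric(n + nn) # extension accrued above each node
  contrast <- sdv <- numeric(nn)

  for (i in seq_along(po_nodes)) {
    p <- po_nodes[i]
    ce <- childs[[p]]
    c1 <- edge[ce[1], 2]; c2 <- edge[ce[2], 2]
    v1 <- el[ce[1]] + v[c1]
    v2 <- el[ce[2]] + v[c2]
    if (v1 + v2 == 0) {
      warning("zero summed branch length at node ", p,
              "; adding epsilon = ", format(eps))
      v1 <- v1 + eps
      v2 <- v2 + eps
    }
    contrast[i] <- (x[c1] - x[c2]) / sqrt(v1 + v2)
    sdv[i] <- sqrt(v1 + v2)
    x[p] <- if (v1 == 0) x[c1] else if (v2 == 0) x[c2] else
      (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    v[p] <- if (v1 + v2 > 0) v1 * v2 / (v1 + v2) else 0
  }
  structure(list(node = po_nodes, contrast = contrast, sd = sdv,
                 n_tips = n, root_value = x[po_nodes[length(po_nodes)]]),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("%d standardized contrasts (%d tips)\n", length(x$contrast), x$n_tips))
  print(data.frame(node = x$node, contrast = x$contrast, sd = x$sd))
  invisible(x)
}

new_pic_cor <- function(r, t, df, p, method, warning_flag = FALSE) {
  structure(list(r = r, t = t, df = df, p = p, method = method,
                 warning_flag = warning_flag), class = "pic_cor")
}

#' @export
print.pic_cor <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, t = %.3f, df = %d, P = %.4g\n",
              x$method, x$r, x$t, x$df, x$p))
  invisible(x)
}

#' Through-origin correlation of two contrast sets
#'
#' Contrasts have arbitrary sign, so their correlation is computed through
#' the origin (no centering): `r = sum(c1*c2)/sqrt(sum(c1^2)*sum(c2^2))`.
#' The t statistic uses `df = k - 1` for `k` contrasts (one through-origin
#' slope estimated), i.e. `n - 2` on an n-tip tree, with a two-tailed p.
#'
#' @param c1,c2 `contrast_set`s computed on the same tree.
#' @return a `pic_cor` object with fields `r`, `t`, `df`, `p`.
#' @export
pic_correlation <- function(c1, c2) {
  stopifnot(inherits(c1, "contrast_set"), inherits(c2, "contrast_set"))
  if (!identical(c1$node, c2$node))
    stop("contrast sets come from different trees or node orders")
  k <- length(c1$contrast)
  if (k < 3) stop("need at least 3 contrasts")
  s11 <- sum(c1$contrast^2)
  s22 <- sum(c2$contrast^2)
  if (s11 == 0 || s22 == 0)
    stop("undefined correlation: a contrast set has zero variation")
  r <- sum(c1$contrast * c2$contrast) / sqrt(s11 * s22)
  df <- k - 1L
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  new_pic_cor(r, t, df, p, "PIC correlation (through origin)")
}

#' Contrast standardization diagnostic
#'
#' Pearson correlation between the absolute value of a trait's contrasts and
#' their standardizing square-root branch lengths. Under Brownian motion on
#' an adequately transformed trait the standardized contrasts are
#' identically distributed and this correlation is centered on zero; a
#' significant correlation flags inadequate standardization.
#'
#' @param c a `contrast_set`.
#' @return a `pic_cor` object (centered Pearson correlation); if the
#'   standard deviations are constant across nodes (e.g. an ultrametric star
#'   tree) the result is `r = 0, p = 1` with `warning_flag = TRUE` and a
#'   warning.
#' @export
standardization_diagnostic <- function(c) {
  stopifnot(inherits(c, "contrast_set"))
  k <- length(c$contrast)
  if (k < 3) stop("need at least 3 contrasts")
  if (stats::sd(c$sd) < 1e-12 * mean(c$sd)) {
    warning("contrast standard deviations are constant; diagnostic undefined")
    return(new_pic_cor(0, 0, k - 2L, 1, "standardization diagnostic",
                       warning_flag = TRUE))
  }
  ct <- stats::cor.test(abs(c$contrast), c$sd)
  new_pic_cor(unname(ct$estimate), unname(ct$statistic),
              as.integer(ct$parameter), ct$p.value,
              "standardization diagnostic")
}

#' Holm step-down adjustment of p-values
#'
#' Controls the family-wise error rate over one family of tests; used here
#' for the 28 pairwise muscle correlations.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Pairwise PIC correlation matrix with joint Holm adjustment
#'
#' Computes contrasts for each trait on the tree, all pairwise
#' through-origin correlations, and Holm-adjusts the `T*(T-1)/2` p-values
#' as one family (28 pairs for the eight muscles).
#'
#' @param tree a rooted binary [ape::phylo].
#' @param traits a named list of named trait vectors, or a matrix/data frame
#'   with species as rownames and traits as columns.
#' @return an object of class `pic_cor_matrix` with symmetric matrices `r`,
#'   `t`, `p`, `p_holm`, and `df`.
#' @export
correlation_matrix <- function(tree, traits) {
  if (is.matrix(traits) || is.data.frame(traits)) {
    m <- as.matrix(traits)
    traits <- lapply(seq_len(ncol(m)), function(j) stats::setNames(m[, j], rownames(m)))
    names(traits) <- colnames(m)
  }
  if (length(traits) < 2) stop("need at least 2 traits")
  if (is.null(names(traits)))
    names(traits) <- paste0("trait", seq_along(traits))
  cs <- lapply(traits, function(tr) compute_contrasts(tree, tr))
  T <- length(traits)
  r <- t_ <- p <- matrix(NA_real_, T, T, dimnames = list(names(traits), names(traits)))
  diag(r) <- 1; diag(p) <- 0
  pairs <- utils::combn(T, 2)
  praw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- pic_correlation(cs[[i]], cs[[j]])
    r[i, j] <- r[j, i] <- res$r
    t_[i, j] <- t_[j, i] <- res$t
    p[i, j] <- p[j, i] <- res$p
    praw[k] <- res$p
  }
  padj <- holm_adjust(praw)
  p_holm <- matrix(NA_real_, T, T, dimnames = dimnames(r))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p_holm[i, j] <- p_holm[j, i] <- padj[k]
  }
  structure(list(r = r, t = t_, p = p, p_holm = p_holm,
                 df = length(cs[[1]]$contrast) - 1L, n_pairs = ncol(pairs)),
            class = "pic_cor_matrix")
}

#' @export
print.pic_cor_matrix <- function(x, ...) {
  cat(sprintf("PIC correlation matrix (%d pairs, df = %d)\n", x$n_pairs, x$df))
  print(round(x$r, 3))
  cat("Holm-adjusted P:\n")
  print(signif(x$p_holm, 3))
  invisible(x)
}

#' Phylogenetic generalized least squares fit
#'
#' Fits `y ~ x` (or an intercept-only model when `x` is `NULL`) by GLS with
#' error covariance equal to the tree's phylogenetic covariance matrix,
#' `b = (X' C^-1 X)^-1 X' C^-1 y`. The intercept is the estimated root
#' state; with no covariate the fit returns the phylogenetic mean. The
#' residuals `y - X b` are the phylogenetically size-corrected trait values
#' when `x` is body size.
#'
#' @param tree a rooted [ape::phylo].
#' @param y named response vector over the tips.
#' @param x optional named covariate vector over the tips.
#' @return an object of class `gls_fit`: `coefficients`, `se` (their
#'   standard errors), `residuals` (named by species), `root_state`,
#'   `sigma2`.
#' @export
phylo_gls_fit <- function(tree, y, x = NULL) {
  validate_phylo(tree)
  sp <- tree$tip.label
  if (is.null(names(y)) || length(setdiff(sp, names(y))))
    stop("y must be named and cover every tip")
  y <- as.numeric(y[sp])
  X <- matrix(1, length(sp), 1, dimnames = list(sp, "(Intercept)"))
  if (!is.null(x)) {
    if (is.null(names(x)) || length(setdiff(sp, names(x))))
      stop("x must be named and cover every tip")
    X <- cbind(X, x = as.numeric(x[sp]))
  }
  C <- phylo_covariance(tree)
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is singular; consider the epsilon policy ",
         "for zero branch lengths (see compute_contrasts)"))
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qf <- qr(Xw)
  if (qf$rank < ncol(X))
    stop("design matrix is singular (constant covariate?)")
  b <- qr.coef(qf, yw)
  names(b) <- colnames(X)
  e <- y - drop(X %*% b)
  names(e) <- sp
  dfres <- length(sp) - ncol(X)
  sigma2 <- sum(qr.resid(qf, yw)^2) / dfres
  XtCiX_inv <- chol2inv(qr.R(qf))
  se <- sqrt(diag(sigma2 * XtCiX_inv))
  names(se) <- colnames(X)
  structure(list(coefficients = b, se = se, residuals = e,
                 root_state = unname(b[1]), sigma2 = sigma2, df = dfres),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit\n")
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Phylogenetic size correction of the fin traits
#'
#' Linearizes the table (cube-root masses, square-root area), then for each
#' muscle, the total muscle mass and the fin area, returns the residuals of
#' a phylogenetic GLS regression on SL. Species with missing fin area are
#' pruned from the tree for the area fit, so the `area` element is keyed by
#' the retained species only.
#'
#' @param tree a rooted binary [ape::phylo] whose tips match the table's
#'   species.
#' @param table a trait table (raw masses; transformed internally).
#' @param traits which traits to correct; defaults to the eight muscles,
#'   `total_mass` and (if present) `area`.
#' @return a named list of named residual vectors.
#' @export
size_correct <- function(tree, table,
                         traits = c(muscle_names(), "total_mass",
                                    if ("area" %in% names(table)) "area")) {
  lt <- linearize(table)
  sl <- stats::setNames(lt$SL, lt$species)
  out <- list()
  for (tr in traits) {
    val <- stats::setNames(lt[[tr]], lt$species)
    keep <- names(val)[!is.na(val)]
    tr_tree <- if (length(keep) < length(val)) prune_to(tree, keep) else tree
    fit <- phylo_gls_fit(tr_tree, val[keep], sl[keep])
    out[[tr]] <- fit$residuals
  }
  out
}
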