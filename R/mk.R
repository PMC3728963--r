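# Equal-rates Mk likelihood machinery for discrete characters: Felsenstein
# pruning with uniform root frequencies, Lewis's variable-sites (Mkv)
# correction, marginal ancestral-state reconstruction, Fitch counting,
# forward simulation, and the ternary 0/1/2 coding of biallelic SNPs.

# k-state symmetric transition probability matrix over time t:
# P[i,i] = 1/k + (k-1)/k * exp(-k q t);  P[i,j] = 1/k - 1/k * exp(-k q t).
mk_pmat <- function(q, k, t) {
  e <- exp(-k * q * t)
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- (1 + (k - 1) * e) / k
  m
}

# states: named vector/factor or species x loci matrix; returns an integer
# matrix (species x loci) of state indices 1..k plus the level set.
mk_code_states <- function(states, levels = NULL, k = NULL) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1,
                                             dimnames = list(names(states), NULL))
  sm <- as.matrix(states)
  obs <- sort(unique(as.vector(sm[!is.na(sm)])))
  if (is.null(levels)) levels <- obs
  bad <- setdiff(obs, levels)
  if (length(bad))
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(k)) k <- length(levels)
  if (k < length(levels)) stop("k smaller than the number of observed states")
  idx <- matrix(match(as.vector(sm), levels), nrow(sm), ncol(sm),
                dimnames = dimnames(sm))
  list(idx = idx, levels = levels, k = k)
}

# Post-order partial likelihoods for one character (column of idx).
# Returns (n_nodes x k) matrix of conditional likelihoods.
mk_partials <- function(tree, idx_col, k, q) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  D <- matrix(0, n + nn, k)
  for (i in seq_len(n)) {
    s <- idx_col[i]
    if (is.na(s)) D[i, ] <- 1 else D[i, s] <- 1 # missing = all states possible
  }
  D[(n + 1):(n + nn), ] <- 1
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- mk_pmat(q, k, po$edge.length[e])
    D[par, ] <- D[par, ] * as.vector(P %*% D[ch, ])
  }
  D
}

# Probability that a character is constant (same state at all tips) under
# the model; the Mkv normalizer 1 - p_const conditions on variability.
mk_p_constant <- function(tree, k, q, n_tips) {
  tot <- 0
  for (s in seq_len(k)) {
    idx <- rep(s, n_tips)
    D <- mk_partials(tree, idx, k, q)
    tot <- tot + sum(D[n_tips + 1, ] / k)
  }
  tot
}

#' Mk log-likelihood of discrete characters on a tree
#'
#' Felsenstein pruning under the equal-rates (symmetric) Mk model with
#' uniform root state frequencies. With `conditioned_on_variable = TRUE`
#' each per-character likelihood is divided by the probability that a
#' character is variable (Lewis's Mkv correction), appropriate when only
#' variable characters were sampled, as for SNPs.
#'
#' Missing states enter the pruning as all-states-possible partials.
#'
#' @param tree a rooted [ape::phylo].
#' @param states named vector (one character) or species x loci matrix of
#'   state symbols; `NA` is missing.
#' @param q symmetric per-pair transition rate (>= 0).
#' @param k number of states; defaults to the number of observed symbols
#'   (or of `levels` if given). For 0/1/2-coded SNPs use `k = 3` even when a
#'   locus shows fewer codes.
#' @param conditioned_on_variable apply the Mkv correction?
#' @param levels optional explicit state space (ordering defines indices).
#' @return the summed log-likelihood over characters.
#' @export
mk_loglik <- function(tree, states, q, k = NULL,
                      conditioned_on_variable = FALSE, levels = NULL) {
  validate_phylo(tree)
  if (q < 0) stop("q must be >= 0")
  cs <- mk_code_states(states, levels = levels, k = k)
  sp <- tree$tip.label
  if (length(setdiff(sp, rownames(cs$idx))))
    stop("states missing for species: ",
         paste(setdiff(sp, rownames(cs$idx)), collapse = ", "))
  idx <- cs$idx[sp, , drop = FALSE]
  n <- length(sp)
  k <- cs$k
  logp_const <- if (conditioned_on_variable) {
    pc <- mk_p_constant(tree, k, q, n)
    if (pc >= 1) stop("variable-sites correction undefined: ",
                      "constant-pattern probability is 1 (q = 0?)")
    log1p(-pc)
  } else 0
  ll <- 0
  for (j in seq_len(ncol(idx))) {
    D <- mk_partials(tree, idx[, j], k, q)
    lik <- sum(D[n + 1, ] / k)
    if (lik <= 0) stop("zero likelihood for character ", j)
    ll <- ll + log(lik) - logp_const
  }
  ll
}

#' Maximum-likelihood estimate of the Mk rate
#'
#' One-dimensional bounded maximization of [mk_loglik()] over `q`.
#'
#' @inheritParams mk_loglik
#' @param upper upper bound of the search interval; defaults to
#'   `100 / mean root-to-tip depth`.
#' @return list with `q` (the ML rate) and `loglik`.
#' @export
mk_fit_q <- function(tree, states, k = NULL, conditioned_on_variable = FALSE,
                     levels = NULL, upper = NULL) {
  validate_phylo(tree)
  cs <- mk_code_states(states, levels = levels, k = k)
  variable <- any(apply(cs$idx, 2, function(col)
    length(unique(col[!is.na(col)])) > 1))
  if (!variable && conditioned_on_variable)
    stop("all characters constant: likelihood undefined under the ",
         "variable-sites correction")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (is.null(upper)) upper <- 100 / mean(depths)
  opt <- stats::optimize(function(q)
    mk_loglik(tree, states, q, k = k,
              conditioned_on_variable = conditioned_on_variable,
              levels = levels),
    interval = c(1e-9, upper), maximum = TRUE, tol = 1e-7)
  list(q = opt$maximum, loglik = opt$objective)
}

#' Marginal ancestral-state reconstruction under Mk
#'
#' Combined downward/upward (inside-outside) pass: the marginal probability
#' of each state at each internal node given all tip states, under the
#' equal-rates Mk model with a uniform root prior. If `q` is not supplied it
#' is first fitted by [mk_fit_q()].
#'
#' @inheritParams mk_loglik
#' @param q transition rate; `NULL` to fit by maximum likelihood.
#' @return an object of class `asr_result`: `prob` (internal nodes x states
#'   matrix of marginal probabilities, rownames = node ids), `q`, `loglik`,
#'   `levels`.
#' @export
marginal_asr <- function(tree, states, q = NULL, k = NULL, levels = NULL) {
  validate_phylo(tree)
  cs <- mk_code_states(states, levels = levels, k = k)
  if (ncol(cs$idx) != 1) stop("marginal_asr reconstructs one character at a time")
  if (is.null(q)) q <- mk_fit_q(tree, states, k = k, levels = levels)$q
  sp <- tree$tip.label
  idx <- cs$idx[sp, 1]
  n <- length(sp)
  nn <- tree$Nnode
  k <- cs$k
  D <- mk_partials(tree, idx, k, q)
  lik <- sum(D[n + 1, ] / k)
  if (lik <= 0) stop("zero likelihood")

  # upward (outside) pass in pre-order
  po <- ape::reorder.phylo(tree, "postorder")
  eord <- rev(seq_len(nrow(po$edge)))
  edge <- po$edge[eord, , drop = FALSE]
  el <- po$edge.length[eord]
  U <- matrix(0, n + nn, k)
  U[n + 1, ] <- 1 / k # uniform root prior
  sib <- integer(nrow(edge)) # sibling-edge partial product per parent
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- mk_pmat(q, k, el[e])
    # parent's outside x contributions of the other children
    other <- which(edge[, 1] == par)
    other <- other[other != e]
    contrib <- U[par, ]
    for (oe in other) {
      Po <- mk_pmat(q, k, el[oe])
      contrib <- contrib * as.vector(Po %*% D[edge[oe, 2], ])
    }
    U[ch, ] <- as.vector(t(P) %*% contrib)
  }
  nodes <- (n + 1):(n + nn)
  prob <- D[nodes, , drop = FALSE] * U[nodes, , drop = FALSE]
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list(nodes, cs$levels)
  structure(list(prob = prob, q = q, loglik = log(lik), levels = cs$levels),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("Marginal ancestral states (Mk, q = %.4g, logL = %.4f)\n",
              x$q, x$loglik))
  print(round(x$prob, 3))
  invisible(x)
}

#' Fitch minimum number of state changes
#'
#' Small-parsimony count of the minimum number of changes of a discrete
#' character on a rooted binary tree; the parsimony lower bound behind
#' statements like "the habitat transition occurred at least six times".
#'
#' @param tree a rooted binary [ape::phylo].
#' @param states named vector of tip states (any discrete symbols).
#' @return integer minimum change count.
#' @export
count_min_transitions <- function(tree, states) {
  validate_phylo(tree, require_binary = TRUE)
  sp <- tree$tip.label
  if (length(setdiff(sp, names(states))))
    stop("states missing for species: ",
         paste(setdiff(sp, names(states)), collapse = ", "))
  lev <- sort(unique(as.character(states[sp])))
  idx <- match(as.character(states[sp]), lev)
  n <- length(sp)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- idx[i]
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  po_nodes <- unique(po$edge[, 1])
  for (p in po_nodes) {
    ch <- po$edge[po$edge[, 1] == p, 2]
    inter <- intersect(sets[[ch[1]]], sets[[ch[2]]])
    if (length(inter)) {
      sets[[p]] <- inter
    } else {
      sets[[p]] <- union(sets[[ch[1]]], sets[[ch[2]]])
      changes <- changes + 1L
    }
  }
  changes
}

#' Forward simulation of an Mk character on a tree
#'
#' Draws a uniform root state, then evolves along each branch in a fixed
#' pre-order using the exact k-state transition probabilities.
#'
#' @param tree a rooted [ape::phylo].
#' @param q symmetric transition rate.
#' @param k number of states.
#' @param seed optional integer seed.
#' @param levels state symbols (default `"0", "1", ...` or `c("B","L")`
#'   style supplied by the caller).
#' @param nchar number of independent characters to simulate.
#' @return named character vector over tips (or species x nchar matrix).
#' @export
simulate_mk <- function(tree, q, k = 2, seed = NULL,
                        levels = as.character(seq_len(k) - 1L), nchar = 1) {
  validate_phylo(tree)
  if (q < 0) stop("q must be >= 0")
  if (length(levels) != k) stop("levels must have length k")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  eord <- rev(seq_len(nrow(po$edge)))
  edge <- po$edge[eord, , drop = FALSE]
  el <- po$edge.length[eord]
  out <- matrix(NA_integer_, n, nchar, dimnames = list(tree$tip.label, NULL))
  for (ch in seq_len(nchar)) {
    st <- integer(n + nn)
    st[n + 1] <- sample.int(k, 1)
    for (e in seq_len(nrow(edge))) {
      P <- mk_pmat(q, k, el[e])
      st[edge[e, 2]] <- sample.int(k, 1, prob = P[st[edge[e, 1]], ])
    }
    out[, ch] <- st[seq_len(n)]
  }
  res <- matrix(levels[out], n, nchar, dimnames = dimnames(out))
  if (nchar == 1) stats::setNames(res[, 1], tree$tip.label) else res
}

#' Ternary 0/1/2 coding of biallelic SNP genotypes
#'
#' Per locus, one homozygote (chosen by seeded randomization) is anchored to
#' code 0, the heterozygote is always 1, and the other homozygote is 2, so
#' heterozygosity is itself a character state (species-level retained
#' polymorphism). The anchoring is recorded so codings are reproducible and
#' invertible up to the 0/2 permutation.
#'
#' @param genotypes species x loci matrix of two-letter genotype strings
#'   (e.g. `"AA"`, `"AT"`); `NA` or `""` is missing.
#' @param seed optional integer seed for the per-locus anchoring draw.
#' @return an object of class `coded_snp`: `codes` (integer species x loci
#'   matrix with values 0/1/2 and NA), `anchors` (data frame: locus,
#'   allele0, allele2, invariant flag), `seed`.
#' @export
code_snp_genotypes <- function(genotypes, seed = NULL) {
  g <- as.matrix(genotypes)
  if (is.null(rownames(g))) stop("genotype matrix needs species rownames")
  if (is.null(colnames(g))) colnames(g) <- paste0("L", seq_len(ncol(g)))
  if (!is.null(seed)) set.seed(seed)
  g[g == ""] <- NA
  codes <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  anchors <- data.frame(locus = colnames(g), allele0 = NA_character_,
                        allele2 = NA_character_, invariant = NA)
  for (j in seq_len(ncol(g))) {
    gj <- g[, j]
    ok <- !is.na(gj)
    if (any(nchar(gj[ok]) != 2) || any(!grepl("^[ACGT]{2}$", gj[ok])))
      stop("locus ", colnames(g)[j], ": genotypes must be two-letter ACGT pairs")
    alleles <- sort(unique(unlist(strsplit(gj[ok], ""))))
    if (length(alleles) > 2)
      stop("locus ", colnames(g)[j], " has more than 2 alleles: ",
           paste(alleles, collapse = ", "))
    a0 <- if (length(alleles) == 2) sample(alleles, 1) else alleles[1]
    a2 <- setdiff(alleles, a0)
    a2 <- if (length(a2)) a2 else NA_character_
    cj <- integer(length(gj))
    first <- substr(gj, 1, 1); second <- substr(gj, 2, 2)
    cj[ok] <- ifelse(first[ok] != second[ok], 1L,
                     ifelse(first[ok] == a0, 0L, 2L))
    cj[!ok] <- NA_integer_
    codes[, j] <- cj
    anchors$allele0[j] <- a0
    anchors$allele2[j] <- a2
    anchors$invariant[j] <- length(unique(cj[ok])) <= 1
  }
  structure(list(codes = codes, anchors = anchors, seed = seed),
            class = "coded_snp")
}

#' @export
print.coded_snp <- function(x, ...) {
  cat(sprintf("Coded SNP matrix: %d species x %d loci (%d invariant)\n",
              nrow(x$codes), ncol(x$codes), sum(x$anchors$invariant)))
  invisible(x)
}

#' Fraction of polymorphic loci in a coded SNP matrix
#'
#' @param coded a `coded_snp` object (or bare integer matrix).
#' @return the proportion of loci with more than one distinct non-missing
#'   code.
#' @export
fraction_polymorphic <- function(coded) {
  codes <- if (inherits(coded, "coded_snp")) coded$codes else as.matrix(coded)
  if (!ncol(codes)) stop("need at least one locus")
  mean(apply(codes, 2, function(col) length(unique(col[!is.na(col)])) > 1))
}
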