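# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: exhaustive enumeration for discrete
# likelihood/parsimony, explicit matrix algebra for GLS, and lm() sequential
# sums of squares for the ANCOVA F.

star_tree <- function(n, depth = 1) {
  parse_newick(paste0("(", paste0("s", seq_len(n), ":", depth, collapse = ","), ");"))
}

# children indices per node from the edge matrix
node_children <- function(tree) {
  ch <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (k in seq_len(nrow(tree$edge)))
    ch[[tree$edge[k, 1]]] <- c(ch[[tree$edge[k, 1]]], tree$edge[k, 2])
  ch
}

# Mk likelihood by summing over every assignment of states to internal nodes.
oracle_mk_lik <- function(tree, states_idx, q, k) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  pmat <- function(t) {
    e <- exp(-k * q * t)
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- (1 + (k - 1) * e) / k
    m
  }
  Ps <- lapply(el, pmat)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- c(states_idx, grid[g, ])
    pr <- 1 / k # uniform root prior, root = n + 1 has index nn-grid col 1
    for (e in seq_len(nrow(edge)))
      pr <- pr * Ps[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    tot <- tot + pr
  }
  tot
}

# Marginal ancestral probabilities by enumeration.
oracle_mk_marginals <- function(tree, states_idx, q, k) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  pmat <- function(t) {
    e <- exp(-k * q * t)
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- (1 + (k - 1) * e) / k
    m
  }
  Ps <- lapply(el, pmat)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- c(states_idx, grid[g, ])
    pr <- 1 / k
    for (e in seq_len(nrow(edge)))
      pr <- pr * Ps[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    w[g] <- pr
  }
  probs <- matrix(0, nn, k)
  for (j in seq_len(nn)) for (s in seq_len(k))
    probs[j, s] <- sum(w[grid[, j] == s])
  probs / rowSums(probs)
}

# Minimum changes by enumerating all internal labelings.
oracle_min_changes <- function(tree, states_idx, k) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- c(states_idx, grid[g, ])
    ch <- sum(st[edge[, 1]] != st[edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# ANCOVA F from explicit residual sums of squares via lm().
oracle_ancova_F <- function(y, x, g) {
  d <- data.frame(y = y, x = x, g = factor(g))
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  r0 <- rss(y ~ x)
  r1 <- rss(y ~ x + g)
  k <- nlevels(d$g)
  n <- nrow(d)
  ((r0 - r1) / (k - 1)) / (r1 / (n - k - 1))
}

# GLS coefficients by explicit matrix inversion.
oracle_gls_coef <- function(C, X, y) {
  Ci <- solve(C)
  solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y
}

# Deterministic generator of a valid ANCOVA test data set: regenerates with
# incremented seeds until both habitat groups have >= 2 species.
gen_ancova_dataset <- function(seed, habitat_effect = 0, n_tips = 24) {
  for (s in seed + 0:50) {
    tr <- generate_yule_tree(n_tips, seed = s)
    g <- generate_trait_table(tr, synth_spec(habitat_effect = habitat_effect,
                                             seed = s + 1))
    grp <- stats::setNames(g$table$habitat, g$table$species)
    if (length(unique(grp)) == 2 && min(table(grp)) >= 2)
      return(list(tree = tr, gen = g,
                  y = stats::setNames(linearize(g$table)$total_mass, g$table$species),
                  x = stats::setNames(g$table$SL, g$table$species),
                  g = grp, seed_used = s))
  }
  stop("no valid data set found")
}
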