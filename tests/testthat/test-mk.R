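test_that("Mk likelihood matches the two-tip closed form and q = 0 limits", {
  for (q in c(0.1, 0.5, 2)) for (t in c(0.3, 1, 2.5)) {
    tr <- parse_newick(sprintf("(A:%g,B:%g);", t, t))
    ll <- mk_loglik(tr, c(A = "0", B = "0"), q, k = 2, levels = c("0", "1"))
    e <- exp(-2 * q * t)
    expect_equal(ll, log(((1 + e)^2 + (1 - e)^2) / 8), tolerance = 1e-12)
  }
  tr <- parse_newick("(A:1,(B:1,C:1):1);")
  expect_equal(mk_loglik(tr, c(A = "x", B = "x", C = "x"), q = 0, k = 2,
                         levels = c("x", "y")),
               log(1 / 2), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(50)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    tr <- generate_yule_tree(n)
    k <- sample(2:3, 1)
    q <- runif(1, 0.05, 1.5)
    idx <- sample.int(k, n, replace = TRUE)
    states <- stats::setNames(as.character(idx - 1), tr$tip.label)
    lev <- as.character(seq_len(k) - 1)
    ll <- mk_loglik(tr, states, q, k = k, levels = lev)
    expect_equal(exp(ll), oracle_mk_lik(tr, idx, q, k), tolerance = 1e-12)
  }
})

test_that("the variable-sites correction raises every per-character likelihood", {
  tr <- generate_yule_tree(8, seed = 51)
  st <- simulate_mk(tr, 0.5, k = 2, seed = 52)
  if (length(unique(st)) == 1) st[1] <- setdiff(c("0", "1"), st[1])
  raw <- mk_loglik(tr, st, 0.4, k = 2, levels = c("0", "1"))
  cor <- mk_loglik(tr, st, 0.4, k = 2, levels = c("0", "1"),
                   conditioned_on_variable = TRUE)
  expect_gt(cor, raw) # divides by a quantity in (0, 1)

  # with q = 0 every character is constant and the correction is undefined
  expect_error(mk_loglik(tr, st, 0, k = 2, levels = c("0", "1"),
                         conditioned_on_variable = TRUE), "undefined")
  const <- stats::setNames(rep("0", 8), tr$tip.label)
  expect_error(mk_fit_q(tr, const, k = 2, levels = c("0", "1"),
                        conditioned_on_variable = TRUE), "constant")
})

test_that("the ML rate is a local optimum and collapses for constant data", {
  tr <- generate_yule_tree(16, seed = 53)
  st <- simulate_mk(tr, 0.6, k = 2, seed = 54)
  fit <- mk_fit_q(tr, st, k = 2)
  ll <- function(q) mk_loglik(tr, st, q, k = 2)
  expect_gte(fit$loglik, ll(0.5 * fit$q))
  expect_gte(fit$loglik, ll(2 * fit$q))

  const <- stats::setNames(rep("0", 16), tr$tip.label)
  expect_lt(mk_fit_q(tr, const, k = 2, levels = c("0", "1"))$q, 1e-4)
})

test_that("marginal reconstructions match enumeration and limiting cases", {
  t2 <- parse_newick("(A:1,B:1);")
  asr <- marginal_asr(t2, c(A = "B", B = "L"), q = 0.3)
  expect_equal(unname(asr$prob[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  set.seed(55)
  for (rep in 1:5) {
    t4 <- generate_yule_tree(4)
    idx <- sample.int(2, 4, replace = TRUE)
    if (length(unique(idx)) == 1) idx[1] <- 3 - idx[1]
    states <- stats::setNames(c("0", "1")[idx], t4$tip.label)
    q <- runif(1, 0.1, 1)
    asr4 <- marginal_asr(t4, states, q = q, levels = c("0", "1"))
    expect_equal(unname(asr4$prob), oracle_mk_marginals(t4, idx, q, 2),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(asr4$prob)), rep(1, nrow(asr4$prob)),
                 tolerance = 1e-9)
  }

  # q -> 0 with all tips benthic: internal nodes surely benthic
  t6 <- generate_yule_tree(6, seed = 56)
  allB <- stats::setNames(rep("B", 6), t6$tip.label)
  asrB <- marginal_asr(t6, allB, q = 1e-8, levels = c("B", "L"))
  expect_true(all(asrB$prob[, "B"] > 1 - 1e-6))
})

test_that("Fitch counts match brute force and its boundary behavior", {
  t2 <- parse_newick("(A:1,B:1);")
  expect_equal(count_min_transitions(t2, c(A = "B", B = "L")), 1L)
  expect_equal(count_min_transitions(t2, c(A = "B", B = "B")), 0L)

  set.seed(57)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    tr <- generate_yule_tree(n)
    idx <- sample.int(2, n, replace = TRUE)
    states <- stats::setNames(c("B", "L")[idx], tr$tip.label)
    fitch <- count_min_transitions(tr, states)
    expect_equal(fitch, oracle_min_changes(tr, idx, 2))
    expect_lte(fitch, n - 1L)
    expect_identical(fitch == 0L, length(unique(states)) == 1L)
  }
})

test_that("Mk simulation respects its rate and is seed-deterministic", {
  tr <- generate_yule_tree(24, seed = 58)
  expect_equal(length(unique(simulate_mk(tr, 0, k = 2, seed = 59))), 1L)
  expect_identical(simulate_mk(tr, 0.5, k = 2, seed = 60),
                   simulate_mk(tr, 0.5, k = 2, seed = 60))

  # average transition counts increase with q
  set.seed(61)
  mean_changes <- sapply(c(0.1, 0.5, 2), function(q)
    mean(replicate(60, count_min_transitions(tr, simulate_mk(tr, q, k = 2)))))
  expect_true(all(diff(mean_changes) > 0))

  # near-stationary tip frequencies for large q * depth
  set.seed(62)
  freq <- mean(replicate(200, mean(simulate_mk(tr, 8, k = 2) == "0")))
  expect_lt(abs(freq - 0.5), 0.05)
})

test_that("SNP coding maps genotypes to anchored 0/1/2 states", {
  g <- matrix(c("AA", "AT", "TT", "AA",
                "CC", "CC", "CC", "CC",
                "GG", "GT", NA, "TT"),
              nrow = 4,
              dimnames = list(paste0("sp", 1:4), c("L1", "L2", "L3")))
  coded <- code_snp_genotypes(g, seed = 1)
  a1 <- coded$anchors$allele0[1]
  expected0 <- ifelse(a1 == "A", 0L, 2L)
  expect_equal(unname(coded$codes[, "L1"]),
               c(expected0, 1L, 2L - expected0, expected0))
  expect_equal(unname(coded$codes[, "L2"]), rep(0L, 4))
  expect_true(coded$anchors$invariant[2])
  expect_false(coded$anchors$invariant[1])
  expect_true(is.na(coded$codes[3, "L3"]))

  expect_identical(code_snp_genotypes(g, seed = 5)$codes,
                   code_snp_genotypes(g, seed = 5)$codes)

  bad <- g
  bad[1, 2] <- "AG" # third allele at locus 2
  expect_error(code_snp_genotypes(bad), "L2")
})

test_that("polymorphic-locus fraction equals a direct column scan", {
  g <- matrix("AA", 5, 10, dimnames = list(paste0("sp", 1:5), NULL))
  coded <- code_snp_genotypes(g)
  expect_equal(fraction_polymorphic(coded), 0)

  g[1, 1:5] <- "AT"
  coded2 <- code_snp_genotypes(g, seed = 2)
  expect_equal(fraction_polymorphic(coded2), 0.5)
  direct <- mean(apply(coded2$codes, 2, function(col)
    length(unique(col[!is.na(col)])) > 1))
  expect_equal(fraction_polymorphic(coded2), direct)
})
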