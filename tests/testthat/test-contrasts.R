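test_that("contrasts match hand-derived closed forms on small trees", {
  cs2 <- compute_contrasts(parse_newick("(A:1,B:1);"), c(A = 3, B = 1))
  expect_equal(abs(cs2$contrast), 2 / sqrt(2), tolerance = 1e-10)
  expect_equal(cs2$sd, sqrt(2), tolerance = 1e-10)

  # ancestral value of (A,B) is the weighted mean 1, branch extended to 1.5
  cs3 <- compute_contrasts(parse_newick("((A:1,B:1):1,C:2);"),
                           c(A = 2, B = 0, C = 1))
  expect_equal(sort(abs(cs3$contrast)), c(0, sqrt(2)), tolerance = 1e-10)
  expect_equal(sort(cs3$sd), sqrt(c(2, 3.5)), tolerance = 1e-10)

  const <- compute_contrasts(generate_yule_tree(10, seed = 2),
                             stats::setNames(rep(4, 10), paste0("t", 1:10)))
  expect_equal(const$contrast, rep(0, 9))

  expect_error(compute_contrasts(parse_newick("(A:1,B:1);"), c(A = 1)), "B")
})

test_that("contrast count is tips - 1 and values agree with an independent implementation", {
  for (s in 1:5) {
    tr <- generate_yule_tree(5 + 4 * s, seed = s)
    y <- simulate_bm(tr, matrix(1), 0, seed = 100 + s)[, 1]
    cs <- compute_contrasts(tr, y)
    expect_length(cs$contrast, length(tr$tip.label) - 1L)
    expect_equal(sort(abs(cs$contrast)),
                 sort(abs(unname(ape::pic(y[tr$tip.label], tr)))),
                 tolerance = 1e-9)
  }
})

test_that("through-origin PIC correlation matches its formula and conventions", {
  tr <- generate_yule_tree(11, seed = 4)
  y <- simulate_bm(tr, matrix(1), 0, seed = 5)[, 1]
  z <- simulate_bm(tr, matrix(1), 0, seed = 6)[, 1]
  c1 <- compute_contrasts(tr, y)
  c2 <- compute_contrasts(tr, z)

  res <- pic_correlation(c1, c2)
  r_brute <- sum(c1$contrast * c2$contrast) /
    sqrt(sum(c1$contrast^2) * sum(c2$contrast^2))
  expect_equal(res$r, r_brute, tolerance = 1e-12)
  expect_equal(res$df, length(c1$contrast) - 1L)
  expect_equal(res$p, 2 * pt(-abs(res$t), res$df), tolerance = 1e-12)

  c2x <- c1; c2x$contrast <- 2 * c1$contrast
  expect_equal(pic_correlation(c1, c2x)$r, 1, tolerance = 1e-12)
  c2x$contrast <- -c1$contrast
  expect_equal(pic_correlation(c1, c2x)$r, -1, tolerance = 1e-12)

  # invariant to simultaneous sign flips (the arbitrary child-order convention)
  flip <- sample(c(-1, 1), length(c1$contrast), replace = TRUE)
  c1f <- c1; c1f$contrast <- c1$contrast * flip
  c2f <- c2; c2f$contrast <- c2$contrast * flip
  expect_equal(pic_correlation(c1f, c2f)$r, res$r, tolerance = 1e-12)

  czero <- c1; czero$contrast <- rep(0, length(c1$contrast))
  expect_error(pic_correlation(c1, czero), "undefined")
})

test_that("PIC correlation p-values are calibrated under the BM null", {
  set.seed(31)
  tr <- generate_yule_tree(32, seed = 31)
  rej <- replicate(500, {
    s <- simulate_bm(tr, diag(2), c(0, 0))
    pic_correlation(compute_contrasts(tr, s[, 1]),
                    compute_contrasts(tr, s[, 2]))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("standardization diagnostic is null under BM and flags degeneracy", {
  set.seed(8)
  tr <- generate_yule_tree(24, seed = 8)
  rs <- replicate(500, {
    y <- simulate_bm(tr, matrix(1), 0)[, 1]
    standardization_diagnostic(compute_contrasts(tr, y))$r
  })
  expect_lt(abs(mean(rs)), 0.05)

  cs <- compute_contrasts(tr, simulate_bm(tr, matrix(1), 0, seed = 9)[, 1])
  mono <- cs
  mono$contrast <- mono$sd * 10 # |contrast| strictly increasing in sd
  expect_gt(standardization_diagnostic(mono)$r, 0.9)

  # constant standardizing sd across nodes (e.g. a clean star phylogeny)
  cst <- compute_contrasts(tr, simulate_bm(tr, matrix(1), 0, seed = 10)[, 1])
  cst$sd <- rep(sqrt(2), length(cst$sd))
  expect_warning(dg <- standardization_diagnostic(cst), "constant")
  expect_true(dg$warning_flag)
  expect_equal(dg$p, 1)
})

test_that("Holm adjustment applies the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  # step-down monotone max rule, hand-derived: sorted (0.01,0.02,0.9) ->
  # (0.03, 0.04, 0.9)
  expect_equal(holm_adjust(c(0.9, 0.01, 0.02)), c(0.9, 0.03, 0.04))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the correlation matrix covers all pairs with one Holm family", {
  tr <- generate_yule_tree(24, seed = 12)
  traits <- simulate_bm(tr, diag(8), rep(0, 8), seed = 13)
  colnames(traits) <- muscle_names()
  cm <- correlation_matrix(tr, traits)
  expect_equal(cm$n_pairs, 28L)
  expect_true(isSymmetric(cm$r))
  up <- upper.tri(cm$p)
  expect_equal(sort(cm$p_holm[up]), sort(holm_adjust(cm$p[up])))

  # family-wise error control for independent traits
  set.seed(14)
  any_sig <- replicate(100, {
    tt <- simulate_bm(tr, diag(4), rep(0, 4))
    colnames(tt) <- paste0("x", 1:4)
    any(correlation_matrix(tr, tt)$p_holm < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("phylogenetic GLS matches matrix-algebra and independent oracles", {
  # star tree: GLS with C proportional to identity equals OLS
  st <- star_tree(8)
  y <- stats::setNames(rnorm(8, 2, 1), st$tip.label)
  x <- stats::setNames(rnorm(8), st$tip.label)
  f <- phylo_gls_fit(st, y, x)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(f$coefficients), unname(ols), tolerance = 1e-10)

  # exact linear data -> zero residuals
  tr <- generate_yule_tree(10, seed = 15)
  x2 <- simulate_bm(tr, matrix(1), 0, seed = 16)[, 1]
  y2 <- 2 + 3 * x2
  expect_equal(max(abs(phylo_gls_fit(tr, y2, x2)$residuals)), 0,
               tolerance = 1e-10)

  # 4-tip tree against the explicit inverse formula
  t4 <- parse_newick("((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  y4 <- c(A = 1.2, B = -0.3, C = 2.5, D = 0.9)
  x4 <- c(A = 0.5, B = 1.1, C = -0.2, D = 2.0)
  C <- phylo_covariance(t4)
  X <- cbind(1, x4[rownames(C)])
  f4 <- phylo_gls_fit(t4, y4, x4)
  expect_equal(unname(f4$coefficients),
               drop(oracle_gls_coef(C, X, y4[rownames(C)])),
               tolerance = 1e-10)

  # intercept-only fit returns the phylogenetic mean
  fm <- phylo_gls_fit(t4, y4)
  Ci <- solve(C)
  expect_equal(fm$root_state,
               drop(sum(Ci %*% y4[rownames(C)]) / sum(Ci)), tolerance = 1e-10)

  # agreement with the phytools implementation of size correction
  tr2 <- generate_yule_tree(12, seed = 17)
  yy <- simulate_bm(tr2, matrix(4), 0, seed = 18)[, 1]
  xx <- simulate_bm(tr2, matrix(2), 0, seed = 19)[, 1]
  ours <- phylo_gls_fit(tr2, yy, xx)$residuals
  theirs <- phytools::phyl.resid(tr2, xx, yy)$resid
  expect_equal(unname(ours[rownames(theirs)]), unname(theirs[, 1]),
               tolerance = 1e-8)

  expect_error(phylo_gls_fit(st, y, stats::setNames(rep(1, 8), st$tip.label)),
               "singular")
})

test_that("size correction prunes the tree for species lacking fin area", {
  tab <- load_builtin_table()
  tr <- generate_yule_tree(24, seed = 20, tip_labels = tab$species)
  res <- size_correct(tr, tab)
  expect_setequal(names(res), c(muscle_names(), "total_mass", "area"))
  expect_length(res$area, 16L)
  expect_setequal(names(res$area), tab$species[!is.na(tab$area)])
  expect_length(res$total_mass, 24L)

  # trait uncorrelated with SL under GLS: residuals = trait - phylo mean
  y <- stats::setNames(rep(5, 24), tab$species) # constant => zero slope
  f <- phylo_gls_fit(tr, y, stats::setNames(tab$SL, tab$species))
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-9)

  # simulated allometry: slope recovered within 2 SE most of the time
  set.seed(21)
  hits <- replicate(100, {
    tt <- generate_yule_tree(24)
    sl <- simulate_bm(tt, matrix(100), 100)[, 1]
    yy <- 0.3 * sl + simulate_bm(tt, matrix(1), 0)[, 1]
    ft <- phylo_gls_fit(tt, yy, sl)
    abs(ft$coefficients["x"] - 0.3) < 2 * ft$se["x"]
  })
  expect_gt(mean(hits), 0.85) # nominal 95% coverage
})
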