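# Generators for synthetic trees, trait tables, habitat characters and SNP
# matrices with the statistical structure the analyses assume, plus the
# ground truth needed to score recovery. Every generator is a pure function
# of its inputs and seed.

#' Specification for a synthetic trait data set
#'
#' Defaults are calibrated to the magnitudes of the built-in 24-species
#' table: SL roughly 70-170 mm, summed muscle mass roughly 50-500 mg, mean
#' muscle proportions set to the observed mean percent contributions, an
#' expected handful (~6-10) of habitat transitions on a 24-tip Yule tree,
#' and 8 of 24 species missing fin area.
#'
#' @param n_tips number of species.
#' @param birth_rate Yule speciation rate (events per time unit).
#' @param rate_matrix 2 x 2 BM rate matrix for (SL, linearized total mass),
#'   trait-units^2 per branch-length unit. The default corresponds to tip
#'   standard deviations of ~26 mm (SL) and ~1.2 mg^(1/3) on trees of depth
#'   ~2.8 (a 24-tip Yule tree at rate 1), with evolutionary correlation 0.9.
#' @param root root state `c(SL, linearized total mass)`.
#' @param habitat_q Mk transition rate of the binary habitat character
#'   (events per branch-length unit).
#' @param habitat_effect additive shift on linearized total mass for benthic
#'   tips (mg^(1/3)).
#' @param muscle_mean_proportions mean proportions of the eight muscles
#'   (sums to 1).
#' @param proportion_concentration Dirichlet concentration of per-species
#'   proportions around the means (larger = less spread; `Inf` = exact).
#' @param area_coef,area_lognorm_sd fin area is
#'   `area_coef * total_mass^(2/3) * exp(N(0, sd))` (mm^2).
#' @param missing_area_fraction fraction of species with fin area set
#'   missing.
#' @param n_loci,heterozygosity SNP matrix defaults (loci count; fraction of
#'   heterozygous calls).
#' @param seed integer seed used by the generators.
#' @return an object of class `synth_spec` (a validated list).
#' @export
synth_spec <- function(n_tips = 24,
                       birth_rate = 1,
                       rate_matrix = matrix(c(243, 8.75, 8.75, 0.52), 2, 2,
                                            dimnames = list(c("SL", "total_mass"),
                                                            c("SL", "total_mass"))),
                       root = c(SL = 105, total_mass = 5.3),
                       habitat_q = 0.35,
                       habitat_effect = 0.8,
                       muscle_mean_proportions = c(ABS = 0.092, ABSp = 0.145,
                                                   ARRV = 0.080, ABP = 0.161,
                                                   ADS = 0.177, ARRD = 0.041,
                                                   ADP = 0.291, ADR = 0.013),
                       proportion_concentration = 150,
                       area_coef = 16.8,
                       area_lognorm_sd = 0.15,
                       missing_area_fraction = 8 / 24,
                       n_loci = 65,
                       heterozygosity = 0.15,
                       seed = NULL) {
  spec <- list(n_tips = n_tips, birth_rate = birth_rate,
               rate_matrix = rate_matrix, root = root, habitat_q = habitat_q,
               habitat_effect = habitat_effect,
               muscle_mean_proportions = muscle_mean_proportions,
               proportion_concentration = proportion_concentration,
               area_coef = area_coef, area_lognorm_sd = area_lognorm_sd,
               missing_area_fraction = missing_area_fraction,
               n_loci = n_loci, heterozygosity = heterozygosity, seed = seed)
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0 || habitat_q < 0) stop("rates must be positive")
  if (abs(sum(muscle_mean_proportions) - 1) > 1e-8)
    stop("muscle_mean_proportions must sum to 1")
  if (!identical(sort(names(muscle_mean_proportions)), sort(muscle_names())))
    stop("muscle_mean_proportions must be named by the eight muscles")
  if (heterozygosity < 0 || heterozygosity > 1)
    stop("heterozygosity must be in [0, 1]")
  if (missing_area_fraction < 0 || missing_area_fraction >= 1)
    stop("missing_area_fraction must be in [0, 1)")
  rate_sqrt(rate_matrix) # errors if not symmetric PSD
  structure(spec, class = "synth_spec")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from two lineages at the root; while `k` lineages are active the
#' next split waits an `Exp(k * birth_rate)` time and hits a uniformly
#' chosen lineage; after the n-th lineage appears a final `Exp(n *
#' birth_rate)` epoch runs to the present. Trees are ultrametric with
#' expected depth `(H_n - 1) / birth_rate` (`H_n` the n-th harmonic number).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer seed.
#' @param tip_labels optional tip names (default `t1, t2, ...`).
#' @return a rooted binary ultrametric [ape::phylo].
#' @export
generate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_labels = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  maxn <- 2L * n_tips
  birth <- numeric(maxn)
  children <- vector("list", maxn)
  active <- c(1L, 2L)
  nxt <- 3L
  t <- 0
  if (n_tips > 2) {
    for (k in 2:(n_tips - 1)) {
      t <- t + stats::rexp(1, rate = k * birth_rate)
      splitter <- active[sample.int(length(active), 1)]
      birth[nxt] <- t
      birth[nxt + 1L] <- t
      children[[splitter]] <- c(nxt, nxt + 1L)
      active <- c(active[active != splitter], nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
  }
  t_end <- t + stats::rexp(1, rate = n_tips * birth_rate)
  tip_counter <- 0L
  lab <- function() {
    tip_counter <<- tip_counter + 1L
    paste0("t", tip_counter)
  }
  sub_newick <- function(i) {
    if (is.null(children[[i]]))
      sprintf("%s:%.12g", lab(), t_end - birth[i])
    else {
      split_t <- birth[children[[i]][1]]
      sprintf("(%s,%s):%.12g",
              sub_newick(children[[i]][1]), sub_newick(children[[i]][2]),
              split_t - birth[i])
    }
  }
  txt <- sprintf("(%s,%s);", sub_newick(1L), sub_newick(2L))
  tree <- parse_newick(txt)
  if (!is.null(tip_labels)) {
    if (length(tip_labels) != n_tips || anyDuplicated(tip_labels))
      stop("tip_labels must be ", n_tips, " unique names")
    tree$tip.label <- tip_labels[as.integer(substring(tree$tip.label, 2))]
  }
  tree
}

#' Perturb a base tree into a posterior-like ensemble
#'
#' Emulates a sample of phylogenetic hypotheses around a point estimate:
#' each tree receives a Poisson(`2 * perturbation`) number of random NNI
#' moves plus lognormal branch-length jitter with log-sd
#' `0.25 * perturbation`. `perturbation = 0` yields identical copies.
#'
#' @param base_tree a rooted binary [ape::phylo].
#' @param n_trees ensemble size.
#' @param perturbation non-negative scalar controlling both topological and
#'   branch-length spread.
#' @param seed optional integer seed.
#' @param source_label passed to [tree_ensemble()].
#' @return a `tree_ensemble`.
#' @export
generate_tree_ensemble <- function(base_tree, n_trees, perturbation = 0.5,
                                   seed = NULL, source_label = "synthetic") {
  validate_phylo(base_tree, require_binary = TRUE)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (perturbation < 0) stop("perturbation must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- base_tree
    if (perturbation > 0) {
      nm <- stats::rpois(1, 2 * perturbation)
      if (nm > 0) {
        tr <- phangorn::rNNI(tr, moves = nm, n = 1)
        if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
      }
      tr$edge.length <- tr$edge.length *
        exp(stats::rnorm(length(tr$edge.length), 0, 0.25 * perturbation))
    }
    trees[[i]] <- tr
  }
  tree_ensemble(trees, source_label = source_label)
}

# Dirichlet draw around mean proportions with concentration parameter.
rdirichlet_mean <- function(n, mean_props, concentration) {
  p <- length(mean_props)
  if (!is.finite(concentration))
    return(matrix(mean_props, n, p, byrow = TRUE,
                  dimnames = list(NULL, names(mean_props))))
  alpha <- concentration * mean_props
  g <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
  out <- g / rowSums(g)
  colnames(out) <- names(mean_props)
  out
}

#' Generate a synthetic trait table with known ground truth
#'
#' SL and linearized (cube-root) total muscle mass co-evolve under bivariate
#' Brownian motion; a binary habitat evolves under Mk; benthic tips receive
#' an additive shift on linearized total mass; per-species muscle
#' proportions are Dirichlet draws around the configured means applied to
#' the back-transformed total; fin area is proportional to total mass^(2/3)
#' with lognormal noise and a configurable missing fraction.
#'
#' To keep all masses and lengths positive on extreme Brownian excursions,
#' SL and linearized total mass are truncated below at 20% of their root
#' values (essentially never reached under the default rates).
#'
#' @param tree a rooted binary [ape::phylo] whose tips become the species.
#' @param spec a [synth_spec()]; its `seed` drives all randomness here.
#' @return a list with `table` (a trait table accepted by every pipeline
#'   stage) and `truth` (habitat history, effect size, rate matrix, realized
#'   Fitch transition count, and the latent linearized masses).
#' @export
generate_trait_table <- function(tree, spec = synth_spec()) {
  validate_phylo(tree, require_binary = TRUE)
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- length(tree$tip.label)
  sim <- simulate_bm(tree, spec$rate_matrix, spec$root)
  SL <- pmax(sim[, 1], 0.2 * spec$root[1])
  m_lin <- pmax(sim[, 2], 0.2 * spec$root[2])
  habitat <- simulate_mk(tree, spec$habitat_q, k = 2, levels = c("B", "L"))
  m_lin <- m_lin + ifelse(habitat == "B", spec$habitat_effect, 0)
  total <- m_lin^3
  props <- rdirichlet_mean(n, spec$muscle_mean_proportions,
                           spec$proportion_concentration)
  masses <- props * total
  area <- spec$area_coef * total^(2 / 3) *
    exp(stats::rnorm(n, 0, spec$area_lognorm_sd))
  n_missing <- round(spec$missing_area_fraction * n)
  if (n_missing > 0) area[sample.int(n, n_missing)] <- NA
  tab <- data.frame(species = tree$tip.label,
                    n = sample.int(4, n, replace = TRUE),
                    habitat = unname(habitat[tree$tip.label]),
                    SL = unname(SL),
                    stringsAsFactors = FALSE)
  for (mu in muscle_names()) tab[[mu]] <- unname(masses[, mu])
  tab$area <- unname(area)
  validate_trait_table(tab)
  truth <- list(habitat = habitat,
                habitat_effect = spec$habitat_effect,
                rate_matrix = spec$rate_matrix,
                root = spec$root,
                habitat_q = spec$habitat_q,
                n_transitions = count_min_transitions(tree, habitat),
                total_mass_lin = stats::setNames(m_lin, tree$tip.label),
                SL = stats::setNames(SL, tree$tip.label))
  list(table = tab, truth = truth)
}

#' Generate a synthetic biallelic SNP genotype matrix
#'
#' Per locus: two distinct bases are drawn, the fixed-allele state evolves
#' on the tree under binary Mk at rate `q`, and each call is independently
#' made heterozygous with probability `heterozygosity` (emulating
#' species-level retained polymorphism). With `ascertained = TRUE` a locus
#' is redrawn until its genotypes are variable across species, emulating
#' SNP ascertainment; if variability cannot be achieved (e.g. `q = 0` and
#' no heterozygosity) a warning is issued and the invariant locus kept.
#'
#' @param tree a rooted [ape::phylo].
#' @param n_loci number of loci.
#' @param q Mk rate of the underlying allele character.
#' @param heterozygosity per-call probability of a heterozygous genotype.
#' @param seed optional integer seed.
#' @param ascertained redraw invariant loci?
#' @param max_tries redraw budget per locus.
#' @return a list with `genotypes` (species x loci matrix of two-letter
#'   strings) and `truth` (underlying 0/1/2 codes with allele 0 = first
#'   drawn base, the allele pairs, and the generating parameters).
#' @export
generate_snp_matrix <- function(tree, n_loci = 65, q = 0.5,
                                heterozygosity = 0.15, seed = NULL,
                                ascertained = TRUE, max_tries = 100) {
  validate_phylo(tree)
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  geno <- matrix(NA_character_, n, n_loci,
                 dimnames = list(tree$tip.label, paste0("L", seq_len(n_loci))))
  codes <- matrix(NA_integer_, n, n_loci, dimnames = dimnames(geno))
  alleles <- data.frame(locus = colnames(geno), allele0 = NA_character_,
                        allele1 = NA_character_)
  warned <- FALSE
  for (j in seq_len(n_loci)) {
    for (try in seq_len(max_tries)) {
      ab <- sample(c("A", "C", "G", "T"), 2)
      st <- simulate_mk(tree, q, k = 2, levels = c("0", "1"))
      het <- stats::runif(n) < heterozygosity
      cj <- ifelse(het, 1L, ifelse(st[tree$tip.label] == "0", 0L, 2L))
      gj <- character(n)
      gj[cj == 0L] <- strrep(ab[1], 2)
      gj[cj == 2L] <- strrep(ab[2], 2)
      gj[cj == 1L] <- paste0(sort(ab)[1], sort(ab)[2])
      if (!ascertained || length(unique(gj)) > 1) break
      if (try == max_tries && !warned) {
        warning("could not ascertain a variable locus in ", max_tries,
                " tries (q too small?); keeping invariant loci")
        warned <- TRUE
      }
    }
    geno[, j] <- gj
    codes[, j] <- cj
    alleles$allele0[j] <- ab[1]
    alleles$allele1[j] <- ab[2]
  }
  list(genotypes = geno,
       truth = list(codes = codes, alleles = alleles, q = q,
                    heterozygosity = heterozygosity))
}
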