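---
title: "Models and design choices in finphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in finphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`finphylo` tests whether pectoral fin musculature in Lake Malawi cichlids
is evolutionarily integrated and associated with benthic versus limnetic
feeding. This vignette is the package's own account of the models it fits,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the validation suite does and does not establish.

## The data model

The unit of analysis is the species. The shipped table holds species means
(over 1-4 dissected individuals) of standard length SL (mm), the wet masses
(mg) of the eight pectoral muscles — four abductors (ABS, ABSp, ARRV, ABP)
and four adductors (ADS, ARRD, ADP, ADR) — pectoral fin area (mm²; missing
for 8 of the 24 species, whose fins were too damaged to measure), and a
binary habitat label (B = benthic, L = limnetic). Note one nomenclature
wrinkle inherited from the source data: the adductor column set used here
(ADS, ARRD, ADP, ADR) is the one the table and results use; anatomical
descriptions of the same system sometimes list an "ADM" in place of "ADP".
Percentage summaries (`percent_contributions`, `summarize_percent`) are
computed at the species level; published per-muscle range endpoints that
derive from individual fish (e.g. a minimum ADR share of 0.1%) are not
reproducible from species means, and the package makes no attempt to.

Before any comparative analysis, masses are cube-rooted and areas
square-rooted (`linearize`) so every trait has the dimension of length,
matching SL. "Total muscle mass" is the sum of the eight dissected muscles
— the only total computable from the table.

## Brownian motion, contrasts, and their correlations

All continuous-trait machinery assumes Brownian motion (BM): independent
Gaussian increments with variance `rate × branch length`. Contrasts
(`compute_contrasts`) follow Felsenstein's pruning recursion exactly; the
sign of each contrast follows the child order as written in the input tree,
a cosmetic convention — every downstream statistic is invariant to
simultaneous sign flips, and the test suite asserts this.

Contrast correlations (`pic_correlation`) are computed through the origin
(contrasts have arbitrary sign, so no centering) with
`df = (number of contrasts) − 1 = n − 2`, charging one degree of freedom
for the through-origin slope. Conventions differ across software here; the
choice is documented so results can be compared with implementations that
use `n − 3`. p-values are two-tailed. For the eight muscles the 28 pairwise
tests form a single Holm family (`correlation_matrix`); the fin-area test
and the standardization diagnostics are separate families.

The standardization diagnostic correlates `|contrast|` with its
standardizing square root branch length; under BM on an adequately
transformed trait this is centered on zero. If the standard deviations are
constant across nodes the correlation is undefined and the function returns
r = 0, p = 1 with a warning flag rather than NaN.

Rate matrices (`estimate_rates`) are REML-style contrast cross-products,
`R[a,b] = Σ c_a c_b / (n − 1)`. The simulator (`simulate_bm`) draws
per-branch increments in a fixed pre-order traversal so that one integer
seed reproduces every draw bit for bit; rank-deficient rate matrices are
handled by an eigenvalue square root.

## Phylogenetic size correction

Because muscle mass scales with body size, analyses use residuals of a GLS
regression of each linearized trait on SL with error covariance equal to
the phylogenetic covariance matrix (shared root-to-MRCA branch length).
This is the standard "phylogenetic residuals" size correction; the
intercept estimates the root state and an intercept-only fit returns the
phylogenetic mean. Species missing fin area are pruned from the tree before
the area fit (pairwise-complete analysis) rather than imputed, so area
results are keyed by the 16 measurable species. Singular covariance
matrices (duplicated zero-length paths) raise an error that points at the
zero-branch epsilon policy instead of failing inside the solver.

## The simulation ANCOVA

The habitat test follows the simulation-based phylogenetic ANCOVA design:

1. the empirical F for habitat is the ordinary common-slope ANCOVA
   sequential-SS F of `y ~ SL + habitat` against `y ~ SL` at the tips;
2. `nsim` replicate data sets are simulated under BM on the candidate tree,
   with rates estimated from the observed data;
3. each simulated trait is affinely rescaled to the empirical mean and
   variance, habitat labels stay fixed at the tips, F is recomputed;
4. p is the proportion of simulated F **strictly greater** than the
   empirical F.

Design choices, each genuinely open and settled as follows:

* **Strict inequality.** Ties occur with probability zero for continuous
  data; a `(r+1)/(n+1)` pseudocount estimator is available via
  `pseudocount = TRUE` (default off) for users who want a never-zero p.
* **Co-simulation.** Whether the size covariate should be re-simulated
  jointly with the response (preserving their evolutionary covariance) or
  held fixed is ambiguous in the design this follows; both modes exist
  (`cosimulate`, default `TRUE`). Type-I error is calibrated in both modes
  in this package's tests, slightly better under co-simulation.
* **Rescaling.** The affine match of simulated mean/variance to the
  empirical values is the most literal reading of "retaining the flock mean
  and variance". F is location-scale invariant, so the choice cannot move
  the test itself; a property test verifies the invariance numerically.
* **Homogeneous slopes.** No habitat × SL interaction is fitted, since a
  single habitat effect is the target of inference.
* **Ensembles.** Per-tree p-values over a tree ensemble are reported as
  mean ± SE (`aggregate_over_trees`), never pooled into one null
  distribution. Failed trees are excluded and logged, not silently dropped.

## Mk, Mkv, ancestral states, and SNP coding

Discrete characters use the equal-rates (symmetric) Mk model with uniform
root frequencies: `P(stay) = 1/k + (k−1)/k·e^(−kqt)`. The likelihood is
Felsenstein pruning; ancestral states are marginal probabilities from a
combined inside-outside pass; `q` is fitted by bounded one-dimensional
optimization on `(1e−9, 100/mean tip depth)` — the ancestral
reconstruction fits `q` by ML rather than fixing it, since the
reconstruction this emulates does not state its rate. Missing states enter
as all-states-possible partials.

For SNPs coded 0/1/2, only variable loci are ever scored, so likelihoods
are conditioned on variability (Mkv): each per-character likelihood is
divided by `1 − P(constant pattern)`. The state space is fixed at `k = 3`
even when a locus shows only two codes, because the coding scheme defines
three possible states; passing an explicit two-symbol `levels` gives the
observed-states convention instead. The "habitat evolved at least six
times" style of statement is operationalized as the Fitch minimum-change
count — a parsimony lower bound — with the likelihood reconstruction shown
alongside.

Genotype coding (`code_snp_genotypes`) anchors one homozygote per locus to
0 by a seeded draw, records the anchoring, and always maps heterozygotes
to 1. The rationale for a heterozygote state: a species scored
heterozygous at a locus retains both alleles as a species-level character
(ancestral polymorphism), which is informative rather than missing.

## Synthetic data: what it emulates and what it does not

The generators define the validation conditions; their defaults were fixed
once from the magnitudes of the real table and not revisited:

* `generate_yule_tree`: pure-birth trees from two root lineages with
  `Exp(k·birth_rate)` epoch waits and a final `Exp(n·birth_rate)` epoch, so
  expected depth is `(H_n − 1)/birth_rate` (≈ 2.78 at n = 24, rate 1) — a
  closed form the tests use as an oracle.
* `synth_spec` defaults: BM rates giving tip SDs of ~26 mm (SL) and
  ~1.2 mg^⅓ (linearized total mass) at that depth, evolutionary correlation
  0.9 between size and mass, root at SL 105 mm / total mass 149 mg; habitat
  Mk rate 0.35 per branch-length unit (≈ 8 expected transitions on a
  24-tip Yule tree, matching a radiation with repeated habitat shifts); a
  benthic shift of +0.8 mg^⅓ on linearized total mass; Dirichlet muscle
  proportions around the observed mean percentage vector with concentration
  150; fin area ∝ total mass^⅔ with 15% lognormal noise and 8/24 missing,
  mirroring the real table.
* `generate_snp_matrix`: the fixed-allele state evolves under binary Mk and
  each call is independently heterozygous with probability
  `heterozygosity` (default 0.15). A symmetric 3-state Mk for the genotype
  itself would force ~⅓ heterozygous calls at stationarity — far from the
  species-level heterozygosity this emulates — so the overlay construction
  was chosen; it also keeps the heterozygosity fraction directly
  interpretable. Ascertainment (`ascertained = TRUE`) redraws invariant
  loci, which is exactly the sampling bias the Mkv correction addresses.

Real data differ from these simulations in ways the tests therefore cannot
vouch for: traits need not be Brownian (no Ornstein-Uhlenbeck or rate-shift
alternatives are fitted), habitat may influence diversification itself,
gene-tree discordance and sequence-level processes are not modeled, and
within-species measurement error is ignored (species means enter as
point values).

## Numerical choices and degenerate inputs

* Polytomies are resolved deterministically into zero-length edges at parse
  time; this leaves the phylogenetic covariance unchanged (tested) and
  makes every downstream algorithm's binary-tree assumption safe.
* A contrast node whose two daughter branches are both zero would divide by
  zero; instead `1e−8 × tree depth` is added to each with a warning.
* GLS solves use Cholesky factors and QR, never explicit inverses; the
  explicit-inverse formula appears only in test oracles.
* PSD checks on rate matrices tolerate eigenvalues down to `−1e−10` times
  the largest magnitude before erroring.
* Mk pruning is run unscaled in likelihood space: with ≤ a few hundred tips
  and per-edge factors bounded below by `1/k − 1/k·e^(−kqt)`, likelihoods
  stay far above double-precision underflow for this package's problem
  sizes.
* `optimize` tolerance for `q̂` is `1e−7`; the fit is deterministic given
  the bounds.

## Validation problem sizes

The test suite validates calibration and recovery at sizes chosen to make
Monte-Carlo bands tight while keeping the default run quick: type-I error
of the simulation ANCOVA on 200 null 24-tip data sets at `nsim = 500`
(band: 3 binomial SEs around 0.05); power ≥ 0.5 under a benthic shift of
1.5 pooled within-group SDs of the response (the plain reading of
"within-group SD"; the covariate-adjusted residual reading gives weaker but
still detectable signal); star-tree agreement with the parametric F
p-value within 0.03 at `nsim = 5000` (BM on a star is iid Gaussian, making
the parametric answer exact); BM rate recovery at 64 tips × 500 replicates
(bias < 10%); evolutionary correlation 0.9 recovered within 0.05 over 200
replicates; Mk `q̂` median within 25% at 64 tips × 100 replicates. Exhaustive
enumeration oracles cover Mk pruning (≤ 6 tips), marginal ancestral states
(4 tips), and Fitch counts (≤ 8 tips); closed forms cover 2- and 3-tip
contrasts and two-tip Mk likelihoods.

## Known limitations

* Pure BM only: no branch-length transformations (λ, κ, δ), no OU, no
  early-burst, no rate shifts.
* The ANCOVA estimates rates from the same data it tests, as the
  simulation design prescribes; at 24 tips this plug-in step is visible as
  slight miscalibration in the covariate-fixed mode (measured, small, and
  reported by the calibration tests for the default mode).
* Tree uncertainty is propagated only by analyzing ensembles of fixed
  trees; no joint inference over tree and trait models.
* The likelihood machinery scores fixed topologies; it does not search
  tree space.
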