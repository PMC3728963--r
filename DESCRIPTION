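Package: finphylo
Title: Comparative Phylogenetics of Benthic/Limnetic Pectoral Fin Divergence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Comparative-methods toolkit for testing habitat-associated trait
    divergence on phylogenies, built around the pectoral fin musculature of
    Lake Malawi cichlid fishes. Implements Felsenstein's phylogenetic
    independent contrasts with through-origin correlations and Holm
    family-wise adjustment, phylogenetic generalized least-squares size
    correction, Brownian-motion rate estimation and seeded multivariate
    simulation, a simulation-based phylogenetic analysis of covariance for a
    categorical habitat effect with a size covariate, equal-rates Mk
    likelihood with Lewis's variable-sites (Mkv) correction, marginal
    ancestral-state reconstruction, Fitch minimum-change counting, ternary
    0/1/2 coding of biallelic SNP genotypes, and generators for synthetic
    Yule trees, trait tables and SNP matrices with known ground truth.
    Ships the 24-species morphometric table (standard length, eight pectoral
    muscle masses, fin area, habitat) used throughout as a worked fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, phangorn, stats, utils
Suggests: testthat (>= 3.0.0), phytools, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
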