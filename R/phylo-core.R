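# Tree data model and I/O. Trees are ape "phylo" objects throughout; every
# entry point validates and, where needed, binarizes with zero-length edges.

#' Validate a phylogeny
#'
#' Checks the structural invariants every analysis in the package relies on:
#' the tree is rooted, has branch lengths, all branch lengths are >= 0, and
#' tip labels are unique and non-empty.
#'
#' @param tree an [ape::phylo] object.
#' @param require_binary if `TRUE`, additionally require every internal node
#'   to have exactly two children.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylo <- function(tree, require_binary = FALSE) {
  if (!inherits(tree, "phylo"))
    stop("expected a 'phylo' object, got ", paste(class(tree), collapse = "/"))
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2L)
    stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label)))
    stop("empty tip labels are not allowed")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths on all non-root edges")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must all be >= 0 and non-missing")
  if (require_binary && !ape::is.binary(tree))
    stop("tree must be binary (resolve polytomies first, see parse_newick)")
  invisible(tree)
}

#' Parse a Newick string into a rooted binary phylogeny
#'
#' Polytomies are resolved deterministically (sequential grouping) into
#' zero-length internal edges, which leaves the phylogenetic covariance
#' structure unchanged. Trees are treated as rooted as written; no
#' re-rooting is performed.
#'
#' @param text a single Newick string (branch lengths required on all
#'   non-root edges; internal labels tolerated and preserved).
#' @return a rooted, binary [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unbalanced ')' at position ", i)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at position ", length(chars))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree))
    stop("malformed Newick: could not parse tree from string")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  validate_phylo(tree, require_binary = TRUE)
}

#' Serialize a phylogeny to Newick
#'
#' Round-trips through [parse_newick()]: topology, labels and branch lengths
#' are preserved (up to numeric formatting).
#'
#' @param tree an [ape::phylo] object.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  validate_phylo(tree)
  ape::write.tree(tree, digits = 12)
}

#' Phylogenetic covariance matrix
#'
#' Under Brownian motion the covariance of two tips equals the summed branch
#' length from the root to their most recent common ancestor; the diagonal
#' holds root-to-tip depths. This matrix is the error covariance used by the
#' GLS size correction and the target of the BM simulator.
#'
#' @param tree an [ape::phylo] object.
#' @return a symmetric positive semi-definite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  validate_phylo(tree)
  ape::vcv.phylo(tree)
}

#' Prune a phylogeny to a subset of tips
#'
#' Degree-2 internal nodes left by the pruning are collapsed with their
#' branch lengths summed, so pairwise path lengths among retained tips are
#' unchanged.
#'
#' @param tree an [ape::phylo] object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned [ape::phylo].
#' @export
prune_to <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip name(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L)
    stop("need at least 2 tips to retain, got ", length(keep))
  ape::keep.tip(tree, keep)
}

#' Bundle trees sharing a tip set into an ensemble
#'
#' An ensemble stands in for a posterior sample of phylogenetic hypotheses
#' (e.g. the trees retained from a Bayesian analysis of one data partition);
#' downstream statistics are computed per tree and summarized as
#' mean +/- standard error across the ensemble.
#'
#' @param trees a list of [ape::phylo] objects or an [ape::multiPhylo].
#' @param source_label short label for the data set the trees came from
#'   (e.g. `"mitochondrial"`, `"SNP"`, `"concatenated"`).
#' @return an object of class `tree_ensemble` (a `multiPhylo` with a
#'   `source_label` attribute).
#' @export
tree_ensemble <- function(trees, source_label = "trees") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("ensemble must contain at least one tree")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_phylo(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " does not share the ensemble tip set")
  }
  structure(trees, class = c("tree_ensemble", "multiPhylo"),
            source_label = source_label)
}

#' Read a tree ensemble from disk
#'
#' Accepts either a single file with one Newick string per line, or a
#' directory of `.nwk` files.
#'
#' @param path file or directory path.
#' @param source_label passed to [tree_ensemble()]; defaults to the file name.
#' @return a `tree_ensemble`.
#' @export
read_tree_ensemble <- function(path, source_label = basename(path)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nwk$", full.names = TRUE))
    if (!length(files)) stop("no .nwk files found in ", path)
    lines <- unlist(lapply(files, readLines))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no Newick strings found in ", path)
  tree_ensemble(lapply(lines, parse_newick), source_label = source_label)
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Tree ensemble '%s': %d trees, %d tips\n",
              attr(x, "source_label"), length(x), length(x[[1]]$tip.label)))
  invisible(x)
}
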