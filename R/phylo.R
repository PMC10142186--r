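# Trees: reading posterior samples, MCC selection, pruning, BM covariance.

.normalize_tips <- function(tree) {
  tree$tip.label <- gsub("_", " ", tree$tip.label)
  tree
}

#' Read a sample of trees from a Newick or Nexus file
#'
#' Detects the format from the file content (`#NEXUS` header). Tip labels are
#' normalized (underscores to spaces) so they match species names in the data
#' tables. All trees must share a single tip set; trees must be rooted and
#' carry branch lengths. Ultrametricity is checked with a relative tolerance
#' of 1e-3 and violations produce a warning, not an error (dated posteriors
#' can carry rounding noise).
#'
#' @param path Path to a Newick (one or more trees) or Nexus file.
#' @return A `multiPhylo` tree sample (possibly of length 1).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  is_nexus <- any(grepl("^\\s*#NEXUS", head_lines, ignore.case = TRUE))
  trees <- if (is_nexus) ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  trees <- lapply(trees, .normalize_tips)
  class(trees) <- "multiPhylo"
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length))
      stop("tree ", i, " has no branch lengths")
    if (!ape::is.rooted(tr))
      stop("tree ", i, " is unrooted; dated posterior trees must be rooted")
    if (anyDuplicated(tr$tip.label))
      stop("tree ", i, " has duplicate tip labels")
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)[-1]) {
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      diff <- c(setdiff(ref, tips), setdiff(tips, ref))
      stop("trees 1 and ", i, " differ in tip sets: ",
           paste(diff, collapse = ", "))
    }
  }
  if (!ape::is.ultrametric(trees[[1]], tol = 1e-3, option = 2))
    warning("tree(s) not ultrametric within relative tolerance 1e-3")
  trees
}

# Canonical string keys for the non-trivial clades of one rooted tree.
.clade_keys <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  keys <- vapply(parts, function(ix) {
    paste(sort(labs[ix]), collapse = "\r")
  }, "")
  sizes <- lengths(parts)
  unique(keys[sizes > 1L & sizes < n])  # drop root clade and (absent) singletons
}

#' Maximum clade credibility tree of a sample
#'
#' Scores every tree in the sample by the sum over its internal (non-trivial)
#' clades of the log of that clade's frequency in the sample, and returns the
#' highest-scoring tree with its own branch lengths (no averaging). This is
#' the standard maxCladeCred criterion: maximizing the product of clade
#' credibilities. Ties are broken by first occurrence in file order.
#'
#' @param sample A `multiPhylo` sample sharing one tip set (see
#'   [read_trees()]).
#' @return List with `tree` (the selected `phylo`) and `score` (sum of log
#'   clade credibilities; 0 when every clade appears in every tree).
#' @export
mcc_tree <- function(sample) {
  if (inherits(sample, "phylo")) sample <- c(sample)
  n_trees <- length(sample)
  if (n_trees == 0L) stop("empty tree sample")
  per_tree <- lapply(sample, .clade_keys)
  freq <- table(unlist(per_tree, use.names = FALSE)) / n_trees
  scores <- vapply(per_tree, function(k) sum(log(freq[k])), 1.0)
  best <- which.max(scores)  # which.max returns the first maximum
  list(tree = sample[[best]], score = unname(scores[best]),
       index = best, scores = unname(scores))
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on the requested tips: pairwise path lengths
#' between retained tips are preserved and degree-2 nodes are collapsed with
#' branch lengths summed.
#'
#' @param tree A rooted `phylo`.
#' @param taxa Character vector of tip labels to keep (must all be present).
#' @return The pruned `phylo`. When the retained tips' MRCA lies below the
#'   original root, the root-to-MRCA path is kept as `$root.edge`, so
#'   root-to-tip depths (and hence the BM covariance) are preserved, not just
#'   tip-to-tip path lengths.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxon set")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop) == 0L) return(tree)
  pr <- ape::keep.tip(tree, taxa)
  # keep.tip reroots at the kept tips' MRCA; restore the dropped root-to-MRCA
  # path as a root edge so root-to-tip depths are preserved
  ref <- taxa[1]
  d_old <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  d_new <- ape::node.depth.edgelength(pr)[match(ref, pr$tip.label)]
  re <- d_old - d_new +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (re > 1e-12) pr$root.edge <- re
  pr
}

#' Brownian-motion covariance matrix of a tree
#'
#' Builds the phylogenetic covariance matrix C with `C[i, j]` equal to the
#' shared branch length from the root to the most recent common ancestor of
#' tips i and j (so `C[i, i]` is the root-to-tip distance). Under Brownian
#' motion with rate `sigma2`, trait covariance among tips is `sigma2 * C`.
#'
#' @param tree A rooted `phylo` with nonnegative branch lengths.
#' @return Object of class `phylo_covariance`: list with `taxa` (tip order)
#'   and `C` (symmetric PSD matrix with dimnames).
#' @export
bm_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  C <- ape::vcv(tree)
  # a root edge is history shared by every tip pair
  if (!is.null(tree$root.edge) && isTRUE(tree$root.edge > 0))
    C <- C + tree$root.edge
  structure(list(taxa = rownames(C), C = C), class = "phylo_covariance")
}

#' @export
print.phylo_covariance <- function(x, ...) {
  cat(sprintf("<phylo_covariance> %d taxa, depth range [%.4g, %.4g]\n",
              length(x$taxa), min(diag(x$C)), max(diag(x$C))))
  invisible(x)
}
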