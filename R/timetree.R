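#' Time-calibrated trees with fossil tips
#'
#' A `timeTree` wraps an [ape::phylo] object together with node ages measured
#' backward from the present (youngest tip = 0, in Myr for typical inputs).
#' Tips whose age exceeds a small tolerance are flagged as fossils; tips at
#' (numerically) zero age are extant. Degree-2 internal nodes are accepted and
#' interpreted as sampled ancestors: fossils that lie directly on a branch.
#'
#' @param phy an object of class `phylo` with branch lengths; must be rooted
#'   and binary (degree-2 "sampled ancestor" nodes are allowed,
#'   multifurcations are not).
#' @return an object of class `timeTree`: a list with elements `phy`, `age`
#'   (numeric, one entry per node, time before present), `height` (root age),
#'   `extant` (logical per tip), `N` (tip count) and `epsAge` (the
#'   extant/fossil tolerance, `1e-6 * height`).
#' @details Ages are computed by root-to-tip accumulation of branch lengths,
#'   so any calibration offset in the input is irrelevant: only branch lengths
#'   matter. The extant/fossil split uses a relative tolerance because
#'   posterior tree samples carry floating-point jitter at the present.
#' @examples
#' tr <- readTimeTree(text = "((A:1,B:0.4):1,C:2);")
#' tr$age        # B is a fossil tip at age 0.6
#' isFossilTip(tr)
#' @seealso [readTimeTree()], [postorderNodes()], [cladeNodes()]
#' @export
timeTree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0)) stop("tree has negative branch lengths")
  n <- length(phy$tip.label)
  if (n < 1L) stop("tree has no tips")
  if (any(!nzchar(phy$tip.label))) stop("tip labels must be non-empty")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  # reject multifurcations; allow degree-2 (sampled-ancestor) nodes
  nchild <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  if (any(nchild > 2L)) stop("multifurcating trees are not supported")
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(n)])
  age <- height - depth
  eps <- 1e-6 * max(height, .Machine$double.eps)
  extant <- age[seq_len(n)] <= eps
  structure(
    list(phy = phy, age = age, height = height, extant = extant,
         N = n, epsAge = eps),
    class = "timeTree")
}

#' Read time-calibrated trees from Newick
#'
#' `readTimeTree()` reads a single Newick tree; `readTimeTrees()` reads a
#' multi-tree file (one Newick string per line, e.g. a posterior tree sample)
#' and returns a list of `timeTree` objects.
#'
#' @param file path to a Newick file.
#' @param text a Newick string, as an alternative to `file`.
#' @return a `timeTree`, or for `readTimeTrees()` a list of them.
#' @export
readTimeTree <- function(file = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) stop("input contains multiple trees; use readTimeTrees()")
  timeTree(phy)
}

#' @rdname readTimeTree
#' @export
readTimeTrees <- function(file = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "phylo")) phy <- structure(list(phy), class = "multiPhylo")
  lapply(unclass(phy), timeTree)
}

#' Write a time tree to Newick
#'
#' @param tree a `timeTree`.
#' @param file output path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths (default 12, enough
#'   for lossless round trips at typical Myr scales).
#' @export
writeTimeTree <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "timeTree"))
  s <- ape::write.tree(tree$phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @export
print.timeTree <- function(x, ...) {
  nf <- sum(!x$extant)
  cat(sprintf(
    "timeTree: %d tips (%d extant, %d fossil), %d internal nodes, root age %.4g\n",
    x$N, sum(x$extant), nf, x$phy$Nnode, x$height))
  invisible(x)
}

rootNode <- function(tree) tree$N + 1L

nNodesTotal <- function(tree) tree$N + tree$phy$Nnode

#' Parent and branch-length lookups
#'
#' `parentOf()` returns, for every node, the index of its parent (`NA` at the
#' root); `branchLengthTo()` the length of the branch subtending each node
#' (`NA` at the root); `childrenOf()` a list of children indices per node.
#'
#' @param tree a `timeTree`.
#' @return vectors/lists indexed like the nodes of `tree$phy` (tips first).
#' @export
parentOf <- function(tree) {
  m <- nNodesTotal(tree)
  p <- rep(NA_integer_, m)
  p[tree$phy$edge[, 2]] <- tree$phy$edge[, 1]
  p
}

#' @rdname parentOf
#' @export
branchLengthTo <- function(tree) {
  m <- nNodesTotal(tree)
  b <- rep(NA_real_, m)
  b[tree$phy$edge[, 2]] <- tree$phy$edge.length
  b
}

#' @rdname parentOf
#' @export
childrenOf <- function(tree) {
  m <- nNodesTotal(tree)
  ch <- vector("list", m)
  e <- tree$phy$edge
  for (i in seq_len(nrow(e))) ch[[e[i, 1]]] <- c(ch[[e[i, 1]]], e[i, 2])
  ch
}

#' Fossil status of tips
#'
#' @param tree a `timeTree`.
#' @return logical vector over tips, `TRUE` for fossil (non-contemporaneous)
#'   tips.
#' @export
isFossilTip <- function(tree) !tree$extant

#' Nodes in child-before-parent order
#'
#' Returns node indices ordered so that every child precedes its parent; the
#' last element is the root. This is the traversal order used by the
#' likelihood and by the Gibbs sweep over ancestral states.
#'
#' @param tree a `timeTree`.
#' @return integer vector of length equal to the number of nodes.
#' @export
postorderNodes <- function(tree) {
  e <- ape::reorder.phylo(tree$phy, "postorder")
  c(e$edge[, 2], rootNode(tree))
}

#' Clade membership
#'
#' The node itself plus all of its descendants (the set of nodes that inherit
#' a rate/trend shift anchored at `node`).
#'
#' @param tree a `timeTree`.
#' @param node a node index (tip or internal).
#' @return integer vector of node indices.
#' @export
cladeNodes <- function(tree, node) {
  m <- nNodesTotal(tree)
  if (node < 1L || node > m) stop("node ", node, " not in tree")
  if (node <= tree$N) return(as.integer(node))
  desc <- phangorn::Descendants(tree$phy, node, type = "all")
  sort(c(as.integer(node), as.integer(desc)))
}
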