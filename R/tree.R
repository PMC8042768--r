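# Rooted-tree input and the postorder/generation bookkeeping used by the
# likelihood engine and the branch-length optimizer.

#' Read and validate a rooted phylogeny
#'
#' Reads a Newick tree and checks that it is rooted, strictly binary, and has
#' branch lengths.  Only fixed topologies are analyzed, so an unrooted
#' (basally trifurcating) tree is rejected with advice to root it — because
#' the SelON process is non-reversible the root placement matters, and an
#' outgroup is recommended to absorb root-adjacent identifiability issues.
#' Missing branch lengths default to 0.05 with a warning.
#'
#' @param path Path to a Newick file (or a Newick string containing `";"`).
#' @return An `ape` `phylo` object, rooted and binary.
#' @export
read_tree <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse Newick input: ", path)
  validate_tree(tree)
}

#' Validate a phylo object for SelON analysis
#'
#' @param tree An `ape` `phylo` object.
#' @param taxa Optional character vector that the tip labels must match
#'   exactly (as a set).
#' @return The tree (postorder, lengths filled in), invisibly checked.
#' @export
validate_tree <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted: please supply a rooted topology ",
         "(including an outgroup is recommended)")
  if (!ape::is.binary(tree))
    stop("tree contains polytomies: please resolve to a binary topology ",
         "(including an outgroup is recommended)")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting every branch to 0.05")
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, tree$tip.label)
    extra <- setdiff(tree$tip.label, taxa)
    if (length(miss) || length(extra))
      stop("tree/alignment taxon mismatch; missing from tree: ",
           paste(miss, collapse = ", "), "; extra in tree: ",
           paste(extra, collapse = ", "))
  }
  tree
}

# ---------------------------------------------------------------------------
# internal: postorder edge structures for the compiled engine
.tree_data <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  edge <- tree$edge
  root <- n_tip + 1L
  # node height in edges above the tips: tips 0, parents max(child) + 1
  height <- integer(n_nodes)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    height[p] <- max(height[p], height[ch] + 1L)
  }
  gen <- height[edge[, 2]]  # branch generation = height of its child node
  sweep_order <- order(gen, seq_len(nrow(edge))) - 1L  # 0-based for C++
  list(tree = tree, edge = edge, lengths = tree$edge.length, n_tip = n_tip,
       n_nodes = n_nodes, root = root, generation = gen,
       sweep_order = sweep_order)
}

# internal: total branch length of the ingroup subtree (all edges below the
# ingroup MRCA), used when an outgroup absorbs root-adjacent branches
.ingroup_tree_length <- function(tree, outgroup) {
  ingroup <- setdiff(tree$tip.label, outgroup)
  mrca <- ape::getMRCA(tree, ingroup)
  desc <- .descendant_edges(tree, mrca)
  sum(tree$edge.length[desc])
}

.descendant_edges <- function(tree, node) {
  edge <- tree$edge
  keep <- logical(nrow(edge))
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- which(edge[, 1] == nd)
    keep[ch] <- TRUE
    stack <- c(stack, edge[ch, 2])
  }
  keep
}
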